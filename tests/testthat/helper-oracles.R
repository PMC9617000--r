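# Independent oracles used across the suite. None of these share code with
# the package implementations they check.

# Brute-force ROI rule: threshold strictly above z_thr, 26-connected
# components via igraph, largest component (ties: smallest member index),
# then the inclusive type-7 percentile rule on z within it.
oracle_roi <- function(z, z_thr = 3.1, pct = 90) {
  d <- dim(z)
  idx <- which(z > z_thr)
  roi <- array(FALSE, d)
  if (length(idx) == 0) return(roi)
  coord <- arrayInd(idx, d)
  edges <- integer(0)
  if (length(idx) > 1) {
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (b <= a) next
        if (all(abs(coord[a, ] - coord[b, ]) <= 1)) {
          edges <- c(edges, a, b)
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  sizes <- table(memb)
  maxsize <- max(sizes)
  cand <- as.integer(names(sizes)[sizes == maxsize])
  seed_of <- vapply(cand, function(cc) min(idx[memb == cc]), numeric(1))
  win <- cand[which.min(seed_of)]
  members <- idx[memb == win]
  vals <- z[members]
  thr <- quantile(vals, pct / 100, type = 7, names = FALSE)
  roi[members[vals >= thr]] <- TRUE
  roi
}

# Hand-rolled Benjamini-Hochberg step-up adjusted p values.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  sorted <- p[o] * n / seq_len(n)
  # enforce monotonicity from the largest rank down
  for (i in seq(n, 1)) {
    adj[i] <- if (i == n) sorted[i] else min(sorted[i], adj[i + 1])
  }
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Small random z map with a couple of planted blobs so components exist.
random_zmap <- function(d = c(10, 10, 4), n_blobs = 2) {
  z <- array(rnorm(prod(d), 0, 1.2), d)
  for (b in seq_len(n_blobs)) {
    cx <- sample(2:(d[1] - 1), 1); cy <- sample(2:(d[2] - 1), 1)
    cz <- sample(seq_len(d[3]), 1)
    w <- sample(1:2, 1)
    xs <- max(1, cx - w):min(d[1], cx + w)
    ys <- max(1, cy - w):min(d[2], cy + w)
    z[xs, ys, cz] <- z[xs, ys, cz] + runif(1, 2.5, 5)
  }
  z
}

# Wrap a single-voxel series into the volume-series container the
# preprocessing pipeline expects.
as_vol_series <- function(y, time) {
  structure(
    list(data = array(y, c(1, 1, 1, length(y))), time = time,
         geometry = acq_geometry(c(1, 1, 1)), paradigm = block_paradigm()),
    class = "nv_vol_series")
}

fig2_truth <- function() {
  list(true_dcbf_bh = 29.2, true_dcmro2_bh = 5.1,
       true_svo2 = 0.62, sao2 = 0.98, hgb = 9.3)
}
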