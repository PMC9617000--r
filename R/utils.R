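#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef dnorm lm median na.omit p.adjust pgamma pnorm pt
#'   qnorm quantile rbinom rnorm sd setNames var
#' @importFrom rlang .data %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance augment
#' @importFrom ggplot2 autoplot
NULL

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a child seed for one subject and modality
#'
#' A single run seed fans out deterministically to per-subject, per-modality
#' seeds so that adding a modality or reordering subjects never changes the
#' draws of another stage. The rule is a fixed affine hash modulo 2^31 - 1.
#'
#' @param seed Integer run seed.
#' @param subject Integer subject index (1-based).
#' @param modality Character modality label (e.g. `"pcasl"`, `"bh"`).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(1, 3, "pcasl")
child_seed <- function(seed, subject, modality) {
  stopifnot(is.numeric(seed), is.numeric(subject))
  m <- sum(utf8ToInt(as.character(modality)) * seq_along(utf8ToInt(as.character(modality))))
  val <- (as.double(seed) * 48271 + as.double(subject) * 100003 + m * 7919) %% 2147483646
  as.integer(val) + 1L
}

# 1D Gaussian smoothing matrix with reflective boundaries; rows sum to 1.
# sigma in voxel units; kernel truncated at ceiling(3*sigma).
gaussian_smooth_matrix <- function(n, sigma) {
  if (sigma <= 0 || n == 1L) return(diag(n))
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (off in -r:r) {
      j <- i + off
      # reflect indices off the edges (mirror without repeating the edge sample
      # twice would need j = 2 - j; classic half-sample reflection used here)
      while (j < 1L || j > n) {
        if (j < 1L) j <- 2L - j
        if (j > n) j <- 2L * n - j
      }
      K[i, j] <- K[i, j] + k[off + r + 1L]
    }
  }
  K
}

# Apply separable per-axis smoothing matrices to a 3D array.
smooth_volume <- function(vol, K1, K2, K3) {
  d <- dim(vol)
  m <- K1 %*% matrix(vol, d[1], d[2] * d[3])
  vol <- array(m, d)
  vol <- aperm(vol, c(2, 1, 3))
  m <- K2 %*% matrix(vol, d[2], d[1] * d[3])
  vol <- aperm(array(m, c(d[2], d[1], d[3])), c(2, 1, 3))
  if (d[3] > 1L) {
    vol <- aperm(vol, c(3, 1, 2))
    m <- K3 %*% matrix(vol, d[3], d[1] * d[2])
    vol <- aperm(array(m, c(d[3], d[1], d[2])), c(2, 3, 1))
  }
  vol
}

# Gaussian-weighted running-line detrending operator.
# Returns the n x n matrix F such that F %*% y is the high-pass filtered,
# mean-centred series: y minus a locally (Gaussian-weighted) fitted straight
# line, with sigma = cutoff / 2 seconds, then centred.
highpass_matrix <- function(time, cutoff) {
  n <- length(time)
  stopifnot(n >= 3, cutoff > 0)
  dt <- median(diff(time))
  if (cutoff <= 2 * dt) {
    abort("highpass cutoff must exceed twice the sampling interval")
  }
  sigma <- cutoff / 2
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w <- dnorm(time - time[i], sd = sigma)
    x <- time - time[i]
    sw <- sum(w); swx <- sum(w * x); swxx <- sum(w * x * x)
    swy_row <- w            # coefficients multiplying y for sum(w*y)
    swxy_row <- w * x       # for sum(w*x*y)
    det <- sw * swxx - swx^2
    # local fit value at x = 0 is intercept of the weighted line
    L[i, ] <- (swxx * swy_row - swx * swxy_row) / det
  }
  Fm <- diag(n) - L
  C <- diag(n) - matrix(1 / n, n, n)
  C %*% Fm
}

# Label 26-connected components of a logical 3D array.
# Returns an integer array of the same shape; 0 = background. Components are
# numbered in order of their smallest linear voxel index.
label_components_26 <- function(mask) {
  d <- dim(mask)
  if (is.null(d)) d <- c(length(mask), 1L, 1L)
  mask <- array(as.logical(mask), d)
  lab <- array(0L, d)
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
  current <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    current <- current + 1L
    queue <- start
    lab[start] <- current
    while (length(queue) > 0L) {
      v <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      z <- (v - 1L) %/% (d[1] * d[2])
      rem <- (v - 1L) %% (d[1] * d[2])
      y <- rem %/% d[1]
      x <- rem %% d[1]
      xs <- x + 1L + nb[, 1]; ys <- y + 1L + nb[, 2]; zs <- z + 1L + nb[, 3]
      ok <- xs >= 1L & xs <= d[1] & ys >= 1L & ys <= d[2] & zs >= 1L & zs <= d[3]
      lin <- xs[ok] + (ys[ok] - 1L) * d[1] + (zs[ok] - 1L) * d[1] * d[2]
      lin <- lin[mask[lin] & lab[lin] == 0L]
      if (length(lin)) {
        lab[lin] <- current
        queue <- c(queue, lin)
      }
    }
  }
  lab
}

# Map a t statistic with (possibly fractional) df to a z score by matching
# tail probabilities, capped at +/- zmax for numerically perfect fits.
t_to_z <- function(t, df, zmax = 40) {
  z <- numeric(length(t))
  pos <- !is.na(t) & t >= 0
  lp <- pt(t[pos], df, lower.tail = FALSE, log.p = TRUE)
  z[pos] <- qnorm(lp, lower.tail = FALSE, log.p = TRUE)
  ln <- pt(t[!pos & !is.na(t)], df, lower.tail = TRUE, log.p = TRUE)
  z[!pos & !is.na(t)] <- -qnorm(ln, lower.tail = FALSE, log.p = TRUE)
  z[is.na(t)] <- NA_real_
  pmin(pmax(z, -zmax), zmax)
}
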