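#' Perfusion-weighted (CBF) series from a dual-echo ASL acquisition
#'
#' Subtracts each label volume from its paired non-labelled control volume
#' (echo 1), yielding one perfusion-weighted volume per pair, time-stamped at
#' the pair midpoint.
#'
#' @param series An `nv_asl_series`.
#' @return An `nv_vol_series`: list with `data` (4D array, one volume per
#'   pair), `time` (s), `geometry`, `paradigm`.
#' @export
#' @examples
#' s <- generate_pcasl_series(acq_geometry(c(6, 6, 2), n_dynamics = 10),
#'                            block_paradigm(segment_duration = 9),
#'                            truth = list(true_dcbf_visact = 0,
#'                                         true_dbold_visact = 0),
#'                            noise_sd = 0)
#' dim(compute_cbf_series(s)$data)[4]  # 10
compute_cbf_series <- function(series) {
  stopifnot(inherits(series, "nv_asl_series"))
  n_vol <- dim(series$echo1)[4]
  if (n_vol %% 2L != 0L) abort("odd volume count: label/control pairing impossible")
  fl <- series$flags
  if (any(fl[seq(1, n_vol, 2)] == fl[seq(2, n_vol, 2)]) ||
      length(unique(fl)) != 2L) {
    abort("label/control flags must strictly alternate")
  }
  ctrl <- which(fl == "control")
  lab <- which(fl == "label")
  d <- dim(series$echo1)[1:3]
  n_pair <- n_vol %/% 2L
  cbf <- series$echo1[, , , ctrl, drop = FALSE] - series$echo1[, , , lab, drop = FALSE]
  tmid <- (series$time[ctrl] + series$time[lab]) / 2
  structure(
    list(data = array(cbf, c(d, n_pair)), time = tmid,
         geometry = series$geometry, paradigm = series$paradigm),
    class = "nv_vol_series"
  )
}

#' BOLD-weighted series from a dual-echo ASL acquisition
#'
#' Extracts the non-labelled (control) volumes of the second echo, which carry
#' the T2*-weighted BOLD contrast.
#'
#' @inheritParams compute_cbf_series
#' @return An `nv_vol_series` of the control echo-2 volumes.
#' @export
asl_bold_series <- function(series) {
  stopifnot(inherits(series, "nv_asl_series"))
  ctrl <- which(series$flags == "control")
  d <- dim(series$echo2)[1:3]
  structure(
    list(data = array(series$echo2[, , , ctrl, drop = FALSE], c(d, length(ctrl))),
         time = series$time[ctrl],
         geometry = series$geometry, paradigm = series$paradigm),
    class = "nv_vol_series"
  )
}

#' Preprocess a volume time series
#'
#' Spatial Gaussian smoothing (FWHM in mm converted per axis by voxel size,
#' reflective boundaries) followed by temporal high-pass filtering
#' (Gaussian-weighted running-line detrending, sigma = cutoff/2) with each
#' voxel's filtered series mean-centred. The smoothed-but-unfiltered series
#' and the filter operator are retained so downstream model fitting can scale
#' responses into percent and propagate the filter into the design and the
#' noise covariance.
#'
#' @param series An `nv_vol_series`.
#' @param smoothing_fwhm Spatial full width at half maximum, mm (0 disables).
#' @param highpass_cutoff High-pass cutoff (full period), seconds; must
#'   exceed twice the sampling interval.
#' @return An `nv_prep_series`: `filtered` and `smoothed` 4D arrays, `time`,
#'   filter matrix `F`, `geometry`, `paradigm`.
#' @export
preprocess <- function(series, smoothing_fwhm = 5, highpass_cutoff = 90) {
  stopifnot(inherits(series, "nv_vol_series"))
  d <- dim(series$data)[1:3]
  n_t <- dim(series$data)[4]
  sig <- smoothing_fwhm / (2 * sqrt(2 * log(2))) / series$geometry$voxel_size
  K1 <- gaussian_smooth_matrix(d[1], sig[1])
  K2 <- gaussian_smooth_matrix(d[2], sig[2])
  K3 <- gaussian_smooth_matrix(d[3], sig[3])
  sm <- series$data
  if (smoothing_fwhm > 0) {
    for (k in seq_len(n_t)) {
      vol <- array(series$data[, , , k, drop = FALSE], d)
      sm[, , , k] <- smooth_volume(vol, K1, K2, K3)
    }
  }
  Fm <- highpass_matrix(series$time, highpass_cutoff)
  Y <- matrix(aperm(sm, c(4, 1, 2, 3)), n_t, prod(d))
  Yf <- Fm %*% Y
  filt <- aperm(array(Yf, c(n_t, d)), c(2, 3, 4, 1))
  structure(
    list(filtered = filt, smoothed = sm, time = series$time, F = Fm,
         geometry = series$geometry, paradigm = series$paradigm),
    class = "nv_prep_series"
  )
}

#' Block-design regressor: boxcar convolved with a gamma HRF
#'
#' Convolves the unit-height stimulation boxcar with a unit-area gamma-density
#' hemodynamic response function of given mean lag and SD (shape
#' `(mean/sd)^2`, scale `sd^2/mean`), evaluated in closed form as differences
#' of gamma CDFs and sampled exactly at the requested times. A sufficiently
#' long block therefore plateaus at exactly 1.
#'
#' @param paradigm A [block_paradigm()].
#' @param time Sampling times, seconds.
#' @param hrf_mean,hrf_sd HRF mean lag and SD, seconds (defaults 6 and 3).
#' @return Numeric vector of regressor values at `time`.
#' @export
#' @examples
#' build_block_regressor(block_paradigm(), seq(0, 486, by = 9.1))
build_block_regressor <- function(paradigm, time, hrf_mean = 6, hrf_sd = 3) {
  stopifnot(inherits(paradigm, "nv_block_paradigm"))
  if (hrf_mean <= 0 || hrf_sd <= 0) abort("hrf parameters must be positive")
  if (paradigm$n_stim_blocks > 0 && max(time) < min(paradigm$onsets)) {
    abort("time axis does not cover the paradigm")
  }
  shape <- (hrf_mean / hrf_sd)^2
  scale <- hrf_sd^2 / hrf_mean
  x <- numeric(length(time))
  for (b in seq_len(paradigm$n_stim_blocks)) {
    x <- x + pgamma(time - paradigm$onsets[b], shape = shape, scale = scale) -
      pgamma(time - paradigm$offsets[b], shape = shape, scale = scale)
  }
  x
}

# Shared GLM engine. Y: n_t x V matrix of raw (smoothed, unfiltered) series;
# x: raw regressor. Filters both sides with Fm, scales each series into % of
# its rest-baseline mean, and returns slope (%), t, z and two-sided p with
# the filter-aware (Worsley-Friston/Satterthwaite) effective df.
glm_engine <- function(Y, x, Fm, time) {
  n_t <- nrow(Y)
  stopifnot(length(x) == n_t)
  # rest-baseline per voxel: the value at regressor = 0 of the raw
  # two-column fit, i.e. the series level with the modelled response removed
  sxx <- sum((x - mean(x))^2)
  if (sxx > 0) {
    slope_raw <- as.numeric(crossprod(x - mean(x), Y)) / sxx
    b0 <- colMeans(Y) - slope_raw * mean(x)
  } else {
    b0 <- colMeans(Y)
  }
  xf <- as.numeric(Fm %*% x)
  X <- cbind(1, xf)
  XtXi <- solve(crossprod(X))
  H <- X %*% XtXi %*% t(X)
  Rm <- diag(n_t) - H
  V <- Fm %*% t(Fm)
  RV <- Rm %*% V
  tr_rv <- sum(diag(RV))
  df_eff <- tr_rv^2 / sum(RV * t(RV))
  A <- XtXi %*% t(X) %*% V %*% X %*% XtXi
  a22 <- A[2, 2]
  Yf <- Fm %*% Y
  ok <- abs(b0) > 1e-8 * max(abs(b0), 1)
  P <- sweep(Yf, 2, ifelse(ok, b0, 1), "/") * 100
  B <- XtXi %*% t(X) %*% P
  slope <- B[2, ]
  res <- P - X %*% B
  rss <- colSums(res^2)
  # numerically perfect fits: residuals at rounding level count as zero
  rss[rss < 1e-18 * colSums(P * P)] <- 0
  sigma2 <- rss / tr_rv
  tstat <- slope / sqrt(pmax(sigma2 * a22, .Machine$double.xmin))
  tstat[sigma2 <= 0 & slope != 0] <- sign(slope[sigma2 <= 0 & slope != 0]) * Inf
  flagged <- !ok | (rss <= 0 & slope == 0)
  slope[!ok] <- 0
  tstat[flagged] <- 0
  z <- t_to_z(tstat, df_eff)
  p <- 2 * pt(abs(tstat), df_eff, lower.tail = FALSE)
  list(beta = slope, t = tstat, z = z, p = p, df = df_eff,
       flagged = flagged, baseline = b0, xf = xf)
}

#' Voxel-wise activation GLM
#'
#' Fits, per voxel, the block regressor to the preprocessed series. Each
#' voxel's series is expressed as percent of its rest-baseline mean
#' (timepoints where the regressor is below 1 % of its peak), the high-pass
#' filter is applied to both the data and the regressor, and ordinary least
#' squares on `[intercept, regressor]` gives the response in percent. The t
#' statistic uses the filter-induced noise covariance with Satterthwaite
#' effective degrees of freedom and is mapped to a z score by tail-probability
#' matching (capped at 40 for numerically perfect fits). Zero-variance voxels
#' are flagged with beta = 0, z = 0.
#'
#' @param prep An `nv_prep_series` from [preprocess()].
#' @param regressor Regressor sampled at `prep$time` (unfiltered; the filter
#'   is applied internally).
#' @return An `nv_glm`: `beta_map`, `z_map`, `t_map`, `p_map` (3D arrays),
#'   `df`, `flagged`, and the regressor.
#' @export
fit_voxelwise_glm <- function(prep, regressor) {
  stopifnot(inherits(prep, "nv_prep_series"))
  d <- dim(prep$smoothed)[1:3]
  n_t <- dim(prep$smoothed)[4]
  if (length(regressor) != n_t) abort("regressor length must match the series")
  Y <- matrix(aperm(prep$smoothed, c(4, 1, 2, 3)), n_t, prod(d))
  fit <- glm_engine(Y, regressor, prep$F, prep$time)
  structure(
    list(beta_map = array(fit$beta, d), z_map = array(fit$z, d),
         t_map = array(fit$t, d), p_map = array(fit$p, d),
         df = fit$df, flagged = array(fit$flagged, d), regressor = regressor),
    class = "nv_glm"
  )
}

#' Select the maximally activated region of interest
#'
#' Thresholds the z map (z strictly above `z_threshold`), finds the largest
#' 26-connected component (ties broken by the smallest linear voxel index),
#' and keeps the voxels at or above the component's `top_percentile`-th
#' percentile of z (linear-interpolation percentile, inclusive threshold). An
#' empty mask is a valid outcome and signals no detectable activation.
#'
#' For distinct z values the inclusive percentile rule keeps exactly
#' `m = n - ceiling((n - 1) * p + 1) + 1` of the component's `n` voxels, and
#' the selection is implemented as the top `m` voxels ranked by z. Ties --
#' which in practice arise only when z saturates at its cap for numerically
#' perfect fits on noise-free data -- are broken deterministically by the
#' effect size (`beta_map`) and then by the smaller linear voxel index, so
#' the upper decile remains the most strongly activated voxels rather than
#' ballooning to every saturated voxel.
#'
#' @param z_map 3D numeric array of z scores.
#' @param z_threshold Cluster-forming threshold (default 3.1).
#' @param top_percentile Percentile kept within the winning component
#'   (default 90, i.e. the upper decile).
#' @param beta_map Optional 3D array used as the tie-breaking secondary key.
#' @return Logical array of the ROI with attribute `cluster_size` (size of
#'   the winning component; 0 if no voxel survives the threshold).
#' @export
select_activation_roi <- function(z_map, z_threshold = 3.1, top_percentile = 90,
                                  beta_map = NULL) {
  stopifnot(is.array(z_map))
  mask <- z_map > z_threshold
  roi <- array(FALSE, dim(z_map))
  if (!any(mask)) {
    attr(roi, "cluster_size") <- 0L
    return(roi)
  }
  lab <- label_components_26(mask)
  sizes <- tabulate(lab[lab > 0L])
  win <- which.max(sizes)           # first maximal = smallest seed index
  comp <- lab == win
  idx <- which(comp)
  n <- length(idx)
  h <- (n - 1) * top_percentile / 100 + 1
  m <- n - ceiling(h - 1e-9) + 1L
  b <- if (is.null(beta_map)) numeric(n) else beta_map[comp]
  ord <- order(z_map[comp], b, -idx, decreasing = TRUE)
  roi[idx[ord[seq_len(m)]]] <- TRUE
  attr(roi, "cluster_size") <- as.integer(sizes[win])
  roi
}

#' Estimate the BOLD and CBF responses within the ROI
#'
#' The BOLD response is the mean of the voxel-wise regression coefficients
#' over the ROI. The CBF response is obtained by taking the ROI-median
#' perfusion time series, expressing it as percent of its rest baseline, and
#' fitting the same filtered block-regressor GLM; the regression coefficient
#' is the CBF change in percent and its two-sided p value gauges whether a
#' perfusion response was detected at all.
#'
#' @param beta_map Voxel-wise BOLD coefficients (% change), 3D array.
#' @param roi_mask Logical ROI array (must be nonempty).
#' @param cbf_prep Preprocessed CBF series (`nv_prep_series`).
#' @param regressor Block regressor at the CBF series' timepoints.
#' @return A list: `delta_bold` (%), `delta_cbf` (%), `p_cbf`, `z_cbf`.
#' @export
estimate_responses <- function(beta_map, roi_mask, cbf_prep, regressor) {
  if (!any(roi_mask)) abort("empty ROI: responses are undefined")
  delta_bold <- mean(beta_map[roi_mask])
  d <- dim(cbf_prep$smoothed)[1:3]
  n_t <- dim(cbf_prep$smoothed)[4]
  Y <- matrix(aperm(cbf_prep$smoothed, c(4, 1, 2, 3)), n_t, prod(d))
  med <- apply(Y[, which(roi_mask), drop = FALSE], 1, median)
  fit <- glm_engine(matrix(med, ncol = 1), regressor, cbf_prep$F, cbf_prep$time)
  list(delta_bold = delta_bold, delta_cbf = fit$beta[1],
       p_cbf = fit$p[1], z_cbf = fit$z[1])
}

#' Full single-subject activation analysis
#'
#' Chains the whole per-subject pipeline: perfusion subtraction, BOLD series
#' extraction, preprocessing, voxel-wise GLM on the BOLD series, z-threshold
#' cluster/percentile ROI selection, and ROI response estimation, recording a
#' quality-control status: `"ok"`, `"no_activation"` (empty ROI),
#' `"no_cbf_response"` (ROI-median perfusion fit not significant at
#' `p_significance`), or `"anomalous"` (CBF response above `max_response` %).
#'
#' @param series An `nv_asl_series`.
#' @param z_threshold,top_percentile ROI-selection parameters.
#' @param smoothing_fwhm,highpass_cutoff Preprocessing parameters.
#' @param hrf_mean,hrf_sd Gamma HRF moments, seconds.
#' @param max_response QC ceiling on the CBF response, percent.
#' @param p_significance Threshold on the ROI perfusion-response p value.
#' @return An `nv_activation`: `beta_map`, `z_map`, `roi_mask`,
#'   `delta_bold`, `delta_cbf`, `p_cbf`, `qc_status`, `cluster_size`.
#' @export
#' @examples
#' s <- generate_pcasl_series(acq_geometry(), block_paradigm(),
#'                            truth = list(true_dcbf_visact = 77.1,
#'                                         true_dbold_visact = 1.5),
#'                            noise_sd = 0)
#' res <- asl_activation(s)
#' c(res$delta_cbf, res$delta_bold)
asl_activation <- function(series, z_threshold = 3.1, top_percentile = 90,
                           smoothing_fwhm = 5, highpass_cutoff = 90,
                           hrf_mean = 6, hrf_sd = 3,
                           max_response = 400, p_significance = 0.05) {
  stopifnot(inherits(series, "nv_asl_series"))
  bold <- asl_bold_series(series)
  cbf <- compute_cbf_series(series)
  bold_p <- preprocess(bold, smoothing_fwhm, highpass_cutoff)
  cbf_p <- preprocess(cbf, smoothing_fwhm, highpass_cutoff)
  x_bold <- build_block_regressor(series$paradigm, bold$time, hrf_mean, hrf_sd)
  x_cbf <- build_block_regressor(series$paradigm, cbf$time, hrf_mean, hrf_sd)
  glm <- fit_voxelwise_glm(bold_p, x_bold)
  roi <- select_activation_roi(glm$z_map, z_threshold, top_percentile,
                               beta_map = glm$beta_map)
  out <- list(beta_map = glm$beta_map, z_map = glm$z_map, roi_mask = roi,
              delta_bold = NA_real_, delta_cbf = NA_real_, p_cbf = NA_real_,
              qc_status = "no_activation",
              cluster_size = attr(roi, "cluster_size"),
              params = list(z_threshold = z_threshold,
                            top_percentile = top_percentile,
                            smoothing_fwhm = smoothing_fwhm,
                            highpass_cutoff = highpass_cutoff,
                            hrf_mean = hrf_mean, hrf_sd = hrf_sd,
                            max_response = max_response))
  if (any(roi)) {
    est <- estimate_responses(glm$beta_map, roi, cbf_p, x_cbf)
    out$delta_bold <- est$delta_bold
    out$delta_cbf <- est$delta_cbf
    out$p_cbf <- est$p_cbf
    out$qc_status <- if (est$p_cbf >= p_significance) {
      "no_cbf_response"
    } else if (est$delta_cbf > max_response) {
      "anomalous"
    } else {
      "ok"
    }
  }
  structure(out, class = "nv_activation")
}

#' Quality-control filter for an activation result
#'
#' Applies the cohort inclusion rule: excluded when no activation pattern was
#' found, when the perfusion response in the activated area was not
#' statistically significant, or when the CBF response is physiologically
#' anomalous (above `max_response`, default 400 %).
#'
#' @param result An `nv_activation`.
#' @param max_response Exclusion ceiling on the CBF response, percent.
#' @return A tibble with `included` (logical) and `reason` (`"ok"`,
#'   `"no_activation"`, `"no_cbf_response"`, `"anomalous"`, or `"motion"`).
#' @export
qc_filter <- function(result, max_response = 400) {
  stopifnot(inherits(result, "nv_activation"))
  reason <- result$qc_status
  if (reason == "ok" && !is.na(result$delta_cbf) &&
      result$delta_cbf > max_response) {
    reason <- "anomalous"
  }
  tibble(included = reason == "ok", reason = reason)
}

#' @export
print.nv_activation <- function(x, ...) {
  cat(sprintf("<nv_activation> qc=%s cluster=%d dBOLD=%s%% dCBF=%s%%\n",
              x$qc_status, x$cluster_size,
              signif(x$delta_bold, 4), signif(x$delta_cbf, 4)))
  invisible(x)
}
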