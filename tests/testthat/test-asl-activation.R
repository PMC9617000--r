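truth0 <- list(true_dcbf_visact = 0, true_dbold_visact = 0)

test_that("perfusion subtraction honours the pairing contract", {
  g <- acq_geometry(c(6, 6, 2), n_dynamics = 54)
  s <- generate_pcasl_series(g, block_paradigm(), truth0, noise_sd = 0)
  cbf <- compute_cbf_series(s)
  expect_equal(dim(cbf$data)[4], 54)
  expect_equal(cbf$time[1], mean(s$time[1:2]))
  # control = label everywhere -> all-zero series
  s0 <- s
  s0$echo1 <- array(500, dim(s$echo1))
  expect_true(all(compute_cbf_series(s0)$data == 0))
  # configured perfusion signal returns exactly (round trip at a voxel)
  g2 <- acq_geometry(c(8, 8, 2), n_dynamics = 54)
  reg <- array(FALSE, c(8, 8, 2)); reg[3:6, 3:6, ] <- TRUE
  s2 <- generate_pcasl_series(g2, block_paradigm(),
                              list(true_dcbf_visact = 40,
                                   true_dbold_visact = 1),
                              noise_sd = 0, region = reg,
                              perfusion_baseline = 80)
  cbf2 <- compute_cbf_series(s2)
  pair_mid <- cbf2$time
  x <- build_block_regressor(s2$paradigm, pair_mid)
  expect_equal(as.numeric(cbf2$data[4, 4, 1, ]), 80 * (1 + 0.4 * x),
               tolerance = 1e-12)
  # contract violations
  s_odd <- s
  s_odd$echo1 <- s$echo1[, , , 1:107]
  expect_error(compute_cbf_series(s_odd), "odd")
  s_bad <- s
  s_bad$flags <- rep("control", 108)
  expect_error(compute_cbf_series(s_bad), "alternat")
})

test_that("preprocessing removes drift, keeps fast structure, respects bounds", {
  tt <- seq(0, 485, by = 4.55)
  # spatially constant volume is untouched by reflective smoothing
  g <- acq_geometry(c(6, 6, 3), n_dynamics = 4)
  const <- structure(
    list(data = array(7, c(6, 6, 3, 8)), time = (0:7) * 4.55,
         geometry = g, paradigm = block_paradigm()),
    class = "nv_vol_series")
  pc <- preprocess(const, smoothing_fwhm = 5, highpass_cutoff = 90)
  expect_equal(pc$smoothed, const$data, tolerance = 1e-12)
  # linear temporal drift is removed almost entirely
  drift <- as_vol_series(10 + 5 * tt / max(tt), tt)
  pd <- preprocess(drift, smoothing_fwhm = 0, highpass_cutoff = 90)
  expect_lt(max(abs(pd$filtered)), 0.01 * 5)
  # a 20-s sinusoid passes with its amplitude preserved within 2 %
  sine <- as_vol_series(sin(2 * pi * tt / 20), tt)
  ps <- preprocess(sine, smoothing_fwhm = 0, highpass_cutoff = 90)
  amp <- (max(ps$filtered) - min(ps$filtered)) / 2
  expect_lt(abs(amp - 1), 0.02)
  expect_error(preprocess(sine, highpass_cutoff = 9), "cutoff")
})

test_that("block regressor equals a numerical convolution oracle", {
  par <- block_paradigm()
  tt <- (0:53) * 9.1 + 4.55
  x <- build_block_regressor(par, tt, hrf_mean = 6, hrf_sd = 3)
  # oracle: discretised convolution of the boxcar with dgamma(shape 4,
  # scale 1.5) -- the moment-matched parameters worked out by hand
  tau <- seq(0, 60, by = 0.002)
  k <- dgamma(tau, shape = 4, scale = 1.5)
  box <- function(t) {
    b <- 0
    for (j in seq_len(par$n_stim_blocks)) {
      b <- b + as.numeric(t - par$onsets[j] >= 0 & t - par$offsets[j] < 0)
    }
    b
  }
  x_num <- vapply(tt, function(t) sum(box(t - tau) * k) * 0.002, numeric(1))
  expect_equal(x, x_num, tolerance = 1e-4)
  # plateau of a long block reaches exactly 1 (unit-area kernel)
  long <- block_paradigm(segment_duration = 200, n_stim_blocks = 1)
  xl <- build_block_regressor(long, seq(0, 600, by = 1))
  expect_equal(max(xl), 1, tolerance = 1e-6)
  # null paradigm -> all-zero regressor
  expect_true(all(build_block_regressor(block_paradigm(n_stim_blocks = 0),
                                        tt) == 0))
  expect_error(build_block_regressor(par, tt, hrf_mean = -1), "positive")
})

test_that("voxelwise GLM matches a hand-coded least-squares oracle", {
  # frozen 10-point worked series
  y <- c(1012.4, 995.1, 1003.7, 1021.9, 1018.2, 990.5, 1007.3, 1013.8,
         998.6, 1009.2)
  tt <- (0:9) * 9.1
  par <- block_paradigm(segment_duration = 18.2, n_stim_blocks = 2)
  x <- build_block_regressor(par, tt)
  prep <- preprocess(as_vol_series(y, tt), smoothing_fwhm = 0,
                     highpass_cutoff = 90)
  fit <- fit_voxelwise_glm(prep, x)

  # oracle: rebuild the Gaussian running-line filter and the two-column LS
  # fit from first principles
  sigma <- 45
  L <- t(vapply(tt, function(t0) {
    w <- exp(-(tt - t0)^2 / (2 * sigma^2))
    xx <- tt - t0
    det <- sum(w) * sum(w * xx^2) - sum(w * xx)^2
    (sum(w * xx^2) * w - sum(w * xx) * w * xx) / det
  }, numeric(length(tt))))
  Fm <- (diag(10) - matrix(1 / 10, 10, 10)) %*% (diag(10) - L)
  b0 <- {
    xc <- x - mean(x)
    slope <- sum(xc * y) / sum(xc^2)
    mean(y) - slope * mean(x)
  }
  P <- 100 * (Fm %*% y) / b0
  X <- cbind(1, Fm %*% x)
  beta <- solve(t(X) %*% X, t(X) %*% P)
  res <- P - X %*% beta
  V <- Fm %*% t(Fm)
  R <- diag(10) - X %*% solve(t(X) %*% X) %*% t(X)
  RV <- R %*% V
  sigma2 <- sum(res^2) / sum(diag(RV))
  A <- solve(t(X) %*% X) %*% t(X) %*% V %*% X %*% solve(t(X) %*% X)
  tstat <- beta[2] / sqrt(sigma2 * A[2, 2])
  dfe <- sum(diag(RV))^2 / sum(RV * t(RV))
  z_or <- qnorm(pt(abs(tstat), dfe, lower.tail = FALSE, log.p = TRUE),
                lower.tail = FALSE, log.p = TRUE) * sign(tstat)

  expect_equal(fit$beta_map[1, 1, 1], beta[2], tolerance = 1e-10)
  expect_equal(fit$z_map[1, 1, 1], z_or, tolerance = 1e-8)

  # exact response: beta recovered, z at the cap
  y2 <- 200 * (1 + 3 / 100 * x)
  prep2 <- preprocess(as_vol_series(y2, tt), smoothing_fwhm = 0,
                      highpass_cutoff = 90)
  fit2 <- fit_voxelwise_glm(prep2, x)
  expect_equal(fit2$beta_map[1, 1, 1], 3, tolerance = 1e-9)
  expect_equal(fit2$z_map[1, 1, 1], 40)
  # beta in % is invariant to global intensity scaling
  prep5 <- preprocess(as_vol_series(5 * y, tt), smoothing_fwhm = 0,
                      highpass_cutoff = 90)
  fit5 <- fit_voxelwise_glm(prep5, x)
  expect_equal(fit5$beta_map[1, 1, 1], fit$beta_map[1, 1, 1],
               tolerance = 1e-10)
})

test_that("null z scores are calibrated to the normal tail", {
  set.seed(31)
  tt <- (0:53) * 9.1
  x <- build_block_regressor(block_paradigm(), tt + 4.55)
  Fm <- neurovasc:::highpass_matrix(tt, 90)
  nv <- 10000
  Y <- matrix(1000 + rnorm(54 * nv, 0, 10), 54, nv)
  fit <- neurovasc:::glm_engine(Y, x, Fm, tt)
  p_exp <- pnorm(-3.1)
  band <- 3 * sqrt(p_exp * (1 - p_exp) / nv)
  expect_lt(abs(mean(fit$z > 3.1) - p_exp), band)
})

test_that("ROI selection equals the brute-force oracle on random maps", {
  library(igraph)
  set.seed(17)
  for (i in 1:100) {
    z <- random_zmap()
    got <- select_activation_roi(z)
    expect_identical(as.logical(got), as.logical(oracle_roi(z)),
                     label = sprintf("map %d", i))
  }
})

test_that("ROI rule picks the upper decile of the largest component", {
  z <- array(0, c(12, 12, 3))
  set.seed(5)
  z[2:6, 2:9, 2] <- 4 + runif(40) / 10        # 40-voxel component
  z[9:10, 9:11, c(1, 3)] <- 5 + runif(12)[1:12] / 10
  z[9:10, 9:11, 1][1] <- 0                    # trim to 10 voxels + 1 gap
  big <- array(FALSE, c(12, 12, 3)); big[2:6, 2:9, 2] <- TRUE
  roi <- select_activation_roi(z)
  expect_equal(sum(roi), 4)
  expect_true(all(big[roi]))
  # all sub-threshold -> empty mask
  expect_equal(sum(select_activation_roi(array(1, c(5, 5, 2)))), 0)
})

test_that("responses aggregate over the ROI as specified", {
  beta <- array(2, c(4, 4, 2))
  roi <- array(FALSE, c(4, 4, 2)); roi[2:3, 2:3, 1] <- TRUE
  flat <- structure(
    list(data = array(60, c(4, 4, 2, 20)), time = (0:19) * 9.1,
         geometry = acq_geometry(c(4, 4, 2)), paradigm = block_paradigm()),
    class = "nv_vol_series")
  prep <- preprocess(flat, smoothing_fwhm = 0, highpass_cutoff = 90)
  x <- build_block_regressor(block_paradigm(), flat$time)
  est <- estimate_responses(beta, roi, prep, x)
  expect_equal(est$delta_bold, 2)
  expect_error(estimate_responses(beta, array(FALSE, c(4, 4, 2)), prep, x),
               "empty ROI")
})

test_that("noise-free responses are recovered exactly across (0, 400]", {
  for (dc in c(0.5, 77.1, 250, 399)) {
    s <- generate_pcasl_series(acq_geometry(), block_paradigm(),
                               list(true_dcbf_visact = dc,
                                    true_dbold_visact = 1.5),
                               noise_sd = 0)
    r <- asl_activation(s)
    expect_equal(r$qc_status, "ok")
    expect_lt(abs(r$delta_cbf - dc), 0.5)
    expect_lt(abs(r$delta_bold - 1.5), 0.5)
  }
})

test_that("QC statuses follow the exclusion rules", {
  # anomalous response above 400 %
  s_hi <- generate_pcasl_series(acq_geometry(), block_paradigm(),
                                list(true_dcbf_visact = 450,
                                     true_dbold_visact = 1.5),
                                noise_sd = 0)
  r_hi <- asl_activation(s_hi)
  expect_equal(r_hi$qc_status, "anomalous")
  q <- qc_filter(r_hi)
  expect_false(q$included)
  expect_equal(q$reason, "anomalous")
  # BOLD activation without a perfusion response
  s_nc <- generate_pcasl_series(acq_geometry(), block_paradigm(),
                                list(true_dcbf_visact = 0,
                                     true_dbold_visact = 2),
                                noise_sd = 0)
  r_nc <- asl_activation(s_nc)
  expect_equal(r_nc$qc_status, "no_cbf_response")
  expect_false(qc_filter(r_nc)$included)
  # flat data: no activation at all
  s_0 <- generate_pcasl_series(acq_geometry(), block_paradigm(), truth0,
                               noise_sd = 0)
  r_0 <- asl_activation(s_0)
  expect_equal(r_0$qc_status, "no_activation")
  expect_equal(qc_filter(r_0)$reason, "no_activation")
  # an ordinary subject passes
  s_ok <- generate_pcasl_series(acq_geometry(), block_paradigm(),
                                list(true_dcbf_visact = 77,
                                     true_dbold_visact = 1.5),
                                noise_sd = 10, seed = 2)
  expect_true(qc_filter(asl_activation(s_ok))$included)
})

test_that("pure-noise subjects do not fabricate responses", {
  n_sub <- 24
  ok <- 0
  zs <- numeric(0)
  for (i in seq_len(n_sub)) {
    s <- generate_pcasl_series(acq_geometry(), block_paradigm(), truth0,
                               noise_sd = 10, seed = 1000 + i)
    r <- asl_activation(s)
    if (i <= 5) zs <- c(zs, as.numeric(r$z_map))
    ok <- ok + (r$qc_status == "ok")
  }
  # the ROI perfusion-significance gate holds false positives near its
  # nominal 5 % level; 6/24 is > 4 SD above that
  expect_lte(ok, 6)
  # smoothing correlates neighbours but voxelwise z stays calibrated
  expect_lt(mean(zs > 3.1), 0.004)
})
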