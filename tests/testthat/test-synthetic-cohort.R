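test_that("identical seed and config reproduce the cohort bit for bit", {
  cfg <- cohort_config(n_subjects = 6, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$cognition, b$cognition)
  ia <- subject_inputs(a, 3)
  ib <- subject_inputs(b, 3)
  expect_identical(ia$pcasl$echo1, ib$pcasl$echo1)
  expect_identical(ia$bh$data, ib$bh$data)
  expect_identical(ia$mrs$rest$intensity, ib$mrs$rest$intensity)
  c2 <- generate_cohort(cohort_config(n_subjects = 6, seed = 43))
  expect_false(identical(a$truth$true_dcbf_visact, c2$truth$true_dcbf_visact))
})

test_that("noise-free coupling limit gives an exact linear cognition score", {
  cpl <- tibble::tibble(outcome = "score", intercept = 0, slope = 2, r2 = 1)
  ch <- generate_cohort(cohort_config(n_subjects = 20, coupling = cpl, seed = 5))
  expect_equal(ch$cognition$score, 2 * ch$truth$true_dcbf_visact,
               tolerance = 1e-12)
})

test_that("cognition noise calibration recovers slope and R2 at n = 500", {
  cpl <- tibble::tibble(outcome = "ist", intercept = 100, slope = 0.112, r2 = 0.13)
  ch <- generate_cohort(cohort_config(n_subjects = 500, coupling = cpl, seed = 7))
  f <- lm(ist ~ true_dcbf_visact, data = cbind(ch$cognition, ch$truth))
  expect_lt(abs(coef(f)[2] - 0.112) / 0.112, 0.10)
  expect_lt(abs(summary(f)$r.squared - 0.13), 0.05)
})

test_that("cohort-level truth distributions converge to the configured values", {
  ch <- generate_cohort(cohort_config(n_subjects = 1000, seed = 11))
  cfg <- ch$config
  for (fld in c("dcbf_visact", "dcbf_bh", "gcbf", "hgb")) {
    col <- if (fld %in% c("gcbf")) paste0("true_", fld) else
      switch(fld, dcbf_visact = "true_dcbf_visact", dcbf_bh = "true_dcbf_bh",
             hgb = "hgb")
    sem <- cfg$sds[[fld]] / sqrt(1000)
    expect_lt(abs(mean(ch$truth[[col]]) - cfg$means[[fld]]), 3 * sem)
    expect_lt(abs(sd(ch$truth[[col]]) - cfg$sds[[fld]]),
              4 * cfg$sds[[fld]] / sqrt(2 * 999))
  }
})

test_that("pCASL generator obeys the acquisition contract", {
  g <- acq_geometry()
  s <- generate_pcasl_series(g, block_paradigm(),
                             truth = list(true_dcbf_visact = 0,
                                          true_dbold_visact = 0),
                             noise_sd = 0)
  expect_equal(dim(s$echo1)[4], 108)           # 54 label/control pairs
  expect_equal(sum(s$flags == "control"), 54)
  cbf <- compute_cbf_series(s)
  # zero response, zero noise: perfusion difference constant over time
  rng <- apply(cbf$data, 1:3, function(v) diff(range(v)))
  expect_lt(max(rng), 1e-12)
  expect_error(generate_pcasl_series(g, block_paradigm(), noise_sd = -1,
                                     truth = list(true_dcbf_visact = 0,
                                                  true_dbold_visact = 0)),
               "noise_sd")
  bad_region <- array(TRUE, c(4, 4, 4))
  expect_error(generate_pcasl_series(g, block_paradigm(), region = bad_region,
                                     truth = list(true_dcbf_visact = 0,
                                                  true_dbold_visact = 0),
                                     noise_sd = 0))
  expect_error(generate_pcasl_series(acq_geometry(n_dynamics = 5),
                                     block_paradigm(),
                                     truth = list(true_dcbf_visact = 0,
                                                  true_dbold_visact = 0),
                                     noise_sd = 0),
               "longer")
})

test_that("velocity maps render laminar vessels with the analytic flow", {
  vm <- generate_velocity_map()
  for (nm in names(vm$rois)) {
    expect_lt(abs(vessel_flow(vm, nm) / vm$analytic_flows[[nm]] - 1), 0.03)
  }
  # additivity across the three vessels
  total <- sum(vapply(names(vm$rois), function(n) vessel_flow(vm, n), 1))
  expect_lt(abs(total / sum(vm$analytic_flows) - 1), 0.03)
  # zero peak velocity -> zero flow
  v0 <- default_vessels()
  v0$vmax_cm_s <- 0
  vm0 <- generate_velocity_map(v0)
  expect_equal(vessel_flow(vm0, "basilar"), 0)
  # overlapping vessels rejected
  bad <- default_vessels()
  bad$cx_cm <- c(0, 0.1, 0.8)
  expect_error(generate_velocity_map(bad), "overlap")
  out <- default_vessels()
  out$cx_cm[1] <- 5
  expect_error(generate_velocity_map(out), "field of view")
})

test_that("oximetry phase maps invert exactly and exercise wrapping", {
  # fully oxygenated blood: no vessel/tissue contrast
  pp1 <- generate_sbo_phase_maps(1.0, noise_sd = 0)
  expect_equal(susceptibility_phase(pp1)$delta_phi, 0, tolerance = 1e-12)
  # round trip at 0.62
  pp <- generate_sbo_phase_maps(0.62, noise_sd = 0)
  sp <- susceptibility_phase(pp)
  expect_equal(svo2_from_phase(sp$delta_phi, pp$delta_te, pp$field_strength,
                               pp$calib),
               0.62, tolerance = 1e-9)
  # a background phase near +pi pushes the stored vessel phase across the
  # branch cut: values are stored wrapped into (-pi, pi] and the automated
  # 2*pi correction recovers the truth
  lo <- generate_sbo_phase_maps(0.62, noise_sd = 0, wrap = TRUE,
                                base_phase = 3.0)
  expect_true(all(lo$phase_te2 <= pi & lo$phase_te2 > -pi))
  splo <- susceptibility_phase(lo)
  expect_gt(splo$n_corrected, 0)
  expect_equal(svo2_from_phase(splo$delta_phi, lo$delta_te, lo$field_strength,
                               lo$calib),
               0.62, tolerance = 1e-9)
  expect_error(generate_sbo_phase_maps(1.2), "svo2")
})

test_that("breath-hold series follow the configured trajectories", {
  bh <- generate_breath_hold_series(breath_hold_paradigm(), fig2_truth(),
                                    flow_noise_sd = 0, svo2_noise_sd = 0)
  expect_equal(nrow(bh$data), 39)
  expect_equal(max(bh$data$time) + diff(bh$data$time)[1] / 2, 276)
  # configured peak +29.2%: max over series of flow/baseline - 1
  expect_equal(max(bh$data$flow / bh$baseline_flow - 1), 0.292,
               tolerance = 1e-12)
  flat <- generate_breath_hold_series(
    breath_hold_paradigm(),
    list(true_dcbf_bh = 0, true_dcmro2_bh = 0, true_svo2 = 0.62,
         sao2 = 0.98, hgb = 9.3),
    flow_noise_sd = 0, svo2_noise_sd = 0)
  expect_lt(diff(range(flat$data$flow)), 1e-12)
  expect_error(
    generate_breath_hold_series(breath_hold_paradigm(baseline = 200),
                                fig2_truth(), seed = 1),
    "longer")
})

test_that("spectra are linear in concentration with the stated line shapes", {
  ppm <- seq(4.2, 0.2, length.out = 1024)
  z <- generate_spectrum(c(lactate = 0, naa = 0), ppm, noise_sd = 0)
  expect_true(all(z$intensity == 0))
  s1 <- generate_spectrum(c(lactate = 1, naa = 5), ppm, noise_sd = 0)
  s2 <- generate_spectrum(c(lactate = 2, naa = 5), ppm, noise_sd = 0)
  # doubling lactate adds exactly one more unit-concentration lactate line
  lac1 <- generate_spectrum(c(lactate = 1), ppm, noise_sd = 0,
                            centers = c(lactate = 1.33))
  expect_equal(s2$intensity - s1$intensity, lac1$intensity, tolerance = 1e-12)
  # and the added line is centred on 1.33 ppm
  expect_equal(ppm[which.max(lac1$intensity)], 1.33, tolerance = 0.01)
  # doubling every concentration doubles the whole spectrum
  s4 <- generate_spectrum(c(lactate = 2, naa = 10), ppm, noise_sd = 0)
  expect_equal(s4$intensity, 2 * s1$intensity, tolerance = 1e-12)
  expect_error(generate_spectrum(c(lactate = -1, naa = 0)), "concentration")
  expect_error(generate_spectrum(c(lactate = 1, naa = 1), linewidth = 0),
               "linewidth")
})

test_that("child seeds are deterministic and spread across modalities", {
  expect_identical(child_seed(1, 2, "pcasl"), child_seed(1, 2, "pcasl"))
  seeds <- c(child_seed(1, 1, "pcasl"), child_seed(1, 2, "pcasl"),
             child_seed(1, 1, "bh"), child_seed(2, 1, "pcasl"))
  expect_equal(length(unique(seeds)), 4)
})
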