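test_that("robust fit handles exact lines and matches OLS on clean data", {
  x <- 1:20
  f <- robust_fit(x, 2 * x + 1)
  expect_equal(f$beta, 2, tolerance = 1e-8)
  expect_equal(f$r_squared, 1)
  # clean Gaussian data: robust slope within half an OLS standard error
  set.seed(12)
  for (i in 1:5) {
    xx <- rnorm(500); yy <- 1 + 0.5 * xx + rnorm(500)
    ols <- lm(yy ~ xx)
    fr <- robust_fit(xx, yy)
    expect_lt(abs(fr$beta - coef(ols)[2]),
              0.5 * summary(ols)$coefficients[2, 2])
  }
  expect_error(robust_fit(rep(1, 10), rnorm(10)), "constant")
  expect_error(robust_fit(1:2, 1:2), "3 complete pairs")
})

test_that("robust fit has bounded influence under 10 % contamination", {
  set.seed(13)
  ratios <- replicate(30, {
    x <- rnorm(100); y <- 1 + 2 * x + rnorm(100, 0, 0.5)
    b_r <- robust_fit(x, y)$beta
    b_o <- coef(lm(y ~ x))[2]
    i <- sample(100, 10)
    y[i] <- y[i] + 30
    c(abs(robust_fit(x, y)$beta - b_r), abs(coef(lm(y ~ x))[2] - b_o))
  })
  expect_lt(mean(ratios[1, ]) / mean(ratios[2, ]), 1 / 3)
  # every replicate stays within the 3x-OLS influence envelope
  expect_true(all(ratios[1, ] < pmax(3 * ratios[2, ], 0.05)))
})

test_that("robust slope p values hold their nominal size under the null", {
  set.seed(14)
  ps <- replicate(1500, robust_fit(rnorm(100), rnorm(100))$p)
  rate <- mean(ps < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 1500))
})

test_that("cohort-coupling slope is recovered across seeded replicates", {
  cpl <- tibble::tibble(outcome = "ist", intercept = 100, slope = 0.112,
                        r2 = 0.13)
  est <- vapply(1:200, function(r) {
    ch <- generate_cohort(cohort_config(n_subjects = 150, coupling = cpl,
                                        seed = 5000 + r))
    robust_fit(ch$truth$true_dcbf_visact, ch$cognition$ist)$beta
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.112) / 0.112, 0.05)
  expect_gt(mean(abs(est - 0.112) / 0.112 < 0.25), 0.6)
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04))$p_fdr, rep(0.04, 4))
  expect_equal(fdr_adjust(0.03)$p_fdr, 0.03)
  expect_false(any(fdr_adjust(rep(1, 6))$significant))
  set.seed(15)
  for (i in 1:1000) {
    p <- runif(sample(1:12, 1))
    adj <- fdr_adjust(p)$p_fdr
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    # monotone nondecreasing in rank
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(fdr_adjust(numeric(0)), "empty")
  expect_error(fdr_adjust(c(0.5, 0)), "0, 1")
})

test_that("forward stepwise selection finds informative covariates", {
  set.seed(16)
  hits <- replicate(100, {
    X <- matrix(rnorm(200 * 6), 200)
    y <- X[, 3] + rnorm(200)          # population R2 = 0.5 for X3
    d <- data.frame(y = y, X)
    s <- stepwise_select(d, "y", paste0("X", 1:6))
    length(s$selected) > 0 && s$selected[1] == "X3"
  })
  expect_gte(mean(hits), 0.95)
  # exact linear response selects exactly that covariate
  d2 <- data.frame(y = 0, X1 = rnorm(50), X2 = rnorm(50), X3 = rnorm(50))
  d2$y <- 4 - 2 * d2$X3
  s2 <- stepwise_select(d2, "y", c("X1", "X2", "X3"))
  expect_equal(s2$selected, "X3")
  expect_equal(s2$adj_r2, 1, tolerance = 1e-10)
  # empty candidate set degrades to the intercept-only model
  s0 <- stepwise_select(d2, "y", character(0))
  expect_equal(s0$selected, character(0))
  expect_equal(length(coef(s0$model)), 1)
})

test_that("intelligence change scores are standardised differences", {
  a <- c(10, 12, 14, 9, 11)
  expect_equal(delta_iq(a, a), rep(0, 5))
  b <- c(100, 90, 110, 95, 105)
  d <- delta_iq(a, b)
  expect_equal(mean(d), 0, tolerance = 1e-14)
  # affine rescaling of either input changes nothing
  expect_equal(delta_iq(a, 3 * b - 40), d, tolerance = 1e-12)
  expect_equal(delta_iq(a / 7 + 2, b), d, tolerance = 1e-12)
  expect_error(delta_iq(rep(1, 5), b), "variance")
})

test_that("attrition ledger reconciles enrolment and exclusions", {
  att <- attrition_accounting(187, c(technical = 4, no_activation = 22,
                                     no_cbf_response = 9, anomalous = 1))
  expect_equal(att$completed, 151)
  expect_equal(att$enrolled, att$completed + sum(att$ledger$n))
  expect_equal(attrition_accounting(50)$completed, 50)
  expect_error(attrition_accounting(10, c(a = 11)), "exceed")
  expect_error(attrition_accounting(10, c(a = -1)), ">= 0")
})

test_that("correlation tables apply FDR within predictor families", {
  set.seed(18)
  n <- 80
  co <- tibble::tibble(p1 = rnorm(n), y1 = rnorm(n), y2 = rnorm(n))
  co$y1 <- 0.8 * co$p1 + rnorm(n, 0, 0.5)
  tab <- correlation_table(co, "p1", c("y1", "y2"))
  expect_equal(nrow(tab), 2)
  expect_true(tab$significant[tab$outcome == "y1"])
  single <- correlation_table(co, "p1", "y1")
  expect_equal(single$p_fdr, single$p)
  # null coupling: family-wise false discoveries stay near the FDR level
  set.seed(19)
  any_sig <- replicate(100, {
    d <- as.data.frame(matrix(rnorm(60 * 9), 60))
    names(d) <- c("x", paste0("y", 1:8))
    tt <- correlation_table(d, "x", paste0("y", 1:8))
    any(tt$significant)
  })
  expect_lte(mean(any_sig), 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
  # configured couplings keep their signs at n = 150
  cpl <- default_cognition_coupling()[1:4, ]
  signs <- replicate(40, {
    ch <- generate_cohort(cohort_config(n_subjects = 150, coupling = cpl,
                                        seed = sample.int(1e6, 1)))
    d <- cbind(ch$truth, ch$cognition)
    tt <- correlation_table(d, "true_dcbf_visact", cpl$outcome)
    mean(sign(tt$beta) == sign(cpl$slope))
  })
  expect_gte(mean(signs), 0.9)
})
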