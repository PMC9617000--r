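#' Robust linear regression of one outcome on one predictor
#'
#' Iteratively reweighted least squares with the Tukey bisquare psi
#' (c = 4.685) and Huber scale, as commonly used for cohort
#' cognition-physiology correlations where single outlying subjects should
#' not drive the slope. R^2 is computed on the weighted fit and the two-sided
#' p value for the slope uses the normal approximation of the IRLS estimate.
#' An exactly collinear (zero-residual) relation short-circuits to the exact
#' least-squares line.
#'
#' @param x Predictor vector.
#' @param y Outcome vector (pairs with missing values are dropped).
#' @return An `nv_robust_fit`: list with `beta`, `intercept`, `r_squared`,
#'   `p`, `se`, `n_used`, and the underlying model object.
#' @export
#' @examples
#' f <- robust_fit(1:10, 2 * (1:10) + 1)
#' c(f$beta, f$r_squared)
robust_fit <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0) abort("constant predictor")
  ols <- lm(y ~ x)
  rss <- sum(stats::resid(ols)^2)
  tss <- sum((y - mean(y))^2)
  if (rss <= 1e-12 * max(tss, 1)) {
    # exact line: robust and LS estimates coincide
    return(structure(list(beta = unname(coef(ols)[2]),
                          intercept = unname(coef(ols)[1]),
                          r_squared = 1, p = .Machine$double.xmin,
                          se = 0, n_used = n, model = ols),
                     class = "nv_robust_fit"))
  }
  fit <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685,
                   scale.est = "Huber", maxit = 100)
  w <- fit$w
  yhat <- stats::fitted(fit)
  ybar_w <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * (y - yhat)^2) / sum(w * (y - ybar_w)^2)
  sm <- summary(fit)$coefficients
  se <- sm[2, 2]
  tval <- sm[2, 3]
  p <- max(2 * pnorm(-abs(tval)), .Machine$double.xmin)
  structure(list(beta = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r_squared = max(0, min(1, r2)), p = p, se = se,
                 n_used = n, model = fit),
            class = "nv_robust_fit")
}

#' @export
print.nv_robust_fit <- function(x, ...) {
  cat(sprintf("<nv_robust_fit> beta=%.4g R2=%.3f p=%.3g n=%d\n",
              x$beta, x$r_squared, x$p, x$n_used))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p values at FDR level `q`; adjusted values are monotone
#' nondecreasing in the rank of the raw p value.
#'
#' @param pvalues Numeric vector of raw p values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return A tibble with `p`, `p_fdr`, `significant`.
#' @export
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))
fdr_adjust <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0) abort("empty p-value vector")
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    abort("p values must lie in (0, 1]")
  }
  adj <- p.adjust(pvalues, method = "BH")
  tibble(p = pvalues, p_fdr = adj, significant = adj <= q)
}

#' Forward stepwise covariate selection by adjusted R^2
#'
#' Starting from the intercept-only model, repeatedly adds the candidate
#' covariate that most increases the adjusted R^2 of the linear model,
#' stopping when no addition improves it (ties resolved by the declared
#' candidate order). Selection halts early rather than fitting models with
#' fewer than 3 residual degrees of freedom.
#'
#' @param data Data frame containing response and candidates.
#' @param response Name of the response column.
#' @param candidates Character vector of candidate covariate names, in
#'   declared priority order.
#' @return A list: `selected` (character), `model` (`lm`), `adj_r2`, and
#'   `steps` (tibble of the selection path).
#' @export
#' @examples
#' d <- data.frame(y = rnorm(50), a = rnorm(50), b = rnorm(50))
#' d$y <- 3 * d$a + rnorm(50, 0, 0.1)
#' stepwise_select(d, "y", c("a", "b"))$selected
stepwise_select <- function(data, response, candidates) {
  data <- as.data.frame(data)
  keep <- stats::complete.cases(data[, c(response, candidates), drop = FALSE])
  data <- data[keep, , drop = FALSE]
  n <- nrow(data)
  selected <- character(0)
  current <- 0   # adjusted R^2 of the intercept-only model
  steps <- tibble(step = integer(0), added = character(0), adj_r2 = numeric(0))
  remaining <- candidates
  repeat {
    if (length(remaining) == 0) break
    if (n <= length(selected) + 1 + 3) break   # keep >= 3 residual df
    best <- NULL; best_r2 <- current
    for (cand in remaining) {
      fml <- stats::reformulate(c(selected, cand), response)
      r2 <- suppressWarnings(summary(lm(fml, data = data)))$adj.r.squared
      if (r2 > best_r2 + 1e-12) {
        best <- cand; best_r2 <- r2
      }
    }
    if (is.null(best)) break
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    current <- best_r2
    steps <- dplyr::bind_rows(steps,
                              tibble(step = length(selected), added = best,
                                     adj_r2 = current))
  }
  fml <- if (length(selected)) stats::reformulate(selected, response) else {
    stats::reformulate("1", response)
  }
  model <- lm(fml, data = data)
  list(selected = selected, model = model, adj_r2 = current, steps = steps)
}

#' Longitudinal intelligence change score
#'
#' Standardises both score vectors to zero mean and unit SD across the
#' cohort, then subtracts (later minus earlier), giving a unit-free change
#' score invariant to affine rescaling of either instrument.
#'
#' @param score_65 Later-life scores.
#' @param score_earlier Earlier scores on the same subjects.
#' @return Numeric change scores, mean exactly zero.
#' @export
#' @examples
#' delta_iq(c(10, 12, 14), c(100, 90, 110))
delta_iq <- function(score_65, score_earlier) {
  if (length(score_65) != length(score_earlier)) abort("length mismatch")
  if (sd(score_65) == 0 || sd(score_earlier) == 0) abort("zero variance score")
  as.numeric(scale(score_65)) - as.numeric(scale(score_earlier))
}

#' Attrition accounting
#'
#' Reconciles the number of completed measurements with the enrolled count
#' and a per-reason exclusion ledger: `completed = enrolled - sum(exclusions)`.
#'
#' @param enrolled Number of enrolled subjects.
#' @param exclusions Named numeric vector of exclusion counts by reason.
#' @return A list: `enrolled`, `completed`, `ledger` (tibble `reason`, `n`).
#' @export
#' @examples
#' attrition_accounting(187, c(technical = 4, no_activation = 22,
#'                             no_cbf_response = 9, anomalous = 1))$completed
attrition_accounting <- function(enrolled, exclusions = numeric(0)) {
  if (any(exclusions < 0) || enrolled < 0) abort("counts must be >= 0")
  completed <- enrolled - sum(exclusions)
  if (completed < 0) abort("exclusions exceed enrolment")
  ledger <- tibble(reason = names(exclusions) %||% character(0),
                   n = as.numeric(exclusions))
  list(enrolled = enrolled, completed = completed, ledger = ledger)
}

#' Cognition-physiology correlation table
#'
#' Fits [robust_fit()] for every (predictor, outcome) pair of the cohort
#' table and applies the Benjamini-Hochberg correction within each predictor
#' family, mirroring the standard layout of cohort correlation tables
#' (one column block per cerebrovascular predictor, rows ordered as given).
#'
#' @param cohort Data frame / tibble, one row per subject.
#' @param predictors Character vector of predictor column names.
#' @param outcomes Character vector of outcome column names.
#' @param q FDR level.
#' @return A tibble: `predictor`, `outcome`, `beta`, `r_squared`, `p`,
#'   `p_fdr`, `significant`, `n_used`.
#' @export
correlation_table <- function(cohort, predictors, outcomes, q = 0.05) {
  if (nrow(cohort) == 0) abort("empty cohort")
  res <- purrr::map_dfr(predictors, function(pr) {
    purrr::map_dfr(outcomes, function(out) {
      f <- robust_fit(cohort[[pr]], cohort[[out]])
      tibble(predictor = pr, outcome = out, beta = f$beta,
             r_squared = f$r_squared, p = f$p, n_used = f$n_used)
    })
  })
  res |>
    dplyr::group_by(.data$predictor) |>
    dplyr::mutate(p_fdr = p.adjust(.data$p, method = "BH"),
                  significant = .data$p_fdr <= q) |>
    dplyr::ungroup() |>
    dplyr::relocate("p_fdr", "significant", .after = "p")
}
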