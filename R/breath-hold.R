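#' Derive arteriovenous O2 difference and CMRO2 series
#'
#' Adds the per-dynamic arteriovenous saturation difference
#' `avo2(t) = sao2 - svo2(t)` and the Fick-principle metabolic rate
#' `cmro2(t) = hgb * flow(t) * avo2(t)` to a breath-hold series. Absolute
#' units cancel in the percent-change analyses downstream.
#'
#' @param series An `nv_bh_series`.
#' @return A tibble with columns `time`, `flow`, `svo2`, `avo2`, `cmro2`.
#' @export
#' @examples
#' bh <- generate_breath_hold_series(
#'   breath_hold_paradigm(),
#'   truth = list(true_dcbf_bh = 20, true_dcmro2_bh = 5,
#'                true_svo2 = 0.62, sao2 = 0.98, hgb = 9.3),
#'   flow_noise_sd = 0, svo2_noise_sd = 0)
#' head(derive_series(bh))
derive_series <- function(series) {
  stopifnot(inherits(series, "nv_bh_series"))
  d <- series$data
  avo2 <- series$sao2 - d$svo2
  if (any(avo2 < 0)) abort("negative arteriovenous difference: svo2 exceeds sao2")
  dplyr::mutate(d, avo2 = avo2, cmro2 = series$hgb * .data$flow * avo2)
}

# Indices of dynamics lying fully inside the pre-first-hold baseline window.
bh_baseline_idx <- function(time, paradigm) {
  dt <- median(diff(time))
  idx <- which(time + dt / 2 <= paradigm$baseline + 1e-9)
  if (length(idx) < 3) abort("baseline window must contain at least 3 samples")
  idx
}

# Percent change from the pre-hold baseline mean.
bh_percent_change <- function(y, base_idx) {
  b <- mean(y[base_idx])
  if (abs(b) < .Machine$double.eps * 100) abort("degenerate (zero-mean) baseline")
  100 * (y / b - 1)
}

#' Cohort-mean breath-hold regressor
#'
#' Converts each subject's series of `measure` to percent change from its
#' pre-first-hold baseline mean, averages across subjects per dynamic, and
#' normalises the mean curve by its largest absolute response so the
#' regressor peaks at magnitude 1 (sign preserved; the arteriovenous
#' difference response is negative).
#'
#' @param series_list List of `nv_bh_series` (all on the same grid).
#' @param measure One of `"flow"`, `"avo2"`, `"cmro2"`.
#' @return Numeric regressor, one value per dynamic, max |value| = 1.
#' @export
build_population_regressor <- function(series_list,
                                       measure = c("flow", "avo2", "cmro2")) {
  measure <- match.arg(measure)
  if (length(series_list) < 1) abort("need at least one subject")
  curves <- vapply(series_list, function(s) {
    d <- derive_series(s)
    bh_percent_change(d[[measure]], bh_baseline_idx(d$time, s$paradigm))
  }, numeric(nrow(series_list[[1]]$data)))
  m <- rowMeans(curves)
  peak <- max(abs(m))
  if (peak <= 0) abort("flat cohort: regressor undefined")
  m / peak
}

#' Breath-hold response GLM for one subject
#'
#' Expresses each derived series (flow, arteriovenous O2 difference, CMRO2)
#' as percent change from the subject's own pre-hold baseline mean and
#' regresses it on `[intercept, regressor]` by ordinary least squares. With
#' the regressor normalised to peak magnitude 1, the coefficient is the
#' percent change from baseline at the response peak; the signed peak change
#' `delta = beta * regressor value at the largest |regressor|` is reported
#' per measure (so a falling arteriovenous difference yields a negative
#' delta).
#'
#' @param series An `nv_bh_series`.
#' @param regressors Named list of regressors (per measure) from
#'   [build_population_regressor()], or a single numeric regressor recycled
#'   for all three measures.
#' @return An `nv_bh_fit`: tibble with one row per measure (`measure`,
#'   `delta` %, `beta`, `se`, `p`) plus attributes.
#' @export
fit_breath_hold_glm <- function(series, regressors) {
  stopifnot(inherits(series, "nv_bh_series"))
  d <- derive_series(series)
  base_idx <- bh_baseline_idx(d$time, series$paradigm)
  if (is.numeric(regressors)) {
    regressors <- list(flow = regressors, avo2 = regressors, cmro2 = regressors)
  }
  rows <- purrr::map_dfr(c("flow", "avo2", "cmro2"), function(ms) {
    r <- regressors[[ms]]
    if (length(r) != nrow(d)) abort("regressor/series length mismatch")
    y <- bh_percent_change(d[[ms]], base_idx)
    fit <- lm(y ~ r)
    sm <- suppressWarnings(summary(fit))$coefficients  # perfect fits are fine
    peak_r <- r[which.max(abs(r))]
    tibble(measure = ms,
           delta = coef(fit)[[2]] * peak_r,
           beta = coef(fit)[[2]],
           se = sm[2, 2],
           p = sm[2, 4])
  })
  structure(rows, class = c("nv_bh_fit", class(rows)),
            baseline_idx = base_idx)
}

#' Two-pass breath-hold analysis of a cohort
#'
#' First pass builds the cohort-mean regressor per measure from all supplied
#' subjects; second pass fits each subject's GLM against those regressors.
#'
#' @param series_list List of `nv_bh_series`.
#' @return A tibble with one row per subject: `subject`, `dcbf_bh`,
#'   `davo2_bh`, `dcmro2_bh` (signed peak percent changes).
#' @export
breath_hold_cohort <- function(series_list) {
  regs <- list(flow = build_population_regressor(series_list, "flow"),
               avo2 = build_population_regressor(series_list, "avo2"),
               cmro2 = build_population_regressor(series_list, "cmro2"))
  purrr::imap_dfr(series_list, function(s, i) {
    fit <- fit_breath_hold_glm(s, regs)
    tibble(subject = if (is.character(i)) i else as.integer(i),
           dcbf_bh = fit$delta[fit$measure == "flow"],
           davo2_bh = fit$delta[fit$measure == "avo2"],
           dcmro2_bh = fit$delta[fit$measure == "cmro2"])
  })
}
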