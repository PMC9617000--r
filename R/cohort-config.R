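#' Default cognition coupling table
#'
#' One row per cognitive outcome coupled to the visual-activation CBF response.
#' `slope` is the change in score per percentage point of CBF response and
#' `r2` the population coefficient of determination of the coupling; both
#' follow the cohort correlation table of the study the package emulates
#' (current intelligence showing the strongest coupling, beta = 0.112,
#' R^2 = 0.13). `intercept` is the score at zero response.
#'
#' @return A tibble with columns `outcome`, `intercept`, `slope`, `r2`.
#' @export
#' @examples
#' default_cognition_coupling()
default_cognition_coupling <- function() {
  tibble::tribble(
    ~outcome,              ~intercept, ~slope,  ~r2,
    "ist_2000r",                100,    0.112, 0.13,
    "ace",                       90,    0.022, 0.04,
    "tmt_a",                     40,   -0.053, 0.07,
    "tmt_b",                     90,   -0.205, 0.11,
    "sdmt",                      45,    0.058, 0.05,
    "pal_first_trial",           18,    0.019, 0.03,
    "pal_total_errors",          15,   -0.045, 0.12,
    "wordpair_learning_errors",  20,   -0.025, 0.01,
    "wordpair_recall_errors",     8,   -0.015, 0.02,
    "prm_pct",                   85,    0.017, 0.01,
    "srm_pct",                   75,    0.056, 0.04,
    "soc_mean_moves",             8,   -0.008, 0.06,
    "soc_mean_time",             20,    0.017, 0.15
  )
}

#' Cohort simulation configuration
#'
#' Bundles every knob of the synthetic cohort: sample size, the population
#' mean/SD of each ground-truth physiological field, per-modality noise
#' levels, the cognition coupling table, and the run seed. Population defaults
#' follow the reported cohort distributions where the study prints them
#' (visual-activation CBF response 77.1 +/- 30.5 %, breath-hold CBF response
#' 22.5 +/- 7.4 %, lactate increment 0.060 +/- 0.126 mmol/l on a ~0.723
#' mmol/l resting level); the remaining fields use values typical for healthy
#' men in their mid-sixties (see the methods vignette).
#'
#' @param n_subjects Number of subjects.
#' @param means,sds Named numeric vectors overriding population means / SDs.
#'   Recognised names: `dcbf_visact`, `dbold_visact`, `dcbf_bh`, `dcmro2_bh`,
#'   `gcbf`, `svo2`, `sao2`, `hgb`, `brain_volume`, `lactate_rest`,
#'   `dlac_abs`, `naa`, `ist_57`, `bpp_20`.
#' @param noise Named numeric vector overriding per-modality noise levels:
#'   `pcasl_sd` (image units per volume), `velocity_sd` (cm/s),
#'   `phase_sd` (rad), `bh_flow_sd` (fraction of baseline flow),
#'   `bh_svo2_sd` (saturation units), `spectrum_sd` (intensity units).
#' @param coupling Cognition coupling tibble, see
#'   [default_cognition_coupling()].
#' @param geometry [acq_geometry()] used for the pCASL simulation.
#' @param paradigm [block_paradigm()] for visual stimulation.
#' @param bh_paradigm [breath_hold_paradigm()].
#' @param seed Integer run seed; the same seed reproduces the cohort exactly.
#' @return An object of class `nv_cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 5, seed = 1)
#' cfg$means[["dcbf_visact"]]
cohort_config <- function(n_subjects = 40L,
                          means = NULL,
                          sds = NULL,
                          noise = NULL,
                          coupling = default_cognition_coupling(),
                          geometry = acq_geometry(),
                          paradigm = block_paradigm(),
                          bh_paradigm = breath_hold_paradigm(),
                          seed = 1L) {
  if (n_subjects < 1) abort("n_subjects must be positive")
  def_means <- c(dcbf_visact = 77.1, dbold_visact = 1.5,
                 dcbf_bh = 22.5, dcmro2_bh = 5.0,
                 gcbf = 50, svo2 = 0.62, sao2 = 0.98, hgb = 9.3,
                 brain_volume = 1300, lactate_rest = 0.723,
                 dlac_abs = 0.060, naa = 10, ist_57 = 100, bpp_20 = 42)
  def_sds <- c(dcbf_visact = 30.5, dbold_visact = 0.6,
               dcbf_bh = 7.4, dcmro2_bh = 2.5,
               gcbf = 8, svo2 = 0.04, sao2 = 0.01, hgb = 0.6,
               brain_volume = 110, lactate_rest = 0.15,
               dlac_abs = 0.126, naa = 1.2, ist_57 = 15, bpp_20 = 8)
  def_noise <- c(pcasl_sd = 10, velocity_sd = 0.5, phase_sd = 0.02,
                 bh_flow_sd = 0.02, bh_svo2_sd = 0.005, spectrum_sd = 0.02)
  if (!is.null(means)) def_means[names(means)] <- means
  if (!is.null(sds)) def_sds[names(sds)] <- sds
  if (!is.null(noise)) def_noise[names(noise)] <- noise
  if (any(def_sds < 0)) abort("population SDs must be >= 0")
  if (any(def_noise < 0)) abort("noise levels must be >= 0")
  stopifnot(all(c("outcome", "intercept", "slope", "r2") %in% names(coupling)))
  if (any(coupling$r2 < 0 | coupling$r2 > 1)) abort("coupling r2 must lie in [0, 1]")
  structure(
    list(n_subjects = as.integer(n_subjects), means = def_means, sds = def_sds,
         noise = def_noise, coupling = as_tibble(coupling),
         geometry = geometry, paradigm = paradigm, bh_paradigm = bh_paradigm,
         seed = as.integer(seed)),
    class = "nv_cohort_config"
  )
}

# Truncated-normal draw by clamping: adequate here because the clamp bounds
# sit several SDs from the defaults; physiological bounds must still hold for
# extreme user configurations.
rnorm_clamped <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws each subject's true physiology from the configured population
#' distributions and builds the cognition/health table. Cognition scores are
#' linear in the true visual-activation CBF response with the configured slope
#' plus Gaussian noise calibrated so the expected sample R^2 equals the
#' configured value (noise variance `slope^2 * var(x) * (1 - R2) / R2` with
#' `var(x)` the configured population variance). Raw imaging inputs for any
#' subject are materialised on demand by [subject_inputs()] from
#' per-subject/per-modality child seeds, so the cohort object stays light.
#'
#' @param config A [cohort_config()].
#' @return An object of class `nv_cohort`: a list with `config`, `truth`
#'   (tibble, one row per subject) and `cognition` (tibble with cognition
#'   scores and health covariates).
#' @export
#' @examples
#' ch <- generate_cohort(cohort_config(n_subjects = 4, seed = 7))
#' ch$truth$true_dcbf_visact
generate_cohort <- function(config) {
  stopifnot(inherits(config, "nv_cohort_config"))
  n <- config$n_subjects
  mu <- config$means; s <- config$sds
  local_seed(config$seed, {
    svo2 <- rnorm_clamped(n, mu["svo2"], s["svo2"], 0.2, 0.9)
    sao2 <- rnorm_clamped(n, mu["sao2"], s["sao2"], 0.85, 1.0)
    svo2 <- pmin(svo2, sao2 - 0.02)
    lac_rest <- rnorm_clamped(n, mu["lactate_rest"], s["lactate_rest"], 0.1, Inf)
    truth <- tibble(
      subject = seq_len(n),
      true_dcbf_visact = rnorm(n, mu["dcbf_visact"], s["dcbf_visact"]),
      true_dbold_visact = rnorm_clamped(n, mu["dbold_visact"], s["dbold_visact"], 0.1, Inf),
      true_dcbf_bh = rnorm(n, mu["dcbf_bh"], s["dcbf_bh"]),
      true_dcmro2_bh = rnorm(n, mu["dcmro2_bh"], s["dcmro2_bh"]),
      true_gcbf = rnorm_clamped(n, mu["gcbf"], s["gcbf"], 10, Inf),
      true_svo2 = svo2,
      sao2 = sao2,
      hgb = rnorm_clamped(n, mu["hgb"], s["hgb"], 4, Inf),
      brain_volume = rnorm_clamped(n, mu["brain_volume"], s["brain_volume"], 600, Inf),
      lactate_rest = lac_rest,
      lactate_stim = pmax(lac_rest + rnorm(n, mu["dlac_abs"], s["dlac_abs"]), 0.05),
      naa = rnorm_clamped(n, mu["naa"], s["naa"], 2, Inf)
    )
    x <- truth$true_dcbf_visact
    sd_x <- s[["dcbf_visact"]]
    cog <- tibble(subject = seq_len(n))
    for (k in seq_len(nrow(config$coupling))) {
      row <- config$coupling[k, ]
      sigma <- if (row$r2 >= 1) {
        0
      } else if (row$r2 <= 0 || row$slope == 0) {
        max(abs(row$slope) * sd_x, 1)      # uncoupled score: pure noise
      } else {
        abs(row$slope) * sd_x * sqrt((1 - row$r2) / row$r2)
      }
      eff <- if (row$r2 <= 0) 0 else row$slope
      cog[[row$outcome]] <- row$intercept + eff * x + rnorm(n, 0, sigma)
    }
    cog$ist_57 <- rnorm(n, mu["ist_57"], s["ist_57"])
    cog$bpp_20 <- rnorm(n, mu["bpp_20"], s["bpp_20"])
    # Health covariates: prevalences and spreads follow the cohort summary
    # table (self-reported health of ~65-year-old men); uncoupled to truth.
    cog$hypertension <- rbinom(n, 1, 0.396)
    cog$diabetes <- rbinom(n, 1, 0.070)
    cog$hypercholesterolemia <- rbinom(n, 1, 0.273)
    cog$hyperlipidemia <- rbinom(n, 1, 0.042)
    cog$heart_disease <- rbinom(n, 1, 0.176)
    cog$stroke <- rbinom(n, 1, 0.053)
    cog$bmi <- rnorm_clamped(n, 27.5, 3.7, 16, Inf)
    cog$pack_years <- rnorm_clamped(n, 9.7, 10, 0, Inf)
    cog$alcohol_units_week <- rnorm_clamped(n, 10.5, 9, 0, Inf)
    cog$exercise_weekly <- rbinom(n, 1, 0.749)
    cog$education_years <- rnorm_clamped(n, 11, 1.5, 7, Inf)
    structure(list(config = config, truth = truth, cognition = cog),
              class = "nv_cohort")
  })
}

#' Materialise the raw synthetic inputs for one subject
#'
#' Regenerates (deterministically, from child seeds of the cohort seed) the
#' raw acquisition-level inputs of one subject: the dual-echo pCASL series,
#' a phase-contrast velocity map scaled to the subject's true global CBF, the
#' dual-echo oximetry phase maps, the breath-hold flow/saturation series, and
#' the resting/stimulated spectra pair.
#'
#' @param cohort An `nv_cohort` from [generate_cohort()].
#' @param subject Subject index.
#' @param modalities Character subset of
#'   `c("pcasl", "velocity", "phase", "bh", "mrs")`.
#' @return A named list with the requested modality objects.
#' @export
subject_inputs <- function(cohort, subject,
                           modalities = c("pcasl", "velocity", "phase", "bh", "mrs")) {
  stopifnot(inherits(cohort, "nv_cohort"))
  tr <- cohort$truth[cohort$truth$subject == subject, ]
  if (nrow(tr) != 1) abort("unknown subject")
  cfg <- cohort$config
  nz <- cfg$noise
  out <- list()
  if ("pcasl" %in% modalities) {
    out$pcasl <- generate_pcasl_series(
      geometry = cfg$geometry, paradigm = cfg$paradigm,
      truth = list(true_dcbf_visact = tr$true_dcbf_visact,
                   true_dbold_visact = tr$true_dbold_visact),
      noise_sd = nz[["pcasl_sd"]],
      seed = child_seed(cfg$seed, subject, "pcasl"))
  }
  if ("velocity" %in% modalities) {
    out$velocity <- generate_velocity_map(
      target_gcbf = tr$true_gcbf, brain_volume = tr$brain_volume,
      noise_sd = nz[["velocity_sd"]],
      seed = child_seed(cfg$seed, subject, "velocity"))
  }
  if ("phase" %in% modalities) {
    out$phase <- generate_sbo_phase_maps(
      svo2 = tr$true_svo2, noise_sd = nz[["phase_sd"]],
      seed = child_seed(cfg$seed, subject, "phase"))
  }
  if ("bh" %in% modalities) {
    out$bh <- generate_breath_hold_series(
      paradigm = cfg$bh_paradigm,
      truth = list(true_dcbf_bh = tr$true_dcbf_bh,
                   true_dcmro2_bh = tr$true_dcmro2_bh,
                   true_svo2 = tr$true_svo2, sao2 = tr$sao2, hgb = tr$hgb),
      flow_noise_sd = nz[["bh_flow_sd"]], svo2_noise_sd = nz[["bh_svo2_sd"]],
      seed = child_seed(cfg$seed, subject, "bh"))
  }
  if ("mrs" %in% modalities) {
    sd_sp <- nz[["spectrum_sd"]]
    out$mrs <- list(
      rest = generate_spectrum(c(lactate = tr$lactate_rest, naa = tr$naa),
                               noise_sd = sd_sp,
                               seed = child_seed(cfg$seed, subject, "mrs_rest")),
      stim = generate_spectrum(c(lactate = tr$lactate_stim, naa = tr$naa),
                               noise_sd = sd_sp,
                               seed = child_seed(cfg$seed, subject, "mrs_stim")))
  }
  out
}

#' @export
print.nv_cohort <- function(x, ...) {
  cat(sprintf("<nv_cohort> %d subjects (seed %d)\n",
              x$config$n_subjects, x$config$seed))
  print(x$truth, n = 5)
  invisible(x)
}
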