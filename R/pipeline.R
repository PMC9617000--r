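# Serialize the resolved configuration into plain lists for YAML emission.
config_as_list <- function(config) {
  list(
    n_subjects = config$n_subjects,
    seed = config$seed,
    means = as.list(config$means),
    sds = as.list(config$sds),
    noise = as.list(config$noise),
    coupling = as.data.frame(config$coupling),
    geometry = unclass(config$geometry),
    paradigm = unclass(config$paradigm),
    bh_paradigm = unclass(config$bh_paradigm)
  )
}

#' Write a simulated 4D series as NIfTI-1
#'
#' @param series An `nv_asl_series` or `nv_vol_series`.
#' @param path Output file path (`.nii` / `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_series_nifti <- function(series, path) {
  arr <- if (inherits(series, "nv_asl_series")) series$echo1 else series$data
  img <- RNifti::asNifti(arr, reference = NULL)
  RNifti::pixdim(img) <- c(series$geometry$voxel_size, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Generates the configured cohort, quantifies every subject (activation
#' responses with QC, resting flow/oximetry physiology, breath-hold
#' reactivity via the two-pass cohort-mean regressor, lactate change), runs
#' the cohort correlation statistics, and writes a reproducible run
#' directory: resolved config (YAML), a stage log, per-subject results,
#' truth-vs-estimate recovery report, correlation and attrition tables
#' (CSV), and a checksummed manifest.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created; must be writable).
#' @param write_imaging Also write each subject's pCASL series as NIfTI
#'   (off by default; the series regenerate deterministically from the seed).
#' @return Invisibly, a list with `results`, `recovery`, `stats`,
#'   `attrition`, `manifest`, and `out_dir`.
#' @export
run_all <- function(config = cohort_config(), out_dir, write_imaging = FALSE) {
  if (missing(out_dir)) abort("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort("output directory could not be created")
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  yaml::write_yaml(config_as_list(config), file.path(out_dir, "config.yaml"))
  log_line("stage=generate n=%d seed=%d", config$n_subjects, config$seed)
  cohort <- generate_cohort(config)

  stage <- function(name, subject, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed for subject %s: %s",
                    name, subject, conditionMessage(e)))
    })
  }

  rows <- list(); bh_list <- list()
  for (i in seq_len(config$n_subjects)) {
    inp <- stage("inputs", i, subject_inputs(cohort, i))
    act <- stage("asl", i, asl_activation(inp$pcasl))
    qc <- qc_filter(act)
    tr <- cohort$truth[i, ]
    phys <- stage("flow_oximetry", i,
                  resting_physiology(inp$velocity, inp$phase,
                                     brain_volume = tr$brain_volume,
                                     hgb = tr$hgb, sao2 = tr$sao2))
    mrs_rest <- stage("mrs", i, fit_spectrum(inp$mrs$rest))
    mrs_stim <- stage("mrs", i, fit_spectrum(inp$mrs$stim))
    lac <- lactate_change(mrs_rest, mrs_stim)
    bh_list[[i]] <- inp$bh
    if (write_imaging) {
      write_series_nifti(inp$pcasl,
                         file.path(out_dir, sprintf("sub-%03d_pcasl.nii.gz", i)))
    }
    rows[[i]] <- dplyr::bind_cols(
      tibble(subject = i, qc_status = act$qc_status, included = qc$included,
             cluster_size = act$cluster_size,
             dcbf_visact = act$delta_cbf, dbold_visact = act$delta_bold,
             p_cbf = act$p_cbf),
      phys,
      tibble(lactate_rest = spec_conc(mrs_rest, "lactate"),
             lactate_stim = spec_conc(mrs_stim, "lactate"),
             naa = spec_conc(mrs_rest, "naa"),
             dlac_pct = lac$dlac_pct, dlac_abs = lac$dlac_abs))
    log_line("stage=subject id=%d qc=%s", i, act$qc_status)
  }
  results <- dplyr::bind_rows(rows)
  log_line("stage=breath_hold n=%d", length(bh_list))
  bh <- stage("breath_hold", "cohort", breath_hold_cohort(bh_list))
  results <- dplyr::left_join(results, bh, by = "subject")

  cog <- cohort$cognition
  if (nrow(cog) >= 3 && "ist_2000r" %in% names(cog)) {
    cog$delta_iq_65_20 <- delta_iq(cog$ist_2000r, cog$bpp_20)
    cog$delta_iq_65_57 <- delta_iq(cog$ist_2000r, cog$ist_57)
  } else {
    cog$delta_iq_65_20 <- NA_real_
    cog$delta_iq_65_57 <- NA_real_
  }
  full <- dplyr::left_join(results, cog, by = "subject")
  included <- dplyr::filter(full, .data$included)
  outcomes <- c(config$coupling$outcome, "delta_iq_65_20", "delta_iq_65_57")
  stats_tbl <- if (nrow(included) >= 3) {
    stage("stats", "cohort",
          correlation_table(included,
                            predictors = c("dcbf_visact", "dbold_visact",
                                           "dcbf_bh"),
                            outcomes = outcomes))
  } else {
    log_line("stage=stats skipped: fewer than 3 included subjects")
    tibble(predictor = character(0), outcome = character(0),
           beta = numeric(0), r_squared = numeric(0), p = numeric(0),
           p_fdr = numeric(0), significant = logical(0),
           n_used = integer(0))
  }
  excl <- table(results$qc_status[results$qc_status != "ok"])
  att <- attrition_accounting(config$n_subjects,
                              setNames(as.numeric(excl), names(excl)))
  recovery <- dplyr::left_join(cohort$truth, results, by = "subject") |>
    dplyr::transmute(subject = .data$subject,
                     qc_status = .data$qc_status,
                     err_dcbf_visact = .data$dcbf_visact - .data$true_dcbf_visact,
                     err_dbold_visact = .data$dbold_visact - .data$true_dbold_visact,
                     err_dcbf_bh = .data$dcbf_bh - .data$true_dcbf_bh,
                     err_dcmro2_bh = .data$dcmro2_bh - .data$true_dcmro2_bh,
                     err_gcbf = .data$gcbf - .data$true_gcbf,
                     err_svo2 = .data$svo2 - .data$true_svo2,
                     err_dlac_pct = .data$dlac_pct -
                       100 * (.data$lactate_stim.x / .data$lactate_rest.x - 1))

  utils::write.csv(results, file.path(out_dir, "subject_results.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(cog, file.path(out_dir, "cognition.csv"), row.names = FALSE)
  utils::write.csv(stats_tbl, file.path(out_dir, "cohort_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(recovery, file.path(out_dir, "recovery.csv"),
                   row.names = FALSE)
  utils::write.csv(dplyr::bind_rows(att$ledger,
                                    tibble(reason = "completed",
                                           n = att$completed)),
                   file.path(out_dir, "attrition.csv"), row.names = FALSE)
  log_line("stage=write done")
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.csv"))
  manifest <- tibble(file = basename(files),
                     md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(list(results = results, recovery = recovery, stats = stats_tbl,
                 attrition = att, manifest = manifest, out_dir = out_dir))
}
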