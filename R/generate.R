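#' Simulate a dual-echo pCASL acquisition
#'
#' Builds a phantom 4D dual-echo series in which echo 1 alternates
#' control/label volumes whose difference is a perfusion-weighted signal, and
#' echo 2 carries the BOLD-weighted signal. A designated "visual cortex"
#' region (by default a full-depth column covering the central ~45 % of the
#' in-plane field of view) modulates perfusion by the configured CBF response
#' and the echo-2 intensity by the configured BOLD response during
#' stimulation, after convolution with the same gamma hemodynamic response
#' function the estimator assumes (mean 6 s, SD 3 s), so that noise-free
#' recovery is exact. Optionally a mismatched HRF can be injected for
#' robustness studies.
#'
#' @param geometry An [acq_geometry()]; `n_dynamics` label/control pairs.
#' @param paradigm A [block_paradigm()]; must fit within the series duration.
#' @param truth List with `true_dcbf_visact` and `true_dbold_visact`
#'   (% change during stimulation at regressor plateau).
#' @param noise_sd Gaussian noise SD per voxel per volume (image units;
#'   baseline intensity is 1000).
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @param region Logical array of `matrix_dims` marking the truly active
#'   region, or `NULL` for the default column.
#' @param m0 Baseline image intensity (arbitrary units).
#' @param perfusion_baseline Baseline control-minus-label difference in the
#'   same units (resting perfusion-weighted signal).
#' @param hrf_mean,hrf_sd Gamma HRF moments in seconds used by the generator;
#'   change them to emulate generator/estimator HRF mismatch.
#' @param control_first Logical; acquisition order of the pair.
#' @return An object of class `nv_asl_series` with elements `echo1`, `echo2`
#'   (4D arrays, volume index last), `flags` (`"control"`/`"label"`), `time`
#'   (volume times, s), `geometry`, `paradigm`, `region`, and the generating
#'   `truth` as an attribute.
#' @export
#' @examples
#' s <- generate_pcasl_series(acq_geometry(c(8, 8, 2), n_dynamics = 54),
#'                            block_paradigm(),
#'                            truth = list(true_dcbf_visact = 50,
#'                                         true_dbold_visact = 1),
#'                            noise_sd = 0, seed = 1)
#' dim(s$echo1)[4]  # 108 volumes = 54 pairs
generate_pcasl_series <- function(geometry, paradigm, truth,
                                  noise_sd = 10, seed = NULL,
                                  region = NULL, m0 = 1000,
                                  perfusion_baseline = 60,
                                  hrf_mean = 6, hrf_sd = 3,
                                  control_first = TRUE) {
  stopifnot(inherits(geometry, "nv_geometry"), inherits(paradigm, "nv_block_paradigm"))
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  d <- geometry$matrix_dims
  n_vol <- 2L * geometry$n_dynamics
  tr_s <- geometry$tr / 1000
  if (paradigm$total_duration > n_vol * tr_s) {
    abort("paradigm is longer than the acquired series")
  }
  if (is.null(region)) {
    region <- default_activation_region(d)
  }
  if (is.null(dim(region)) || !all(dim(region) == d)) {
    abort("activation region does not match the image matrix")
  }
  region <- array(as.logical(region), dim = d)
  t_vol <- (seq_len(n_vol) - 1) * tr_s
  pair_mid <- (t_vol[seq(1, n_vol, by = 2)] + t_vol[seq(2, n_vol, by = 2)]) / 2
  x_vol <- build_block_regressor(paradigm, t_vol, hrf_mean, hrf_sd)
  x_pair <- build_block_regressor(paradigm, pair_mid, hrf_mean, hrf_sd)
  dcbf <- truth$true_dcbf_visact
  dbold <- truth$true_dbold_visact
  flags <- rep(if (control_first) c("control", "label") else c("label", "control"),
               geometry$n_dynamics)
  echo1 <- array(0, c(d, n_vol))
  echo2 <- array(0, c(d, n_vol))
  reg <- as.numeric(region)
  nvox <- prod(d)
  local_seed(seed, {
    for (k in seq_len(n_vol)) {
      pair <- (k + 1L) %/% 2L
      perf <- perfusion_baseline * (1 + dcbf / 100 * x_pair[pair] * reg)
      sgn <- if (flags[k] == "control") 0.5 else -0.5
      e1 <- m0 + sgn * perf
      e2 <- m0 * (1 + dbold / 100 * x_vol[k] * reg)
      if (noise_sd > 0) {
        e1 <- e1 + rnorm(nvox, 0, noise_sd)
        e2 <- e2 + rnorm(nvox, 0, noise_sd)
      }
      echo1[, , , k] <- e1
      echo2[, , , k] <- e2
    }
  })
  structure(
    list(echo1 = echo1, echo2 = echo2, flags = flags, time = t_vol,
         geometry = geometry, paradigm = paradigm, region = region),
    truth = truth,
    class = "nv_asl_series"
  )
}

# Full-depth in-plane column spanning the central ~45% of x and y; constant
# along z so reflective-boundary smoothing leaves the pattern's depth profile
# untouched and the region keeps a fully interior core.
default_activation_region <- function(d) {
  w <- max(3L, round(0.45 * d[1])); h <- max(3L, round(0.45 * d[2]))
  x0 <- (d[1] - w) %/% 2L + 1L; y0 <- (d[2] - h) %/% 2L + 1L
  region <- array(FALSE, d)
  region[x0:(x0 + w - 1L), y0:(y0 + h - 1L), ] <- TRUE
  region
}

#' Simulate a phase-contrast velocity map
#'
#' Renders each vessel as a circular cross-section carrying a laminar
#' (parabolic) through-plane velocity profile `v(r) = vmax (1 - (r/R)^2)` on a
#' 2D pixel grid, plus optional Gaussian noise on the background and vessels.
#' The analytic flow of each vessel, `60 * pi R^2 vmax / 2` ml/min, is
#' returned alongside for validation. When `target_gcbf` is supplied the peak
#' velocities are rescaled so the summed analytic flow matches that global CBF
#' for the given brain volume.
#'
#' @param vessels Tibble with columns `name`, `cx_cm`, `cy_cm`, `radius_cm`,
#'   `vmax_cm_s`; default emulates the two internal carotids and the basilar
#'   artery.
#' @param n Grid size (pixels per side).
#' @param pixel_size_cm Pixel edge length in cm.
#' @param noise_sd Velocity noise SD in cm/s.
#' @param seed Integer seed.
#' @param target_gcbf Optional global CBF (ml/100g/min) to calibrate total
#'   flow against; requires `brain_volume`.
#' @param brain_volume Brain volume in ml (with `target_gcbf`).
#' @param density Brain density g/ml used in the calibration.
#' @return An object of class `nv_velocity_map`: `velocity` (cm/s matrix),
#'   `pixel_area_cm2`, `rois` (named logical masks), `vessels`, and
#'   `analytic_flows` (ml/min).
#' @export
#' @examples
#' vm <- generate_velocity_map()
#' vm$analytic_flows
generate_velocity_map <- function(vessels = default_vessels(),
                                  n = 96L, pixel_size_cm = 0.025,
                                  noise_sd = 0, seed = NULL,
                                  target_gcbf = NULL, brain_volume = NULL,
                                  density = 1.05) {
  stopifnot(all(c("name", "cx_cm", "cy_cm", "radius_cm", "vmax_cm_s") %in% names(vessels)))
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  half <- n * pixel_size_cm / 2
  if (any(abs(vessels$cx_cm) + vessels$radius_cm > half |
          abs(vessels$cy_cm) + vessels$radius_cm > half)) {
    abort("vessel outside the field of view")
  }
  nv <- nrow(vessels)
  if (nv > 1) {
    for (i in seq_len(nv - 1)) for (j in (i + 1):nv) {
      gap <- sqrt((vessels$cx_cm[i] - vessels$cx_cm[j])^2 +
                  (vessels$cy_cm[i] - vessels$cy_cm[j])^2)
      if (gap < vessels$radius_cm[i] + vessels$radius_cm[j]) {
        abort("overlapping vessels")
      }
    }
  }
  if (!is.null(target_gcbf)) {
    if (is.null(brain_volume)) abort("brain_volume required with target_gcbf")
    target_flow <- target_gcbf * brain_volume * density / 100   # ml/min
    current <- sum(60 * pi * vessels$radius_cm^2 * vessels$vmax_cm_s / 2)
    vessels$vmax_cm_s <- vessels$vmax_cm_s * target_flow / current
  }
  ax <- (seq_len(n) - (n + 1) / 2) * pixel_size_cm
  X <- matrix(ax, n, n); Y <- matrix(ax, n, n, byrow = TRUE)
  vel <- matrix(0, n, n)
  rois <- list()
  for (i in seq_len(nv)) {
    r2 <- (X - vessels$cx_cm[i])^2 + (Y - vessels$cy_cm[i])^2
    inside <- r2 < vessels$radius_cm[i]^2
    vel[inside] <- vessels$vmax_cm_s[i] * (1 - r2[inside] / vessels$radius_cm[i]^2)
    rois[[vessels$name[i]]] <- inside
  }
  if (noise_sd > 0) {
    local_seed(seed, vel <- vel + matrix(rnorm(n * n, 0, noise_sd), n, n))
  }
  structure(
    list(velocity = vel, pixel_area_cm2 = pixel_size_cm^2, rois = rois,
         vessels = vessels,
         analytic_flows = setNames(60 * pi * vessels$radius_cm^2 * vessels$vmax_cm_s / 2,
                                   vessels$name)),
    class = "nv_velocity_map"
  )
}

#' @rdname generate_velocity_map
#' @export
default_vessels <- function() {
  tibble::tribble(
    ~name,            ~cx_cm, ~cy_cm, ~radius_cm, ~vmax_cm_s,
    "carotid_left",    -0.70,  -0.30,       0.25,         40,
    "carotid_right",    0.70,  -0.30,       0.25,         40,
    "basilar",          0.00,   0.65,       0.20,         30
  )
}

# wrap into (-pi, pi]
wrap_phase <- function(x) x - 2 * pi * ceiling((x - pi) / (2 * pi))

#' Simulate dual-echo oximetry phase maps
#'
#' Builds a 2D dual-echo phase-map pair over a phantom sagittal sinus: the
#' per-voxel inter-echo phase difference inside the vessel exceeds the tissue
#' reference by the forward susceptibility model value for the requested
#' venous saturation ([phase_from_svo2()]); tissue carries only the common
#' background offset. Phases are optionally wrapped into `(-pi, pi]` to
#' exercise alias correction downstream.
#'
#' @param svo2 True venous oxygen saturation (fraction in `[0, 1]`).
#' @param geometry Acquisition timing; defaults to the oximetry protocol
#'   (TE 10.89 / 24.16 ms at 3 T).
#' @param calib An [oximetry_calibration()].
#' @param n Grid size.
#' @param noise_sd Phase noise SD, radians.
#' @param base_phase Background phase offset common to both echoes, radians.
#' @param wrap Logical; store wrapped phases.
#' @param seed Integer seed.
#' @return An object of class `nv_phase_pair`: `phase_te1`, `phase_te2`,
#'   `delta_te` (ms), `field_strength` (T), `vessel_mask`, `tissue_mask`,
#'   `calib`.
#' @export
#' @examples
#' pp <- generate_sbo_phase_maps(0.62, noise_sd = 0)
#' svo2_from_phase(susceptibility_phase(pp)$delta_phi,
#'                 pp$delta_te, pp$field_strength, pp$calib)
generate_sbo_phase_maps <- function(svo2,
                                    geometry = acq_geometry(
                                      matrix_dims = c(48L, 48L, 1L),
                                      voxel_size = c(0.5, 0.5, 8),
                                      tr = 90, te1 = 10.89, te2 = 24.16,
                                      n_dynamics = 5L),
                                    calib = oximetry_calibration(),
                                    n = NULL, noise_sd = 0,
                                    base_phase = 0.3, wrap = TRUE,
                                    seed = NULL) {
  if (svo2 < 0 || svo2 > 1) abort("svo2 must lie in [0, 1]")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  n <- n %||% geometry$matrix_dims[1]
  delta_te <- geometry$te2 - geometry$te1
  dphi <- phase_from_svo2(svo2, delta_te, geometry$field_strength, calib)
  ax <- seq_len(n) - (n + 1) / 2
  R2 <- outer(ax, ax, function(a, b) a^2 + b^2)
  vessel <- R2 < 4.5^2
  tissue <- R2 >= 6.5^2 & R2 < 11^2
  p1 <- matrix(base_phase, n, n)
  p2 <- matrix(base_phase, n, n)
  p2[vessel] <- p2[vessel] + dphi
  local_seed(seed, {
    if (noise_sd > 0) {
      p1 <- p1 + matrix(rnorm(n * n, 0, noise_sd), n, n)
      p2 <- p2 + matrix(rnorm(n * n, 0, noise_sd), n, n)
    }
  })
  if (wrap) {
    p1 <- wrap_phase(p1)
    p2 <- wrap_phase(p2)
  }
  structure(
    list(phase_te1 = p1, phase_te2 = p2, delta_te = delta_te,
         field_strength = geometry$field_strength,
         vessel_mask = vessel, tissue_mask = tissue, calib = calib),
    truth = list(svo2 = svo2, dphi = dphi),
    class = "nv_phase_pair"
  )
}

#' Simulate a breath-hold flow/oximetry series
#'
#' Produces per-dynamic sagittal-sinus blood flow and venous saturation over
#' the breath-hold paradigm (default 39 dynamics over 276 s). The flow series
#' follows baseline times `1 + peak/100 * h(t)` where `h` is a smooth
#' ramp-and-decay response per hold (raised-cosine ramp to the end of the
#' hold, exponential recovery), normalised so its maximum over the sampled
#' dynamics is exactly 1 -- the configured value is therefore the true peak
#' change. The saturation series is chosen so that the Fick-derived CMRO2
#' series (or, alternatively, the arteriovenous saturation difference series
#' if `truth$true_davo2_bh` is given) follows the same response shape with
#' its own configured peak change.
#'
#' @param paradigm A [breath_hold_paradigm()].
#' @param truth List with `true_dcbf_bh` (%), one of `true_dcmro2_bh` or
#'   `true_davo2_bh` (%), and resting `true_svo2`, `sao2`, `hgb`.
#' @param n_dynamics,total_duration Sampling grid (39 over 276 s).
#' @param baseline_flow Resting sagittal-sinus flow, ml/min.
#' @param recovery_tau Post-hold exponential recovery constant, s.
#' @param flow_noise_sd Flow noise SD as a fraction of baseline flow.
#' @param svo2_noise_sd Saturation noise SD (absolute).
#' @param seed Integer seed.
#' @return An object of class `nv_bh_series`: `data` (tibble with `time`,
#'   `flow`, `svo2`), scalars `sao2`, `hgb`, `baseline_flow`, the `paradigm`,
#'   and the generating `truth`/response shape as attributes.
#' @export
#' @examples
#' bh <- generate_breath_hold_series(
#'   breath_hold_paradigm(),
#'   truth = list(true_dcbf_bh = 29.2, true_dcmro2_bh = 5.1,
#'                true_svo2 = 0.62, sao2 = 0.98, hgb = 9.3),
#'   flow_noise_sd = 0, svo2_noise_sd = 0)
#' nrow(bh$data)  # 39
generate_breath_hold_series <- function(paradigm, truth,
                                        n_dynamics = 39L, total_duration = 276,
                                        baseline_flow = 350, recovery_tau = 15,
                                        flow_noise_sd = 0.02,
                                        svo2_noise_sd = 0.005,
                                        seed = NULL) {
  stopifnot(inherits(paradigm, "nv_bh_paradigm"))
  if (max(paradigm$offsets) > total_duration) {
    abort("paradigm is longer than the acquired series")
  }
  if (flow_noise_sd < 0 || svo2_noise_sd < 0) abort("noise must be >= 0")
  dt <- total_duration / n_dynamics
  time <- (seq_len(n_dynamics) - 0.5) * dt
  h <- bh_response_shape(time, paradigm, recovery_tau)
  f <- truth$true_dcbf_bh
  flow0 <- baseline_flow * (1 + f / 100 * h)
  avo2_base <- truth$sao2 - truth$true_svo2
  if (avo2_base <= 0) abort("resting svo2 must be below sao2")
  if (!is.null(truth$true_davo2_bh)) {
    avo2 <- avo2_base * (1 + truth$true_davo2_bh / 100 * h)
  } else {
    cmro2 <- truth$hgb * baseline_flow * avo2_base *
      (1 + truth$true_dcmro2_bh / 100 * h)
    avo2 <- cmro2 / (truth$hgb * flow0)
  }
  svo2 <- truth$sao2 - avo2
  flow <- flow0
  local_seed(seed, {
    if (flow_noise_sd > 0) {
      flow <- flow + rnorm(n_dynamics, 0, flow_noise_sd * baseline_flow)
    }
    if (svo2_noise_sd > 0) {
      svo2 <- svo2 + rnorm(n_dynamics, 0, svo2_noise_sd)
    }
  })
  svo2 <- pmin(pmax(svo2, 0), truth$sao2 - 1e-6)
  structure(
    list(data = tibble(time = time, flow = flow, svo2 = svo2),
         sao2 = truth$sao2, hgb = truth$hgb,
         baseline_flow = baseline_flow, paradigm = paradigm),
    truth = truth, shape = h,
    class = "nv_bh_series"
  )
}

# Smooth ramp-and-decay response shape, normalised to max 1 on the grid.
bh_response_shape <- function(time, paradigm, recovery_tau) {
  h <- numeric(length(time))
  for (b in seq_len(paradigm$n_holds)) {
    on <- paradigm$onsets[b]; off <- paradigm$offsets[b]
    ramp <- time >= on & time <= off
    h[ramp] <- h[ramp] + 0.5 * (1 - cos(pi * (time[ramp] - on) / (off - on)))
    post <- time > off
    h[post] <- h[post] + exp(-(time[post] - off) / recovery_tau)
  }
  m <- max(h)
  if (m > 0) h <- h / m
  h
}

#' Simulate a long-echo-time MR spectrum
#'
#' Sum of Lorentzian resonances on a descending ppm axis: lactate at 1.33 ppm
#' (the doublet is modelled unresolved as a single line) and NAA at 2.01 ppm,
#' with line areas proportional to concentration, plus Gaussian noise.
#'
#' @param concentrations Named numeric, mmol/l: `lactate`, `naa` (additional
#'   names are rendered at the centers given in `centers`).
#' @param ppm Descending ppm axis.
#' @param linewidth Lorentzian half width at half maximum, ppm.
#' @param noise_sd Intensity noise SD.
#' @param seed Integer seed.
#' @param calibration_scale Area per mmol/l (intensity scale).
#' @param centers Named chemical shifts, ppm.
#' @param echo_time Echo time in ms (metadata).
#' @return An object of class `nv_spectrum`: tibble with `ppm`, `intensity`
#'   plus attributes `echo_time`, `linewidth`, `calibration_scale`.
#' @export
#' @examples
#' sp <- generate_spectrum(c(lactate = 0.723, naa = 10), noise_sd = 0)
#' fit_spectrum(sp)
generate_spectrum <- function(concentrations,
                              ppm = seq(4.2, 0.2, length.out = 1024),
                              linewidth = 0.02, noise_sd = 0, seed = NULL,
                              calibration_scale = 1,
                              centers = c(lactate = 1.33, naa = 2.01),
                              echo_time = 288) {
  if (any(concentrations < 0)) abort("concentrations must be >= 0")
  if (linewidth <= 0) abort("linewidth must be positive")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  stopifnot(all(diff(ppm) < 0))
  intensity <- numeric(length(ppm))
  for (nm in names(concentrations)) {
    x0 <- centers[[nm]]
    area <- concentrations[[nm]] * calibration_scale
    intensity <- intensity + area / pi * linewidth / ((ppm - x0)^2 + linewidth^2)
  }
  local_seed(seed, {
    if (noise_sd > 0) intensity <- intensity + rnorm(length(ppm), 0, noise_sd)
  })
  structure(
    tibble(ppm = ppm, intensity = intensity),
    echo_time = echo_time, linewidth = linewidth,
    calibration_scale = calibration_scale, truth = concentrations,
    class = c("nv_spectrum", "tbl_df", "tbl", "data.frame")
  )
}
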