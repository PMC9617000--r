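#' Oximetry calibration constants
#'
#' Constants of the infinite-cylinder susceptibility model relating the
#' inter-echo phase contrast of venous blood to its oxygen saturation:
#' the susceptibility difference between fully deoxygenated red cells and
#' tissue per unit hematocrit (SI convention, `4*pi*0.27e-6` by default),
#' the hematocrit, and the vessel angle to the main field (0 = parallel,
#' appropriate for a sagittal-sinus slice prescribed perpendicular to the
#' vessel). All three are exposed because reported literature values vary.
#'
#' @param delta_chi_do Susceptibility difference per unit Hct, SI
#'   (dimensionless).
#' @param hct Hematocrit fraction in (0, 1).
#' @param vessel_angle Vessel angle from B0, radians.
#' @return An object of class `nv_oxi_calib`.
#' @export
oximetry_calibration <- function(delta_chi_do = 4 * pi * 0.27e-6,
                                 hct = 0.42, vessel_angle = 0) {
  if (delta_chi_do <= 0) abort("delta_chi_do must be positive")
  if (hct <= 0 || hct >= 1) abort("hct must lie in (0, 1)")
  structure(list(delta_chi_do = delta_chi_do, hct = hct,
                 vessel_angle = vessel_angle),
            class = "nv_oxi_calib")
}

GYROMAGNETIC_H <- 2.6752218744e8  # proton gyromagnetic ratio, rad/s/T

#' Forward susceptibility-oximetry model
#'
#' Inter-echo intravascular-minus-tissue phase difference for a long
#' cylindrical vessel:
#' `dphi = gamma * B0 * dTE * (dChi_do * Hct * (1 - SvO2) / 6) * (3 cos^2(theta) - 1)`.
#'
#' @param svo2 Venous oxygen saturation, fraction.
#' @param delta_te Inter-echo time, ms.
#' @param field_strength B0 in tesla.
#' @param calib An [oximetry_calibration()].
#' @return Phase difference in radians.
#' @export
#' @examples
#' phase_from_svo2(0.62, 24.16 - 10.89, 3)
phase_from_svo2 <- function(svo2, delta_te, field_strength,
                            calib = oximetry_calibration()) {
  if (delta_te <= 0) abort("delta_te must be positive")
  geom <- 3 * cos(calib$vessel_angle)^2 - 1
  GYROMAGNETIC_H * field_strength * (delta_te / 1000) *
    calib$delta_chi_do * calib$hct * (1 - svo2) / 6 * geom
}

#' Invert the susceptibility-oximetry model
#'
#' Solves the infinite-cylinder model of [phase_from_svo2()] for the venous
#' oxygen saturation. Results outside `[0, 1]` are clamped with a warning. A
#' vessel angle at the magic angle (`3 cos^2 theta - 1` within 1e-6 of zero)
#' leaves the model uninformative and is an error.
#'
#' @param delta_phi Inter-echo intravascular-vs-tissue phase difference,
#'   radians.
#' @inheritParams phase_from_svo2
#' @return Venous oxygen saturation, fraction in `[0, 1]`.
#' @export
#' @examples
#' svo2_from_phase(phase_from_svo2(0.62, 13.27, 3), 13.27, 3)
svo2_from_phase <- function(delta_phi, delta_te, field_strength,
                            calib = oximetry_calibration()) {
  if (delta_te <= 0) abort("delta_te must be positive")
  geom <- 3 * cos(calib$vessel_angle)^2 - 1
  if (abs(geom) < 1e-6) abort("vessel at the magic angle: saturation undefined")
  scale <- GYROMAGNETIC_H * field_strength * (delta_te / 1000) *
    calib$delta_chi_do * calib$hct / 6 * geom
  svo2 <- 1 - delta_phi / scale
  if (any(svo2 < 0 | svo2 > 1)) {
    warn("estimated SvO2 outside [0, 1]; clamped")
    svo2 <- pmin(pmax(svo2, 0), 1)
  }
  svo2
}

#' Inter-echo phase contrast between vessel and tissue
#'
#' Forms the per-voxel inter-echo phase difference, applies automated alias
#' correction to the vessel voxels (each is shifted by the multiple of 2*pi
#' that brings it within pi of the tissue median difference), and returns
#' the mean vessel-minus-tissue contrast.
#'
#' @param pair An `nv_phase_pair`.
#' @return A list: `delta_phi` (radians), `n_corrected` (vessel voxels that
#'   required a 2*pi shift), `ambiguous` (TRUE when any corrected voxel sat
#'   within pi/100 of the +/-pi ambiguity boundary).
#' @export
susceptibility_phase <- function(pair) {
  stopifnot(inherits(pair, "nv_phase_pair"))
  if (!any(pair$vessel_mask) || !any(pair$tissue_mask)) {
    abort("vessel and tissue masks must be nonempty")
  }
  if (any(pair$vessel_mask & pair$tissue_mask)) abort("masks must be disjoint")
  d <- pair$phase_te2 - pair$phase_te1
  tis <- d[pair$tissue_mask]
  ves <- d[pair$vessel_mask]
  med <- median(tis)
  k <- round((ves - med) / (2 * pi))
  corrected <- ves - 2 * pi * k
  resid <- corrected - med
  ambiguous <- any(abs(abs(resid) - pi) < pi / 100)
  if (ambiguous) {
    warn("phase difference within pi/100 of the aliasing boundary; flagged ambiguous")
  }
  list(delta_phi = mean(corrected) - mean(tis),
       n_corrected = sum(k != 0L), ambiguous = ambiguous)
}

#' Blood flow through a vessel ROI
#'
#' Mean through-plane velocity over the ROI times the ROI area, converted
#' from cm^3/s to ml/min.
#'
#' @param map An `nv_velocity_map`.
#' @param roi_name Name of the ROI in `map$rois`.
#' @return Flow in ml/min.
#' @export
#' @examples
#' vm <- generate_velocity_map()
#' vessel_flow(vm, "basilar")
vessel_flow <- function(map, roi_name) {
  stopifnot(inherits(map, "nv_velocity_map"))
  roi <- map$rois[[roi_name]]
  if (is.null(roi) || !any(roi)) abort("empty or unknown ROI")
  mean(map$velocity[roi]) * sum(roi) * map$pixel_area_cm2 * 60
}

#' Global CBF from total arterial inflow
#'
#' Normalises the summed arterial flow to brain weight, with weight derived
#' from brain volume at a density of 1.05 g/ml:
#' `gCBF = 100 * sum(flows) / (volume * density)` in ml/100g/min.
#'
#' @param flows Vessel flows, ml/min.
#' @param brain_volume Brain volume, ml.
#' @param density Brain density, g/ml.
#' @return Global CBF in ml/100g/min.
#' @export
#' @examples
#' total_gcbf(c(300, 300, 100), 1333.3)  # ~50
total_gcbf <- function(flows, brain_volume, density = 1.05) {
  if (any(flows < 0)) abort("flows must be >= 0")
  if (brain_volume <= 0) abort("brain_volume must be positive")
  100 * sum(flows) / (brain_volume * density)
}

#' Fick-principle cerebral metabolic rate of oxygen
#'
#' `gCMRO2 = [Hgb] * gCBF * (SaO2 - SvO2)` in umol O2 per 100 g per minute.
#' The hemoglobin concentration follows the monomer convention used by
#' Danish clinical chemistry (mmol/l of heme groups, each binding one O2),
#' so no tetramer factor of 4 is applied.
#'
#' @param hgb Hemoglobin concentration, mmol/l (monomer convention).
#' @param gcbf Global CBF, ml/100g/min.
#' @param sao2,svo2 Arterial and venous oxygen saturations, fractions with
#'   `0 <= svo2 <= sao2 <= 1`.
#' @return gCMRO2 in umol/100g/min.
#' @export
#' @examples
#' cmro2_fick(9.3, 50, 0.98, 0.60)  # 176.7
cmro2_fick <- function(hgb, gcbf, sao2, svo2) {
  if (any(svo2 > sao2)) abort("svo2 must not exceed sao2")
  if (any(svo2 < 0) || any(sao2 > 1)) abort("saturations must lie in [0, 1]")
  hgb * gcbf * (sao2 - svo2)
}

#' Resting physiology from raw maps
#'
#' Convenience chain for one subject: vessel flows from the velocity map are
#' summed into global CBF, the phase pair yields the venous saturation, and
#' the Fick principle combines them with the measured hemoglobin and arterial
#' saturation into the global CMRO2.
#'
#' @param velocity_map An `nv_velocity_map`.
#' @param phase_pair An `nv_phase_pair`.
#' @param brain_volume Brain volume, ml.
#' @param hgb Hemoglobin, mmol/l.
#' @param sao2 Arterial saturation, fraction.
#' @param density Brain density, g/ml.
#' @return A one-row tibble: `gcbf`, `svo2`, `sao2`, `hgb`, `gcmro2`,
#'   `total_flow`, `brain_weight`.
#' @export
resting_physiology <- function(velocity_map, phase_pair, brain_volume,
                               hgb, sao2, density = 1.05) {
  flows <- vapply(names(velocity_map$rois),
                  function(nm) vessel_flow(velocity_map, nm), numeric(1))
  gcbf <- total_gcbf(flows, brain_volume, density)
  sp <- susceptibility_phase(phase_pair)
  svo2 <- svo2_from_phase(sp$delta_phi, phase_pair$delta_te,
                          phase_pair$field_strength, phase_pair$calib)
  svo2 <- min(svo2, sao2)
  tibble(gcbf = gcbf, svo2 = svo2, sao2 = sao2, hgb = hgb,
         gcmro2 = cmro2_fick(hgb, gcbf, sao2, svo2),
         total_flow = sum(flows), brain_weight = brain_volume * density)
}
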