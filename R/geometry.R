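#' Acquisition geometry
#'
#' Describes the image grid and timing of a simulated acquisition. The default
#' matches the dual-echo pCASL protocol (TR 4550 ms, TE 13 / 31.7 ms, 54
#' label/control dynamics) on a reduced 32 x 32 x 8 matrix so that a full
#' cohort simulates in seconds; the matrix is configurable up to
#' acquisition-scale sizes.
#'
#' @param matrix_dims Integer triple, image matrix in voxels.
#' @param voxel_size Numeric triple, voxel edge lengths in mm.
#' @param tr Repetition time in ms (per volume).
#' @param te1,te2 Echo times in ms; `te1 < te2`.
#' @param field_strength Main field in tesla.
#' @param n_dynamics Number of dynamics. For ASL one dynamic is one
#'   label/control pair (two volumes).
#' @return An object of class `nv_geometry`.
#' @export
#' @examples
#' acq_geometry()
acq_geometry <- function(matrix_dims = c(32L, 32L, 8L),
                         voxel_size = c(2.75, 2.75, 5),
                         tr = 4550,
                         te1 = 13,
                         te2 = 31.7,
                         field_strength = 3,
                         n_dynamics = 54L) {
  stopifnot(length(matrix_dims) == 3, all(matrix_dims >= 1),
            length(voxel_size) == 3, all(voxel_size > 0),
            tr > 0, te1 > 0, te2 > te1, field_strength > 0, n_dynamics >= 1)
  structure(
    list(matrix_dims = as.integer(matrix_dims), voxel_size = as.numeric(voxel_size),
         tr = tr, te1 = te1, te2 = te2,
         field_strength = field_strength, n_dynamics = as.integer(n_dynamics)),
    class = "nv_geometry"
  )
}

#' Block stimulation paradigm
#'
#' Alternating rest/stimulation segments of equal duration, starting and
#' ending with rest. The default is the visual paradigm: four 54-s flickering
#' checkerboard blocks separated (and flanked) by 54-s rest, 486 s in total.
#'
#' @param segment_duration Segment length in seconds.
#' @param n_stim_blocks Number of stimulation blocks.
#' @return An object of class `nv_block_paradigm` with fields
#'   `segment_duration`, `n_stim_blocks`, `total_duration`, and the per-block
#'   stimulus `onsets`/`offsets` (seconds).
#' @export
#' @examples
#' block_paradigm()
block_paradigm <- function(segment_duration = 54, n_stim_blocks = 4L) {
  stopifnot(segment_duration > 0, n_stim_blocks >= 0)
  n_stim_blocks <- as.integer(n_stim_blocks)
  onsets <- if (n_stim_blocks > 0) segment_duration * (2 * seq_len(n_stim_blocks) - 1) else numeric(0)
  structure(
    list(segment_duration = segment_duration,
         n_stim_blocks = n_stim_blocks,
         total_duration = segment_duration * (2 * n_stim_blocks + 1),
         onsets = onsets,
         offsets = onsets + segment_duration),
    class = "nv_block_paradigm"
  )
}

#' Breath-hold paradigm
#'
#' Timing of the breath-hold challenge: an initial free-breathing baseline,
#' then `n_holds` holds of `hold_duration` seconds separated by
#' `break_duration`-second breaks (defaults 50 s baseline, two 36-s holds,
#' 50-s break).
#'
#' @param baseline Baseline duration before the first hold, seconds.
#' @param hold_duration Duration of each hold, seconds.
#' @param n_holds Number of holds.
#' @param break_duration Break between holds, seconds.
#' @return An object of class `nv_bh_paradigm` with hold `onsets`/`offsets`.
#' @export
#' @examples
#' breath_hold_paradigm()
breath_hold_paradigm <- function(baseline = 50, hold_duration = 36,
                                 n_holds = 2L, break_duration = 50) {
  stopifnot(baseline > 0, hold_duration > 0, n_holds >= 1, break_duration >= 0)
  n_holds <- as.integer(n_holds)
  onsets <- baseline + (seq_len(n_holds) - 1) * (hold_duration + break_duration)
  structure(
    list(baseline = baseline, hold_duration = hold_duration,
         n_holds = n_holds, break_duration = break_duration,
         onsets = onsets, offsets = onsets + hold_duration),
    class = "nv_bh_paradigm"
  )
}

#' @export
print.nv_geometry <- function(x, ...) {
  cat(sprintf("<nv_geometry> %s voxels @ %s mm, TR %g ms, TE %g/%g ms, %g T, %d dynamics\n",
              paste(x$matrix_dims, collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x"),
              x$tr, x$te1, x$te2, x$field_strength, x$n_dynamics))
  invisible(x)
}

#' @export
print.nv_block_paradigm <- function(x, ...) {
  cat(sprintf("<nv_block_paradigm> %d stim blocks of %g s (total %g s)\n",
              x$n_stim_blocks, x$segment_duration, x$total_duration))
  invisible(x)
}

#' @export
print.nv_bh_paradigm <- function(x, ...) {
  cat(sprintf("<nv_bh_paradigm> %g s baseline, %d holds of %g s, %g s breaks\n",
              x$baseline, x$n_holds, x$hold_duration, x$break_duration))
  invisible(x)
}
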