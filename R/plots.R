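#' Plot an activation z map
#'
#' Mid-axial slice of the z map with the selected ROI outlined by tiles.
#'
#' @param object An `nv_activation`.
#' @param slice Axial slice index (default: middle slice).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nv_activation <- function(object, slice = NULL, ...) {
  d <- dim(object$z_map)
  slice <- slice %||% ((d[3] + 1) %/% 2)
  df <- tidyr::expand_grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$z <- as.numeric(object$z_map[, , slice])
  df$roi <- as.logical(object$roi_mask[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$z)) +
    ggplot2::geom_tile(data = df[df$roi, , drop = FALSE],
                       fill = NA, colour = "red", linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("z map, slice %d (qc: %s)", slice,
                                  object$qc_status),
                  fill = "z")
}

#' Plot a breath-hold series with its derived measures
#'
#' Percent change from baseline of flow, arteriovenous O2 difference, and
#' CMRO2 through the paradigm, with the hold windows shaded.
#'
#' @param object An `nv_bh_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nv_bh_series <- function(object, ...) {
  d <- derive_series(object)
  base_idx <- bh_baseline_idx(d$time, object$paradigm)
  long <- tidyr::pivot_longer(
    tibble(time = d$time,
           flow = bh_percent_change(d$flow, base_idx),
           avo2 = bh_percent_change(d$avo2, base_idx),
           cmro2 = bh_percent_change(d$cmro2, base_idx)),
    -"time", names_to = "measure", values_to = "pct")
  holds <- tibble(on = object$paradigm$onsets, off = object$paradigm$offsets)
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$pct,
                                     colour = .data$measure)) +
    ggplot2::geom_rect(data = holds,
                       ggplot2::aes(xmin = .data$on, xmax = .data$off,
                                    ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, alpha = 0.15) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "% change from baseline",
                  colour = NULL)
}

#' Plot a spectrum
#'
#' Intensity against the (reversed) ppm axis, the conventional display for
#' in vivo spectra.
#'
#' @param object An `nv_spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nv_spectrum <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$ppm, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity (a.u.)")
}

#' Forest-style plot of a correlation table
#'
#' Slopes with FDR-significance highlighting, faceted by predictor.
#'
#' @param tbl Output of [correlation_table()].
#' @return A ggplot object.
#' @export
plot_correlations <- function(tbl) {
  ggplot2::ggplot(tbl, ggplot2::aes(.data$beta, .data$outcome,
                                    colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~predictor, scales = "free_x") +
    ggplot2::labs(x = "slope (per % response)", y = NULL,
                  colour = "FDR significant")
}
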