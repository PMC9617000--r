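#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an activation result
#'
#' @param x An `nv_activation`.
#' @param ... Unused.
#' @return One-row tibble with the response estimates and QC status.
#' @export
tidy.nv_activation <- function(x, ...) {
  tibble(delta_bold = x$delta_bold, delta_cbf = x$delta_cbf,
         p_cbf = x$p_cbf, qc_status = x$qc_status,
         cluster_size = x$cluster_size, roi_size = sum(x$roi_mask))
}

#' @rdname tidy.nv_activation
#' @export
glance.nv_activation <- function(x, ...) {
  tibble(qc_status = x$qc_status, cluster_size = x$cluster_size,
         max_z = max(x$z_map), z_threshold = x$params$z_threshold)
}

#' Tidy a robust regression fit
#'
#' @param x An `nv_robust_fit`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient term.
#' @export
tidy.nv_robust_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", "x"),
         estimate = c(x$intercept, x$beta),
         std.error = c(NA_real_, x$se),
         p.value = c(NA_real_, x$p))
}

#' @rdname tidy.nv_robust_fit
#' @export
glance.nv_robust_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, p.value = x$p, nobs = x$n_used)
}

#' Tidy a breath-hold fit
#'
#' @param x An `nv_bh_fit`.
#' @param ... Unused.
#' @return Tibble with one row per measure (already tidy).
#' @export
tidy.nv_bh_fit <- function(x, ...) {
  as_tibble(x)
}

#' Tidy a spectrum fit
#'
#' @param x An `nv_spec_fit`.
#' @param ... Unused.
#' @return Tibble with one row per metabolite.
#' @export
tidy.nv_spec_fit <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.nv_spec_fit
#' @export
glance.nv_spec_fit <- function(x, ...) {
  tibble(residual_norm = attr(x, "residual_norm"),
         converged = attr(x, "converged"))
}
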