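#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the affinity calibration
#'
#' @param x A `tbp_affinity_fit` from [fit_affinity_model()].
#' @param ... Unused.
#' @return The per-ODN calibration tibble (observed, fitted, residual).
#' @method tidy tbp_affinity_fit
#' @export
tidy.tbp_affinity_fit <- function(x, ...) x$calibration

#' @rdname tidy.tbp_affinity_fit
#' @return For `glance()`: a one-row tibble with `n_odns`,
#'   `max_abs_residual`, `sigma`.
#' @method glance tbp_affinity_fit
#' @export
glance.tbp_affinity_fit <- function(x, ...) {
  tibble::tibble(n_odns = nrow(x$calibration),
                 max_abs_residual = max(abs(x$calibration$residual)),
                 sigma = x$model$sigma)
}

#' Tidy a kinetics K_D fit
#'
#' @param x A `tbp_kd_fit` from [fit_kd()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`kd_nM`, `vmax`):
#'   `estimate`, `std_error`.
#' @method tidy tbp_kd_fit
#' @export
tidy.tbp_kd_fit <- function(x, ...) {
  tibble::tibble(term = c("kd_nM", "vmax"),
                 estimate = c(x$kd_nM, x$vmax),
                 std_error = c(x$kd_sem, x$vmax_sem))
}

#' @rdname tidy.tbp_kd_fit
#' @return For `glance()`: a one-row tibble with fit diagnostics.
#' @method glance tbp_kd_fit
#' @export
glance.tbp_kd_fit <- function(x, ...) {
  rss <- if (is.null(x$fit)) NA_real_ else sum(resid(x$fit)^2)
  tibble::tibble(kd_nM = x$kd_nM, vmax = x$vmax, rss = rss,
                 converged = x$converged,
                 identifiability_warning = x$identifiability_warning,
                 n = nrow(x$data))
}
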