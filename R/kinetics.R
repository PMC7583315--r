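#' Fit K_D from saturation-binding kinetics
#'
#' Fits the one-site hyperbolic saturation model
#' \deqn{v = V_{max} \, c / (K_D + c)}
#' to (concentration, rate) points by Levenberg-Marquardt nonlinear least
#' squares with positivity bounds. Standard errors come from the curvature
#' of the objective at the optimum. Initial values: \eqn{V_{max}^{(0)}} =
#' the largest observed rate, \eqn{K_D^{(0)}} = the concentration closest
#' to half-maximal rate.
#'
#' When the fitted K_D exceeds the largest tested concentration, the data
#' never approach saturation and the estimate is poorly identified; the
#' `identifiability_warning` flag is raised.
#'
#' @param data Tibble or data frame with columns `conc_nM` (> 0) and
#'   `rate` (>= 0); replicates allowed, at least 3 distinct
#'   concentrations.
#' @param tbp_concentration Metadata only: the fixed protein concentration
#'   of the assay, in nM.
#' @return An object of class `tbp_kd_fit`: `kd_nM`, `kd_sem`, `vmax`,
#'   `vmax_sem`, `converged`, `identifiability_warning`, plus the
#'   underlying `nls` fit and the data. Supports [generics::tidy()],
#'   [generics::glance()] and [plot_kinetics()].
#' @export
#' @examples
#' d <- sim_kinetics(kd_nM = 100, vmax = 1, noise_sd = 0, seed = 1)
#' fit_kd(d)
fit_kd <- function(data, tbp_concentration = 2) {
  if (!all(c("conc_nM", "rate") %in% names(data))) {
    abort("data needs columns conc_nM and rate")
  }
  conc <- as.numeric(data$conc_nM)
  rate <- as.numeric(data$rate)
  if (any(conc <= 0)) abort("concentrations must be positive")
  if (any(rate < 0)) abort("rates must be non-negative")
  if (length(unique(conc)) < 3L) {
    abort("need at least 3 distinct concentrations to fit K_D and Vmax")
  }
  vmax0 <- max(rate)
  kd0 <- conc[which.min(abs(rate - vmax0 / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(rate ~ vmax * conc / (kd + conc),
                      start = list(vmax = vmax0, kd = kd0),
                      lower = c(vmax = 1e-12, kd = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(kd_nM = NA_real_, kd_sem = NA_real_,
                          vmax = NA_real_, vmax_sem = NA_real_,
                          converged = FALSE,
                          identifiability_warning = FALSE,
                          diagnostics = conditionMessage(fit),
                          fit = NULL, data = tibble::as_tibble(data),
                          tbp_concentration = tbp_concentration),
                     class = "tbp_kd_fit"))
  }
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(vmax = NA_real_, kd = NA_real_))
  structure(list(
    kd_nM = unname(est["kd"]), kd_sem = unname(se["kd"]),
    vmax = unname(est["vmax"]), vmax_sem = unname(se["vmax"]),
    converged = fit$convInfo$isConv,
    identifiability_warning = max(conc) < unname(est["kd"]),
    diagnostics = fit$convInfo$stopMessage,
    fit = fit, data = tibble::as_tibble(data),
    tbp_concentration = tbp_concentration),
    class = "tbp_kd_fit")
}

#' @export
print.tbp_kd_fit <- function(x, ...) {
  cat("<tbp_kd_fit>\n")
  if (!x$converged) {
    cat("  fit did not converge:", x$diagnostics, "\n")
    return(invisible(x))
  }
  cat(sprintf("  K_D  = %.4g +/- %.2g nM\n", x$kd_nM, x$kd_sem))
  cat(sprintf("  Vmax = %.4g +/- %.2g\n", x$vmax, x$vmax_sem))
  if (x$identifiability_warning) {
    cat("  warning: no saturation observed (max concentration < K_D)\n")
  }
  invisible(x)
}
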