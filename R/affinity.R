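#' Score a 26-bp window: estimated -ln K_D of the TBP-DNA complex
#'
#' Deterministic sequence-based estimate of the binding free energy scale
#' \eqn{-\ln K_D} (K_D in molar) for a single 26-bp window, under a
#' calibrated affinity model. Larger values mean tighter binding (smaller
#' K_D).
#'
#' @param seq Character vector of 26-bp DNA sequences (A/C/G/T, case
#'   insensitive).
#' @param model A `tbp_affinity_model`; defaults to the packaged calibrated
#'   model.
#' @return Numeric vector of \eqn{-\ln K_D} values, ln-molar units.
#' @export
#' @examples
#' window_affinity("GAGGTCGCCGCGTATAAATAGTGAGA")
window_affinity <- function(seq, model = default_affinity_model()) {
  vapply(seq, function(s) {
    f <- window_features(s, model)
    unname(model$coef["intercept"] +
             model$coef["stop"] * f[["stop"]] +
             model$coef["slide"] * f[["slide"]] +
             model$coef["bend"] * f[["bend"]] +
             sum(model$dinucleotide * f[.DINUCS]))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Promoter-level TBP affinity estimate
#'
#' Scans every 26-bp window of each sequence with [window_affinity()] and
#' reports the strongest site (maximal \eqn{-\ln K_D}, i.e. minimal K_D):
#' one K_D per entered allele, as a promoter presents one best TBP site.
#' The standard error is the model's calibration residual SD (`sigma`), a
#' configuration constant, not a per-sequence quantity.
#'
#' @param seq Character vector of DNA sequences, each at least 26 bp.
#' @inheritParams window_affinity
#' @return A tibble with one row per sequence: `neglog_kd` (ln-molar),
#'   `se`, `kd_nM`, `best_window_offset` (0-based offset of the best
#'   window's 5' end).
#' @export
#' @examples
#' promoter_affinity(table2_promoters()$sequence[1])
promoter_affinity <- function(seq, model = default_affinity_model()) {
  purrr::map_dfr(seq, function(s) {
    L <- nchar(s)
    if (L < model$window_length) {
      abort(paste0("sequence of length ", L, " is shorter than the ",
                   model$window_length, "-bp scoring window"))
    }
    starts <- seq_len(L - model$window_length + 1L)
    scores <- window_affinity(
      substring(s, starts, starts + model$window_length - 1L), model)
    best <- which.max(scores)
    tibble::tibble(neglog_kd = scores[best], se = model$sigma,
                   kd_nM = neglog_to_kd_nm(scores[best]),
                   best_window_offset = best - 1L)
  })
}

#' Convert between K_D in nM and -ln K_D (ln-molar units)
#'
#' `kd_nm_to_neglog(39)` is 17.06 to two decimals; the two functions are
#' mutual inverses.
#'
#' @param kd_nM Dissociation constant in nanomolar; must be positive.
#' @param neglog_kd \eqn{-\ln K_D} with K_D in molar.
#' @return Numeric vector.
#' @export
#' @examples
#' kd_nm_to_neglog(39)
#' neglog_to_kd_nm(kd_nm_to_neglog(39))
kd_nm_to_neglog <- function(kd_nM) {
  if (any(!is.finite(kd_nM)) || any(kd_nM <= 0)) {
    abort("kd_nM must be positive and finite")
  }
  -log(kd_nM * 1e-9)
}

#' @rdname kd_nm_to_neglog
#' @export
neglog_to_kd_nm <- function(neglog_kd) {
  exp(-neglog_kd) * 1e9
}
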