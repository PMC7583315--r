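#' Build the prediction-versus-experiment comparison table
#'
#' Converts measured K_D (nM) to \eqn{-\ln K_D} (ln-molar), and computes
#' the per-SNP allele effects \eqn{\Delta\ln K_D = (-\ln K_D)_{min} -
#' (-\ln K_D)_{wt}} on both the predicted and the measured scale. ODNs
#' must come in complete WT/min pairs per (gene, rsid).
#'
#' @param odns ODN tibble in the shape of [odn_table2()].
#' @return The input with `measured_neglog_kd`, `predicted_delta` and
#'   `measured_delta` appended (the deltas are repeated on both rows of a
#'   pair).
#' @export
#' @examples
#' build_comparison()
build_comparison <- function(odns = odn_table2()) {
  pairs <- odns %>%
    group_by(.data$gene_id, .data$rsid) %>%
    summarise(ok = dplyr::n() == 2L &&
                sum(.data$allele_class == "WT") == 1L &&
                sum(.data$allele_class == "min") == 1L,
              .groups = "drop")
  if (any(!pairs$ok)) {
    abort("ODNs must come in complete WT/min pairs per (gene_id, rsid)")
  }
  odns %>%
    mutate(measured_neglog_kd = kd_nm_to_neglog(.data$measured_kd_nM)) %>%
    group_by(.data$gene_id, .data$rsid) %>%
    mutate(
      predicted_delta =
        .data$predicted_neglog_kd[.data$allele_class == "min"] -
        .data$predicted_neglog_kd[.data$allele_class == "WT"],
      measured_delta =
        .data$measured_neglog_kd[.data$allele_class == "min"] -
        .data$measured_neglog_kd[.data$allele_class == "WT"]) %>%
    ungroup()
}

#' Correlation coefficients with significance
#'
#' Thin wrappers returning a one-row tibble (`method`, `estimate`,
#' `p_value`, `n`). Pearson's p comes from the t transform with n-2
#' degrees of freedom; Kendall's tau is the tie-corrected tau-b;
#' Goodman-Kruskal's gamma counts concordant and discordant pairs,
#' excluding ties, with a large-sample normal p approximation.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return A one-row tibble.
#' @export
#' @examples
#' cmp <- build_comparison()
#' pearson_r(cmp$predicted_neglog_kd, cmp$measured_neglog_kd)
pearson_r <- function(x, y) cor_tidy(x, y, "pearson")

#' @rdname pearson_r
#' @export
spearman_rho <- function(x, y) cor_tidy(x, y, "spearman")

#' @rdname pearson_r
#' @export
kendall_tau <- function(x, y) cor_tidy(x, y, "kendall")

cor_tidy <- function(x, y, method) {
  check_cor_input(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = method))
  tibble::tibble(method = method, estimate = unname(ct$estimate),
                 p_value = ct$p.value, n = length(x))
}

check_cor_input <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3L) abort("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) abort("missing values are not supported")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation is undefined for a constant vector")
  }
  invisible(NULL)
}

#' @rdname pearson_r
#' @export
gk_gamma <- function(x, y) {
  check_cor_input(x, y)
  n <- length(x)
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  prod_ <- dx * dy
  upper <- upper.tri(prod_)
  C <- sum(prod_[upper] > 0)
  D <- sum(prod_[upper] < 0)
  if (C + D == 0) abort("gamma is undefined: all pairs are tied")
  g <- (C - D) / (C + D)
  p <- if (abs(g) >= 1) 0 else {
    z <- g * sqrt((C + D) / (n * (1 - g^2)))
    2 * pnorm(-abs(z))
  }
  tibble::tibble(method = "gk_gamma", estimate = g, p_value = p, n = n)
}

#' Prediction-versus-experiment correlation panel
#'
#' Computes all four correlation coefficients (Pearson, Spearman, Kendall
#' tau-b, Goodman-Kruskal gamma) between predicted and measured
#' \eqn{-\ln K_D} on two scales: absolute (one point per allele) and
#' relative (one \eqn{\Delta\ln K_D} point per SNP).
#'
#' @param comparison Comparison table from [build_comparison()].
#' @return A tibble with columns `scale` (`"absolute"`, `"delta"`),
#'   `method`, `estimate`, `p_value`, `n`.
#' @export
#' @examples
#' validate_predictions()
validate_predictions <- function(comparison = build_comparison()) {
  deltas <- comparison %>%
    distinct(.data$gene_id, .data$rsid, .data$predicted_delta,
             .data$measured_delta)
  panel <- function(x, y, scale) {
    bind_rows(pearson_r(x, y), spearman_rho(x, y), kendall_tau(x, y),
              gk_gamma(x, y)) %>%
      mutate(scale = scale, .before = 1)
  }
  bind_rows(
    panel(comparison$predicted_neglog_kd, comparison$measured_neglog_kd,
          "absolute"),
    panel(deltas$predicted_delta, deltas$measured_delta, "delta"))
}
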