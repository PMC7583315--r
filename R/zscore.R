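#' Compare two allele affinity estimates: Fisher Z marker call
#'
#' Computes the allele effect \eqn{\Delta\ln K_D = \ln K_D(wt) - \ln
#' K_D(min) = (-\ln K_D)_{min} - (-\ln K_D)_{wt}}, its Fisher Z statistic
#' \eqn{Z = \Delta / \sqrt{se_{wt}^2 + se_{min}^2}}, the one-sided
#' standard-normal tail significance \eqn{\alpha}, the qualitative
#' decision, and the heuristic prioritisation rank. Under the
#' proportionality premise (expression scales with TBP-promoter affinity)
#' the expression change of the minor-allele carrier is reported as the
#' ratio \eqn{e^{\Delta}}.
#'
#' A negative \eqn{\Delta} (affinity loss in the minor allele) that clears
#' the significance threshold is called `deficiency_significant`
#' (expected underexpression); a positive one `excess_significant`.
#'
#' @param est_wt,est_min One-row affinity tibbles from
#'   [promoter_affinity()] (columns `neglog_kd`, `se`), wild-type and
#'   minor allele. Both must come from the same model configuration.
#' @param alpha_threshold Significance threshold (default 0.05).
#' @param rsid,gene_id Optional identifiers carried into the output.
#' @param rank_bins Upper alpha bounds of ranks A-D; calls between the last
#'   bound and `alpha_threshold` rank E. Heuristic, configuration-exposed.
#' @return A one-row tibble: `rsid`, `gene_id`, `neglog_kd_wt`, `se_wt`,
#'   `kd_wt_nM`, `neglog_kd_min`, `se_min`, `kd_min_nM`, `delta_ln_kd`,
#'   `z`, `alpha`, `decision`, `rank_rho`, `expression_ratio`.
#' @export
#' @examples
#' m <- default_affinity_model()
#' odns <- odn_table2()
#' wt <- promoter_affinity(odns$sequence[1], m)
#' mn <- promoter_affinity(odns$sequence[2], m)
#' compare_alleles(wt, mn, rsid = odns$rsid[1], gene_id = "SHOX")
compare_alleles <- function(est_wt, est_min, alpha_threshold = 0.05,
                            rsid = NA_character_, gene_id = NA_character_,
                            rank_bins = c(A = 1e-6, B = 1e-4, C = 1e-3,
                                          D = 1e-2)) {
  if (est_wt$se[[1]] <= 0 || est_min$se[[1]] <= 0) {
    abort("standard errors must be positive (model configuration error)")
  }
  delta <- est_min$neglog_kd[[1]] - est_wt$neglog_kd[[1]]
  z <- delta / sqrt(est_wt$se[[1]]^2 + est_min$se[[1]]^2)
  alpha <- pnorm(-abs(z))
  decision <- if (alpha >= alpha_threshold) {
    "insignificant"
  } else if (delta < 0) {
    "deficiency_significant"
  } else {
    "excess_significant"
  }
  rank <- if (decision == "insignificant") NA_character_ else {
    assign_rank(alpha, alpha_threshold = alpha_threshold,
                rank_bins = rank_bins)
  }
  tibble::tibble(
    rsid = rsid, gene_id = gene_id,
    neglog_kd_wt = est_wt$neglog_kd[[1]], se_wt = est_wt$se[[1]],
    kd_wt_nM = neglog_to_kd_nm(est_wt$neglog_kd[[1]]),
    neglog_kd_min = est_min$neglog_kd[[1]], se_min = est_min$se[[1]],
    kd_min_nM = neglog_to_kd_nm(est_min$neglog_kd[[1]]),
    delta_ln_kd = delta, z = z, alpha = alpha,
    decision = decision, rank_rho = rank,
    expression_ratio = exp(delta))
}

#' Heuristic prioritisation rank of a significant marker call
#'
#' Maps a significance level to the ranks `A` (best) through `E` (worst):
#' `A` for \eqn{\alpha \le 10^{-6}}, `B` \eqn{\le 10^{-4}}, `C`
#' \eqn{\le 10^{-3}}, `D` \eqn{\le 10^{-2}}, `E` below the significance
#' threshold. Defined only for significant calls; smaller alpha never
#' yields a later letter.
#'
#' @param alpha Significance level(s) in `(0, alpha_threshold)`.
#' @inheritParams compare_alleles
#' @return Character vector of ranks.
#' @export
#' @examples
#' assign_rank(c(1e-7, 0.04))
assign_rank <- function(alpha, alpha_threshold = 0.05,
                        rank_bins = c(A = 1e-6, B = 1e-4, C = 1e-3,
                                      D = 1e-2)) {
  if (any(alpha >= alpha_threshold) || any(alpha <= 0)) {
    abort(paste0("rank is undefined for alpha outside (0, ",
                 alpha_threshold, ") — the call is insignificant"))
  }
  bounds <- c(sort(rank_bins), setNames(alpha_threshold, "E"))
  names(bounds)[findInterval(alpha, c(0, head(bounds, -1)),
                             left.open = TRUE)]
}

#' Scan a SNP table against promoters: one marker call per SNP
#'
#' For each SNP, substitutes the minor allele into its promoter
#' ([apply_allele()]), estimates both alleles' affinities
#' ([promoter_affinity()]) and emits the Fisher Z marker call
#' ([compare_alleles()]). Output preserves SNP input order.
#'
#' @param promoters Promoter tibble from [read_promoters()].
#' @param snps SNP tibble from [read_snps()].
#' @param model A `tbp_affinity_model`.
#' @inheritParams compare_alleles
#' @return A marker-call tibble, one row per SNP.
#' @export
#' @examples
#' scan_snps(table2_promoters(), table2_snps())
scan_snps <- function(promoters, snps, model = default_affinity_model(),
                      alpha_threshold = 0.05) {
  missing <- setdiff(snps$gene_id, promoters$gene_id)
  if (length(missing)) {
    abort(paste0("no promoter supplied for gene(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(snps) == 0L) return(empty_marker_calls())
  purrr::map_dfr(seq_len(nrow(snps)), function(i) {
    snp <- snps[i, ]
    prom <- promoters[match(snp$gene_id, promoters$gene_id), ]
    alleles <- apply_allele(prom, snp)
    est_wt <- promoter_affinity(alleles$wt_sequence, model)
    est_min <- promoter_affinity(alleles$minor_sequence, model)
    compare_alleles(est_wt, est_min, alpha_threshold = alpha_threshold,
                    rsid = snp$rsid, gene_id = snp$gene_id)
  })
}

# schema of the marker-call table, for empty scans
empty_marker_calls <- function() {
  tibble::tibble(
    rsid = character(), gene_id = character(),
    neglog_kd_wt = numeric(), se_wt = numeric(), kd_wt_nM = numeric(),
    neglog_kd_min = numeric(), se_min = numeric(), kd_min_nM = numeric(),
    delta_ln_kd = numeric(), z = numeric(), alpha = numeric(),
    decision = character(), rank_rho = character(),
    expression_ratio = numeric())
}
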