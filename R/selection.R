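#' Exact binomial tail probability
#'
#' Exact tail probabilities of the Binomial(n, p0) distribution, computed
#' from the exact probability mass function (no normal approximation) —
#' the count tables involved can be as small as a dozen trials. The
#' two-sided probability uses the minimum-likelihood rule: the sum of
#' P(X = x) over all x no more likely than the observed k.
#'
#' @param n Number of trials.
#' @param k Observed count, `0 <= k <= n`.
#' @param p0 Null success probability in (0, 1).
#' @param tail `"ge"` (P(X >= k)), `"le"` (P(X <= k)) or `"two_sided"`.
#' @return A probability.
#' @export
#' @examples
#' binom_tail(12, 6, 0.2, "ge")
binom_tail <- function(n, k, p0, tail = c("ge", "le", "two_sided")) {
  tail <- match.arg(tail)
  if (length(n) != 1L || length(k) != 1L || n < 0 || k < 0 || k > n ||
      n != round(n) || k != round(k)) {
    abort("need integer 0 <= k <= n")
  }
  if (p0 <= 0 || p0 >= 1) abort("p0 must be in (0, 1)")
  switch(tail,
    ge = pbinom(k - 1, n, p0, lower.tail = FALSE),
    le = pbinom(k, n, p0),
    two_sided = {
      d <- dbinom(0:n, n, p0)
      # relative tolerance guards ties against floating-point noise
      sum(d[d <= d[k + 1] * (1 + 1e-7)])
    })
}

#' Tally marker calls into selection-count rows
#'
#' Aggregates a marker-call table into per-class counts: genes and SNPs
#' screened, significant calls (`n_res`), affinity direction split
#' (`n_gt` excess / affinity-increasing, `n_lt` deficiency /
#' affinity-decreasing), and — where annotations are supplied — the split
#' by annotated effect on the phenotype (`n_up` / `n_dn`). Insignificant
#' calls count toward `n_snp` only.
#'
#' Annotations map `(gene_id, expression_direction)` to a potential
#' effect: `expression_direction` is `"over"` for excess calls and
#' `"under"` for deficiency calls; `potential_effect` is `"increase"` or
#' `"decrease"`. Significant calls with no matching annotation are counted
#' in `n_unclassified` with a warning and excluded from `n_up`/`n_dn`.
#'
#' @param calls Marker-call tibble from [scan_snps()].
#' @param annotations Optional tibble (`gene_id`, `expression_direction`,
#'   `potential_effect`).
#' @param classes Optional tibble (`gene_id`, `class_label`) mapping genes
#'   to classes; unmapped genes error. Without it all calls form one
#'   `"TOTAL"` class.
#' @return A selection-count tibble (one row per class).
#' @export
tally_selection <- function(calls, annotations = NULL, classes = NULL) {
  if (nrow(calls) == 0L) {
    return(tibble::tibble(class_label = "TOTAL", n_gene = 0L, n_snp = 0L,
                          n_res = 0L, n_gt = 0L, n_lt = 0L, n_up = 0L,
                          n_dn = 0L, n_unclassified = 0L))
  }
  if (is.null(classes)) {
    calls <- dplyr::mutate(calls, class_label = "TOTAL")
  } else {
    unmapped <- setdiff(unique(calls$gene_id), classes$gene_id)
    if (length(unmapped)) {
      abort(paste0("gene(s) missing from the class map: ",
                   paste(unmapped, collapse = ", ")))
    }
    calls <- dplyr::left_join(calls, classes, by = "gene_id")
  }
  sig <- dplyr::filter(calls, .data$decision != "insignificant")
  if (!is.null(annotations) && nrow(sig)) {
    sig <- sig %>%
      mutate(expression_direction = ifelse(
        .data$decision == "excess_significant", "over", "under")) %>%
      left_join(annotations, by = c("gene_id", "expression_direction"))
    n_missing <- sum(is.na(sig$potential_effect))
    if (n_missing > 0) {
      warn(paste0(n_missing,
                  " significant call(s) lack an annotation; excluded from ",
                  "n_up/n_dn"))
    }
  } else {
    sig$potential_effect <- NA_character_
  }
  calls %>%
    group_by(.data$class_label) %>%
    summarise(n_gene = dplyr::n_distinct(.data$gene_id),
              n_snp = dplyr::n(), .groups = "drop") %>%
    left_join(
      sig %>%
        group_by(.data$class_label) %>%
        summarise(
          n_res = dplyr::n(),
          n_gt = sum(.data$decision == "excess_significant"),
          n_lt = sum(.data$decision == "deficiency_significant"),
          n_up = sum(.data$potential_effect %in% "increase"),
          n_dn = sum(.data$potential_effect %in% "decrease"),
          n_unclassified = sum(is.na(.data$potential_effect)),
          .groups = "drop"),
      by = "class_label") %>%
    mutate(dplyr::across(c("n_res", "n_gt", "n_lt", "n_up", "n_dn",
                           "n_unclassified"),
                         ~ tidyr::replace_na(.x, 0L)))
}

#' Selection-pressure report over count rows
#'
#' For each selection-count row, tests two null hypotheses with exact
#' binomial probabilities:
#'
#' * **Neutral-selection null** — under the genome-wide norm, SNPs
#'   damaging TBP sites outnumber improving ones fourfold, so
#'   affinity-increasing calls arise with probability `p0 = 0.2`. The
#'   reported `p_norm_null` is the right tail P(X >= n_gt) when `n_gt`
#'   exceeds its null expectation and the left cumulative P(X <= n_gt)
#'   otherwise (both tails are also reported explicitly as `p_norm_ge`
#'   and `p_norm_le`).
#' * **Equal-split null** — the annotated phenotype-increasing and
#'   -decreasing markers are binomially equally likely; `p_equal_null` is
#'   the exact two-sided probability at p = 1/2.
#'
#' Empty rows (`n_res = 0`) report probability 1.
#'
#' @param counts Selection-count tibble ([tally_selection()] or
#'   [selection_table1()]).
#' @param p0 Null proportion of affinity-increasing markers (default 0.2,
#'   the fourfold damage prevalence of the genome-wide norm).
#' @return `counts` with columns `p_norm_null`, `p_norm_ge`, `p_norm_le`,
#'   `p_equal_null` appended.
#' @export
#' @examples
#' selection_report(selection_table1())
selection_report <- function(counts, p0 = 0.2) {
  stats <- purrr::map_dfr(seq_len(nrow(counts)), function(i) {
    n <- counts$n_res[i]
    k <- counts$n_gt[i]
    if (is.na(n) || n == 0) {
      return(tibble::tibble(p_norm_null = 1, p_norm_ge = 1, p_norm_le = 1,
                            p_equal_null = 1))
    }
    ge <- binom_tail(n, k, p0, "ge")
    le <- binom_tail(n, k, p0, "le")
    up <- counts$n_up[i]
    dn <- counts$n_dn[i]
    eq <- if (is.na(up) || is.na(dn) || up + dn == 0) NA_real_ else {
      binom_tail(up + dn, up, 0.5, "two_sided")
    }
    tibble::tibble(p_norm_null = if (k > p0 * n) ge else le,
                   p_norm_ge = ge, p_norm_le = le, p_equal_null = eq)
  })
  dplyr::bind_cols(counts, stats)
}
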