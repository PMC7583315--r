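#' EMSA-verified ODN panel: five promoter SNPs, two alleles each
#'
#' The in vitro validation panel of the study this package models: five
#' Y-linked promoter SNPs (SHOX, GTPBP6, ASMT, ZFY, CDY2A), each represented
#' by a pair of 26-bp oligodeoxyribonucleotides (ODNs) identical to the
#' promoter around the SNP, one per allele. Each row carries the in silico
#' predicted \eqn{-\ln K_D} (ln-molar units) and the EMSA-measured
#' \eqn{K_D \pm} SEM in nM.
#'
#' Two of the published rsID labels are internally inconsistent between the
#' panel table and the running text (ZFY and CDY2A); both spellings are kept
#' (`rsid` is the panel label, `rsid_alt` the text spelling) and flagged in
#' `id_conflict` rather than silently resolved.
#'
#' @return A tibble with one row per allele (10 rows): `gene_id`, `rsid`,
#'   `rsid_alt`, `id_conflict`, `allele_class` (`"WT"` or `"min"`),
#'   `allele_label`, `offset` (TSS-relative position of the variant base),
#'   `sequence` (26-bp, uppercase), `snp_position` (1-based position of the
#'   variant base within the ODN), `predicted_neglog_kd`, `measured_kd_nM`,
#'   `measured_sem_nM`.
#' @export
#' @examples
#' odn_table2()
odn_table2 <- function() {
  tibble::tibble(
    gene_id = rep(c("SHOX", "GTPBP6", "ASMT", "ZFY", "CDY2A"), each = 2),
    rsid = rep(c("rs1452787381", "rs1393008234", "rs1402972626",
                 "rs1452787381", "rs20067072"), each = 2),
    rsid_alt = rep(c(NA_character_, NA_character_, NA_character_,
                     "rs1388535808;rs996955491", "rs200670724"), each = 2),
    id_conflict = rep(c(FALSE, FALSE, FALSE, TRUE, TRUE), each = 2),
    allele_class = rep(c("WT", "min"), times = 5),
    allele_label = c("-45A", "-45G", "-24G", "-24T", "-30G", "-30A",
                     "-56C", "-56T", "-24G", "-24t"),
    offset = rep(c(-45L, -24L, -30L, -56L, -24L), each = 2),
    sequence = toupper(c(
      "gaggtcgccgcgtAtaaatagtgaga", "gaggtcgccgcgtGtaaatagtgaga",
      "atcacgagcacgtGatgaggagcggc", "atcacgagcacgtTatgaggagcggc",
      "ggtgaccttttgtGcccagaataggt", "ggtgaccttttgtAcccagaataggt",
      "ggcggagggggccCaactaccatccc", "ggcggagggggccTaactaccatccc",
      "agaatgttccataTaatcgtcatagc", "agaatgttccataCaatcgtcatagc")),
    snp_position = 14L,
    predicted_neglog_kd = c(20.31, 19.21, 17.30, 18.68, 18.18,
                            18.93, 17.67, 18.18, 19.27, 18.76),
    measured_kd_nM = c(39, 260, 1500, 1400, 600, 1000, 1000, 2000, 160, 500),
    measured_sem_nM = c(7, 70, 200, 200, 300, 300, 400, 1000, 30, 200)
  )
}

#' Marker count table over Y-chromosome gene classes
#'
#' Counts of candidate regulatory SNP markers per gene class: genes analysed
#' (`n_gene`), SNPs screened (`n_snp`), significant marker calls (`n_res`),
#' split by predicted affinity direction (`n_gt` increasing, `n_lt`
#' decreasing) and by literature-annotated effect on male reproductive
#' potential (`n_up` increasing, `n_dn` decreasing). Rows with
#' `context = TRUE` are external reference rows (genome-wide norm for
#' transcription-factor sites, clinical markers, female reproductive
#' potential) carried for comparison; the remaining rows partition the
#' Y-chromosome screen.
#'
#' The PAR1 row is stored with the tabulated digits (143/68); the running
#' text gives 146/68, and the discrepancy is flagged in `note` rather than
#' resolved.
#'
#' @return A tibble of selection-count rows.
#' @export
#' @examples
#' selection_table1()
selection_table1 <- function() {
  tibble::tibble(
    class_label = c("genome_norm_tf_sites", "clinical_tbp_markers",
                    "female_reproductive_potential",
                    "PAR1", "PAR2", "paralogous", "unique",
                    "y_linked_subtotal", "TOTAL"),
    context = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    n_gene = c(1e4, 33, 22, 15, 3, 8, 6, 32, 63),
    n_snp  = c(1e5, 203, 129, 899, 135, 56, 41, 1131, 1206),
    n_res  = c(1000, 51, 24, 211, 25, 13, 12, 261, 261),
    n_gt   = c(200, 14, 19, 143, 20, 8, 6, 176, 176),
    n_lt   = c(800, 37, 5, 68, 5, 5, 6, 85, 85),
    n_up   = c(NA, NA, NA, 101, 10, 4, 4, 119, 119),
    n_dn   = c(NA, NA, NA, 110, 15, 9, 8, 142, 142),
    note = c(NA, NA, NA,
             "affinity split tabulated as 143/68; running text says 146/68",
             NA, NA, NA, NA, NA)
  )
}

# deterministic C-rich flank: no TATA-like material, no A/T content
.flank <- function(n) {
  if (n == 0L) return("")
  substr(strrep("CCC", ceiling(n / 3)), 1L, n)
}

#' Synthetic 70-bp promoters embedding the validated ODN panel
#'
#' Builds one synthetic 70-bp sense-strand promoter per panel SNP by
#' embedding the wild-type 26-bp ODN at its published TSS offset inside
#' deterministic C-only flanks. The flanks contain no TATA-like material,
#' so the promoter's best TBP site is the embedded element; the
#' best-window scan may still settle on a window shifted by a few bases
#' relative to the ODN's own frame (the scored window is chosen freely
#' within the promoter), so promoter-level estimates can differ from the
#' pure 26-bp ODN scores by a few tenths of an ln unit while each SNP's
#' affinity-change sign is preserved. These sequences are synthetic
#' constructs (only the 26-bp core is genomic); they stand in for the
#' promoter extraction that the original study performed on the reference
#' genome.
#'
#' @return A promoter tibble (`gene_id`, `tss`, `strand`, `sequence`)
#'   with one row per panel gene.
#' @seealso [odn_table2()], [table2_snps()]
#' @export
table2_promoters <- function() {
  odns <- odn_table2() %>% dplyr::filter(.data$allele_class == "WT")
  seqs <- purrr::map2_chr(odns$sequence, odns$offset, function(s, off) {
    start <- off + 71L - 13L            # 1-based index of the ODN 5' end
    paste0(.flank(start - 1L), s, .flank(70L - (start + 25L)))
  })
  tibble::tibble(
    gene_id = odns$gene_id,
    tss = 1000L,
    strand = "+",
    sequence = seqs
  )
}

#' SNP table for the validated ODN panel
#'
#' The five panel SNPs as a TSS-offset SNP table matching
#' [table2_promoters()]: reference allele = the wild-type ODN base,
#' alternate allele = the minor ODN base at the same position.
#'
#' @return A SNP tibble (`rsid`, `gene_id`, `offset`, `ref_allele`,
#'   `alt_allele`).
#' @export
table2_snps <- function() {
  odns <- odn_table2()
  wt <- odns %>% dplyr::filter(.data$allele_class == "WT")
  mn <- odns %>% dplyr::filter(.data$allele_class == "min")
  tibble::tibble(
    rsid = wt$rsid,
    gene_id = wt$gene_id,
    offset = wt$offset,
    ref_allele = substr(wt$sequence, wt$snp_position, wt$snp_position),
    alt_allele = substr(mn$sequence, mn$snp_position, mn$snp_position)
  )
}
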