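test_that("FASTA promoters parse, validate and round-trip byte-identically", {
  fa <- system.file("extdata", "table2_synthetic_promoters.fa",
                    package = "tbpsnp")
  proms <- read_promoters(fa)
  expect_equal(nrow(proms), 5L)
  expect_equal(proms$gene_id,
               c("SHOX", "GTPBP6", "ASMT", "ZFY", "CDY2A"))
  expect_true(all(nchar(proms$sequence) == 70L))

  # write -> read recovers the table; write matches the shipped file bytes
  tmp <- withr::local_tempfile(fileext = ".fa")
  write_promoters(proms, tmp)
  expect_identical(read_promoters(tmp), proms)
  expect_identical(readLines(tmp), readLines(fa))

  # the shipped file is exactly what the generator produces
  expect_identical(proms, table2_promoters())
})

test_that("malformed promoter input is rejected with a named record", {
  tmp <- withr::local_tempfile(fileext = ".fa")

  writeLines(c(">SHOX|tss=1000|strand=+", strrep("A", 69)), tmp)
  expect_error(read_promoters(tmp), "length 69.*SHOX")

  writeLines(c(">broken header", strrep("A", 70)), tmp)
  expect_error(read_promoters(tmp), "malformed FASTA header")

  writeLines(c(">X|tss=1000|strand=+",
               paste0(strrep("A", 69), "N")), tmp)
  expect_error(read_promoters(tmp), "non-ACGT")

  expect_error(read_promoters(file.path(tempdir(), "absent.fa")),
               "not found")
})

test_that("SNP TSV round-trips and rejects indels and bad offsets", {
  snps <- table2_snps()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_snps(snps, tmp)
  expect_identical(read_snps(tmp), snps)

  bad <- snps
  bad$alt_allele[2] <- "AT"
  write_snps(bad, tmp)
  expect_error(read_snps(tmp), "indel|single-base")

  bad <- snps
  bad$offset[1] <- -71L
  write_snps(bad, tmp)
  expect_error(read_snps(tmp), "outside the promoter range")
})

test_that("the VCF adapter converts SNVs to TSS offsets and drops indels", {
  proms <- table2_promoters()   # tss = 1000 for every record
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chrY\t955\trs1\tA\tG\t.\t.\t.",     # offset -45 (SHOX ref base A)
    "chrY\t976\trs2\tG\tT\t.\t.\t.",     # offset -24
    "chrY\t960\trs3\tAT\tA\t.\t.\t.",    # indel: dropped with a warning
    "chrY\t10\trs4\tC\tT\t.\t.\t."),     # outside every promoter
    vcf)
  expect_warning(snps <- read_snps_vcf(vcf, proms), "non-SNV")
  expect_equal(nrow(snps), 2L)
  expect_equal(snps$offset, c(-45L, -24L))
  expect_equal(snps$gene_id[1], "SHOX")
  expect_equal(snps$ref_allele, c("A", "G"))
})

test_that("apply_allele reproduces the published SHOX allele pair", {
  pair <- apply_allele(table2_promoters()[1, ], table2_snps()[1, ])
  odns <- odn_table2()
  # the embedded 26-mers are the published ODN alleles
  expect_identical(substr(pair$wt_sequence, 13, 38), odns$sequence[1])
  expect_identical(substr(pair$minor_sequence, 13, 38), odns$sequence[2])
  # the alleles differ at exactly offset -45 (position 26 of the 70-mer)
  diff_at <- which(strsplit(pair$wt_sequence, "")[[1]] !=
                     strsplit(pair$minor_sequence, "")[[1]])
  expect_identical(diff_at, 26L)
})

test_that("apply_allele flags stale coordinates and bad offsets", {
  prom <- table2_promoters()[1, ]
  snp <- table2_snps()[1, ]

  snp_bad <- snp
  snp_bad$ref_allele <- "C"
  expect_error(apply_allele(prom, snp_bad), "mismatch.*stale")

  snp_bad <- snp
  snp_bad$offset <- -71L
  expect_error(apply_allele(prom, snp_bad), "outside the promoter range")

  # ref == alt is the identity edit
  snp_id <- snp
  snp_id$alt_allele <- snp_id$ref_allele
  pair <- apply_allele(prom, snp_id)
  expect_identical(pair$wt_sequence, pair$minor_sequence)
})

test_that("every substitution changes exactly one base (exhaustive)", {
  set.seed(11)
  prom <- tibble::tibble(gene_id = "R1", tss = 1000L, strand = "+",
                         sequence = rand_dna(70))
  bases <- strsplit(prom$sequence, "")[[1]]
  for (offset in -70:-1) {
    ref <- bases[offset + 71L]
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      snp <- tibble::tibble(rsid = "x", gene_id = "R1", offset = offset,
                            ref_allele = ref, alt_allele = alt)
      pair <- apply_allele(prom, snp)
      expect_identical(pair$wt_sequence, prom$sequence)
      expect_identical(nchar(pair$minor_sequence), 70L)
      hamming <- sum(strsplit(pair$wt_sequence, "")[[1]] !=
                       strsplit(pair$minor_sequence, "")[[1]])
      expect_identical(hamming, 1L)
    }
  }
})

test_that("the packaged ODN fixture is complete and consistent", {
  odns <- odn_table2()
  expect_equal(nrow(odns), 10L)
  expect_equal(nrow(dplyr::distinct(odns, gene_id, rsid)), 5L)
  expect_true(all(nchar(odns$sequence) == 26L))
  expect_true(all(odns$measured_sem_nM >= 0))
  expect_true(all(table(odns$gene_id) == 2L))
  # panel/text rsID disagreements are flagged, not resolved
  expect_identical(odns$gene_id[odns$id_conflict], rep(c("ZFY", "CDY2A"), each = 2))
  # the shipped TSV matches the in-code fixture
  tsv <- system.file("extdata", "table2_odns.tsv", package = "tbpsnp")
  expect_equal(as.data.frame(readr::read_tsv(tsv, show_col_types = FALSE)),
               as.data.frame(odns))
})
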