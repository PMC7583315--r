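#' Read 70-bp proximal promoter sequences from FASTA
#'
#' Headers must follow the grammar `>GENE|tss=<int>|strand=+`. Sequences are
#' sense-strand proximal promoters covering positions \eqn{-70\ldots-1}
#' upstream of the transcription start site (TSS).
#'
#' @param path Path to a FASTA file.
#' @param length Required sequence length (default 70).
#' @return A tibble with columns `gene_id`, `tss`, `strand`, `sequence`
#'   (uppercase), in file order.
#' @export
#' @examples
#' fa <- system.file("extdata", "table2_synthetic_promoters.fa",
#'                   package = "tbpsnp")
#' read_promoters(fa)
read_promoters <- function(path, length = 70L) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readDNAStringSet(path)
  headers <- names(set)
  parsed <- purrr::map(headers, parse_promoter_header)
  seqs <- toupper(as.character(set))
  promoters <- tibble::tibble(
    gene_id = purrr::map_chr(parsed, "gene_id"),
    tss = purrr::map_int(parsed, "tss"),
    strand = purrr::map_chr(parsed, "strand"),
    sequence = unname(seqs)
  )
  validate_promoters(promoters, length = length, headers = headers)
  promoters
}

parse_promoter_header <- function(header) {
  m <- regexec("^([^|]+)\\|tss=(-?[0-9]+)\\|strand=([+-])$", header)
  parts <- regmatches(header, m)[[1]]
  if (length(parts) != 4L) {
    abort(paste0("malformed FASTA header (expected 'GENE|tss=<int>|strand=+'): '",
                 header, "'"))
  }
  list(gene_id = parts[2], tss = as.integer(parts[3]), strand = parts[4])
}

validate_promoters <- function(promoters, length = 70L, headers = NULL) {
  labels <- if (is.null(headers)) promoters$gene_id else headers
  if (any(!nzchar(promoters$gene_id))) {
    abort("promoter record with empty gene_id")
  }
  bad_len <- nchar(promoters$sequence) != length
  if (any(bad_len)) {
    abort(paste0("promoter sequence of length ",
                 nchar(promoters$sequence)[bad_len][1], " (expected ", length,
                 ") in record '", labels[bad_len][1], "'"))
  }
  bad_alpha <- grepl(paste0("[^", paste(.BASES, collapse = ""), "]"),
                     promoters$sequence)
  if (any(bad_alpha)) {
    abort(paste0("non-ACGT base in record '", labels[bad_alpha][1], "'"))
  }
  invisible(promoters)
}

#' Write promoters to FASTA
#'
#' Inverse of [read_promoters()]: one record per row, header
#' `>GENE|tss=<int>|strand=+`, sequence on a single line, so that
#' write-then-read round-trips byte-identically.
#'
#' @param promoters Promoter tibble (`gene_id`, `tss`, `strand`, `sequence`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(promoters, path) {
  lines <- as.vector(rbind(
    sprintf(">%s|tss=%d|strand=%s",
            promoters$gene_id, as.integer(promoters$tss), promoters$strand),
    promoters$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Read a SNP allele table (TSV)
#'
#' Canonical columns: `rsid`, `gene`, `offset`, `ref`, `alt`. Offsets are
#' 1-based negative distances upstream of the TSS (\eqn{-45} is the 45th
#' base before the TSS). Only single-base substitutions are accepted.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with columns `rsid`, `gene_id`, `offset`, `ref_allele`,
#'   `alt_allele`.
#' @export
read_snps <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(
    rsid = readr::col_character(), gene = readr::col_character(),
    offset = readr::col_integer(), ref = readr::col_character(),
    alt = readr::col_character()))
  snps <- tibble::tibble(
    rsid = raw$rsid, gene_id = raw$gene,
    offset = raw$offset,
    ref_allele = toupper(raw$ref), alt_allele = toupper(raw$alt))
  validate_snps(snps)
  snps
}

#' Write a SNP allele table (TSV)
#'
#' @param snps SNP tibble as returned by [read_snps()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_snps <- function(snps, path) {
  out <- tibble::tibble(rsid = snps$rsid, gene = snps$gene_id,
                        offset = snps$offset, ref = snps$ref_allele,
                        alt = snps$alt_allele)
  readr::write_tsv(out, path)
  invisible(path)
}

validate_snps <- function(snps) {
  single <- nchar(snps$ref_allele) == 1L & nchar(snps$alt_allele) == 1L
  if (any(!single)) {
    abort(paste0("only single-base substitutions are supported; record '",
                 snps$rsid[!single][1], "' is an indel or multi-base variant"))
  }
  bad_base <- !(snps$ref_allele %in% .BASES) | !(snps$alt_allele %in% .BASES)
  if (any(bad_base)) {
    abort(paste0("non-ACGT allele in record '", snps$rsid[bad_base][1], "'"))
  }
  out_of_range <- snps$offset < -70L | snps$offset > -1L
  if (any(out_of_range)) {
    abort(paste0("offset ", snps$offset[out_of_range][1], " of record '",
                 snps$rsid[out_of_range][1],
                 "' is outside the promoter range [-70, -1]"))
  }
  invisible(snps)
}

#' Minimal VCF adapter for SNP input
#'
#' Accepts a plain-text VCF and converts SNV records to TSS offsets using
#' the promoter metadata: a variant at genomic position POS belongs to a
#' sense-strand promoter when `POS` lies in `[tss - 70, tss - 1]`, with
#' offset `POS - tss`. Non-SNV records (indels, multi-allelic ALT) are
#' dropped with a warning. Variants falling in no supplied promoter are
#' dropped silently.
#'
#' @param path Path to a VCF file (uncompressed).
#' @param promoters Promoter tibble from [read_promoters()].
#' @return A SNP tibble as from [read_snps()].
#' @export
read_snps_vcf <- function(path, promoters) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) {
    return(tibble::tibble(rsid = character(), gene_id = character(),
                          offset = integer(), ref_allele = character(),
                          alt_allele = character()))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  short <- lengths(f) < 5L
  if (any(short)) abort("malformed VCF record (fewer than 5 fields)")
  pos <- as.integer(purrr::map_chr(f, 2))
  id <- purrr::map_chr(f, 3)
  ref <- toupper(purrr::map_chr(f, 4))
  alt <- toupper(purrr::map_chr(f, 5))
  snv <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% .BASES & alt %in% .BASES
  if (any(!snv)) {
    warn(paste0("dropping ", sum(!snv), " non-SNV VCF record(s)"))
  }
  hits <- purrr::map_dfr(which(snv), function(i) {
    j <- which(pos[i] >= promoters$tss - 70L & pos[i] <= promoters$tss - 1L)
    if (length(j) == 0L) return(NULL)
    j <- j[1]
    tibble::tibble(rsid = id[i], gene_id = promoters$gene_id[j],
                   offset = pos[i] - promoters$tss[j],
                   ref_allele = ref[i], alt_allele = alt[i])
  })
  if (nrow(hits)) validate_snps(hits)
  hits
}

#' Apply a SNP to a promoter: wild-type and minor allele sequences
#'
#' Substitutes the alternate allele at the SNP's TSS offset. The reference
#' allele must match the promoter base at that offset; a mismatch signals
#' stale coordinates and is an error. Offsets index the 70-mer as
#' \eqn{-70 \leftrightarrow} position 1, \eqn{-1 \leftrightarrow} position
#' 70.
#'
#' @param promoter One promoter row (tibble or list with `gene_id`,
#'   `sequence`).
#' @param snp One SNP row (tibble or list with `rsid`, `offset`,
#'   `ref_allele`, `alt_allele`).
#' @return A tibble with one row: `wt_sequence`, `minor_sequence`.
#' @export
#' @examples
#' p <- table2_promoters()[1, ]
#' s <- table2_snps()[1, ]
#' apply_allele(p, s)
apply_allele <- function(promoter, snp) {
  seq <- toupper(promoter$sequence[[1]])
  offset <- as.integer(snp$offset[[1]])
  if (offset < -70L || offset > -1L) {
    abort(paste0("offset ", offset, " outside the promoter range [-70, -1]"))
  }
  idx <- offset + 71L
  ref <- toupper(snp$ref_allele[[1]])
  alt <- toupper(snp$alt_allele[[1]])
  if (nchar(ref) != 1L || nchar(alt) != 1L) {
    abort("only single-base substitutions are supported")
  }
  have <- substr(seq, idx, idx)
  if (have != ref) {
    abort(paste0("reference allele mismatch for '", snp$rsid[[1]], "' in '",
                 promoter$gene_id[[1]], "': promoter has ", have,
                 " at offset ", offset, " but the SNP table says ", ref,
                 " (stale coordinates?)"))
  }
  minor <- seq
  substr(minor, idx, idx) <- alt
  tibble::tibble(wt_sequence = seq, minor_sequence = minor)
}
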