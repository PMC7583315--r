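#' Simulate a promoter with a planted TATA element and one SNP
#'
#' Generates a 70-bp sense-strand promoter over a GC-biased background
#' with a 15-bp TATA-like element planted at a fixed offset, plus one
#' substitution SNP with a known-direction effect on TBP affinity:
#'
#' * `"damage"` — the SNP replaces a consensus-matching base inside the
#'   planted element by a consensus-breaking one (affinity loss, expected
#'   call direction *deficiency*);
#' * `"improve"` — the element is planted with `n_core_mismatches`
#'   consensus violations and the SNP repairs one of them (affinity gain,
#'   *excess*);
#' * `"neutral"` — the SNP falls outside every 26-bp window that contains
#'   the element, at a position verified to leave the promoter score
#'   unchanged exactly.
#'
#' Every generated SNP is verified against the scoring model itself, so
#' the recorded `truth_direction` holds by construction. Output is fully
#' deterministic given `seed`.
#'
#' @param effect `"damage"`, `"improve"` or `"neutral"`.
#' @param gc_background Background GC fraction in (0, 1); human proximal
#'   promoters are GC-rich, default 0.6.
#' @param planted_offset TSS offset of the element's 5' end (the TATA box
#'   sits around 30 bp upstream of the TSS); default -31.
#' @param n_core_mismatches Consensus violations planted in the element
#'   (default 0; must be >= 1 for `"improve"`).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param model Scoring model used to verify effect directions.
#' @param gene_id Identifier for the generated records.
#' @return A list with `promoter` (one-row promoter tibble), `snp`
#'   (one-row SNP tibble) and `truth_direction` (`"deficiency"`,
#'   `"excess"` or `"neutral"`).
#' @export
#' @examples
#' sim_promoter_snp("damage", seed = 1)
sim_promoter_snp <- function(effect = c("damage", "improve", "neutral"),
                             gc_background = 0.6, planted_offset = -31L,
                             n_core_mismatches = NULL, seed = NULL,
                             model = default_affinity_model(),
                             gene_id = "SIM1") {
  effect <- match.arg(effect)
  if (gc_background <= 0 || gc_background >= 1) {
    abort("gc_background must be in (0, 1)")
  }
  if (is.null(n_core_mismatches)) {
    n_core_mismatches <- if (effect == "improve") 2L else 0L
  }
  if (effect == "improve" && n_core_mismatches < 1L) {
    abort(paste0("cannot generate an improving SNP on a perfect-consensus ",
                 "element: set n_core_mismatches >= 1"))
  }
  core_start <- planted_offset + 71L
  k <- model$core_length
  if (core_start < 1L || core_start + k - 1L > 70L) {
    abort("planted element must lie fully inside the 70-mer")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  for (attempt in 1:25) {
    wt <- plant_element(gc_background, core_start, model, n_core_mismatches)
    out <- switch(effect,
      damage = pick_core_snp(wt, core_start, model, direction = -1),
      improve = pick_core_snp(wt, core_start, model, direction = +1),
      neutral = pick_neutral_snp(wt, core_start, model))
    if (!is.null(out)) {
      return(list(
        promoter = tibble::tibble(gene_id = gene_id, tss = 1000L,
                                  strand = "+", sequence = wt),
        snp = tibble::tibble(
          rsid = sprintf("sim_%s_%d", effect, out$idx - 71L),
          gene_id = gene_id, offset = out$idx - 71L,
          ref_allele = substr(wt, out$idx, out$idx),
          alt_allele = out$alt),
        truth_direction = switch(effect, damage = "deficiency",
                                 improve = "excess", neutral = "neutral")))
    }
  }
  abort(paste0("could not generate a '", effect,
               "' SNP under these settings"))
}

# random background with a consensus-sampled element, optionally degraded
plant_element <- function(gc, core_start, model, n_mismatches) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  x <- sample(.BASES, 70L, replace = TRUE, prob = p)
  k <- model$core_length
  core_pos <- which(colSums(model$pwm > 0) > 0)    # consensus positions
  for (j in core_pos) {
    best <- model$pwm[, j] == max(model$pwm[, j])
    x[core_start + j - 1L] <- sample(.BASES[best], 1L)
  }
  if (n_mismatches > 0L) {
    deg <- sample(core_pos, n_mismatches)
    for (j in deg) {
      worst <- model$pwm[, j] == min(model$pwm[, j])
      x[core_start + j - 1L] <- sample(.BASES[worst], 1L)
    }
  }
  paste(x, collapse = "")
}

# SNP inside the element moving the base down (direction -1) or up (+1)
# the position weight order; verified against the promoter-level score
pick_core_snp <- function(wt, core_start, model, direction) {
  base_score <- promoter_affinity(wt, model)$neglog_kd
  core_pos <- sample(which(colSums(model$pwm > 0) > 0))
  for (j in core_pos) {
    idx <- core_start + j - 1L
    ref <- substr(wt, idx, idx)
    w_ref <- model$pwm[ref, j]
    alts <- .BASES[if (direction < 0) model$pwm[, j] < w_ref
                   else model$pwm[, j] > w_ref]
    for (alt in sample2(alts)) {
      minor <- wt
      substr(minor, idx, idx) <- alt
      delta <- promoter_affinity(minor, model)$neglog_kd - base_score
      if (sign(delta) == direction) return(list(idx = idx, alt = alt))
    }
  }
  NULL
}

# SNP outside every window containing the element, with exactly zero effect
pick_neutral_snp <- function(wt, core_start, model) {
  k <- model$core_length
  w <- model$window_length
  covered <- max(1L, core_start - (w - k)):min(70L, core_start + w - 1L)
  candidates <- setdiff(1:70, covered)
  if (length(candidates) == 0L) return(NULL)
  base_score <- promoter_affinity(wt, model)$neglog_kd
  for (idx in sample2(candidates)) {
    ref <- substr(wt, idx, idx)
    for (alt in sample2(setdiff(.BASES, ref))) {
      minor <- wt
      substr(minor, idx, idx) <- alt
      if (promoter_affinity(minor, model)$neglog_kd == base_score) {
        return(list(idx = idx, alt = alt))
      }
    }
  }
  NULL
}

# sample() without the length-1 surprise
sample2 <- function(x) if (length(x) <= 1L) x else sample(x)

#' Simulate marker count tables under an improve:damage regime
#'
#' Draws selection-count rows with `n_gt ~ Binomial(n_res,
#' improve_fraction)` and `n_up ~ Binomial(n_res, up_fraction)`,
#' emulating a screen whose significant calls split between
#' affinity-increasing and -decreasing markers at a chosen rate (e.g.
#' the genome-norm 1:4 regime has `improve_fraction = 0.2`).
#'
#' @param n_res Number of significant marker calls per table.
#' @param improve_fraction Probability that a call increases affinity.
#' @param up_fraction Probability that a call is annotated
#'   phenotype-increasing.
#' @param n_tables Number of tables to draw.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A selection-count tibble with `n_tables` rows.
#' @export
#' @examples
#' sim_counts(n_res = 1000, improve_fraction = 0.2, seed = 7)
sim_counts <- function(n_res, improve_fraction = 0.2, up_fraction = 0.5,
                       n_tables = 1L, seed = NULL) {
  stopifnot(n_res >= 0, improve_fraction >= 0, improve_fraction <= 1,
            up_fraction >= 0, up_fraction <= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  n_gt <- rbinom(n_tables, n_res, improve_fraction)
  n_up <- rbinom(n_tables, n_res, up_fraction)
  tibble::tibble(
    class_label = sprintf("sim%d", seq_len(n_tables)),
    n_gene = NA_integer_, n_snp = NA_integer_,
    n_res = as.integer(n_res), n_gt = n_gt,
    n_lt = as.integer(n_res) - n_gt,
    n_up = n_up, n_dn = as.integer(n_res) - n_up)
}

#' Simulate a saturation-binding kinetics dataset
#'
#' Rates follow the one-site model \eqn{v = V_{max} c / (K_D + c)} with
#' multiplicative Gaussian noise (`noise_sd` is the coefficient of
#' variation, e.g. 0.05 for 5% noise), clipped at zero.
#'
#' @param kd_nM True dissociation constant, nM.
#' @param vmax True maximal rate.
#' @param noise_sd Noise coefficient of variation (0 = noiseless).
#' @param concentrations ODN concentrations in nM (the assay design used
#'   four, spanning roughly 0.25-4 times K_D).
#' @param replicates Replicates per concentration.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A tibble with columns `conc_nM`, `rate`.
#' @export
#' @examples
#' sim_kinetics(kd_nM = 100, vmax = 1, noise_sd = 0.05, seed = 1)
sim_kinetics <- function(kd_nM = 100, vmax = 1, noise_sd = 0.05,
                         concentrations = c(25, 50, 100, 400),
                         replicates = 1L, seed = NULL) {
  stopifnot(kd_nM > 0, vmax > 0, noise_sd >= 0,
            all(concentrations > 0), replicates >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  conc <- rep(concentrations, each = replicates)
  truth <- vmax * conc / (kd_nM + conc)
  rate <- pmax(0, truth * (1 + rnorm(length(conc), 0, noise_sd)))
  tibble::tibble(conc_nM = conc, rate = rate)
}
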