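# independent brute-force oracles, kept free of the implementation paths

# binomial tails by direct log-choose summation
bf_binom_tail <- function(n, k, p0, tail) {
  pmf <- function(x) exp(lchoose(n, x) + x * log(p0) + (n - x) * log(1 - p0))
  masses <- vapply(0:n, pmf, numeric(1))
  switch(tail,
         ge = sum(masses[(k + 1):(n + 1)]),
         le = sum(masses[1:(k + 1)]),
         two_sided = sum(masses[masses <= masses[k + 1] * (1 + 1e-7)]))
}

# concordant/discordant pair counting by explicit double loop
bf_pairs <- function(x, y) {
  C <- 0L; D <- 0L; Tx <- 0L; Ty <- 0L; Txy <- 0L
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
    if (sx == 0 && sy == 0) Txy <- Txy + 1L
    else if (sx == 0) Tx <- Tx + 1L
    else if (sy == 0) Ty <- Ty + 1L
    else if (sx == sy) C <- C + 1L
    else D <- D + 1L
  }
  list(C = C, D = D, Tx = Tx, Ty = Ty, Txy = Txy)
}

bf_gamma <- function(x, y) {
  p <- bf_pairs(x, y)
  (p$C - p$D) / (p$C + p$D)
}

# tie-corrected tau-b from pair counts
bf_tau_b <- function(x, y) {
  p <- bf_pairs(x, y)
  (p$C - p$D) / sqrt((p$C + p$D + p$Tx) * (p$C + p$D + p$Ty))
}

rand_dna <- function(L, prob = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = prob),
        collapse = "")
}

# random marker-call table with the columns tally_selection() consumes
rand_calls <- function(n, p_sig = 0.7, genes = paste0("G", 1:5)) {
  decision <- ifelse(runif(n) < p_sig,
                     ifelse(runif(n) < 0.5, "excess_significant",
                            "deficiency_significant"),
                     "insignificant")
  tibble::tibble(rsid = sprintf("rs%06d", seq_len(n)),
                 gene_id = sample(genes, n, replace = TRUE),
                 decision = decision)
}
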