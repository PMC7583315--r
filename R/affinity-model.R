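#' Construct a TBP affinity model configuration
#'
#' The model estimates \eqn{-\ln K_D} (ln-molar units) of the TBP-DNA
#' complex for a 26-bp sequence window as a linear combination of three
#' elementary-step terms plus a dinucleotide fine-energy table:
#'
#' \deqn{-\ln K_D = c_0 + c_{stop} S_{stop} + c_{slide} S_{slide} +
#'       c_{bend} S_{bend} + \sum_d n_d D_d}
#'
#' * `S_stop` — site recognition: the best 15-bp core score under a fixed
#'   TATA-box position weight table (TBP stops at the TATA element);
#' * `S_slide` — one-dimensional sliding along AT-rich tracts: the maximal
#'   A/T count over all `slide_window`-bp windows;
#' * `S_bend` — DNA deformation: the number of TA and AT steps, the
#'   pyrimidine-purine kink sites at which TBP bends the helix;
#' * `n_d D_d` — dinucleotide step counts times calibrated fine-energy
#'   adjustments absorbing sequence effects the three coarse terms miss.
#'
#' The combination coefficients and the dinucleotide table are calibrated
#' against the EMSA-validated ODN panel by [fit_affinity_model()]; the
#' position weight table and window definitions are fixed model structure.
#'
#' @param pwm 4 x `core_length` numeric matrix (rows `A`,`C`,`G`,`T`) of
#'   position weights for the core-recognition term.
#' @param coef Named numeric: `intercept`, `stop`, `slide`, `bend`.
#' @param dinucleotide Named numeric of length 16 (AA, AC, ..., TT):
#'   fine-energy per dinucleotide step.
#' @param sigma Residual standard deviation of the calibrated estimator in
#'   ln units; used as the standard error of every per-allele estimate.
#' @param slide_window Window length (bp) of the sliding term.
#' @param window_length Scoring window length; fixed at 26 bp, the ODN
#'   length the calibration data use.
#' @param core_length Length of the recognition core; fixed at 15 bp.
#' @return An object of class `tbp_affinity_model`.
#' @seealso [fit_affinity_model()], [default_affinity_model()],
#'   [window_affinity()]
#' @export
affinity_model <- function(pwm = tata_pwm_prior(),
                           coef = c(intercept = 0, stop = 1, slide = 1,
                                    bend = 1),
                           dinucleotide = setNames(rep(0, 16), .DINUCS),
                           sigma = 0.20,
                           slide_window = 9L,
                           window_length = 26L,
                           core_length = 15L) {
  stopifnot(is.matrix(pwm), nrow(pwm) == 4L, ncol(pwm) == core_length)
  if (!identical(rownames(pwm), .BASES)) {
    abort("pwm must have rownames A, C, G, T")
  }
  if (anyNA(pwm)) abort("pwm must be fully populated for {A,C,G,T}")
  coef <- coef[c("intercept", "stop", "slide", "bend")]
  if (anyNA(coef)) abort("coef must name intercept, stop, slide, bend")
  dinucleotide <- dinucleotide[.DINUCS]
  if (anyNA(dinucleotide)) abort("dinucleotide must cover all 16 steps")
  if (!is.numeric(sigma) || sigma <= 0) abort("sigma must be > 0")
  if (window_length != 26L) abort("window_length is fixed at 26")
  structure(
    list(pwm = pwm, coef = coef, dinucleotide = dinucleotide,
         sigma = as.numeric(sigma), slide_window = as.integer(slide_window),
         window_length = 26L, core_length = as.integer(core_length)),
    class = "tbp_affinity_model")
}

#' @export
print.tbp_affinity_model <- function(x, ...) {
  cat("<tbp_affinity_model>\n")
  cat(sprintf("  window %d bp, core %d bp, slide window %d bp, sigma %.3f\n",
              x$window_length, x$core_length, x$slide_window, x$sigma))
  cat("  coefficients:",
      paste(sprintf("%s=%.4g", names(x$coef), x$coef), collapse = ", "), "\n")
  cat("  dinucleotide fine-energy range: [",
      sprintf("%.4g", min(x$dinucleotide)), ", ",
      sprintf("%.4g", max(x$dinucleotide)), "]\n", sep = "")
  invisible(x)
}

#' TATA-box position weight table used by the recognition term
#'
#' A 15-position weight table with the 8-bp TATA consensus `TATAWAWR`
#' occupying positions 4-11: weight 1 for the invariant consensus base,
#' 0.5 for each base allowed at a degenerate (`W`, `R`) position, 0
#' elsewhere. Flank positions carry no weight; they pad the core so a
#' 26-bp window is scanned with the element in its natural central
#' context.
#'
#' @return A 4 x 15 numeric matrix with rownames `A`,`C`,`G`,`T`.
#' @export
tata_pwm_prior <- function() {
  pwm <- matrix(0, 4L, 15L, dimnames = list(.BASES, NULL))
  core <- c("T", "A", "T", "A", "W", "A", "W", "R")
  for (j in seq_along(core)) {
    p <- j + 3L
    b <- switch(core[j], W = c("A", "T"), R = c("A", "G"), core[j])
    pwm[b, p] <- if (core[j] %in% c("W", "R")) 0.5 else 1
  }
  pwm
}

# base-index encoding of sequences; errors on non-ACGT
encode_seq <- function(seq) {
  x <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], .BASES)
  if (anyNA(x)) abort(paste0("non-ACGT base in sequence '", seq, "'"))
  x
}

# the three elementary terms + dinucleotide counts for one 26-bp window
window_features <- function(seq, model) {
  x <- encode_seq(seq)
  L <- length(x)
  if (L != model$window_length) {
    abort(paste0("sequence of length ", L, " (expected ",
                 model$window_length, ")"))
  }
  k <- model$core_length
  stop_term <- max(vapply(seq_len(L - k + 1L), function(i) {
    sum(model$pwm[cbind(x[i:(i + k - 1L)], seq_len(k))])
  }, numeric(1)))
  w <- model$slide_window
  is_at <- x == 1L | x == 4L
  slide_term <- max(vapply(seq_len(L - w + 1L), function(i) {
    sum(is_at[i:(i + w - 1L)])
  }, numeric(1)))
  steps <- (head(x, -1L) - 1L) * 4L + tail(x, -1L)   # 1..16 in .DINUCS order
  n_d <- tabulate(steps, nbins = 16L)
  bend_term <- n_d[13L] + n_d[4L]                    # TA + AT
  c(stop = stop_term, slide = slide_term, bend = bend_term,
    setNames(n_d, .DINUCS))
}

affinity_design_matrix <- function(seqs, model) {
  feats <- t(vapply(seqs, window_features, numeric(19), model = model))
  cbind(intercept = 1, feats)
}

# minimum-norm exact least squares: smallest weighted deviation from the
# prior parameter vector that reproduces the calibration values exactly
min_norm_solve <- function(X, y, theta0, wpen) {
  r <- y - as.vector(X %*% theta0)
  Xs <- sweep(X, 2L, sqrt(wpen), "/")
  delta <- as.vector(MASS::ginv(Xs) %*% r) / sqrt(wpen)
  theta0 + delta
}

#' Calibrate the affinity model against the validated ODN panel
#'
#' Fits the combination coefficients and the dinucleotide fine-energy table
#' so that the model reproduces the panel's per-allele \eqn{-\ln K_D}
#' values exactly (minimum-norm least squares: among all parameter vectors
#' that interpolate the panel, the one closest to the structural prior —
#' unit combination coefficients, zero fine-energies — under the given
#' penalty weights). The position weight table and window definitions stay
#' fixed.
#'
#' Calibration quality out of sample is reported by leave-one-out
#' refitting ([loo_affinity_model()]); with ten calibration points the
#' out-of-sample residuals are an honest measure of how much of the
#' underlying sequence-affinity map the model family captures.
#'
#' @param odns ODN calibration tibble with columns `sequence` and
#'   `predicted_neglog_kd` (default: the packaged panel, [odn_table2()]).
#' @param prior A `tbp_affinity_model` giving the structural prior.
#' @param penalty Named numeric penalty weights for deviations from the
#'   prior: `coef` (the three combination coefficients) and `dinucleotide`.
#'   The intercept is effectively unpenalised.
#' @return A `tbp_affinity_fit`: list with `model` (the calibrated
#'   `tbp_affinity_model`) and `calibration` (per-ODN observed, fitted and
#'   residual values).
#' @export
#' @examples
#' fit <- fit_affinity_model()
#' fit$calibration
fit_affinity_model <- function(odns = odn_table2(),
                               prior = affinity_model(),
                               penalty = c(coef = 1, dinucleotide = 1)) {
  y <- odns$predicted_neglog_kd
  X <- affinity_design_matrix(odns$sequence, prior)
  theta0 <- c(prior$coef["intercept"], prior$coef["stop"],
              prior$coef["slide"], prior$coef["bend"], prior$dinucleotide)
  wpen <- c(1e-4, rep(penalty[["coef"]], 3L),
            rep(penalty[["dinucleotide"]], 16L))
  theta <- min_norm_solve(X, y, theta0, wpen)
  model <- affinity_model(
    pwm = prior$pwm,
    coef = c(intercept = theta[[1]], stop = theta[[2]],
             slide = theta[[3]], bend = theta[[4]]),
    dinucleotide = setNames(theta[5:20], .DINUCS),
    sigma = prior$sigma,
    slide_window = prior$slide_window,
    core_length = prior$core_length)
  fitted <- as.vector(X %*% theta)
  calibration <- tibble::tibble(
    gene_id = odns[["gene_id"]] %||% NA_character_,
    rsid = odns[["rsid"]] %||% NA_character_,
    allele_class = odns[["allele_class"]] %||% NA_character_,
    sequence = odns$sequence,
    observed = y, fitted = fitted, residual = fitted - y)
  structure(list(model = model, calibration = calibration,
                 prior = prior, penalty = penalty),
            class = "tbp_affinity_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tbp_affinity_fit <- function(x, ...) {
  cat("<tbp_affinity_fit> calibrated on", nrow(x$calibration), "ODNs\n")
  cat(sprintf("  max |residual| = %.3g ln units\n",
              max(abs(x$calibration$residual))))
  print(x$model)
  invisible(x)
}

#' Leave-one-out residuals of the affinity calibration
#'
#' Repeats the full calibration of [fit_affinity_model()] with each ODN
#' held out in turn and records the prediction error at the held-out
#' point. This is the out-of-sample accuracy of the calibrated model
#' family on the panel.
#'
#' @inheritParams fit_affinity_model
#' @return The calibration tibble with an extra `loo_residual` column.
#' @export
loo_affinity_model <- function(odns = odn_table2(),
                               prior = affinity_model(),
                               penalty = c(coef = 1, dinucleotide = 1)) {
  full <- fit_affinity_model(odns, prior, penalty)
  loo <- vapply(seq_len(nrow(odns)), function(i) {
    f <- fit_affinity_model(odns[-i, ], prior, penalty)
    window_affinity(odns$sequence[i], f$model) - odns$predicted_neglog_kd[i]
  }, numeric(1))
  dplyr::mutate(full$calibration, loo_residual = loo)
}

#' The package's default calibrated affinity model
#'
#' The model returned by [fit_affinity_model()] on the packaged ODN panel,
#' computed once per session and cached. All scoring functions use it when
#' no model is supplied.
#'
#' @return A `tbp_affinity_model`.
#' @export
default_affinity_model <- function() {
  if (is.null(.pkg_env$default_model)) {
    .pkg_env$default_model <- fit_affinity_model()$model
  }
  .pkg_env$default_model
}

#' Read / write an affinity model configuration (YAML)
#'
#' Flat plain-text serialisation of a `tbp_affinity_model`, so a calibrated
#' configuration can be versioned and shared.
#'
#' @param model A `tbp_affinity_model`.
#' @param path File path.
#' @return `write_affinity_model()` returns `path` invisibly;
#'   `read_affinity_model()` returns a `tbp_affinity_model`.
#' @export
write_affinity_model <- function(model, path) {
  payload <- list(
    window_length = model$window_length,
    core_length = model$core_length,
    slide_window = model$slide_window,
    sigma = model$sigma,
    coef = as.list(model$coef),
    dinucleotide = as.list(model$dinucleotide),
    pwm = setNames(lapply(.BASES, function(b) unname(model$pwm[b, ])),
                   .BASES))
  yaml::write_yaml(payload, path, precision = 15L)
  invisible(path)
}

#' @rdname write_affinity_model
#' @export
read_affinity_model <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  p <- yaml::read_yaml(path)
  pwm <- do.call(rbind, p$pwm[.BASES])
  rownames(pwm) <- .BASES
  affinity_model(
    pwm = pwm,
    coef = unlist(p$coef)[c("intercept", "stop", "slide", "bend")],
    dinucleotide = unlist(p$dinucleotide)[.DINUCS],
    sigma = p$sigma,
    slide_window = p$slide_window,
    core_length = p$core_length)
}
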