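#' MAF-dependent scale of an effect-size standard error
#'
#' The standard error of a per-allele log odds ratio (or standardised linear
#' effect) factorises into a sample-size part and an allele-frequency part;
#' `sigma_maf` is the frequency part only, `1 / sqrt(2 f (1 - f))` for
#' alternative-allele frequency `f`. Dividing effect estimates by this scale
#' puts SNPs of different frequency on a common footing without shrinking
#' smaller studies relative to larger ones.
#'
#' @param alt_freq alternative-allele frequency, strictly in (0, 1).
#' @return positive numeric vector, same length as `alt_freq`.
#' @export
sigma_maf <- function(alt_freq) {
  if (any(!is.finite(alt_freq)) || any(alt_freq <= 0) || any(alt_freq >= 1))
    stop_data("allele frequency must lie strictly in (0, 1)")
  1 / sqrt(2 * alt_freq * (1 - alt_freq))
}

#' Wakefield log approximate Bayes factor
#'
#' Asymptotic Bayes factor comparing "this variant is causal" (effect drawn
#' from N(0, W)) against the null, computed from the effect estimate and its
#' standard error alone:
#' `log ABF = 0.5 log(se^2 / (se^2 + W)) + 0.5 z^2 W / (se^2 + W)` with
#' `z = beta / se`. Working in log space avoids overflow for large `z`.
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), positive.
#' @param W prior variance of the causal effect (default `0.2^2`, the
#'   conventional prior standard deviation of 0.2 for log odds ratios).
#' @return numeric vector of log ABFs.
#' @export
log_abf <- function(beta, se, W = 0.04) {
  if (any(se <= 0) || any(!is.finite(se))) stop_data("se must be positive and finite")
  if (W < 0) stop_data("prior variance W must be >= 0")
  z2 <- (beta / se)^2
  r <- W / (se^2 + W)
  0.5 * log1p(-r) + 0.5 * z2 * r
}

#' Single-causal-variant posterior probabilities within one LD block
#'
#' Under the assumption of at most one causal variant per block, the
#' posterior probability that variant `i` is the causal one is the softmax
#' of the log ABFs over the block (computed with log-sum-exp). Optionally a
#' null model ("no causal variant in this block") receives prior mass via
#' `null_odds`, the prior odds of the null against the one-causal-variant
#' hypothesis (with the causal variant uniform over the block); posteriors
#' then sum to less than 1.
#'
#' @param labf numeric vector of log ABFs for the block's variants.
#' @param null_odds `NULL` (default, pure softmax) or a positive prior odds
#'   for the within-block null model.
#' @return numeric vector of posterior probabilities.
#' @export
block_posteriors <- function(labf, null_odds = NULL) {
  if (!length(labf)) stop_data("empty block")
  if (is.null(null_odds)) {
    return(exp(labf - logsumexp(labf)))
  }
  if (null_odds <= 0) stop_data("null_odds must be positive")
  k <- length(labf)
  lnum <- labf - log(k)
  ldenom <- logsumexp(c(lnum, log(null_odds)))
  exp(lnum - ldenom)
}

#' Combine per-study posteriors into one per-variant weight
#'
#' The overall shrinkage weight for a SNP is a weighted average of its
#' posterior probabilities of causality across the input studies; it is
#' close to zero wherever no study shows association in the region, limiting
#' the influence of study-specific technical noise.
#'
#' @param pp matrix of posterior probabilities, studies in rows, variants in
#'   columns.
#' @param study_weights optional non-negative per-study weights (normalised
#'   internally); default equal.
#' @return numeric vector of per-variant weights in `[0, 1]`.
#' @export
combine_weights <- function(pp, study_weights = NULL) {
  pp <- as.matrix(pp)
  sw <- study_weights %||% rep(1, nrow(pp))
  if (length(sw) != nrow(pp))
    stop_data("study_weights length (", length(sw), ") != number of studies (",
              nrow(pp), ")")
  if (any(sw < 0) || sum(sw) == 0) stop_data("study_weights must be non-negative, not all zero")
  sw <- sw / sum(sw)
  as.vector(crossprod(pp, sw))
}

#' Compute shrinkage weights over a shared variant index
#'
#' Runs single-causal-variant fine-mapping per study and LD block, averages
#' the posteriors across studies, and attaches the MAF scale. The result
#' holds everything `shrink()` and basis construction need.
#'
#' @param studies list of panel-aligned `sumstats` sharing an index.
#' @param panel the `ref_panel` the studies are aligned to (provides
#'   `alt_freq` and `block`).
#' @param index optional character vector of variant keys to restrict to
#'   (e.g. the output of [intersect_studies()]); default all panel variants.
#' @param W prior variance of the causal effect, see [log_abf()].
#' @param study_weights see [combine_weights()].
#' @param null_odds see [block_posteriors()].
#' @param keep_pp keep the per-study posterior matrix (memory at scale)?
#' @return an object of class `shrinkage_weights`: list with `index` (keys),
#'   `alt_freq`, `block`, `sigma_maf`, `w`, optional `pp`, and `prior`.
#' @export
compute_shrinkage <- function(studies, panel, index = NULL, W = 0.04,
                              study_weights = NULL, null_odds = NULL,
                              keep_pp = TRUE) {
  stopifnot(inherits(panel, "ref_panel"))
  pv <- panel$variants
  index <- index %||% pv$key
  pidx <- match(index, pv$key)
  if (anyNA(pidx)) stop_data("index contains variants absent from the panel")
  blk <- pv$block[pidx]
  f <- pv$alt_freq[pidx]
  pp <- matrix(NA_real_, nrow = length(studies), ncol = length(index),
               dimnames = list(vapply(studies, `[[`, "", "trait_id"), index))
  for (t in seq_along(studies)) {
    s <- studies[[t]]
    if (!isTRUE(s$aligned)) stop_data("study '", s$trait_id, "' is not panel-aligned")
    m <- match(index, s$snps$key)
    if (anyNA(m)) stop_data("study '", s$trait_id, "' lacks variants of the shared index")
    beta <- s$snps$beta[m]; se <- s$snps$se[m]
    if (anyNA(beta) || anyNA(se))
      stop_data("study '", s$trait_id, "' has missing effects on the shared index")
    labf <- log_abf(beta, se, W)
    for (b in split(seq_along(index), blk)) {
      pp[t, b] <- block_posteriors(labf[b], null_odds = null_odds)
    }
  }
  w <- combine_weights(pp, study_weights)
  structure(list(index = index, alt_freq = f, block = blk,
                 sigma_maf = sigma_maf(f), w = w,
                 pp = if (keep_pp) pp else NULL,
                 prior = list(W = W, null_odds = null_odds,
                              study_weights = study_weights)),
            class = "shrinkage_weights")
}

#' @export
print.shrinkage_weights <- function(x, ...) {
  cat("Shrinkage weights over", length(x$index), "variants; W =", x$prior$W,
      "; mean w =", signif(mean(x$w), 3), "\n")
  invisible(x)
}

#' Transform effect estimates for basis construction or projection
#'
#' Three transforms of a study's effects onto the weights' variant index:
#' \describe{
#'   \item{continuous}{`gamma = w * beta / sigma_maf` — the fine-mapping
#'     shrinkage used throughout.}
#'   \item{naive}{`gamma = beta`, no shrinkage (comparison mode).}
#'   \item{z_threshold}{`gamma = beta / se` when the two-sided normal p-value
#'     is at most 0.001, else 0 (hard-thresholding comparison mode; ties at
#'     exactly p = 0.001 are kept).}
#' }
#' Variants missing from the study yield `NA` here; their resolution (zero
#' fill) belongs to projection.
#'
#' @param ss a panel-aligned `sumstats`.
#' @param weights a `shrinkage_weights`.
#' @param mode one of `"continuous"`, `"naive"`, `"z_threshold"`.
#' @return numeric vector of transformed effects over `weights$index`.
#' @export
shrink <- function(ss, weights, mode = c("continuous", "naive", "z_threshold")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ss, "sumstats"), inherits(weights, "shrinkage_weights"))
  m <- match(weights$index, ss$snps$key)
  if (anyNA(m)) stop_data("study '", ss$trait_id,
                          "' is not aligned to the weights' variant index")
  beta <- ss$snps$beta[m]; se <- ss$snps$se[m]
  switch(mode,
    continuous = weights$w * beta / weights$sigma_maf,
    naive = beta,
    z_threshold = {
      z <- beta / se
      p <- 2 * stats::pnorm(-abs(z))
      ifelse(!is.na(p) & p <= 0.001, z, ifelse(is.na(p), NA_real_, 0))
    })
}
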