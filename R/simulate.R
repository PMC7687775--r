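# Synthetic reference panels and multi-trait GWAS summary statistics with
# known ground truth: shared latent components, block-structured LD,
# sample-size-scaled sampling noise, and study- or cohort-specific
# technical noise.

#' Define a simulation scenario
#'
#' The scenario fixes the generative conditions for a synthetic reference
#' panel and a set of GWAS: block count and size, within-block LD decay,
#' allele frequencies, the number of latent risk components, trait loadings
#' on them, causal-variant density (at most one causal variant per block per
#' component, matching the modelling assumption of the basis method), case
#' and control counts, and technical noise. Effects are parameterised on the
#' standardised-genotype scale; `effect_sd` is the standard deviation of a
#' causal standardised effect, so with the default 10,000 effective samples
#' a typical causal variant reaches `|z|` near 5.
#'
#' @param seed RNG seed (mandatory; every draw is deterministic given it).
#' @param n_snps,n_blocks total SNP count and LD-block count.
#' @param within_block_ld AR(1) decay: `cor(i, j) = rho^|i-j|` within a
#'   block (`"exchangeable"` uses constant `rho` off-diagonal instead).
#' @param ld_type `"ar1"` (default) or `"exchangeable"`.
#' @param freq_range alternative-allele frequencies are drawn uniformly on
#'   this interval, which must lie within (0.01, 0.99).
#' @param n_traits number of diseases.
#' @param n_components number of latent risk components `K`.
#' @param effect_sd standard deviation of a causal standardised effect.
#' @param component_scale length-`K` relative strengths of the components
#'   (default geometric decay 0.8^(k-1), making components separable).
#' @param causal_density fraction of blocks carrying a causal variant per
#'   component.
#' @param n_cases,n_controls per-trait sample sizes (scalar or length
#'   `n_traits`).
#' @param technical_noise_sd standard deviation (standardised scale) of the
#'   study/cohort technical artifact added to every SNP; studies sharing a
#'   cohort label share one artifact vector.
#' @param loadings optional `n_traits x K` loading matrix; generated (QR
#'   orthogonalised Gaussian, scaled) when `NULL`.
#' @param cohorts optional length-`n_traits` cohort labels (default: each
#'   study its own cohort).
#' @param replicates optional data.frame describing additional studies that
#'   replicate a disease's true effects: columns `disease` (index into the
#'   traits), `n_cases`, `n_controls`, optional `cohort` and `label`.
#' @return list of class `sim_scenario`.
#' @export
simulation_scenario <- function(seed,
                                n_snps = 20000, n_blocks = 200,
                                within_block_ld = 0.9,
                                ld_type = c("ar1", "exchangeable"),
                                freq_range = c(0.05, 0.95),
                                n_traits = 10, n_components = 3,
                                effect_sd = 0.05,
                                component_scale = 0.8^(seq_len(n_components) - 1),
                                causal_density = 0.05,
                                n_cases = 5000, n_controls = 5000,
                                technical_noise_sd = 0.002,
                                loadings = NULL, cohorts = NULL,
                                replicates = NULL) {
  if (missing(seed)) stop_data("a seed is mandatory in a simulation scenario")
  ld_type <- match.arg(ld_type)
  stopifnot(n_snps > 0, n_blocks > 0, n_blocks <= n_snps,
            n_traits > 0, n_components > 0,
            within_block_ld >= 0, within_block_ld < 1,
            causal_density > 0, causal_density <= 1,
            length(component_scale) == n_components)
  if (freq_range[1] <= 0.01 || freq_range[2] >= 0.99 ||
      freq_range[1] >= freq_range[2])
    stop_data("freq_range must lie strictly within (0.01, 0.99)")
  if (any(c(n_cases, n_controls) <= 0)) stop_data("sample sizes must be positive")
  structure(list(seed = as.integer(seed), n_snps = as.integer(n_snps),
                 n_blocks = as.integer(n_blocks),
                 within_block_ld = within_block_ld, ld_type = ld_type,
                 freq_range = freq_range, n_traits = as.integer(n_traits),
                 n_components = as.integer(n_components),
                 effect_sd = effect_sd, component_scale = component_scale,
                 causal_density = causal_density,
                 n_cases = rep_len(n_cases, n_traits),
                 n_controls = rep_len(n_controls, n_traits),
                 technical_noise_sd = technical_noise_sd,
                 loadings = loadings, cohorts = cohorts,
                 replicates = replicates),
            class = "sim_scenario")
}

# effective sample size of a case-control study
n_eff <- function(n_cases, n_controls) 4 / (1 / n_cases + 1 / n_controls)

# non-palindromic ordered ref/alt pairs
.allele_pairs <- cbind(ref = c("A", "A", "C", "C", "G", "G", "T", "T"),
                       alt = c("C", "G", "A", "T", "A", "T", "C", "G"))

#' Simulate a reference panel with block-structured LD
#'
#' Variants are laid out on one chromosome in `n_blocks` contiguous blocks
#' of near-equal size; within-block LD is AR(1) (`rho^|i-j|`) or
#' exchangeable, and correlation across blocks is zero. Allele pairs are
#' drawn from the non-palindromic combinations so that harmonisation never
#' discards simulated variants; frequencies are uniform on the scenario's
#' range. Per-block Cholesky factors are cached on the returned object for
#' fast repeated noise generation.
#'
#' @param scenario a `sim_scenario`.
#' @return a `ref_panel` (with an `ld_chol` cache).
#' @export
simulate_panel <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  with_seed(scenario$seed, {
    p <- scenario$n_snps
    sizes <- rep(p %/% scenario$n_blocks, scenario$n_blocks)
    extra <- p - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
    block <- rep(sprintf("b%04d", seq_len(scenario$n_blocks)), sizes)
    pair <- .allele_pairs[sample.int(8, p, replace = TRUE), , drop = FALSE]
    v <- data.table(chr = "1", pos = seq_len(p) * 1000L,
                    ref = pair[, "ref"], alt = pair[, "alt"],
                    alt_freq = stats::runif(p, scenario$freq_range[1],
                                            scenario$freq_range[2]),
                    block = block)
    rho <- scenario$within_block_ld
    ld <- lapply(split(seq_len(p), block), function(ii) {
      s <- length(ii)
      R <- if (scenario$ld_type == "ar1") rho^abs(outer(seq_len(s), seq_len(s), `-`))
           else matrix(rho, s, s) + diag(1 - rho, s)
      keys <- variant_key(v$chr[ii], v$pos[ii], v$ref[ii], v$alt[ii])
      dimnames(R) <- list(keys, keys)
      R
    })
    panel <- reference_panel(v, ld)
    panel$ld_chol <- lapply(panel$ld, chol)
    panel
  })
}

# upper-triangular Cholesky factors of the panel's LD blocks, cached when
# available (simulate_panel attaches them)
panel_chol <- function(panel) {
  if (!is.null(panel$ld_chol)) return(panel$ld_chol)
  if (is.null(panel$ld)) return(NULL)
  lapply(panel$ld, chol)
}

# draw one standardised-scale correlated noise vector over the panel
block_noise <- function(panel, chol_cache = NULL) {
  v <- panel$variants
  x <- stats::rnorm(nrow(v))
  U <- chol_cache %||% panel_chol(panel)
  if (is.null(U)) return(x)
  for (b in names(U)) {
    ii <- which(v$block == b)
    x[ii] <- crossprod(U[[b]], x[ii])
  }
  x
}

# build an already-aligned sumstats object over the panel index
aligned_sumstats <- function(panel, beta, se, trait_id,
                             n_cases = NA, n_controls = NA) {
  v <- panel$variants
  d <- data.table(chr = v$chr, pos = v$pos, ref = v$ref, alt = v$alt,
                  beta = beta, se = se)
  d[, key := v$key]
  structure(list(trait_id = trait_id, snps = d,
                 n_cases = n_cases, n_controls = n_controls,
                 provenance = "simulated", aligned = TRUE),
            class = "sumstats")
}

#' Simulate multi-trait GWAS summary statistics with ground truth
#'
#' True standardised effects are `Lambda %*% t(U)` for a trait-by-component
#' loading matrix `Lambda` and sparse per-component causal patterns `U`
#' (at most one causal SNP per block per component). Marginal (LD-tagged)
#' effects are obtained by multiplying through the within-block correlation;
#' estimates add block-correlated sampling noise scaled by the study's
#' effective sample size, plus a cohort-level technical artifact. Reported
#' effects and standard errors are on the per-allele scale
#' (`beta = beta_std * sigma_maf`, `se = sigma_maf / sqrt(n_eff)`).
#'
#' @param scenario a `sim_scenario`.
#' @param panel the matching `ref_panel` from [simulate_panel()].
#' @return list with `studies` (panel-aligned `sumstats`, diseases first,
#'   then any replicates) and `truth` (loadings, causal patterns, marginal
#'   standardised effects, causal keys, cohort assignment).
#' @export
simulate_traits <- function(scenario, panel) {
  stopifnot(inherits(scenario, "sim_scenario"), inherits(panel, "ref_panel"))
  v <- panel$variants
  p <- nrow(v)
  K <- scenario$n_components
  nt <- scenario$n_traits
  with_seed(scenario$seed + 1L, {
    blocks <- split(seq_len(p), v$block)
    # sparse causal patterns, one SNP per causal block per component
    U <- matrix(0, p, K)
    causal <- vector("list", K)
    for (k in seq_len(K)) {
      nb <- max(1L, stats::rbinom(1, length(blocks), scenario$causal_density))
      chosen <- sample(names(blocks), nb)
      snp <- vapply(chosen, function(b) {
        ii <- blocks[[b]]
        if (length(ii) == 1) ii else sample(ii, 1)
      }, 0L)
      U[snp, k] <- stats::rnorm(nb, 0, scenario$effect_sd)
      causal[[k]] <- v$key[snp]
    }
    # trait loadings: orthogonalised Gaussian columns, scaled so a typical
    # entry is O(1), then by the per-component strengths
    L <- scenario$loadings
    if (is.null(L)) {
      G <- matrix(stats::rnorm(nt * K), nt, K)
      if (K <= nt) {
        # orthogonal columns keep the latent components identifiable
        L <- qr.Q(qr(G)) * sqrt(nt)
      } else {
        L <- G  # more components than traits: no orthogonal choice exists
      }
      L <- sweep(L, 2, scenario$component_scale, `*`)
    }
    stopifnot(nrow(L) == nt, ncol(L) == K)
    # marginal standardised patterns: LD-tag the causal effects
    Um <- U
    if (!is.null(panel$ld)) {
      for (b in names(blocks)) {
        ii <- blocks[[b]]
        if (any(U[ii, ] != 0))
          Um[ii, ] <- panel$ld[[b]] %*% U[ii, , drop = FALSE]
      }
    }
    beta_std_true <- Um %*% t(L)          # p x n_traits
    smaf <- sigma_maf(v$alt_freq)
    Uc <- panel_chol(panel)

    cohorts <- scenario$cohorts %||% paste0("cohort", seq_len(nt))
    rep_tab <- scenario$replicates
    n_rep <- if (is.null(rep_tab)) 0L else nrow(rep_tab)
    all_cohorts <- c(cohorts, if (n_rep) as.character(
      rep_tab$cohort %||% paste0("repcohort", seq_len(n_rep))))
    artifacts <- list()
    for (co in unique(all_cohorts))
      artifacts[[co]] <- stats::rnorm(p, 0, scenario$technical_noise_sd)

    make_study <- function(beta_std, nca, nco, cohort, label) {
      ne <- n_eff(nca, nco)
      noise <- block_noise(panel, Uc) / sqrt(ne)
      bhat_std <- beta_std + noise + artifacts[[cohort]]
      aligned_sumstats(panel, beta = bhat_std * smaf,
                       se = smaf / sqrt(ne), trait_id = label,
                       n_cases = nca, n_controls = nco)
    }
    studies <- vector("list", nt + n_rep)
    labels <- sprintf("trait%02d", seq_len(nt))
    for (t in seq_len(nt))
      studies[[t]] <- make_study(beta_std_true[, t], scenario$n_cases[t],
                                 scenario$n_controls[t], cohorts[t], labels[t])
    if (n_rep) {
      rlab <- as.character(rep_tab$label %||%
                             paste0(labels[rep_tab$disease], "_rep"))
      rco <- as.character(rep_tab$cohort %||% paste0("repcohort", seq_len(n_rep)))
      for (r in seq_len(n_rep)) {
        d <- rep_tab$disease[r]
        studies[[nt + r]] <- make_study(beta_std_true[, d],
                                        rep_tab$n_cases[r], rep_tab$n_controls[r],
                                        rco[r], rlab[r])
      }
      labels <- c(labels, rlab)
    }
    names(studies) <- labels
    list(studies = studies,
         truth = list(loadings = L, patterns = U, marginal_patterns = Um,
                      beta_std = beta_std_true, causal = causal,
                      cohorts = all_cohorts))
  })
}

#' Simulate a null GWAS (no true effects)
#'
#' All true effects are zero; estimates are block-correlated sampling noise
#' with standard errors from the effective sample size. As the sample size
#' grows, estimates and hence projections converge to the synthetic
#' control's exact zero.
#'
#' @param panel a `ref_panel`.
#' @param n_cases,n_controls sample sizes.
#' @param seed RNG seed.
#' @param trait_id study label.
#' @return a panel-aligned `sumstats`.
#' @export
simulate_null_study <- function(panel, n_cases, n_controls, seed,
                                trait_id = "null_study") {
  stopifnot(inherits(panel, "ref_panel"))
  ne <- n_eff(n_cases, n_controls)
  smaf <- sigma_maf(panel$variants$alt_freq)
  with_seed(seed, {
    bhat_std <- block_noise(panel) / sqrt(ne)
    aligned_sumstats(panel, beta = bhat_std * smaf, se = smaf / sqrt(ne),
                     trait_id = trait_id, n_cases = n_cases,
                     n_controls = n_controls)
  })
}

#' Draw genotype dosages consistent with a panel's LD
#'
#' Gaussian dosage model: each individual's dosage at SNP `i` is
#' `2 f_i + sqrt(2 f_i (1 - f_i)) x_i` with `x` block-correlated standard
#' normals, so dosage correlations match the panel's LD matrices in
#' expectation. Useful for validating the panel generator empirically.
#'
#' @param panel a `ref_panel`.
#' @param n number of individuals.
#' @param seed RNG seed.
#' @return `n x p` numeric matrix of dosages.
#' @export
sample_dosages <- function(panel, n, seed) {
  v <- panel$variants
  p <- nrow(v)
  Uc <- panel_chol(panel)
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    if (!is.null(Uc)) {
      for (b in names(Uc)) {
        ii <- which(v$block == b)
        X[, ii] <- X[, ii, drop = FALSE] %*% Uc[[b]]
      }
    }
    sweep(sweep(X, 2, sqrt(2 * v$alt_freq * (1 - v$alt_freq)), `*`),
          2, 2 * v$alt_freq, `+`)
  })
}
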