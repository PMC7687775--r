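# Projection of independent studies into a basis, with LD-aware inference.

# internal: per-variant transformed effect and its coefficient on beta_hat,
# using the weights frozen in the basis; missing variants contribute zero.
gamma_and_coef <- function(basis, beta, se) {
  v <- basis$variants
  switch(basis$mode,
    continuous = {
      a <- v$w / v$sigma_maf
      list(gamma = ifelse(is.na(beta), 0, a * beta), coef = a)
    },
    naive = list(gamma = ifelse(is.na(beta), 0, beta),
                 coef = rep(1, length(beta))),
    z_threshold = {
      p <- 2 * stats::pnorm(-abs(beta / se))
      keep <- !is.na(p) & p <= 0.001
      list(gamma = ifelse(keep, beta / se, 0),
           coef = ifelse(keep, 1 / se, 0))
    },
    stop_data("unknown basis mode: ", basis$mode))
}

# match a study to the basis index, returning beta/se in basis order
match_to_basis <- function(basis, ss) {
  stopifnot(inherits(ss, "sumstats"))
  m <- match(basis$index, ss$snps$key)
  list(beta = ss$snps$beta[m], se = ss$snps$se[m])
}

#' Project a study into basis space
#'
#' Applies the basis' frozen shrinkage transform to the study's harmonised
#' effect estimates and multiplies by the sparse rotation. The result,
#' `delta`, is the difference between the projected study and the projected
#' synthetic control (whose effects are all zero, so the two routes — sparse
#' product of uncentred effects, or difference of centred projections —
#' coincide). Variants absent from the study contribute zero, which biases
#' `delta` towards the null (conservative).
#'
#' @param basis a built `gwas_basis`.
#' @param ss a `sumstats` aligned to the basis index (see [basis_panel()]
#'   and [align_to_panel()]).
#' @param missing_warn warn when the missing fraction exceeds this (default 0.05).
#' @param missing_max error when it exceeds this (default 1 = never).
#' @return list with `delta` (length-m named vector) and `missing_fraction`.
#' @export
project_deltas <- function(basis, ss, missing_warn = 0.05, missing_max = 1) {
  bs <- match_to_basis(basis, ss)
  miss <- mean(is.na(bs$beta))
  if (miss > missing_max)
    stop_data(ss$trait_id, ": ", round(100 * miss, 1),
              "% of basis variants missing (limit ", 100 * missing_max, "%)")
  if (miss > missing_warn)
    warning(ss$trait_id, ": ", round(100 * miss, 1),
            "% of basis variants missing; projection biased towards null",
            call. = FALSE)
  g <- gamma_and_coef(basis, bs$beta, bs$se)
  delta <- drop(crossprod(sparse_rotation(basis), g$gamma))
  names(delta) <- colnames(basis$rotation)
  list(delta = delta, missing_fraction = miss)
}

#' LD-aware covariance of a projected delta vector
#'
#' Treats the projection as a fixed linear score of the study's effect
#' estimates: with per-variant coefficients `a_ik` (sparse rotation times
#' the frozen shrinkage transform), the covariance is
#' `Var(delta)_kl = sum_blocks sum_{i,j in block} a_ik a_jl r_ij se_i se_j`,
#' with correlation across LD blocks treated as zero. Missing variants
#' (coefficient zero) contribute nothing.
#'
#' @param basis a built `gwas_basis`.
#' @param ss the study, aligned to the basis index.
#' @param panel `ref_panel` carrying per-block LD matrices for at least the
#'   blocks containing driver SNPs (required for `ld = "panel"`).
#' @param ld `"panel"` (use within-block correlations) or `"independent"`
#'   (treat all SNPs as uncorrelated; diagonal-LD fallback).
#' @return m x m symmetric covariance matrix.
#' @export
delta_covariance <- function(basis, ss, panel = NULL,
                             ld = c("panel", "independent")) {
  ld <- match.arg(ld)
  bs <- match_to_basis(basis, ss)
  g <- gamma_and_coef(basis, bs$beta, bs$se)
  se <- ifelse(is.na(bs$se), 0, bs$se)
  coef <- ifelse(is.na(bs$beta), 0, g$coef)
  A <- sparse_rotation(basis) * coef        # p x m, rows scaled
  m <- ncol(A)
  if (ld == "independent") {
    V <- crossprod(A * se)
  } else {
    if (is.null(panel) || is.null(panel$ld))
      stop_data("ld = 'panel' requires a panel with LD matrices")
    active <- rowSums(A != 0) > 0 & se > 0
    blocks <- unique(basis$variants$block[active])
    missing_ld <- setdiff(blocks, names(panel$ld))
    if (length(missing_ld))
      stop_data("no LD matrix for block(s) containing driver SNPs: ",
                paste(utils::head(missing_ld, 5), collapse = ", "))
    V <- matrix(0, m, m)
    pk <- panel$variants$key
    for (b in blocks) {
      bi <- which(basis$variants$block == b)
      keys <- basis$index[bi]
      R <- panel$ld[[b]][keys, keys, drop = FALSE]
      s <- se[bi]
      V <- V + crossprod(A[bi, , drop = FALSE], (R * tcrossprod(s)) %*%
                           A[bi, , drop = FALSE])
    }
  }
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(basis$rotation), colnames(basis$rotation))
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) > 0 && min(ev) < max(ev) * 1e-10)
    attr(V, "near_singular") <- TRUE
  V
}

#' Overall chi-square test of a projected trait
#'
#' Tests the null hypothesis that the whole delta vector is zero:
#' `T = delta' V^{-1} delta` referred to a chi-square distribution with
#' degrees of freedom equal to the rank of `V` (a pseudo-inverse is used
#' when `V` is rank-deficient).
#'
#' @param delta length-m vector.
#' @param var_delta m x m covariance, or a length-m vector of variances
#'   (treated as a diagonal covariance).
#' @return list with `chisq`, `df`, `p`.
#' @export
test_overall <- function(delta, var_delta) {
  if (is.null(dim(var_delta))) var_delta <- diag(var_delta, length(delta))
  e <- eigen((var_delta + t(var_delta)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-8
  rank <- sum(pos)
  if (rank == 0) return(list(chisq = 0, df = 0L, p = 1))
  y <- crossprod(e$vectors[, pos, drop = FALSE], delta)
  T <- sum(y^2 / e$values[pos])
  list(chisq = T, df = as.integer(rank),
       p = stats::pchisq(T, df = rank, lower.tail = FALSE))
}

#' Per-component z tests of a projected trait
#'
#' @param delta length-m vector.
#' @param var_delta covariance matrix or vector of variances.
#' @return data.table with columns `component`, `delta`, `var_delta`, `z`, `p`.
#' @export
test_components <- function(delta, var_delta) {
  v <- if (is.null(dim(var_delta))) var_delta else diag(var_delta)
  z <- delta / sqrt(v)
  z[v == 0 & delta == 0] <- 0
  data.table(component = names(delta) %||% paste0("PC", seq_along(delta)),
             delta = as.numeric(delta), var_delta = as.numeric(v),
             z = as.numeric(z), p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjustment within categories
#'
#' Step-up BH FDR adjustment run independently within each level of
#' `groups` (e.g. the broad trait categories a projection batch belongs
#' to), or jointly when `groups` is `NULL`.
#'
#' @param p numeric vector of p-values.
#' @param groups optional vector of category labels, same length as `p`.
#' @return numeric vector of adjusted values.
#' @export
fdr_adjust <- function(p, groups = NULL) {
  if (is.null(groups)) return(stats::p.adjust(p, method = "BH"))
  if (length(groups) != length(p)) stop_data("groups must match p in length")
  out <- rep(NA_real_, length(p))
  for (g in split(seq_along(p), groups)) out[g] <- stats::p.adjust(p[g], "BH")
  out
}

#' Project a study and test it
#'
#' One-stop wrapper: computes `delta`, its LD-aware covariance, the overall
#' chi-square test and per-component z tests. FDR adjustment across a batch
#' of traits is done afterwards with [projection_table()].
#'
#' @inheritParams project_deltas
#' @inheritParams delta_covariance
#' @param category optional label used later for category-wise FDR.
#' @return an object of class `basis_projection`.
#' @export
project_study <- function(basis, ss, panel = NULL,
                          ld = c("panel", "independent"),
                          category = NA_character_,
                          missing_warn = 0.05, missing_max = 1) {
  ld <- match.arg(ld)
  pr <- project_deltas(basis, ss, missing_warn = missing_warn,
                       missing_max = missing_max)
  V <- delta_covariance(basis, ss, panel = panel, ld = ld)
  ov <- test_overall(pr$delta, V)
  comp <- test_components(pr$delta, V)
  structure(list(trait_id = ss$trait_id, category = category,
                 delta = pr$delta, var_delta = V,
                 z = stats::setNames(comp$z, comp$component),
                 p_component = stats::setNames(comp$p, comp$component),
                 chisq = ov$chisq, df = ov$df, p_overall = ov$p,
                 missing_fraction = pr$missing_fraction),
            class = "basis_projection")
}

#' @export
print.basis_projection <- function(x, ...) {
  cat("Projection of '", x$trait_id, "': chi-square ", signif(x$chisq, 4),
      " (df ", x$df, "), p = ", format.pval(x$p_overall), "\n", sep = "")
  invisible(x)
}

#' Long results table for a batch of projections, with FDR
#'
#' One row per trait and component, mirroring the per-component delta,
#' its variance and z/p, plus the overall chi-square p-value. FDR columns
#' are computed by Benjamini-Hochberg independently within each trait
#' category: `fdr.overall` across traits (one p per trait), `fdr.delta`
#' across traits within each component separately.
#'
#' @param projections list of `basis_projection` objects.
#' @return data.table with columns `trait`, `category`, `component`,
#'   `delta`, `var.delta`, `z`, `p.delta`, `fdr.delta`, `p.overall`,
#'   `fdr.overall`.
#' @export
projection_table <- function(projections) {
  stopifnot(length(projections) > 0)
  tab <- rbindlist(lapply(projections, function(pr) {
    data.table(trait = pr$trait_id, category = pr$category,
               component = names(pr$delta), delta = as.numeric(pr$delta),
               var.delta = diag(pr$var_delta), z = as.numeric(pr$z),
               p.delta = as.numeric(pr$p_component),
               p.overall = pr$p_overall)
  }))
  ids <- vapply(projections, `[[`, "", "trait_id")
  if (anyDuplicated(ids)) stop_data("duplicate trait ids among projections")
  ov <- unique(tab[, .(trait, category, p.overall)])
  ov[, fdr.overall := fdr_adjust(p.overall, groups = category)]
  tab <- merge(tab, ov[, .(trait, fdr.overall)], by = "trait", sort = FALSE)
  tab[, fdr.delta := fdr_adjust(p.delta, groups = paste(category, component)),
      by = NULL]
  setcolorder(tab, c("trait", "category", "component", "delta", "var.delta",
                     "z", "p.delta", "fdr.delta", "p.overall", "fdr.overall"))
  tab[]
}

#' Flag significant traits and trait-component pairs
#'
#' A trait is overall-significant when its overall FDR is strictly below
#' `overall_fdr`; a trait-component pair is component-significant when the
#' trait is overall-significant *and* the component FDR is strictly below
#' `component_fdr` (conjunction rule; equality is not flagged).
#'
#' @param tab output of [projection_table()].
#' @param overall_fdr,component_fdr thresholds (default 0.01 each).
#' @return the table with logical columns `overall_significant` and
#'   `component_significant` added.
#' @export
flag_significant <- function(tab, overall_fdr = 0.01, component_fdr = 0.01) {
  tab <- copy(as.data.table(tab))
  tab[, overall_significant := fdr.overall < overall_fdr]
  tab[, component_significant := overall_significant & fdr.delta < component_fdr]
  tab[]
}
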