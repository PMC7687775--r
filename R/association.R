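# Downstream analyses of projected traits: consistency testing,
# subset-selected FDR over driver SNPs, and trait clustering.

#' Weighted Spearman rank correlation
#'
#' Both vectors are converted to ranks (average ranks for ties) and a
#' weighted Pearson correlation is computed on the ranks with the supplied
#' non-negative weights. With equal weights this reduces exactly to the
#' ordinary Spearman correlation.
#'
#' @param x,y numeric vectors of equal length.
#' @param w non-negative weights, not all zero.
#' @return correlation in `[-1, 1]`.
#' @export
weighted_spearman <- function(x, y, w = rep(1, length(x))) {
  if (length(x) != length(y) || length(x) != length(w))
    stop_data("x, y, w must have equal length")
  if (any(w < 0) || sum(w) == 0) stop_data("weights must be non-negative, not all zero")
  rx <- rank(x); ry <- rank(y)
  weighted_pearson(rx, ry, w)
}

weighted_pearson <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  cov <- sum(w * (x - mx) * (y - my))
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0) stop_data("zero variance in weighted correlation")
  cov / sqrt(vx * vy)
}

# squared correlation between variant `key` and each of `kept` (same block
# assumed handled by caller); missing LD treated as uncorrelated
block_r2 <- function(panel, block, key, kept) {
  if (is.null(panel$ld) || !block %in% names(panel$ld)) return(rep(0, length(kept)))
  as.numeric(panel$ld[[block]][key, kept])^2
}

# greedy LD pruning: iterate keys in priority order, keep a key when its r2
# with every previously kept key (necessarily same-block; cross-block r = 0)
# satisfies the threshold. strict = TRUE keeps only r2 < threshold,
# strict = FALSE keeps r2 <= threshold.
greedy_ld_prune <- function(keys, blocks, panel, r2, strict = TRUE) {
  keep <- logical(length(keys))
  kept_by_block <- list()
  for (i in seq_along(keys)) {
    b <- blocks[i]
    prev <- kept_by_block[[b]]
    ok <- if (is.null(prev)) TRUE else {
      r2s <- block_r2(panel, b, keys[i], prev)
      if (strict) all(r2s < r2) else all(r2s <= r2)
    }
    if (ok) {
      keep[i] <- TRUE
      kept_by_block[[b]] <- c(prev, keys[i])
    }
  }
  keep
}

#' Consistency test of a projection on one component
#'
#' A significant projection should reflect many small effects acting in
#' consistent directions, not a chance overlap between one heavily-weighted
#' driver SNP and one large trait effect. This test prunes the component's
#' driver SNPs to low pairwise LD (r-squared below `r2_max`, greedily in
#' decreasing order of rotation weight), computes the weighted Spearman
#' correlation between the study's transformed effects and the rotation
#' entries (weights `w / sigma_maf`), and assesses significance by
#' permutation of the study's values.
#'
#' @param ss the projected study, aligned to the basis index.
#' @param basis a built `gwas_basis`.
#' @param k component (number or `"PCk"` name).
#' @param panel `ref_panel` with LD matrices for pruning.
#' @param r2_max LD pruning threshold (default 0.01).
#' @param n_perm number of permutations (default 10,000).
#' @param seed RNG seed for the permutations (mandatory, for reproducibility).
#' @return list of class `consistency_result`: `trait_id`, `component`,
#'   `rho`, `p_perm`, `n_snps`, `n_perm`.
#' @export
consistency_test <- function(ss, basis, k, panel, r2_max = 0.01,
                             n_perm = 10000, seed) {
  if (missing(seed)) stop_data("a permutation seed is required")
  if (is.character(k)) k <- match(k, colnames(basis$rotation))
  if (is.na(k) || k < 1 || k > basis$m) stop_data("no such component")
  drv <- which(basis$driver[, k])
  if (!length(drv)) stop_data("component has no driver SNPs")
  ord <- drv[order(-abs(basis$rotation[drv, k]))]
  keep <- greedy_ld_prune(basis$index[ord], basis$variants$block[ord],
                          panel, r2 = r2_max, strict = TRUE)
  idx <- ord[keep]
  bs <- match_to_basis(basis, ss)
  present <- !is.na(bs$beta[idx])
  idx <- idx[present]
  if (length(idx) < 3)
    stop_data("fewer than 3 pruned driver SNPs available; correlation meaningless")
  g <- gamma_and_coef(basis, bs$beta, bs$se)
  x <- g$gamma[idx]
  y <- basis$rotation[idx, k]
  wts <- basis$variants$w[idx] / basis$variants$sigma_maf[idx]
  if (all(wts == 0)) wts <- rep(1, length(idx))
  rho <- weighted_spearman(x, y, wts)
  rx <- rank(x); ry <- rank(y)
  exceed <- with_seed(seed, {
    n_ex <- 0L
    for (i in seq_len(n_perm)) {
      rp <- weighted_pearson(rx[sample.int(length(rx))], ry, wts)
      if (abs(rp) >= abs(rho)) n_ex <- n_ex + 1L
    }
    n_ex
  })
  structure(list(trait_id = ss$trait_id,
                 component = colnames(basis$rotation)[k],
                 rho = rho, p_perm = (1 + exceed) / (n_perm + 1),
                 n_snps = length(idx), n_perm = n_perm),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  cat("Consistency of '", x$trait_id, "' on ", x$component, ": rho = ",
      signif(x$rho, 3), ", permutation p = ", signif(x$p_perm, 3),
      " (", x$n_snps, " pruned driver SNPs)\n", sep = "")
  invisible(x)
}

#' Subset-selected FDR over driver SNPs of significant components
#'
#' Restricting attention to the driver SNPs of a trait's significant
#' components shrinks the multiple-testing burden relative to a genome-wide
#' scan. GWAS p-values (two-sided normal, from `beta/se`) are computed at
#' the union of those driver SNPs and Benjamini-Hochberg adjusted within
#' this subset only ("subset-selected" FDR). SNPs are then ordered by
#' increasing ssFDR (ties broken by smaller p, then by variant key) and any
#' SNP in LD (r-squared above `r2_prune`) with a higher-placed SNP is marked
#' pruned.
#'
#' @param ss the trait's summary statistics, aligned to the basis index.
#' @param basis a built `gwas_basis`.
#' @param significant_components component names or numbers significant for
#'   this trait.
#' @param panel optional `ref_panel` with LD matrices; without it no
#'   pruning is possible and all SNPs are retained.
#' @param r2_prune LD pruning threshold (default 0.1); SNPs with r-squared
#'   strictly above it relative to a higher-placed SNP are pruned.
#' @return data.table with one row per driver SNP present in the study:
#'   variant fields, `components`, `p_gwas`, `ssfdr`, `pruned`; ordered by
#'   increasing ssFDR.
#' @export
subset_selected_fdr <- function(ss, basis, significant_components,
                                panel = NULL, r2_prune = 0.1) {
  if (!length(significant_components)) stop_data("no significant components given")
  ks <- significant_components
  if (is.character(ks)) ks <- match(ks, colnames(basis$rotation))
  if (anyNA(ks)) stop_data("unknown component name(s)")
  drv <- rowSums(basis$driver[, ks, drop = FALSE]) > 0
  idx <- which(drv)
  comps <- apply(basis$driver[idx, ks, drop = FALSE], 1, function(r)
    paste(colnames(basis$rotation)[ks][r], collapse = ","))
  bs <- match_to_basis(basis, ss)
  present <- !is.na(bs$beta[idx])
  idx <- idx[present]; comps <- comps[present]
  if (!length(idx)) stop_data("no driver SNP of the significant components is present in the study")
  z <- bs$beta[idx] / bs$se[idx]
  p <- 2 * stats::pnorm(-abs(z))
  ssfdr <- stats::p.adjust(p, method = "BH")
  v <- basis$variants[idx]
  out <- data.table(chr = v$chr, pos = v$pos,
                    ref = v$ref, alt = v$alt, block = v$block,
                    components = comps, p_gwas = p, ssfdr = ssfdr)
  out[, key := basis$index[idx]]
  setcolorder(out, "key")
  setorder(out, ssfdr, p_gwas, key)
  keep <- greedy_ld_prune(out$key, out$block, panel %||% list(ld = NULL),
                          r2 = r2_prune, strict = FALSE)
  out[, pruned := !keep]
  out[]
}

#' Hierarchical clustering of projected traits
#'
#' Agglomerative clustering of the traits' delta vectors using Euclidean
#' distance and, by default, Ward's criterion in its squared-distance form
#' (`"ward.D2"`). Ties are resolved deterministically by input order. The
#' dendrogram is also rendered as Newick text.
#'
#' @param projections list of `basis_projection` objects, or a numeric
#'   matrix with one row per trait (rownames = trait ids).
#' @param subset optional component names/indices to cluster on.
#' @param method linkage method passed to [stats::hclust()].
#' @return list with `hclust` (the tree), `newick` (character), and
#'   `merges` (data.table of merge heights).
#' @export
cluster_traits <- function(projections, subset = NULL, method = "ward.D2") {
  X <- if (is.matrix(projections)) projections
       else do.call(rbind, lapply(projections, function(p) p$delta))
  if (!is.matrix(X) || nrow(X) < 2) stop_data("need at least 2 traits to cluster")
  if (is.null(rownames(X)) && !is.matrix(projections))
    rownames(X) <- vapply(projections, `[[`, "", "trait_id")
  if (is.null(rownames(X))) stop_data("trait matrix must have rownames")
  if (anyDuplicated(rownames(X)))
    stop_data("duplicate trait ids: ",
              paste(unique(rownames(X)[duplicated(rownames(X))]), collapse = ", "))
  if (!is.null(subset)) X <- X[, subset, drop = FALSE]
  hc <- stats::hclust(stats::dist(X), method = method)
  nwk <- ape::write.tree(ape::as.phylo(hc))
  merges <- data.table(step = seq_len(nrow(hc$merge)),
                       left = hc$merge[, 1], right = hc$merge[, 2],
                       height = hc$height)
  list(hclust = hc, newick = nwk, merges = merges)
}
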