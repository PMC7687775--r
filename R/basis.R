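#' Assemble the trait-by-SNP effect matrix, with synthetic control
#'
#' Stacks the transformed effects of the training studies over their shared
#' variant index and appends a synthetic control trait whose effects are all
#' zero — the limit of a null GWAS as the sample size tends to infinity,
#' which anchors the origin of the basis space.
#'
#' @param studies list of panel-aligned `sumstats` covering the weights'
#'   shared index.
#' @param weights a `shrinkage_weights` over that index.
#' @param mode transform mode, see [shrink()].
#' @param control_label row label for the synthetic control.
#' @return an `effect_matrix`: list with `traits`, `values` (traits x SNPs),
#'   `index` and `mode`.
#' @export
assemble_effect_matrix <- function(studies, weights,
                                   mode = c("continuous", "naive", "z_threshold"),
                                   control_label = "control") {
  mode <- match.arg(mode)
  ids <- vapply(studies, `[[`, "", "trait_id")
  if (anyDuplicated(ids)) stop_data("duplicate trait ids among studies")
  if (control_label %in% ids)
    stop_data("control label '", control_label, "' collides with a trait id")
  vals <- t(vapply(studies, shrink, numeric(length(weights$index)),
                   weights = weights, mode = mode))
  if (anyNA(vals))
    stop_data("missing transformed effects; studies must cover the shared index")
  vals <- rbind(vals, 0)
  rownames(vals) <- c(ids, control_label)
  colnames(vals) <- weights$index
  structure(list(traits = rownames(vals), values = vals,
                 index = weights$index, mode = mode,
                 control = control_label),
            class = "effect_matrix")
}

#' Fit the mean-centred PCA decomposition of an effect matrix
#'
#' Columns are mean-centred (no variance scaling) and decomposed by thin
#' SVD. The sign of each rotation column is fixed so that its entry of
#' largest absolute value is positive; PCA signs are otherwise arbitrary
#' and would break serialisation and regression tests.
#'
#' @param M an `effect_matrix`.
#' @return a `gwas_basis` (untrimmed: all `min(n, p)` components retained,
#'   no sparsification yet).
#' @export
fit_basis <- function(M) {
  stopifnot(inherits(M, "effect_matrix"))
  X <- M$values
  n <- nrow(X)
  if (n < 3) stop_data("need at least 3 rows (traits + control) for PCA")
  if (all(X == 0)) stop_data("effect matrix is identically zero")
  col_means <- colMeans(X)
  Xc <- sweep(X, 2, col_means)
  sv <- svd(Xc, nu = min(n, ncol(X)), nv = min(n, ncol(X)))
  rot <- sv$v
  # deterministic sign: largest-|entry| coefficient positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- Xc %*% rot
  colnames(rot) <- colnames(scores) <- paste0("PC", seq_len(ncol(rot)))
  rownames(scores) <- M$traits
  rownames(rot) <- M$index
  structure(list(traits = M$traits, control = M$control, mode = M$mode,
                 index = M$index, col_means = col_means,
                 rotation = rot, scores = scores, d = sv$d[seq_len(ncol(rot))],
                 m = ncol(rot), alpha = NULL, driver = NULL, tol = NULL,
                 variants = NULL, prior = NULL, version = basis_format_version()),
            class = "gwas_basis")
}

basis_format_version <- function() "1"

#' @export
print.gwas_basis <- function(x, ...) {
  cat("GWAS basis:", length(x$traits) - 1, "traits + control,",
      length(x$index), "SNPs,", x$m, "components (mode:", x$mode,
      if (!is.null(x$alpha)) ", sparsified", ")\n")
  invisible(x)
}

#' Select the informative rank by mean squared reconstruction error
#'
#' For each truncation rank the mean squared error between the centred
#' matrix and its rank-limited reconstruction is computed; the smallest rank
#' attaining the minimum (within an absolute tolerance of 1e-12, so that a
#' numerically-zero trailing component is never retained) is returned.
#' For a generic mean-centred matrix of `n` rows this is `n - 1`: centring
#' removes one degree of freedom, so the final component carries no signal.
#'
#' @param M the `effect_matrix` the basis was fitted to.
#' @param basis the fitted `gwas_basis`.
#' @return integer rank.
#' @export
select_rank <- function(M, basis) {
  stopifnot(inherits(basis, "gwas_basis"))
  d2 <- basis$d^2
  np <- nrow(M$values) * ncol(M$values)
  # MSE after keeping the first m' components = sum of remaining d^2 / (n p)
  mse <- rev(cumsum(rev(c(d2[-1], 0)))) / np
  which(mse <= min(mse) + 1e-12)[1]
}

#' Sparsify rotation columns and identify driver SNPs
#'
#' For each retained component `k`, rotation entries with absolute value at
#' or below a threshold `alpha_k` are zeroed. The threshold is the largest
#' value on the (exact, finite) grid of sorted distinct absolute rotation
#' entries such that the distortion
#' `D_k(alpha) = 1 - cor(Mc Q_k, Mc Q_k(alpha))` — the loss of correlation
#' between training-trait projections through the full and the thresholded
#' column — stays below `tol`. The grid is scanned exhaustively, so a
#' locally non-monotone `D_k` cannot mislead the search. SNPs surviving the
#' mask are the component's driver SNPs.
#'
#' @param basis a fitted (rank-trimmed) `gwas_basis`.
#' @param M the training `effect_matrix`.
#' @param tol distortion tolerance, in (0, 1); default 0.001.
#' @return the basis with `alpha`, `driver` (logical SNP x component matrix)
#'   and `distortion` filled in.
#' @export
sparsify_basis <- function(basis, M, tol = 0.001) {
  stopifnot(inherits(basis, "gwas_basis"), inherits(M, "effect_matrix"))
  if (tol <= 0 || tol >= 1) stop_data("tol must lie in (0, 1)")
  Xc <- sweep(M$values, 2, basis$col_means)
  p <- length(basis$index)
  alpha <- numeric(basis$m)
  dist_at_alpha <- numeric(basis$m)
  driver <- matrix(FALSE, p, basis$m,
                   dimnames = list(basis$index, colnames(basis$rotation)))
  for (k in seq_len(basis$m)) {
    q <- basis$rotation[, k]
    aq <- abs(q)
    proj_full <- Xc %*% q
    if (stats::sd(proj_full) == 0)
      stop_data("component ", k, " has zero-variance training projection")
    ord <- order(aq)
    # cumulative projection lost when zeroing entries in ascending |q| order
    contrib <- Xc[, ord, drop = FALSE] *
      matrix(q[ord], nrow(Xc), p, byrow = TRUE)
    cum <- t(apply(contrib, 1, cumsum))
    aso <- aq[ord]
    # candidate alphas: the distinct |q| values except the maximum (masking
    # at the maximum would zero the whole column); boundary index = last
    # position carrying each distinct value
    bound <- which(aso < c(aso[-1], Inf))
    bound <- bound[bound < p]
    Dk <- vapply(bound, function(j) {
      masked <- proj_full - cum[, j]
      if (stats::sd(masked) == 0) return(Inf)
      1 - stats::cor(proj_full, masked)[1]
    }, 0)
    ok <- which(Dk < tol)
    if (length(ok)) {
      j <- bound[max(ok)]
      alpha[k] <- aso[j]
      dist_at_alpha[k] <- Dk[max(ok)]
    } else {
      alpha[k] <- 0
      dist_at_alpha[k] <- 0
    }
    driver[, k] <- aq > alpha[k]
  }
  basis$alpha <- alpha
  basis$driver <- driver
  basis$distortion <- dist_at_alpha
  basis$tol <- tol
  basis
}

#' Sparse rotation matrix of a basis
#'
#' The rotation with entries outside the driver sets set to exact zero.
#' @param basis a sparsified `gwas_basis`.
#' @return p x m numeric matrix.
#' @export
sparse_rotation <- function(basis) {
  if (is.null(basis$driver)) stop_data("basis has not been sparsified")
  basis$rotation * basis$driver
}

#' Driver SNPs of one component
#' @param basis a sparsified `gwas_basis`.
#' @param k component number.
#' @return character vector of variant keys.
#' @export
driver_snps <- function(basis, k) {
  if (is.null(basis$driver)) stop_data("basis has not been sparsified")
  basis$index[basis$driver[, k]]
}

#' Build a basis end to end
#'
#' Convenience orchestrator: assemble the effect matrix (with synthetic
#' control), fit the mean-centred PCA, select the informative rank by
#' reconstruction error, trim, and sparsify. The shrinkage weights and the
#' variant metadata are frozen into the returned basis so that projection of
#' later studies reuses exactly the training transform.
#'
#' @inheritParams assemble_effect_matrix
#' @param panel the `ref_panel` behind the weights (variant metadata).
#' @param tol sparsification tolerance, see [sparsify_basis()].
#' @return a sparsified, rank-trimmed `gwas_basis`.
#' @export
build_basis <- function(studies, weights, panel,
                        mode = c("continuous", "naive", "z_threshold"),
                        tol = 0.001, control_label = "control") {
  mode <- match.arg(mode)
  M <- assemble_effect_matrix(studies, weights, mode = mode,
                              control_label = control_label)
  b <- fit_basis(M)
  m <- select_rank(M, b)
  b$rotation <- b$rotation[, seq_len(m), drop = FALSE]
  b$scores <- b$scores[, seq_len(m), drop = FALSE]
  b$d <- b$d[seq_len(m)]
  b$m <- m
  b <- sparsify_basis(b, M, tol = tol)
  pv <- panel$variants[match(b$index, panel$variants$key)]
  bv <- data.table(chr = pv$chr, pos = pv$pos, ref = pv$ref,
                   alt = pv$alt, alt_freq = pv$alt_freq,
                   block = pv$block, sigma_maf = weights$sigma_maf,
                   w = weights$w, col_means = unname(b$col_means))
  bv[, key := b$index]
  b$variants <- bv
  b$prior <- weights$prior
  b
}

#' Reference-panel view of a basis' variant table
#'
#' Builds a `ref_panel` from the variant metadata frozen in a basis, so that
#' new studies can be aligned to the basis index with [align_to_panel()].
#' @param basis a `gwas_basis` built with [build_basis()] (or loaded).
#' @param ld optional per-block LD matrices to attach.
#' @return a `ref_panel`.
#' @export
basis_panel <- function(basis, ld = NULL) {
  if (is.null(basis$variants)) stop_data("basis carries no variant metadata")
  reference_panel(basis$variants[, .(chr, pos, ref, alt, alt_freq, block)], ld)
}

#' Save a basis to a directory of plain-text files
#'
#' Writes a versioned container: `manifest.json` (traits, mode, tolerance,
#' prior, thresholds, file checksums) plus TSVs for the variant table (with
#' centring vector, shrinkage weights) and the rotation and score matrices.
#' All numbers are serialised with 17 significant digits so that
#' save -> load -> save is byte-identical and projections through a loaded
#' basis match the in-memory one exactly.
#'
#' @param basis a sparsified `gwas_basis`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_basis <- function(basis, path) {
  if (is.null(basis$driver) || is.null(basis$variants))
    stop_data("only a fully built basis (build_basis) can be saved")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  v <- basis$variants
  vt <- data.table(chr = v$chr, pos = v$pos, ref = v$ref, alt = v$alt,
                   alt_freq = num_chr(v$alt_freq), block = v$block,
                   sigma_maf = num_chr(v$sigma_maf), w = num_chr(v$w),
                   col_means = num_chr(v$col_means))
  fwrite(vt, file.path(path, "variants.tsv"), sep = "\t")
  rot <- as.data.table(apply(basis$rotation, 2, num_chr))
  fwrite(rot, file.path(path, "rotation.tsv"), sep = "\t")
  sc <- as.data.table(apply(basis$scores, 2, num_chr))
  sc <- cbind(data.table(trait = basis$traits), sc)
  fwrite(sc, file.path(path, "scores.tsv"), sep = "\t")
  files <- c("variants.tsv", "rotation.tsv", "scores.tsv")
  sums <- as.list(tools::md5sum(file.path(path, files)))
  names(sums) <- files
  manifest <- list(
    format_version = basis_format_version(),
    traits = basis$traits, control = basis$control, mode = basis$mode,
    m = basis$m, tol = num_chr(basis$tol),
    alpha = num_chr(basis$alpha), distortion = num_chr(basis$distortion),
    d = num_chr(basis$d),
    prior = list(W = num_chr(basis$prior$W %||% NA_real_),
                 null_odds = if (is.null(basis$prior$null_odds)) NULL
                             else num_chr(basis$prior$null_odds)),
    checksums = sums)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              null = "null"),
             file.path(path, "manifest.json"))
  invisible(path)
}

#' Load a basis saved by [save_basis()]
#'
#' @param path directory written by [save_basis()].
#' @return a `gwas_basis`.
#' @export
load_basis <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop_data("no manifest.json under ", path)
  manifest <- jsonlite::fromJSON(mf)
  if (!identical(manifest$format_version, basis_format_version()))
    stop_data("basis format version mismatch: found '",
              manifest$format_version, "', expected '",
              basis_format_version(), "'")
  for (f in names(manifest$checksums)) {
    got <- unname(tools::md5sum(file.path(path, f)))
    if (!identical(got, unname(manifest$checksums[[f]])))
      stop_data("checksum mismatch for ", f, " under ", path)
  }
  v <- fread(file.path(path, "variants.tsv"),
             colClasses = list(character = c("chr", "ref", "alt", "block")))
  v[, key := variant_key(chr, pos, ref, alt)]
  rot <- as.matrix(fread(file.path(path, "rotation.tsv")))
  sc <- fread(file.path(path, "scores.tsv"))
  traits <- sc$trait
  scores <- as.matrix(sc[, !"trait"])
  rownames(scores) <- traits
  rownames(rot) <- v$key
  alpha <- as.numeric(manifest$alpha)
  driver <- sweep(abs(rot), 2, alpha, `>`)
  b <- structure(list(
    traits = traits, control = manifest$control, mode = manifest$mode,
    index = v$key, col_means = stats::setNames(v$col_means, v$key),
    rotation = rot, scores = scores, d = as.numeric(manifest$d),
    m = manifest$m, alpha = alpha, driver = driver,
    distortion = as.numeric(manifest$distortion),
    tol = as.numeric(manifest$tol),
    variants = v[],
    prior = list(W = as.numeric(manifest$prior$W),
                 null_odds = if (is.null(manifest$prior$null_odds)) NULL
                             else as.numeric(manifest$prior$null_odds)),
    version = manifest$format_version), class = "gwas_basis")
  b
}
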