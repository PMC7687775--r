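test_that("weighted Spearman reduces to Spearman under equal weights", {
  set.seed(6)
  for (i in 1:5) {
    x <- rnorm(40); y <- x + rnorm(40)
    expect_equal(weighted_spearman(x, y),
                 stats::cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
  # perfect monotone agreement
  x <- rnorm(20)
  expect_equal(weighted_spearman(x, exp(x), runif(20)), 1, tolerance = 1e-12)
  expect_equal(weighted_spearman(x, -x, runif(20)), -1, tolerance = 1e-12)
  expect_error(weighted_spearman(1:3, 1:2), "equal length")
  expect_error(weighted_spearman(1:3, 1:3, c(0, 0, 0)), "not all zero")
})

test_that("the consistency test detects coherent projections and is reproducible", {
  fx <- small_sim()
  b <- fx$basis
  rep1 <- small_replicate()
  ks <- which(colSums(b$driver) >= 30)
  k <- ks[length(ks)]
  r1 <- consistency_test(rep1, b, k, fx$panel, n_perm = 500, seed = 11)
  r2 <- consistency_test(rep1, b, k, fx$panel, n_perm = 500, seed = 11)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_gte(r1$p_perm, 1 / 501)
  expect_lte(r1$p_perm, 1)
  expect_lte(abs(r1$rho), 1)
  # pruned SNPs are in low LD by construction: counts shrink vs the raw set
  expect_lt(r1$n_snps, sum(b$driver[, k]))
  # a study whose effects are the rotation column itself is perfectly consistent
  ideal <- panel_sumstats(fx$panel,
                          beta = b$rotation[, k] * b$variants$sigma_maf /
                            pmax(b$variants$w, 1e-6),
                          se = rep(0.01, 2000), "ideal")
  ri <- consistency_test(ideal, b, k, fx$panel, n_perm = 200, seed = 2)
  expect_equal(ri$rho, 1, tolerance = 1e-9)
  expect_equal(ri$p_perm, 1 / 201)
  # fewer than 3 pruned driver SNPs is an explicit error
  bclip <- b
  bclip$driver[, k] <- FALSE
  bclip$driver[which(b$driver[, k])[1:2], k] <- TRUE
  expect_error(consistency_test(rep1, bclip, k, fx$panel, n_perm = 99, seed = 1),
               "fewer than 3")
  expect_error(consistency_test(rep1, b, k, fx$panel, n_perm = 99), "seed")
})

test_that("subset-selected FDR works on crafted LD structures", {
  # one block of two tightly linked SNPs (r^2 = 0.9) plus one independent SNP
  v <- data.frame(chr = "1", pos = c(100L, 200L, 900L), ref = "A",
                  alt = c("G", "C", "G"), alt_freq = c(0.3, 0.3, 0.2),
                  block = c("b1", "b1", "b2"))
  keys <- paste(v$chr, v$pos, v$ref, v$alt, sep = ":")
  R <- matrix(c(1, sqrt(0.9), sqrt(0.9), 1), 2,
              dimnames = list(keys[1:2], keys[1:2]))
  panel <- reference_panel(v, ld = list(b1 = R))
  # minimal handmade basis over these 3 SNPs
  rot <- matrix(c(0.8, 0.5, 0.33), 3, 1, dimnames = list(keys, "PC1"))
  basis <- structure(list(
    traits = c("t", "control"), control = "control", mode = "continuous",
    index = keys, col_means = rep(0, 3), rotation = rot,
    scores = matrix(0, 2, 1), d = 1, m = 1L, alpha = 0.1,
    driver = matrix(TRUE, 3, 1, dimnames = list(keys, "PC1")),
    distortion = 0, tol = 0.001,
    variants = local({
      vt <- data.table::data.table(
        chr = v$chr, pos = v$pos, ref = v$ref, alt = v$alt,
        alt_freq = v$alt_freq, block = v$block,
        sigma_maf = sigma_maf(v$alt_freq), w = c(0.9, 0.8, 0.5),
        col_means = 0)
      vt[, key := keys][]
    }),
    prior = list(W = 0.04)), class = "gwas_basis")
  ss <- panel_sumstats(panel, beta = c(0.5, 0.45, 0.1),
                       se = c(0.1, 0.1, 0.1), "s")
  hits <- subset_selected_fdr(ss, basis, "PC1", panel = panel)
  expect_equal(nrow(hits), 3)
  # BH within the subset: check against p.adjust on the same three p-values
  p <- 2 * pnorm(-abs(c(5, 4.5, 1)))
  expect_equal(hits$ssfdr, sort(stats::p.adjust(p, "BH")))
  # the weaker of the two linked SNPs is pruned, the independent one kept
  expect_equal(hits$pruned, c(FALSE, TRUE, FALSE))
  # single-SNP subset: ssFDR equals the raw p-value
  b1 <- basis
  b1$driver[2:3, 1] <- FALSE
  h1 <- subset_selected_fdr(ss, b1, "PC1", panel = panel)
  expect_equal(h1$ssfdr, h1$p_gwas)
  expect_error(subset_selected_fdr(ss, basis, character(0)), "no significant")
  expect_error(subset_selected_fdr(ss, basis, "PC9"), "unknown")
})

test_that("subset-selected FDR output is order-invariant up to documented tie-breaks", {
  fx <- small_sim()
  b <- fx$basis
  rep1 <- small_replicate()
  ks <- colnames(b$rotation)[colSums(b$driver) >= 20][1:2]
  h1 <- subset_selected_fdr(rep1, b, ks, panel = fx$panel)
  h2 <- subset_selected_fdr(rep1, b, rev(ks), panel = fx$panel)
  expect_equal(h1$key, h2$key)
  expect_equal(h1$pruned, h2$pruned)
})

test_that("null traits rarely clear the subset-selected FDR threshold", {
  fx <- small_sim()
  b <- fx$basis
  ks <- colnames(b$rotation)[which.max(colSums(b$driver))]
  nhits <- sapply(1:30, function(s) {
    ns <- simulate_null_study(fx$panel, 2000, 2000, seed = 3000 + s)
    h <- subset_selected_fdr(ns, b, ks, panel = fx$panel)
    # hits are LD-pruned, as reported
    sum(h$ssfdr < 0.01 & !h$pruned)
  })
  expect_lt(mean(nhits), 0.05)
})

test_that("trait clustering matches a brute-force Ward.D2 oracle", {
  set.seed(13)
  for (i in 1:3) {
    X <- matrix(rnorm(7 * 4), 7, dimnames = list(paste0("t", 1:7), NULL))
    cl <- cluster_traits(X)
    oracle <- brute_ward_d2(X)
    expect_equal(cl$hclust$height, oracle$heights, tolerance = 1e-10)
    expect_identical(hclust_merge_sets(cl$hclust), oracle$merges)
  }
})

test_that("clustering handles degenerate geometry deterministically", {
  X <- rbind(a = c(0, 0), b = c(0, 0), c = c(5, 5))
  cl <- cluster_traits(X)
  expect_equal(cl$hclust$height[1], 0)
  expect_identical(sort(hclust_merge_sets(cl$hclust)[[1]]), c(1L, 2L))
  # 1-D: nearest pair merges first
  X2 <- matrix(c(0, 0.1, 10), 3, dimnames = list(c("x", "y", "z"), NULL))
  cl2 <- cluster_traits(X2)
  expect_identical(sort(hclust_merge_sets(cl2$hclust)[[1]]), c(1L, 2L))
  expect_match(cl2$newick, "^\\(")
  expect_error(cluster_traits(X[1, , drop = FALSE]), "at least 2")
  rownames(X) <- c("a", "a", "c")
  expect_error(cluster_traits(X), "duplicate")
})

test_that("stronger component signals come with higher consistency", {
  fx <- small_sim()
  b <- fx$basis
  k <- which.max(colSums(b$driver))
  lambdas <- runif(60, 0, 1.5)
  base <- fx$sim$studies[[1]]
  stats <- t(sapply(seq_along(lambdas), function(i) {
    noise <- simulate_null_study(fx$panel, 3000, 3000, seed = 500 + i)
    ss <- base
    ss$snps$beta <- lambdas[i] * base$snps$beta + noise$snps$beta
    d <- project_deltas(b, ss)$delta
    V <- delta_covariance(b, ss, panel = fx$panel)
    r <- consistency_test(ss, b, k, fx$panel, n_perm = 49, seed = i)
    c(z = unname(abs(d[k]) / sqrt(V[k, k])), rho = abs(r$rho))
  }))
  ct <- stats::cor.test(stats[, "z"], stats[, "rho"], method = "spearman",
                        alternative = "greater", exact = FALSE)
  expect_lt(ct$p.value, 0.01)
})
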