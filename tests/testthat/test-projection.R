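test_that("projection of an all-zero study is exactly zero, and is linear", {
  fx <- small_sim()
  b <- fx$basis
  zero <- panel_sumstats(fx$panel, beta = rep(0, 2000), se = rep(0.01, 2000), "zero")
  expect_identical(unname(project_deltas(b, zero)$delta), rep(0, b$m))
  s1 <- fx$sim$studies[[1]]; s2 <- fx$sim$studies[[2]]
  s12 <- s1; s12$snps$beta <- s1$snps$beta + s2$snps$beta
  expect_equal(project_deltas(b, s12)$delta,
               project_deltas(b, s1)$delta + project_deltas(b, s2)$delta,
               tolerance = 1e-12)
})

test_that("sparse projection equals the centred-difference route and tracks full scores", {
  fx <- small_sim()
  b <- fx$basis
  ss <- fx$sim$studies[[3]]
  g <- shrink(ss, fx$weights, "continuous")
  Qs <- sparse_rotation(b)
  # route 1: uncentred effects through the sparse rotation
  d1 <- drop(crossprod(Qs, g))
  # route 2: centred projection of the trait minus centred projection of control
  d2 <- drop((g - b$col_means) %*% Qs) - drop((0 - b$col_means) %*% Qs)
  expect_equal(unname(d1), unname(project_deltas(b, ss)$delta), tolerance = 1e-12)
  expect_equal(unname(d1), unname(d2), tolerance = 1e-12)
  # across training traits, sparse deltas correlate > 0.999 with full-rotation
  # scores relative to control, per component
  ids <- setdiff(b$traits, b$control)
  D <- t(vapply(ids, function(id)
    unname(project_deltas(b, fx$sim$studies[[id]])$delta), numeric(b$m)))
  S <- sweep(b$scores[ids, , drop = FALSE], 2, b$scores[b$control, ])
  for (k in seq_len(b$m)) expect_gt(stats::cor(D[, k], S[, k]), 0.999)
})

test_that("missing variants are zero-filled, warned about, and bias deltas towards null", {
  fx <- small_sim()
  b <- fx$basis
  rep1 <- small_replicate()
  full <- project_deltas(b, rep1)$delta
  drop_frac <- function(ss, frac, seed) {
    with_mask <- ss
    set.seed(seed)
    ii <- sample(nrow(ss$snps), round(frac * nrow(ss$snps)))
    with_mask$snps$beta[ii] <- NA
    with_mask$snps$se[ii] <- NA
    with_mask
  }
  expect_warning(pr <- project_deltas(b, drop_frac(rep1, 0.3, 1)),
                 "missing")
  expect_equal(pr$missing_fraction, 0.3, tolerance = 0.01)
  # mean |delta| over random masks shrinks as missingness grows
  norms <- sapply(c(0, 0.4, 0.8), function(frac) {
    mean(sapply(1:8, function(s) {
      d <- suppressWarnings(project_deltas(b, drop_frac(rep1, frac, s)))$delta
      sum(abs(d))
    }))
  })
  expect_true(all(diff(norms) < 0))
  expect_error(project_deltas(b, drop_frac(rep1, 0.5, 1), missing_max = 0.2),
               "missing")
})

test_that("the analytic delta covariance matches Monte-Carlo resampling", {
  sc <- simulation_scenario(seed = 4, n_snps = 30, n_blocks = 3, n_traits = 5,
                            causal_density = 0.9)
  panel <- simulate_panel(sc)
  sim <- simulate_traits(sc, panel)
  w <- compute_shrinkage(sim$studies, panel, keep_pp = FALSE)
  b <- build_basis(sim$studies, w, panel)
  ss <- sim$studies[[1]]
  V <- delta_covariance(b, ss, panel = panel)
  # Monte-Carlo oracle: resample beta ~ N(beta_hat, LD-structured se)
  nmc <- 2e4
  A <- sparse_rotation(b) * (b$variants$w / b$variants$sigma_maf)
  se <- ss$snps$se
  set.seed(9)
  Z <- matrix(rnorm(30 * nmc), 30, nmc)
  for (bl in names(panel$ld)) {
    ii <- which(panel$variants$block == bl)
    Z[ii, ] <- crossprod(chol(panel$ld[[bl]]), Z[ii, , drop = FALSE])
  }
  D <- crossprod(A, ss$snps$beta + Z * se)
  Vmc <- stats::cov(t(D))
  mc_se <- diag(Vmc) * sqrt(2 / (nmc - 1))
  expect_true(all(abs(diag(V) - diag(Vmc)) < 3 * mc_se))
  # independent-SNP mode agrees with the sum-of-squares closed form
  Vi <- delta_covariance(b, ss, ld = "independent")
  expect_equal(unname(Vi), unname(crossprod(A * se)), tolerance = 1e-12)
  # identity LD matrices reduce the panel route to the independent one
  panel_id <- panel
  panel_id$ld <- lapply(panel$ld, function(m) diag(nrow(m)) + 0 * m)
  panel_id$ld_chol <- NULL
  expect_equal(delta_covariance(b, ss, panel = panel_id), Vi, tolerance = 1e-12)
})

test_that("degenerate covariance inputs are handled explicitly", {
  sc <- simulation_scenario(seed = 4, n_snps = 30, n_blocks = 3, n_traits = 5,
                            causal_density = 0.9)
  panel <- simulate_panel(sc)
  sim <- simulate_traits(sc, panel)
  w <- compute_shrinkage(sim$studies, panel, keep_pp = FALSE)
  b <- build_basis(sim$studies, w, panel)
  ss <- sim$studies[[1]]
  # all standard errors zero -> zero covariance
  ss0 <- ss; ss0$snps$se <- rep(0, nrow(ss$snps))
  expect_equal(unname(delta_covariance(b, ss0, ld = "independent")),
               matrix(0, b$m, b$m))
  # a missing LD block for driver SNPs is an error naming the block
  panel_broken <- panel
  panel_broken$ld <- panel$ld[-1]
  panel_broken$ld_chol <- NULL
  expect_error(delta_covariance(b, ss, panel = panel_broken), "b0001")
})

test_that("the overall chi-square test matches its reference distribution", {
  expect_equal(test_overall(rep(0, 5), diag(5)),
               list(chisq = 0, df = 5L, p = 1))
  # frozen quantile oracle: qchisq(0.95, df = 13) = 22.36203
  delta <- c(sqrt(22.362), rep(0, 12))
  r <- test_overall(delta, diag(13))
  expect_equal(r$chisq, 22.362, tolerance = 1e-6)
  expect_equal(r$p, 0.05, tolerance = 1e-4)
  # rank-deficient covariance: pseudo-inverse with reduced df
  V <- tcrossprod(c(1, 1)) # rank 1
  r2 <- test_overall(c(1, 1), V)
  expect_equal(r2$df, 1L)
  expect_equal(r2$chisq, 1, tolerance = 1e-10)
})

test_that("per-component z tests are two-sided and sign-symmetric", {
  r <- test_components(c(0, 1.959964, -1.959964), diag(3))
  expect_equal(r$p[1], 1)
  expect_equal(r$p[2], 0.05, tolerance = 1e-6)
  expect_equal(r$p[2], r$p[3])
  expect_equal(r$z[3], -1.959964)
})

test_that("BH adjustment is step-up, monotone, and independent per category", {
  # oracle: p * n / i with cumulative minimum from the largest p down
  bh <- function(p) {
    n <- length(p); o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n); out[o] <- pmin(adj, 1); out
  }
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(2)
  p <- runif(50)
  expect_equal(fdr_adjust(p), bh(p))
  expect_equal(fdr_adjust(0.007), 0.007)
  g <- rep(c("a", "b"), each = 25)
  joint <- fdr_adjust(p)
  per <- fdr_adjust(p, groups = g)
  expect_equal(per[g == "a"], bh(p[g == "a"]))
  expect_equal(per[g == "b"], bh(p[g == "b"]))
  expect_false(isTRUE(all.equal(joint, per)))
  expect_error(fdr_adjust(p, groups = g[-1]), "length")
})

test_that("significance flags follow the strict conjunction rule", {
  tab <- data.table::data.table(
    trait = c("a", "a", "b", "b", "c", "c"),
    category = "x", component = rep(c("PC1", "PC2"), 3),
    delta = 0, var.delta = 1, z = 0, p.delta = 0,
    fdr.delta = c(0.005, 0.5, 0.005, 0.005, 0.01, 0.001),
    p.overall = 0, fdr.overall = c(0.001, 0.001, 0.5, 0.5, 0.01, 0.01))
  fl <- flag_significant(tab, overall_fdr = 0.01, component_fdr = 0.01)
  # trait a: overall significant, PC1 only
  expect_equal(fl[trait == "a", component_significant], c(TRUE, FALSE))
  # trait b: never flagged regardless of component FDR
  expect_equal(fl[trait == "b", component_significant], c(FALSE, FALSE))
  # trait c: equality at the threshold is not flagged (strict inequality)
  expect_equal(fl[trait == "c", overall_significant], c(FALSE, FALSE))
})

test_that("power grows with the scale of true effects", {
  fx <- small_sim()
  b <- fx$basis
  base <- fx$sim$studies[[2]]
  V <- delta_covariance(b, base, panel = fx$panel)
  med_T <- sapply(c(0, 0.5, 1, 2), function(lam) {
    Ts <- sapply(1:6, function(s) {
      noise <- simulate_null_study(fx$panel, 5000, 5000, seed = 100 + s)
      ss <- base
      ss$snps$beta <- lam * base$snps$beta + noise$snps$beta
      test_overall(project_deltas(b, ss)$delta, V)$chisq
    })
    stats::median(Ts)
  })
  expect_true(all(diff(med_T) > 0))
})

test_that("projection p-values are calibrated under the null", {
  fx <- small_sim()
  b <- fx$basis
  V <- delta_covariance(b, simulate_null_study(fx$panel, 5000, 5000, seed = 1),
                        panel = fx$panel)
  ps <- sapply(1:400, function(i) {
    ns <- simulate_null_study(fx$panel, 5000, 5000, seed = 20000 + i)
    test_overall(project_deltas(b, ns)$delta, V)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
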