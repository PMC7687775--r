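# Fixtures built in code; the moderately expensive ones are memoised so the
# whole suite pays for them once.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# hand-built 6-variant, 2-block panel with AR(1)-style LD
tiny_panel <- function(rho = 0.8) {
  v <- data.frame(chr = "1", pos = c(100L, 200L, 300L, 400L, 500L, 600L),
                  ref = c("A", "C", "G", "T", "A", "C"),
                  alt = c("G", "T", "A", "C", "C", "A"),
                  alt_freq = c(0.5, 0.1, 0.3, 0.25, 0.4, 0.2),
                  block = rep(c("b1", "b2"), each = 3))
  keys <- paste(v$chr, v$pos, v$ref, v$alt, sep = ":")
  mk <- function(i) {
    R <- rho^abs(outer(1:3, 1:3, `-`))
    dimnames(R) <- list(keys[i], keys[i])
    R
  }
  reference_panel(v, ld = list(b1 = mk(1:3), b2 = mk(4:6)))
}

# a sumstats object over a panel, built directly (already aligned)
panel_sumstats <- function(panel, beta, se, trait_id = "t",
                           n_cases = NA, n_controls = NA) {
  v <- panel$variants
  ss <- sumstats(data.frame(chr = v$chr, pos = v$pos, ref = v$ref,
                            alt = v$alt, beta = 1, se = 1),
                 trait_id = trait_id, n_cases = n_cases,
                 n_controls = n_controls)
  ss$snps$beta <- beta
  ss$snps$se <- se
  ss$aligned <- TRUE
  ss
}

write_ss_file <- function(d, path = tempfile(fileext = ".tsv")) {
  data.table::fwrite(data.table::as.data.table(d), path, sep = "\t")
  path
}

# default small simulation: 8 traits, 2000 SNPs, 40 blocks
small_sim <- function() {
  memo("small_sim", function() {
    sc <- simulation_scenario(seed = 42, n_snps = 2000, n_blocks = 40,
                              n_traits = 8, n_components = 3)
    panel <- simulate_panel(sc)
    sim <- simulate_traits(sc, panel)
    weights <- compute_shrinkage(sim$studies, panel,
                                 index = intersect_studies(sim$studies))
    M <- assemble_effect_matrix(sim$studies, weights)
    basis <- build_basis(sim$studies, weights, panel)
    list(scenario = sc, panel = panel, sim = sim, weights = weights,
         M = M, basis = basis)
  })
}

# a small-cohort replicate of trait 1 on the small_sim panel
small_replicate <- function() {
  memo("small_replicate", function() {
    fx <- small_sim()
    sc <- simulation_scenario(seed = 42, n_snps = 2000, n_blocks = 40,
                              n_traits = 8, n_components = 3,
                              replicates = data.frame(disease = 1,
                                                      n_cases = 500,
                                                      n_controls = 5000))
    simulate_traits(sc, fx$panel)$studies[["trait01_rep"]]
  })
}

# brute-force Ward.D2 agglomeration via Lance-Williams updates, used as an
# independent oracle for cluster_traits on small inputs
brute_ward_d2 <- function(X) {
  n <- nrow(X)
  d2 <- as.matrix(stats::dist(X))^2
  active <- seq_len(n)
  sizes <- rep(1, n)
  members <- as.list(seq_len(n))
  heights <- numeric(0)
  merges <- list()
  while (length(active) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a < b) {
        i <- active[a]; j <- active[b]
        if (d2[i, j] < bd) { bd <- d2[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(bd))
    merges <- c(merges, list(sort(unlist(members[c(i, j)]))))
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * bd) /
        (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    members[[i]] <- unlist(members[c(i, j)])
    active <- setdiff(active, j)
  }
  list(heights = heights, merges = merges)
}

# merge sets of an hclust, for comparison with the brute-force oracle
hclust_merge_sets <- function(hc) {
  n <- length(hc$order)
  out <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    grab <- function(x) if (x < 0) -x else out[[x]]
    out[[s]] <- sort(c(grab(hc$merge[s, 1]), grab(hc$merge[s, 2])))
  }
  out
}
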