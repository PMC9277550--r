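test_that("succession tables are deterministic under a fixed seed", {
  p <- succession_params(n_taxa = 8, seed = 99)
  a1 <- generate_succession(p)
  a2 <- generate_succession(p)
  expect_identical(a1, a2)
  a3 <- generate_succession(succession_params(n_taxa = 8, seed = 100))
  expect_false(identical(abund_matrix(a1), abund_matrix(a3)))
})

test_that("sample sums equal the sequencing depth", {
  a <- generate_succession(succession_params(n_taxa = 12, depth = 5000,
                                             seed = 3))
  expect_identical(nrow(a), 18L)
  expect_true(all(rowSums(abund_matrix(a)) == 5000))
})

test_that("the noiseless limit reproduces latent intensities within rounding", {
  p <- succession_params(n_taxa = 5, n_replicates = 1, depth = 1e6,
                         concentration = Inf, seed = 4)
  a <- generate_succession(p)
  rel <- abund_matrix(to_relative(a))
  s <- seq(0, 1, length.out = 6)
  lat <- vapply(1:5, function(j) {
    pr <- p$profiles[j, ]
    pr$weight * fermnet:::trajectory(pr$kind, s, pr$midpoint, pr$rate,
                                     floor = pr$floor)
  }, numeric(6))
  expect_equal(unname(rel), lat / rowSums(lat), tolerance = 1e-5)
})

test_that("rising taxa end above where they start (smooth, deep settings)", {
  for (seed in 1:5) {
    prof <- withr::with_seed(seed, fermnet:::random_profiles(10))
    prof$kind[1] <- "rising"
    p <- succession_params(10, profiles = prof, depth = 1e4,
                           concentration = 100, stage_noise_sd = 0,
                           seed = seed)
    rel <- to_relative(generate_succession(p))
    m <- abund_matrix(rel)[, prof$taxon[1]]
    first <- mean(m[rel$stage == "A"])
    last <- mean(m[rel$stage == "F"])
    expect_gt(last, first)
  }
})

test_that("unknown trajectory kinds are rejected", {
  prof <- fermnet:::random_profiles(3)
  prof$kind[2] <- "wobbling"
  expect_error(succession_params(3, profiles = prof), "unknown trajectory")
})

test_that("volatiles follow the planted log-linear model exactly when noise-free", {
  a <- generate_succession(succession_params(n_taxa = 4, seed = 6))
  taxa <- taxa_names(a)
  B <- matrix(0, 4, 3, dimnames = list(taxa, c("c1", "c2", "c3")))
  truth0 <- association_truth(B, baseline = c(1, 2, 3), noise_sd = 0)
  v0 <- generate_volatiles(a, truth0, seed = 1)
  m0 <- volatile_matrix(v0, level = "sample")
  expect_equal(unname(apply(m0, 2, stats::sd)), rep(0, 3))
  expect_equal(unname(m0[1, c("c1", "c2", "c3")]), exp(c(1, 2, 3)))

  B[2, "c2"] <- 4
  truth1 <- association_truth(B, noise_sd = 0)
  v1 <- generate_volatiles(a, truth1, seed = 1)
  rel <- abund_matrix(to_relative(a))
  m1 <- volatile_matrix(v1, level = "sample")
  expect_equal(unname(cor(rel[, taxa[2]], log(m1[, "c2"]))), 1,
               tolerance = 1e-12)
})

test_that("strong planted effects give near-perfect correlations across seeds", {
  # taxon spread >= 0.2, sigma = 0.05, B = 3: |r| > 0.9 nearly always
  hits <- 0
  n_runs <- 60
  for (seed in seq_len(n_runs)) {
    rel_x <- withr::with_seed(seed, runif(18, 0.05, 0.45))
    counts <- round(1e4 * cbind(A = rel_x, B = 1 - rel_x))
    a <- abund_tbl(data.frame(stage = rep(LETTERS[1:6], each = 3),
                              replicate = rep(1:3, 6), counts))
    truth <- association_truth(
      matrix(c(3, 0), 2, 1, dimnames = list(c("A", "B"), "k")),
      noise_sd = 0.05)
    v <- generate_volatiles(a, truth, seed = seed)
    r <- cor(rel_x, log(volatile_matrix(v, level = "sample")[, "k"]))
    if (abs(r) > 0.9) hits <- hits + 1
  }
  expect_gte(hits / n_runs, 0.95)
})

test_that("truth report matches a brute-force scan of B", {
  taxa <- paste0("t", 1:6)
  comps <- paste0("c", 1:4)
  B <- matrix(0, 6, 4, dimnames = list(taxa, comps))
  expect_identical(truth_report(association_truth(B)),
                   list(core_taxa = character(0),
                        core_compounds = character(0)))
  B[3, 2] <- 1.5
  tr <- truth_report(association_truth(B))
  expect_identical(tr, list(core_taxa = "t3", core_compounds = "c2"))

  set.seed(8)
  B[sample(length(B), 5)] <- rnorm(5)
  tr2 <- truth_report(association_truth(B))
  expect_identical(tr2$core_taxa, taxa[apply(B != 0, 1, any)])
  expect_identical(tr2$core_compounds, comps[apply(B != 0, 2, any)])
})

test_that("mismatched B dimensions are an error", {
  a <- generate_succession(succession_params(n_taxa = 4, seed = 9))
  B <- matrix(1, 3, 2, dimnames = list(paste0("x", 1:3), c("c1", "c2")))
  expect_error(generate_volatiles(a, association_truth(B)),
               "do not match")
})

test_that("stronger effects cannot weaken the expected planted correlation", {
  mean_abs_r <- function(effect) {
    rs <- vapply(1:10, function(seed) {
      st <- simulate_ferment_study(n_taxa = 12, n_core = 1, n_compounds = 2,
                                   effect = effect, seed = seed)
      rel <- abund_matrix(to_relative(st$abund))
      vm <- volatile_matrix(st$volatiles, level = "sample")
      core <- st$truth$core_taxa
      comp <- st$truth$core_compounds[1]
      ids <- paste0(st$abund$stage, ".", st$abund$replicate)
      abs(cor(rel[, core], log(vm[ids, comp])))
    }, numeric(1))
    mean(rs)
  }
  expect_lte(mean_abs_r(0.5), mean_abs_r(2) + 0.02)
  expect_lte(mean_abs_r(2), mean_abs_r(6) + 0.02)
})

test_that("the packaged study simulation is reproducible end to end", {
  s1 <- simulate_ferment_study(n_taxa = 10, n_core = 2, n_compounds = 4,
                               seed = 11)
  s2 <- simulate_ferment_study(n_taxa = 10, n_core = 2, n_compounds = 4,
                               seed = 11)
  expect_identical(abund_matrix(s1$abund), abund_matrix(s2$abund))
  expect_identical(s1$volatiles$concentration, s2$volatiles$concentration)
  expect_identical(s1$truth$core_taxa, s2$truth$core_taxa)
  expect_length(s1$truth$core_taxa, 2L)
})
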