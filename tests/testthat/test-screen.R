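test_that("stability filter applies prevalence and CV rules", {
  cfg <- screen_config()
  expect_true(stability_filter(c(5, 4, 6, 5, 5, 4), cfg)$passed)
  expect_false(stability_filter(c(9, 0, 0, 0, 0, 0), cfg)$passed)
  res <- stability_filter(rep(10, 6), screen_config(max_cv = 1e-9))
  expect_identical(res$cv, 0)
  expect_true(res$passed)
  # CV cap rejects erratic series even when prevalence holds
  wild <- stability_filter(c(1, 100, 1, 100, 1, 100),
                           screen_config(max_cv = 0.5))
  expect_false(wild$passed)
  expect_error(stability_filter(numeric(), cfg), "empty")
})

test_that("screen flags combine with strict thresholds", {
  st <- simulate_ferment_study(n_taxa = 12, n_core = 2, n_compounds = 4,
                               seed = 2)
  scr <- suppressWarnings(screen_core(st$abund, st$volatiles,
                                      cfg = screen_config(top_n = 12)))
  expect_identical(scr$taxa$passed,
                   scr$taxa$passed_stability & scr$taxa$passed_vip &
                     scr$taxa$passed_r)
  # exact threshold equality must not pass (strict inequality)
  row <- scr$taxa[1, ]
  cfg_eq <- screen_config(vip_threshold = row$vip,
                          r_threshold = row$max_abs_r, top_n = 12)
  scr_eq <- suppressWarnings(screen_core(st$abund, st$volatiles, cfg = cfg_eq))
  expect_false(scr_eq$taxa$passed_vip[1])
  expect_false(scr_eq$taxa$passed_r[1])
})

test_that("a taxon absent from every stage can never be core", {
  st <- simulate_ferment_study(n_taxa = 8, n_core = 1, n_compounds = 2,
                               seed = 3)
  ab <- st$abund
  gone <- taxa_names(ab)[1]
  ab[[gone]] <- 0
  scr <- suppressWarnings(screen_core(ab, st$volatiles,
                                      cfg = screen_config(top_n = 8)))
  row <- scr$taxa[scr$taxa$name == gone, ]
  if (nrow(row)) expect_false(row$passed)
})

test_that("raising thresholds never adds core members", {
  st <- simulate_ferment_study(n_taxa = 15, n_core = 3, n_compounds = 6,
                               seed = 4)
  base <- suppressWarnings(screen_core(st$abund, st$volatiles,
                                       cfg = screen_config(top_n = 15), A = 2))
  for (bump in list(c(0.2, 0), c(0, 0.1), c(0.3, 0.2))) {
    cfg2 <- screen_config(vip_threshold = 1 + bump[1],
                          r_threshold = 0.6 + bump[2], top_n = 15)
    scr2 <- suppressWarnings(screen_core(st$abund, st$volatiles, cfg = cfg2,
                                         A = 2))
    expect_true(all(scr2$taxa$name[scr2$taxa$passed] %in%
                      base$taxa$name[base$taxa$passed]))
    expect_true(all(scr2$volatiles$name[scr2$volatiles$passed] %in%
                      base$volatiles$name[base$volatiles$passed]))
  }
})

test_that("bipartite network edges connect only core members above threshold", {
  st <- simulate_ferment_study(n_taxa = 15, n_core = 3, n_compounds = 6,
                               seed = 5)
  scr <- suppressWarnings(screen_core(st$abund, st$volatiles,
                                      cfg = screen_config(top_n = 15), A = 2))
  edges <- bipartite_network(scr)
  core_t <- scr$taxa$name[scr$taxa$passed]
  core_v <- scr$volatiles$name[scr$volatiles$passed]
  expect_true(all(edges$node_a %in% core_t))
  expect_true(all(edges$node_b %in% core_v))
  expect_true(all(abs(edges$r) > scr$config$r_threshold))
  expect_identical(edges$sign, ifelse(edges$r >= 0, "+", "-"))
  expect_true(all(edges$type_b == "volatile"))
})

test_that("no core taxa means an empty bipartite network", {
  st <- simulate_ferment_study(n_taxa = 10, n_core = 2, n_compounds = 4,
                               seed = 6)
  scr <- suppressWarnings(screen_core(
    st$abund, st$volatiles,
    cfg = screen_config(vip_threshold = 50, r_threshold = 0.99, top_n = 10),
    A = 2))
  expect_identical(sum(scr$taxa$passed), 0L)
  expect_identical(nrow(scr$edges), 0L)
})

test_that("planted core taxa are recovered on an easy instance", {
  st <- simulate_ferment_study(seed = 1)
  scr <- suppressWarnings(screen_core(st$abund, st$volatiles))
  rec <- scr$taxa$name[scr$taxa$passed]
  expect_true(all(st$truth$core_taxa %in% rec))
})
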