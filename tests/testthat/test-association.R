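test_that("correlation matrix matches the direct-sum formula", {
  set.seed(21)
  x <- matrix(rnorm(5 * 4), 5, 4, dimnames = list(NULL, letters[1:4]))
  cm <- correlation_matrix(x)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(cm$r[i, j], pearson_oracle(x[, i], x[, j]),
                 tolerance = 1e-12)
  }
  expect_equal(diag(cm$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cm$r, t(cm$r))
  expect_equal(cm$p, t(cm$p))
})

test_that("perfect correlation and anticorrelation are exact", {
  x <- c(1, 2, 5, 7)
  cm <- correlation_matrix(cbind(a = x, b = x, c = -x))
  expect_equal(cm$r["a", "b"], 1)
  expect_equal(cm$r["a", "c"], -1)
  expect_equal(cm$p["a", "c"], 0)
})

test_that("hand-computed Pearson example r = 0.8", {
  cm <- correlation_matrix(cbind(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4)))
  expect_equal(cm$r["x", "y"], 0.8)
})

test_that("p-values come from the exact t transform and shrink with |r|", {
  set.seed(22)
  x <- matrix(rnorm(8 * 3), 8, 3)
  cm <- correlation_matrix(x)
  r <- cm$r[1, 2]
  n <- 8
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(cm$p[1, 2], 2 * pt(abs(tstat), n - 2, lower.tail = FALSE))
  rs <- seq(0.1, 0.95, by = 0.05)
  ps <- fermnet:::r_to_p(rs, 10)
  expect_true(all(diff(ps) < 0))
})

test_that("correlation invariances hold under transforms", {
  set.seed(23)
  x <- matrix(rexp(30), 10, 3)
  aff <- sweep(sweep(x, 2, c(2, 5, 0.3), "*"), 2, c(1, -4, 7), "+")
  expect_equal(correlation_matrix(x)$r, correlation_matrix(aff)$r,
               tolerance = 1e-12, ignore_attr = TRUE)
  mono <- cbind(exp(x[, 1]), x[, 2]^3, log(x[, 3] + 1))
  expect_equal(correlation_matrix(x, "spearman")$r,
               correlation_matrix(mono, "spearman")$r,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("network thresholding is strict and monotone", {
  set.seed(24)
  x <- matrix(rnorm(12 * 8), 12, 8,
              dimnames = list(NULL, paste0("v", 1:8)))
  cm <- correlation_matrix(x)
  # exact threshold equality is excluded
  cm2 <- cm
  cm2$r[1, 2] <- cm2$r[2, 1] <- 0.9
  cm2$p[1, 2] <- cm2$p[2, 1] <- 1e-6
  net <- cooccurrence_network(cm2, r_threshold = 0.9, p_threshold = 0.01)
  expect_false(any(net$node_a == "v1" & net$node_b == "v2"))
  cm2$r[1, 2] <- cm2$r[2, 1] <- 0.95
  net2 <- cooccurrence_network(cm2, r_threshold = 0.9, p_threshold = 0.01)
  row <- net2[net2$node_a == "v1" & net2$node_b == "v2", ]
  expect_identical(nrow(row), 1L)
  expect_identical(row$sign, "+")

  # edge sets shrink as thresholds tighten
  for (i in 1:10) {
    rt <- runif(1, 0.2, 0.8)
    pt_ <- runif(1, 0.005, 0.2)
    loose <- cooccurrence_network(cm, rt, pt_)
    tight <- cooccurrence_network(cm, min(rt + 0.1, 0.95), pt_ / 2)
    key <- function(e) paste(e$node_a, e$node_b)
    expect_true(all(key(tight) %in% key(loose)))
  }
  expect_error(cooccurrence_network(cm, 1.2, 0.01), "inside \\(0, 1\\)")
})

test_that("taxa-volatile correlations align replicates when present", {
  st <- simulate_ferment_study(n_taxa = 10, n_core = 2, n_compounds = 4,
                               seed = 5)
  cc <- taxa_volatile_correlations(st$abund, st$volatiles)
  expect_identical(cc$alignment, "replicate")
  expect_identical(cc$n, 18L)
  expect_identical(dim(cc$r), c(10L, 4L))
  # planted association shows up as a strong correlation
  core <- st$truth$core_taxa[1]
  comp <- colnames(st$truth$B)[which(st$truth$B[core, ] != 0)[1]]
  expect_gt(abs(cc$r[core, comp]), 0.9)
})

test_that("stage-mean alignment is used for per-stage volatile tables", {
  t <- toy_counts()
  v <- toy_volatiles()
  cc <- taxa_volatile_correlations(t, v)
  expect_identical(cc$alignment, "stage")
  expect_identical(cc$n, 4L)
  # identical series correlate exactly
  rel <- to_relative(t)
  stage_means <- apply(abund_matrix(rel), 2, function(col) tapply(col, rel$stage, mean))
  v2 <- volatile_tbl(tibble::tibble(stage = rownames(stage_means),
                                    compound = "mirror", class = "ester",
                                    concentration = stage_means[, "TaxA"]))
  cc2 <- taxa_volatile_correlations(t, v2)
  expect_equal(cc2$r["TaxA", "mirror"], 1, tolerance = 1e-12)
})

test_that("degenerate correlation inputs error or warn as promised", {
  expect_error(correlation_matrix(matrix(rnorm(6), 3, 2)), "at least 4")
  t <- abund_tbl(data.frame(stage = LETTERS[1:4], replicate = 1,
                            con = rep(0.5, 4), up = seq(0.1, 0.4, 0.1),
                            down = seq(0.4, 0.1, -0.1)),
                 mode = "relative")
  v <- toy_volatiles()
  expect_warning(taxa_volatile_correlations(t, v), "constant taxon")
})
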