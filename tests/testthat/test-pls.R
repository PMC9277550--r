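test_that("an exact univariate linear relation is fit by one component", {
  x <- matrix(c(1, 2, 3, 4, 5), ncol = 1)
  y <- 3 * x - 7
  fit <- fit_pls2(x, y, A = 1)
  expect_equal(unname(predict(fit)), unname(y), tolerance = 1e-9)
  expect_equal(unname(fit$vip), 1)  # single predictor: VIP forced to 1
})

test_that("one-component weights are proportional to X'y (PLS1 closed form)", {
  set.seed(31)
  X <- matrix(rnorm(12), 4, 3)
  y <- rnorm(4)
  fit <- fit_pls2(X, y, A = 1, scale = FALSE)
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  w_ref <- drop(crossprod(Xc, yc))
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  expect_equal(abs(sum(fit$W[, 1] * w_ref)), 1, tolerance = 1e-9)
})

test_that("score vectors are mutually orthogonal", {
  set.seed(32)
  X <- matrix(rnorm(60), 10, 6)
  Y <- matrix(rnorm(30), 10, 3)
  fit <- fit_pls2(X, Y, A = 3)
  g <- crossprod(fit$T)
  expect_equal(g - diag(diag(g)), matrix(0, 3, 3), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_equal(colSums(fit$W^2), rep(1, 3), tolerance = 1e-9)
})

test_that("VIP squares always sum to the number of predictors", {
  set.seed(33)
  for (i in 1:25) {
    n <- sample(5:15, 1)
    p <- sample(2:8, 1)
    m <- sample(1:4, 1)
    A <- sample(seq_len(min(n - 1, p, 3)), 1)
    X <- matrix(rnorm(n * p), n, p)
    Y <- matrix(rnorm(n * m), n, m)
    fit <- fit_pls2(X, Y, A = A)
    expect_equal(sum(fit$vip^2), p, tolerance = 1e-6)
  }
})

test_that("a lone informative predictor dominates the VIP ranking", {
  set.seed(34)
  X <- matrix(rnorm(100), 20, 5)
  y <- 2 * X[, 1]
  fit <- fit_pls2(X, y, A = 1)
  expect_identical(unname(which.max(fit$vip)), 1L)
  expect_gt(fit$vip[1], 1)
})

test_that("training residuals shrink as components are added", {
  set.seed(35)
  X <- matrix(rnorm(48), 8, 6)
  Y <- matrix(rnorm(16), 8, 2)
  fit <- fit_pls2(X, Y, A = 4)
  rss <- vapply(1:4, function(a) sum((Y - predict(fit, ncomp = a))^2),
                numeric(1))
  expect_true(all(diff(rss) <= 1e-8))
})

test_that("fit is invariant to predictor ordering", {
  set.seed(36)
  X <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, paste0("x", 1:5)))
  Y <- matrix(rnorm(16), 8, 2)
  fit1 <- fit_pls2(X, Y, A = 2)
  perm <- sample(5)
  fit2 <- fit_pls2(X[, perm], Y, A = 2)
  expect_equal(predict(fit2, X[, perm]), predict(fit1, X),
               tolerance = 1e-8)
  expect_equal(fit2$vip[colnames(X)], fit1$vip[colnames(X)],
               tolerance = 1e-8)
})

test_that("VIP agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(37)
  X <- matrix(rnorm(80), 16, 5, dimnames = list(NULL, paste0("x", 1:5)))
  Y <- X[, 1] - 2 * X[, 3] + matrix(rnorm(32, sd = 0.3), 16, 2)
  fit <- fit_pls2(X, Y, A = 2)
  ref <- mixOmics::pls(X, Y, ncomp = 2, mode = "regression", scale = TRUE)
  vref <- mixOmics::vip(ref)
  expect_equal(unname(fit$vip[colnames(X)]), unname(vref[colnames(X), 2]),
               tolerance = 0.05)
})

test_that("component selection picks 1 for rank-1 and pure-noise responses", {
  set.seed(38)
  # rank-1 X driving y exactly: one latent direction explains everything
  t_lat <- rnorm(12)
  X <- outer(t_lat, c(1, 2, -1)) + matrix(rnorm(36, sd = 1e-4), 12, 3)
  y_exact <- t_lat
  cv <- select_components_cv(X, y_exact, A_max = 3)
  expect_identical(cv$chosen_A, 1L)
  expect_gt(cv$q2$q2[1], 0.95)

  y_noise <- matrix(rnorm(12), 12, 1)
  cv0 <- select_components_cv(X, y_noise, A_max = 4)
  expect_identical(cv0$chosen_A, 1L)
  expect_lte(min(cv0$q2$q2), 0)
  expect_lte(cv0$chosen_A, 4)
})

test_that("degenerate PLS inputs raise the promised errors", {
  X <- matrix(rnorm(20), 10, 2)
  Y <- matrix(rnorm(10), 10, 1)
  expect_error(fit_pls2(X, Y, A = 5), "exceeds")
  expect_error(fit_pls2(X[1:2, ], Y[1:2, , drop = FALSE], A = 1),
               "at least 3")
  expect_warning(fit_pls2(cbind(X, 0), Y, A = 1), "constant")
  expect_error(select_components_cv(X, Y, A_max = 0), "at least 1")
})
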