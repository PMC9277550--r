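#' Fit a PLS2 regression by NIPALS
#'
#' Partial least squares with a multivariate response, fitted by the
#' classical NIPALS algorithm with block deflation. Both blocks are
#' autoscaled (centered, unit variance) internally by default, matching
#' common chemometrics practice; the preprocessing parameters are stored
#' so predictions return to the original scale.
#'
#' Per component: starting from `u` = first column of the deflated `Y`,
#' iterate `w = X'u / ||X'u||`, `t = X w`, `q = Y't / (t't)`,
#' `u = Y q / (q'q)` until the score vector `t` changes by less than
#' `tol` (max 5000 iterations); then `p = X't / (t't)`, deflate
#' `X <- X - t p'` and `Y <- Y - t q'`. The explained sum of squares of
#' `Y` attributed to component `a` is `ssy_a = (t't)(q'q)`.
#'
#' @param X Samples-by-predictors matrix or data frame (n >= 3).
#' @param Y Samples-by-responses matrix, data frame, or vector.
#' @param A Number of components, `A <= min(n - 1, p)`.
#' @param scale Autoscale both blocks (default `TRUE`). Centering is
#'   always applied.
#' @param tol,max_iter NIPALS convergence tolerance on `t` and iteration
#'   cap.
#' @return Object of class `pls_fit`: weights `W` (unit-norm columns),
#'   scores `T`, X-loadings `P`, Y-loadings `Q`, `ssy`, `vip`,
#'   preprocessing parameters and the original dimensions.
#' @seealso [vip_scores()], [select_components_cv()], [predict.pls_fit()]
#' @export
fit_pls2 <- function(X, Y, A, scale = TRUE, tol = 1e-10, max_iter = 5000) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  n <- nrow(X)
  if (n < 3) stop("PLS needs at least 3 samples", call. = FALSE)
  if (nrow(Y) != n) stop("X and Y row counts differ", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(Y))) {
    stop("X and Y must be finite", call. = FALSE)
  }

  drop_const <- function(m, label) {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      warning("dropping constant ", label, " column(s): ",
              paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
      m <- m[, sds > 0, drop = FALSE]
    }
    m
  }
  X <- drop_const(X, "X")
  Y <- drop_const(Y, "Y")
  p <- ncol(X)
  m <- ncol(Y)
  if (p == 0L || m == 0L) stop("no non-constant columns left", call. = FALSE)
  if (A > min(n - 1, p)) {
    stop(sprintf("A = %d exceeds min(n - 1, p) = %d", A, min(n - 1, p)),
         call. = FALSE)
  }

  x_center <- colMeans(X)
  y_center <- colMeans(Y)
  x_scale <- if (scale) apply(X, 2, stats::sd) else rep(1, p)
  y_scale <- if (scale) apply(Y, 2, stats::sd) else rep(1, m)
  Xd <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  Yd <- sweep(sweep(Y, 2, y_center), 2, y_scale, "/")
  X0 <- Xd
  Y0 <- Yd

  W <- matrix(0, p, A, dimnames = list(colnames(X), NULL))
  P <- matrix(0, p, A, dimnames = list(colnames(X), NULL))
  Q <- matrix(0, m, A, dimnames = list(colnames(Y), NULL))
  Tm <- matrix(0, n, A)
  ssy <- numeric(A)

  for (a in seq_len(A)) {
    u <- Yd[, 1]
    t_old <- rep(Inf, n)
    delta <- Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xd, u))
      nw <- sqrt(sum(w^2))
      if (nw == 0) stop("degenerate weight vector in component ", a,
                        call. = FALSE)
      w <- w / nw
      t_new <- drop(Xd %*% w)
      q <- drop(crossprod(Yd, t_new)) / sum(t_new^2)
      u <- drop(Yd %*% q) / sum(q^2)
      delta <- sqrt(sum((t_new - t_old)^2))
      t_old <- t_new
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      # a near-tie of latent directions makes the power iteration crawl;
      # any vector in the tied subspace yields an equivalent fit, so a
      # slowly rotating but numerically settled iterate is accepted
      if (delta / sqrt(sum(t_old^2)) > 1e-4) {
        stop("NIPALS did not converge for component ", a, call. = FALSE)
      }
    }
    tt <- sum(t_old^2)
    pl <- drop(crossprod(Xd, t_old)) / tt
    q <- drop(crossprod(Yd, t_old)) / tt
    Xd <- Xd - tcrossprod(t_old, pl)
    Yd <- Yd - tcrossprod(t_old, q)
    W[, a] <- w
    P[, a] <- pl
    Q[, a] <- q
    Tm[, a] <- t_old
    ssy[a] <- tt * sum(q^2)
  }

  fit <- structure(list(A = A, W = W, T = Tm, P = P, Q = Q, ssy = ssy,
                        x_center = x_center, x_scale = x_scale,
                        y_center = y_center, y_scale = y_scale,
                        X = X0, Y = Y0, n = n, scale = scale),
                   class = "pls_fit")
  fit$vip <- vip_scores(fit)
  fit
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a ssy_a w_ja^2 / sum_a ssy_a)` over the fitted
#' components (weight columns are unit norm). The squares sum to the
#' number of predictors, so VIP > 1 marks predictors contributing more
#' than average to the explained response variance.
#'
#' @param model A [fit_pls2()] fit.
#' @return Named numeric vector, one score per predictor.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_fit"))
  if (sum(model$ssy) <= 0) {
    stop("model explains none of Y; VIP undefined", call. = FALSE)
  }
  p <- nrow(model$W)
  w2 <- sweep(model$W^2, 2, colSums(model$W^2), "/")  # guard rounding
  vip2 <- p * drop(w2 %*% model$ssy) / sum(model$ssy)
  sqrt(stats::setNames(vip2, rownames(model$W)))
}

#' Predict from a PLS fit
#'
#' Uses the standard regression coefficients `B = W (P'W)^{-1} Q'` on
#' the autoscaled blocks, back-transformed to the original Y scale.
#'
#' @param object A `pls_fit`.
#' @param newdata Samples-by-predictors matrix with the training
#'   predictor columns; defaults to the training X.
#' @param ncomp Number of components to use (default all).
#' @param ... Unused.
#' @export
predict.pls_fit <- function(object, newdata = NULL, ncomp = object$A, ...) {
  W <- object$W[, seq_len(ncomp), drop = FALSE]
  P <- object$P[, seq_len(ncomp), drop = FALSE]
  Q <- object$Q[, seq_len(ncomp), drop = FALSE]
  B <- W %*% solve(crossprod(P, W)) %*% base::t(Q)
  if (is.null(newdata)) {
    Xs <- object$X
  } else {
    newdata <- as.matrix(newdata)
    if (!is.null(colnames(newdata))) {
      newdata <- newdata[, rownames(object$W), drop = FALSE]
    }
    Xs <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, "/")
  }
  Ys <- Xs %*% B
  sweep(sweep(Ys, 2, object$y_scale, "*"), 2, object$y_center, "+")
}

#' Leave-one-out component selection
#'
#' Computes `Q2(A) = 1 - PRESS(A) / SS(Y)` by leave-one-out
#' cross-validation on the autoscaled response and picks the largest
#' component count whose marginal `Q2` gain exceeds `gain` (at least 1),
#' the usual chemometrics stopping rule.
#'
#' @inheritParams fit_pls2
#' @param A_max Largest component count to consider.
#' @param gain Marginal Q2 improvement required to keep a component.
#' @return List of class `pls_cv`: tibble `q2` (`A`, `q2`, `gain`),
#'   `chosen_A`, `rule`.
#' @export
select_components_cv <- function(X, Y, A_max, scale = TRUE, gain = 0.05) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  n <- nrow(X)
  if (n < 4) stop("leave-one-out selection needs at least 4 samples",
                  call. = FALSE)
  if (A_max < 1) stop("A_max must be at least 1", call. = FALSE)
  A_max <- min(A_max, n - 2, ncol(X))

  press <- matrix(0, n, A_max)
  for (i in seq_len(n)) {
    fit <- fit_pls2(X[-i, , drop = FALSE], Y[-i, , drop = FALSE],
                    A = A_max, scale = scale)
    for (a in seq_len(A_max)) {
      pred <- predict(fit, X[i, , drop = FALSE], ncomp = a)
      resid <- (Y[i, colnames(pred)] - pred) / fit$y_scale
      press[i, a] <- sum(resid^2)
    }
  }
  y_center <- colMeans(Y)
  y_scale <- if (scale) apply(Y, 2, stats::sd) else rep(1, ncol(Y))
  Ys <- sweep(sweep(Y, 2, y_center), 2, y_scale, "/")
  ssy <- sum(Ys^2)
  q2 <- 1 - colSums(press) / ssy
  gains <- diff(c(0, q2))
  passing <- which(gains > gain)
  chosen <- if (length(passing)) max(passing) else 1L
  structure(list(q2 = tibble::tibble(A = seq_len(A_max), q2 = q2,
                                     gain = gains),
                 chosen_A = chosen,
                 rule = sprintf("largest A with marginal Q2 gain > %g", gain)),
            class = "pls_cv")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("# PLS2 fit (NIPALS): %d samples, %d predictors, %d responses, %d components\n",
              x$n, nrow(x$W), nrow(x$Q), x$A))
  ssy_tot <- sum(x$Y^2)
  cat(sprintf("  Y variance explained: %.1f%%\n", 100 * sum(x$ssy) / ssy_tot))
  cat(sprintf("  VIP > 1: %d of %d predictors\n", sum(x$vip > 1), nrow(x$W)))
  invisible(x)
}

#' Tidy a PLS fit
#'
#' One row per predictor: NIPALS weights per component and the VIP
#' score.
#'
#' @param x A `pls_fit`.
#' @param ... Unused.
#' @export
tidy.pls_fit <- function(x, ...) {
  w <- `colnames<-`(x$W, paste0("w", seq_len(x$A)))
  dplyr::bind_cols(tibble::tibble(term = rownames(x$W)),
                   tibble::as_tibble(w),
                   tibble::tibble(vip = unname(x$vip)))
}

#' @rdname tidy.pls_fit
#' @export
glance.pls_fit <- function(x, ...) {
  tibble::tibble(n = x$n, p = nrow(x$W), m = nrow(x$Q), A = x$A,
                 r2y = sum(x$ssy) / sum(x$Y^2),
                 n_vip_gt1 = sum(x$vip > 1))
}
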