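#' Principal component analysis with a deterministic sign convention
#'
#' Exact SVD-based PCA. Each component's sign is fixed so that the
#' largest-magnitude entry of its loading vector is positive, making
#' results reproducible across platforms. Community snapshots are
#' typically run centered on relative abundances; volatile profiles
#' centered and variance-scaled (concentrations span several orders of
#' magnitude) -- both are arguments, not policy.
#'
#' @param x Samples-by-variables matrix or data frame (numeric columns
#'   only; a `row_id`-style first column of labels is used as row names).
#' @param center,unit_variance Column centering / scaling flags.
#' @return Object of class `pca_ord`: `scores` and `loadings` tibbles,
#'   `var_explained` (fractions summing to 1), `sdev`, and the
#'   preprocessing record.
#' @export
#' @examples
#' pca(matrix(rnorm(20), 5, 4))
pca <- function(x, center = TRUE, unit_variance = FALSE) {
  if (is.data.frame(x)) {
    labels <- if (!is.numeric(x[[1]])) as.character(x[[1]]) else NULL
    if (!is.null(labels)) x <- x[-1]
    x <- as.matrix(x)
    if (!is.null(labels)) rownames(x) <- labels
  }
  if (nrow(x) < 2) stop("PCA needs at least 2 samples", call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- paste0("sample", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("var", seq_len(ncol(x)))

  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) stop("matrix is constant: no variance to decompose",
                          call. = FALSE)
  if (unit_variance && any(sds == 0)) {
    stop("zero-variance columns cannot be variance-scaled; drop them first",
         call. = FALSE)
  }
  proc <- scale(x, center = center, scale = if (unit_variance) sds else FALSE)
  sv <- svd(proc)
  k <- sum(sv$d > max(sv$d) * 1e-12)
  k <- max(k, 1L)
  d <- sv$d[seq_len(k)]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(d, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: dominant loading entry positive
  for (a in seq_len(k)) {
    i <- which.max(abs(loadings[, a]))
    if (loadings[i, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  ve <- d^2 / sum(sv$d^2)
  pcs <- paste0("PC", seq_len(k))
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(row_id = rownames(x)),
                              tibble::as_tibble(`colnames<-`(scores, pcs))),
    loadings = dplyr::bind_cols(tibble::tibble(variable = colnames(x)),
                                tibble::as_tibble(`colnames<-`(loadings, pcs))),
    var_explained = stats::setNames(ve, pcs),
    sdev = d / sqrt(max(1, nrow(x) - 1)),
    center = center, unit_variance = unit_variance,
    processed = proc), class = "pca_ord")
}

#' @export
print.pca_ord <- function(x, ...) {
  cat("# PCA:", nrow(x$scores), "samples,", nrow(x$loadings), "variables\n")
  ve <- round(100 * x$var_explained[seq_len(min(3, length(x$var_explained)))], 1)
  cat("  variance explained:", paste0(names(ve), " ", ve, "%", collapse = ", "),
      "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy PCA results
#'
#' @param x A `pca_ord` object.
#' @param matrix `"scores"`, `"loadings"` or `"eigenvalues"`.
#' @param ... Unused.
#' @export
tidy.pca_ord <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                         ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
         scores = x$scores,
         loadings = x$loadings,
         eigenvalues = tibble::tibble(component = names(x$var_explained),
                                      sdev = x$sdev,
                                      var_explained = unname(x$var_explained)))
}

#' @rdname tidy.pca_ord
#' @export
glance.pca_ord <- function(x, ...) {
  tibble::tibble(n_components = length(x$var_explained),
                 pc1_var = unname(x$var_explained[1]),
                 pc2_var = if (length(x$var_explained) > 1)
                   unname(x$var_explained[2]) else NA_real_)
}
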