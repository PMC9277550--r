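#' Correlation matrix with t-based p-values
#'
#' Pairwise Pearson or Spearman correlations with two-sided p-values
#' from the exact t transform `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom. Zero-variance variables yield `NA`
#' correlations (they are reported, and excluded from networks).
#'
#' @param x Samples-by-variables numeric matrix or data frame (>= 4
#'   samples; p-values are meaningless below that).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with matrices `r`, `p` and the sample size `n`.
#' @export
correlation_matrix <- function(x, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (nrow(x) < 4) stop("need at least 4 samples for correlation p-values",
                        call. = FALSE)
  r <- suppressWarnings(stats::cor(x, method = method))
  diag(r) <- 1
  p <- r_to_p(r, nrow(x))
  list(r = r, p = p, n = nrow(x))
}

# two-sided p from correlation via the t transform; |r| = 1 -> p = 0
r_to_p <- function(r, n) {
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  if (is.matrix(p)) diag(p) <- 0
  p
}

#' Thresholded co-occurrence / co-exclusion network
#'
#' Keeps variable pairs with `|r| > r_threshold` and `p < p_threshold`
#' (both strict). Positive correlations are co-occurrence edges,
#' negative ones co-exclusion. Endpoints are ordered canonically so the
#' undirected edge list is deterministic.
#'
#' @param cm Output of [correlation_matrix()], or a list with `r`, `p`.
#' @param r_threshold,p_threshold Strict cut-offs in (0, 1).
#' @param types Optional named character vector of node types.
#' @param adjust Optional p-value adjustment method (e.g. `"BH"`)
#'   applied to the lower-triangle p-values before thresholding;
#'   `"none"` (default) matches plain per-pair testing.
#' @return Tibble of edges: `node_a`, `node_b`, `type_a`, `type_b`,
#'   `r`, `p`, `sign`.
#' @export
cooccurrence_network <- function(cm, r_threshold = 0.7, p_threshold = 0.01,
                                 types = NULL, adjust = "none") {
  for (thr in c(r_threshold, p_threshold)) {
    if (!is.numeric(thr) || thr <= 0 || thr >= 1) {
      stop("thresholds must lie strictly inside (0, 1)", call. = FALSE)
    }
  }
  r <- cm$r
  p <- cm$p
  idx <- which(upper.tri(r), arr.ind = TRUE)
  pvec <- p[idx]
  if (adjust != "none") pvec <- stats::p.adjust(pvec, method = adjust)
  rvec <- r[idx]
  keep <- !is.na(rvec) & abs(rvec) > r_threshold & pvec < p_threshold
  a <- rownames(r)[idx[keep, 1]]
  b <- colnames(r)[idx[keep, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  node_type <- function(nm) {
    if (is.null(types)) rep(NA_character_, length(nm)) else unname(types[nm])
  }
  out <- tibble::tibble(node_a = a, node_b = b,
                        type_a = node_type(a), type_b = node_type(b),
                        r = rvec[keep], p = pvec[keep],
                        sign = ifelse(rvec[keep] >= 0, "+", "-"))
  dplyr::arrange(out, .data$node_a, .data$node_b)
}

#' Taxa-by-volatile cross-correlation block
#'
#' Correlates taxon relative abundances with volatile concentrations
#' over aligned samples. When both tables carry replicates the alignment
#' is replicate-level; otherwise both sides are collapsed to stage means
#' (the usual case when volatiles are only reported per stage).
#' Not-detected concentrations are treated as 0 (below detection).
#'
#' @param abund An [abund_tbl]; counts are converted to relative
#'   abundances.
#' @param v A [volatile_tbl].
#' @param method `"pearson"` or `"spearman"`.
#' @return List with cross-block matrices `r`, `p` (taxa x compounds),
#'   `n`, and `alignment` (`"replicate"` or `"stage"`).
#' @export
taxa_volatile_correlations <- function(abund, v,
                                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (abund_mode(abund) == "counts") abund <- to_relative(abund)
  common <- intersect(unique(abund$stage), unique(v$stage))
  if (length(common) == 0L) stop("no common stages between tables",
                                 call. = FALSE)
  vd <- tibble::as_tibble(v)
  replicate_level <- any(!is.na(vd$replicate))
  if (replicate_level) {
    am <- abund_matrix(abund)
    rownames(am) <- paste0(abund$stage, ".", abund$replicate)
    vm <- volatile_matrix(v, level = "sample", nd = 0)
    ids <- intersect(rownames(am), rownames(vm))
    am <- am[ids, , drop = FALSE]
    vm <- vm[ids, , drop = FALSE]
    alignment <- "replicate"
  } else {
    am <- apply(abund_matrix(abund), 2, function(col) {
      tapply(col, abund$stage, mean)
    })
    vm <- volatile_matrix(v, level = "stage", nd = 0)
    am <- am[common, , drop = FALSE]
    vm <- vm[common, , drop = FALSE]
    alignment <- "stage"
  }
  n <- nrow(am)
  if (n < 4) stop("fewer than 4 aligned samples", call. = FALSE)
  if (method == "spearman") {
    am <- apply(am, 2, rank)
    vm <- apply(vm, 2, rank)
  }
  r <- suppressWarnings(stats::cor(am, vm))
  constant <- apply(am, 2, stats::sd) == 0
  if (any(constant)) {
    warning("constant taxon series excluded from correlations: ",
            paste(colnames(am)[constant], collapse = ", "), call. = FALSE)
  }
  list(r = r, p = r_to_p(r, n), n = n, alignment = alignment)
}
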