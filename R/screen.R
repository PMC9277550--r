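#' Configuration for the core-microbiota screen
#'
#' The screen keeps a taxon (or volatile) when all three criteria hold:
#' (i) stable presence across the fermentation -- nonzero in at least
#' `ceil(min_stage_prevalence * n_stages)` stages, optionally with a cap
#' on the coefficient of variation of its nonzero stage values;
#' (ii) PLS VIP strictly greater than `vip_threshold`;
#' (iii) at least one cross-correlation with the other block of absolute
#' value strictly greater than `r_threshold`.
#'
#' @param vip_threshold VIP cut-off (strict; default 1.0).
#' @param r_threshold Correlation cut-off (strict; default 0.6).
#' @param min_stage_prevalence Fraction of stages a series must be
#'   nonzero in (default 0.5).
#' @param max_cv Optional cap on the CV of nonzero stage values.
#' @param top_n Number of most-abundant taxa entering the screen
#'   (default 40).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(vip_threshold = 1.0, r_threshold = 0.6,
                          min_stage_prevalence = 0.5, max_cv = NULL,
                          top_n = 40) {
  stopifnot(vip_threshold > 0, r_threshold > 0,
            min_stage_prevalence > 0, min_stage_prevalence <= 1, top_n >= 1)
  structure(list(vip_threshold = vip_threshold, r_threshold = r_threshold,
                 min_stage_prevalence = min_stage_prevalence,
                 max_cv = max_cv, top_n = top_n),
            class = "screen_config")
}

#' Stability criterion for a stage series
#'
#' @param series Per-stage abundance or concentration values (length >=
#'   2; `NA` counts as absent).
#' @param cfg A [screen_config()].
#' @return List `passed`, `n_nonzero`, `n_required`, `cv` (CV of the
#'   nonzero values, `NA` if none).
#' @export
stability_filter <- function(series, cfg = screen_config()) {
  if (length(series) == 0L) stop("empty series", call. = FALSE)
  if (length(series) < 2L) stop("stability needs at least 2 stages",
                                call. = FALSE)
  present <- !is.na(series) & series > 0
  n_req <- ceiling(cfg$min_stage_prevalence * length(series))
  vals <- series[present]
  cv <- if (length(vals) >= 2 && mean(vals) > 0) {
    stats::sd(vals) / mean(vals)
  } else if (length(vals) >= 1) 0 else NA_real_
  passed <- sum(present) >= n_req &&
    (is.null(cfg$max_cv) || (!is.na(cv) && cv <= cfg$max_cv))
  list(passed = passed, n_nonzero = sum(present), n_required = n_req,
       cv = cv)
}

#' Three-criteria core screen
#'
#' Screens taxa and volatiles for membership in the core functional
#' microbiota / core volatile set: stable presence, VIP > threshold, and
#' a strong cross-correlation (see [screen_config()]). Taxa enter as the
#' `top_n` most abundant; the PLS2 model regresses all volatiles on
#' those taxa, and volatile VIPs come from a second fit with the blocks
#' swapped (volatiles predicting taxa).
#'
#' @param abund An [abund_tbl] (counts or relative).
#' @param v A [volatile_tbl].
#' @param cfg A [screen_config()].
#' @param A Number of PLS components; `NULL` (default) selects by
#'   leave-one-out Q2 via [select_components_cv()].
#' @param method Correlation method for criterion (iii).
#' @return Object of class `core_screen`: tibbles `taxa` and
#'   `volatiles` (per-candidate flags and diagnostics), `edges` (the
#'   bipartite network among core members), the fitted models and the
#'   config.
#' @export
screen_core <- function(abund, v, cfg = screen_config(), A = NULL,
                        method = "pearson") {
  rel <- if (abund_mode(abund) == "counts") to_relative(abund) else abund
  top <- top_n_taxa(rel, cfg$top_n)

  # align X (taxa) and Y (volatiles) on the same samples
  cc <- taxa_volatile_correlations(top, v, method = method)
  if (cc$alignment == "replicate") {
    am <- abund_matrix(top)
    rownames(am) <- paste0(top$stage, ".", top$replicate)
    vm <- volatile_matrix(v, level = "sample", nd = 0)
  } else {
    am <- apply(abund_matrix(top), 2, function(col) tapply(col, top$stage, mean))
    vm <- volatile_matrix(v, level = "stage", nd = 0)
  }
  ids <- intersect(rownames(am), rownames(vm))
  am <- am[ids, , drop = FALSE]
  vm <- vm[ids, , drop = FALSE]

  if (is.null(A)) {
    A <- select_components_cv(am, vm, A_max = min(5, nrow(am) - 2))$chosen_A
  }
  n <- nrow(am)
  fit_xy <- suppressWarnings(fit_pls2(am, vm, A = min(A, n - 1, ncol(am))))
  fit_yx <- suppressWarnings(fit_pls2(vm, am, A = min(A, n - 1, ncol(vm))))

  stages <- sort(unique(top$stage))
  stage_mean <- function(mat, grp) {
    apply(mat, 2, function(col) tapply(col, grp, mean))
  }
  taxa_stage <- stage_mean(abund_matrix(top), top$stage)
  vol_stage <- volatile_matrix(v, level = "stage", nd = NA)

  flag_block <- function(names_all, stage_mat, vip, r_block, margin) {
    purrr::map_dfr(names_all, function(nm) {
      stab <- stability_filter(stage_mat[, nm], cfg)
      vip_val <- if (nm %in% names(vip)) unname(vip[nm]) else NA_real_
      rvals <- if (margin == 1) r_block[nm, ] else r_block[, nm]
      max_abs_r <- if (all(is.na(rvals))) NA_real_ else max(abs(rvals),
                                                            na.rm = TRUE)
      tibble::tibble(
        name = nm,
        passed_stability = stab$passed,
        n_stages_present = stab$n_nonzero, cv = stab$cv,
        vip = vip_val, max_abs_r = max_abs_r,
        passed_vip = !is.na(vip_val) && vip_val > cfg$vip_threshold,
        passed_r = !is.na(max_abs_r) && max_abs_r > cfg$r_threshold)
    }) |>
      dplyr::mutate(passed = .data$passed_stability & .data$passed_vip &
                      .data$passed_r)
  }

  taxa_tbl <- flag_block(colnames(am), taxa_stage, fit_xy$vip, cc$r, 1)
  vol_tbl <- flag_block(colnames(vm), vol_stage, fit_yx$vip, cc$r, 2)

  res <- structure(list(taxa = taxa_tbl, volatiles = vol_tbl,
                        r = cc$r, p = cc$p, n = cc$n,
                        alignment = cc$alignment,
                        fit_taxa = fit_xy, fit_volatiles = fit_yx,
                        config = cfg,
                        kingdom = abund_kingdom(abund)),
                   class = "core_screen")
  res$edges <- bipartite_network(res)
  res
}

#' Bipartite core-taxon / core-volatile network
#'
#' Emits one edge per (core taxon, core volatile) pair whose absolute
#' correlation exceeds the screening threshold, with sign and node-type
#' attributes ready for [write_edge_list()].
#'
#' @param res A [screen_core()] result.
#' @return Edge tibble (`node_a` = taxon, `node_b` = volatile).
#' @export
bipartite_network <- function(res) {
  stopifnot(inherits(res, "core_screen"))
  core_t <- res$taxa$name[res$taxa$passed]
  core_v <- res$volatiles$name[res$volatiles$passed]
  taxon_type <- paste0("taxon-", res$kingdom %||% "unknown")
  out <- tibble::tibble(node_a = character(), node_b = character(),
                        type_a = character(), type_b = character(),
                        r = numeric(), p = numeric(), sign = character())
  for (tx in core_t) {
    for (vv in core_v) {
      rr <- res$r[tx, vv]
      if (!is.na(rr) && abs(rr) > res$config$r_threshold) {
        out <- dplyr::bind_rows(out, tibble::tibble(
          node_a = tx, node_b = vv, type_a = taxon_type, type_b = "volatile",
          r = rr, p = res$p[tx, vv], sign = ifelse(rr >= 0, "+", "-")))
      }
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.core_screen <- function(x, ...) {
  cat(sprintf("# Core screen (%s alignment, n = %d): %d/%d core taxa, %d/%d core volatiles, %d edges\n",
              x$alignment, x$n,
              sum(x$taxa$passed), nrow(x$taxa),
              sum(x$volatiles$passed), nrow(x$volatiles),
              nrow(x$edges)))
  invisible(x)
}

#' @rdname screen_core
#' @param x A `core_screen` object.
#' @param ... Unused.
#' @export
glance.core_screen <- function(x, ...) {
  tibble::tibble(n_core_taxa = sum(x$taxa$passed),
                 n_core_volatiles = sum(x$volatiles$passed),
                 n_edges = nrow(x$edges),
                 alignment = x$alignment, n = x$n)
}
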