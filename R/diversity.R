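#' Alpha-diversity estimators
#'
#' Classical per-sample community summaries. Richness-type estimators
#' (observed richness, Chao1, Good's coverage) are defined on integer
#' counts; evenness-type indices (Shannon, Simpson) accept counts or
#' proportions, which are normalized internally.
#'
#' `chao1()` is the bias-corrected form
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` with `F1`/`F2` the singleton and
#' doubleton counts. `goods_coverage()` is `1 - F1 / N`. `simpson()`
#' returns the Gini--Simpson index `1 - sum(p^2)` by default; set
#' `dominance = TRUE` for `sum(p^2)`.
#'
#' @param counts Nonnegative numeric vector (integers for the
#'   richness-type estimators).
#' @param base Logarithm base for `shannon()`: `exp(1)` (default) or 2.
#' @param dominance Return the Simpson dominance form instead of
#'   Gini--Simpson.
#' @return A single number.
#' @name alpha-diversity
NULL

check_counts <- function(counts, integer_only = FALSE) {
  if (length(counts) == 0L || all(counts == 0)) {
    stop("counts are empty or all zero", call. = FALSE)
  }
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (integer_only && any(abs(counts - round(counts)) > 1e-8)) {
    stop("this estimator is defined on integer counts", call. = FALSE)
  }
  counts
}

#' @rdname alpha-diversity
#' @export
observed_richness <- function(counts) {
  check_counts(counts, integer_only = TRUE)
  sum(counts > 0)
}

#' @rdname alpha-diversity
#' @export
chao1 <- function(counts) {
  check_counts(counts, integer_only = TRUE)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  sum(counts > 0) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' @rdname alpha-diversity
#' @export
shannon <- function(counts, base = exp(1)) {
  check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' @rdname alpha-diversity
#' @export
simpson <- function(counts, dominance = FALSE) {
  check_counts(counts)
  p <- counts / sum(counts)
  d <- sum(p^2)
  if (dominance) d else 1 - d
}

#' @rdname alpha-diversity
#' @export
goods_coverage <- function(counts) {
  check_counts(counts, integer_only = TRUE)
  1 - sum(counts == 1) / sum(counts)
}

#' Per-sample alpha-diversity table
#'
#' Applies all five estimators to every sample of a counts-mode
#' abundance table. An optional seeded subsampling (rarefaction without
#' replacement) to a common depth is available but off by default.
#'
#' @param t An [abund_tbl] in counts mode.
#' @param base Shannon log base.
#' @param rarefy_to Optional depth for seeded subsampling without
#'   replacement before estimation.
#' @param seed Seed used when `rarefy_to` is set.
#' @return Tibble with one row per sample: `sample_id`, `stage`,
#'   `replicate`, `observed_species`, `chao1`, `shannon`, `simpson`,
#'   `goods_coverage`.
#' @export
alpha_diversity <- function(t, base = exp(1), rarefy_to = NULL, seed = 1) {
  if (abund_mode(t) != "counts") {
    stop("alpha_diversity() requires a counts-mode table", call. = FALSE)
  }
  m <- abund_matrix(t)
  if (!is.null(rarefy_to)) {
    m <- withr::with_seed(seed, {
      base::t(apply(m, 1, subsample_counts, depth = rarefy_to))
    })
  }
  purrr::map_dfr(seq_len(nrow(m)), function(i) {
    x <- m[i, ]
    tibble::tibble(sample_id = t$sample_id[i], stage = t$stage[i],
                   replicate = t$replicate[i],
                   observed_species = observed_richness(x),
                   chao1 = chao1(x), shannon = shannon(x, base = base),
                   simpson = simpson(x), goods_coverage = goods_coverage(x))
  })
}

# draw `depth` reads without replacement from a count vector
subsample_counts <- function(x, depth) {
  total <- sum(x)
  if (depth >= total) return(x)
  drawn <- sample.int(total, depth)
  breaks <- c(0, cumsum(x))
  as.numeric(table(factor(findInterval(drawn, breaks, left.open = TRUE),
                          levels = seq_along(x))))
}

#' Stage-wise OTU presence sets
#'
#' Pools replicates within each stage (presence = pooled count > 0) and
#' reports per-stage richness, the size of the all-stage intersection,
#' and per-stage unique counts (taxa seen in exactly one stage).
#'
#' @param t An [abund_tbl] in counts mode.
#' @param stages Optional subset/order of stage labels; unknown labels
#'   are an error.
#' @return List with `per_stage` (tibble `stage`, `n_otus`, `n_unique`),
#'   `shared_all` (integer) and `sets` (named list of taxon character
#'   vectors).
#' @export
stage_otu_sets <- function(t, stages = NULL) {
  if (abund_mode(t) != "counts") {
    stop("presence/absence sets require a counts-mode table", call. = FALSE)
  }
  if (is.null(stages)) stages <- unique(t$stage)
  unknown <- setdiff(stages, t$stage)
  if (length(unknown)) stop("unknown stage label: ", unknown[1], call. = FALSE)
  m <- abund_matrix(t)
  sets <- lapply(stages, function(s) {
    colnames(m)[colSums(m[t$stage == s, , drop = FALSE]) > 0]
  })
  names(sets) <- stages
  all_taxa <- unlist(sets)
  n_stages_seen <- table(all_taxa)
  per_stage <- tibble::tibble(
    stage = stages,
    n_otus = unname(vapply(sets, length, integer(1))),
    n_unique = unname(vapply(sets, function(s) {
      sum(n_stages_seen[s] == 1)
    }, integer(1))))
  list(per_stage = per_stage,
       shared_all = length(Reduce(intersect, sets)),
       sets = sets)
}
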