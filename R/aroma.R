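#' Internal-standard semi-quantification
#'
#' Converts GC-MS peak areas to concentrations against a spiked internal
#' standard: `conc_i = area_i / is_area * is_conc`. With the study's
#' spiking scheme (2 uL of a 30 mg/mL 3-octanol stock into a 10 mL
#' sample) the internal-standard concentration is 6000 ug/L.
#'
#' @param areas Named numeric vector of compound peak areas.
#' @param is_area Internal-standard peak area (> 0).
#' @param is_conc Internal-standard concentration in ug/L (> 0).
#' @return Tibble `compound`, `area`, `concentration`.
#' @export
quantify_internal_standard <- function(areas, is_area, is_conc = 6000) {
  if (!is.numeric(is_area) || is_area <= 0) {
    stop("internal-standard area must be positive", call. = FALSE)
  }
  if (is_conc <= 0) stop("internal-standard concentration must be positive",
                         call. = FALSE)
  tibble::tibble(
    compound = if (is.null(names(areas)))
      paste0("compound", seq_along(areas)) else names(areas),
    area = as.numeric(areas),
    concentration = as.numeric(areas) / is_area * is_conc)
}

# step banding of an OAV value; [0.1, 1] is the middle band, inclusive
oav_band <- function(oav) {
  dplyr::case_when(is.na(oav) ~ NA_character_,
                   oav < 0.1 ~ "<0.1",
                   oav <= 1 ~ "0.1-1",
                   TRUE ~ ">1")
}

#' Odor activity values at a fermentation stage
#'
#' OAV is concentration divided by odor threshold; values above 1 mark
#' compounds expected to contribute perceptibly to aroma. One record per
#' compound: OAV and band are `NA` when the compound is not detected at
#' the stage or its threshold is unavailable.
#'
#' @param v A [volatile_tbl].
#' @param th Threshold table from [read_odor_thresholds()] /
#'   [load_table1_fixture()].
#' @param stage Stage label (default `"F"`, the end of fermentation).
#' @param threshold_policy How to collapse a threshold range: `"low"`
#'   (default, aroma-conservative), `"high"`, or `"midpoint"`.
#' @return Tibble `compound`, `class`, `stage`, `concentration`,
#'   `threshold`, `oav`, `band`.
#' @export
compute_oav <- function(v, th, stage = "F",
                        threshold_policy = c("low", "high", "midpoint")) {
  threshold_policy <- match.arg(threshold_policy)
  d <- tibble::as_tibble(v)
  if (!stage %in% d$stage) stop("unknown stage: ", stage, call. = FALSE)
  d <- d[d$stage == stage, , drop = FALSE]
  if (!is.na(d$replicate[1]) && any(!is.na(d$replicate))) {
    d <- dplyr::summarise(dplyr::group_by(d, .data$compound, .data$class),
                          concentration = mean(.data$concentration, na.rm = TRUE),
                          .groups = "drop")
    d$stage <- stage
  }
  th$threshold <- switch(threshold_policy,
                         low = th$threshold_low,
                         high = th$threshold_high,
                         midpoint = (th$threshold_low + th$threshold_high) / 2)
  out <- dplyr::left_join(d, th[c("compound", "threshold")], by = "compound")
  out$oav <- out$concentration / out$threshold
  out$band <- oav_band(out$oav)
  out[c("compound", "class", "stage", "concentration", "threshold",
        "oav", "band")]
}

#' Compare computed OAV bands against published bands
#'
#' Recomputes final-stage OAV bands and lines them up with a published
#' band column, flagging mismatches instead of asserting agreement --
#' printed tables are known to contain inconsistencies (in the shipped
#' fixture, ethanol's published "> 1" cannot be derived from its
#' final-stage concentration and threshold).
#'
#' @inheritParams compute_oav
#' @return Tibble with `computed_band`, `printed_band` and a logical
#'   `match` (`NA` when either band is undefined).
#' @export
oav_band_agreement <- function(v, th, stage = "F",
                               threshold_policy = "low") {
  rec <- compute_oav(v, th, stage = stage,
                     threshold_policy = threshold_policy)
  out <- dplyr::left_join(rec, th[c("compound", "printed_band")],
                          by = "compound")
  out$computed_band <- out$band
  out$match <- ifelse(is.na(out$computed_band) | is.na(out$printed_band),
                      NA, out$computed_band == out$printed_band)
  out[c("compound", "class", "concentration", "threshold", "oav",
        "computed_band", "printed_band", "match")]
}

#' Cluster volatile temporal profiles
#'
#' Groups compounds by the shape of their concentration trajectory over
#' stages: per-compound stage profiles are z-scored (not-detected taken
#' as 0, i.e. below detection, before scaling) and clustered by
#' agglomerative hierarchical clustering (Euclidean distance, average
#' linkage by default), cut into `k` groups. With `k = 2` this separates
#' fruit-borne volatiles that fade early from fermentation products that
#' accumulate late.
#'
#' @param v A [volatile_tbl].
#' @param k Number of clusters (2 <= k <= number of compounds).
#' @param method Linkage passed to [stats::hclust()].
#' @param distance Distance measure passed to [stats::dist()].
#' @return Tibble `compound`, `cluster` plus the `hclust` tree in
#'   attribute `"tree"`.
#' @export
cluster_volatile_profiles <- function(v, k = 2, method = "average",
                                      distance = "euclidean") {
  m <- volatile_matrix(v, level = "stage", nd = 0)     # stages x compounds
  prof <- base::t(m)                                   # compounds x stages
  if (k < 2 || k > nrow(prof)) {
    stop("k must be between 2 and the number of compounds", call. = FALSE)
  }
  sds <- apply(prof, 1, stats::sd)
  z <- (prof - rowMeans(prof)) / ifelse(sds > 0, sds, 1)
  tree <- stats::hclust(stats::dist(z, method = distance), method = method)
  cl <- stats::cutree(tree, k = k)
  out <- tibble::tibble(compound = rownames(prof), cluster = unname(cl))
  attr(out, "tree") <- tree
  out
}
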