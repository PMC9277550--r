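#' Construct an abundance table
#'
#' An abundance table is a tibble with one row per sample, metadata columns
#' `sample_id`, `stage`, `replicate`, and one numeric column per taxon.
#' Fermentation stages are labels (the shipped study design uses A--F for
#' days 0, 3, 6, 9, 13, 16); replicates are integers within stage.
#'
#' @param data A data frame with `stage` and `replicate` columns plus
#'   numeric taxon columns. A `sample_id` column is created from
#'   `stage`/`replicate` when absent.
#' @param kingdom Kingdom label for all taxa in the table, typically
#'   `"fungal"` or `"bacterial"`.
#' @param mode `"counts"` or `"relative"`. `NULL` (default) auto-detects:
#'   rows summing to 1 within `1e-6` are taken as relative abundances.
#' @return A tibble of class `abund_tbl` with attributes `kingdom` and
#'   `mode`.
#' @export
#' @examples
#' abund_tbl(data.frame(stage = c("A", "B"), replicate = 1L,
#'                      TaxonX = c(3, 5), TaxonY = c(1, 0)),
#'           kingdom = "fungal")
abund_tbl <- function(data, kingdom = "fungal", mode = NULL) {
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0L) stop("abundance table is empty", call. = FALSE)
  for (col in c("stage", "replicate")) {
    if (!col %in% names(data)) {
      stop("abundance table needs a '", col, "' column", call. = FALSE)
    }
  }
  data$stage <- as.character(data$stage)
  data$replicate <- as.integer(data$replicate)
  if (!"sample_id" %in% names(data)) {
    data$sample_id <- paste0(data$stage, data$replicate)
  }
  meta <- c("sample_id", "stage", "replicate")
  data <- dplyr::relocate(data, dplyr::all_of(meta))
  taxa <- setdiff(names(data), meta)
  if (length(taxa) == 0L) stop("abundance table has no taxon columns", call. = FALSE)
  if (anyDuplicated(taxa)) stop("duplicate taxon names", call. = FALSE)

  m <- as.matrix(data[taxa])
  if (!is.numeric(m)) stop("taxon columns must be numeric", call. = FALSE)
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("negative abundance at sample '%s', taxon '%s'",
                 data$sample_id[bad[1, 1]], taxa[bad[1, 2]]), call. = FALSE)
  }
  dup <- duplicated(data[c("stage", "replicate")])
  if (any(dup)) {
    stop(sprintf("duplicate (stage, replicate) pair: (%s, %d)",
                 data$stage[dup][1], data$replicate[dup][1]), call. = FALSE)
  }
  if (is.null(mode)) {
    mode <- if (all(abs(rowSums(m) - 1) <= 1e-6)) "relative" else "counts"
  }
  mode <- match.arg(mode, c("counts", "relative", "relative_subset"))
  if (mode == "relative" && any(abs(rowSums(m) - 1) > 1e-9)) {
    stop("mode = 'relative' but sample rows do not sum to 1", call. = FALSE)
  }
  structure(data,
            class = c("abund_tbl", class(tibble::tibble())),
            kingdom = kingdom, mode = mode)
}

#' @rdname abund_tbl
#' @param t An `abund_tbl`.
#' @export
taxa_names <- function(t) {
  setdiff(names(t), c("sample_id", "stage", "replicate"))
}

#' @rdname abund_tbl
#' @export
abund_matrix <- function(t) {
  m <- as.matrix(t[taxa_names(t)])
  rownames(m) <- t$sample_id
  m
}

abund_mode <- function(t) attr(t, "mode")
abund_kingdom <- function(t) attr(t, "kingdom")

# Rebuild an abund_tbl from metadata plus a new taxon matrix, keeping attrs.
rebuild_abund <- function(t, m, mode = abund_mode(t)) {
  out <- dplyr::bind_cols(t[c("sample_id", "stage", "replicate")],
                          tibble::as_tibble(m))
  abund_tbl(out, kingdom = abund_kingdom(t), mode = mode)
}

#' Read an abundance table from TSV
#'
#' Expects taxa as columns and samples as rows, with metadata columns
#' `stage` and `replicate` (and optionally `sample_id`). The mode
#' (counts vs. relative abundance) is auto-detected from row sums.
#'
#' @param path Path to a UTF-8 tab-separated file.
#' @param kingdom Kingdom label attached to the table.
#' @return An [abund_tbl].
#' @export
read_abundance_table <- function(path, kingdom = "fungal") {
  data <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  abund_tbl(data, kingdom = kingdom)
}

#' Write an abundance table to TSV
#'
#' @param t An [abund_tbl].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(t, path) {
  readr::write_tsv(tibble::as_tibble(t), path, progress = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Divides each sample row by its total so rows sum to one.
#'
#' @param t An [abund_tbl] in counts mode (relative input is returned
#'   unchanged).
#' @return An [abund_tbl] with `mode = "relative"`.
#' @export
to_relative <- function(t) {
  if (abund_mode(t) == "relative") return(t)
  m <- abund_matrix(t)
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    stop(sprintf("sample '%s' has zero total abundance",
                 t$sample_id[which(tot <= 0)[1]]), call. = FALSE)
  }
  rebuild_abund(t, sweep(m, 1, tot, "/"), mode = "relative")
}

#' Aggregate taxa into higher-rank groups
#'
#' Sums member abundances within each group; per-sample totals are
#' conserved exactly. Taxa missing from the mapping are pooled into
#' `other`.
#'
#' @param t An [abund_tbl].
#' @param mapping Named character vector `taxon -> group`.
#' @param other Group label for unmapped taxa.
#' @return An [abund_tbl] over the groups.
#' @export
aggregate_taxa <- function(t, mapping, other = "Other") {
  if (length(mapping) == 0L) stop("empty taxon mapping", call. = FALSE)
  taxa <- taxa_names(t)
  grp <- unname(mapping[taxa])
  grp[is.na(grp)] <- other
  m <- abund_matrix(t)
  agg <- t(rowsum(base::t(m), group = grp))
  rebuild_abund(t, agg[, sort(colnames(agg)), drop = FALSE])
}

#' Keep the n most abundant taxa
#'
#' Ranks taxa by mean relative abundance across samples; ties are broken
#' towards the lexicographically smaller taxon name so the selection is
#' deterministic.
#'
#' @param t An [abund_tbl] in relative mode.
#' @param n Number of taxa to keep; if `n` exceeds the number of taxa all
#'   are kept.
#' @return An [abund_tbl] restricted to the selected taxa (rows no longer
#'   sum to one, so the result is flagged as counts-free `"relative"`
#'   values of the original table).
#' @export
top_n_taxa <- function(t, n) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0) {
    stop("n must be a positive integer", call. = FALSE)
  }
  if (abund_mode(t) != "relative") {
    stop("top_n_taxa() expects a relative-abundance table; see to_relative()",
         call. = FALSE)
  }
  m <- abund_matrix(t)
  means <- colMeans(m)
  ord <- order(-means, colnames(m))
  keep <- sort(colnames(m)[ord[seq_len(min(n, ncol(m)))]])
  rebuild_abund(t, m[, keep, drop = FALSE], mode = "relative_subset")
}

#' @export
print.abund_tbl <- function(x, ...) {
  cat(sprintf("# Abundance table: %d samples x %d taxa (%s, %s)\n",
              nrow(x), length(taxa_names(x)),
              abund_kingdom(x), abund_mode(x)))
  NextMethod()
}
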