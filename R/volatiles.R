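#' Construct a volatile-compound concentration table
#'
#' A long tibble with one row per (stage, replicate, compound): columns
#' `stage`, `replicate` (`NA` for stage-level means), `compound`, `class`
#' (one of ester, alcohol, aldehyde, ketone, terpene, phenol, acid) and
#' `concentration` in ug/L. `NA` concentration means "not detected" (Nd),
#' which is distinct from a measured zero.
#'
#' @param data Data frame with the columns above.
#' @return A tibble of class `volatile_tbl`.
#' @export
volatile_tbl <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("stage", "compound", "class", "concentration")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!"replicate" %in% names(data)) data$replicate <- NA_integer_
  data$stage <- as.character(data$stage)
  data$compound <- as.character(data$compound)
  if (any(data$concentration < 0, na.rm = TRUE)) {
    stop("negative concentration", call. = FALSE)
  }
  key <- data[c("stage", "replicate", "compound")]
  if (anyDuplicated(key)) stop("duplicate (stage, replicate, compound) rows",
                               call. = FALSE)
  cls <- dplyr::distinct(data, .data$compound, .data$class)
  if (anyDuplicated(cls$compound)) {
    stop("a compound carries more than one class label", call. = FALSE)
  }
  structure(data, class = c("volatile_tbl", class(tibble::tibble())))
}

#' Widen a volatile table into a samples-by-compounds matrix
#'
#' @param v A [volatile_tbl].
#' @param level `"sample"` keeps replicate rows (row names
#'   `stage`/`stage.replicate`); `"stage"` averages detected replicate
#'   concentrations per stage.
#' @param nd Value substituted for not-detected entries (default 0,
#'   i.e. below detection limit); use `NA` to keep them missing.
#' @return Numeric matrix, rows ordered by stage then replicate.
#' @export
volatile_matrix <- function(v, level = c("sample", "stage"), nd = 0) {
  level <- match.arg(level)
  d <- tibble::as_tibble(v)
  if (level == "stage") {
    d <- dplyr::summarise(dplyr::group_by(d, .data$stage, .data$compound),
                          concentration = if (all(is.na(.data$concentration)))
                            NA_real_ else
                            mean(.data$concentration, na.rm = TRUE),
                          .groups = "drop")
    d$row_id <- d$stage
  } else {
    d$row_id <- ifelse(is.na(d$replicate), d$stage,
                       paste0(d$stage, ".", d$replicate))
  }
  w <- tidyr::pivot_wider(d[c("row_id", "compound", "concentration")],
                          names_from = "compound",
                          values_from = "concentration")
  w <- w[order(w$row_id), , drop = FALSE]
  m <- as.matrix(w[-1])
  rownames(m) <- w$row_id
  if (!is.na(nd)) m[is.na(m)] <- nd
  m
}

#' @rdname volatile_tbl
#' @param path CSV path (long format, UTF-8).
#' @export
read_volatile_table <- function(path) {
  volatile_tbl(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname volatile_tbl
#' @param v A [volatile_tbl].
#' @export
write_volatile_table <- function(v, path) {
  readr::write_csv(tibble::as_tibble(v), path, progress = FALSE)
  invisible(path)
}

#' Read an odor-threshold table
#'
#' The CSV has columns `compound` and `odor_threshold`; thresholds may be
#' a single value, a range like `"20-50"`, or `"/"` for unavailable. An
#' optional `printed_band` column carries a published OAV band for
#' agreement checks.
#'
#' @param path CSV path.
#' @return Tibble with `compound`, `threshold_low`, `threshold_high`
#'   (equal for single values, `NA` when unavailable) and `printed_band`.
#' @export
read_odor_thresholds <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  parse_th <- function(s) {
    s <- trimws(s)
    if (is.na(s) || s == "/" || s == "") return(c(NA_real_, NA_real_))
    parts <- strsplit(s, "-", fixed = TRUE)[[1]]
    lo <- as.numeric(parts[1])
    hi <- if (length(parts) > 1) as.numeric(parts[2]) else lo
    if (is.na(lo) || lo <= 0 || hi < lo) {
      stop("bad odor threshold: ", s, call. = FALSE)
    }
    c(lo, hi)
  }
  th <- t(unname(vapply(raw$odor_threshold, parse_th, numeric(2))))
  out <- tibble::tibble(
    compound = raw$compound,
    threshold_low = th[, 1],
    threshold_high = th[, 2],
    printed_band = if ("printed_band" %in% names(raw)) {
      b <- raw$printed_band
      b[!is.na(b) & b == ""] <- NA_character_
      b
    } else NA_character_
  )
  if (anyDuplicated(out$compound)) stop("duplicate compound in threshold table",
                                        call. = FALSE)
  out
}

#' Load the published flat-peach-wine volatile table
#'
#' Returns the 53-compound stage-by-compound concentration table from the
#' flat-peach-wine fermentation study (stages A--F, means of n = 3 with
#' standard deviations kept in an `sd` column), together with the odor
#' thresholds and the published OAV bands. Compound classes follow the
#' printed table sections verbatim (the lactone 4-undecanolide sits under
#' aldehydes, the other lactones under esters). "Nd" entries are `NA`.
#'
#' @return A list with elements `volatiles` (a [volatile_tbl] with an
#'   extra `sd` column) and `thresholds` (see [read_odor_thresholds()]).
#' @export
load_table1_fixture <- function() {
  vfile <- system.file("extdata", "table1_volatiles.csv", package = "fermnet",
                       mustWork = TRUE)
  tfile <- system.file("extdata", "table1_thresholds.csv", package = "fermnet",
                       mustWork = TRUE)
  raw <- readr::read_csv(vfile, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  long <- tidyr::pivot_longer(raw,
                              cols = dplyr::matches("^[A-F]_(mean|sd)$"),
                              names_to = c("stage", ".value"),
                              names_sep = "_")
  long$concentration <- suppressWarnings(
    ifelse(long$mean == "Nd", NA_real_, as.numeric(long$mean)))
  long$sd <- suppressWarnings(as.numeric(long$sd))
  long$retention_index <- suppressWarnings(as.numeric(long$retention_index))
  v <- volatile_tbl(long[c("stage", "compound", "class", "concentration",
                           "sd", "retention_index")])
  list(volatiles = v, thresholds = read_odor_thresholds(tfile))
}
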