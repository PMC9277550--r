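#' Write and read weighted edge lists
#'
#' Tab-separated edge lists with columns `node_a`, `node_b`, `type_a`,
#' `type_b`, `r`, `p`, `sign`, importable by Cytoscape and other network
#' viewers. Node types tag the layer of each endpoint
#' (`taxon-fungal` / `taxon-bacterial` / `volatile`).
#'
#' @param edges Tibble of edges as produced by [cooccurrence_network()]
#'   or [bipartite_network()].
#' @param path Output path.
#' @return `path` invisibly (`write_edge_list`), or the edge tibble
#'   (`read_edge_list`).
#' @export
write_edge_list <- function(edges, path) {
  cols <- c("node_a", "node_b", "type_a", "type_b", "r", "p", "sign")
  edges <- tibble::as_tibble(edges)
  for (col in setdiff(cols, names(edges))) {
    edges[[col]] <- if (col %in% c("r", "p")) NA_real_ else NA_character_
  }
  readr::write_tsv(edges[cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    node_a = "c", node_b = "c", type_a = "c", type_b = "c",
                    r = "d", p = "d", sign = "c"))
}
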