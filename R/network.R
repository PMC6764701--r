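#' Extract the top-K most confident predicted edges
#'
#' Sorts scorable predictions by score descending (ties broken by `tf_id`,
#' then `target_id`, for reproducibility) and retains the first `k`. If
#' fewer than `k` scorable pairs exist, all are returned with a warning.
#'
#' @param predictions Prediction tibble from [predict_links()].
#' @param k Number of edges to retain (>= 1).
#' @return A `pixlink_network`: tibble of `tf_id`, `target_id`, `score` with
#'   attribute `k`.
#' @export
top_k_edges <- function(predictions, k) {
  stopifnot(k >= 1)
  p <- dplyr::filter(predictions, .data$scorable)
  p <- dplyr::arrange(p, dplyr::desc(.data$score), .data$tf_id,
                      .data$target_id)
  if (k > nrow(p)) {
    warning(sprintf("requested k=%d but only %d scorable pairs; returning all",
                    k, nrow(p)))
    k <- nrow(p)
  }
  net <- dplyr::select(p[seq_len(k), ], "tf_id", "target_id", "score")
  attr(net, "k") <- as.integer(k)
  class(net) <- c("pixlink_network", class(net))
  net
}

#' Hub genes of a predicted subnetwork
#'
#' Counts, for every node of the retained top-K subnetwork, the number of
#' incident edges. Both roles are reported: out-degree for TFs, in-degree
#' for targets, and their sum as `degree` (a gene acting as both contributes
#' in both roles). Hubs are the nodes with `degree >= min_degree`. The full
#' degree table is always attached so any hub cutoff can be re-queried.
#'
#' @param network A `pixlink_network` from [top_k_edges()].
#' @param min_degree Minimum incident-edge count to call a node a hub.
#' @return A `pixlink_hubs` list: `hubs` tibble (`gene_id`, `out_degree`,
#'   `in_degree`, `degree`, sorted by degree descending), `degree_table`
#'   (same columns, all nodes), `min_degree`.
#' @export
extract_hubs <- function(network, min_degree = 2) {
  if (nrow(network) == 0) stop("network is empty")
  outd <- dplyr::count(network, gene_id = .data$tf_id, name = "out_degree")
  ind <- dplyr::count(network, gene_id = .data$target_id, name = "in_degree")
  deg <- dplyr::full_join(outd, ind, by = "gene_id")
  deg$out_degree <- dplyr::coalesce(deg$out_degree, 0L)
  deg$in_degree <- dplyr::coalesce(deg$in_degree, 0L)
  deg$degree <- deg$out_degree + deg$in_degree
  deg <- dplyr::arrange(deg, dplyr::desc(.data$degree), .data$gene_id)
  structure(list(
    hubs = dplyr::filter(deg, .data$degree >= min_degree),
    degree_table = deg,
    min_degree = min_degree
  ), class = "pixlink_hubs")
}

#' @export
print.pixlink_hubs <- function(x, ...) {
  cat(sprintf("<pixlink_hubs> %d hubs at degree >= %d (of %d nodes)\n",
              nrow(x$hubs), x$min_degree, nrow(x$degree_table)))
  print(utils::head(x$hubs, 10))
  invisible(x)
}

#' @rdname extract_hubs
#' @param x A `pixlink_hubs`.
#' @param ... Unused.
#' @export
tidy.pixlink_hubs <- function(x, ...) x$degree_table

#' Count a TF's high-confidence predicted targets
#'
#' Number of predictions for one TF whose score strictly exceeds
#' `score_floor` (e.g. the links a model assigns probability above 0.8).
#'
#' @param predictions Prediction tibble from [predict_links()].
#' @param tf_id TF identifier present in `predictions`.
#' @param score_floor Strict lower bound on the score.
#' @return Integer count.
#' @export
count_high_confidence_targets <- function(predictions, tf_id,
                                          score_floor = 0.8) {
  p <- dplyr::filter(predictions, .data$scorable)
  if (!tf_id %in% p$tf_id)
    stop("no predictions for TF: ", tf_id)
  sum(p$tf_id == tf_id & p$score > score_floor)
}

#' Export a predicted network
#'
#' `"SIF"` writes one `tf_id<TAB>regulates<TAB>target_id` line per edge
#' (the Cytoscape simple-interaction format); `"GraphML"` writes an igraph
#' GraphML file with the score as an edge attribute; `"TSV"` writes
#' `tf_id`, `target_id`, `score` with full-precision scores so a read-back
#' reproduces the edge list exactly.
#'
#' @param network A `pixlink_network`.
#' @param format `"SIF"`, `"GraphML"` or `"TSV"`.
#' @param path Destination file.
#' @return The path, invisibly.
#' @export
export_network <- function(network, format = c("SIF", "GraphML", "TSV"),
                           path) {
  format <- match.arg(format)
  switch(format,
    SIF = writeLines(
      sprintf("%s\tregulates\t%s", network$tf_id, network$target_id), path),
    GraphML = {
      g <- igraph::graph_from_data_frame(
        data.frame(from = network$tf_id, to = network$target_id,
                   score = network$score), directed = TRUE)
      igraph::write_graph(g, path, format = "graphml")
    },
    TSV = {
      df <- data.frame(tf_id = network$tf_id, target_id = network$target_id,
                       score = sprintf("%.17g", network$score))
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  invisible(path)
}

#' Read a TSV network written by [export_network()]
#' @param path TSV path.
#' @return A `pixlink_network` tibble.
#' @export
read_network_tsv <- function(path) {
  df <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  class(df) <- c("pixlink_network", class(df))
  df
}

#' Write the gene list of a subnetwork (for external enrichment services)
#' @param network A `pixlink_network`.
#' @param path Destination text file, one gene id per line.
#' @return The path, invisibly.
#' @export
export_gene_list <- function(network, path) {
  writeLines(sort(unique(c(network$tf_id, network$target_id))), path)
  invisible(path)
}
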