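#' Per-timestamp topology summary
#'
#' Average node-importance measures used to demonstrate that the networks
#' change from stage to stage: mean normalized shortest-path betweenness
#' (normalized by (n-1)(n-2)/2), mean normalized closeness ((n-1) / sum of
#' distances), and mean local clustering coefficient (nodes of degree < 2
#' contribute 0). Shortest paths are unweighted; edge weights are retained
#' on the network but unused here. The mean |r| of the retained
#' (non-augmented) edges is reported as a fourth diagnostic, covering the
#' reading of average edge correlation as an importance summary.
#'
#' @param net a connected `coexpression_network`.
#' @return an object of class `topology_summary` (also a one-row data frame)
#'   with `timestamp`, `avg_betweenness`, `avg_closeness`,
#'   `avg_clustering_coefficient`, `mean_abs_corr`, `n_nodes`, `n_edges`.
#' @export
summarize_topology <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  g <- as_igraph(net)
  if (!igraph::is_connected(g)) {
    stop("network is disconnected; run enforce_connectivity() upstream")
  }
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA,
                             normalized = TRUE)
  clo <- igraph::closeness(g, weights = NA, normalized = TRUE)
  cc <- igraph::transitivity(g, type = "local", weights = NA)
  cc[is.nan(cc) | is.na(cc)] <- 0
  kept <- net$edges[!net$edges$augmented, , drop = FALSE]
  out <- data.frame(
    timestamp = net$timestamp,
    avg_betweenness = mean(btw),
    avg_closeness = mean(clo),
    avg_clustering_coefficient = mean(cc),
    mean_abs_corr = if (nrow(kept)) mean(kept$weight) else NA_real_,
    n_nodes = length(net$gene_ids),
    n_edges = nrow(net$edges))
  class(out) <- c("topology_summary", class(out))
  out
}

#' Topology trajectory over a network series
#'
#' @param nets list of >= 2 connected `coexpression_network` objects, in
#'   timestamp order.
#' @return data frame with one [summarize_topology()] row per timestamp, in
#'   input order.
#' @export
topology_trajectory <- function(nets) {
  stopifnot(length(nets) >= 2)
  out <- do.call(rbind, lapply(nets, summarize_topology))
  rownames(out) <- NULL
  out
}

#' Write topology summaries as TSV
#'
#' @param summaries output of [topology_trajectory()].
#' @param path output path.
#' @export
write_topology_tsv <- function(summaries, path) {
  utils::write.table(summaries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
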