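#' Pearson correlation matrix of selected genes
#'
#' Correlation of each gene pair across the samples of one timestamp — the
#' continuous precursor of the thresholded co-expression network. A gene with
#' zero variance gets correlation 0 to every partner (with a warning) rather
#' than propagating NaN.
#'
#' @param dataset an [expression_dataset()] (>= 3 samples).
#' @param genes optional gene ids to restrict to (default: all genes).
#' @return symmetric numeric matrix with unit diagonal.
#' @export
correlation_matrix <- function(dataset, genes = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(genes)) genes <- dataset$gene_ids
  if (!all(genes %in% dataset$gene_ids)) stop("genes absent from dataset")
  x <- dataset$values[genes, , drop = FALSE]
  if (ncol(x) < 3) stop("need >= 3 samples to correlate")
  sds <- apply(x, 1, stats::sd)
  r <- suppressWarnings(stats::cor(t(x)))
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s); correlations set to 0")
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  diag(r) <- 1
  dimnames(r) <- list(genes, genes)
  r
}

#' Threshold a correlation matrix into a co-expression network
#'
#' Ranks all n(n-1)/2 gene pairs by correlation strength and retains exactly
#' the top fraction `q` (default 10%), i.e. `ceiling(q * P)` pairs, turning
#' the continuous matrix into a discrete weighted network. Absolute
#' correlation is ranked by default so that strong negative co-expression is
#' kept; `mode = "signed"` ranks the signed value instead. Ties at the
#' boundary are broken by lexicographic gene-id pair order, making the output
#' deterministic. Edge weights are always |r|.
#'
#' @param corr symmetric correlation matrix with gene ids as dimnames.
#' @param q fraction of pairs to retain, in (0, 1].
#' @param timestamp integer timestamp index recorded on the network.
#' @param mode `"absolute"` (default) or `"signed"` ranking.
#' @return an object of class `coexpression_network`: fields `timestamp`,
#'   `gene_ids`, `edges` (data frame `gene_a`, `gene_b`, `weight`,
#'   `augmented`), `threshold_value` (smallest retained ranking score) and
#'   `q`.
#' @export
threshold_network <- function(corr, q = 0.10, timestamp = 0L,
                              mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  genes <- rownames(corr)
  stopifnot(!is.null(genes), nrow(corr) == ncol(corr))
  if (max(abs(corr - t(corr))) > 1e-8) stop("correlation matrix not symmetric")
  n <- length(genes)
  ut <- which(upper.tri(corr), arr.ind = TRUE)
  r <- corr[ut]
  score <- if (mode == "absolute") abs(r) else r
  P <- n * (n - 1) / 2
  m <- ceiling(q * P)
  # lexicographic tie-break via the genes' lexicographic ranks
  lex <- rank(genes, ties.method = "first")
  ia <- ut[, 1]; ib <- ut[, 2]
  la <- pmin(lex[ia], lex[ib]); lb <- pmax(lex[ia], lex[ib])
  ord <- order(-score, la, lb)
  keep <- ord[seq_len(m)]
  ga <- genes[ia[keep]]; gb <- genes[ib[keep]]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  edges <- data.frame(gene_a = ga, gene_b = gb,
                      weight = abs(r[keep]), augmented = FALSE,
                      stringsAsFactors = FALSE)
  structure(
    list(timestamp = as.integer(timestamp), gene_ids = genes, edges = edges,
         threshold_value = min(score[keep]), q = q, mode = mode),
    class = "coexpression_network")
}

#' @exportS3Method base::print
print.coexpression_network <- function(x, ...) {
  cat(sprintf(
    "coexpression_network: t=%d, %d nodes, %d edges (%d augmented), |r| cutoff %.3f\n",
    x$timestamp, length(x$gene_ids), nrow(x$edges), sum(x$edges$augmented),
    x$threshold_value))
  invisible(x)
}

#' Convert a network to an igraph object
#'
#' @param net a `coexpression_network`.
#' @return an undirected weighted [igraph::graph] over all network nodes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  igraph::graph_from_data_frame(
    net$edges[, c("gene_a", "gene_b", "weight")],
    directed = FALSE,
    vertices = data.frame(name = net$gene_ids, stringsAsFactors = FALSE))
}

#' Enforce connectivity of a thresholded network
#'
#' Constructed networks are required to be connected (a path between every
#' node pair). If thresholding left several components, the single strongest
#' (highest |r|) edge joining two different components is added repeatedly
#' until one component remains; at most n-1 additions. Added edges are
#' flagged in the `augmented` column; thresholded edges are untouched.
#'
#' @param net a `coexpression_network` built from `corr`.
#' @param corr the correlation matrix the network was thresholded from.
#' @return the connected `coexpression_network`.
#' @export
enforce_connectivity <- function(net, corr) {
  stopifnot(inherits(net, "coexpression_network"))
  g <- as_igraph(net)
  comp <- igraph::components(g)$membership
  if (max(comp) == 1) return(net)
  genes <- net$gene_ids
  a <- abs(corr[genes, genes])
  comp <- unname(comp[genes])
  while (max(comp) > 1) {
    mask <- outer(comp, comp, "!=")
    cand <- a * mask
    idx <- arrayInd(which.max(cand), dim(cand))
    i <- idx[1]; j <- idx[2]
    ga <- min(genes[i], genes[j]); gb <- max(genes[i], genes[j])
    net$edges <- rbind(net$edges, data.frame(
      gene_a = ga, gene_b = gb, weight = a[i, j], augmented = TRUE,
      stringsAsFactors = FALSE))
    comp[comp == comp[j]] <- comp[i]
    comp <- match(comp, sort(unique(comp)))
  }
  rownames(net$edges) <- NULL
  net
}

#' Build a connected co-expression network from expression data
#'
#' Convenience wrapper: [correlation_matrix()] then [threshold_network()]
#' then [enforce_connectivity()].
#'
#' @inheritParams correlation_matrix
#' @inheritParams threshold_network
#' @return a connected `coexpression_network`.
#' @export
build_network <- function(dataset, genes = NULL, q = 0.10, timestamp = 0L,
                          mode = c("absolute", "signed")) {
  corr <- correlation_matrix(dataset, genes)
  net <- threshold_network(corr, q = q, timestamp = timestamp, mode = mode)
  enforce_connectivity(net, corr)
}

#' Power-law fit of the degree distribution
#'
#' Diagnostic for scale-free character of a constructed network: least
#' squares of log frequency against log degree over degrees with nonzero
#' frequency. Reported as a diagnostic only, never used as a construction
#' gate.
#'
#' @param net a `coexpression_network` with >= 20 nodes.
#' @return list with `powerlaw_exponent` (positive slope magnitude) and
#'   `r_squared`.
#' @export
degree_distribution_fit <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  if (length(net$gene_ids) < 20) stop("need >= 20 nodes")
  deg <- igraph::degree(as_igraph(net))
  deg <- deg[deg > 0]
  tb <- table(deg)
  if (length(tb) < 3) stop("fewer than 3 distinct degrees; no power-law fit")
  d <- as.numeric(names(tb))
  f <- as.numeric(tb)
  fit <- stats::lm(log(f) ~ log(d))
  list(powerlaw_exponent = -unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared)
}

#' Write a network as a weighted edge-list TSV (optionally GraphML)
#'
#' @param net a `coexpression_network`.
#' @param path output TSV path (`gene_a`, `gene_b`, `weight`, `augmented`).
#' @param graphml_path optional GraphML output path.
#' @export
write_edgelist_tsv <- function(net, path, graphml_path = NULL) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
  }
  invisible(path)
}
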