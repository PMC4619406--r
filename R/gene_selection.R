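#' Rank genes by patient-vs-control discrimination
#'
#' Per-gene two-sided Welch two-sample t-test of patient against control
#' expression, the entry filter of the network analysis: from the full
#' measured gene set, only the genes that best distinguish disease from
#' health enter the co-expression networks. The Welch (unequal-variance)
#' variant is used because group variances differ in real cohorts.
#'
#' Conventions for degenerate genes: both groups constant with identical
#' means gives t = 0, p = 1 (no evidence); both constant with different
#' means gives |t| = Inf, p = 0.
#'
#' @param patients an [expression_dataset()] of patient samples (typically
#'   baseline only — the same selected list is reused for all timestamps).
#' @param controls an [expression_dataset()] of control samples over the same
#'   gene universe.
#' @return data frame with columns `gene_id`, `t_statistic`, `p_value`,
#'   `rank`, ordered by ascending p-value with ties broken by gene id.
#' @export
rank_genes <- function(patients, controls) {
  stopifnot(inherits(patients, "expression_dataset"),
            inherits(controls, "expression_dataset"))
  genes <- intersect(patients$gene_ids, controls$gene_ids)
  if (!length(genes)) stop("patient and control datasets share no genes")
  if (ncol(patients$values) < 2 || ncol(controls$values) < 2) {
    stop("need >=2 samples per group for a t-test")
  }
  xp <- patients$values[genes, , drop = FALSE]
  xc <- controls$values[genes, , drop = FALSE]
  t_stat <- numeric(length(genes))
  p_val <- numeric(length(genes))
  for (i in seq_along(genes)) {
    x <- xp[i, ]; y <- xc[i, ]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (mean(x) == mean(y)) { t_stat[i] <- 0; p_val[i] <- 1 }
      else { t_stat[i] <- sign(mean(x) - mean(y)) * Inf; p_val[i] <- 0 }
    } else {
      ht <- stats::t.test(x, y, var.equal = FALSE)
      t_stat[i] <- unname(ht$statistic)
      p_val[i] <- ht$p.value
    }
  }
  ord <- order(p_val, genes)
  out <- data.frame(gene_id = genes[ord], t_statistic = t_stat[ord],
                    p_value = p_val[ord], rank = seq_along(genes),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Select the top-k discriminating genes
#'
#' @param ranking output of [rank_genes()].
#' @param k number of genes to keep (default 2000, the conventional entry
#'   size for whole-blood co-expression networks of this design).
#' @return character vector of `k` gene ids in ranking order.
#' @export
select_top_genes <- function(ranking, k = 2000) {
  stopifnot(is.data.frame(ranking), "gene_id" %in% names(ranking))
  if (k > nrow(ranking)) {
    stop(sprintf("k = %d exceeds the %d ranked genes", k, nrow(ranking)))
  }
  if (k == 0) return(character(0))
  ranking$gene_id[seq_len(k)]
}

#' Write a gene ranking as TSV / a selected gene list as plain text
#'
#' @param ranking output of [rank_genes()].
#' @param path output path.
#' @export
write_ranking_tsv <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking_tsv
#' @param genes character vector of gene ids (one id per output line).
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}
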