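#' Longitudinal expression dataset
#'
#' Container for a genes x samples matrix of log-scale expression values at one
#' (or several pooled) timestamps, together with per-sample metadata. This is
#' the input type of every downstream stage of the pipeline.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row names
#'   are gene ids, column names are sample ids; both must be unique. Missing
#'   values are rejected: upstream normalization is expected to yield complete
#'   matrices, and correlations over silently dropped entries would not be
#'   comparable across gene pairs.
#' @param metadata data frame with one row per sample, in column order of
#'   `values`. Must contain a `sample_id` column matching `colnames(values)`;
#'   conventional columns are `group` ("patient"/"control"), `timestamp`
#'   (integer index 0..T-1), `disease_state` ("AD"/"ID") and `response_path`
#'   ("responder"/"non_responder").
#'
#' @return An object of class `expression_dataset` with fields `gene_ids`,
#'   `sample_ids`, `values` and `metadata`.
#' @export
expression_dataset <- function(values, metadata) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("`values` must have gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(gene_ids)) stop("gene ids must be unique")
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (anyNA(values)) {
    stop("expression matrix contains missing values; complete data required")
  }
  if (!is.data.frame(metadata)) stop("`metadata` must be a data.frame")
  if (!"sample_id" %in% names(metadata)) {
    stop("`metadata` must contain a sample_id column")
  }
  if (nrow(metadata) != ncol(values) ||
      !identical(as.character(metadata$sample_id), sample_ids)) {
    stop("metadata rows must match the sample columns (same ids, same order)")
  }
  structure(
    list(gene_ids = gene_ids, sample_ids = sample_ids,
         values = values, metadata = metadata),
    class = "expression_dataset"
  )
}

#' @exportS3Method base::print
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  if ("group" %in% names(x$metadata)) {
    tb <- table(x$metadata$group)
    cat("  groups:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  if ("timestamp" %in% names(x$metadata)) {
    cat("  timestamps:",
        paste(sort(unique(x$metadata$timestamp)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset an expression dataset by gene ids
#'
#' @param dataset an [expression_dataset()].
#' @param genes character vector of gene ids to keep (order preserved).
#' @return an `expression_dataset` restricted to `genes`.
#' @export
subset_genes <- function(dataset, genes) {
  stopifnot(inherits(dataset, "expression_dataset"))
  missing <- setdiff(genes, dataset$gene_ids)
  if (length(missing)) {
    stop("genes not present in dataset: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  expression_dataset(dataset$values[genes, , drop = FALSE], dataset$metadata)
}

#' Subset an expression dataset by a metadata predicate
#'
#' @param dataset an [expression_dataset()].
#' @param keep logical vector over samples, or character vector of sample ids.
#' @return an `expression_dataset` restricted to the selected samples.
#' @export
subset_samples <- function(dataset, keep) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.character(keep)) keep <- dataset$sample_ids %in% keep
  stopifnot(is.logical(keep), length(keep) == length(dataset$sample_ids))
  expression_dataset(dataset$values[, keep, drop = FALSE],
                     dataset$metadata[keep, , drop = FALSE])
}

#' Pool several expression datasets into one
#'
#' Column-binds the sample blocks of datasets sharing one gene universe, e.g.
#' the per-timestamp outputs of [simulate_dataset()] into a single cohort
#' table that stage designs can then slice ([assemble_stage_datasets()]).
#'
#' @param datasets list of [expression_dataset()] objects over identical genes.
#' @return a pooled `expression_dataset`.
#' @export
combine_datasets <- function(datasets) {
  stopifnot(length(datasets) >= 1)
  g <- datasets[[1]]$gene_ids
  for (d in datasets) {
    if (!identical(d$gene_ids, g)) stop("datasets must share an identical gene universe")
  }
  values <- do.call(cbind, lapply(datasets, function(d) d$values))
  metadata <- do.call(rbind, lapply(datasets, function(d) d$metadata))
  rownames(metadata) <- NULL
  expression_dataset(values, metadata)
}

#' Write / read expression matrices as TSV
#'
#' The on-disk format is plain tab-separated text: first column `gene_id`,
#' then one column per sample; the optional metadata table is a second TSV
#' with one row per sample.
#'
#' @param dataset an [expression_dataset()].
#' @param path path of the expression TSV.
#' @param metadata_path optional path of the sample metadata TSV.
#' @export
write_expression_tsv <- function(dataset, path, metadata_path = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  df <- data.frame(gene_id = dataset$gene_ids, dataset$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path)) {
    utils::write.table(dataset$metadata, metadata_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_expression_tsv
#' @return `read_expression_tsv()` returns an `expression_dataset`. Missing
#'   values in the file are an error, not imputed.
#' @export
read_expression_tsv <- function(path, metadata_path = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("first column of expression TSV must be gene_id")
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$gene_id
  if (!is.null(metadata_path)) {
    metadata <- utils::read.table(metadata_path, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
  } else {
    metadata <- data.frame(sample_id = colnames(values), stringsAsFactors = FALSE)
  }
  expression_dataset(values, metadata)
}
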