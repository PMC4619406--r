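#' Overlap similarity of two modules
#'
#' The matching metric of the temporal tracker: the size of the gene-set
#' intersection divided by the size of the larger set,
#' `|a n b| / max(|a|, |b|)`. Symmetric, in `[0, 1]`, and 1 only for
#' identical sets.
#'
#' @param a,b non-empty character vectors of gene ids.
#' @return numeric similarity in `[0, 1]`.
#' @export
module_similarity <- function(a, b) {
  if (!length(a) || !length(b)) stop("module gene sets must be non-empty")
  a <- unique(a); b <- unique(b)
  length(intersect(a, b)) / max(length(a), length(b))
}

#' Track a module into the next timestamp's catalog
#'
#' Finds the module of the next catalog with the highest overlap similarity
#' to `module`; if no candidate reaches the overlap threshold `alpha`, the
#' module has no match (an empty tracking result). Ties are broken by the
#' smallest module id, making the argmax deterministic.
#'
#' @param module a [gene_module()].
#' @param catalog_next list of `gene_module` at the next timestamp.
#' @param alpha overlap threshold in (0, 1].
#' @return an object of class `track_result`: `source_id`, `matched_id`
#'   (`NA` if unmatched), `similarity`, `alpha`. `matched_id` is non-NA iff
#'   `similarity >= alpha`.
#' @export
track_module <- function(module, catalog_next, alpha) {
  stopifnot(alpha > 0, alpha <= 1)
  res <- structure(list(source_id = module$module_id, matched_id = NA_character_,
                        similarity = 0, alpha = alpha),
                   class = "track_result")
  if (!length(catalog_next)) return(res)
  sims <- vapply(catalog_next, function(m) {
    module_similarity(module$gene_ids, m$gene_ids)
  }, numeric(1))
  ids <- vapply(catalog_next, function(m) m$module_id, character(1))
  best <- order(-sims, ids)[1]
  res$similarity <- sims[best]
  if (sims[best] >= alpha) res$matched_id <- ids[best]
  res
}

set_containment <- function(a, b) {
  # |a n b| / |b|
  length(intersect(unique(a), unique(b))) / length(unique(b))
}

#' Classify the five evolutionary events between two consecutive catalogs
#'
#' Event definitions over the module sets C^i and C^{i+1}:
#' \itemize{
#'   \item split: source x with at least two targets y whose coverage
#'     `|Vx n Vy| / |Vy| >= alpha` (each target is mostly a piece of x);
#'   \item merge: target y with at least two sources x covered by it,
#'     `|Vx n Vy| / |Vx| >= alpha`;
#'   \item continue: source with a tracking match ([track_module()]) in the
#'     next catalog, unless already emitted as a split source or a merge
#'     contributor (precedence split/merge > continue);
#'   \item dissolve: source covered by no split, merge or continue record;
#'   \item form: target covered by no split, merge or continue record.
#' }
#' The coverage-based dissolve/form rules implement the prose reading
#' (dissolve = no similar module in the next timestamp, form = none in the
#' previous one) and guarantee that every module of both catalogs appears in
#' at least one record per transition. All threshold comparisons use `>=`.
#'
#' @param catalog_i,catalog_next lists of `gene_module` at timestamps i and
#'   i+1.
#' @param alpha overlap threshold in (0, 1].
#' @param transition integer label i stored on the records (default: the
#'   timestamp of the first source module, else 0).
#' @return list of `event_record` objects: `transition`, `type`,
#'   `source_ids`, `target_ids`, `similarities`.
#' @export
classify_events <- function(catalog_i, catalog_next, alpha,
                            transition = NULL) {
  stopifnot(alpha > 0, alpha <= 1)
  if (is.null(transition)) {
    transition <- if (length(catalog_i)) catalog_i[[1]]$timestamp else 0L
  }
  src_ids <- vapply(catalog_i, function(m) m$module_id, character(1))
  tgt_ids <- vapply(catalog_next, function(m) m$module_id, character(1))
  ns <- length(catalog_i); nt <- length(catalog_next)
  rec <- function(type, sources, targets, sims) {
    structure(list(transition = as.integer(transition), type = type,
                   source_ids = sources, target_ids = targets,
                   similarities = sims),
              class = "event_record")
  }
  events <- list()
  covered_src <- character(0)
  covered_tgt <- character(0)

  if (ns && nt) {
    cov_in_tgt <- matrix(0, ns, nt) # |Vx n Vy| / |Vy|
    cov_of_src <- matrix(0, ns, nt) # |Vx n Vy| / |Vx|
    for (x in seq_len(ns)) for (y in seq_len(nt)) {
      inter <- length(intersect(catalog_i[[x]]$gene_ids,
                                catalog_next[[y]]$gene_ids))
      cov_in_tgt[x, y] <- inter / length(catalog_next[[y]]$gene_ids)
      cov_of_src[x, y] <- inter / length(catalog_i[[x]]$gene_ids)
    }
    # splits
    for (x in seq_len(ns)) {
      ys <- which(cov_in_tgt[x, ] >= alpha)
      if (length(ys) >= 2) {
        ys <- ys[order(tgt_ids[ys])]
        events[[length(events) + 1]] <- rec(
          "split", src_ids[x], tgt_ids[ys], cov_in_tgt[x, ys])
        covered_src <- c(covered_src, src_ids[x])
        covered_tgt <- c(covered_tgt, tgt_ids[ys])
      }
    }
    # merges
    merge_src <- character(0)
    for (y in seq_len(nt)) {
      xs <- which(cov_of_src[, y] >= alpha)
      if (length(xs) >= 2) {
        xs <- xs[order(src_ids[xs])]
        events[[length(events) + 1]] <- rec(
          "merge", src_ids[xs], tgt_ids[y], cov_of_src[xs, y])
        covered_src <- c(covered_src, src_ids[xs])
        covered_tgt <- c(covered_tgt, tgt_ids[y])
        merge_src <- c(merge_src, src_ids[xs])
      }
    }
    # forward continues (suppressed for split sources and merge contributors)
    sim <- matrix(0, ns, nt)
    for (x in seq_len(ns)) for (y in seq_len(nt)) {
      sim[x, y] <- module_similarity(catalog_i[[x]]$gene_ids,
                                     catalog_next[[y]]$gene_ids)
    }
    for (x in seq_len(ns)) {
      if (src_ids[x] %in% covered_src) next
      tr <- track_module(catalog_i[[x]], catalog_next, alpha)
      if (!is.na(tr$matched_id)) {
        events[[length(events) + 1]] <- rec(
          "continue", src_ids[x], tr$matched_id, tr$similarity)
        covered_src <- c(covered_src, src_ids[x])
        covered_tgt <- c(covered_tgt, tr$matched_id)
      }
    }
    # backward continues: a target with an alpha-similar source is the
    # continuation of its best backward match even when that source was
    # claimed by a split or merge; without this, such targets would be
    # mislabelled as newly formed (and form counts would not be monotone
    # in alpha)
    for (y in seq_len(nt)) {
      if (tgt_ids[y] %in% covered_tgt) next
      if (max(sim[, y]) >= alpha) {
        x <- order(-sim[, y], src_ids)[1]
        events[[length(events) + 1]] <- rec(
          "continue", src_ids[x], tgt_ids[y], sim[x, y])
        covered_src <- c(covered_src, src_ids[x])
        covered_tgt <- c(covered_tgt, tgt_ids[y])
      }
    }
  }
  # dissolve / form by exhaustiveness
  for (id in setdiff(src_ids, covered_src)) {
    events[[length(events) + 1]] <- rec("dissolve", id, character(0), numeric(0))
  }
  for (id in setdiff(tgt_ids, covered_tgt)) {
    events[[length(events) + 1]] <- rec("form", character(0), id, numeric(0))
  }
  events
}

#' Tally event counts and fractions per transition
#'
#' @param events list of `event_record` (one or more transitions).
#' @return data frame of class `event_tally`: one row per transition with
#'   counts of the five types and fractions summing to 1 (all-zero rows for
#'   an empty event list are guarded to fractions 0).
#' @export
tally_events <- function(events) {
  types <- c("form", "dissolve", "continue", "split", "merge")
  if (!length(events)) {
    out <- data.frame(transition = integer(0))
    for (ty in types) out[[ty]] <- integer(0)
    for (ty in types) out[[paste0("frac_", ty)]] <- numeric(0)
    class(out) <- c("event_tally", class(out))
    return(out)
  }
  trans <- vapply(events, function(e) e$transition, integer(1))
  etype <- vapply(events, function(e) e$type, character(1))
  out <- do.call(rbind, lapply(sort(unique(trans)), function(tr) {
    cnt <- vapply(types, function(ty) sum(trans == tr & etype == ty), integer(1))
    tot <- sum(cnt)
    row <- data.frame(transition = tr)
    for (ty in types) row[[ty]] <- cnt[[ty]]
    for (ty in types) {
      row[[paste0("frac_", ty)]] <- if (tot > 0) cnt[[ty]] / tot else 0
    }
    row
  }))
  rownames(out) <- NULL
  class(out) <- c("event_tally", class(out))
  out
}

#' Classify events across all adjacent transitions of a catalog
#'
#' @param catalog a `module_catalog` over >= 2 timestamps.
#' @param alpha overlap threshold.
#' @return list of `event_record` over all adjacent transitions.
#' @export
classify_catalog_events <- function(catalog, alpha) {
  stopifnot(length(catalog) >= 2)
  ts <- as.integer(names(catalog))
  events <- list()
  for (i in seq_len(length(catalog) - 1)) {
    events <- c(events, classify_events(catalog[[i]], catalog[[i + 1]],
                                        alpha, transition = ts[i]))
  }
  events
}

#' Sweep the overlap threshold over a module catalog
#'
#' Re-classifies all adjacent transitions at each threshold in `alphas` and
#' tallies the event types. Because every matching condition is a `>= alpha`
#' comparison, raising alpha can only remove split/merge/continue coverage,
#' so the summed form+dissolve count is non-decreasing in alpha; this is
#' asserted on every sweep.
#'
#' @param catalog a `module_catalog` over >= 2 timestamps.
#' @param alphas strictly increasing thresholds in (0, 1]; default the
#'   conventional 0.12, 0.16, 0.20 band.
#' @return named list (alpha as name) of [tally_events()] data frames.
#' @export
sweep_alpha <- function(catalog, alphas = c(0.12, 0.16, 0.20)) {
  if (any(diff(alphas) <= 0)) stop("alphas must be strictly increasing")
  stopifnot(all(alphas > 0), all(alphas <= 1))
  tallies <- lapply(alphas, function(a) {
    tally_events(classify_catalog_events(catalog, a))
  })
  names(tallies) <- as.character(alphas)
  fd <- vapply(tallies, function(tb) sum(tb$form) + sum(tb$dissolve), numeric(1))
  if (any(diff(fd) < 0)) {
    stop("internal error: form+dissolve counts decreased with alpha")
  }
  tallies
}

#' Write events as JSON lines / tallies as TSV
#'
#' @param events list of `event_record`.
#' @param path output path (one JSON object per line).
#' @export
write_events_jsonl <- function(events, path) {
  lines <- vapply(events, function(e) {
    jsonlite::toJSON(unclass(e), auto_unbox = FALSE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_events_jsonl
#' @param tally an `event_tally`.
#' @export
write_tally_tsv <- function(tally, path) {
  utils::write.table(tally, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
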