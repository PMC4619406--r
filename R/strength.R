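#' Raw module strength in one network
#'
#' A module is strong when its genes interact more among themselves than
#' with the rest of the network: strength = W_in / (W_in + W_out), where
#' W_in sums the weights of edges with both endpoints inside the module and
#' W_out those with exactly one endpoint inside. In `[0, 1]`; 1 iff the
#' module is perfectly insulated (W_out = 0, W_in > 0); a module with no
#' incident edges scores 0 by convention.
#'
#' @param genes character vector of module gene ids (or a [gene_module()]),
#'   a subset of the network's nodes.
#' @param net a connected `coexpression_network`.
#' @return numeric strength in `[0, 1]`.
#' @export
raw_strength <- function(genes, net) {
  if (inherits(genes, "gene_module")) genes <- genes$gene_ids
  stopifnot(inherits(net, "coexpression_network"))
  if (!all(genes %in% net$gene_ids)) {
    stop("module genes must be a subset of the network nodes")
  }
  ina <- net$edges$gene_a %in% genes
  inb <- net$edges$gene_b %in% genes
  w_in <- sum(net$edges$weight[ina & inb])
  w_out <- sum(net$edges$weight[xor(ina, inb)])
  if (w_in + w_out == 0) return(0)
  w_in / (w_in + w_out)
}

#' Temporal smoothing of a strength trajectory
#'
#' Module strength is expected to change gradually between adjacent
#' snapshots (treatment response develops over weeks to months, and single-
#' snapshot estimates are noisy), so the per-timestamp raw strengths are
#' smoothed by exactly minimizing
#' \deqn{\sum_t (x_t - r_t)^2 + \lambda \sum_{t \ge 2} (x_t - x_{t-1})^2,}
#' a tridiagonal ridge on successive differences solved in closed form.
#' `lambda = 0` returns the raw vector unchanged; a constant vector is a
#' fixed point for every `lambda`.
#'
#' @param raw numeric vector of raw strengths (length >= 1).
#' @param lambda smoothness weight in `[0, 1)` scale-free units (any
#'   non-negative value is accepted).
#' @return the smoothed vector, same length.
#' @export
smooth_trajectory <- function(raw, lambda) {
  stopifnot(is.numeric(raw), length(raw) >= 1, lambda >= 0)
  T <- length(raw)
  if (lambda == 0 || T == 1) return(raw)
  D <- diff(diag(T)) # (T-1) x T first-difference operator
  M <- diag(T) + lambda * crossprod(D)
  as.numeric(solve(M, raw))
}

#' Strength trajectories of a candidate module set over a network series
#'
#' Scores every candidate module against every timestamp's network
#' ([raw_strength()]), smooths each trajectory ([smooth_trajectory()]),
#' normalizes across modules per timestamp ([normalize_catalog()]) and
#' classifies the progression pattern ([classify_pattern()]; only when the
#' series has 4 timestamps, otherwise the pattern is `NA`). Candidate genes
#' absent from a network's node set are dropped for that timestamp's score
#' (candidate modules come from all stages, networks from one).
#'
#' @param modules list of `gene_module` (e.g. [deduplicate_catalog()] output).
#' @param nets list of connected networks in timestamp order.
#' @param config a [strength_config()].
#' @return list of `strength_trajectory` objects with fields `module_id`,
#'   `raw_strengths`, `smoothed_strengths`, `normalized_strengths`,
#'   `pattern`.
#' @export
strength_trajectories <- function(modules, nets, config = strength_config()) {
  stopifnot(length(modules) >= 1, length(nets) >= 1)
  trajs <- lapply(modules, function(m) {
    raw <- vapply(nets, function(net) {
      genes <- intersect(m$gene_ids, net$gene_ids)
      if (!length(genes)) return(0)
      raw_strength(genes, net)
    }, numeric(1))
    structure(list(module_id = m$module_id, raw_strengths = raw,
                   smoothed_strengths = smooth_trajectory(raw, config$lambda),
                   normalized_strengths = NULL, pattern = NA_character_),
              class = "strength_trajectory")
  })
  trajs <- normalize_catalog(trajs)
  if (length(nets) == 4) {
    for (i in seq_along(trajs)) {
      trajs[[i]]$pattern <- classify_pattern(trajs[[i]], config)
    }
  }
  trajs
}

#' Strength-analysis configuration
#'
#' @param lambda temporal smoothness weight. The default 0.15 damps
#'   visit-level noise while leaking only about lambda/(1+2*lambda) ~ 11%
#'   of a single-visit jump into the neighbouring visit — comfortably below
#'   the pattern amplitude `delta`, so the late-rise/early-drop patterns the
#'   classifier defines survive smoothing. (Stronger smoothing would spread
#'   a one-visit jump across its neighbour and contradict the classifier's
#'   own steady-phase requirement.)
#' @param tau_flat flat-trajectory cutoff on the normalized range (default
#'   0.05): modules whose strength never moves more than this are treated as
#'   non-informative for response and removed from pattern analysis.
#' @param delta pattern amplitude (default 0.2 normalized units): the
#'   minimum rise or drop that counts as a dramatic change.
#' @return an object of class `strength_config`.
#' @export
strength_config <- function(lambda = 0.15, tau_flat = 0.05, delta = 0.2) {
  stopifnot(lambda >= 0, tau_flat > 0, delta > 0)
  structure(list(lambda = lambda, tau_flat = tau_flat, delta = delta),
            class = "strength_config")
}

#' Min-max normalize strengths across modules, per timestamp
#'
#' A module is only strong relative to the other modules of the same
#' snapshot, so smoothed strengths are min-max scaled to `[0, 1]` across
#' modules at each timestamp; a degenerate timestamp where all modules are
#' equal maps to 0.5. Ranks within a timestamp are preserved.
#'
#' @param trajectories list of >= 2 `strength_trajectory` objects.
#' @return the same list with `normalized_strengths` filled.
#' @export
normalize_catalog <- function(trajectories) {
  if (length(trajectories) < 2) {
    for (i in seq_along(trajectories)) {
      trajectories[[i]]$normalized_strengths <-
        rep(0.5, length(trajectories[[i]]$smoothed_strengths))
    }
    return(trajectories)
  }
  S <- do.call(rbind, lapply(trajectories, function(x) x$smoothed_strengths))
  for (t in seq_len(ncol(S))) {
    lo <- min(S[, t]); hi <- max(S[, t])
    S[, t] <- if (hi > lo) (S[, t] - lo) / (hi - lo) else 0.5
  }
  for (i in seq_along(trajectories)) {
    trajectories[[i]]$normalized_strengths <- S[i, ]
  }
  trajectories
}

#' Classify the progression pattern of a 4-timestamp trajectory
#'
#' Labels, checked in order on the normalized strengths x1..x4 (first match
#' wins, so every trajectory gets exactly one deterministic label):
#' \itemize{
#'   \item `flat`: max - min < tau_flat (uninformative, removed downstream);
#'   \item `pattern1_late_rise`: low and steady over the first three
#'     timestamps (range < delta), then a dramatic final rise
#'     (x4 - mean(x1..x3) >= delta);
#'   \item `pattern2_hill`: peak at timestamp 2 or 3, rising at least delta
#'     from x1 and falling at least delta to x4;
#'   \item `pattern3_early_drop`: x1 - mean(x2..x4) >= delta;
#'   \item `other`.
#' }
#'
#' @param traj a `strength_trajectory` with normalized strengths of length 4
#'   (the four-visit study design; other lengths are an error), or a bare
#'   numeric vector of length 4.
#' @param config a [strength_config()].
#' @return one of `"flat"`, `"pattern1_late_rise"`, `"pattern2_hill"`,
#'   `"pattern3_early_drop"`, `"other"`.
#' @export
classify_pattern <- function(traj, config = strength_config()) {
  x <- if (inherits(traj, "strength_trajectory")) traj$normalized_strengths else traj
  if (length(x) != 4) stop("pattern classification requires exactly 4 timestamps")
  d <- config$delta
  if (max(x) - min(x) < config$tau_flat) return("flat")
  if (x[4] - mean(x[1:3]) >= d && (max(x[1:3]) - min(x[1:3])) < d) {
    return("pattern1_late_rise")
  }
  peak <- which.max(x)
  if (peak %in% c(2, 3) && x[peak] - x[1] >= d && x[peak] - x[4] >= d) {
    return("pattern2_hill")
  }
  if (x[1] - mean(x[2:4]) >= d) return("pattern3_early_drop")
  "other"
}

#' Compare strength trajectories between two groups
#'
#' Scores the divergence of each candidate module's normalized trajectory
#' between two network series (e.g. active- vs inactive-disease groups):
#' per-module mean absolute difference, and per pattern (labels taken from
#' group A) the fraction of modules whose difference exceeds `delta`. A
#' pattern is reported `divergent` when more than half its modules exceed
#' `delta`, else `shared`.
#'
#' @param traj_a,traj_b lists of classified `strength_trajectory` over the
#'   same candidate modules (compared on the intersection of module ids;
#'   disjoint sets are an error).
#' @param delta divergence threshold (normalized units).
#' @return list with `per_module` (data frame: module_id, pattern,
#'   mean_abs_diff) and `per_pattern` (data frame: pattern, n_modules,
#'   divergent_fraction, status).
#' @export
compare_groups <- function(traj_a, traj_b, delta = 0.2) {
  ids_a <- vapply(traj_a, function(x) x$module_id, character(1))
  ids_b <- vapply(traj_b, function(x) x$module_id, character(1))
  common <- intersect(ids_a, ids_b)
  if (!length(common)) stop("groups share no candidate modules")
  per_module <- do.call(rbind, lapply(common, function(id) {
    a <- traj_a[[match(id, ids_a)]]
    b <- traj_b[[match(id, ids_b)]]
    data.frame(module_id = id, pattern = a$pattern,
               mean_abs_diff = mean(abs(a$normalized_strengths -
                                          b$normalized_strengths)),
               stringsAsFactors = FALSE)
  }))
  per_pattern <- do.call(rbind, lapply(unique(per_module$pattern), function(p) {
    sub <- per_module[per_module$pattern == p, ]
    frac <- mean(sub$mean_abs_diff > delta)
    data.frame(pattern = p, n_modules = nrow(sub), divergent_fraction = frac,
               status = if (frac > 0.5) "divergent" else "shared",
               stringsAsFactors = FALSE)
  }))
  rownames(per_module) <- rownames(per_pattern) <- NULL
  list(per_module = per_module, per_pattern = per_pattern)
}

#' Write strength trajectories as TSV
#'
#' @param trajectories list of `strength_trajectory`.
#' @param path output path; one row per module-timestamp with raw, smoothed
#'   and normalized strengths and the pattern label.
#' @export
write_strength_tsv <- function(trajectories, path) {
  rows <- do.call(rbind, lapply(trajectories, function(x) {
    data.frame(module_id = x$module_id,
               timestamp = seq_along(x$raw_strengths) - 1L,
               raw = x$raw_strengths, smoothed = x$smoothed_strengths,
               normalized = x$normalized_strengths,
               pattern = x$pattern, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
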