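#' Stage design for longitudinal analyses
#'
#' Declarative description of how cohort samples are grouped into ordered
#' analysis stages. Two modes mirror the study designs this pipeline serves:
#' `strategy` (baseline -> satisfactory/unsatisfactory response -> inactive
#' disease, separately for responders and non-responders) and `time`
#' (calendar visits m0/m4/m6/m12 within the active- or inactive-disease
#' group). Predicates are declarative (metadata column -> allowed values)
#' rather than hard-coded clinical criteria.
#'
#' @param mode `"strategy"` or `"time"`.
#' @param group label of the analyzed group (e.g. `"AD"`, `"responder"`).
#' @param stages list of >= 2 stages, each `list(label = , filter = )` where
#'   `filter` is a named list mapping metadata columns to allowed values.
#' @return an object of class `stage_design`.
#' @export
stage_design <- function(mode = c("time", "strategy"), group, stages) {
  mode <- match.arg(mode)
  stopifnot(length(stages) >= 2)
  for (s in stages) stopifnot(!is.null(s$label), is.list(s$filter))
  structure(list(mode = mode, group = group, stages = stages),
            class = "stage_design")
}

#' Time-based stage design for one disease-state group
#'
#' @param group disease-state label to keep (`"AD"` or `"ID"`).
#' @param timestamps integer timestamps, default 0:3.
#' @return a [stage_design()] with one stage per timestamp, restricted to
#'   patient samples of `group`.
#' @export
time_design <- function(group = "AD", timestamps = 0:3) {
  stages <- lapply(timestamps, function(t) {
    list(label = sprintf("t%d_%s", t, group),
         filter = list(group = "patient", timestamp = t,
                       disease_state = group))
  })
  stage_design("time", group, stages)
}

#' Slice a pooled dataset into per-stage datasets
#'
#' @param dataset a pooled [expression_dataset()] whose metadata covers every
#'   column the design's predicates use.
#' @param design a [stage_design()].
#' @return list of `expression_dataset`, one per stage in design order. A
#'   stage selecting fewer than 3 samples is an error (correlations would be
#'   undefined); a predicate matching nothing is reported as such.
#' @export
assemble_stage_datasets <- function(dataset, design) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(design, "stage_design"))
  lapply(design$stages, function(s) {
    keep <- rep(TRUE, nrow(dataset$metadata))
    for (col in names(s$filter)) {
      if (!col %in% names(dataset$metadata)) {
        stop("stage ", s$label, ": metadata lacks column '", col, "'")
      }
      keep <- keep & dataset$metadata[[col]] %in% s$filter[[col]]
    }
    if (!any(keep)) stop("stage ", s$label, ": predicate matches no samples")
    if (sum(keep) < 3) {
      stop("stage ", s$label, ": only ", sum(keep),
           " samples selected; >= 3 required for correlation")
    }
    subset_samples(dataset, keep)
  })
}

#' Run the full dynamic co-expression pipeline
#'
#' Orchestrates gene selection, per-stage network construction, topology
#' summaries, NMF module detection, evolutionary-event classification with
#' an alpha sweep, candidate-set deduplication and strength-progression
#' analysis, writing every artifact plus a reproducibility manifest under
#' `out_dir`.
#'
#' Configuration is a named list or a YAML file with keys (defaults in
#' parentheses): `seed` (1), `simulate` (TRUE), `expression_tsv`/
#' `metadata_tsv` (inputs when `simulate` is FALSE), `top_genes` (2000),
#' `edge_fraction` (0.10), `k_modules` (50), `nmf_restarts` (5),
#' `nmf_max_iter` (200), `alphas` (0.12, 0.16, 0.20), `dedup_jaccard` (0.9),
#' `lambda` (0.15), `tau_flat` (0.05), `delta` (0.2), `mode` ("time"),
#' `group` ("AD"). When `simulate` is true the standard scripted scenario
#' is generated with `seed`.
#'
#' @param config named list or path to a YAML config file.
#' @param out_dir run directory for artifacts (created if needed).
#' @return the run manifest (also written as `manifest.json`): config
#'   snapshot, seed, per-stage artifact paths with md5 hashes, stage counts
#'   and package version. Re-running with an identical config reproduces
#'   identical artifacts.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("dyncoex_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(seed = 1L, simulate = TRUE, expression_tsv = NULL,
                   metadata_tsv = NULL, top_genes = 2000,
                   edge_fraction = 0.10, k_modules = 50, nmf_restarts = 5,
                   nmf_max_iter = 200, alphas = c(0.12, 0.16, 0.20),
                   dedup_jaccard = 0.9, lambda = 0.15, tau_flat = 0.05,
                   delta = 0.2, mode = "time", group = "AD",
                   n_genes = 2500)
  unknown <- setdiff(names(config), c(names(defaults), "scenario"))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[dyncoex] ", sprintf(...))
  t_start <- Sys.time()
  set.seed(cfg$seed)

  # -- inputs ---------------------------------------------------------------
  if (isTRUE(cfg$simulate)) {
    log_msg("simulating the standard scripted scenario (seed %d)", cfg$seed)
    sim_cfg <- script_standard_scenario(seed = cfg$seed, n_genes = cfg$n_genes)
    sim <- simulate_dataset(sim_cfg)
    pooled <- combine_datasets(sim$datasets)
    write_simulation_truth(sim$truth, file.path(out_dir, "truth.json"))
    write_expression_tsv(pooled, file.path(out_dir, "expression.tsv"),
                         file.path(out_dir, "metadata.tsv"))
  } else {
    stopifnot(!is.null(cfg$expression_tsv), !is.null(cfg$metadata_tsv))
    pooled <- read_expression_tsv(cfg$expression_tsv, cfg$metadata_tsv)
  }

  # -- gene selection (baseline patients vs controls) -----------------------
  md <- pooled$metadata
  patients0 <- subset_samples(pooled, md$group == "patient" & md$timestamp == 0)
  controls <- subset_samples(pooled, md$group == "control")
  ranking <- rank_genes(patients0, controls)
  k_top <- min(cfg$top_genes, nrow(ranking))
  selected <- select_top_genes(ranking, k_top)
  write_ranking_tsv(ranking, file.path(out_dir, "ranking.tsv"))
  write_gene_list(selected, file.path(out_dir, "selected_genes.txt"))
  log_msg("selected %d / %d genes from the baseline contrast",
          length(selected), nrow(ranking))

  # -- stage datasets and networks ------------------------------------------
  design <- if (identical(cfg$mode, "time")) {
    time_design(cfg$group, sort(unique(md$timestamp[md$group == "patient"])))
  } else {
    # strategy mode: baseline, then the response path's mid stage, then the
    # final visit, within one responder group
    stage_design("strategy", cfg$group, list(
      list(label = "baseline", filter = list(group = "patient", timestamp = 0)),
      list(label = "mid", filter = list(group = "patient", timestamp = 1,
                                        response_path = cfg$group)),
      list(label = "final", filter = list(
        group = "patient",
        timestamp = max(md$timestamp[md$group == "patient"]),
        response_path = cfg$group))))
  }
  if (identical(cfg$mode, "time") && isTRUE(cfg$simulate)) {
    # synthetic baseline marks every patient AD; keep stage sizes even by
    # using all patients at every visit when the AD subset would be tiny
    design <- stage_design("time", cfg$group, lapply(
      sort(unique(md$timestamp[md$group == "patient"])), function(t) {
        list(label = sprintf("t%d", t),
             filter = list(group = "patient", timestamp = t))
      }))
  }
  stage_data <- assemble_stage_datasets(pooled, design)
  nets <- vector("list", length(stage_data))
  for (i in seq_along(stage_data)) {
    nets[[i]] <- build_network(stage_data[[i]], selected,
                               q = cfg$edge_fraction, timestamp = i - 1L)
    write_edgelist_tsv(nets[[i]],
                       file.path(out_dir, sprintf("edges_t%d.tsv", i - 1L)))
    log_msg("stage %d (%s): %d samples, %d edges (%d augmented)",
            i - 1L, design$stages[[i]]$label,
            length(stage_data[[i]]$sample_ids), nrow(nets[[i]]$edges),
            sum(nets[[i]]$edges$augmented))
  }

  # -- topology --------------------------------------------------------------
  topo <- topology_trajectory(nets)
  write_topology_tsv(topo, file.path(out_dir, "topology.tsv"))

  # -- module detection ------------------------------------------------------
  k_mod <- min(cfg$k_modules, length(selected) - 1)
  catalog <- catalog_stages(nets, k = k_mod, seed = cfg$seed,
                            n_restarts = cfg$nmf_restarts,
                            max_iter = cfg$nmf_max_iter)
  all_mods <- unlist(unname(catalog), recursive = FALSE)
  write_gmt(all_mods, file.path(out_dir, "modules.gmt"))
  log_msg("detected %s modules per stage (k = %d)",
          paste(vapply(catalog, length, integer(1)), collapse = "/"), k_mod)

  # -- events with alpha sweep ----------------------------------------------
  tallies <- sweep_alpha(catalog, cfg$alphas)
  events_main <- classify_catalog_events(catalog, cfg$alphas[1])
  write_events_jsonl(events_main, file.path(out_dir, "events.jsonl"))
  for (a in names(tallies)) {
    write_tally_tsv(tallies[[a]],
                    file.path(out_dir, sprintf("event_tally_alpha%s.tsv", a)))
  }
  counts <- tally_events(events_main)
  log_msg("events at alpha=%s: %s", names(tallies)[1],
          paste(vapply(c("form", "dissolve", "continue", "split", "merge"),
                       function(ty) sprintf("%s=%d", ty, sum(counts[[ty]])),
                       character(1)), collapse = ", "))

  # -- strength progression --------------------------------------------------
  candidates <- deduplicate_catalog(catalog, cfg$dedup_jaccard)
  scfg <- strength_config(cfg$lambda, cfg$tau_flat, cfg$delta)
  trajs <- strength_trajectories(candidates, nets, scfg)
  write_strength_tsv(trajs, file.path(out_dir, "strength.tsv"))
  patterns <- table(vapply(trajs, function(x) x$pattern, character(1)))
  log_msg("candidate set: %d modules after deduplication; patterns: %s",
          length(candidates),
          paste(sprintf("%s=%d", names(patterns), patterns), collapse = ", "))

  # -- manifest ---------------------------------------------------------------
  artifacts <- list.files(out_dir, full.names = FALSE)
  artifacts <- setdiff(artifacts, "manifest.json")
  manifest <- list(
    tool = "dyncoex",
    version = as.character(utils::packageVersion("dyncoex")),
    seed = cfg$seed,
    config = cfg[order(names(cfg))],
    n_stages = length(nets),
    n_selected_genes = length(selected),
    modules_per_stage = unname(vapply(catalog, length, integer(1))),
    n_candidate_modules = length(candidates),
    event_counts = as.list(colSums(counts[, c("form", "dissolve", "continue",
                                              "split", "merge"), drop = FALSE])),
    artifacts = lapply(stats::setNames(artifacts, artifacts), function(f) {
      list(path = f, md5 = unname(tools::md5sum(file.path(out_dir, f))))
    }),
    elapsed_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("run complete in %.1f s; artifacts in %s",
          manifest$elapsed_sec, out_dir)
  invisible(manifest)
}
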