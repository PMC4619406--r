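#' Planted co-expression module
#'
#' Describes one ground-truth module of the synthetic cohort: which genes it
#' contains at each timestamp (an empty set means the module is absent then),
#' and optionally a per-timestamp target correlation overriding the global
#' `within_module_corr` (used e.g. to plant a module whose internal cohesion
#' rises only late in the series).
#'
#' @param module_id identifier string.
#' @param gene_ids_per_timestamp named list, names "0".."T-1", each element a
#'   character vector of gene ids (possibly empty).
#' @param corr_per_timestamp optional named numeric vector (same names) of
#'   target pairwise correlations in `[0, 1)`.
#' @return an object of class `planted_module`.
#' @export
planted_module <- function(module_id, gene_ids_per_timestamp,
                           corr_per_timestamp = NULL) {
  stopifnot(is.character(module_id), length(module_id) == 1)
  stopifnot(is.list(gene_ids_per_timestamp))
  if (is.null(names(gene_ids_per_timestamp)) ||
      any(names(gene_ids_per_timestamp) == "")) {
    stop("gene_ids_per_timestamp must be named by timestamp index")
  }
  sizes <- lengths(gene_ids_per_timestamp)
  if (all(sizes == 0)) stop("module must be non-empty at >=1 timestamp")
  if (!is.null(corr_per_timestamp)) {
    stopifnot(all(corr_per_timestamp >= 0), all(corr_per_timestamp < 1))
  }
  structure(list(module_id = module_id,
                 gene_ids_per_timestamp = gene_ids_per_timestamp,
                 corr_per_timestamp = corr_per_timestamp),
            class = "planted_module")
}

#' Scripted evolutionary event
#'
#' Ground-truth record of one module transition in the synthetic scenario.
#' Arities are enforced: `form` has no sources, `dissolve` no targets,
#' `continue` is 1-to-1, `split` 1-to-many (>=2), `merge` many-to-1 (>=2).
#'
#' @param transition integer i, denoting the transition i -> i+1.
#' @param type one of `"form"`, `"dissolve"`, `"continue"`, `"split"`, `"merge"`.
#' @param source_ids module ids at timestamp i.
#' @param target_ids module ids at timestamp i+1.
#' @return an object of class `planted_event`.
#' @export
planted_event <- function(transition, type,
                          source_ids = character(), target_ids = character()) {
  type <- match.arg(type, c("form", "dissolve", "continue", "split", "merge"))
  ns <- length(source_ids); nt <- length(target_ids)
  ok <- switch(type,
    form = ns == 0 && nt == 1,
    dissolve = ns == 1 && nt == 0,
    continue = ns == 1 && nt == 1,
    split = ns == 1 && nt >= 2,
    merge = ns >= 2 && nt == 1
  )
  if (!ok) stop(sprintf("inconsistent arity for %s event (%d sources, %d targets)",
                        type, ns, nt))
  structure(list(transition = as.integer(transition), type = type,
                 source_ids = as.character(source_ids),
                 target_ids = as.character(target_ids)),
            class = "planted_event")
}

#' Simulation configuration
#'
#' Parameters of the synthetic longitudinal cohort. The generator emulates a
#' treatment-response study design: patients sampled at every timestamp,
#' healthy controls sampled once at baseline, planted co-expression modules
#' whose gene sets evolve across timestamps by a scripted set of events, a
#' patient-vs-control mean shift on module genes (so disease-associated genes
#' are selectable by a baseline t-test), and i.i.d. Gaussian noise elsewhere.
#'
#' Expression model for gene g, sample s, module m at timestamp t:
#' \deqn{x_{gs} = \mu_g(\mathrm{group}) + \sigma(\sqrt{\rho}\,f_{ms} +
#'   \sqrt{1-\rho}\,\epsilon_{gs})}
#' with f and eps standard normal, so that the population pairwise correlation
#' of two genes sharing module m is exactly rho — an analytic oracle for the
#' tests. Non-module genes are pure noise; controls carry no module structure
#' (co-expression is modeled as a disease-state property).
#'
#' @param n_genes size of the gene universe.
#' @param n_patient_samples_per_timestamp patients profiled per timestamp.
#' @param n_control_samples healthy controls (baseline only).
#' @param n_timestamps number of timestamps T >= 2 (default 4: m0/m4/m6/m12).
#' @param planted_modules list of [planted_module()] objects.
#' @param event_script list of [planted_event()] objects (ground truth only;
#'   the scripted gene sets, not this list, drive generation).
#' @param noise_sd standard deviation of the stochastic term (log-units, > 0).
#' @param within_module_corr default target pairwise correlation in `[0, 1)`.
#' @param de_effect_size patient-vs-control mean shift (log-units) applied to
#'   every gene that belongs to a planted module at any timestamp.
#' @param baseline_mean grand mean of log-expression (log2-intensity scale).
#' @param overlap_cap maximum allowed overlap between two planted modules at
#'   one timestamp, as a fraction of the smaller module.
#' @param timestamp_labels optional character labels (metadata only).
#' @param seed integer random seed; identical seeds give identical matrices.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2500,
                              n_patient_samples_per_timestamp = 30,
                              n_control_samples = 20,
                              n_timestamps = 4,
                              planted_modules = list(),
                              event_script = list(),
                              noise_sd = 1,
                              within_module_corr = 0.8,
                              de_effect_size = 1.5,
                              baseline_mean = 7,
                              overlap_cap = 0.2,
                              timestamp_labels = NULL,
                              seed = 1L) {
  cfg <- structure(
    list(n_genes = as.integer(n_genes),
         n_patient_samples_per_timestamp = as.integer(n_patient_samples_per_timestamp),
         n_control_samples = as.integer(n_control_samples),
         n_timestamps = as.integer(n_timestamps),
         planted_modules = planted_modules,
         event_script = event_script,
         noise_sd = noise_sd,
         within_module_corr = within_module_corr,
         de_effect_size = de_effect_size,
         baseline_mean = baseline_mean,
         overlap_cap = overlap_cap,
         timestamp_labels = timestamp_labels,
         seed = as.integer(seed)),
    class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the invariants: T >= 2, 0 <= rho < 1, noise_sd > 0, planted gene
#' sets inside the gene universe, and pairwise module overlap at any one
#' timestamp no larger than `overlap_cap` of the smaller module.
#'
#' @param config a [simulation_config()].
#' @return `config`, invisibly; errors describe the violated invariant.
#' @export
validate_simulation_config <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_timestamps < 2) stop("n_timestamps must be >= 2")
  if (config$within_module_corr < 0 || config$within_module_corr >= 1) {
    stop("within_module_corr must be in [0, 1)")
  }
  if (config$noise_sd <= 0) stop("noise_sd must be > 0")
  universe <- gene_universe(config$n_genes)
  for (m in config$planted_modules) {
    stopifnot(inherits(m, "planted_module"))
    ts_idx <- as.integer(names(m$gene_ids_per_timestamp))
    if (any(ts_idx < 0 | ts_idx >= config$n_timestamps)) {
      stop("module ", m$module_id, ": timestamp index outside 0..T-1")
    }
    for (gs in m$gene_ids_per_timestamp) {
      if (!all(gs %in% universe)) {
        stop("module ", m$module_id,
             ": gene ids outside the gene universe (universe too small?)")
      }
    }
  }
  for (t in 0:(config$n_timestamps - 1)) {
    sets <- lapply(config$planted_modules, module_genes_at, t)
    nm <- vapply(config$planted_modules, function(m) m$module_id, character(1))
    nonempty <- which(lengths(sets) > 0)
    if (length(nonempty) >= 2) {
      for (a in utils::head(nonempty, -1)) for (b in nonempty[nonempty > a]) {
        ov <- length(intersect(sets[[a]], sets[[b]]))
        cap <- config$overlap_cap * min(length(sets[[a]]), length(sets[[b]]))
        if (ov > cap) {
          stop(sprintf(
            "modules %s and %s overlap by %d genes at timestamp %d, above the cap of %.1f",
            nm[a], nm[b], ov, t, cap))
        }
      }
    }
  }
  invisible(config)
}

gene_universe <- function(n_genes) {
  sprintf("g%05d", seq_len(n_genes))
}

module_genes_at <- function(module, t) {
  gs <- module$gene_ids_per_timestamp[[as.character(t)]]
  if (is.null(gs)) character(0) else gs
}

module_corr_at <- function(module, t, default) {
  if (is.null(module$corr_per_timestamp)) return(default)
  rho <- module$corr_per_timestamp[[as.character(t)]]
  if (is.null(rho) || is.na(rho)) default else rho
}

#' Simulate a longitudinal expression cohort
#'
#' Draws one [expression_dataset()] per timestamp under the shared-latent-
#' factor model described in [simulation_config()], plus a ground-truth
#' record. Patient samples at timestamp t carry the planted module structure
#' of t; control samples (timestamp 0 only) are independent noise around the
#' healthy mean. When planted modules overlap (allowed up to `overlap_cap`),
#' a gene takes the latent factor of the first module listing it.
#'
#' @param config a valid [simulation_config()].
#' @return list with `datasets` (list of `expression_dataset`, one per
#'   timestamp) and `truth` (class `simulation_truth`: planted modules, event
#'   script, per-gene patient/control means).
#' @export
simulate_dataset <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  genes <- gene_universe(config$n_genes)
  T <- config$n_timestamps
  n_p <- config$n_patient_samples_per_timestamp
  n_c <- config$n_control_samples
  labels <- config$timestamp_labels
  if (is.null(labels)) {
    labels <- if (T == 4) c("m0", "m4", "m6", "m12") else paste0("t", 0:(T - 1))
  }

  module_ever <- unique(unlist(lapply(config$planted_modules, function(m) {
    unlist(m$gene_ids_per_timestamp, use.names = FALSE)
  })))
  mu_control <- stats::setNames(rep(config$baseline_mean, config$n_genes), genes)
  mu_patient <- mu_control
  mu_patient[module_ever] <- mu_patient[module_ever] + config$de_effect_size

  # stable per-patient phenotype labels used by the stage designs
  disease_state <- rep(c("AD", "ID"), length.out = n_p)
  response_path <- rep(c("non_responder", "responder"), length.out = n_p)

  datasets <- vector("list", T)
  for (t in 0:(T - 1)) {
    pat_ids <- sprintf("p%02d_%s", seq_len(n_p), labels[t + 1])
    eps <- matrix(stats::rnorm(config$n_genes * n_p), config$n_genes, n_p,
                  dimnames = list(genes, pat_ids))
    # pure-noise patients first; module genes overwritten below
    x <- mu_patient + config$noise_sd * eps
    claimed <- character(0)
    for (m in config$planted_modules) {
      gs <- setdiff(module_genes_at(m, t), claimed)
      if (!length(gs)) next
      rho <- module_corr_at(m, t, config$within_module_corr)
      f <- stats::rnorm(n_p)
      x[gs, ] <- mu_patient[gs] + config$noise_sd *
        (sqrt(rho) * matrix(f, length(gs), n_p, byrow = TRUE) +
           sqrt(1 - rho) * eps[gs, , drop = FALSE])
      claimed <- c(claimed, module_genes_at(m, t))
    }
    meta <- data.frame(
      sample_id = pat_ids, group = "patient", timestamp = t,
      timestamp_label = labels[t + 1],
      disease_state = if (t == 0) "AD" else disease_state,
      response_path = response_path,
      stringsAsFactors = FALSE)
    if (t == 0 && n_c > 0) {
      ctl_ids <- sprintf("c%02d", seq_len(n_c))
      ctl <- mu_control + config$noise_sd *
        matrix(stats::rnorm(config$n_genes * n_c), config$n_genes, n_c,
               dimnames = list(genes, ctl_ids))
      x <- cbind(x, ctl)
      meta <- rbind(meta, data.frame(
        sample_id = ctl_ids, group = "control", timestamp = 0,
        timestamp_label = labels[1], disease_state = "healthy",
        response_path = "none", stringsAsFactors = FALSE))
    }
    datasets[[t + 1]] <- expression_dataset(x, meta)
  }

  truth <- structure(
    list(planted_modules = config$planted_modules,
         event_script = config$event_script,
         mu_patient = mu_patient, mu_control = mu_control),
    class = "simulation_truth")
  list(datasets = datasets, truth = truth)
}

#' Canned four-timestamp benchmark scenario
#'
#' Returns a simulation configuration whose event script exercises each of
#' the five evolutionary events at least once over four timestamps. The 290
#' module genes form a full partition at every timestamp (the usual design
#' of dynamic planted-partition benchmarks): a module that dissolves hands
#' its genes to several surviving modules, and a module that forms draws
#' its genes from several donors, each donation staying well below the
#' overlap threshold so that form/dissolve remain distinguishable from
#' continuation. The script:
#' \itemize{
#'   \item `CONT` persists through all four timestamps;
#'   \item `SPL` splits into `SPL1` + `SPL2` at transition 1 -> 2;
#'   \item `MGA` + `MGB` merge into `MG` at transition 1 -> 2;
#'   \item `DIS` dissolves after baseline (genes absorbed by CONT/MGA/MGB);
#'   \item `FORM` forms at timestamp 1 (genes drawn from CONT/SPL/MGA/MGB).
#' }
#' Module sizes (30-103 genes) sit inside the 30-180 range typical of
#' co-expression modules.
#'
#' @param seed random seed stored in the config.
#' @param n_genes gene universe size.
#' @param within_module_corr,noise_sd,de_effect_size generator parameters,
#'   see [simulation_config()].
#' @return a [simulation_config()].
#' @export
script_standard_scenario <- function(seed = 1L, n_genes = 2500,
                                     within_module_corr = 0.8,
                                     noise_sd = 1, de_effect_size = 1.5) {
  genes <- gene_universe(n_genes)
  take <- function(from, n) genes[seq(from, length.out = n)]
  g_cont <- take(1, 60)
  g_spl <- take(61, 60)
  g_spl1 <- g_spl[1:30]
  g_spl2 <- g_spl[31:60]
  g_mga <- take(121, 35)
  g_mgb <- take(156, 35)
  g_dis <- take(191, 50)   # dissolves after t0; absorbed by CONT/SPL/MGA/MGB
  g_form <- take(241, 50)  # forms at t1; drawn from CONT/SPL/MGA/MGB at t0
  none <- character(0)

  # each donation is <= 26% of the donor/recipient, well under the overlap
  # threshold band, so absorption never masquerades as continuation
  cont_t1 <- c(g_cont, g_dis[1:13])
  spl_t1 <- c(g_spl, g_dis[14:26])
  mods <- list(
    planted_module("CONT", list(
      "0" = c(g_cont, g_form[1:13]), "1" = cont_t1,
      "2" = cont_t1, "3" = cont_t1)),
    planted_module("SPL", list(
      "0" = c(g_spl, g_form[14:26]), "1" = spl_t1, "2" = none, "3" = none)),
    planted_module("SPL1", list(
      "0" = none, "1" = none,
      "2" = c(g_spl1, g_dis[14:19]), "3" = c(g_spl1, g_dis[14:19]))),
    planted_module("SPL2", list(
      "0" = none, "1" = none,
      "2" = c(g_spl2, g_dis[20:26]), "3" = c(g_spl2, g_dis[20:26]))),
    planted_module("MGA", list(
      "0" = c(g_mga, g_form[27:38]), "1" = c(g_mga, g_dis[27:38]),
      "2" = none, "3" = none)),
    planted_module("MGB", list(
      "0" = c(g_mgb, g_form[39:50]), "1" = c(g_mgb, g_dis[39:50]),
      "2" = none, "3" = none)),
    planted_module("MG", list(
      "0" = none, "1" = none,
      "2" = c(g_mga, g_mgb, g_dis[27:50]), "3" = c(g_mga, g_mgb, g_dis[27:50]))),
    planted_module("DIS", list(
      "0" = g_dis, "1" = none, "2" = none, "3" = none)),
    planted_module("FORM", list(
      "0" = none, "1" = g_form, "2" = g_form, "3" = g_form))
  )
  events <- list(
    planted_event(0, "continue", "CONT", "CONT"),
    planted_event(0, "continue", "SPL", "SPL"),
    planted_event(0, "continue", "MGA", "MGA"),
    planted_event(0, "continue", "MGB", "MGB"),
    planted_event(0, "dissolve", "DIS", none),
    planted_event(0, "form", none, "FORM"),
    planted_event(1, "continue", "CONT", "CONT"),
    planted_event(1, "split", "SPL", c("SPL1", "SPL2")),
    planted_event(1, "merge", c("MGA", "MGB"), "MG"),
    planted_event(1, "continue", "FORM", "FORM"),
    planted_event(2, "continue", "CONT", "CONT"),
    planted_event(2, "continue", "SPL1", "SPL1"),
    planted_event(2, "continue", "SPL2", "SPL2"),
    planted_event(2, "continue", "MG", "MG"),
    planted_event(2, "continue", "FORM", "FORM")
  )
  simulation_config(
    n_genes = n_genes, n_timestamps = 4,
    planted_modules = mods, event_script = events,
    noise_sd = noise_sd, within_module_corr = within_module_corr,
    de_effect_size = de_effect_size, seed = seed)
}

#' Serialize / restore ground truth as JSON
#'
#' @param truth a `simulation_truth` (from [simulate_dataset()]).
#' @param path output JSON path.
#' @export
write_simulation_truth <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  obj <- list(
    planted_modules = lapply(truth$planted_modules, function(m) {
      list(module_id = m$module_id,
           gene_ids_per_timestamp = m$gene_ids_per_timestamp,
           corr_per_timestamp = as.list(m$corr_per_timestamp))
    }),
    event_script = lapply(truth$event_script, unclass),
    mu_patient = as.list(truth$mu_patient),
    mu_control = as.list(truth$mu_control))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_simulation_truth
#' @export
read_simulation_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  mods <- lapply(obj$planted_modules, function(m) {
    gipt <- lapply(m$gene_ids_per_timestamp, function(v) unlist(v, use.names = FALSE))
    gipt <- lapply(gipt, function(v) if (is.null(v)) character(0) else as.character(v))
    corr <- if (length(m$corr_per_timestamp)) {
      stats::setNames(vapply(m$corr_per_timestamp, as.numeric, numeric(1)),
                      names(m$corr_per_timestamp))
    } else NULL
    planted_module(m$module_id, gipt, corr)
  })
  events <- lapply(obj$event_script, function(e) {
    planted_event(e$transition, e$type,
                  as.character(unlist(e$source_ids)),
                  as.character(unlist(e$target_ids)))
  })
  structure(
    list(planted_modules = mods, event_script = events,
         mu_patient = unlist(obj$mu_patient),
         mu_control = unlist(obj$mu_control)),
    class = "simulation_truth")
}
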