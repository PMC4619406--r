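# dyncoex

Dynamic gene co-expression network analysis of longitudinal cohorts:
per-visit network construction, overlapping module detection, formal
tracking of module evolutionary events, and module strength progression.

## Who this is for

Longitudinal transcriptomic studies — e.g. whole-blood expression of
patients sampled at baseline and at several points during therapy — often
show that *which genes* are differentially expressed changes less than *how
genes organize* into co-expressed modules. `dyncoex` analyzes that
reorganization. Each visit becomes a weighted co-expression network over one
shared set of disease-discriminating genes; modules detected per visit are
tracked across adjacent visits; and each module's cohesion is followed over
the whole course.

## The method in brief

1. **Gene selection.** Welch t-tests of baseline patients vs healthy
   controls; the 2,000 smallest-p genes enter every network.
2. **Networks per visit** `W^i`. Pearson correlation of all gene pairs; the
   top 10% of pairs by |r| become edges (exactly `ceiling(q·P)` of
   `P = n(n−1)/2`); the graph is augmented to connectivity with the
   strongest inter-component correlations.
3. **Modules per visit** `C^i = {C_1^i, …}`. Non-negative matrix
   factorization of the weighted adjacency, `A ≈ WH` with k = 50 factors;
   gene g joins module j when `H[j,g] ≥ 0.8·max_j' H[j',g]` (overlapping
   membership, every gene covered).
4. **Evolutionary events.** Modules of adjacent visits are matched through
   the overlap similarity `|V_x^i ∩ V_z^{i+1}| / max(|V_x^i|, |V_z^{i+1}|)`
   against a threshold α (swept over 0.12/0.16/0.20). Five events are
   classified: **form**, **dissolve**, **continue**, **split**
   (`|V_x ∩ V_y| / |V_y| ≥ α` for ≥ 2 targets y) and **merge**
   (`|V_x ∩ V_y| / |V_x| ≥ α` for ≥ 2 sources x).
5. **Strength progression.** Each candidate module (deduplicated union of
   all visits' modules) is scored against every visit's network as
   `W_in / (W_in + W_out)`, smoothed in time by an exact quadratic
   penalty on successive differences, min–max normalized across modules per
   visit, and classified as flat / late-rise / hill / early-drop / other.

A synthetic-cohort generator with planted, evolving modules
(`simulate_dataset()`, `script_standard_scenario()`) makes the whole
pipeline testable end to end without external data.

## Worked example

```r
library(dyncoex)

# a scripted 4-visit cohort: one module continues, one splits, two merge,
# one dissolves, one forms
cfg <- script_standard_scenario(seed = 11, n_genes = 600)
sim <- simulate_dataset(cfg)

d0 <- sim$datasets[[1]]
ranking <- rank_genes(subset_samples(d0, d0$metadata$group == "patient"),
                      subset_samples(d0, d0$metadata$group == "control"))
selected <- select_top_genes(ranking, 500)

nets <- lapply(seq_along(sim$datasets), function(i) {
  d <- sim$datasets[[i]]
  build_network(subset_samples(d, d$metadata$group == "patient"),
                selected, q = 0.10, timestamp = i - 1L)
})
catalog <- catalog_stages(nets, k = 5, seed = 1, n_restarts = 3)
tally_events(classify_catalog_events(catalog, alpha = 0.35))
```

```
  transition form dissolve continue split merge frac_form frac_dissolve
1          0    1        1        4     0     0 0.1666667     0.1666667
2          1    0        0        2     1     1 0.0000000     0.0000000
3          2    0        0        5     0     0 0.0000000     0.0000000
```

The tally reads off the planted script exactly: at the first transition one
module forms and one dissolves while four persist; at the second, one
splits (1 → 2) and two merge (2 → 1); afterwards all five persist. Strength
progression over the same series:

```r
cands <- deduplicate_catalog(catalog)   # 20 candidate modules
trajs <- strength_trajectories(cands, nets)
table(vapply(trajs, function(x) x$pattern, character(1)))
```

```
              other       pattern2_hill pattern3_early_drop
                 11                   4                   5
```

Here no candidate is flat — every planted module's insulation changes as
gene sets are handed over between visits — and the hill / early-drop labels
mark the modules whose cohesion peaks mid-course or starts high and decays.

The full orchestration (selection → networks → topology → modules → events
with α sweep → strengths, with logging, artifact files and a reproducibility
manifest) is one call:

```r
manifest <- run_pipeline(list(seed = 1), out_dir = "run1")
```

or, from a shell, `Rscript inst/scripts/run_pipeline.R --config run.yaml
--out run1`. Configuration is documented in `?run_pipeline`.

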