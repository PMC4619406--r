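test_that("raw strength is the internal fraction of incident weight", {
  nodes <- c("a", "b", "c", "d")
  edges <- data.frame(gene_a = c("a", "b", "c"), gene_b = c("b", "c", "d"),
                      weight = c(0.9, 0.8, 0.5), stringsAsFactors = FALSE)
  net <- make_net(edges, nodes)
  # internal {0.9, 0.8}, one boundary edge 0.5
  expect_equal(raw_strength(c("a", "b", "c"), net), 1.7 / 2.2)
  # whole network: no boundary
  expect_equal(raw_strength(nodes, net), 1)
  # single node with only external edges
  expect_equal(raw_strength("d", net), 0)
  expect_error(raw_strength(c("a", "zz"), net), "subset")
  # module with no incident edges at all
  net2 <- make_net(edges, c(nodes, "e"))
  expect_equal(raw_strength("e", net2), 0)
})

test_that("strength is 1 exactly for insulated modules", {
  set.seed(19)
  for (rep in 1:20) {
    net <- random_connected_net(15)
    genes <- sample(net$gene_ids, 6)
    s <- raw_strength(genes, net)
    expect_gte(s, 0); expect_lte(s, 1)
    ina <- net$edges$gene_a %in% genes
    inb <- net$edges$gene_b %in% genes
    insulated <- sum(net$edges$weight[xor(ina, inb)]) == 0 &&
      sum(net$edges$weight[ina & inb]) > 0
    expect_equal(s == 1, insulated)
  }
})

test_that("smoothing solves the penalized least-squares problem exactly", {
  expect_equal(smooth_trajectory(c(0.3, 0.9, 0.1), 0), c(0.3, 0.9, 0.1))
  expect_equal(smooth_trajectory(rep(0.4, 4), 2.5), rep(0.4, 4))
  # dense normal-equations oracle on the stated example
  raw <- c(1, 0, 1, 0)
  D <- diff(diag(4))
  oracle <- solve(diag(4) + 1 * crossprod(D), raw)
  expect_equal(smooth_trajectory(raw, 1), as.numeric(oracle), tolerance = 1e-12)
  # optimality and normal-equations residual on random cases
  set.seed(23)
  for (rep in 1:20) {
    T <- sample(3:8, 1)
    r <- runif(T)
    lam <- runif(1, 0, 2)
    x <- smooth_trajectory(r, lam)
    obj <- function(v) sum((v - r)^2) + lam * sum(diff(v)^2)
    expect_lte(obj(x), obj(r) + 1e-12)
    M <- diag(T) + lam * crossprod(diff(diag(T)))
    expect_lt(max(abs(M %*% x - r)), 1e-8)
  }
})

test_that("per-timestamp normalization scales to [0,1] and keeps ranks", {
  tr <- function(id, v) structure(
    list(module_id = id, raw_strengths = v, smoothed_strengths = v,
         normalized_strengths = NULL, pattern = NA_character_),
    class = "strength_trajectory")
  out <- normalize_catalog(list(tr("a", c(0.2, 0.5)), tr("b", c(0.8, 0.5))))
  expect_equal(out[[1]]$normalized_strengths, c(0, 0.5))
  expect_equal(out[[2]]$normalized_strengths, c(1, 0.5))
  # rank preservation on random catalogs
  set.seed(29)
  trajs <- lapply(1:6, function(i) tr(paste0("m", i), runif(4)))
  out2 <- normalize_catalog(trajs)
  S_raw <- do.call(rbind, lapply(trajs, `[[`, "smoothed_strengths"))
  S_nrm <- do.call(rbind, lapply(out2, `[[`, "normalized_strengths"))
  for (t in 1:4) {
    expect_equal(order(S_raw[, t]), order(S_nrm[, t]))
    expect_equal(min(S_nrm[, t]), 0)
    expect_equal(max(S_nrm[, t]), 1)
  }
})

test_that("progression patterns are classified per the stated rules", {
  cfg <- strength_config(delta = 0.2, tau_flat = 0.05)
  expect_equal(classify_pattern(c(0.1, 0.1, 0.1, 0.9), cfg), "pattern1_late_rise")
  expect_equal(classify_pattern(c(0.1, 0.8, 0.7, 0.1), cfg), "pattern2_hill")
  expect_equal(classify_pattern(c(0.9, 0.2, 0.15, 0.1), cfg), "pattern3_early_drop")
  expect_equal(classify_pattern(c(0.5, 0.5, 0.5, 0.5), cfg), "flat")
  expect_equal(classify_pattern(c(0.1, 0.5, 0.2, 0.6), cfg), "other")
  expect_error(classify_pattern(c(0.1, 0.2, 0.3), cfg), "4 timestamps")
  # exhaustive and deterministic over random vectors
  set.seed(37)
  labels <- c("flat", "pattern1_late_rise", "pattern2_hill",
              "pattern3_early_drop", "other")
  for (rep in 1:200) {
    x <- runif(4)
    l1 <- classify_pattern(x, cfg)
    expect_true(l1 %in% labels)
    expect_identical(l1, classify_pattern(x, cfg))
  }
})

test_that("group comparison flags planted divergence and shared patterns", {
  tr <- function(id, v, pat) structure(
    list(module_id = id, raw_strengths = v, smoothed_strengths = v,
         normalized_strengths = v, pattern = pat),
    class = "strength_trajectory")
  a <- list(tr("m1", c(0.1, 0.1, 0.1, 0.9), "pattern1_late_rise"),
            tr("m2", c(0.5, 0.5, 0.5, 0.5), "flat"))
  # identical groups: everything shared
  same <- compare_groups(a, a)
  expect_true(all(same$per_module$mean_abs_diff == 0))
  expect_true(all(same$per_pattern$status == "shared"))
  # m1 strengthens only in group A
  b <- list(tr("m1", c(0.1, 0.1, 0.1, 0.1), "pattern1_late_rise"),
            tr("m2", c(0.5, 0.5, 0.5, 0.5), "flat"))
  div <- compare_groups(a, b, delta = 0.15)
  row <- div$per_pattern[div$per_pattern$pattern == "pattern1_late_rise", ]
  expect_equal(row$status, "divergent")
  expect_true(all(div$per_pattern$divergent_fraction >= 0 &
                    div$per_pattern$divergent_fraction <= 1))
  # disjoint module sets are an error
  c_ <- list(tr("zz", c(0, 0, 0, 0), "flat"))
  expect_error(compare_groups(a, c_), "share no")
})

test_that("trajectory scoring integrates strength, smoothing and patterns", {
  set.seed(41)
  net <- random_connected_net(30, p = 0.25)
  nets <- lapply(0:3, function(t) { net$timestamp <- t; net })
  mods <- list(gene_module("m1", 0, net$gene_ids[1:8]),
               gene_module("m2", 0, net$gene_ids[9:20]))
  trajs <- strength_trajectories(mods, nets, strength_config())
  expect_length(trajs, 2)
  for (x in trajs) {
    expect_length(x$raw_strengths, 4)
    expect_true(all(x$normalized_strengths >= 0 & x$normalized_strengths <= 1))
    # identical networks at all timestamps: constant trajectories
    expect_equal(length(unique(round(x$raw_strengths, 12))), 1)
    expect_false(is.na(x$pattern))
  }
})
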