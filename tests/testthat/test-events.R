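gm <- function(id, genes, t = 0) gene_module(id, t, genes)

test_that("module similarity follows the max-denominator overlap formula", {
  expect_equal(module_similarity(c("a", "b"), c("a", "b")), 1)
  expect_equal(module_similarity(c("a", "b"), c("c", "d")), 0)
  a <- paste0("g", 1:6); b <- paste0("g", 4:13)
  expect_equal(module_similarity(a, b), 3 / 10)
  expect_equal(module_similarity(a, b), module_similarity(b, a))
  expect_error(module_similarity(character(0), "a"), "non-empty")
})

test_that("tracking returns the argmax match or none, deterministically", {
  src <- gm("s", paste0("g", 1:10))
  cat_next <- list(gm("t1_a", paste0("g", 1:10), 1),
                   gm("t1_b", paste0("g", 5:14), 1))
  tr <- track_module(src, cat_next, alpha = 0.5)
  expect_equal(tr$matched_id, "t1_a")
  expect_equal(tr$similarity, 1)
  # below alpha -> none
  tr2 <- track_module(src, list(gm("t1_c", paste0("h", 1:10), 1)), alpha = 0.2)
  expect_true(is.na(tr2$matched_id))
  # empty next catalog -> none
  expect_true(is.na(track_module(src, list(), alpha = 0.5)$matched_id))
  # ties broken by smallest module id
  tie <- list(gm("t1_z", paste0("g", 1:5), 1), gm("t1_a", paste0("g", 6:10), 1))
  expect_equal(track_module(src, tie, alpha = 0.1)$matched_id, "t1_a")
})

test_that("tracking equals a brute-force scan on random catalogs", {
  set.seed(90)
  pool <- paste0("g", 1:50)
  for (rep in 1:20) {
    src <- gm("s", sample(pool, sample(5:15, 1)))
    cat_next <- random_catalog(sample(5:20, 1), pool, 1)
    alpha <- runif(1, 0.05, 0.6)
    tr <- track_module(src, cat_next, alpha)
    sims <- vapply(cat_next, function(m) module_similarity(src$gene_ids, m$gene_ids),
                   numeric(1))
    ids <- vapply(cat_next, `[[`, "", "module_id")
    best <- ids[order(-sims, ids)][1]
    if (max(sims) >= alpha) expect_equal(tr$matched_id, best)
    else expect_true(is.na(tr$matched_id))
    expect_equal(tr$similarity, max(sims))
  }
})

test_that("scripted split and merge configurations are classified", {
  # one module whose halves each dominate a next-timestamp module
  src <- list(gm("t0_s", paste0("g", 1:20)))
  tgt <- list(gm("t1_a", paste0("g", 1:10), 1), gm("t1_b", paste0("g", 11:20), 1))
  ev <- classify_events(src, tgt, alpha = 0.5)
  types <- vapply(ev, `[[`, "", "type")
  expect_equal(sum(types == "split"), 1)
  sp <- ev[[which(types == "split")]]
  expect_equal(sp$source_ids, "t0_s")
  expect_setequal(sp$target_ids, c("t1_a", "t1_b"))

  # three modules folding into one
  src3 <- list(gm("t0_a", paste0("g", 1:8)), gm("t0_b", paste0("g", 9:16)),
               gm("t0_c", paste0("g", 17:24)))
  tgt3 <- list(gm("t1_m", paste0("g", 1:24), 1))
  ev3 <- classify_events(src3, tgt3, alpha = 0.5)
  types3 <- vapply(ev3, `[[`, "", "type")
  expect_equal(sum(types3 == "merge"), 1)
  mg <- ev3[[which(types3 == "merge")]]
  expect_setequal(mg$source_ids, c("t0_a", "t0_b", "t0_c"))
  expect_equal(mg$target_ids, "t1_m")
})

test_that("zero-overlap modules dissolve and form", {
  src <- list(gm("t0_x", paste0("g", 1:10)))
  tgt <- list(gm("t1_y", paste0("h", 1:10), 1))
  ev <- classify_events(src, tgt, alpha = 0.2)
  types <- vapply(ev, `[[`, "", "type")
  expect_setequal(types, c("dissolve", "form"))
})

test_that("every module appears in at least one record per transition", {
  set.seed(14)
  pool <- paste0("g", 1:60)
  for (rep in 1:25) {
    ci <- random_catalog(sample(3:10, 1), pool, 0)
    cn <- random_catalog(sample(3:10, 1), pool, 1)
    alpha <- runif(1, 0.1, 0.9)
    ev <- classify_events(ci, cn, alpha)
    src_cov <- unique(unlist(lapply(ev, `[[`, "source_ids")))
    tgt_cov <- unique(unlist(lapply(ev, `[[`, "target_ids")))
    expect_true(all(vapply(ci, `[[`, "", "module_id") %in% src_cov))
    expect_true(all(vapply(cn, `[[`, "", "module_id") %in% tgt_cov))
  }
})

test_that("tallies count and normalize the five types", {
  ev <- list(
    classify_events(list(gm("a", paste0("g", 1:5))),
                    list(gm("b", paste0("g", 1:5), 1)), 0.5)[[1]])
  one_each <- list(
    structure(list(transition = 0L, type = "form", source_ids = character(0),
                   target_ids = "x", similarities = numeric(0)),
              class = "event_record"),
    structure(list(transition = 0L, type = "dissolve", source_ids = "a",
                   target_ids = character(0), similarities = numeric(0)),
              class = "event_record"),
    structure(list(transition = 0L, type = "continue", source_ids = "a",
                   target_ids = "b", similarities = 1), class = "event_record"),
    structure(list(transition = 0L, type = "split", source_ids = "a",
                   target_ids = c("b", "c"), similarities = c(1, 1)),
              class = "event_record"),
    structure(list(transition = 0L, type = "merge", source_ids = c("a", "b"),
                   target_ids = "c", similarities = c(1, 1)),
              class = "event_record"))
  tb <- tally_events(one_each)
  fracs <- unlist(tb[1, paste0("frac_", c("form", "dissolve", "continue",
                                          "split", "merge"))])
  expect_equal(unname(fracs), rep(0.2, 5))
  expect_equal(sum(fracs), 1, tolerance = 1e-9)
  # empty input: guarded zero tally
  empty <- tally_events(list())
  expect_equal(nrow(empty), 0)
})

test_that("at alpha = 1 all non-identical modules dissolve and form", {
  set.seed(2)
  pool <- paste0("g", 1:40)
  ci <- random_catalog(5, pool, 0)
  cn <- random_catalog(6, pool, 1)
  ev <- classify_events(ci, cn, alpha = 1)
  types <- vapply(ev, `[[`, "", "type")
  expect_equal(sum(types == "dissolve"), 5)
  expect_equal(sum(types == "form"), 6)
})

test_that("form+dissolve counts are non-decreasing in alpha", {
  set.seed(101)
  pool <- paste0("g", 1:60)
  for (rep in 1:100) {
    stages <- list("0" = random_catalog(sample(3:8, 1), pool, 0),
                   "1" = random_catalog(sample(3:8, 1), pool, 1))
    catalog <- structure(stages, class = "module_catalog", k = 8)
    tallies <- sweep_alpha(catalog, c(0.12, 0.16, 0.20))
    fd <- vapply(tallies, function(tb) sum(tb$form) + sum(tb$dissolve),
                 numeric(1))
    expect_true(all(diff(fd) >= 0))
  }
})

test_that("an alpha sweep returns one tally per threshold", {
  set.seed(6)
  pool <- paste0("g", 1:40)
  catalog <- structure(list("0" = random_catalog(4, pool, 0),
                            "1" = random_catalog(4, pool, 1),
                            "2" = random_catalog(4, pool, 2)),
                       class = "module_catalog", k = 4)
  tallies <- sweep_alpha(catalog, c(0.12, 0.16, 0.20))
  expect_length(tallies, 3)
  expect_named(tallies, c("0.12", "0.16", "0.2"))
  for (tb in tallies) expect_equal(tb$transition, c(0, 1))
  expect_error(sweep_alpha(catalog, c(0.2, 0.12)), "increasing")
})

test_that("events serialize as JSON lines", {
  src <- list(gm("t0_x", paste0("g", 1:10)))
  tgt <- list(gm("t1_y", paste0("g", 1:10), 1))
  ev <- classify_events(src, tgt, alpha = 0.5)
  path <- tempfile(fileext = ".jsonl")
  write_events_jsonl(ev, path)
  lines <- readLines(path)
  expect_length(lines, length(ev))
  parsed <- jsonlite::fromJSON(lines[1])
  expect_equal(parsed$type, "continue")
})
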