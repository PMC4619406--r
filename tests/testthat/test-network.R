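test_that("correlation matrix matches the textbook formula", {
  set.seed(21)
  x <- matrix(rnorm(200), 10, 20,
              dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:20)))
  r <- correlation_matrix(tiny_dataset(x))
  expect_equal(diag(r), setNames(rep(1, 10), rownames(x)))
  expect_lt(max(abs(r - t(r))), 1e-12)
  for (i in 1:9) for (j in (i + 1):10) {
    a <- x[i, ]; b <- x[j, ]
    oracle <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(r[i, j], oracle, tolerance = 1e-10)
  }
})

test_that("perfect anticorrelation and zero-variance genes are handled", {
  x <- matrix(rnorm(30), 3, 10,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:10)))
  x["g2", ] <- -x["g1", ]
  x["g3", ] <- 5
  expect_warning(r <- correlation_matrix(tiny_dataset(x)), "zero-variance")
  expect_equal(r["g1", "g2"], -1, tolerance = 1e-12)
  expect_equal(r["g1", "g3"], 0)
  expect_equal(r["g3", "g3"], 1)
})

test_that("thresholding retains exactly the top fraction of pairs", {
  set.seed(33)
  n <- 40
  x <- matrix(rnorm(n * 15), n, 15,
              dimnames = list(sprintf("g%02d", 1:n), paste0("s", 1:15)))
  corr <- correlation_matrix(tiny_dataset(x))
  P <- n * (n - 1) / 2
  for (q in c(0.05, 0.10, 0.37, 1)) {
    net <- threshold_network(corr, q = q)
    expect_equal(nrow(net$edges), ceiling(q * P))
  }
  expect_error(threshold_network(corr, q = 0), "q must be")
  expect_error(threshold_network(corr, q = 1.2), "q must be")
})

test_that("threshold selection equals a brute-force sort on distinct values", {
  set.seed(8)
  n <- 5
  x <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(c("a", "b", "c", "d", "e"), paste0("s", 1:12)))
  corr <- correlation_matrix(tiny_dataset(x))
  net <- threshold_network(corr, q = 0.2) # ceiling(0.2 * 10) = 2 pairs
  ut <- which(upper.tri(corr), arr.ind = TRUE)
  vals <- abs(corr[ut])
  top <- order(-vals)[1:2]
  expected <- apply(ut[top, , drop = FALSE], 1, function(ij) {
    paste(sort(rownames(corr)[ij]), collapse = "|")
  })
  got <- paste(net$edges$gene_a, net$edges$gene_b, sep = "|")
  expect_setequal(got, expected)
  expect_equal(net$threshold_value, min(vals[top]), tolerance = 1e-12)
})

test_that("thresholding is invariant under gene relabeling", {
  set.seed(55)
  n <- 12
  x <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(sprintf("g%02d", 1:n), paste0("s", 1:10)))
  corr <- correlation_matrix(tiny_dataset(x))
  net <- threshold_network(corr, q = 0.3)
  perm <- sample(n)
  net_p <- threshold_network(corr[perm, perm], q = 0.3)
  canon <- function(net) {
    e <- net$edges
    sort(paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b)))
  }
  expect_identical(canon(net), canon(net_p))
})

test_that("connectivity augmentation adds exactly the strongest bridges", {
  # two planted cliques joined by one weak cross-pair
  set.seed(71)
  nodes <- sprintf("g%02d", 1:10)
  corr <- diag(10)
  dimnames(corr) <- list(nodes, nodes)
  for (i in 1:5) for (j in 1:5) if (i != j) corr[i, j] <- 0.9
  for (i in 6:10) for (j in 6:10) if (i != j) corr[i, j] <- 0.85
  corr[3, 8] <- corr[8, 3] <- 0.4 # the strongest inter-clique pair
  corr[2, 9] <- corr[9, 2] <- 0.2
  net <- threshold_network(corr, q = 0.44) # ceiling(19.8) = 20: the clique edges only
  expect_gt(length(unique(igraph::components(as_igraph(net))$membership)), 1)
  fixed <- enforce_connectivity(net, corr)
  aug <- fixed$edges[fixed$edges$augmented, ]
  expect_equal(nrow(aug), 1)
  expect_equal(sort(c(aug$gene_a, aug$gene_b)), c("g03", "g08"))
  expect_true(igraph::is_connected(as_igraph(fixed)))
  # already-connected network passes through untouched
  expect_identical(enforce_connectivity(fixed, corr), fixed)
})

test_that("k components need exactly k-1 augmented edges", {
  set.seed(91)
  blocks <- list(1:4, 5:8, 9:12, 13:16)
  nodes <- sprintf("g%02d", 1:16)
  corr <- diag(16) * 0 + stats::runif(256, 0, 0.05)
  corr <- (corr + t(corr)) / 2
  for (b in blocks) for (i in b) for (j in b) if (i != j) corr[i, j] <- 0.9
  diag(corr) <- 1
  dimnames(corr) <- list(nodes, nodes)
  net <- threshold_network(corr, q = 0.2)
  comp <- igraph::components(as_igraph(net))$no
  fixed <- enforce_connectivity(net, corr)
  expect_equal(sum(fixed$edges$augmented), comp - 1)
  expect_true(igraph::is_connected(as_igraph(fixed)))
})

test_that("degree distribution fit flags scale-free-like graphs", {
  set.seed(5)
  g <- igraph::sample_pa(1000, m = 3, directed = FALSE)
  el <- igraph::as_edgelist(g)
  nodes <- sprintf("g%04d", 1:1000)
  net <- make_net(data.frame(gene_a = nodes[pmin(el[, 1], el[, 2])],
                             gene_b = nodes[pmax(el[, 1], el[, 2])],
                             weight = 0.5, stringsAsFactors = FALSE), nodes)
  fit <- degree_distribution_fit(net)
  expect_gte(fit$r_squared, 0.7)
  expect_gt(fit$powerlaw_exponent, 0)
  # a near-regular random graph fits a power law worse
  g2 <- igraph::sample_gnp(1000, 0.01)
  el2 <- igraph::as_edgelist(g2)
  net2 <- make_net(data.frame(gene_a = nodes[pmin(el2[, 1], el2[, 2])],
                              gene_b = nodes[pmax(el2[, 1], el2[, 2])],
                              weight = 0.5, stringsAsFactors = FALSE), nodes)
  fit2 <- degree_distribution_fit(net2)
  expect_lt(fit2$r_squared, fit$r_squared)
})

test_that("regular graphs cannot be fitted", {
  nodes <- sprintf("g%02d", 1:20)
  ring <- data.frame(gene_a = nodes, gene_b = nodes[c(2:20, 1)],
                     weight = 0.5, stringsAsFactors = FALSE)
  swap <- ring$gene_a > ring$gene_b
  tmp <- ring$gene_a[swap]; ring$gene_a[swap] <- ring$gene_b[swap]
  ring$gene_b[swap] <- tmp
  expect_error(degree_distribution_fit(make_net(ring, nodes)),
               "fewer than 3 distinct degrees")
})

test_that("edge lists round-trip through TSV", {
  net <- random_connected_net(15)
  path <- tempfile(fileext = ".tsv")
  write_edgelist_tsv(net, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(net$edges))
  expect_equal(back$weight, net$edges$weight, tolerance = 1e-12)
})
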