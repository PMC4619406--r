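# Brute-force oracles and small fixture builders, independent of the package
# implementation paths they check.

# Welch two-sample t from the textbook formula
welch_brute <- function(x, y) {
  nx <- length(x); ny <- length(y)
  se2 <- stats::var(x) / nx + stats::var(y) / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((stats::var(x) / nx)^2 / (nx - 1) + (stats::var(y) / ny)^2 / (ny - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

# adjacency list from an edge data frame over nodes 1..n (ignoring weights)
adj_from_edges <- function(edges, nodes) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

bfs_dist_counts <- function(adj, src) {
  nodes <- names(adj)
  d <- stats::setNames(rep(Inf, length(nodes)), nodes)
  nsp <- stats::setNames(rep(0, length(nodes)), nodes)
  d[src] <- 0; nsp[src] <- 1
  frontier <- src
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) for (w in adj[[v]]) {
      if (is.infinite(d[w])) {
        d[w] <- d[v] + 1
        nxt <- c(nxt, w)
      }
      if (d[w] == d[v] + 1) nsp[w] <- nsp[w] + nsp[v]
    }
    frontier <- unique(nxt)
  }
  list(d = d, nsp = nsp)
}

# all-pairs-BFS betweenness / closeness / clustering (unweighted, normalized)
brute_topology <- function(net) {
  nodes <- net$gene_ids
  n <- length(nodes)
  adj <- adj_from_edges(net$edges, nodes)
  bfs <- lapply(stats::setNames(nodes, nodes), function(s) bfs_dist_counts(adj, s))
  btw <- stats::setNames(rep(0, n), nodes)
  for (si in seq_len(n - 1)) for (ti in (si + 1):n) {
    s <- nodes[si]; t <- nodes[ti]
    dst <- bfs[[s]]$d[t]
    if (is.infinite(dst)) next
    for (v in nodes) {
      if (v == s || v == t) next
      if (bfs[[s]]$d[v] + bfs[[v]]$d[t] == dst) {
        btw[v] <- btw[v] + bfs[[s]]$nsp[v] * bfs[[v]]$nsp[t] / bfs[[s]]$nsp[t]
      }
    }
  }
  btw <- btw / ((n - 1) * (n - 2) / 2)
  clo <- vapply(nodes, function(s) (n - 1) / sum(bfs[[s]]$d[-match(s, nodes)]),
                numeric(1))
  cc <- vapply(nodes, function(v) {
    nb <- adj[[v]]
    if (length(nb) < 2) return(0)
    m <- 0
    for (i in seq_len(length(nb) - 1)) for (j in (i + 1):length(nb)) {
      if (nb[j] %in% adj[[nb[i]]]) m <- m + 1
    }
    m / choose(length(nb), 2)
  }, numeric(1))
  list(avg_betweenness = mean(btw), avg_closeness = mean(clo),
       avg_clustering_coefficient = mean(cc))
}

# build a coexpression_network directly from an edge table
make_net <- function(edges, nodes, timestamp = 0L) {
  edges$augmented <- if (is.null(edges$augmented)) FALSE else edges$augmented
  structure(
    list(timestamp = as.integer(timestamp), gene_ids = nodes, edges = edges,
         threshold_value = min(edges$weight), q = NA_real_, mode = "absolute"),
    class = "coexpression_network")
}

# random connected graph as a coexpression_network
random_connected_net <- function(n, p = 0.15) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  el <- igraph::as_edgelist(g)
  nodes <- sprintf("g%02d", seq_len(n))
  edges <- data.frame(gene_a = nodes[pmin(el[, 1], el[, 2])],
                      gene_b = nodes[pmax(el[, 1], el[, 2])],
                      weight = stats::runif(nrow(el), 0.3, 1),
                      augmented = FALSE, stringsAsFactors = FALSE)
  make_net(edges, nodes)
}

# random module catalog over a shared gene pool
random_catalog <- function(n_modules, pool, timestamp = 0L,
                           size_range = c(5, 15)) {
  lapply(seq_len(n_modules), function(j) {
    sz <- sample(size_range[1]:size_range[2], 1)
    gene_module(sprintf("t%d_m%02d", timestamp, j), timestamp,
                sample(pool, sz))
  })
}

# tiny expression dataset with given matrix
tiny_dataset <- function(values) {
  metadata <- data.frame(sample_id = colnames(values), stringsAsFactors = FALSE)
  expression_dataset(values, metadata)
}
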