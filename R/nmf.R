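#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the Frobenius error ||A - WH||_F^2 over non-negative factors
#' with Lee-Seung multiplicative updates, best of `n_restarts` random
#' initializations. The objective is non-increasing across iterations (a
#' property the tests assert). `A` may be a sparse [Matrix::Matrix], which
#' keeps updates cheap for thresholded adjacency matrices.
#'
#' @param A non-negative matrix (dense or sparse), n x p.
#' @param k inner dimension (number of factors), k < min(n, p).
#' @param seed integer; restart r uses seed + r - 1, so results are
#'   reproducible.
#' @param n_restarts random restarts; the factorization with the smallest
#'   final error is returned.
#' @param max_iter maximum multiplicative updates per restart.
#' @param tol relative decrease of the objective below which a restart stops.
#' @param init `"nndsvd"` (default) seeds the first restart with the
#'   non-negative double SVD of A — for near-block-diagonal adjacency
#'   matrices this starts close to the community indicators, which random
#'   initialization often misses — and the remaining restarts randomly;
#'   `"random"` uses random restarts only.
#' @return list with `W` (n x k), `H` (k x p), `loss` (objective trace of the
#'   winning restart), `converged` (logical; FALSE means max_iter was hit and
#'   the best iterate is returned with a warning).
#' @export
nmf_factorize <- function(A, k, seed = 1L, n_restarts = 5,
                          max_iter = 200, tol = 1e-4,
                          init = c("nndsvd", "random")) {
  init <- match.arg(init)
  n <- nrow(A); p <- ncol(A)
  if (k >= min(n, p)) stop("k must be smaller than both matrix dimensions")
  if (min(A) < 0) stop("A must be non-negative")
  A <- methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")
  normA2 <- sum(A@x^2)
  eps <- 1e-10
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    if (r == 1 && init == "nndsvd") {
      sv <- nndsvd_init(A, k)
      W <- sv$W; H <- sv$H
    } else {
      W <- matrix(stats::runif(n * k, 0.1, 1), n, k)
      H <- matrix(stats::runif(k * p, 0.1, 1), k, p)
    }
    loss <- numeric(0)
    prev <- Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      W <- W * as.matrix(Matrix::tcrossprod(A, H)) / (W %*% tcrossprod(H) + eps)
      WtA <- as.matrix(Matrix::crossprod(W, A))
      H <- H * WtA / (crossprod(W) %*% H + eps)
      # ||A - WH||^2 = ||A||^2 - 2 <A, WH> + ||WH||^2, all terms sparse-cheap
      cur <- normA2 - 2 * sum(WtA * H) + sum(crossprod(W) * tcrossprod(H))
      loss <- c(loss, cur)
      if (is.finite(prev) && prev - cur <= tol * max(prev, eps)) {
        converged <- TRUE
        break
      }
      prev <- cur
    }
    fit <- list(W = W, H = H, loss = loss, converged = converged)
    if (is.null(best) || utils::tail(loss, 1) < utils::tail(best$loss, 1)) {
      best <- fit
    }
  }
  if (!best$converged) {
    warning("NMF did not converge within max_iter; returning best iterate")
  }
  best
}

# Non-negative double SVD initialization (symmetric input): keeps, for each
# leading singular pair, whichever sign section carries more energy. Zeros
# are lifted to a small positive constant so multiplicative updates can move
# every entry.
nndsvd_init <- function(A, k) {
  es <- eigen(as.matrix(A), symmetric = TRUE)
  ord <- order(-abs(es$values))[seq_len(k)]
  n <- nrow(A)
  W <- matrix(0, n, k); H <- matrix(0, k, n)
  for (j in seq_len(k)) {
    lam <- es$values[ord[j]]
    u <- es$vectors[, ord[j]]
    v <- sign(lam) * u
    sig <- abs(lam)
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    if (sqrt(sum(up^2)) * sqrt(sum(vp^2)) >= sqrt(sum(un^2)) * sqrt(sum(vn^2))) {
      nu <- sqrt(sum(up^2)); nv <- sqrt(sum(vp^2))
      scale <- sqrt(sig * nu * nv)
      W[, j] <- if (nu > 0) scale * up / nu else 0
      H[j, ] <- if (nv > 0) scale * vp / nv else 0
    } else {
      nu <- sqrt(sum(un^2)); nv <- sqrt(sum(vn^2))
      scale <- sqrt(sig * nu * nv)
      W[, j] <- if (nu > 0) scale * un / nu else 0
      H[j, ] <- if (nv > 0) scale * vn / nv else 0
    }
  }
  floor_val <- mean(abs(A@x)) * 1e-4
  W[W < floor_val] <- floor_val
  H[H < floor_val] <- floor_val
  list(W = W, H = H)
}

#' A gene module at one timestamp
#'
#' @param module_id identifier (globally unique when produced by
#'   [catalog_stages()], timestamp-prefixed).
#' @param timestamp integer timestamp index.
#' @param gene_ids non-empty character vector of member genes.
#' @param loadings optional per-gene membership scores.
#' @return an object of class `gene_module`.
#' @export
gene_module <- function(module_id, timestamp, gene_ids, loadings = NULL) {
  if (!length(gene_ids)) stop("gene module must be non-empty")
  structure(list(module_id = module_id, timestamp = as.integer(timestamp),
                 gene_ids = unique(as.character(gene_ids)),
                 loadings = loadings),
            class = "gene_module")
}

#' Detect overlapping modules in one network by NMF
#'
#' Factorizes the symmetric non-negative weighted adjacency matrix (entries
#' are edge weights |r|, zero otherwise) as A ~ W H with inner dimension `k`.
#' Gene g is assigned to module j iff `H[j, g] >= membership_cutoff *
#' max_j' H[j', g]` — a relative rule that allows overlapping membership
#' while guaranteeing each gene at least one module (a gene whose loadings
#' are all zero falls back to its largest-loading row). Empty modules are
#' dropped, so up to `k` modules are returned.
#'
#' @param net a connected `coexpression_network`.
#' @param k preset module count (default 50), k < number of nodes.
#' @param seed,n_restarts,max_iter,tol passed to [nmf_factorize()].
#' @param membership_cutoff relative loading cutoff c in (0, 1], default 0.8.
#' @return list of [gene_module()] objects (ids `t<timestamp>_m<j>`).
#' @export
detect_modules <- function(net, k = 50, seed = 1L, n_restarts = 5,
                           membership_cutoff = 0.8, max_iter = 200,
                           tol = 1e-4) {
  stopifnot(inherits(net, "coexpression_network"))
  genes <- net$gene_ids
  n <- length(genes)
  if (k >= n) stop("k must be smaller than the number of network nodes")
  A <- network_adjacency(net)
  fit <- nmf_factorize(A, k, seed = seed, n_restarts = n_restarts,
                       max_iter = max_iter, tol = tol)
  H <- fit$H
  colnames(H) <- genes
  members <- vector("list", k)
  mx <- apply(H, 2, max)
  arg <- apply(H, 2, which.max)
  for (g in seq_len(n)) {
    js <- if (mx[g] <= 0) arg[g] else which(H[, g] >= membership_cutoff * mx[g])
    for (j in js) members[[j]] <- c(members[[j]], genes[g])
  }
  out <- list()
  for (j in seq_len(k)) {
    if (!length(members[[j]])) next
    id <- sprintf("t%d_m%02d", net$timestamp, j)
    out[[length(out) + 1]] <- gene_module(
      id, net$timestamp, members[[j]],
      loadings = stats::setNames(H[j, members[[j]]], members[[j]]))
  }
  out
}

network_adjacency <- function(net) {
  genes <- net$gene_ids
  ia <- match(net$edges$gene_a, genes)
  ib <- match(net$edges$gene_b, genes)
  Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia),
                       x = rep(net$edges$weight, 2),
                       dims = c(length(genes), length(genes)),
                       dimnames = list(genes, genes))
}

#' Detect modules at every timestamp of a network series
#'
#' @param nets list of >= 2 connected networks in timestamp order.
#' @param k preset module count per stage (default 50).
#' @param seed,n_restarts,membership_cutoff,max_iter,tol see
#'   [detect_modules()]; each stage uses `seed + 1000 * timestamp`.
#' @return an object of class `module_catalog`: named list (timestamp as
#'   name) of lists of `gene_module`, with attribute `k`.
#' @export
catalog_stages <- function(nets, k = 50, seed = 1L, n_restarts = 5,
                           membership_cutoff = 0.8, max_iter = 200,
                           tol = 1e-4) {
  stopifnot(length(nets) >= 2)
  stages <- lapply(nets, function(net) {
    detect_modules(net, k = k, seed = seed + 1000L * net$timestamp,
                   n_restarts = n_restarts,
                   membership_cutoff = membership_cutoff,
                   max_iter = max_iter, tol = tol)
  })
  names(stages) <- vapply(nets, function(n) as.character(n$timestamp), character(1))
  structure(stages, class = "module_catalog", k = k)
}

#' Jaccard index of two gene sets
#'
#' @param a,b character vectors.
#' @return |a n b| / |a u b|.
#' @export
jaccard_index <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

#' Deduplicate a multi-stage module catalog into a candidate set
#'
#' Modules re-detected at several timestamps are near-identical gene sets;
#' for strength progression each distinct module should be scored once
#' against every timestamp's network. Pairs with Jaccard >= `jaccard_cutoff`
#' are grouped by union-find and the earliest-timestamp representative
#' (smallest module id on ties) of each group is kept. Output order is
#' deterministic: by timestamp, then module id.
#'
#' @param catalog a `module_catalog` (or plain list of `gene_module`).
#' @param jaccard_cutoff duplicate threshold, default 0.9.
#' @return list of `gene_module` — the deduplicated candidate set.
#' @export
deduplicate_catalog <- function(catalog, jaccard_cutoff = 0.9) {
  mods <- if (inherits(catalog, "module_catalog")) {
    unlist(unname(catalog), recursive = FALSE)
  } else catalog
  if (!length(mods)) return(list())
  ord <- order(vapply(mods, function(m) m$timestamp, integer(1)),
               vapply(mods, function(m) m$module_id, character(1)))
  mods <- mods[ord]
  n <- length(mods)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (jaccard_index(mods[[i]]$gene_ids, mods[[j]]$gene_ids) >= jaccard_cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  mods[sort(unique(roots))]
}

#' Write / read gene modules in GMT format
#'
#' One line per module: module id, a description field carrying the
#' timestamp, then tab-separated gene ids.
#'
#' @param modules list of `gene_module`.
#' @param path output path.
#' @export
write_gmt <- function(modules, path) {
  lines <- vapply(modules, function(m) {
    paste(c(m$module_id, sprintf("timestamp=%d", m$timestamp), m$gene_ids),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    ts <- sub("^timestamp=", "", parts[2])
    gene_module(parts[1], as.integer(ts), parts[-(1:2)])
  })
}
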