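# Independent oracles and fixture builders used across the suite.

# all permutations of 1..n, iteratively (independent of package internals)
perm_list <- function(n) {
  out <- list(1L)
  for (k in 2:n) {
    out <- unlist(lapply(out, function(p) {
      lapply(seq_len(k), function(pos) append(p, k, after = pos - 1L))
    }), recursive = FALSE)
  }
  out
}

# ANOSIM R from a full distance matrix and labels, by the defining formula
anosim_R_oracle <- function(dmat, groups) {
  dmat <- as.matrix(dmat)
  n <- nrow(dmat)
  pairs <- which(upper.tri(dmat), arr.ind = TRUE)
  dvals <- dmat[pairs]
  rk <- rank(dvals)
  within <- groups[pairs[, 1]] == groups[pairs[, 2]]
  (mean(rk[!within]) - mean(rk[within])) / (n * (n - 1) / 4)
}

anosim_exhaustive_oracle <- function(dmat, groups) {
  n <- nrow(as.matrix(dmat))
  obs <- anosim_R_oracle(dmat, groups)
  stats <- vapply(perm_list(n), function(p) anosim_R_oracle(dmat, groups[p]),
                  numeric(1))
  list(R = obs, p = mean(stats >= obs - 1e-12), n_perm = length(stats))
}

mantel_exhaustive_oracle <- function(m1, m2, method = "pearson",
                                     alternative = "two.sided") {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  n <- nrow(m1)
  ut <- upper.tri(m1)
  obs <- cor(m1[ut], m2[ut], method = method)
  stats <- vapply(perm_list(n), function(p) {
    mp <- m2[p, p]
    cor(m1[ut], mp[ut], method = method)
  }, numeric(1))
  p <- if (alternative == "two.sided") {
    mean(abs(stats) >= abs(obs) - 1e-12)
  } else {
    mean(stats >= obs - 1e-12)
  }
  list(r = obs, p = p, n_perm = length(stats))
}

# weighted modularity by the defining double sum
modularity_oracle <- function(edges, membership, weights) {
  ids <- names(membership)
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  for (k in seq_len(nrow(edges))) {
    W[edges$from[k], edges$to[k]] <- weights[k]
    W[edges$to[k], edges$from[k]] <- weights[k]
  }
  tw2 <- sum(W) # = 2 * total edge weight
  strength <- rowSums(W)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + W[i, j] - strength[i] * strength[j] / tw2
      }
    }
  }
  unname(q / tw2)
}

# construct a co_network directly from an edge table (for closed-form tests)
make_net <- function(edges, node_ids = NULL, abundance = NULL,
                     pearson = NULL, modules = NULL) {
  if (is.null(node_ids)) node_ids <- sort(unique(c(edges$from, edges$to)))
  n <- length(node_ids)
  if (is.null(abundance)) abundance <- rep(1 / n, n)
  if (!"rho" %in% names(edges)) edges[["rho"]] <- rep(0.8, nrow(edges))
  if (!"p" %in% names(edges)) edges[["p"]] <- rep(1e-4, nrow(edges))
  if (!"q" %in% names(edges)) edges[["q"]] <- edges[["p"]]
  edges[["sign"]] <- ifelse(edges[["rho"]] >= 0, 1L, -1L)
  deg <- table(factor(c(edges$from, edges$to), levels = node_ids))
  if (is.null(pearson)) {
    pearson <- matrix(0, n, n, dimnames = list(node_ids, node_ids))
    for (k in seq_len(nrow(edges))) {
      pearson[edges$from[k], edges$to[k]] <- edges$rho[k]
      pearson[edges$to[k], edges$from[k]] <- edges$rho[k]
    }
    diag(pearson) <- 1
  }
  structure(list(
    nodes = tibble::tibble(node_id = node_ids,
                           abundance = abundance,
                           degree = as.integer(deg[node_ids]),
                           module = if (is.null(modules)) NA_integer_ else
                             as.integer(modules[node_ids])),
    edges = tibble::as_tibble(edges[, c("from", "to", "rho", "p", "q", "sign")]),
    pearson = pearson,
    spearman = pearson,
    n_samples = 10L,
    params = list(rho_min = 0.6, alpha = 0.05, correction = "BH"),
    modularity = NA_real_), class = "co_network")
}

# complete graph edge table on ids
complete_edges <- function(ids, rho = 0.8) {
  idx <- t(utils::combn(ids, 2))
  data.frame(from = idx[, 1], to = idx[, 2], rho = rho,
             p = 1e-5, q = 1e-5, stringsAsFactors = FALSE)
}

# random undirected graph as an edge table with random weights
random_graph_edges <- function(n, p_edge = 0.4, seed = 1) {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n))
  idx <- t(utils::combn(ids, 2))
  keep <- runif(nrow(idx)) < p_edge
  idx <- idx[keep, , drop = FALSE]
  ne <- nrow(idx)
  data.frame(from = idx[, 1], to = idx[, 2],
             rho = if (ne) runif(ne, 0.3, 1) * sample(c(-1, 1), ne, TRUE) else numeric(0),
             p = rep(1e-5, ne), q = rep(1e-5, ne), stringsAsFactors = FALSE)
}

# small default community spec used by several tests
small_spec <- function(seed = 1, ...) {
  community_spec(n_samples_per_group = c(clay_loam = 20, sandy = 20),
                 n_taxa = 80, sequencing_depth = 5000, seed = seed, ...)
}

# fixed-point secondary-extinction simulation, independent implementation
extinction_oracle <- function(adj, s, b, removed) {
  n <- nrow(adj)
  alive <- setdiff(seq_len(n), removed)
  repeat {
    gone <- c()
    for (i in alive) {
      nb <- intersect(which(adj[i, ]), alive)
      if (!length(nb)) { gone <- c(gone, i); next }
      num <- sum(b[nb] * s[i, nb]); den <- sum(b[nb])
      if (den <= 0 || num / den <= 0) gone <- c(gone, i)
    }
    if (!length(gone)) break
    alive <- setdiff(alive, gone)
    if (!length(alive)) break
  }
  length(alive) / n
}
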