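#' Pairwise Spearman correlations with t-approximation p-values
#'
#' Computes the full taxon x taxon Spearman rank correlation matrix (midrank
#' ties) and two-sided p-values from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Correlations of `|rho| = 1` get `p = 0` (below any representable
#' threshold). Zero-variance taxa cannot be ranked meaningfully: their rows
#' and columns are set to `NA` and a message names them.
#'
#' @param ft A feature table with at least 4 samples (filter taxa first; see
#'   [filter_taxa()]).
#' @return List with `rho` and `p` (symmetric matrices) and `n` (sample
#'   count).
#' @export
spearman_matrix <- function(ft) {
  validate_feature_table(ft)
  vals <- ft_values(ft)
  n <- nrow(vals)
  if (n < 4) abort("need at least 4 samples for correlation p-values.")
  sds <- apply(vals, 2, sd)
  rho <- suppressWarnings(cor(vals, method = "spearman"))
  if (any(sds == 0)) {
    inform(paste0("zero-variance taxa excluded from correlations: ",
                  paste(colnames(vals)[sds == 0], collapse = ", ")))
    rho[sds == 0, ] <- NA_real_
    rho[, sds == 0] <- NA_real_
  }
  r2 <- pmin(rho^2, 1)
  tstat <- abs(rho) * sqrt((n - 2) / pmax(1 - r2, 0))
  p <- 2 * pt(tstat, df = n - 2, lower.tail = FALSE)
  p[r2 >= 1] <- 0
  diag(rho) <- 1
  diag(p) <- 0
  list(rho = rho, p = p, n = n)
}

#' Build a signed Spearman co-occurrence network
#'
#' Keeps an edge between two taxa when `|rho| >= rho_min` and the (optionally
#' Benjamini-Hochberg corrected) p-value is below `alpha`. The defaults
#' (`|rho| >= 0.6`, BH-corrected `p < 0.05`) follow common practice in
#' microbiome co-occurrence studies and are fully configurable; they are
#' recorded in the returned object. Isolated nodes are dropped by default.
#' The network also retains the Pearson correlation matrix on relative
#' abundances among its nodes — the association strength used by the
#' robustness statistic — and per-node mean relative abundance.
#'
#' @param ft A feature table (the group's samples only, pre-filtered).
#' @param rho_min Minimum absolute Spearman correlation, in \[0, 1\].
#' @param alpha Significance threshold, in (0, 1\].
#' @param correction `"BH"` or `"none"`.
#' @param corr Optional precomputed result of [spearman_matrix()].
#' @param keep_isolated Keep nodes without any retained edge.
#' @return A `co_network` object: list with `nodes` (tibble: `node_id`,
#'   `abundance`, `degree`, `module`), `edges` (tibble: `from`, `to`, `rho`,
#'   `p`, `q`, `sign`), `pearson` and `spearman` matrices over the nodes,
#'   `n_samples`, `params`, and `modularity` (NA until [detect_modules()]).
#' @export
build_network <- function(ft, rho_min = 0.6, alpha = 0.05,
                          correction = c("BH", "none"), corr = NULL,
                          keep_isolated = FALSE) {
  correction <- match.arg(correction)
  # rho_min above 1 is allowed and simply yields an empty network
  stopifnot(rho_min >= 0, alpha > 0, alpha <= 1)
  validate_feature_table(ft)
  if (is.null(corr)) corr <- spearman_matrix(ft)
  rho <- corr$rho; p <- corr$p
  taxa <- colnames(rho)
  rel <- ft_values(to_relative_abundance(ft))[, taxa, drop = FALSE]
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  pv <- p[ut]
  tested <- !is.na(pv)
  qv <- rep(NA_real_, length(pv))
  qv[tested] <- p.adjust(pv[tested], method = "BH")
  crit <- if (correction == "BH") qv else pv
  rv <- rho[ut]
  keep <- tested & abs(rv) >= rho_min & crit < alpha
  edges <- tibble(
    from = taxa[ut[keep, 1]],
    to = taxa[ut[keep, 2]],
    rho = rv[keep],
    p = pv[keep],
    q = qv[keep],
    sign = ifelse(rv[keep] >= 0, 1L, -1L)
  )
  if (nrow(edges) == 0) warn("no edges pass the thresholds: empty network.")
  ok_taxa <- taxa[!is.na(diag(p)) & !apply(is.na(rho), 2, all)]
  node_ids <- if (keep_isolated) ok_taxa else {
    intersect(taxa, unique(c(edges$from, edges$to)))
  }
  deg <- table(factor(c(edges$from, edges$to), levels = node_ids))
  nodes <- tibble(node_id = node_ids,
                  abundance = colMeans(rel[, node_ids, drop = FALSE]),
                  degree = as.integer(deg[node_ids]),
                  module = NA_integer_)
  pear <- suppressWarnings(cor(rel[, node_ids, drop = FALSE], method = "pearson"))
  pear[is.na(pear)] <- 0
  structure(list(nodes = nodes, edges = edges,
                 pearson = pear,
                 spearman = rho[node_ids, node_ids, drop = FALSE],
                 n_samples = nrow(rel),
                 params = list(rho_min = rho_min, alpha = alpha,
                               correction = correction),
                 modularity = NA_real_),
            class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf("# Co-occurrence network: %d nodes, %d edges (|rho| >= %g, %s p < %g)\n",
              nrow(x$nodes), nrow(x$edges), x$params$rho_min,
              if (x$params$correction == "BH") "BH" else "raw",
              x$params$alpha))
  if (!is.na(x$modularity)) {
    cat(sprintf("# %d modules, modularity Q = %.3f\n",
                length(unique(x$nodes$module)), x$modularity))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.co_network <- function(x, ...) x$edges

#' @exportS3Method generics::glance
glance.co_network <- function(x, ...) topology_report(x)

#' Average node degree
#'
#' `(1/n) * sum(k_i) = 2 l / n` where `l` is the edge count. An empty
#' network has average degree 0.
#'
#' @param net A `co_network`.
#' @return A single number.
#' @export
average_degree <- function(net) {
  stopifnot(inherits(net, "co_network"))
  n <- nrow(net$nodes)
  if (n == 0) return(0)
  2 * nrow(net$edges) / n
}

#' Network density
#'
#' Realized over possible links: `2 l / (n (n - 1))`, in \[0, 1\].
#'
#' @param net A `co_network` with at least 2 nodes.
#' @return A single number.
#' @export
network_density <- function(net) {
  stopifnot(inherits(net, "co_network"))
  n <- nrow(net$nodes)
  if (n < 2) abort("density needs at least 2 nodes.")
  2 * nrow(net$edges) / (n * (n - 1))
}

#' Louvain module detection
#'
#' Community detection on the `|rho|`-weighted graph (Louvain, the algorithm
#' behind the usual interactive network tools), deterministic given the
#' seed. Modularity is
#' `Q = (1/2w) * sum_ij (w_ij - w_i w_j / 2w) * delta(c_i, c_j)`.
#' Isolated nodes each form their own module.
#'
#' @param net A `co_network` with at least one edge.
#' @param resolution Louvain resolution parameter.
#' @param seed Integer seed.
#' @return `net` with `nodes$module` filled in and `modularity` set.
#' @export
detect_modules <- function(net, resolution = 1, seed = 1) {
  stopifnot(inherits(net, "co_network"))
  if (nrow(net$edges) == 0) abort("module detection needs at least one edge.")
  g <- as_igraph(net)
  w <- abs(igraph::E(g)$rho)
  comm <- local_seed(seed, igraph::cluster_louvain(g, weights = w,
                                                   resolution = resolution))
  memb <- igraph::membership(comm)
  net$nodes$module <- as.integer(memb[net$nodes$node_id])
  net$modularity <- igraph::modularity(g, memb, weights = w)
  net
}

#' Identify module hubs
#'
#' Ranks nodes by within-module degree z-score
#' `Z_i = (k_i_within - mean_module) / sd_module`, the standard module-hub
#' criterion in microbial network ecology. Nodes in size-1 modules get
#' `Z = -Inf`; a module whose within-degrees are constant gets `Z = 0`.
#' Ties break by total degree, then node id.
#'
#' @param net A `co_network` with modules detected.
#' @param top_k Number of hubs to return.
#' @return Tibble of the `top_k` hubs: `node_id`, `module`, `z_score`,
#'   `degree`, ordered by rank.
#' @export
identify_module_hubs <- function(net, top_k = 5) {
  stopifnot(inherits(net, "co_network"), top_k >= 0, top_k <= nrow(net$nodes))
  if (all(is.na(net$nodes$module))) abort("run detect_modules() first.")
  nodes <- net$nodes
  mod_of <- setNames(nodes$module, nodes$node_id)
  within_deg <- setNames(numeric(nrow(nodes)), nodes$node_id)
  same <- mod_of[net$edges$from] == mod_of[net$edges$to]
  for (v in c(net$edges$from[same], net$edges$to[same])) {
    within_deg[v] <- within_deg[v] + 1
  }
  z <- numeric(nrow(nodes))
  for (m in unique(nodes$module)) {
    members <- nodes$node_id[nodes$module == m]
    if (length(members) == 1) {
      z[nodes$module == m] <- -Inf
    } else {
      kw <- within_deg[members]
      s <- sd(kw)
      z[nodes$module == m] <- if (s == 0) 0 else (kw - mean(kw)) / s
    }
  }
  ranked <- tibble(node_id = nodes$node_id, module = nodes$module,
                   z_score = z, degree = nodes$degree) |>
    dplyr::arrange(dplyr::desc(.data$z_score), dplyr::desc(.data$degree),
                   .data$node_id)
  head(ranked, top_k)
}

#' Topological summary of a network
#'
#' @param net A `co_network`.
#' @return One-row tibble: node/edge counts, average degree, density,
#'   modularity and module count (NA before [detect_modules()]), and the
#'   positive edge fraction.
#' @export
topology_report <- function(net) {
  stopifnot(inherits(net, "co_network"))
  n <- nrow(net$nodes)
  tibble(n_nodes = n,
         n_edges = nrow(net$edges),
         average_degree = average_degree(net),
         density = if (n >= 2) network_density(net) else NA_real_,
         modularity = net$modularity,
         n_modules = if (all(is.na(net$nodes$module))) NA_integer_ else
           length(unique(net$nodes$module)),
         positive_edge_fraction = if (nrow(net$edges)) mean(net$edges$sign > 0)
           else NA_real_)
}
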