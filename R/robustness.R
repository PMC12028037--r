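# adjacency (logical) over net nodes, in node order
net_adjacency <- function(net) {
  ids <- net$nodes$node_id
  A <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(net$edges)) {
    A[cbind(net$edges$from, net$edges$to)] <- TRUE
    A[cbind(net$edges$to, net$edges$from)] <- TRUE
  }
  A
}

# One removal experiment: seed the removal set, then propagate secondary
# extinctions to a fixed point. A remaining species goes extinct when it has
# no remaining edges or when its abundance-weighted mean association strength
# over remaining neighbours, sum(b_j s_ij) / sum(b_j), is <= 0.
propagate_extinctions <- function(A, s, b, removed_idx) {
  n <- length(b)
  alive <- rep(TRUE, n)
  alive[removed_idx] <- FALSE
  repeat {
    idx <- which(alive)
    if (!length(idx)) break
    Ai <- A[idx, idx, drop = FALSE]
    num <- (Ai * s[idx, idx, drop = FALSE]) %*% b[idx]
    den <- Ai %*% b[idx]
    ext <- den <= 0 | num <= 0
    if (!any(ext)) break
    alive[idx[ext]] <- FALSE
  }
  sum(alive) / n
}

#' Network robustness under node removal
#'
#' Stability index: the proportion of species remaining after a removal
#' protocol and the propagation of secondary extinctions. Protocols:
#' `"random_fraction"` removes `floor(parameter * n)` uniformly random nodes
#' per iteration (Monte Carlo over `n_iterations`); `"targeted_hubs"`
#' deterministically removes the top `parameter` module hubs (one
#' iteration; requires [detect_modules()]). After the primary removal, a
#' remaining species i goes extinct when it has no remaining edges or when
#' its abundance-weighted mean association strength
#' `sum_j b_j s_ij / sum_j b_j` over remaining neighbours j is <= 0, where
#' `b_j` is the mean relative abundance of species j and `s_ij` the Pearson
#' correlation of relative abundances; extinctions are repeated to a fixed
#' point.
#'
#' @param net A nonempty `co_network`.
#' @param protocol `"random_fraction"` or `"targeted_hubs"`.
#' @param parameter Removal fraction in (0, 1) or hub count.
#' @param n_iterations Monte Carlo iterations for the random protocol.
#' @param seed Integer seed.
#' @param abundances Optional named abundance vector overriding the
#'   network's per-node mean relative abundances (used for per-sample
#'   stability).
#' @return A `robustness_result`: list with `protocol`, `parameter`,
#'   `n_iterations`, `seed`, `proportion_remaining` (mean over iterations)
#'   and `per_iteration`.
#' @export
robustness <- function(net, protocol = c("random_fraction", "targeted_hubs"),
                       parameter = 0.5, n_iterations = 999, seed = 1,
                       abundances = NULL) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(net, "co_network"))
  n <- nrow(net$nodes)
  if (n == 0) abort("robustness of an empty network is undefined.")
  A <- net_adjacency(net)
  s <- net$pearson
  b <- net$nodes$abundance
  if (!is.null(abundances)) {
    miss <- setdiff(net$nodes$node_id, names(abundances))
    if (length(miss)) abort("`abundances` must cover every network node.")
    b <- as.numeric(abundances[net$nodes$node_id])
  }
  if (protocol == "random_fraction") {
    stopifnot(parameter > 0, parameter < 1)
    n_remove <- floor(parameter * n)
    if (n_remove < 1) abort("removal fraction too small: no node would be removed.")
    per_iter <- local_seed(seed, vapply(seq_len(n_iterations), function(it) {
      propagate_extinctions(A, s, b, sample.int(n, n_remove))
    }, numeric(1)))
  } else {
    stopifnot(parameter >= 1, parameter <= n)
    if (all(is.na(net$nodes$module))) {
      abort("targeted_hubs protocol requires detect_modules() first.")
    }
    hubs <- identify_module_hubs(net, top_k = as.integer(parameter))
    per_iter <- propagate_extinctions(A, s, b,
                                      match(hubs$node_id, net$nodes$node_id))
    n_iterations <- 1L
  }
  structure(list(protocol = protocol, parameter = parameter,
                 n_iterations = n_iterations, seed = seed,
                 proportion_remaining = mean(per_iter),
                 per_iteration = per_iter),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("# Robustness (%s, parameter = %g): %.4f remaining (%d iteration%s)\n",
              x$protocol, x$parameter, x$proportion_remaining,
              x$n_iterations, if (x$n_iterations > 1) "s" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.robustness_result <- function(x, ...) {
  tibble(iteration = seq_along(x$per_iteration),
         proportion_remaining = x$per_iteration)
}

#' @exportS3Method generics::glance
glance.robustness_result <- function(x, ...) {
  tibble(protocol = x$protocol, parameter = x$parameter,
         n_iterations = x$n_iterations, seed = x$seed,
         proportion_remaining = x$proportion_remaining)
}

# induced subnetwork on a subset of node ids
induce_subnetwork <- function(net, node_ids) {
  keep <- net$nodes$node_id %in% node_ids
  ids <- net$nodes$node_id[keep]
  edges <- dplyr::filter(net$edges, .data$from %in% ids, .data$to %in% ids)
  nodes <- net$nodes[keep, , drop = FALSE]
  deg <- table(factor(c(edges$from, edges$to), levels = ids))
  nodes$degree <- as.integer(deg[nodes$node_id])
  structure(list(nodes = nodes, edges = edges,
                 pearson = net$pearson[ids, ids, drop = FALSE],
                 spearman = net$spearman[ids, ids, drop = FALSE],
                 n_samples = net$n_samples, params = net$params,
                 modularity = NA_real_),
            class = "co_network")
}

#' Per-sample stability score
#'
#' The study-level robustness statistic describes one network per group; a
#' per-sample stability is needed to correlate stability with per-sample
#' environmental variables and to enter path models. Here it is defined
#' explicitly as the robustness of the subnetwork induced by the taxa
#' present (abundance > 0) in the sample, with the extinction rule weighted
#' by that sample's own relative abundances. Each sample uses a seed derived
#' deterministically from `seed` and its position.
#'
#' @param ft Feature table in relative mode (the same samples the network
#'   was built from, or any samples over its taxa).
#' @param net A `co_network`.
#' @param parameter Removal fraction in (0, 1).
#' @param n_iterations Monte Carlo iterations per sample.
#' @param seed Integer base seed.
#' @return Tibble: `sample_id`, `stability` (NA for samples whose present
#'   taxa include no network node).
#' @export
sample_stability <- function(ft, net, parameter = 0.5, n_iterations = 100,
                             seed = 1) {
  validate_feature_table(ft)
  if (!identical(abundance_mode(ft), "relative")) {
    abort("per-sample stability uses relative abundances; run to_relative_abundance() first.")
  }
  vals <- ft_values(ft)
  res <- vapply(seq_len(nrow(vals)), function(i) {
    present <- colnames(vals)[vals[i, ] > 0]
    ids <- intersect(net$nodes$node_id, present)
    if (length(ids) < 2) return(NA_real_)
    sub <- induce_subnetwork(net, ids)
    if (floor(parameter * length(ids)) < 1) return(1)
    b <- vals[i, ids]
    r <- robustness(sub, protocol = "random_fraction", parameter = parameter,
                    n_iterations = n_iterations,
                    seed = (seed + 7919L * i) %% .Machine$integer.max,
                    abundances = b)
    r$proportion_remaining
  }, numeric(1))
  tibble(sample_id = rownames(vals), stability = res)
}

#' Robustness across a sweep of removal fractions
#'
#' Convenience utility mapping [robustness()] over several removal
#' fractions (attack-tolerance curve).
#'
#' @param net A `co_network`.
#' @param fractions Removal fractions in (0, 1).
#' @param n_iterations Iterations per fraction.
#' @param seed Integer seed.
#' @return Tibble: `fraction`, `proportion_remaining`.
#' @export
robustness_sweep <- function(net, fractions = seq(0.1, 0.9, by = 0.1),
                             n_iterations = 200, seed = 1) {
  tibble(fraction = fractions,
         proportion_remaining = vapply(fractions, function(f) {
           robustness(net, "random_fraction", f, n_iterations,
                      seed = seed)$proportion_remaining
         }, numeric(1)))
}
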