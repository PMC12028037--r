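#' Shannon diversity of one abundance vector
#'
#' `H = -sum(p_i * log(p_i))` over the positive entries of the normalized
#' vector. Natural log by default, matching common ecological convention;
#' a `base` argument is provided (e.g. 2 for bits).
#'
#' @param x Nonnegative abundance vector with positive sum.
#' @param base Logarithm base.
#' @return Shannon index in `[0, log(length(x), base)]`.
#' @examples
#' shannon_index(c(1, 1, 1, 1)) # log(4)
#' @export
shannon_index <- function(x, base = exp(1)) {
  if (any(x < 0) || anyNA(x)) abort("abundances must be nonnegative and complete.")
  s <- sum(x)
  if (s <= 0) abort("cannot compute Shannon index of an all-zero vector.")
  p <- x[x > 0] / s
  -sum(p * log(p, base = base))
}

#' Per-sample alpha diversity
#'
#' @param ft A feature table.
#' @param base Logarithm base for the Shannon index.
#' @return A tibble with columns `sample_id`, `shannon`.
#' @export
alpha_diversity <- function(ft, base = exp(1)) {
  validate_feature_table(ft)
  vals <- ft_values(ft)
  tibble(sample_id = rownames(vals),
         shannon = apply(vals, 1, shannon_index, base = base))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)`, computed on the table's
#' stored values (normalize first with [to_relative_abundance()] to compare
#' compositions rather than loads).
#'
#' @param ft A feature table.
#' @return A `dist` object labelled by sample id, values in \[0, 1\].
#' @export
bray_curtis <- function(ft) {
  validate_feature_table(ft)
  vals <- ft_values(ft)
  if (any(rowSums(vals) <= 0)) {
    abort("Bray-Curtis is undefined for all-zero samples.")
  }
  vegan::vegdist(vals, method = "bray")
}

# Accept dist or symmetric matrix; return a checked `dist`.
as_dist_checked <- function(d, what = "distance matrix") {
  if (inherits(d, "dist")) return(d)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12) {
    abort(sprintf("%s must be symmetric.", what))
  }
  if (any(diag(d) != 0)) abort(sprintf("%s must have a zero diagonal.", what))
  if (any(d < 0)) abort(sprintf("%s must be nonnegative.", what))
  as.dist(d)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: Gower double-centering of `-d^2 / 2`, symmetric
#' eigendecomposition, and coordinates `eigenvector * sqrt(eigenvalue)` for
#' the positive eigenvalues. Percent explained is reported relative to the
#' sum of the positive eigenvalues; negative eigenvalues (possible for
#' non-Euclidean dissimilarities such as Bray-Curtis) are dropped without
#' correction by default, with a Lingoes additive correction behind a flag.
#'
#' @param d A `dist` or symmetric distance matrix.
#' @param k Number of axes to return (truncated with a warning if fewer
#'   positive eigenvalues exist).
#' @param correction `"none"` or `"lingoes"`.
#' @return A `pcoa_ordination` object: list with `coordinates` (tibble,
#'   `sample_id` + `PCo1..PCok`), `eigenvalues`, and `pct_explained`.
#' @export
pcoa_ordination <- function(d, k = 2, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  d <- as_dist_checked(d)
  n <- attr(d, "Size")
  if (k > n - 1) abort("k must be at most n - 1.")
  if (correction == "lingoes") {
    ev <- cmdscale(d, k = 1, eig = TRUE)$eig
    c_add <- max(0, -min(ev))
    if (c_add > 0) {
      m <- as.matrix(d)
      m[m > 0] <- sqrt(m[m > 0]^2 + 2 * c_add)
      d <- as.dist(m)
    }
  }
  fit <- suppressWarnings(cmdscale(d, k = min(k, n - 1), eig = TRUE))
  eig <- fit$eig
  tol <- max(abs(eig)) * 1e-8
  npos <- sum(eig > tol)
  if (k > npos) {
    warn(sprintf("only %d positive eigenvalues; returning %d axes.", npos, npos))
    k <- npos
  }
  pts <- fit$points[, seq_len(k), drop = FALSE]
  ids <- attr(d, "Labels") %||% paste0("s", seq_len(n))
  coords <- tibble::as_tibble(as.data.frame(pts), .name_repair = "minimal")
  names(coords) <- paste0("PCo", seq_len(k))
  pct <- 100 * eig[seq_len(npos)] / sum(eig[seq_len(npos)])
  structure(list(coordinates = dplyr::bind_cols(tibble(sample_id = ids), coords),
                 eigenvalues = eig[seq_len(npos)],
                 pct_explained = pct),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat(sprintf("# PCoA: %d samples, %d axes kept\n",
              nrow(x$coordinates), ncol(x$coordinates) - 1L))
  cat("pct explained:", paste0(sprintf("%.2f", head(x$pct_explained, 5)), "%",
                               collapse = ", "), "\n")
  invisible(x)
}

# all permutations of 1..n as a list (n <= 8 guarded by callers)
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 1L
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[k]] <- append(p, n, after = pos - 1L)
      k <- k + 1L
    }
  }
  out
}

#' Analysis of similarity (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group ones. All pairwise distances are midranked;
#' `R = (mean between-rank - mean within-rank) / (N(N-1)/4)`, in \[-1, 1\].
#' The p-value uses the one-sided (large R) add-one permutation estimator
#' `p = (1 + #\{R_perm >= R_obs\}) / (1 + n_perm)`. With
#' `exhaustive = TRUE` all label permutations are enumerated instead and the
#' p-value is the exact proportion (identity included).
#'
#' @param d A `dist` or symmetric distance matrix.
#' @param groups Group label per sample; at least two groups, each with at
#'   least two members.
#' @param n_perm Number of random permutations.
#' @param seed Integer seed for the permutations.
#' @param exhaustive Enumerate all permutations (only sensible for n <= 8).
#' @return One-row tibble: `statistic`, `p_value`, `n_perm`, `seed`.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = 1, exhaustive = FALSE) {
  d <- as_dist_checked(d)
  n <- attr(d, "Size")
  groups <- as.character(groups)
  stopifnot(length(groups) == n, n_perm >= 1)
  if (length(unique(groups)) < 2) abort("need at least two groups.")
  if (any(table(groups) < 2)) abort("every group needs at least two members.")
  rk <- rank(as.numeric(d)) # midranks
  denom <- n * (n - 1) / 4
  # column-major lower-triangle indices match the dist vector ordering
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  pair_i <- idx[, 1]; pair_j <- idx[, 2]
  r_stat <- function(g) {
    within <- g[pair_i] == g[pair_j]
    (mean(rk[!within]) - mean(rk[within])) / denom
  }
  obs <- r_stat(groups)
  if (exhaustive) {
    if (n > 8) abort("exhaustive enumeration is limited to n <= 8.")
    perms <- all_permutations(n)
    stats <- vapply(perms, function(p) r_stat(groups[p]), numeric(1))
    p_val <- mean(stats >= obs - 1e-12)
    n_used <- length(perms)
  } else {
    stats <- local_seed(seed, vapply(seq_len(n_perm), function(b) {
      r_stat(groups[sample.int(n)])
    }, numeric(1)))
    p_val <- (1 + sum(stats >= obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  tibble(statistic = obs, p_value = p_val, n_perm = n_used, seed = seed)
}

#' Mantel test between two distance matrices
#'
#' Correlates the upper-triangle entries of two distance matrices and
#' assesses significance by jointly permuting the rows and columns of the
#' second matrix. Two-sided by default (`p = (1 + #\{|r_perm| >= |r_obs|\}) /
#' (1 + n_perm)`); a one-sided (positive association) alternative is
#' available. `exhaustive = TRUE` enumerates every permutation.
#'
#' @param d1,d2 `dist` objects or symmetric matrices over the same samples
#'   (ids must match when labelled).
#' @param method Correlation method for the triangles.
#' @param n_perm Number of random permutations.
#' @param seed Integer seed.
#' @param alternative `"two.sided"` or `"greater"`.
#' @param exhaustive Enumerate all permutations (n <= 8).
#' @return One-row tibble: `statistic`, `p_value`, `n_perm`, `seed`.
#' @export
mantel_test <- function(d1, d2, method = c("pearson", "spearman"),
                        n_perm = 999, seed = 1,
                        alternative = c("two.sided", "greater"),
                        exhaustive = FALSE) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  d1 <- as_dist_checked(d1); d2 <- as_dist_checked(d2)
  n <- attr(d1, "Size")
  if (attr(d2, "Size") != n) abort("distance matrices must have the same size.")
  l1 <- attr(d1, "Labels"); l2 <- attr(d2, "Labels")
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2)) {
    abort("distance matrix ids do not match.")
  }
  if (n < 4) abort("Mantel test needs at least 4 samples.")
  m2 <- as.matrix(d2)
  v1 <- as.numeric(d1)
  if (sd(v1) == 0 || sd(as.numeric(d2)) == 0) {
    abort("zero-variance distance matrix: Mantel correlation undefined.")
  }
  ut <- upper.tri(m2)
  r_for <- function(perm) cor(v1, as.numeric(as.dist(m2[perm, perm])), method = method)
  obs <- cor(v1, as.numeric(d2), method = method)
  cmp <- function(r) {
    if (alternative == "two.sided") abs(r) >= abs(obs) - 1e-12 else r >= obs - 1e-12
  }
  if (exhaustive) {
    if (n > 8) abort("exhaustive enumeration is limited to n <= 8.")
    perms <- all_permutations(n)
    stats <- vapply(perms, r_for, numeric(1))
    p_val <- mean(cmp(stats))
    n_used <- length(perms)
  } else {
    stats <- local_seed(seed, vapply(seq_len(n_perm), function(b) {
      r_for(sample.int(n))
    }, numeric(1)))
    p_val <- (1 + sum(cmp(stats))) / (1 + n_perm)
    n_used <- n_perm
  }
  tibble(statistic = obs, p_value = p_val, n_perm = n_used, seed = seed)
}

#' Pairwise geodesic distances between samples
#'
#' Distances on the WGS84 ellipsoid (geodesic inverse problem, via
#' `geosphere::distGeo`), in meters.
#'
#' @param meta Sample metadata with `sample_id`, `latitude`, `longitude`.
#' @return A `dist` object in meters, labelled by sample id.
#' @export
geodesic_distances <- function(meta) {
  meta <- validate_sample_metadata(meta)
  if (anyNA(meta$latitude) || anyNA(meta$longitude)) {
    abort("metadata has missing coordinates.")
  }
  pts <- cbind(meta$longitude, meta$latitude)
  m <- geosphere::distm(pts, fun = geosphere::distGeo)
  dimnames(m) <- list(meta$sample_id, meta$sample_id)
  m[abs(m) < 1e-9] <- 0
  diag(m) <- 0
  as.dist(m)
}
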