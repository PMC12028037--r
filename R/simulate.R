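# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Specify a synthetic two-group community
#'
#' Builds the specification object consumed by [generate_community()]. The
#' defaults emulate the structure of a mangrove-soil fungal survey: two soil
#' types (clay loam sampled at one site, sandy soil at two sites, 25 samples
#' per site), group-specific dominant taxon classes (a Dothideomycetes-
#' dominated clay loam versus a more even, Sordariomycetes/Eurotiomycetes-led
#' sandy community, which also gives the sandy group the higher Shannon
#' diversity), and correlation blocks that give the clay-loam group a strong
#' cooperative (positively correlated) guild and the sandy group weaker mixed
#' associations — so the clay-loam group has the more cohesive, more robust
#' network.
#'
#' @param n_samples_per_group Named integer vector of samples per group (a
#'   scalar is recycled).
#' @param n_taxa Total number of taxa.
#' @param group_labels Character vector of group (soil type) labels.
#' @param sites_per_group Named list mapping each group to its site labels;
#'   samples are split evenly across a group's sites.
#' @param taxon_classes Character vector of class labels taxa are assigned to
#'   (round-robin).
#' @param dominance_profile Named list: per group, a named numeric vector of
#'   class weights (summing to 1) concentrating abundance on that group's
#'   dominant classes.
#' @param correlation_blocks List of blocks, each a list with elements
#'   `taxa` (integer indices), `rho` (target pairwise Spearman correlation in
#'   \[0, 1)), `sign` (`"positive"` or `"negative"`; negative blocks split
#'   into two anti-correlated halves), optional `group` (block active only in
#'   that group; `NULL` = all groups) and optional `weight_boost`
#'   (multiplier on the block taxa's base abundance, default 3).
#' @param sequencing_depth Expected library size per sample.
#' @param dispersion Negative-binomial dispersion phi (variance =
#'   mu + phi * mu^2); must be > 0.
#' @param count_model `"nb"` (negative binomial through a Gaussian copula,
#'   the default) or `"multinomial"` (fixed depth; block correlation injected
#'   on the log-probability scale, approximate).
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A `community_spec` object (a validated list).
#' @export
community_spec <- function(n_samples_per_group = c(clay_loam = 25, sandy = 50),
                           n_taxa = 120,
                           group_labels = c("clay_loam", "sandy"),
                           sites_per_group = list(clay_loam = "LZ",
                                                  sandy = c("SK", "ZZ")),
                           taxon_classes = c("Dothideomycetes", "Sordariomycetes",
                                             "Eurotiomycetes", "Tremellomycetes",
                                             "Saccharomycetes", "Agaricomycetes",
                                             "other"),
                           dominance_profile = list(
                             clay_loam = c(Dothideomycetes = 0.64,
                                           Sordariomycetes = 0.19,
                                           Eurotiomycetes = 0.08,
                                           Tremellomycetes = 0.03,
                                           Saccharomycetes = 0.02,
                                           Agaricomycetes = 0.02,
                                           other = 0.02),
                             sandy = c(Dothideomycetes = 0.07,
                                       Sordariomycetes = 0.25,
                                       Eurotiomycetes = 0.23,
                                       Tremellomycetes = 0.15,
                                       Saccharomycetes = 0.10,
                                       Agaricomycetes = 0.10,
                                       other = 0.10)),
                           correlation_blocks = list(
                             list(taxa = 1:15, rho = 0.75, sign = "positive",
                                  group = "clay_loam", weight_boost = 3),
                             list(taxa = 16:25, rho = 0.60, sign = "positive",
                                  group = "sandy", weight_boost = 2),
                             list(taxa = 26:33, rho = 0.55, sign = "negative",
                                  group = "sandy", weight_boost = 2)),
                           sequencing_depth = 20000,
                           dispersion = 0.5,
                           count_model = c("nb", "multinomial"),
                           seed = 1) {
  count_model <- match.arg(count_model)
  if (length(n_samples_per_group) == 1L) {
    n_samples_per_group <- setNames(rep(n_samples_per_group, length(group_labels)),
                                    group_labels)
  }
  if (is.null(names(n_samples_per_group))) {
    names(n_samples_per_group) <- group_labels
  }
  stopifnot(all(group_labels %in% names(n_samples_per_group)),
            all(group_labels %in% names(sites_per_group)),
            all(group_labels %in% names(dominance_profile)),
            n_taxa >= 1, sequencing_depth >= 1, dispersion > 0)
  for (g in group_labels) {
    w <- dominance_profile[[g]]
    if (abs(sum(w) - 1) > 1e-8) abort(sprintf("dominance profile for '%s' must sum to 1.", g))
    if (!all(names(w) %in% taxon_classes)) abort("dominance profile names must be taxon classes.")
  }
  all_block_taxa <- integer(0)
  for (b in correlation_blocks) {
    stopifnot(is.numeric(b$taxa), length(b$taxa) >= 2)
    if (!is.numeric(b$rho) || abs(b$rho) >= 1 || b$rho < 0) {
      abort("block target rho must lie in [0, 1); use sign = \"negative\" for negative blocks.")
    }
    if (!b$sign %in% c("positive", "negative")) abort("block sign must be 'positive' or 'negative'.")
    if (!is.null(b$group) && !b$group %in% group_labels) abort("block group must be a group label.")
    all_block_taxa <- c(all_block_taxa, b$taxa)
  }
  if (anyDuplicated(all_block_taxa)) abort("correlation blocks must be disjoint.")
  if (length(all_block_taxa) > n_taxa) abort("n_taxa must cover all block taxa.")
  if (length(all_block_taxa) && max(all_block_taxa) > n_taxa) abort("block taxon index exceeds n_taxa.")
  structure(list(n_samples_per_group = n_samples_per_group, n_taxa = n_taxa,
                 group_labels = group_labels, sites_per_group = sites_per_group,
                 taxon_classes = taxon_classes, dominance_profile = dominance_profile,
                 correlation_blocks = correlation_blocks,
                 sequencing_depth = sequencing_depth, dispersion = dispersion,
                 count_model = count_model, seed = seed),
            class = "community_spec")
}

#' Generate a synthetic community with known ground truth
#'
#' Draws a samples x taxa count table plus matching sample metadata.
#' Mechanism: (1) per-group base relative abundances are class weights from
#' the dominance profile divided among class members and jittered by
#' log-normal taxon effects, with block taxa boosted so the correlated guilds
#' are abundant enough to drive cohesion; (2) a Gaussian copula injects the
#' requested pairwise Spearman correlation within each active block (latent
#' equicorrelated factors, sign-split for negative blocks), leaving marginals
#' intact; (3) counts are drawn as negative binomial at the sequencing depth
#' via quantile transform of the copula uniforms (or multinomial behind the
#' flag). Deterministic given `spec$seed`.
#'
#' @param spec A [community_spec()].
#' @return A list with elements `feature_table` (counts mode) and `metadata`
#'   (tibble with `sample_id`, `site`, `soil_type`, placeholder coordinates).
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  local_seed(spec$seed, {
    classes <- rep(spec$taxon_classes, length.out = spec$n_taxa)
    taxon_ids <- sprintf("t%03d", seq_len(spec$n_taxa))
    rows <- list()
    meta <- list()
    for (g in spec$group_labels) {
      n_s <- spec$n_samples_per_group[[g]]
      # base relative abundances for this group
      w_class <- spec$dominance_profile[[g]]
      base <- w_class[classes] / as.numeric(table(classes)[classes])
      base <- base * rlnorm(spec$n_taxa, 0, 1)
      for (b in spec$correlation_blocks) {
        if (is.null(b$group) || identical(b$group, g)) {
          base[b$taxa] <- base[b$taxa] * (b$weight_boost %||% 3)
        }
      }
      pi_g <- base / sum(base)
      # latent Gaussian matrix: correlated within active blocks, independent elsewhere
      z <- matrix(rnorm(n_s * spec$n_taxa), n_s, spec$n_taxa)
      for (b in spec$correlation_blocks) {
        if (!is.null(b$group) && !identical(b$group, g)) next
        r <- 2 * sin(pi * b$rho / 6) # Pearson latent corr giving Spearman rho
        f <- rnorm(n_s)
        sgn <- rep(1, length(b$taxa))
        if (identical(b$sign, "negative")) {
          sgn[seq_len(floor(length(b$taxa) / 2))] <- -1
        }
        eps <- matrix(rnorm(n_s * length(b$taxa)), n_s)
        zb <- sqrt(1 - r) * eps + sqrt(r) * f # f recycles down columns
        z[, b$taxa] <- sweep(zb, 2, sgn, `*`)
      }
      mu <- spec$sequencing_depth * pi_g
      if (spec$count_model == "nb") {
        size <- 1 / spec$dispersion
        u <- pnorm(z)
        counts <- vapply(seq_len(spec$n_taxa), function(t) {
          qnbinom(u[, t], size = size, mu = mu[t])
        }, numeric(n_s))
        counts <- matrix(counts, n_s, spec$n_taxa)
      } else {
        counts <- t(vapply(seq_len(n_s), function(s) {
          pr <- pi_g * exp(z[s, ])
          as.numeric(stats::rmultinom(1, spec$sequencing_depth, pr / sum(pr)))
        }, numeric(spec$n_taxa)))
      }
      sites <- rep(spec$sites_per_group[[g]], length.out = n_s)
      sites <- sort(sites)
      ids <- paste0(sites, "_", stats::ave(seq_len(n_s), sites, FUN = seq_along))
      rownames(counts) <- ids
      rows[[g]] <- counts
      meta[[g]] <- tibble(sample_id = ids, site = sites, soil_type = g,
                          latitude = NA_real_, longitude = NA_real_)
    }
    m <- do.call(rbind, rows)
    colnames(m) <- taxon_ids
    ft <- feature_table(m, mode = "counts")
    attr(ft, "taxon_class") <- setNames(classes, taxon_ids)
    list(feature_table = validate_feature_table(ft),
         metadata = dplyr::bind_rows(meta))
  })
}

#' Specify ground truth for a latent path model
#'
#' Defines the data-generating causal structure used by [generate_env()]:
#' an ordered set of latent variables connected by a strictly
#' lower-triangular path coefficient matrix (a DAG), each measured by one or
#' more manifest variables through loadings.
#'
#' @param latent_names Character vector, in causal (topological) order.
#' @param path_matrix Square numeric matrix, `path_matrix[i, j]` = effect of
#'   latent `j` on latent `i`; must be strictly lower triangular.
#' @param loadings Named list (or scalar) of per-latent loading values in
#'   (0, 1\]; recycled over a latent's manifests.
#' @param noise_sd Standard deviation of manifest measurement noise.
#' @return A `path_truth` object.
#' @export
path_truth <- function(latent_names, path_matrix, loadings = 0.8, noise_sd = 0.6) {
  L <- length(latent_names)
  path_matrix <- as.matrix(path_matrix)
  stopifnot(nrow(path_matrix) == L, ncol(path_matrix) == L, noise_sd >= 0)
  if (any(path_matrix[upper.tri(path_matrix, diag = TRUE)] != 0)) {
    abort("path_matrix must be strictly lower triangular (latents in causal order; cycles are not representable).")
  }
  if (!is.list(loadings)) {
    loadings <- setNames(rep(list(loadings), L), latent_names)
  }
  if (any(vapply(loadings, function(l) any(abs(l) > 1 | l <= 0), logical(1)))) {
    abort("loadings must lie in (0, 1].")
  }
  dimnames(path_matrix) <- list(latent_names, latent_names)
  structure(list(latent_names = latent_names, path_matrix = path_matrix,
                 loadings = loadings, noise_sd = noise_sd),
            class = "path_truth")
}

#' Generate environmental variables from a latent path model
#'
#' Latent scores are generated recursively along the DAG: exogenous latents
#' are standard normal; each endogenous latent is the path-weighted sum of
#' its parents plus Gaussian noise scaled so every latent has unit population
#' variance (so a single path coefficient is also the latent correlation).
#' Manifests are `loading * latent + N(0, noise_sd)`. The hidden latent
#' scores are returned alongside the observed matrix so estimation methods
#' can be tested for parameter recovery.
#'
#' @param meta Sample metadata (supplies `sample_id` and sample count).
#' @param truth A [path_truth()].
#' @param manifest_map Named list mapping each latent to the names of its
#'   manifest variables (at least one per latent).
#' @param seed Integer seed.
#' @return A list with `env` (tibble: `sample_id` + manifests) and
#'   `latent_scores` (tibble: `sample_id` + latent scores).
#' @export
generate_env <- function(meta, truth, manifest_map, seed = 1) {
  stopifnot(inherits(truth, "path_truth"))
  L <- length(truth$latent_names)
  miss <- setdiff(truth$latent_names, names(manifest_map))
  if (length(miss) || any(lengths(manifest_map[truth$latent_names]) < 1)) {
    abort("manifest_map must assign at least one manifest to every latent.")
  }
  n <- nrow(meta)
  local_seed(seed, {
    B <- truth$path_matrix
    scores <- matrix(0, n, L, dimnames = list(NULL, truth$latent_names))
    Sigma <- diag(L) # population latent covariance, built recursively
    for (i in seq_len(L)) {
      beta <- B[i, seq_len(i - 1), drop = TRUE]
      if (i == 1 || all(beta == 0)) {
        scores[, i] <- rnorm(n)
      } else {
        idx <- seq_len(i - 1)
        var_pred <- as.numeric(t(beta) %*% Sigma[idx, idx] %*% beta)
        if (var_pred >= 1) {
          abort(sprintf("path coefficients into '%s' imply variance >= 1.",
                        truth$latent_names[i]))
        }
        scores[, i] <- scores[, idx, drop = FALSE] %*% beta +
          rnorm(n, 0, sqrt(1 - var_pred))
        Sigma[i, idx] <- Sigma[idx, idx] %*% beta
        Sigma[idx, i] <- Sigma[i, idx]
      }
    }
    env <- list(sample_id = as.character(meta$sample_id))
    for (i in seq_len(L)) {
      lat <- truth$latent_names[i]
      mans <- manifest_map[[lat]]
      lam <- rep(truth$loadings[[lat]], length.out = length(mans))
      for (k in seq_along(mans)) {
        env[[mans[k]]] <- lam[k] * scores[, i] + rnorm(n, 0, truth$noise_sd)
      }
    }
    list(env = tibble::as_tibble(env),
         latent_scores = tibble::as_tibble(cbind(
           tibble(sample_id = as.character(meta$sample_id)),
           as.data.frame(scores))))
  })
}

#' Assign jittered site coordinates to samples
#'
#' Places each sample at its site center plus a uniform displacement of at
#' most `jitter_m` meters (uniform over a disc), emulating plot-scale
#' scatter around a handful of survey sites.
#'
#' @param meta Sample metadata with a `site` column.
#' @param site_centers Named list mapping each site to `c(latitude, longitude)`
#'   in decimal degrees. Defaults place three mangrove sites on the southern
#'   China coast.
#' @param jitter_m Maximum displacement in meters.
#' @param seed Integer seed.
#' @return `meta` with `latitude` and `longitude` filled in.
#' @export
generate_coordinates <- function(meta,
                                 site_centers = list(LZ = c(20.56, 110.04),
                                                     SK = c(21.48, 109.72),
                                                     ZZ = c(21.60, 108.23)),
                                 jitter_m = 100, seed = 1) {
  unknown <- setdiff(unique(meta$site), names(site_centers))
  if (length(unknown)) {
    abort(paste0("no site center for site(s): ", paste(unknown, collapse = ", "), "."))
  }
  n <- nrow(meta)
  local_seed(seed, {
    r <- jitter_m * sqrt(runif(n))
    theta <- runif(n, 0, 2 * pi)
    lat0 <- vapply(meta$site, function(s) site_centers[[s]][1], numeric(1))
    lon0 <- vapply(meta$site, function(s) site_centers[[s]][2], numeric(1))
    meta$latitude <- lat0 + (r * cos(theta)) / 111320
    meta$longitude <- lon0 + (r * sin(theta)) / (111320 * cos(lat0 * pi / 180))
    validate_sample_metadata(meta)
  })
}
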