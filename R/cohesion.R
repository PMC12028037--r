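#' Per-taxon connectedness
#'
#' For each taxon, the mean of its retained positive pairwise correlations
#' (positive connectedness, >= 0) and the mean of its retained negative
#' correlations (negative connectedness, <= 0); 0 where none are retained.
#' "Retained" follows `corr_source`: the edges of the significance-filtered
#' co-occurrence network (default), or every correlation passing the
#' significance test regardless of the `|rho|` edge threshold. An optional
#' taxon-shuffle null-model correction (off by default) subtracts the mean
#' correlation observed after permuting each taxon's abundances across
#' samples, removing the background correlation expected from abundance
#' structure alone.
#'
#' @param ft A feature table (>= 4 samples).
#' @param net Optional prebuilt `co_network`; built with the given
#'   thresholds when `NULL`.
#' @param corr_source `"network_edges"` or `"all_significant"`.
#' @param rho_min,alpha,correction Thresholds passed to [build_network()] /
#'   the significance filter when `net` is `NULL`.
#' @param null_model Apply the taxon-shuffle null correction.
#' @param n_null Number of shuffles for the null correction.
#' @param seed Seed for the null correction.
#' @return Tibble with `taxon_id`, `positive`, `negative` for every taxon in
#'   `ft`.
#' @export
connectedness <- function(ft, net = NULL,
                          corr_source = c("network_edges", "all_significant"),
                          rho_min = 0.6, alpha = 0.05,
                          correction = c("BH", "none"),
                          null_model = FALSE, n_null = 100, seed = 1) {
  corr_source <- match.arg(corr_source)
  correction <- match.arg(correction)
  validate_feature_table(ft)
  taxa <- ft_taxa(ft)
  out <- tibble(taxon_id = taxa, positive = 0, negative = 0)
  if (length(taxa) < 2) return(out)
  corr <- spearman_matrix(ft)
  null_shift <- NULL
  if (null_model) {
    vals <- ft_values(ft)
    null_shift <- local_seed(seed, {
      acc <- matrix(0, ncol(vals), ncol(vals))
      for (b in seq_len(n_null)) {
        shuf <- apply(vals, 2, sample)
        acc <- acc + suppressWarnings(cor(shuf, method = "spearman"))
      }
      acc / n_null
    })
    null_shift[is.na(null_shift)] <- 0
  }
  if (corr_source == "network_edges") {
    if (is.null(net)) {
      net <- build_network(ft, rho_min = rho_min, alpha = alpha,
                           correction = correction)
    }
    rho_mat <- matrix(NA_real_, length(taxa), length(taxa),
                      dimnames = list(taxa, taxa))
    if (nrow(net$edges)) {
      e <- net$edges
      rr <- e$rho
      if (!is.null(null_shift)) {
        rr <- rr - null_shift[cbind(match(e$from, taxa), match(e$to, taxa))]
      }
      rho_mat[cbind(e$from, e$to)] <- rr
      rho_mat[cbind(e$to, e$from)] <- rr
    }
  } else {
    rho_mat <- corr$rho
    p <- corr$p
    ut <- upper.tri(p)
    crit <- p
    if (correction == "BH") {
      qv <- rep(NA_real_, sum(ut))
      ok <- !is.na(p[ut])
      qv[ok] <- p.adjust(p[ut][ok], method = "BH")
      crit[ut] <- qv
      crit[lower.tri(crit)] <- t(crit)[lower.tri(crit)]
    }
    rho_mat[is.na(crit) | crit >= alpha] <- NA_real_
    if (!is.null(null_shift)) rho_mat <- rho_mat - null_shift
    diag(rho_mat) <- NA_real_
  }
  pos <- apply(rho_mat, 1, function(r) {
    r <- r[!is.na(r) & r > 0]
    if (length(r)) mean(r) else 0
  })
  neg <- apply(rho_mat, 1, function(r) {
    r <- r[!is.na(r) & r < 0]
    if (length(r)) mean(r) else 0
  })
  out$positive <- as.numeric(pos[taxa])
  out$negative <- as.numeric(neg[taxa])
  out$positive[is.na(out$positive)] <- 0
  out$negative[is.na(out$negative)] <- 0
  out
}

#' Per-sample cohesion
#'
#' Community complexity index: for each sample,
#' `cohesion = sum_i abundance_i * connectedness_i` over all taxa, computed
#' separately for positive and negative connectedness. Positive cohesion
#' tracks the extent of cooperative (positively correlated) structure a
#' sample's abundant taxa participate in; negative cohesion (<= 0) tracks
#' competitive structure; total cohesion is their combined magnitude,
#' `positive + |negative|`.
#'
#' @param ft A feature table in relative mode (see
#'   [to_relative_abundance()]).
#' @param conn Connectedness table from [connectedness()], computed on the
#'   same taxa.
#' @return Tibble: `sample_id`, `positive_cohesion`, `negative_cohesion`,
#'   `total_cohesion`.
#' @export
cohesion <- function(ft, conn) {
  validate_feature_table(ft)
  if (!identical(abundance_mode(ft), "relative")) {
    abort("cohesion is defined on relative abundances; run to_relative_abundance() first.")
  }
  taxa <- ft_taxa(ft)
  if (!setequal(taxa, conn$taxon_id)) {
    abort("taxa in `conn` do not match the feature table.")
  }
  vals <- ft_values(ft)[, conn$taxon_id, drop = FALSE]
  pos <- as.numeric(vals %*% conn$positive)
  neg <- as.numeric(vals %*% conn$negative)
  tibble(sample_id = rownames(vals),
         positive_cohesion = pos,
         negative_cohesion = neg,
         total_cohesion = pos + abs(neg))
}
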