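#' Construct a feature table
#'
#' A feature table is the pipeline's universal input: a samples x taxa
#' abundance matrix held as a tibble whose first column is `sample_id` and
#' whose remaining columns are numeric taxon abundances. The table carries an
#' abundance mode: `"counts"` (nonnegative reals, typically sequencing read
#' counts) or `"relative"` (every row sums to 1).
#'
#' @param x A numeric matrix (samples x taxa, with dimnames), or a data frame
#'   with a `sample_id` column and numeric taxon columns.
#' @param mode Abundance mode, `"counts"` or `"relative"`.
#' @return A `mycostab_ft` tibble.
#' @examples
#' m <- matrix(c(2, 2, 0, 5), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("taxA", "taxB")))
#' feature_table(m)
#' @export
feature_table <- function(x, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- paste0("sample", seq_len(nrow(x)))
    if (is.null(colnames(x))) colnames(x) <- paste0("taxon", seq_len(ncol(x)))
    out <- tibble::as_tibble(as.data.frame(x), rownames = "sample_id")
  } else {
    out <- tibble::as_tibble(x)
    if (!"sample_id" %in% names(out)) {
      abort("`x` must have a `sample_id` column (or be a matrix with rownames).")
    }
    out <- dplyr::relocate(out, "sample_id")
  }
  out$sample_id <- as.character(out$sample_id)
  new_feature_table(out, mode = mode)
}

new_feature_table <- function(df, mode) {
  structure(df,
    class = c("mycostab_ft", class(tibble::tibble())),
    abundance_mode = mode
  )
}

#' @rdname feature_table
#' @export
is_feature_table <- function(x) inherits(x, "mycostab_ft")

#' @rdname feature_table
#' @param ft A feature table.
#' @export
abundance_mode <- function(ft) attr(ft, "abundance_mode")

# matrix view (samples x taxa)
ft_values <- function(ft) {
  m <- as.matrix(as.data.frame(ft)[, -1, drop = FALSE])
  rownames(m) <- ft$sample_id
  m
}

ft_taxa <- function(ft) setdiff(names(ft), "sample_id")

#' Validate a feature table
#'
#' Checks the container invariants: numeric nonnegative values with no
#' missing entries, unique sample and taxon identifiers, and (for
#' `mode = "relative"`) unit row sums within 1e-9.
#'
#' @param ft A feature table.
#' @return `ft`, invisibly, if valid; otherwise an error naming the offending
#'   row/column.
#' @export
validate_feature_table <- function(ft) {
  if (!is_feature_table(ft)) abort("not a feature table.")
  vals <- ft_values(ft)
  if (!is.numeric(vals)) abort("taxon columns must be numeric.")
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    abort(sprintf("missing value at sample '%s', taxon '%s'.",
                  rownames(vals)[bad[1]], colnames(vals)[bad[2]]))
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative abundance at sample '%s', taxon '%s'.",
                  rownames(vals)[bad[1]], colnames(vals)[bad[2]]))
  }
  if (anyDuplicated(ft$sample_id)) {
    abort(sprintf("duplicated sample id '%s'.",
                  ft$sample_id[duplicated(ft$sample_id)][1]))
  }
  if (anyDuplicated(colnames(vals))) {
    abort(sprintf("duplicated taxon id '%s'.",
                  colnames(vals)[duplicated(colnames(vals))][1]))
  }
  if (identical(abundance_mode(ft), "relative")) {
    rs <- rowSums(vals)
    off <- which(abs(rs - 1) > 1e-9)
    if (length(off)) {
      abort(sprintf("relative-mode row '%s' sums to %.12g, not 1.",
                    rownames(vals)[off[1]], rs[off[1]]))
    }
  }
  invisible(ft)
}

#' Convert a feature table to relative abundances
#'
#' Divides each sample row by its total so rows sum to 1. Idempotent on
#' already-relative tables. The cohesion and robustness statistics are defined
#' on relative abundances, so this is the canonical normalization step before
#' them.
#'
#' @param ft A feature table; every row sum must be positive.
#' @return The feature table with `mode = "relative"`.
#' @export
to_relative_abundance <- function(ft) {
  validate_feature_table(ft)
  vals <- ft_values(ft)
  rs <- rowSums(vals)
  if (any(rs <= 0)) {
    abort(sprintf("sample '%s' has zero total abundance; cannot normalize.",
                  rownames(vals)[which(rs <= 0)[1]]))
  }
  feature_table(vals / rs, mode = "relative")
}

#' Filter taxa by prevalence and mean relative abundance
#'
#' Retains taxa present (abundance > 0) in at least `min_prevalence` of
#' samples and with mean relative abundance at least `min_mean_abundance`.
#' Column order is preserved. Rank-correlation p-values are meaningless for
#' near-absent taxa, so a prevalence filter is applied before network
#' construction; the default (20% prevalence, no abundance floor) is
#' deliberately mild and fully overridable.
#'
#' @param ft A feature table.
#' @param min_prevalence Minimum fraction of samples in which a taxon must be
#'   present, in \[0, 1\].
#' @param min_mean_abundance Minimum mean relative abundance, in \[0, 1\].
#' @return The filtered feature table (same mode as input).
#' @export
filter_taxa <- function(ft, min_prevalence = 0.2, min_mean_abundance = 0) {
  validate_feature_table(ft)
  stopifnot(min_prevalence >= 0, min_prevalence <= 1,
            min_mean_abundance >= 0, min_mean_abundance <= 1)
  vals <- ft_values(ft)
  rel <- ft_values(to_relative_abundance(ft))
  prev <- colMeans(vals > 0)
  mab <- colMeans(rel)
  keep <- prev >= min_prevalence & mab >= min_mean_abundance
  if (!any(keep)) abort("filter would remove all taxa.")
  feature_table(vals[, keep, drop = FALSE], mode = abundance_mode(ft))
}

#' Subset a feature table to a set of samples
#'
#' @param ft A feature table.
#' @param sample_ids Sample ids to keep, in the requested order.
#' @return The subsetted feature table (same mode).
#' @export
subset_samples <- function(ft, sample_ids) {
  validate_feature_table(ft)
  miss <- setdiff(sample_ids, ft$sample_id)
  if (length(miss)) {
    abort(paste0("unknown sample id(s): ", paste(head(miss, 3), collapse = ", "), "."))
  }
  feature_table(ft_values(ft)[sample_ids, , drop = FALSE],
                mode = abundance_mode(ft))
}

#' @export
print.mycostab_ft <- function(x, ...) {
  cat(sprintf("# Feature table: %d samples x %d taxa (mode: %s)\n",
              nrow(x), length(ft_taxa(x)), abundance_mode(x)))
  NextMethod()
}
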