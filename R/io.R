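#' Read a feature table from file
#'
#' Reads a tab-separated abundance table (header row + id column) or a
#' BIOM-format table (via the biomformat package). Orientation is normalized
#' to the package-internal convention of samples as rows; amplicon exports
#' commonly come in either orientation, so it is declared with a flag rather
#' than guessed.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"biom"`.
#' @param orientation For TSV input: `"samples"` if rows are samples,
#'   `"taxa"` if rows are taxa (the table is transposed on read). BIOM tables
#'   are observation x sample by convention and are always transposed.
#' @param mode Abundance mode of the stored values.
#' @return A validated feature table.
#' @export
read_feature_table <- function(path, format = c("tsv", "biom"),
                               orientation = c("samples", "taxa"),
                               mode = c("counts", "relative")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  mode <- match.arg(mode)
  if (!file.exists(path)) abort(sprintf("file not found: '%s'.", path))
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("reading BIOM files requires the 'biomformat' package.")
    }
    m <- t(as.matrix(biomformat::biom_data(biomformat::read_biom(path))))
  } else {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    if (orientation == "taxa") m <- t(m)
  }
  storage.mode(m) <- "double"
  validate_feature_table(feature_table(m, mode = mode))
}

#' Write a feature table to TSV
#'
#' @param ft A feature table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  validate_feature_table(ft)
  write_tsv_id(as.data.frame(ft), path)
}

write_tsv_id <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects a TSV with columns `sample_id`, `site`, `soil_type`, `latitude`,
#' `longitude`. Coordinates are validated against the usual decimal-degree
#' ranges.
#'
#' @param path Path to a TSV file.
#' @return A tibble of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'.", path))
  meta <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
  validate_sample_metadata(meta)
}

#' Validate sample metadata
#'
#' @param meta A data frame of per-sample metadata.
#' @return `meta` as a tibble, invisibly-validated.
#' @export
validate_sample_metadata <- function(meta) {
  meta <- tibble::as_tibble(meta)
  need <- c("sample_id", "site", "soil_type", "latitude", "longitude")
  miss <- setdiff(need, names(meta))
  if (length(miss)) abort(paste0("metadata missing column(s): ",
                                 paste(miss, collapse = ", "), "."))
  if (anyDuplicated(meta$sample_id)) abort("duplicated sample_id in metadata.")
  ok_coord <- is.na(meta$latitude) |
    (meta$latitude >= -90 & meta$latitude <= 90 &
       meta$longitude >= -180 & meta$longitude <= 180)
  if (!all(ok_coord)) {
    abort(sprintf("out-of-range coordinates for sample '%s'.",
                  meta$sample_id[!ok_coord][1]))
  }
  meta
}

#' Read an environmental matrix
#'
#' Reads a TSV of per-sample environmental measurements (first column
#' `sample_id`, remaining columns numeric variables such as temperature,
#' salinity, pH, nutrient concentrations and soil texture fractions).
#' Missing values fail by default; per-variable mean imputation is available
#' but must be requested explicitly, since silent imputation hides data
#' problems.
#'
#' @param path Path to a TSV file.
#' @param missing `"fail"` (default) or `"mean"` (impute the per-variable
#'   mean).
#' @return A tibble, first column `sample_id`.
#' @export
read_env_matrix <- function(path, missing = c("fail", "mean")) {
  missing <- match.arg(missing)
  if (!file.exists(path)) abort(sprintf("file not found: '%s'.", path))
  env <- tibble::as_tibble(read.delim(path, check.names = FALSE,
                                      stringsAsFactors = FALSE))
  names(env)[1] <- "sample_id"
  env$sample_id <- as.character(env$sample_id)
  if (anyDuplicated(names(env))) abort("duplicated variable names in env matrix.")
  vars <- setdiff(names(env), "sample_id")
  for (v in vars) {
    if (anyNA(env[[v]])) {
      if (missing == "fail") {
        abort(sprintf("missing values in environmental variable '%s' (use missing = \"mean\" to impute).", v))
      }
      env[[v]][is.na(env[[v]])] <- mean(env[[v]], na.rm = TRUE)
    }
  }
  env
}

#' Derive stoichiometric ratios
#'
#' Adds `C:N` (= TC/TN) and `C:P` (= TC/TP) columns when absent and the
#' component totals are present.
#'
#' @param env Environmental tibble with `TC`, `TN`, `TP` columns.
#' @return `env` with ratio columns appended where derivable.
#' @export
derive_nutrient_ratios <- function(env) {
  if (!"C:N" %in% names(env) && all(c("TC", "TN") %in% names(env))) {
    env[["C:N"]] <- env$TC / env$TN
  }
  if (!"C:P" %in% names(env) && all(c("TC", "TP") %in% names(env))) {
    env[["C:P"]] <- env$TC / env$TP
  }
  env
}

#' Export a co-occurrence network to file
#'
#' Writes either a weighted edge list (TSV with columns `from`, `to`, `rho`,
#' `p`, `q`, `sign`) or a GraphML file with the same edge attributes plus
#' per-node mean relative abundance and module id.
#'
#' @param net A `co_network` object.
#' @param path Output path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "co_network"))
  if (format == "edgelist") {
    write_tsv_id(as.data.frame(net$edges), path)
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a co-occurrence network to an igraph object
#'
#' @param net A `co_network` object.
#' @return An igraph graph with edge attributes `rho`, `p`, `q`, `sign` and
#'   node attributes `abundance`, `module`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "co_network"))
  verts <- as.data.frame(net$nodes[, c("node_id", "abundance", "module")])
  verts$module <- ifelse(is.na(verts$module), -1L, verts$module)
  edges <- as.data.frame(net$edges)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Read a network edge list or GraphML file back as an edge tibble
#'
#' @param path Path written by [export_network()].
#' @param format `"edgelist"` or `"graphml"`.
#' @return A tibble of edges with attributes `rho`, `p`, `q`, `sign`.
#' @export
read_network_edges <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE,
                                 colClasses = c(from = "character", to = "character")))
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_data_frame(g, what = "edges")
    tibble::as_tibble(el)
  }
}
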