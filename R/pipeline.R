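#' Default environmental ground truth for simulation
#'
#' Two latent drivers measured on a standardized scale: soil properties
#' (ORP, pH, temperature, salinity and the three texture fractions) and
#' nutrients (inorganic nitrogen species, carbon/sulfur/phosphorus totals
#' and ions), with nutrients partly determined by soil properties.
#'
#' @return List with `truth` (a [path_truth()]) and `manifest_map`.
#' @export
default_env_truth <- function() {
  latents <- c("soil_properties", "nutrients")
  pm <- matrix(0, 2, 2)
  pm[2, 1] <- 0.5
  list(truth = path_truth(latents, pm, loadings = 0.8, noise_sd = 0.6),
       manifest_map = list(
         soil_properties = c("ORP", "pH", "temperature", "salinity",
                             "clay", "silt", "sand"),
         nutrients = c("NH4_N", "NO2_N", "NO3_N", "TIC", "TOC", "TC", "TN",
                       "PO4", "TP", "SO4", "TS")))
}

#' Default study path model
#'
#' The paper-shaped inner model: soil properties, nutrients, geographic
#' distance, alpha diversity and beta diversity each pointing at community
#' complexity (total cohesion) and stability (per-sample robustness).
#' Per-sample manifests: alpha diversity = Shannon index; beta diversity =
#' scores on the first two principal coordinates of Bray-Curtis; geographic
#' distance = mean geodesic distance to all other samples; complexity =
#' total cohesion; stability = per-sample robustness.
#'
#' @param scheme Inner estimation scheme.
#' @return A [path_model()].
#' @export
default_study_model <- function(scheme = "centroid") {
  env_map <- default_env_truth()$manifest_map
  latents <- c("soil_properties", "nutrients", "geographic_distance",
               "alpha_diversity", "beta_diversity", "complexity", "stability")
  edges <- tidyr::expand_grid(
    from = latents[1:5], to = c("complexity", "stability"))
  path_model(latents, as.data.frame(edges),
             blocks = c(env_map,
                        list(geographic_distance = "geo_distance",
                             alpha_diversity = "shannon",
                             beta_diversity = c("PCo1", "PCo2"),
                             complexity = "total_cohesion",
                             stability = "stability")),
             scheme = scheme)
}

config_defaults <- function() {
  list(
    group_var = "soil_type",
    filter = list(min_prevalence = 0.2, min_mean_abundance = 0),
    network = list(rho_min = 0.6, alpha = 0.05, correction = "BH"),
    diversity = list(n_perm = 999, pcoa_axes = 2),
    stability = list(removal_fraction = 0.5, n_hubs = 5,
                     n_iterations = 200, sample_n_iterations = 50),
    drivers = list(correction = "none"),
    plspm = list(enabled = TRUE, n_boot = 200, scheme = "centroid")
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML/JSON config (or takes a list), rejects unknown keys, checks
#' value ranges, requires an explicit seed for every stochastic run, and
#' fills documented defaults. All applied defaults are recorded so the run
#' manifest carries a complete audit trail.
#'
#' @param config Path to a YAML/JSON file, or a list.
#' @return A normalized `run_config` list with attribute
#'   `defaults_applied`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  known_top <- c("seed", "output_dir", "simulate", "input", "group_var",
                 "filter", "network", "diversity", "stability", "drivers",
                 "plspm")
  problems <- character(0)
  unknown <- setdiff(names(config), known_top)
  if (length(unknown)) {
    problems <- c(problems, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  if (is.null(config$seed)) {
    problems <- c(problems, "missing required key: seed (every stochastic stage must be seeded)")
  } else if (!is.numeric(config$seed) || length(config$seed) != 1) {
    problems <- c(problems, "seed must be a single integer")
  }
  if (is.null(config$simulate) && is.null(config$input)) {
    problems <- c(problems, "one of `simulate` or `input` is required")
  }
  defaults <- config_defaults()
  applied <- character(0)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) {
      config[[k]] <- defaults[[k]]
      applied <- c(applied, k)
    } else if (is.list(defaults[[k]])) {
      unknown_sub <- setdiff(names(config[[k]]), names(defaults[[k]]))
      if (length(unknown_sub)) {
        problems <- c(problems, paste0("unknown key(s) in `", k, "`: ",
                                       paste(unknown_sub, collapse = ", ")))
      }
      for (kk in setdiff(names(defaults[[k]]), names(config[[k]]))) {
        config[[k]][[kk]] <- defaults[[k]][[kk]]
        applied <- c(applied, paste0(k, ".", kk))
      }
    }
  }
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(config$network$alpha > 0 && config$network$alpha <= 1,
      "network.alpha must be in (0, 1]")
  chk(config$network$rho_min >= 0, "network.rho_min must be >= 0")
  chk(config$network$correction %in% c("BH", "none"),
      "network.correction must be 'BH' or 'none'")
  chk(config$filter$min_prevalence >= 0 && config$filter$min_prevalence <= 1,
      "filter.min_prevalence must be in [0, 1]")
  chk(config$stability$removal_fraction > 0 && config$stability$removal_fraction < 1,
      "stability.removal_fraction must be in (0, 1)")
  chk(config$diversity$n_perm >= 1, "diversity.n_perm must be >= 1")
  chk(config$drivers$correction %in% c("BH", "none"),
      "drivers.correction must be 'BH' or 'none'")
  if (!is.null(config$plspm$latents) && anyDuplicated(config$plspm$latents)) {
    problems <- c(problems, "duplicate latent name in plspm spec")
  }
  if (length(problems)) {
    abort(paste0("invalid configuration:\n",
                 paste0("  - ", problems, collapse = "\n")))
  }
  config$seed <- as.integer(config$seed)
  structure(config, class = "run_config", defaults_applied = applied)
}

write_json_result <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes (optionally) simulation, then diversity, network, stability,
#' driver and PLS-PM stages per group, writing every result as TSV/JSON
#' (and networks additionally as GraphML) into a run directory together
#' with a manifest recording the normalized configuration, its hash, all
#' seeds and per-file checksums. Identical configurations produce
#' byte-identical result tables.
#'
#' @param config A `run_config` from [validate_config()], or a path/list
#'   accepted by it.
#' @param output_dir Run directory (overrides `config$output_dir`).
#' @return The run directory path, invisibly.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out <- output_dir %||% config$output_dir
  if (is.null(out)) abort("no output directory given.")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    inform(sprintf("[%s] running", name))
    tryCatch(code, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  files <- character(0)
  keep <- function(p) { files <<- c(files, p); p }

  # --- inputs ---------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      sim_args <- config$simulate
      if (!is.null(sim_args$n_samples_per_group)) {
        sim_args$n_samples_per_group <- unlist(sim_args$n_samples_per_group)
      }
      spec <- do.call(community_spec, c(sim_args, list(seed = config$seed)))
      com <- generate_community(spec)
      com$metadata <- generate_coordinates(com$metadata, seed = config$seed + 1L)
      et <- default_env_truth()
      envgen <- generate_env(com$metadata, et$truth, et$manifest_map,
                             seed = config$seed + 2L)
      list(ft = com$feature_table, meta = com$metadata, env = envgen$env)
    })
    ft <- sim$ft; meta <- sim$meta; env <- sim$env
    keep(write_feature_table(ft, file.path(out, "feature_table.tsv")))
    keep(write_tsv_id(as.data.frame(meta), file.path(out, "metadata.tsv")))
    keep(write_tsv_id(as.data.frame(env), file.path(out, "env.tsv")))
  } else {
    ft <- read_feature_table(config$input$feature_table)
    meta <- read_sample_metadata(config$input$metadata)
    env <- read_env_matrix(config$input$env)
  }
  env <- derive_nutrient_ratios(env)
  meta <- meta[match(ft$sample_id, meta$sample_id), ]
  group_var <- config$group_var
  groups <- setNames(as.character(meta[[group_var]]), meta$sample_id)
  rel_all <- to_relative_abundance(ft)

  # --- diversity ------------------------------------------------------------
  stage("diversity", {
    alpha <- alpha_diversity(ft)
    keep(write_tsv_id(as.data.frame(alpha), file.path(out, "alpha_diversity.tsv")))
    bc <- bray_curtis(rel_all)
    keep(write_tsv_id(as.data.frame(as.matrix(bc)) |>
                        tibble::rownames_to_column("sample_id"),
                      file.path(out, "bray_curtis.tsv")))
    ord <- pcoa_ordination(bc, k = config$diversity$pcoa_axes)
    keep(write_tsv_id(as.data.frame(ord$coordinates),
                      file.path(out, "pcoa_coordinates.tsv")))
    geo <- geodesic_distances(meta)
    tests <- list(
      anosim_group = as.list(anosim_test(bc, groups[ft$sample_id],
                                         n_perm = config$diversity$n_perm,
                                         seed = config$seed + 10L)),
      anosim_site = as.list(anosim_test(bc, meta$site,
                                        n_perm = config$diversity$n_perm,
                                        seed = config$seed + 11L)),
      mantel_geo = as.list(mantel_test(bc, geo,
                                       n_perm = config$diversity$n_perm,
                                       seed = config$seed + 12L)),
      pct_explained = ord$pct_explained[1:2]
    )
    keep(write_json_result(tests, file.path(out, "diversity_tests.json")))
  })

  geo <- geodesic_distances(meta)
  geo_m <- as.matrix(geo)
  mean_geo <- rowSums(geo_m) / (nrow(geo_m) - 1)

  # --- per-group network / stability / drivers / plspm ----------------------
  for (g in unique(groups)) {
    gdir <- file.path(out, paste0("group_", g))
    dir.create(gdir, showWarnings = FALSE)
    sel <- ft$sample_id[groups[ft$sample_id] == g]
    ft_g <- feature_table(ft_values(ft)[sel, , drop = FALSE],
                          mode = abundance_mode(ft))
    net <- stage(paste0("network:", g), {
      ftf <- filter_taxa(ft_g, config$filter$min_prevalence,
                         config$filter$min_mean_abundance)
      net <- build_network(ftf, rho_min = config$network$rho_min,
                           alpha = config$network$alpha,
                           correction = config$network$correction)
      net <- detect_modules(net, seed = config$seed + 20L)
      keep(export_network(net, file.path(gdir, "network_edges.tsv"), "edgelist"))
      keep(export_network(net, file.path(gdir, "network.graphml"), "graphml"))
      keep(write_tsv_id(as.data.frame(topology_report(net)),
                        file.path(gdir, "topology.tsv")))
      hubs <- identify_module_hubs(net, top_k = min(config$stability$n_hubs,
                                                    nrow(net$nodes)))
      keep(write_tsv_id(as.data.frame(hubs), file.path(gdir, "module_hubs.tsv")))
      attr(net, "filtered_ft") <- ftf
      net
    })
    rel_g <- to_relative_abundance(attr(net, "filtered_ft"))
    coh <- stage(paste0("stability:", g), {
      conn <- connectedness(attr(net, "filtered_ft"), net = net)
      coh <- cohesion(rel_g, conn)
      keep(write_tsv_id(as.data.frame(coh), file.path(gdir, "cohesion.tsv")))
      rob_r <- robustness(net, "random_fraction",
                          config$stability$removal_fraction,
                          n_iterations = config$stability$n_iterations,
                          seed = config$seed + 30L)
      rob_t <- robustness(net, "targeted_hubs",
                          min(config$stability$n_hubs, nrow(net$nodes)),
                          seed = config$seed + 31L)
      keep(write_json_result(list(random = as.list(glance(rob_r)),
                                  targeted = as.list(glance(rob_t))),
                             file.path(gdir, "robustness.json")))
      stab <- sample_stability(rel_g, net,
                               parameter = config$stability$removal_fraction,
                               n_iterations = config$stability$sample_n_iterations,
                               seed = config$seed + 32L)
      keep(write_tsv_id(as.data.frame(stab), file.path(gdir, "stability.tsv")))
      dplyr::left_join(coh, stab, by = "sample_id")
    })
    responses <- dplyr::left_join(alpha_diversity(ft_g), coh, by = "sample_id")
    stage(paste0("drivers:", g), {
      env_g <- env[match(sel, env$sample_id), ]
      dt <- driver_correlations(env_g, responses,
                                correction = config$drivers$correction)
      keep(write_tsv_id(as.data.frame(dt), file.path(gdir, "driver_table.tsv")))
    })
    if (isTRUE(config$plspm$enabled)) {
      stage(paste0("plspm:", g), {
        bc_g <- bray_curtis(rel_g)
        ord_g <- pcoa_ordination(bc_g, k = 2)
        dat <- env[match(sel, env$sample_id), ] |>
          dplyr::left_join(responses, by = "sample_id") |>
          dplyr::left_join(ord_g$coordinates, by = "sample_id") |>
          dplyr::mutate(geo_distance = mean_geo[sel])
        dat <- dat[complete.cases(dat), ]
        model <- default_study_model(scheme = config$plspm$scheme)
        fit <- fit_plspm(dat, model)
        boot <- bootstrap_paths(dat, model, n_boot = config$plspm$n_boot,
                                seed = config$seed + 40L)
        keep(write_tsv_id(as.data.frame(boot), file.path(gdir, "plspm_paths.tsv")))
        keep(write_tsv_id(as.data.frame(fit$effects),
                          file.path(gdir, "plspm_effects.tsv")))
        keep(write_json_result(list(glance = as.list(glance(fit)),
                                    r_squared = as.list(fit$r_squared)),
                               file.path(gdir, "plspm_summary.json")))
      })
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mycostab")),
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    defaults_applied = attr(config, "defaults_applied"),
    seed = config$seed,
    files = {
      fs <- sort(unique(files))
      setNames(as.list(tools::md5sum(fs)),
               sub(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", out), "/?"),
                   "", fs))
    }
  )
  write_json_result(manifest, file.path(out, "manifest.json"))
  inform(sprintf("[done] %d result files in %s", length(unique(files)), out))
  invisible(out)
}
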