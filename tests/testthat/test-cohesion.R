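test_that("connectedness averages retained correlations by sign", {
  # taxon a: retained +0.8, +0.6 and -0.4 -> (0.7, -0.4)
  edges <- data.frame(from = c("a", "a", "a", "b"),
                      to = c("b", "c", "d", "c"),
                      rho = c(0.8, 0.6, -0.4, 0.5))
  net <- make_net(edges)
  m <- matrix(rpois(6 * 4, 20), 6, 4,
              dimnames = list(paste0("s", 1:6), c("a", "b", "c", "d")))
  ft <- feature_table(m)
  conn <- connectedness(ft, net = net)
  expect_equal(conn$positive[conn$taxon_id == "a"], 0.7)
  expect_equal(conn$negative[conn$taxon_id == "a"], -0.4)
  expect_equal(conn$positive[conn$taxon_id == "b"], mean(c(0.8, 0.5)))
  expect_equal(conn$negative[conn$taxon_id == "b"], 0)

  # taxa without retained correlations get (0, 0)
  empty <- make_net(data.frame(from = character(), to = character(),
                               rho = numeric()), node_ids = c("a", "b"))
  conn0 <- connectedness(ft, net = empty)
  expect_true(all(conn0$positive == 0 & conn0$negative == 0))
})

test_that("all-significant connectedness matches brute-force enumeration", {
  set.seed(10)
  m <- matrix(rpois(12 * 5, 35), 12, 5,
              dimnames = list(paste0("s", 1:12), paste0("t", 1:5)))
  m[, 2] <- m[, 1] + rpois(12, 2)
  m[, 5] <- max(m[, 4]) - m[, 4] + rpois(12, 2)
  ft <- feature_table(m)
  conn <- connectedness(ft, corr_source = "all_significant",
                        alpha = 0.3, correction = "none")
  corr <- spearman_matrix(ft)
  for (i in 1:5) {
    keep <- corr$p[i, ] < 0.3 & seq_len(5) != i
    r <- corr$rho[i, keep]
    pos_or <- if (any(r > 0)) mean(r[r > 0]) else 0
    neg_or <- if (any(r < 0)) mean(r[r < 0]) else 0
    expect_equal(conn$positive[i], pos_or)
    expect_equal(conn$negative[i], neg_or)
  }
})

test_that("cohesion equals hand-computed dot products", {
  abund <- rbind(s1 = c(0.5, 0.3, 0.2, 0.0),
                 s2 = c(0.1, 0.1, 0.4, 0.4),
                 s3 = c(0.25, 0.25, 0.25, 0.25))
  colnames(abund) <- c("a", "b", "c", "d")
  ft <- feature_table(abund, mode = "relative")
  conn <- tibble::tibble(taxon_id = c("a", "b", "c", "d"),
                         positive = c(0.7, 0.5, 0.0, 0.2),
                         negative = c(-0.4, 0.0, -0.3, 0.0))
  res <- cohesion(ft, conn)
  for (s in 1:3) {
    pos_or <- sum(abund[s, ] * conn$positive)
    neg_or <- sum(abund[s, ] * conn$negative)
    expect_equal(res$positive_cohesion[s], pos_or, tolerance = 1e-12)
    expect_equal(res$negative_cohesion[s], neg_or, tolerance = 1e-12)
    expect_equal(res$total_cohesion[s], pos_or + abs(neg_or), tolerance = 1e-12)
  }
  # zero connectedness implies zero cohesion
  conn0 <- conn; conn0$positive <- 0; conn0$negative <- 0
  expect_true(all(cohesion(ft, conn0)$total_cohesion == 0))
  # taxa with zero abundance in a sample cannot contribute
  conn_d <- conn; conn_d$positive[4] <- 99
  expect_equal(cohesion(ft, conn_d)$positive_cohesion[1],
               res$positive_cohesion[1] + 0.0 * 99)
  # mode and taxon mismatch guards
  expect_error(cohesion(feature_table(abund * 10, mode = "counts"), conn),
               "relative")
  expect_error(cohesion(ft, conn[1:3, ]), "taxa")
})

test_that("all-positive correlation structure gives zero negative cohesion", {
  spec <- community_spec(
    n_samples_per_group = c(g = 30), group_labels = "g",
    sites_per_group = list(g = "S"), n_taxa = 20, taxon_classes = "c1",
    dominance_profile = list(g = c(c1 = 1)),
    correlation_blocks = list(list(taxa = 1:8, rho = 0.8, sign = "positive",
                                   weight_boost = 2)),
    sequencing_depth = 10000, seed = 2)
  ft <- generate_community(spec)$feature_table
  net <- build_network(ft, rho_min = 0.5)
  if (nrow(net$edges) > 0 && all(net$edges$sign > 0)) {
    conn <- connectedness(ft, net = net)
    coh <- cohesion(to_relative_abundance(ft), conn)
    expect_true(all(coh$negative_cohesion == 0))
    expect_equal(coh$total_cohesion, coh$positive_cohesion)
  } else {
    conn <- connectedness(ft, net = net)
    expect_true(all(conn$negative[net$edges$sign > 0] <= 0))
  }
})

test_that("robustness closed forms hold exactly", {
  # complete positive graph, equal abundances, 50% removal: exactly 0.5
  k10 <- make_net(complete_edges(sprintf("n%02d", 1:10), rho = 0.8))
  k10$pearson[] <- 1
  r <- robustness(k10, "random_fraction", 0.5, n_iterations = 25, seed = 1)
  expect_true(all(r$per_iteration == 0.5))
  expect_equal(r$proportion_remaining, 0.5)

  # star graph, targeted removal of the hub: total collapse
  star <- make_net(data.frame(from = "hub", to = paste0("leaf", 1:7),
                              rho = 0.9, p = 1e-5, q = 1e-5))
  star <- detect_modules(star, seed = 1)
  rt <- robustness(star, "targeted_hubs", 1)
  expect_equal(rt$proportion_remaining, 0)

  expect_error(robustness(k10, "random_fraction", 0.05), "no node")
  k10b <- k10; k10b$nodes$module <- NA_integer_
  expect_error(robustness(k10b, "targeted_hubs", 2), "detect_modules")
})

test_that("secondary extinctions match an independent fixed-point simulation", {
  set.seed(11)
  e <- random_graph_edges(10, 0.45, seed = 3)
  net <- make_net(e, node_ids = sprintf("v%02d", 1:10),
                  abundance = runif(10, 0.02, 0.2))
  adj <- matrix(FALSE, 10, 10, dimnames = dimnames(net$pearson))
  adj[cbind(net$edges$from, net$edges$to)] <- TRUE
  adj <- adj | t(adj)
  for (sd_i in 1:5) {
    removed <- withr::with_seed(sd_i, sample.int(10, 5))
    r_pkg <- withr::with_seed(sd_i, robustness(net, "random_fraction", 0.5,
                                               n_iterations = 1, seed = sd_i))
    # the package draws the same removal set under the same seed
    r_or <- extinction_oracle(adj, net$pearson, net$nodes$abundance, removed)
    expect_equal(r_pkg$per_iteration, r_or)
  }
})

test_that("robustness decreases with removal fraction in expectation", {
  spec <- small_spec(seed = 4)
  com <- generate_community(spec)
  sel <- com$metadata$sample_id[com$metadata$soil_type == "clay_loam"]
  ftg <- subset_samples(com$feature_table, sel)
  net <- build_network(filter_taxa(ftg))
  sweep <- robustness_sweep(net, fractions = c(0.2, 0.4, 0.6, 0.8),
                            n_iterations = 200, seed = 5)
  expect_true(all(diff(sweep$proportion_remaining) <= 0.02))
})

test_that("per-sample stability is reproducible and bounded", {
  spec <- small_spec(seed = 6)
  com <- generate_community(spec)
  sel <- com$metadata$sample_id[com$metadata$soil_type == "clay_loam"]
  ftg <- subset_samples(com$feature_table, sel)
  rel <- to_relative_abundance(filter_taxa(ftg))
  net <- build_network(filter_taxa(ftg))
  s1 <- sample_stability(rel, net, n_iterations = 20, seed = 3)
  s2 <- sample_stability(rel, net, n_iterations = 20, seed = 3)
  expect_identical(s1, s2)
  expect_true(all(s1$stability >= 0 & s1$stability <= 1, na.rm = TRUE))
})
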