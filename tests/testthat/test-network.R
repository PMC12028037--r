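test_that("Spearman matrix matches a direct rank-formula oracle", {
  set.seed(6)
  m <- matrix(rpois(8 * 4, 30), 8, 4,
              dimnames = list(paste0("s", 1:8), paste0("t", 1:4)))
  ft <- feature_table(m)
  res <- spearman_matrix(ft)
  n <- 8
  for (i in 1:3) for (j in (i + 1):4) {
    r_or <- cor(rank(m[, i]), rank(m[, j])) # Pearson on midranks
    expect_equal(res$rho[i, j], r_or, tolerance = 1e-10)
    t_or <- abs(r_or) * sqrt((n - 2) / (1 - r_or^2))
    expect_equal(res$p[i, j], 2 * pt(t_or, n - 2, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  expect_true(all(diag(res$rho) == 1))
  # perfectly monotone pair
  m2 <- cbind(t1 = 1:8, t2 = (1:8)^2, t3 = rpois(8, 10) + 1)
  rownames(m2) <- paste0("s", 1:8)
  res2 <- spearman_matrix(feature_table(m2))
  expect_equal(res2$rho["t1", "t2"], 1)
  expect_identical(res2$p["t1", "t2"], 0)
  # zero-variance taxon is excluded with a message
  m3 <- cbind(m, tz = rep(2, 8))
  expect_message(res3 <- spearman_matrix(feature_table(m3)), "tz")
  expect_true(all(is.na(res3$rho["tz", colnames(m)])))
})

test_that("edge filtering matches hand enumeration and extreme thresholds", {
  set.seed(7)
  m <- matrix(rpois(12 * 6, 40), 12, 6,
              dimnames = list(paste0("s", 1:12), paste0("t", 1:6)))
  m[, 2] <- m[, 1] + rpois(12, 3) # strongly correlated pair
  ft <- feature_table(m)
  corr <- spearman_matrix(ft)

  full <- build_network(ft, rho_min = 0, alpha = 1, correction = "none")
  expect_identical(nrow(full$edges), 15L)

  expect_warning(empty <- build_network(ft, rho_min = 1.01), "empty")
  expect_identical(nrow(empty$edges), 0L)

  # brute-force enumeration of the surviving edge set
  net <- build_network(ft, rho_min = 0.4, alpha = 0.05, correction = "BH")
  ut <- which(upper.tri(corr$rho), arr.ind = TRUE)
  q <- p.adjust(corr$p[ut], method = "BH")
  expected <- paste(colnames(m)[ut[, 1]], colnames(m)[ut[, 2]])[
    abs(corr$rho[ut]) >= 0.4 & q < 0.05]
  expect_setequal(paste(net$edges$from, net$edges$to), expected)
})

test_that("build_network is monotone in its thresholds", {
  set.seed(8)
  for (rep in 1:3) {
    m <- matrix(rpois(10 * 8, 25), 10, 8,
                dimnames = list(paste0("s", 1:10), paste0("t", 1:8)))
    ft <- feature_table(m)
    key <- function(net) paste(net$edges$from, net$edges$to)
    loose <- build_network(ft, rho_min = 0.2, alpha = 0.5, correction = "none")
    tighter_rho <- build_network(ft, rho_min = 0.5, alpha = 0.5, correction = "none")
    tighter_alpha <- build_network(ft, rho_min = 0.2, alpha = 0.1, correction = "none")
    expect_true(all(key(tighter_rho) %in% key(loose)))
    expect_true(all(key(tighter_alpha) %in% key(loose)))
  }
})

test_that("degree and density closed forms and identity hold", {
  path5 <- make_net(data.frame(from = c("a", "b", "c", "d"),
                               to = c("b", "c", "d", "e")))
  expect_equal(average_degree(path5), 1.6)
  expect_equal(network_density(path5), 0.4)
  k4 <- make_net(complete_edges(letters[1:4]))
  expect_equal(average_degree(k4), 3)
  k5 <- make_net(complete_edges(letters[1:5]))
  expect_equal(network_density(k5), 1)
  # identity and brute-force counts on random graphs
  for (s in 1:5) {
    n <- sample(3:12, 1)
    e <- random_graph_edges(n, 0.5, seed = s)
    if (nrow(e) == 0) next
    net <- make_net(e, node_ids = sprintf("v%02d", 1:n))
    expect_equal(average_degree(net), 2 * nrow(e) / n)
    expect_equal(network_density(net), nrow(e) / choose(n, 2))
    expect_equal(network_density(net), average_degree(net) / (n - 1),
                 tolerance = 1e-12)
  }
})

test_that("Louvain modules and modularity agree with exhaustive oracles", {
  # two K4 cliques joined by one bridge
  e <- rbind(complete_edges(paste0("a", 1:4)), complete_edges(paste0("b", 1:4)),
             data.frame(from = "a1", to = "b1", rho = 0.8, p = 1e-5, q = 1e-5))
  net <- make_net(e)
  net <- detect_modules(net, seed = 1)
  expect_identical(length(unique(net$nodes$module)), 2L)
  ma <- net$nodes$module[net$nodes$node_id %in% paste0("a", 1:4)]
  expect_identical(length(unique(ma)), 1L)
  # modularity equals the defining formula on the found partition
  memb <- setNames(net$nodes$module, net$nodes$node_id)
  expect_equal(net$modularity,
               modularity_oracle(net$edges, memb, abs(net$edges$rho)),
               tolerance = 1e-9)
  # ... and equals the best of all bipartitions
  ids <- net$nodes$node_id
  best <- -Inf
  for (mask in 0:(2^8 - 1)) {
    part <- setNames(bitwAnd(bitwShiftR(mask, 0:7), 1), ids)
    best <- max(best, modularity_oracle(net$edges, part, abs(net$edges$rho)))
  }
  expect_equal(net$modularity, best, tolerance = 1e-9)

  # complete graph: single module, Q = 0
  k6 <- detect_modules(make_net(complete_edges(letters[1:6])), seed = 1)
  expect_identical(length(unique(k6$nodes$module)), 1L)
  expect_equal(k6$modularity, 0, tolerance = 1e-12)

  # determinism
  n1 <- detect_modules(net, seed = 42)
  n2 <- detect_modules(net, seed = 42)
  expect_identical(n1$nodes$module, n2$nodes$module)

  # random graphs: reported Q always equals the oracle on the partition
  for (s in 1:4) {
    e <- random_graph_edges(sample(4:12, 1), 0.5, seed = s + 10)
    if (nrow(e) == 0) next
    netr <- detect_modules(make_net(e), seed = 2)
    membr <- setNames(netr$nodes$module, netr$nodes$node_id)
    expect_equal(netr$modularity,
                 modularity_oracle(netr$edges, membr, abs(netr$edges$rho)),
                 tolerance = 1e-9)
  }
})

test_that("module hubs are ranked by within-module degree z-score", {
  star <- make_net(data.frame(from = "hub", to = paste0("leaf", 1:5),
                              rho = 0.8, p = 1e-5, q = 1e-5))
  star <- detect_modules(star, seed = 1)
  expect_identical(identify_module_hubs(star, 1)$node_id, "hub")
  expect_identical(nrow(identify_module_hubs(star, 0)), 0L)

  # two symmetric modules, each with one clear max-degree node
  mod1 <- data.frame(from = "h1", to = paste0("x", 1:3))
  mod2 <- data.frame(from = "h2", to = paste0("y", 1:3))
  extra <- data.frame(from = c("x1", "y1"), to = c("x2", "y2"))
  net <- make_net(rbind(mod1, mod2, extra))
  net$nodes$module <- ifelse(net$nodes$node_id %in% c("h1", paste0("x", 1:3)),
                             1L, 2L)
  hubs <- identify_module_hubs(net, 2)
  expect_setequal(hubs$node_id, c("h1", "h2"))
})

test_that("topology report is internally consistent", {
  set.seed(9)
  m <- matrix(rpois(12 * 8, 30), 12, 8,
              dimnames = list(paste0("s", 1:12), paste0("t", 1:8)))
  m[, 2] <- m[, 1] + rpois(12, 2)
  m[, 4] <- m[, 3] + rpois(12, 2)
  ft <- feature_table(m)
  net <- build_network(ft, rho_min = 0.3, alpha = 0.2, correction = "none")
  rep <- topology_report(net)
  expect_equal(rep$average_degree, 2 * rep$n_edges / rep$n_nodes, tolerance = 1e-12)
  expect_equal(rep$density, rep$average_degree / (rep$n_nodes - 1), tolerance = 1e-12)
  expect_true(rep$density >= 0 && rep$density <= 1)
})
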