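chain_model <- function() {
  path_model(c("X", "M", "Y"),
             data.frame(from = c("X", "M"), to = c("M", "Y")),
             blocks = list(X = "x1", M = "m1", Y = "y1"))
}

test_that("single-manifest models reduce to correlations and OLS", {
  set.seed(15)
  d <- tibble::tibble(x1 = rnorm(60))
  d$m1 <- 0.6 * d$x1 + rnorm(60, 0, 0.8)
  d$y1 <- 0.5 * d$m1 + rnorm(60, 0, 0.8)

  biv <- path_model(c("X", "Y"), data.frame(from = "X", to = "Y"),
                    blocks = list(X = "x1", Y = "y1"))
  f <- fit_plspm(d, biv)
  expect_equal(tidy(f)$estimate, cor(d$x1, d$y1), tolerance = 1e-9)

  fc <- fit_plspm(d, chain_model())
  est <- tidy(fc)
  # standardized OLS oracle for each regression in the chain
  b1 <- unname(coef(lm(scale(m1) ~ scale(x1), d))[2])
  b2 <- unname(coef(lm(scale(y1) ~ scale(m1), d))[2])
  expect_equal(est$estimate[est$from == "X" & est$to == "M"], b1,
               tolerance = 1e-9)
  expect_equal(est$estimate[est$from == "M" & est$to == "Y"], b2,
               tolerance = 1e-9)
})

test_that("latent scores are standardized and loadings bounded", {
  set.seed(16)
  d <- as.data.frame(matrix(rnorm(80 * 6), 80, 6))
  names(d) <- c(paste0("a", 1:3), paste0("b", 1:3))
  d$b1 <- d$a1 + rnorm(80, 0, 0.5)
  m <- path_model(c("A", "B"), data.frame(from = "A", to = "B"),
                  blocks = list(A = paste0("a", 1:3), B = paste0("b", 1:3)))
  f <- fit_plspm(d, m)
  sc <- as.matrix(f$scores)
  for (j in 1:2) {
    expect_lt(abs(mean(sc[, j])), 1e-9)
    expect_equal(sqrt(mean((sc[, j] - mean(sc[, j]))^2)), 1, tolerance = 1e-9)
  }
  expect_true(all(abs(f$loadings$loading) <= 1 + 1e-9))
  # sign convention: mean loading positive per latent
  ml <- tapply(f$loadings$loading, f$loadings$latent, mean)
  expect_true(all(ml > 0))
})

test_that("effects decompose along directed paths", {
  mk_fit <- function(latents, B) {
    structure(list(path_coefficients = B,
                   model = list(latents = latents)), class = "plspm_fit")
  }
  # chain a -> b (0.5), b -> c (0.4): indirect a->c = 0.2
  B <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  B["b", "a"] <- 0.5; B["c", "b"] <- 0.4
  eff <- effects_decomposition(mk_fit(c("a", "b", "c"), B))
  ac <- eff[eff$from == "a" & eff$to == "c", ]
  expect_equal(ac$direct, 0)
  expect_equal(ac$indirect, 0.2)
  expect_equal(ac$total, 0.2)
  # unconnected pair: all zero
  B2 <- matrix(0, 3, 3, dimnames = dimnames(B))
  B2["b", "a"] <- 0.7
  eff2 <- effects_decomposition(mk_fit(c("a", "b", "c"), B2))
  expect_true(all(unlist(eff2[eff2$to == "c", c("direct", "indirect", "total")]) == 0))
  # diamond: a -> b, a -> c, b -> d, c -> d plus a -> d direct
  lat <- c("a", "b", "c", "d")
  B3 <- matrix(0, 4, 4, dimnames = list(lat, lat))
  B3["b", "a"] <- 0.5; B3["c", "a"] <- -0.3
  B3["d", "b"] <- 0.4; B3["d", "c"] <- 0.6; B3["d", "a"] <- 0.2
  eff3 <- effects_decomposition(mk_fit(lat, B3))
  ad <- eff3[eff3$from == "a" & eff3$to == "d", ]
  expect_equal(ad$direct, 0.2)
  expect_equal(ad$indirect, 0.5 * 0.4 + (-0.3) * 0.6) # path enumeration
  expect_equal(ad$total, ad$direct + ad$indirect)
  # identity holds on every row of a real fit
  set.seed(17)
  d <- tibble::tibble(x1 = rnorm(50), m1 = rnorm(50), y1 = rnorm(50))
  fr <- fit_plspm(d, chain_model())
  expect_equal(fr$effects$total, fr$effects$direct + fr$effects$indirect)
})

test_that("flipping one block's manifests flips its paths but not |effects|", {
  set.seed(18)
  d <- as.data.frame(matrix(rnorm(100 * 4), 100, 4))
  names(d) <- c("a1", "a2", "b1", "b2")
  d$b1 <- d$a1 + rnorm(100, 0, 0.6)
  d$b2 <- d$a1 + rnorm(100, 0, 0.6)
  m <- path_model(c("A", "B"), data.frame(from = "A", to = "B"),
                  blocks = list(A = c("a1", "a2"), B = c("b1", "b2")))
  f1 <- fit_plspm(d, m)
  d2 <- d
  d2$a1 <- -d$a1; d2$a2 <- -d$a2
  f2 <- fit_plspm(d2, m)
  expect_equal(abs(tidy(f1)$estimate), abs(tidy(f2)$estimate), tolerance = 1e-9)
  expect_equal(f1$gof, f2$gof, tolerance = 1e-9)
})

test_that("degenerate inputs are rejected", {
  set.seed(19)
  d <- tibble::tibble(x1 = rnorm(30), y1 = rnorm(30))
  m <- path_model(c("X", "Y"), data.frame(from = "X", to = "Y"),
                  blocks = list(X = "x1", Y = "y1"))
  d0 <- d; d0$x1 <- 1
  expect_error(fit_plspm(d0, m), "zero-variance")
  expect_error(path_model(c("X", "X"), data.frame(from = "X", to = "X"),
                          blocks = list(X = "x1")), "duplicated")
  # collinear predecessors
  d2 <- tibble::tibble(x1 = rnorm(40))
  d2$x2 <- d2$x1
  d2$y1 <- rnorm(40)
  m2 <- path_model(c("A", "B", "Y"),
                   data.frame(from = c("A", "B"), to = c("Y", "Y")),
                   blocks = list(A = "x1", B = "x2", Y = "y1"))
  expect_error(fit_plspm(d2, m2), "collinear")
})

test_that("parameter recovery on generated truth (quick check)", {
  pm <- matrix(0, 3, 3); pm[3, 1] <- 0.5; pm[3, 2] <- -0.3
  tr <- path_truth(c("A", "B", "C"), pm, loadings = 0.8, noise_sd = 0.6)
  mm <- list(A = paste0("a", 1:8), B = paste0("b", 1:8), C = paste0("c", 1:8))
  meta <- tibble::tibble(sample_id = as.character(1:500))
  mod <- path_model(c("A", "B", "C"),
                    data.frame(from = c("A", "B"), to = c("C", "C")),
                    blocks = mm)
  ests <- sapply(1:8, function(s) {
    g <- generate_env(meta, tr, mm, seed = 100 + s)
    tidy(fit_plspm(g$env, mod))$estimate
  })
  expect_lt(abs(mean(ests[1, ]) - 0.5), 0.07)
  expect_lt(abs(mean(ests[2, ]) + 0.3), 0.07)
})

test_that("bootstrap is deterministic and detects strong paths", {
  set.seed(20)
  d <- tibble::tibble(x1 = rnorm(200))
  d$y1 <- 0.7 * d$x1 + rnorm(200, 0, sqrt(1 - 0.49))
  m <- path_model(c("X", "Y"), data.frame(from = "X", to = "Y"),
                  blocks = list(X = "x1", Y = "y1"))
  b1 <- bootstrap_paths(d, m, n_boot = 200, seed = 5)
  b2 <- bootstrap_paths(d, m, n_boot = 200, seed = 5)
  expect_identical(b1, b2)
  expect_gt(b1$ci_low, 0) # CI excludes 0 for a strong path
  expect_lt(b1$p_value, 0.05)
  expect_error(bootstrap_paths(d, m, n_boot = 50), "at least 100")
})
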