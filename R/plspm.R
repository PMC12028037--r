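pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

std_pop <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, pop_sd)
  if (any(sdv == 0)) {
    abort(paste0("zero-variance manifest(s): ",
                 paste(colnames(X)[sdv == 0], collapse = ", "), "."))
  }
  sweep(sweep(X, 2, mu), 2, sdv, `/`)
}

#' Specify a latent path model
#'
#' Latent variables in causal order, connected by a strictly
#' lower-triangular adjacency (so the inner model is a DAG by construction),
#' each measured reflectively (mode A) by a nonempty block of manifest
#' variables.
#'
#' @param latents Character vector of latent names, in causal order.
#' @param paths Either a strictly lower-triangular 0/1 matrix
#'   (`paths[i, j] = 1` for an edge latent j -> latent i) or a data frame
#'   with `from`, `to` columns.
#' @param blocks Named list mapping every latent to its manifest variable
#'   names; every manifest belongs to exactly one block.
#' @param scheme Inner estimation scheme: `"centroid"` (default, the
#'   classical choice), `"factorial"`, or `"path"`.
#' @return A `path_model` object.
#' @export
path_model <- function(latents, paths, blocks,
                       scheme = c("centroid", "factorial", "path")) {
  scheme <- match.arg(scheme)
  L <- length(latents)
  if (anyDuplicated(latents)) abort("duplicated latent name.")
  if (is.data.frame(paths)) {
    adj <- matrix(0, L, L, dimnames = list(latents, latents))
    for (k in seq_len(nrow(paths))) {
      i <- match(paths$to[k], latents); j <- match(paths$from[k], latents)
      if (is.na(i) || is.na(j)) abort("path endpoints must be latent names.")
      adj[i, j] <- 1
    }
    paths <- adj
  }
  paths <- as.matrix(paths)
  stopifnot(nrow(paths) == L, ncol(paths) == L)
  if (any(paths[upper.tri(paths, diag = TRUE)] != 0)) {
    abort("paths must be strictly lower triangular in the latent order (DAG).")
  }
  dimnames(paths) <- list(latents, latents)
  miss <- setdiff(latents, names(blocks))
  if (length(miss) || any(lengths(blocks[latents]) < 1)) {
    abort("every latent needs a nonempty manifest block.")
  }
  mans <- unlist(blocks[latents], use.names = FALSE)
  if (anyDuplicated(mans)) abort("every manifest must appear in exactly one block.")
  connected <- rowSums(paths) + colSums(paths)
  if (any(connected == 0)) {
    abort(sprintf("latent '%s' is isolated (no inner path).",
                  latents[which(connected == 0)[1]]))
  }
  structure(list(latents = latents, paths = paths, blocks = blocks[latents],
                 scheme = scheme),
            class = "path_model")
}

# Core iterative estimation on a pre-standardized matrix. Returns outer
# weights, standardized latent scores and path coefficients; used by both
# fit_plspm() and the bootstrap loop.
plspm_engine <- function(X, model, max_iter = 300, tol = 1e-7) {
  latents <- model$latents
  L <- length(latents)
  blocks_idx <- lapply(model$blocks, function(m) match(m, colnames(X)))
  adj <- model$paths != 0
  neigh <- adj | t(adj)
  n <- nrow(X)
  scores <- matrix(0, n, L, dimnames = list(NULL, latents))
  w <- lapply(blocks_idx, function(ii) {
    y <- rowSums(X[, ii, drop = FALSE])
    rep(1 / pop_sd(y), length(ii))
  })
  for (b in seq_len(L)) {
    scores[, b] <- X[, blocks_idx[[b]], drop = FALSE] %*% w[[b]]
  }
  delta <- Inf
  for (iter in seq_len(max_iter)) {
    w_old <- unlist(w)
    C <- crossprod(scores) / n
    Z <- matrix(0, n, L)
    for (b in seq_len(L)) {
      nb <- which(neigh[b, ])
      e <- switch(model$scheme,
        centroid = sign(C[b, nb]),
        factorial = C[b, nb],
        path = {
          pred <- which(adj[b, ]); succ <- which(adj[, b])
          ee <- numeric(length(nb))
          if (length(pred)) {
            cf <- solve(C[pred, pred, drop = FALSE], C[pred, b])
            ee[match(pred, nb)] <- cf
          }
          if (length(succ)) ee[match(succ, nb)] <- C[b, succ]
          ee
        })
      e[e == 0 & model$scheme == "centroid"] <- 1 # zero correlation tie-break
      Z[, b] <- scores[, nb, drop = FALSE] %*% e
    }
    for (b in seq_len(L)) {
      Xb <- X[, blocks_idx[[b]], drop = FALSE]
      wb <- as.numeric(crossprod(Xb, Z[, b])) / n # mode A
      j <- which.max(abs(wb))
      if (wb[j] < 0) wb <- -wb # sign stabilization during iteration
      y <- Xb %*% wb
      sdv <- pop_sd(y)
      if (sdv == 0) abort("degenerate latent score (zero variance).")
      w[[b]] <- wb / sdv
      scores[, b] <- y / sdv
    }
    delta <- max(abs(unlist(w) - w_old))
    if (delta < tol) break
  }
  if (delta >= tol) {
    abort(sprintf("PLS-PM did not converge in %d iterations (last max weight change %.3g).",
                  max_iter, delta))
  }
  # orient each latent so its mean loading is positive
  for (b in seq_len(L)) {
    lo <- as.numeric(crossprod(X[, blocks_idx[[b]], drop = FALSE], scores[, b])) / n
    if (mean(lo) < 0) {
      w[[b]] <- -w[[b]]
      scores[, b] <- -scores[, b]
    }
  }
  # path coefficients by OLS of each endogenous score on its predecessors
  B <- matrix(0, L, L, dimnames = list(latents, latents))
  r2 <- setNames(rep(NA_real_, L), latents)
  C <- crossprod(scores) / n
  for (i in seq_len(L)) {
    pred <- which(adj[i, ])
    if (!length(pred)) next
    Cp <- C[pred, pred, drop = FALSE]
    if (kappa(Cp) > 1e8) abort("collinear predecessor latents.")
    beta <- solve(Cp, C[pred, i])
    B[i, pred] <- beta
    r2[i] <- as.numeric(t(beta) %*% C[pred, i])
  }
  list(weights = w, scores = scores, paths = B, r2 = r2,
       iterations = iter, blocks_idx = blocks_idx)
}

#' Fit a PLS path model
#'
#' Partial least squares path modeling, Lohmoeller style: manifests are
#' standardized (population variance, so latent scores have mean 0 and
#' population sd 1); outer weights start equal within each block; outer and
#' inner estimation alternate (mode A outer update = manifest/inner-proxy
#' covariances; inner proxy per `scheme`, centroid by default) until the
#' largest weight change falls below `tol`. Path coefficients are then OLS
#' regressions among latent scores, loadings are manifest-score
#' correlations, effects decompose along directed paths, and
#' `gof = sqrt(mean communality x mean R^2)`. Each latent's sign is fixed so
#' its mean loading is positive.
#'
#' @param data Data frame containing every manifest variable (a `sample_id`
#'   column is carried through to the scores).
#' @param model A [path_model()].
#' @param max_iter Maximum outer/inner iterations.
#' @param tol Convergence tolerance on outer weights.
#' @return A `plspm_fit` object; see [tidy.plspm_fit()],
#'   [glance.plspm_fit()], [effects_decomposition()].
#' @export
fit_plspm <- function(data, model, max_iter = 300, tol = 1e-7) {
  stopifnot(inherits(model, "path_model"))
  mans <- unlist(model$blocks, use.names = FALSE)
  miss <- setdiff(mans, names(data))
  if (length(miss)) {
    abort(paste0("manifest(s) missing from data: ", paste(miss, collapse = ", "), "."))
  }
  X <- as.matrix(as.data.frame(data)[, mans, drop = FALSE])
  if (anyNA(X)) abort("manifest data contain missing values.")
  max_pred <- max(rowSums(model$paths != 0))
  if (nrow(X) <= max_pred) abort("need more samples than predecessors of any latent.")
  Xs <- std_pop(X)
  eng <- plspm_engine(Xs, model, max_iter = max_iter, tol = tol)
  latents <- model$latents
  loadings <- purrr::imap_dfr(model$blocks, function(m, lat) {
    tibble(latent = lat, manifest = m,
           weight = eng$weights[[lat]],
           loading = as.numeric(cor(Xs[, m, drop = FALSE],
                                    eng$scores[, lat])))
  })
  scores <- tibble::as_tibble(as.data.frame(eng$scores))
  if ("sample_id" %in% names(data)) {
    scores <- dplyr::bind_cols(tibble(sample_id = as.character(data$sample_id)),
                               scores)
  }
  communality <- mean(loadings$loading^2)
  r2 <- eng$r2
  gof <- sqrt(communality * mean(r2, na.rm = TRUE))
  fit <- structure(list(model = model, weights = eng$weights,
                        loadings = loadings, scores = scores,
                        path_coefficients = eng$paths, r_squared = r2,
                        communality = communality, gof = gof,
                        iterations = eng$iterations, n = nrow(X)),
                   class = "plspm_fit")
  fit$effects <- effects_decomposition(fit)
  fit
}

#' @export
print.plspm_fit <- function(x, ...) {
  cat(sprintf("# PLS-PM fit: %d latents, n = %d, %d iterations, GoF = %.3f\n",
              length(x$model$latents), x$n, x$iterations, x$gof))
  print(tidy(x))
  invisible(x)
}

#' Tidy the inner model of a PLS-PM fit
#'
#' @param x A `plspm_fit`.
#' @param ... Unused.
#' @return Tibble of inner paths: `from`, `to`, `estimate`.
#' @exportS3Method generics::tidy
tidy.plspm_fit <- function(x, ...) {
  B <- x$path_coefficients
  idx <- which(x$model$paths != 0, arr.ind = TRUE)
  tibble(from = colnames(B)[idx[, 2]], to = rownames(B)[idx[, 1]],
         estimate = B[idx])
}

#' One-row summary of a PLS-PM fit
#'
#' @param x A `plspm_fit`.
#' @param ... Unused.
#' @return Tibble: goodness of fit, mean R-squared, mean communality,
#'   iterations, n.
#' @exportS3Method generics::glance
glance.plspm_fit <- function(x, ...) {
  tibble(gof = x$gof,
         mean_r_squared = mean(x$r_squared, na.rm = TRUE),
         mean_communality = x$communality,
         iterations = x$iterations, n = x$n)
}

#' Direct, indirect and total effects
#'
#' For every ordered latent pair (earlier -> later in the causal order):
#' direct effect = path coefficient (0 without an edge); indirect effect =
#' sum over all directed paths of length >= 2 of the product of
#' coefficients, obtained from the matrix series `(I - B)^{-1} - I`
#' (finite because the inner model is a DAG); total = direct + indirect.
#'
#' @param fit A `plspm_fit`.
#' @return Tibble: `from`, `to`, `direct`, `indirect`, `total`.
#' @export
effects_decomposition <- function(fit) {
  B <- fit$path_coefficients
  L <- nrow(B)
  total <- solve(diag(L) - B) - diag(L)
  lat <- fit$model$latents
  grid <- which(lower.tri(matrix(0, L, L)), arr.ind = TRUE)
  tibble(from = lat[grid[, 2]], to = lat[grid[, 1]],
         direct = B[grid],
         indirect = total[grid] - B[grid],
         total = total[grid])
}

#' Bootstrap inference for PLS-PM path coefficients
#'
#' Resamples rows with replacement, refits, and summarizes each path's
#' bootstrap distribution: standard error, percentile confidence interval,
#' and a two-sided percentile p-value against 0
#' (`p = 2 * min(P(b* <= 0), P(b* >= 0))`). Non-convergent resamples are
#' dropped and counted; more than 20% dropped is an error. Deterministic
#' given `seed`.
#'
#' @param data,model As in [fit_plspm()].
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @param conf Confidence level for the percentile interval.
#' @param max_iter,tol Passed to the fitting engine.
#' @return Tibble per path: `from`, `to`, `estimate`, `boot_mean`, `se`,
#'   `ci_low`, `ci_high`, `p_value`, `n_boot_used`.
#' @export
bootstrap_paths <- function(data, model, n_boot = 500, seed = 1, conf = 0.95,
                            max_iter = 300, tol = 1e-7) {
  if (n_boot < 100) abort("n_boot must be at least 100.")
  fit <- fit_plspm(data, model, max_iter = max_iter, tol = tol)
  est <- tidy(fit)
  mans <- unlist(model$blocks, use.names = FALSE)
  X <- as.matrix(as.data.frame(data)[, mans, drop = FALSE])
  idx_paths <- which(model$paths != 0, arr.ind = TRUE)
  draws <- local_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      rows <- sample.int(nrow(X), replace = TRUE)
      res <- tryCatch(
        plspm_engine(std_pop(X[rows, , drop = FALSE]), model,
                     max_iter = max_iter, tol = tol),
        error = function(e) NULL)
      if (is.null(res)) return(NULL)
      res$paths[idx_paths]
    })
  })
  ok <- !vapply(draws, is.null, logical(1))
  if (mean(!ok) > 0.2) {
    abort(sprintf("%.0f%% of bootstrap resamples failed to converge.",
                  100 * mean(!ok)))
  }
  mat <- do.call(rbind, draws[ok])
  a <- (1 - conf) / 2
  est$boot_mean <- colMeans(mat)
  est$se <- apply(mat, 2, sd)
  est$ci_low <- apply(mat, 2, quantile, probs = a)
  est$ci_high <- apply(mat, 2, quantile, probs = 1 - a)
  est$p_value <- apply(mat, 2, function(v) {
    min(1, 2 * min(mean(v <= 0), mean(v >= 0)))
  })
  est$n_boot_used <- sum(ok)
  est
}
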