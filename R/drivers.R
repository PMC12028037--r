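p_stars <- function(p) {
  dplyr::case_when(is.na(p) ~ "", p < 0.001 ~ "***", p < 0.01 ~ "**",
                   p < 0.05 ~ "*", TRUE ~ "")
}

# Spearman rho + t-approximation p for two vectors (shared with the network
# module's matrix version).
spearman_pair <- function(x, y) {
  n <- length(x)
  if (sd(x) == 0 || sd(y) == 0) return(c(rho = NA_real_, p = NA_real_))
  rho <- cor(x, y, method = "spearman")
  if (abs(rho) >= 1) return(c(rho = rho, p = 0))
  tstat <- abs(rho) * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p = 2 * pt(tstat, df = n - 2, lower.tail = FALSE))
}

#' Environmental driver correlation table
#'
#' Spearman rank correlations between every environmental variable and every
#' response (e.g. Shannon index, positive/negative/total cohesion,
#' stability), with t-approximation p-values, optional Benjamini-Hochberg
#' correction within each response column, and significance stars
#' (* p < 0.05, ** p < 0.01, *** p < 0.001, applied to q when correction is
#' on). No correction is the default, matching the reproduce-first
#' convention of raw-p heatmaps; BH is recommended when screening many
#' variables. Constant variables are flagged not-computable (`NA`).
#'
#' @param env Environmental tibble: `sample_id` + numeric variables.
#' @param responses Per-sample response tibble: `sample_id` + numeric
#'   responses, matching samples.
#' @param correction `"none"` or `"BH"` (within each response column).
#' @return A `driver_table` tibble: `variable`, `response`, `rho`, `p`, `q`,
#'   `stars`.
#' @export
driver_correlations <- function(env, responses, correction = c("none", "BH")) {
  correction <- match.arg(correction)
  if (!"sample_id" %in% names(env) || !"sample_id" %in% names(responses)) {
    abort("both tables need a sample_id column.")
  }
  if (!setequal(env$sample_id, responses$sample_id)) {
    abort("env and responses cover different samples.")
  }
  responses <- responses[match(env$sample_id, responses$sample_id), ]
  vars <- setdiff(names(env), "sample_id")
  resp <- setdiff(names(responses), "sample_id")
  grid <- tidyr::expand_grid(variable = vars, response = resp)
  out <- purrr::pmap_dfr(grid, function(variable, response) {
    est <- spearman_pair(env[[variable]], responses[[response]])
    tibble(variable = variable, response = response,
           rho = est[["rho"]], p = est[["p"]])
  })
  out <- out |>
    dplyr::group_by(.data$response) |>
    dplyr::mutate(q = p.adjust(.data$p, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::mutate(stars = p_stars(if (correction == "BH") .data$q else .data$p))
  class(out) <- c("driver_table", class(out))
  attr(out, "correction") <- correction
  out
}

#' Simple linear regression
#'
#' Ordinary least squares of `y` on `x` with the two-sided t-test on the
#' slope.
#'
#' @param x,y Numeric vectors, `n >= 3`, `var(x) > 0`.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
simple_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) abort("need at least 3 observations.")
  if (var(x) == 0) abort("x has zero variance.")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  tibble(slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r_squared = sm$r.squared,
         p_value = sm$coefficients["x", "Pr(>|t|)"],
         n = length(x))
}
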