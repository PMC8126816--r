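#' Exact two-sided Mann-Whitney test
#'
#' Rank-sum comparison of two small groups, the workhorse test for
#' per-subject imaging and emissions metrics at n = 3-6 per arm. The U
#' statistic counts pairwise wins of the first group over the second, ties
#' counting one half. For pooled sizes `n_a + n_b <= max_exact` the null
#' distribution of U is obtained by exhaustive enumeration of all
#' `choose(n_a + n_b, n_a)` group assignments of the observed pooled values
#' (a conditional exact test, valid under ties); the two-sided p-value is
#' twice the smaller tail probability, capped at 1. With complete separation
#' at n = 4 vs 4 this gives p = 2/70 = 0.0286, the smallest level the design
#' can achieve. Larger samples fall back to the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param values_a,values_b Numeric per-subject metric values (non-empty).
#' @param labels Length-2 character vector of group names.
#' @param max_exact Largest pooled size for which enumeration is used.
#' @return An object of class `mw_exact` with fields `labels`, `values_a`,
#'   `values_b`, `u_statistic`, `p_two_sided`, `method`. See [tidy.mw_exact()].
#' @examples
#' mann_whitney_exact(c(2.1, 2.3, 2.0, 2.5), c(1.2, 1.3, 1.1, 1.4))  # p = 0.0286
#' @export
mann_whitney_exact <- function(values_a, values_b, labels = c("A", "B"),
                               max_exact = 14L) {
  if (!length(values_a) || !length(values_b)) abort("both groups must be non-empty.")
  if (!is.numeric(values_a) || !is.numeric(values_b) ||
      anyNA(values_a) || anyNA(values_b)) {
    abort("group values must be numeric with no missing values.")
  }
  n_a <- length(values_a); n_b <- length(values_b); n <- n_a + n_b
  pooled <- c(values_a, values_b)
  r <- rank(pooled)                      # midranks under ties
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  if (n <= max_exact) {
    assign_a <- utils::combn(n, n_a)
    u_null <- colSums(matrix(r[assign_a], nrow = n_a)) - n_a * (n_a + 1) / 2
    eps <- 1e-9
    p_lo <- mean(u_null <= u_obs + eps)
    p_hi <- mean(u_null >= u_obs - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact enumeration"
  } else {
    mu <- n_a * n_b / 2
    ties <- table(pooled)
    correction <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n_a * n_b / 12 * (n + 1 - correction))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (abs(u_obs - mu) - 0.5) / sigma    # continuity-corrected
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal approximation"
  }
  structure(
    list(labels = labels, values_a = values_a, values_b = values_b,
         n_a = n_a, n_b = n_b, u_statistic = u_obs, p_two_sided = p,
         method = method),
    class = "mw_exact"
  )
}

#' @export
print.mw_exact <- function(x, ...) {
  cat(sprintf("Mann-Whitney (%s): %s (n=%d) vs %s (n=%d)\n",
              x$method, x$labels[1], x$n_a, x$labels[2], x$n_b))
  cat(sprintf("  U = %g, two-sided p = %.4g\n", x$u_statistic, x$p_two_sided))
  invisible(x)
}

#' One-way ANOVA with Dunnett many-to-one comparisons against a control
#'
#' Histology damage scores and similar endpoints are compared across several
#' treatment arms against a shared naive/control arm: a one-way ANOVA
#' (pooled-variance F) followed by Dunnett's multiple-comparison procedure.
#' Dunnett-adjusted two-sided p-values are computed from the null
#' distribution of the maximum absolute Dunnett t statistic, estimated by
#' seeded Monte-Carlo: each draw simulates group means from their null
#' normal distributions and an independent pooled variance from its
#' chi-squared distribution, preserving the correlation induced by the
#' shared control and the uncertainty of the variance estimate. With exactly
#' two groups the procedure reduces to the pooled two-sample t-test (a
#' closed form the Monte-Carlo estimate converges to).
#'
#' Degenerate input with zero residual variance (e.g. an all-zero damage
#' table) is reported as p = 1 everywhere with a warning rather than an
#' error, so uniformly undamaged cohorts aggregate cleanly.
#'
#' @param data Data frame with one row per analysis unit.
#' @param value,group Columns (unquoted) holding the metric and arm label.
#' @param control Label of the control arm.
#' @param ndraws Monte-Carlo draws for the max-|t| null (default 1e5).
#' @param seed Integer seed making the adjustment reproducible.
#' @return An object of class `dunnett_mc`: ANOVA `f`/`p`/dfs and a
#'   `comparisons` tibble (group, estimate = mean difference from control,
#'   t, unadjusted two-sided t p, Dunnett-adjusted p). See
#'   [tidy.dunnett_mc()].
#' @examples
#' d <- data.frame(score = c(0, 0, 1, 0, 2, 3, 2, 3),
#'                 arm = rep(c("naive", "treated"), each = 4))
#' anova_dunnett(d, score, arm, control = "naive", seed = 1)
#' @export
anova_dunnett <- function(data, value, group, control, ndraws = 1e5, seed = 1L) {
  stopifnot(is.data.frame(data))
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- as.character(rlang::eval_tidy(rlang::enquo(group), data))
  if (!is.numeric(v)) abort("`value` must be numeric.")
  if (!control %in% g) abort(sprintf("control group '%s' not found.", control))
  sizes <- table(g)
  if (any(sizes < 2L)) abort("every group needs at least 2 values for the ANOVA.")
  if (length(sizes) < 2L) abort("at least two groups (control + one) are required.")
  ndraws <- check_count(ndraws, "ndraws")

  others <- setdiff(names(sizes), control)
  k <- length(sizes)
  n_tot <- length(v)
  df_err <- n_tot - k
  means <- tapply(v, g, mean)
  ss_err <- sum(tapply(v, g, function(x) sum((x - mean(x))^2)))
  ms_err <- ss_err / df_err
  grand <- mean(v)
  ss_grp <- sum(sizes * (means[names(sizes)] - grand)^2)
  ms_grp <- ss_grp / (k - 1)

  if (ms_err <= 0) {
    warn("zero residual variance: reporting p = 1 for the ANOVA and all comparisons.")
    comparisons <- tibble(group = others,
                          estimate = as.numeric(means[others] - means[control]),
                          t = NA_real_, p_unadjusted = 1, p_adjusted = 1)
    return(new_dunnett(control, comparisons, f = NA_real_, p = 1,
                       df1 = k - 1L, df2 = df_err, ms_error = 0,
                       ndraws = ndraws, seed = seed))
  }

  f <- ms_grp / ms_err
  p_f <- stats::pf(f, k - 1, df_err, lower.tail = FALSE)
  se <- sqrt(ms_err * (1 / sizes[others] + 1 / sizes[control]))
  est <- means[others] - means[control]
  t_obs <- as.numeric(est / se)
  p_unadj <- 2 * pt(-abs(t_obs), df_err)

  # Null of max_i |T_i|: group means ~ N(0, 1/n_i), shared control mean,
  # pooled SD ~ sqrt(chisq_df/df); all draws independent across replicates.
  n_ctl <- as.numeric(sizes[control])
  n_oth <- as.numeric(sizes[others])
  max_abs_t <- with_seed_(derive_seed(seed), {
    z_ctl <- rnorm(ndraws, 0, 1 / sqrt(n_ctl))
    s <- sqrt(rchisq(ndraws, df_err) / df_err)
    m <- matrix(0, ndraws, length(others))
    for (j in seq_along(others)) {
      z_j <- rnorm(ndraws, 0, 1 / sqrt(n_oth[j]))
      m[, j] <- abs(z_j - z_ctl) / (s * sqrt(1 / n_oth[j] + 1 / n_ctl))
    }
    apply(m, 1, max)
  })
  p_adj <- vapply(t_obs, function(tt) mean(max_abs_t >= abs(tt)), numeric(1))

  comparisons <- tibble(group = others, estimate = as.numeric(est),
                        t = t_obs, p_unadjusted = as.numeric(p_unadj),
                        p_adjusted = p_adj)
  new_dunnett(control, comparisons, f = f, p = p_f, df1 = k - 1L,
              df2 = df_err, ms_error = ms_err, ndraws = ndraws, seed = seed)
}

new_dunnett <- function(control, comparisons, f, p, df1, df2, ms_error,
                        ndraws, seed) {
  structure(
    list(control = control, comparisons = comparisons, f = f, p = p,
         df1 = df1, df2 = df2, ms_error = ms_error, ndraws = ndraws,
         seed = seed),
    class = "dunnett_mc"
  )
}

#' @export
print.dunnett_mc <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$f, x$p))
  cat(sprintf("Dunnett comparisons vs '%s' (Monte-Carlo, %d draws):\n",
              x$control, x$ndraws))
  print(x$comparisons)
  invisible(x)
}

#' The semi-quantitative histology damage rubric
#'
#' Ordinal 0-3 scale used to score each high-power field for red-blood-cell
#' extravasation and for vacuolation: 0 = none (complete absence),
#' 1 = mild (sparse small sites), 2 = moderate (singular large or multiple
#' small sites), 3 = severe (multiple large sites).
#'
#' @return Tibble with columns `value` (0:3) and `label`.
#' @export
damage_rubric <- function() {
  tibble(value = 0:3, label = c("none", "mild", "moderate", "severe"))
}

#' Aggregate ordinal damage scores hierarchically
#'
#' Damage scoring is nested: several 20x images per tissue section, several
#' sections per subject. Scores are averaged up the hierarchy
#' (image -> section -> subject) to the requested `level`, then summarized
#' per group and endpoint as mean and SEM over the units at that level
#' (SEM = SD / sqrt(n); 0 when a single unit). Which level is the right unit
#' of inference depends on the design, so all three are exposed.
#'
#' @param scores Data frame with columns `group`, `subject_id`, `section_id`,
#'   `image_id`, `endpoint` (e.g. `"rbc_extravasation"`, `"vacuolation"`),
#'   `score` (integers in 0:3, see [damage_rubric()]).
#' @param level Aggregation unit: `"image"`, `"section"` or `"subject"`.
#' @return Tibble: `group`, `endpoint`, `level`, `n` (units), `mean`, `sem`.
#' @examples
#' df <- data.frame(group = "FUS", subject_id = "m1", section_id = "s1",
#'                  image_id = paste0("i", 1:4),
#'                  endpoint = "vacuolation", score = c(0, 1, 2, 3))
#' aggregate_scores(df, level = "image")  # mean 1.5, sem 0.6455
#' @export
aggregate_scores <- function(scores, level = c("image", "section", "subject")) {
  level <- match.arg(level)
  need <- c("group", "subject_id", "section_id", "image_id", "endpoint", "score")
  if (!all(need %in% names(scores))) {
    abort(sprintf("`scores` must have columns %s.", paste(need, collapse = ", ")))
  }
  if (!all(scores$score %in% 0:3)) {
    abort("scores must be integers in 0:3 (none/mild/moderate/severe rubric).")
  }
  by_image <- scores |>
    dplyr::group_by(.data$group, .data$endpoint, .data$subject_id,
                    .data$section_id, .data$image_id) |>
    dplyr::summarise(value = mean(.data$score), .groups = "drop")
  units <- switch(
    level,
    image = by_image,
    section = by_image |>
      dplyr::group_by(.data$group, .data$endpoint, .data$subject_id,
                      .data$section_id) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop"),
    subject = by_image |>
      dplyr::group_by(.data$group, .data$endpoint, .data$subject_id,
                      .data$section_id) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
      dplyr::group_by(.data$group, .data$endpoint, .data$subject_id) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  )
  units |>
    dplyr::group_by(.data$group, .data$endpoint) |>
    dplyr::summarise(
      level = level, n = dplyr::n(), mean = mean(.data$value),
      sem = if (dplyr::n() > 1L) sd(.data$value) / sqrt(dplyr::n()) else 0,
      .groups = "drop"
    )
}
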