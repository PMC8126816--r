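#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Mann-Whitney comparison
#'
#' @param x An `mw_exact` object from [mann_whitney_exact()].
#' @param ... Unused.
#' @return One-row tibble: group labels and sizes, `u_statistic`,
#'   `p_two_sided`, `method`.
#' @method tidy mw_exact
#' @export
tidy.mw_exact <- function(x, ...) {
  tibble(group_a = x$labels[1], group_b = x$labels[2],
         n_a = x$n_a, n_b = x$n_b,
         u_statistic = x$u_statistic, p_two_sided = x$p_two_sided,
         method = x$method)
}

#' @rdname tidy.mw_exact
#' @method glance mw_exact
#' @export
glance.mw_exact <- function(x, ...) tidy(x, ...)

#' Tidy Dunnett many-to-one comparisons
#'
#' `tidy()` returns one row per non-control group (estimate, t, unadjusted
#' and Dunnett-adjusted p); `glance()` returns the one-way ANOVA summary.
#'
#' @param x A `dunnett_mc` object from [anova_dunnett()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy dunnett_mc
#' @export
tidy.dunnett_mc <- function(x, ...) {
  dplyr::mutate(x$comparisons, control = x$control, .before = 1)
}

#' @rdname tidy.dunnett_mc
#' @method glance dunnett_mc
#' @export
glance.dunnett_mc <- function(x, ...) {
  tibble(statistic = x$f, p_value = x$p, df = x$df1, df_residual = x$df2,
         ms_error = x$ms_error, n_comparisons = nrow(x$comparisons),
         mc_draws = x$ndraws)
}
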