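#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_raster
#'   geom_errorbar geom_point labs scale_fill_viridis_c theme_minimal
#'   position_dodge coord_fixed
#' @export
ggplot2::autoplot

#' Plot an amplitude spectrum
#'
#' Line plot of the single-sided amplitude spectrum of a burst, frequency in
#' MHz. Restrict with `fmax` to zoom on the band region of interest.
#'
#' @param object A `cavi_spectrum` tibble from [amplitude_spectrum()].
#' @param fmax Optional upper frequency limit, Hz.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cavi_spectrum
#' @export
autoplot.cavi_spectrum <- function(object, fmax = NULL, ...) {
  d <- if (is.null(fmax)) object else object[object$frequency <= fmax, ]
  ggplot(d, aes(x = .data$frequency / 1e6, y = .data$amplitude)) +
    geom_line(linewidth = 0.3) +
    labs(x = "Frequency (MHz)", y = "Amplitude (V)") +
    theme_minimal()
}

#' Plot a cavitation dose profile
#'
#' Bar chart of per-band dose (V s, or dimensionless when normalized).
#'
#' @param object A `dose_profile` from [accumulate_dose()] /
#'   [normalize_dose()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dose_profile
#' @export
autoplot.dose_profile <- function(object, ...) {
  ylab <- if (is_normalized(object)) "Normalized dose" else
    expression("Cavitation dose (V" %.% "s)")
  ggplot(as_tibble(object), aes(x = .data$band, y = .data$dose)) +
    geom_col(fill = "grey35") +
    labs(x = "Band", y = ylab) +
    theme_minimal()
}

#' Plot a hemisphere phantom
#'
#' Intensity raster of the phantom image (row 1 at the top).
#'
#' @param object A `hemisphere_phantom`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hemisphere_phantom
#' @export
autoplot.hemisphere_phantom <- function(object, ...) {
  img <- object$image
  d <- tibble(
    row = rep(seq_len(nrow(img)), times = ncol(img)),
    col = rep(seq_len(ncol(img)), each = nrow(img)),
    intensity = as.vector(img)
  )
  ggplot(d, aes(x = .data$col, y = -.data$row, fill = .data$intensity)) +
    geom_raster() +
    scale_fill_viridis_c(name = "Intensity") +
    coord_fixed() +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot a band-wise group comparison
#'
#' Group mean with SEM error bars per band, as produced by
#' [compare_emissions()].
#'
#' @param comparison Tibble from [compare_emissions()].
#' @return A ggplot.
#' @export
plot_group_comparison <- function(comparison) {
  long <- dplyr::bind_rows(
    tibble(band = comparison$band, group = comparison$group_a,
           mean = comparison$mean_a, sem = comparison$sem_a),
    tibble(band = comparison$band, group = comparison$group_b,
           mean = comparison$mean_b, sem = comparison$sem_b)
  )
  ggplot(long, aes(x = .data$band, y = .data$mean, fill = .data$group)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem),
                  position = position_dodge(width = 0.8), width = 0.25) +
    labs(x = "Band", y = "Group mean (+/- SEM)", fill = NULL) +
    theme_minimal()
}

#' Plot aggregated damage scores
#'
#' Mean with SEM error bars per group and endpoint, as produced by
#' [aggregate_scores()].
#'
#' @param summary_tbl Tibble from [aggregate_scores()].
#' @return A ggplot.
#' @export
plot_damage_scores <- function(summary_tbl) {
  ggplot(summary_tbl,
         aes(x = .data$group, y = .data$mean, fill = .data$endpoint)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem),
                  position = position_dodge(width = 0.8), width = 0.25) +
    labs(x = NULL, y = "Damage score (mean +/- SEM)", fill = NULL) +
    theme_minimal()
}
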