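#' Generate a hemisphere contrast-enhancement phantom
#'
#' Synthetic stand-in for a contrast-enhanced grayscale brain slice after
#' unilateral blood-brain-barrier opening: both hemispheres sit at a common
#' background intensity, and a contiguous region of interest covering
#' `roi_fraction` of the treated hemisphere is raised to
#' `background * enhancement_factor` (gadolinium leakage through the opened
#' barrier), with optional zero-mean Gaussian pixel noise. Hemispheres are
#' the left and right halves of the image split at the midline column
#' (row-major, origin top-left); the ROI is the top rows of the treated
#' half. The noiseless hemisphere-mean fold is analytic:
#' `1 + roi_fraction * (enhancement_factor - 1)`.
#'
#' Noisy intensities are clipped at 0 to keep the image physical; keep
#' `noise_sd` well below `background` so clipping is negligible and the fold
#' estimator stays unbiased.
#'
#' @param nrow,ncol Image dimensions in pixels; `ncol` must be even.
#' @param background Background intensity (arbitrary units > 0).
#' @param enhancement_factor Intensity multiplier inside the ROI (>= 1).
#' @param roi_fraction Fraction (0, 1] of the treated hemisphere enhanced.
#' @param noise_sd SD of added Gaussian pixel noise (>= 0).
#' @param treated_side `"left"` or `"right"`.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return An object of class `hemisphere_phantom`: `image`, `treated_mask`
#'   and `contralateral_mask` matrices plus the generation parameters and
#'   the analytic noiseless fold `fold_expected`.
#' @examples
#' ph <- generate_enhancement_phantom(enhancement_factor = 3, roi_fraction = 0.25)
#' enhancement_fold(ph)$fold  # 1.5
#' @export
generate_enhancement_phantom <- function(nrow = 128, ncol = 128,
                                         background = 100,
                                         enhancement_factor = 2,
                                         roi_fraction = 0.5,
                                         noise_sd = 0,
                                         treated_side = c("left", "right"),
                                         seed = 0L) {
  treated_side <- match.arg(treated_side)
  nrow <- check_count(nrow, "nrow", min = 2L)
  ncol <- check_count(ncol, "ncol", min = 2L)
  if (ncol %% 2L) abort("`ncol` must be even so the midline splits the image.")
  check_number(background, "background", min = 0, strict = TRUE)
  check_number(enhancement_factor, "enhancement_factor", min = 1)
  check_number(roi_fraction, "roi_fraction", min = 0, strict = TRUE)
  if (roi_fraction > 1) abort("`roi_fraction` must be in (0, 1].")
  check_number(noise_sd, "noise_sd", min = 0)

  half <- ncol %/% 2L
  left_cols <- seq_len(half)
  right_cols <- half + seq_len(half)
  treated_cols <- if (treated_side == "left") left_cols else right_cols
  contra_cols <- if (treated_side == "left") right_cols else left_cols

  mask <- function(cols) {
    m <- matrix(FALSE, nrow, ncol); m[, cols] <- TRUE; m
  }
  treated_mask <- mask(treated_cols)
  contra_mask <- mask(contra_cols)

  image <- matrix(background, nrow, ncol)
  # contiguous ROI: top rows of the treated half, rounded to whole pixels
  n_roi <- round(roi_fraction * nrow * half)
  if (n_roi >= 1L) {
    roi_rows_full <- n_roi %/% half
    remainder <- n_roi %% half
    if (roi_rows_full >= 1L) {
      image[seq_len(roi_rows_full), treated_cols] <- background * enhancement_factor
    }
    if (remainder >= 1L) {
      image[roi_rows_full + 1L, treated_cols[seq_len(remainder)]] <-
        background * enhancement_factor
    }
  }
  if (noise_sd > 0) {
    image <- image + with_seed_(derive_seed(seed),
                                matrix(rnorm(nrow * ncol, 0, noise_sd), nrow, ncol))
    image[image < 0] <- 0
  }
  structure(
    list(image = image, treated_mask = treated_mask,
         contralateral_mask = contra_mask,
         background = background, enhancement_factor = enhancement_factor,
         roi_fraction = roi_fraction, noise_sd = noise_sd,
         treated_side = treated_side, seed = seed,
         fold_expected = 1 + roi_fraction * (enhancement_factor - 1)),
    class = "hemisphere_phantom"
  )
}

#' @export
print.hemisphere_phantom <- function(x, ...) {
  cat(sprintf("<hemisphere_phantom> %d x %d, %s hemisphere treated\n",
              nrow(x$image), ncol(x$image), x$treated_side))
  cat(sprintf("  enhancement %g over %.0f%% of hemisphere, noise sd %g; expected fold %.4g\n",
              x$enhancement_factor, 100 * x$roi_fraction, x$noise_sd,
              x$fold_expected))
  invisible(x)
}

#' Hemisphere enhancement fold of a contrast image
#'
#' Quantifies blood-brain-barrier disruption as the fold difference in mean
#' grayscale signal intensity between the treated hemisphere and the
#' contralateral (untreated) hemisphere of the same image, the contralateral
#' side serving as the internal reference. Invariant under global intensity
#' rescaling.
#'
#' @param image A numeric intensity matrix, or a `hemisphere_phantom` (whose
#'   masks are then used).
#' @param treated_mask,contralateral_mask Logical (or 0/1) matrices matching
#'   `image`; disjoint and non-empty. Default to the left/right halves of
#'   the image split at the midline column when both are `NULL`.
#' @return One-row tibble: `mean_treated`, `mean_contralateral`, `fold`,
#'   `n_pixels_treated`, `n_pixels_contralateral`.
#' @examples
#' img <- matrix(100, 64, 64); img[, 1:32] <- 200
#' enhancement_fold(img)  # fold 2 (left half treated by default)
#' @export
enhancement_fold <- function(image, treated_mask = NULL,
                             contralateral_mask = NULL) {
  if (inherits(image, "hemisphere_phantom")) {
    if (is.null(treated_mask)) treated_mask <- image$treated_mask
    if (is.null(contralateral_mask)) contralateral_mask <- image$contralateral_mask
    image <- image$image
  }
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("`image` must be a numeric matrix.")
  }
  if (is.null(treated_mask) && is.null(contralateral_mask)) {
    half <- ncol(image) %/% 2L
    treated_mask <- col(image) <= half
    contralateral_mask <- col(image) > half & col(image) <= 2L * half
  }
  for (m in list(treated_mask, contralateral_mask)) {
    if (length(m) != length(image)) abort("mask dimensions must match the image.")
  }
  treated_mask <- as.logical(treated_mask); dim(treated_mask) <- dim(image)
  contralateral_mask <- as.logical(contralateral_mask)
  dim(contralateral_mask) <- dim(image)
  for (m in list(treated_mask, contralateral_mask)) {
    if (!any(m)) abort("masks must be non-empty.")
  }
  if (any(treated_mask & contralateral_mask)) abort("masks must be disjoint.")
  mt <- mean(image[treated_mask])
  mc <- mean(image[contralateral_mask])
  if (mc <= 0) abort("contralateral mean intensity must be > 0.")
  tibble(mean_treated = mt, mean_contralateral = mc, fold = mt / mc,
         n_pixels_treated = sum(treated_mask),
         n_pixels_contralateral = sum(contralateral_mask))
}

#' Compare per-subject enhancement folds between two groups
#'
#' Group mean with SEM and the exact two-sided Mann-Whitney p-value on
#' per-subject hemisphere folds.
#'
#' @param data Data frame with one row per subject.
#' @param fold,group Columns (unquoted) holding the fold and the arm label.
#' @return One-row tibble: per-group mean/SEM/n, `u`, `p`, `method`.
#' @examples
#' d <- data.frame(fold = c(2.1, 2.3, 2.0, 2.5, 1.2, 1.3, 1.1, 1.4),
#'                 arm = rep(c("Iso", "KD"), each = 4))
#' group_enhancement(d, fold, arm)  # p = 0.0286
#' @export
group_enhancement <- function(data, fold, group) {
  stopifnot(is.data.frame(data))
  v <- rlang::eval_tidy(rlang::enquo(fold), data)
  g <- as.character(rlang::eval_tidy(rlang::enquo(group), data))
  groups <- unique(g)
  if (length(groups) != 2L) abort("exactly two groups are required.")
  va <- v[g == groups[1]]; vb <- v[g == groups[2]]
  mw <- mann_whitney_exact(va, vb, labels = groups)
  sem <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_
  tibble(group_a = groups[1], mean_a = mean(va), sem_a = sem(va), n_a = length(va),
         group_b = groups[2], mean_b = mean(vb), sem_b = sem(vb), n_b = length(vb),
         u = mw$u_statistic, p = mw$p_two_sided, method = mw$method)
}
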