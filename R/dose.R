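#' Accumulate per-burst Vrms into a treatment-level cavitation dose
#'
#' The cavitation dose of a band over a treatment is the sum over bursts of
#' that band's Vrms times the individual sonication (burst) duration, in
#' volt-seconds. Stable cavitation is tracked through the narrowband doses,
#' inertial cavitation through the broadband dose.
#'
#' @param records Per-burst band table from [analyze_treatment()]: columns
#'   `burst_index`, `band`, `vrms`, `duration`.
#' @return A `dose_profile`: a tibble with columns `band` and `dose` (V s),
#'   one row per band, plus attributes `normalized = FALSE` and `n_bursts`.
#'   An empty record table yields an all-zero profile over the table's band
#'   levels.
#' @examples
#' sched <- treatment_schedule(total_duration = 6)
#' tr <- synthesize_treatment(emission_model(c("2" = 0.5)), sched, seed = 1)
#' tr |> analyze_treatment(spectral_bands(1.1e6)) |> accumulate_dose()
#' @export
accumulate_dose <- function(records) {
  need <- c("band", "vrms", "duration")
  if (!all(need %in% names(records))) {
    abort("`records` must have columns band, vrms, duration (see analyze_treatment()).")
  }
  if (any(records$vrms < 0) || any(records$duration <= 0)) {
    abort("vrms must be >= 0 and durations > 0.")
  }
  band <- if (is.factor(records$band)) records$band
          else factor(records$band, levels = unique(records$band))
  out <- records |>
    dplyr::mutate(band = band) |>
    dplyr::group_by(band, .drop = FALSE) |>
    dplyr::summarise(dose = sum(.data$vrms * .data$duration), .groups = "drop")
  n_bursts <- if (nrow(records)) dplyr::n_distinct(records$burst_index) else 0L
  new_dose_profile(out, normalized = FALSE, n_bursts = n_bursts)
}

new_dose_profile <- function(tbl, normalized, n_bursts, baseline_id = NULL) {
  structure(as_tibble(tbl),
            normalized = normalized, n_bursts = n_bursts,
            baseline_id = baseline_id,
            class = c("dose_profile", class(as_tibble(tbl))))
}

#' @export
print.dose_profile <- function(x, ...) {
  cat(sprintf("<dose_profile> %s, %d bursts\n",
              if (isTRUE(attr(x, "normalized"))) "normalized (dimensionless)"
              else "raw (V s)",
              attr(x, "n_bursts")))
  NextMethod()
}

#' Is a dose profile baseline-normalized?
#' @param x A `dose_profile`.
#' @return Logical flag.
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

#' Normalize a treatment dose profile against a matched baseline
#'
#' Emissions recorded with microbubbles at treatment pressure are reported
#' relative to a matched low-pressure scan without microbubbles (see
#' [generate_baseline()]): each band's dose is divided by the corresponding
#' baseline dose, giving dimensionless per-band ratios. Hydrophone
#' sensitivity cancels in the ratio. Dividing by a silent band is refused:
#' every baseline dose used as a denominator must exceed `floor`.
#'
#' @param treatment,baseline Unnormalized `dose_profile`s over the same band
#'   set (same schedule, processed identically).
#' @param floor Numeric floor (V s) below which a baseline dose counts as
#'   silent; the default 1e-12 only rejects exact or machine-level zeros.
#' @return A normalized `dose_profile` (dimensionless `dose` column).
#' @examples
#' sched <- treatment_schedule(total_duration = 6)
#' bands <- spectral_bands(1.1e6)
#' trt <- synthesize_treatment(
#'   emission_model(c("1" = 0.5, "2" = 0.2), noise_floor_rms = 1e-4),
#'   sched, seed = 1) |> analyze_treatment(bands) |> accumulate_dose()
#' bl <- generate_baseline(sched, seed = 2) |>
#'   analyze_treatment(bands) |> accumulate_dose()
#' normalize_dose(trt, bl)
#' @export
normalize_dose <- function(treatment, baseline, floor = 1e-12) {
  stopifnot(inherits(treatment, "dose_profile"), inherits(baseline, "dose_profile"))
  if (is_normalized(treatment) || is_normalized(baseline)) {
    abort("both profiles must be unnormalized dose profiles.")
  }
  if (!identical(as.character(treatment$band), as.character(baseline$band))) {
    abort("band sets of treatment and baseline profiles do not match.")
  }
  silent <- baseline$dose <= floor
  if (any(silent)) {
    abort(sprintf(
      "baseline dose is zero/near-zero in band(s) %s; regenerate the baseline with a noise floor.",
      paste(as.character(baseline$band)[silent], collapse = ", ")))
  }
  out <- tibble(band = treatment$band, dose = treatment$dose / baseline$dose)
  new_dose_profile(out, normalized = TRUE, n_bursts = attr(treatment, "n_bursts"),
                   baseline_id = attr(baseline, "n_bursts"))
}

#' Analyze, accumulate and normalize a whole group study
#'
#' Convenience pipeline for the output of [generate_group_study()]: every
#' subject's recording is analyzed into a per-burst band table, accumulated
#' into a dose profile, and normalized against the shared baseline profile.
#'
#' @param study Tibble from [generate_group_study()] (`subject`, `group`,
#'   `recording` list-column).
#' @param bands A [spectral_bands()].
#' @param baseline Unnormalized baseline `dose_profile` shared by all
#'   subjects, or `NULL` to return raw doses.
#' @param method Vrms estimator, see [band_vrms()].
#' @return Tidy tibble: `subject`, `group`, `band`, `dose`, `normalized`.
#' @export
study_dose_table <- function(study, bands, baseline = NULL,
                             method = c("peak", "rms")) {
  method <- match.arg(method)
  stopifnot(all(c("subject", "group", "recording") %in% names(study)))
  purrr::map2_dfr(study$recording, seq_len(nrow(study)), function(rec, i) {
    prof <- accumulate_dose(analyze_treatment(rec, bands, method))
    if (!is.null(baseline)) prof <- normalize_dose(prof, baseline)
    tibble(subject = study$subject[i], group = study$group[i],
           band = prof$band, dose = prof$dose,
           normalized = is_normalized(prof))
  })
}

#' Compare normalized emission doses between two groups, band by band
#'
#' For each requested band, runs the exact two-sided Mann-Whitney test (see
#' [mann_whitney_exact()]) on per-subject normalized doses and reports group
#' mean with SEM. The default report covers the bands usually shown for
#' microbubble treatments — the 2nd, 3rd and 4th harmonics and the broadband
#' residual — though any band present in the table may be requested.
#'
#' @param dose_table Tidy per-subject dose table (e.g. from
#'   [study_dose_table()]): columns `subject`, `group`, `band`, `dose`,
#'   `normalized`. Exactly two groups; all doses must be normalized.
#' @param bands Character vector of band labels to report.
#' @return A tibble with one row per band: group means and SEMs, the
#'   Mann-Whitney `u` statistic and exact two-sided `p`.
#' @export
compare_emissions <- function(dose_table,
                              bands = c("2f", "3f", "4f", "broadband")) {
  need <- c("subject", "group", "band", "dose", "normalized")
  if (!all(need %in% names(dose_table))) {
    abort("`dose_table` must have columns subject, group, band, dose, normalized.")
  }
  if (!nrow(dose_table)) abort("`dose_table` is empty.")
  if (!all(dose_table$normalized)) {
    abort("doses must be baseline-normalized before group comparison.")
  }
  groups <- unique(as.character(dose_table$group))
  if (length(groups) != 2L) abort("exactly two groups are required.")
  missing <- setdiff(bands, as.character(unique(dose_table$band)))
  if (length(missing)) {
    abort(sprintf("band(s) not present in the dose table: %s",
                  paste(missing, collapse = ", ")))
  }
  sem <- function(v) if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_
  purrr::map_dfr(bands, function(b) {
    sub <- dplyr::filter(dose_table, as.character(band) == b)
    va <- sub$dose[sub$group == groups[1]]
    vb <- sub$dose[sub$group == groups[2]]
    mw <- mann_whitney_exact(va, vb, labels = groups)
    tibble(band = b,
           group_a = groups[1], mean_a = mean(va), sem_a = sem(va),
           group_b = groups[2], mean_b = mean(vb), sem_b = sem(vb),
           n_a = length(va), n_b = length(vb),
           u = mw$u_statistic, p = mw$p_two_sided,
           method = mw$method)
  })
}
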