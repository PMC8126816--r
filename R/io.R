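#' Construct a continuous (unsegmented) recording
#'
#' Acquisition-side representation of a hydrophone record before burst
#' segmentation: one long voltage series at a uniform rate.
#'
#' @param samples Numeric voltage samples.
#' @param sampling_rate Sampling rate, Hz.
#' @param source Optional file reference (metadata).
#' @return An object of class `continuous_recording`.
#' @export
continuous_recording <- function(samples, sampling_rate, source = NULL) {
  if (!is.numeric(samples) || length(samples) < 2L) {
    abort("`samples` must be a numeric vector with at least 2 elements.")
  }
  check_number(sampling_rate, "sampling_rate", min = 0, strict = TRUE)
  structure(
    list(samples = as.numeric(samples), sampling_rate = sampling_rate,
         total_duration = length(samples) / sampling_rate, source = source),
    class = "continuous_recording"
  )
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d samples @ %g MHz (%.4g s)\n",
              length(x$samples), x$sampling_rate / 1e6, x$total_duration))
  invisible(x)
}

#' Flatten a treatment recording into one continuous series
#'
#' Places each burst at its scheduled offset in a zero-padded continuous
#' series spanning the full treatment (inter-burst gaps are silent). Useful
#' for exercising burst segmentation and for single-stream export.
#'
#' @param treatment A `treatment_recording`.
#' @return A [continuous_recording()].
#' @export
flatten_treatment <- function(treatment) {
  stopifnot(inherits(treatment, "treatment_recording"))
  sched <- treatment$schedule
  fs <- sched$sampling_rate
  n_total <- ceiling(sched$n_bursts / sched$prf * fs)
  x <- numeric(n_total)
  for (b in treatment$bursts) {
    start <- round(b$start_time * fs)
    x[start + seq_along(b$samples)] <- b$samples
  }
  continuous_recording(x, fs)
}

#' Segment a continuous recording into bursts
#'
#' With a schedule, cuts the half-open windows
#' `[k/prf, k/prf + burst_duration)` for `k = 0 ... n_bursts - 1`. Without
#' one, detects bursts from the short-time energy profile: frames whose RMS
#' exceeds `threshold_factor` times the noise-floor estimate (the median
#' frame RMS) are marked active, contiguous active runs become bursts, and
#' each boundary is then refined to the first/last sample whose magnitude
#' exceeds the amplitude threshold.
#'
#' @param rec A [continuous_recording()].
#' @param schedule A [treatment_schedule()], or `NULL` for detection mode.
#' @param threshold_factor Energy threshold as a multiple of the noise-floor
#'   estimate (detection mode).
#' @param frame_samples Frame length for the short-time energy profile.
#' @return A `treatment_recording` (with `schedule = NULL` in detection
#'   mode).
#' @export
segment_bursts <- function(rec, schedule = NULL, threshold_factor = 5,
                           frame_samples = 256L) {
  stopifnot(inherits(rec, "continuous_recording"))
  x <- rec$samples
  fs <- rec$sampling_rate
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "treatment_schedule"))
    if (abs(fs - schedule$sampling_rate) > 1e-9 * fs) {
      abort("recording and schedule sampling rates differ.")
    }
    n_b <- schedule$samples_per_burst
    if (length(x) < n_b) abort("recording is shorter than one scheduled burst.")
    k_max <- min(schedule$n_bursts,
                 floor((length(x) - n_b) / (fs / schedule$prf)) + 1L)
    bursts <- lapply(seq_len(k_max) - 1L, function(k) {
      start <- round(k / schedule$prf * fs)
      burst_recording(x[start + seq_len(n_b)], fs,
                      start_time = k / schedule$prf, burst_index = k)
    })
    return(structure(list(bursts = bursts, schedule = schedule),
                     class = "treatment_recording"))
  }
  # detection mode
  n_frames <- floor(length(x) / frame_samples)
  if (n_frames < 2L) abort("recording too short for burst detection.")
  frame_rms <- sqrt(colMeans(matrix(
    x[seq_len(n_frames * frame_samples)]^2, nrow = frame_samples)))
  noise_floor <- median(frame_rms)
  thr <- threshold_factor * max(noise_floor, .Machine$double.eps)
  active <- frame_rms > thr
  if (!any(active)) abort("no bursts detected above the energy threshold.")
  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  amp_thr <- thr  # refine on |sample| against the same RMS-scale threshold
  bursts <- list()
  idx <- 0L
  for (r in which(runs$values)) {
    lo <- (starts[r] - 1L) * frame_samples + 1L
    hi <- min(ends[r] * frame_samples, length(x))
    # refine boundaries within one frame of the coarse edges
    lo_w <- max(1L, lo - frame_samples)
    hi_w <- min(length(x), hi + frame_samples)
    seg <- abs(x[lo_w:hi_w]) > amp_thr
    if (!any(seg)) next
    first <- lo_w + which(seg)[1] - 1L
    last <- lo_w + which(seg)[sum(seg)] - 1L
    bursts[[length(bursts) + 1L]] <-
      burst_recording(x[first:last], fs, start_time = (first - 1L) / fs,
                      burst_index = idx)
    idx <- idx + 1L
  }
  if (!length(bursts)) abort("no bursts detected above the energy threshold.")
  structure(list(bursts = bursts, schedule = NULL),
            class = "treatment_recording")
}

#' Write / read one burst as a two-column CSV
#'
#' Plain-text interchange format: columns `time_s` and `volts`, full double
#' precision. The reader infers the sampling rate from the median time step.
#'
#' @param burst A [burst_recording()].
#' @param path CSV file path.
#' @return `write_burst_csv()` returns `path` invisibly; `read_burst_csv()`
#'   returns a [burst_recording()].
#' @export
write_burst_csv <- function(burst, path) {
  stopifnot(inherits(burst, "burst_recording"))
  t <- burst$start_time + (seq_along(burst$samples) - 1) / burst$sampling_rate
  readr::write_csv(tibble(time_s = t, volts = burst$samples), path)
  invisible(path)
}

#' @rdname write_burst_csv
#' @export
read_burst_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  # parse doubles via strtod (as.numeric) for a bit-exact round trip
  d <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()))
  if (!all(c("time_s", "volts") %in% names(d)) || nrow(d) < 2L) {
    abort("CSV must have columns time_s, volts with >= 2 rows.")
  }
  d$time_s <- suppressWarnings(as.numeric(d$time_s))
  d$volts <- suppressWarnings(as.numeric(d$volts))
  if (anyNA(d$time_s) || anyNA(d$volts)) abort("malformed CSV: non-numeric cells.")
  dt <- median(diff(d$time_s))
  if (!is.finite(dt) || dt <= 0) abort("cannot infer sampling rate from time_s.")
  burst_recording(d$volts, sampling_rate = 1 / dt, start_time = d$time_s[1])
}

#' Write / read a treatment recording as a CSV directory
#'
#' One `burst_%04d.csv` per burst ([write_burst_csv()] format) plus a
#' `treatment.json` manifest holding the sampling rate, PRF, fundamental and
#' per-burst start times, so the round trip restores the schedule exactly.
#'
#' @param treatment A `treatment_recording`.
#' @param dir Directory (created if needed).
#' @return `write_treatment_csv()` returns `dir` invisibly;
#'   `read_treatment_csv()` returns a `treatment_recording`.
#' @export
write_treatment_csv <- function(treatment, dir) {
  stopifnot(inherits(treatment, "treatment_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(treatment$bursts)) {
    write_burst_csv(treatment$bursts[[i]],
                    file.path(dir, sprintf("burst_%04d.csv", i - 1L)))
  }
  sched <- treatment$schedule
  manifest <- list(
    n_bursts = length(treatment$bursts),
    start_times = vapply(treatment$bursts, `[[`, numeric(1), "start_time"),
    schedule = if (is.null(sched)) NULL else
      sched[c("prf", "burst_duration", "total_duration",
              "fundamental", "sampling_rate")]
  )
  jsonlite::write_json(manifest, file.path(dir, "treatment.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_treatment_csv
#' @export
read_treatment_csv <- function(dir) {
  manifest_path <- file.path(dir, "treatment.json")
  if (!file.exists(manifest_path)) {
    abort(sprintf("manifest not found: %s", manifest_path))
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  sched <- if (!is.null(manifest$schedule)) {
    do.call(treatment_schedule, manifest$schedule)
  }
  bursts <- lapply(seq_len(manifest$n_bursts), function(i) {
    b <- read_burst_csv(file.path(dir, sprintf("burst_%04d.csv", i - 1L)))
    if (!is.null(sched)) b$sampling_rate <- sched$sampling_rate
    b$duration <- length(b$samples) / b$sampling_rate
    b$burst_index <- i - 1L
    b
  })
  structure(list(bursts = bursts, schedule = sched),
            class = "treatment_recording")
}

#' Write / read a hemisphere phantom as 16-bit TIFFs with a JSON sidecar
#'
#' `image.tif` (intensities scaled to the 16-bit range by the recorded
#' `scale`), `treated_mask.tif`, `contralateral_mask.tif`, and
#' `phantom.json` with the generation parameters, the intensity scale and
#' the seed. Intensities are kept as real values in memory and quantized to
#' 16 bits only on export.
#'
#' @param phantom A `hemisphere_phantom`.
#' @param dir Directory (created if needed).
#' @return `write_phantom_tiff()` returns `dir` invisibly;
#'   `read_phantom_tiff()` returns a `hemisphere_phantom` (intensities
#'   quantized to 16 bits).
#' @export
write_phantom_tiff <- function(phantom, dir) {
  stopifnot(inherits(phantom, "hemisphere_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  max_int <- max(phantom$image, 1e-12)
  tiff::writeTIFF(phantom$image / max_int, file.path(dir, "image.tif"),
                  bits.per.sample = 16)
  tiff::writeTIFF(phantom$treated_mask * 1, file.path(dir, "treated_mask.tif"),
                  bits.per.sample = 16)
  tiff::writeTIFF(phantom$contralateral_mask * 1,
                  file.path(dir, "contralateral_mask.tif"),
                  bits.per.sample = 16)
  meta <- phantom[c("background", "enhancement_factor", "roi_fraction",
                    "noise_sd", "treated_side", "seed", "fold_expected")]
  meta$scale <- max_int
  jsonlite::write_json(meta, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_phantom_tiff
#' @export
read_phantom_tiff <- function(dir) {
  meta_path <- file.path(dir, "phantom.json")
  if (!file.exists(meta_path)) abort(sprintf("sidecar not found: %s", meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  img <- tiff::readTIFF(file.path(dir, "image.tif")) * meta$scale
  structure(
    list(image = img,
         treated_mask = tiff::readTIFF(file.path(dir, "treated_mask.tif")) > 0.5,
         contralateral_mask =
           tiff::readTIFF(file.path(dir, "contralateral_mask.tif")) > 0.5,
         background = meta$background,
         enhancement_factor = meta$enhancement_factor,
         roi_fraction = meta$roi_fraction, noise_sd = meta$noise_sd,
         treated_side = meta$treated_side, seed = meta$seed,
         fold_expected = meta$fold_expected),
    class = "hemisphere_phantom"
  )
}

#' Read a damage-score table from TSV
#'
#' Expected columns: `group`, `subject_id`, `section_id`, `image_id`,
#' `endpoint`, `score` (see [aggregate_scores()]).
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_scores_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  d <- readr::read_tsv(path, col_types = readr::cols())
  need <- c("group", "subject_id", "section_id", "image_id", "endpoint", "score")
  if (!all(need %in% names(d))) {
    abort(sprintf("score TSV must have columns %s.", paste(need, collapse = ", ")))
  }
  d
}
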