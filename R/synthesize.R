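#' Construct a burst recording from raw samples
#'
#' Container for one hydrophone burst: a uniformly sampled voltage series
#' plus its sampling rate. Normally produced by [synthesize_burst()] or by
#' the readers/segmenter; exposed for users bringing their own arrays.
#'
#' @param samples Numeric voltage samples.
#' @param sampling_rate Sampling rate, Hz.
#' @param start_time Burst start relative to treatment start, s.
#' @param burst_index 0-based burst index within its treatment.
#' @return An object of class `burst_recording` with fields `samples`,
#'   `sampling_rate`, `duration`, `start_time`, `burst_index`.
#' @export
burst_recording <- function(samples, sampling_rate, start_time = 0,
                            burst_index = 0L) {
  if (!is.numeric(samples) || length(samples) < 2L) {
    abort("`samples` must be a numeric vector with at least 2 elements.")
  }
  check_number(sampling_rate, "sampling_rate", min = 0, strict = TRUE)
  structure(
    list(samples = as.numeric(samples), sampling_rate = sampling_rate,
         duration = length(samples) / sampling_rate,
         start_time = start_time, burst_index = as.integer(burst_index)),
    class = "burst_recording"
  )
}

#' @export
print.burst_recording <- function(x, ...) {
  cat(sprintf("<burst_recording> #%d: %d samples @ %g MHz (%.3g ms), t0 = %g s\n",
              x$burst_index, length(x$samples), x$sampling_rate / 1e6,
              1e3 * x$duration, x$start_time))
  invisible(x)
}

# White noise band-limited to (0, ceiling] by spectral masking, scaled so the
# expected time-domain RMS equals `rms`. DC is excluded.
band_limited_noise <- function(n, fs, rms, ceiling) {
  if (rms <= 0) return(numeric(n))
  x <- rnorm(n)
  freq <- (seq_len(n) - 1) * fs / n
  freq_alias <- pmin(freq, fs - freq)        # two-sided |frequency| per bin
  keep <- freq_alias <= ceiling & freq_alias > 0
  if (!any(keep)) return(numeric(n))
  X <- fft(x)
  X[!keep] <- 0
  frac <- sum(keep) / n
  Re(fft(X, inverse = TRUE)) / n * (rms / sqrt(frac))
}

#' Synthesize one sonication burst
#'
#' Renders the voltage series a passive cavitation detector would record for
#' burst `burst_index` of a treatment: tones at each active band multiplier
#' times the schedule fundamental, a band-limited broadband noise continuum,
#' and a full-band noise floor, per the [emission_model()]. Deterministic:
#' the burst drawn for a given `(seed, burst_index)` is always bit-identical,
#' regardless of which other bursts are generated.
#'
#' @param model An [emission_model()].
#' @param schedule A [treatment_schedule()]. Its Nyquist frequency must
#'   exceed the model's `broadband_ceiling` whenever broadband noise is on.
#' @param burst_index 0-based index, `< schedule$n_bursts`.
#' @param seed Integer master seed for the treatment this burst belongs to.
#' @return A [burst_recording()] of `schedule$samples_per_burst` samples.
#' @examples
#' sched <- treatment_schedule(total_duration = 4)
#' mod <- emission_model(band_amplitudes = c("2" = 1))
#' b <- synthesize_burst(mod, sched, burst_index = 0, seed = 1)
#' sqrt(mean(b$samples^2))  # ~ 1/sqrt(2), the RMS of a unit tone
#' @export
synthesize_burst <- function(model, schedule, burst_index, seed) {
  stopifnot(inherits(model, "emission_model"),
            inherits(schedule, "treatment_schedule"))
  burst_index <- check_count(burst_index, "burst_index", min = 0L)
  if (burst_index >= schedule$n_bursts) {
    abort(sprintf("`burst_index` must be < n_bursts = %d.", schedule$n_bursts))
  }
  if (model$broadband_noise_rms > 0 &&
      schedule$sampling_rate / 2 <= model$broadband_ceiling) {
    abort("sampling_rate/2 must exceed the model's broadband_ceiling.")
  }
  n <- schedule$samples_per_burst
  t <- (seq_len(n) - 1) / schedule$sampling_rate
  amps <- model$band_amplitudes
  mult <- as.numeric(names(amps))
  if (any(amps > 0) &&
      max(mult[amps > 0]) * schedule$fundamental >= schedule$sampling_rate / 2) {
    abort("an active tone lies at or above Nyquist; raise sampling_rate.")
  }
  with_seed_(derive_seed(seed, burst_index), {
    jitter <- if (model$amplitude_jitter_sigma > 0) {
      exp(rnorm(1L, 0, model$amplitude_jitter_sigma))
    } else 1
    phases <- if (model$phase_policy == "random") {
      stats::runif(length(mult), 0, 2 * pi)
    } else rep(0, length(mult))
    x <- numeric(n)
    for (i in seq_along(mult)) {
      if (amps[i] > 0) {
        x <- x + jitter * amps[i] *
          sin(2 * pi * mult[i] * schedule$fundamental * t + phases[i])
      }
    }
    x <- x + band_limited_noise(n, schedule$sampling_rate,
                                jitter * model$broadband_noise_rms,
                                model$broadband_ceiling)
    if (model$noise_floor_rms > 0) x <- x + rnorm(n, 0, model$noise_floor_rms)
    burst_recording(x, schedule$sampling_rate,
                    start_time = burst_index / schedule$prf,
                    burst_index = burst_index)
  })
}

#' Synthesize a full burst-train treatment recording
#'
#' Generates all `schedule$n_bursts` bursts of a treatment (burst k starting
#' at `k / prf` seconds) by repeated [synthesize_burst()] calls, each with
#' its own derived sub-seed.
#'
#' @inheritParams synthesize_burst
#' @return An object of class `treatment_recording`: a list with `bursts`
#'   (list of [burst_recording()]) and the `schedule`.
#' @examples
#' sched <- treatment_schedule()  # 60 bursts
#' mod <- emission_model(band_amplitudes = c("1" = 0.5, "2" = 0.2))
#' tr <- synthesize_treatment(mod, treatment_schedule(total_duration = 6), seed = 1)
#' length(tr$bursts)
#' @export
synthesize_treatment <- function(model, schedule, seed) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  bursts <- lapply(seq_len(schedule$n_bursts) - 1L, function(k) {
    synthesize_burst(model, schedule, k, seed)
  })
  structure(list(bursts = bursts, schedule = schedule),
            class = "treatment_recording")
}

#' @export
print.treatment_recording <- function(x, ...) {
  cat(sprintf("<treatment_recording> %d bursts", length(x$bursts)))
  if (!is.null(x$schedule)) {
    cat(sprintf(" (%g ms @ %g Hz PRF, f0 %g MHz)", 1e3 * x$schedule$burst_duration,
                x$schedule$prf, x$schedule$fundamental / 1e6))
  }
  cat("\n")
  invisible(x)
}

#' Generate the low-pressure no-microbubble baseline recording
#'
#' Treatment protocols include a low-pressure scan without microbubbles
#' (e.g. 0.005 MPa) against which emissions are later normalized. Without
#' bubbles there is no cavitation: the recording contains only the
#' fundamental leak-through and the electronic noise floor. This helper
#' builds that reference with the identical schedule as the treatment it
#' will normalize, so per-band doses divide like for like.
#'
#' A strictly positive `noise_floor_rms` is recommended: it gives the
#' baseline a finite broadband dose, which downstream normalization requires
#' (dividing by an exactly silent band is an error there).
#'
#' @param schedule The [treatment_schedule()] shared with the treatment scan.
#' @param fundamental_amplitude Tone amplitude (volts) at f0 during the
#'   low-pressure scan.
#' @param noise_floor_rms Electronic noise floor RMS, volts.
#' @param seed Integer seed.
#' @return A `treatment_recording`.
#' @export
generate_baseline <- function(schedule, fundamental_amplitude = 0.01,
                              noise_floor_rms = 1e-4, seed = 0L) {
  model <- emission_model(
    band_amplitudes = c("1" = fundamental_amplitude),
    broadband_noise_rms = 0, noise_floor_rms = noise_floor_rms,
    amplitude_jitter_sigma = 0, phase_policy = "zero"
  )
  synthesize_treatment(model, schedule, seed)
}

#' Generate a two-group treatment study
#'
#' Simulates `n_per_group` subjects per arm, each receiving one treatment
#' recording drawn from that arm's emission model under the shared schedule.
#' Per-subject seeds are derived from the master seed by a fixed chain, so
#' increasing `n_per_group` extends the study without perturbing earlier
#' subjects.
#'
#' @param model_a,model_b [emission_model()]s for the two arms.
#' @param n_per_group Subjects per arm (>= 1).
#' @param schedule Shared [treatment_schedule()].
#' @param seed Integer master seed.
#' @param labels Length-2 character vector of arm names.
#' @return A tibble with one row per subject: `subject`, `group`, and a
#'   list-column `recording` of `treatment_recording`s.
#' @examples
#' sched <- treatment_schedule(total_duration = 4, burst_duration = 0.002,
#'                             fundamental = 1e5, sampling_rate = 2e6)
#' m <- emission_model(band_amplitudes = c("2" = 0.5), amplitude_jitter_sigma = 0.2,
#'                     phase_policy = "random", broadband_ceiling = 9e5)
#' study <- generate_group_study(m, m, n_per_group = 2, schedule = sched, seed = 1)
#' study
#' @export
generate_group_study <- function(model_a, model_b, n_per_group, schedule, seed,
                                 labels = c("A", "B")) {
  n_per_group <- check_count(n_per_group, "n_per_group")
  stopifnot(length(labels) == 2L)
  rows <- purrr::map(seq_len(2L * n_per_group), function(i) {
    arm <- if (i <= n_per_group) 1L else 2L
    idx <- ((i - 1L) %% n_per_group) + 1L
    model <- if (arm == 1L) model_a else model_b
    tibble(
      subject = sprintf("%s%d", labels[arm], idx),
      group = labels[arm],
      # seeds keyed by (arm, subject index): growing the study never
      # perturbs existing subjects in either arm
      recording = list(synthesize_treatment(model, schedule,
                                            seed = derive_seed(seed, arm, idx)))
    )
  })
  dplyr::bind_rows(rows)
}
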