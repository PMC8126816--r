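#' Define a burst-mode sonication schedule
#'
#' A focused-ultrasound treatment is delivered as a train of short bursts:
#' `burst_duration` seconds of continuous-wave excitation at the transducer
#' `fundamental`, repeated at the pulse repetition frequency `prf` for
#' `total_duration` seconds. The defaults are a common small-animal
#' blood-brain-barrier-opening protocol: 10 ms bursts at 0.5 Hz PRF for
#' 2 min (60 bursts) with a 1.1 MHz transducer. `sampling_rate` is the
#' hydrophone digitization rate; the default 25 MHz puts Nyquist (12.5 MHz)
#' above the 10 MHz broadband analysis ceiling.
#'
#' @param prf Pulse repetition frequency, Hz.
#' @param burst_duration Burst (sonication) length, s. Must be <= `1/prf`.
#' @param total_duration Treatment length, s. The number of bursts is
#'   `floor(total_duration * prf)` and must be >= 1.
#' @param fundamental Transducer drive frequency f0, Hz.
#' @param sampling_rate Hydrophone sampling rate, Hz.
#' @return An object of class `treatment_schedule` with the fields above plus
#'   `n_bursts` and `samples_per_burst`.
#' @examples
#' sched <- treatment_schedule()
#' sched$n_bursts            # 60
#' sched$samples_per_burst   # 250000
#' @export
treatment_schedule <- function(prf = 0.5, burst_duration = 0.010,
                               total_duration = 120, fundamental = 1.1e6,
                               sampling_rate = 25e6) {
  check_number(prf, "prf", min = 0, strict = TRUE)
  check_number(burst_duration, "burst_duration", min = 0, strict = TRUE)
  check_number(total_duration, "total_duration", min = 0, strict = TRUE)
  check_number(fundamental, "fundamental", min = 0, strict = TRUE)
  check_number(sampling_rate, "sampling_rate", min = 0, strict = TRUE)
  if (burst_duration > 1 / prf) {
    abort("`burst_duration` must not exceed the pulse period 1/prf.")
  }
  n_bursts <- floor(total_duration * prf)
  if (n_bursts < 1) abort("Schedule yields zero bursts: total_duration * prf < 1.")
  structure(
    list(prf = prf, burst_duration = burst_duration,
         total_duration = total_duration, fundamental = fundamental,
         sampling_rate = sampling_rate, n_bursts = as.integer(n_bursts),
         samples_per_burst = as.integer(round(burst_duration * sampling_rate))),
    class = "treatment_schedule"
  )
}

#' @export
print.treatment_schedule <- function(x, ...) {
  cat(sprintf("<treatment_schedule> %d bursts of %g ms at %g Hz PRF (%g s total)\n",
              x$n_bursts, 1e3 * x$burst_duration, x$prf, x$total_duration))
  cat(sprintf("  f0 = %g MHz, fs = %g MHz (%d samples/burst)\n",
              x$fundamental / 1e6, x$sampling_rate / 1e6, x$samples_per_burst))
  invisible(x)
}

#' Parameterize the acoustic emission content of synthetic bursts
#'
#' Phenomenological model of what a passive cavitation detector records
#' during one burst: a sum of narrowband tones at multiples of the
#' fundamental (subharmonic 0.5f, fundamental f, ultraharmonics 1.5f/2.5f/
#' 3.5f, harmonics 2f/3f/4f — the signatures of stable cavitation), plus a
#' band-limited white-noise continuum (the broadband signature of inertial
#' cavitation), plus an always-on electronic noise floor. No bubble-dynamics
#' model is implied; amplitudes are set directly.
#'
#' Per-burst variability is modeled as a shared multiplicative lognormal
#' jitter applied to the tone amplitudes and broadband RMS: each burst draws
#' `exp(rnorm(1, 0, amplitude_jitter_sigma))`, so log-amplitudes jitter
#' symmetrically and the geometric mean across bursts recovers the nominal
#' amplitude.
#'
#' @param band_amplitudes Named numeric vector of tone amplitudes (volts,
#'   zero-to-peak), names are band multipliers among
#'   `c("0.5", "1", "1.5", "2", "2.5", "3", "3.5", "4")`. Missing bands are 0.
#' @param broadband_noise_rms RMS (volts) of the broadband white-noise
#'   component, band-limited to below `broadband_ceiling`.
#' @param noise_floor_rms RMS (volts) of full-band electronic noise.
#' @param amplitude_jitter_sigma Log-space SD of the per-burst multiplicative
#'   jitter (0 = none).
#' @param phase_policy `"zero"` (every tone starts at phase 0) or `"random"`
#'   (independent uniform phases per burst).
#' @param broadband_ceiling Upper frequency limit (Hz) of the broadband noise
#'   component; default 10 MHz.
#' @return An object of class `emission_model`.
#' @examples
#' # harmonics-rich stable cavitation with a little inertial broadband:
#' mod <- emission_model(
#'   band_amplitudes = c("1" = 1, "2" = 0.3, "3" = 0.1, "4" = 0.03),
#'   broadband_noise_rms = 0.01, noise_floor_rms = 1e-4,
#'   amplitude_jitter_sigma = 0.2, phase_policy = "random"
#' )
#' @export
emission_model <- function(band_amplitudes = c("1" = 1),
                           broadband_noise_rms = 0, noise_floor_rms = 0,
                           amplitude_jitter_sigma = 0,
                           phase_policy = c("zero", "random"),
                           broadband_ceiling = 10e6) {
  phase_policy <- match.arg(phase_policy)
  allowed <- c(0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4)
  amps <- setNames(numeric(length(allowed)), as.character(allowed))
  if (length(band_amplitudes)) {
    if (is.null(names(band_amplitudes))) {
      abort("`band_amplitudes` must be named by band multiplier (e.g. \"2\").")
    }
    mult <- as.numeric(names(band_amplitudes))
    if (anyNA(mult) || !all(mult %in% allowed)) {
      abort("band multipliers must be among 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4.")
    }
    if (any(band_amplitudes < 0)) abort("tone amplitudes must be >= 0.")
    amps[as.character(mult)] <- as.numeric(band_amplitudes)
  }
  check_number(broadband_noise_rms, "broadband_noise_rms", min = 0)
  check_number(noise_floor_rms, "noise_floor_rms", min = 0)
  check_number(amplitude_jitter_sigma, "amplitude_jitter_sigma", min = 0)
  check_number(broadband_ceiling, "broadband_ceiling", min = 0, strict = TRUE)
  structure(
    list(band_amplitudes = amps, broadband_noise_rms = broadband_noise_rms,
         noise_floor_rms = noise_floor_rms,
         amplitude_jitter_sigma = amplitude_jitter_sigma,
         phase_policy = phase_policy, broadband_ceiling = broadband_ceiling),
    class = "emission_model"
  )
}

#' @export
print.emission_model <- function(x, ...) {
  on <- x$band_amplitudes[x$band_amplitudes > 0]
  cat("<emission_model>\n")
  if (length(on)) {
    cat("  tones (V): ",
        paste(sprintf("%s x f0 = %g", names(on), on), collapse = ", "), "\n", sep = "")
  } else {
    cat("  no tones\n")
  }
  cat(sprintf("  broadband RMS %g V (< %g MHz), floor %g V, jitter sigma %g, %s phases\n",
              x$broadband_noise_rms, x$broadband_ceiling / 1e6, x$noise_floor_rms,
              x$amplitude_jitter_sigma, x$phase_policy))
  invisible(x)
}
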