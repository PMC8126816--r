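#' Define the analysis band set for cavitation emissions
#'
#' Passive cavitation emissions are scored in narrow bands centered at
#' multiples of the transmit fundamental f0: the subharmonic (0.5f), the
#' fundamental (f), the ultraharmonics (1.5f, 2.5f, 3.5f) and the harmonics
#' (2f, 3f, 4f). Each band is `2 * half_bandwidth` wide (a 200 Hz bandwidth
#' by default). Everything else between `broadband_floor` and
#' `broadband_ceiling` is the broadband residual, the signature of inertial
#' cavitation; the ceiling defaults to 10 MHz and the floor to 0.1 MHz to
#' keep DC and low-frequency drift out of the residual.
#'
#' @param fundamental Transmit frequency f0, Hz.
#' @param multipliers Band centers as multiples of f0.
#' @param half_bandwidth Half-width of each narrowband, Hz (100 Hz gives the
#'   200 Hz bandwidth filter).
#' @param broadband_floor,broadband_ceiling Frequency limits of the broadband
#'   residual, Hz.
#' @return An object of class `spectral_bands`.
#' @examples
#' spectral_bands(1.1e6)
#' @export
spectral_bands <- function(fundamental,
                           multipliers = c(0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4),
                           half_bandwidth = 100,
                           broadband_floor = 1e5, broadband_ceiling = 10e6) {
  check_number(fundamental, "fundamental", min = 0, strict = TRUE)
  check_number(half_bandwidth, "half_bandwidth", min = 0, strict = TRUE)
  check_number(broadband_floor, "broadband_floor", min = 0)
  check_number(broadband_ceiling, "broadband_ceiling", min = 0, strict = TRUE)
  if (broadband_floor >= broadband_ceiling) {
    abort("`broadband_floor` must be below `broadband_ceiling`.")
  }
  multipliers <- sort(unique(as.numeric(multipliers)))
  if (!length(multipliers) || any(multipliers <= 0)) {
    abort("`multipliers` must be positive.")
  }
  centers <- multipliers * fundamental
  if (any(diff(centers) <= 2 * half_bandwidth)) {
    abort("narrowbands overlap: centers closer than the full bandwidth.")
  }
  structure(
    list(fundamental = fundamental, multipliers = multipliers,
         half_bandwidth = half_bandwidth, broadband_floor = broadband_floor,
         broadband_ceiling = broadband_ceiling),
    class = "spectral_bands"
  )
}

#' @export
print.spectral_bands <- function(x, ...) {
  cat(sprintf("<spectral_bands> f0 = %g MHz; bands %s (+/- %g Hz)\n",
              x$fundamental / 1e6,
              paste(band_label(x$multipliers), collapse = " "), x$half_bandwidth))
  cat(sprintf("  broadband residual: %g - %g MHz\n",
              x$broadband_floor / 1e6, x$broadband_ceiling / 1e6))
  invisible(x)
}

# Single-sided DFT of a burst. amp is calibrated so an on-grid tone of
# amplitude A peaks at A; power is each bin's contribution to mean(x^2),
# so sum(power) == mean(x^2) exactly (Parseval).
burst_fft <- function(burst) {
  x <- burst$samples
  n <- length(x)
  if (n < 2L) abort("burst must hold at least 2 samples.")
  X <- fft(x)
  n_half <- floor(n / 2) + 1L
  idx <- seq_len(n_half)
  mod2 <- Mod(X[idx])^2
  amp <- Mod(X[idx]) / n
  power <- mod2 / n^2
  interior <- idx > 1L & !(n %% 2L == 0L & idx == n_half)
  amp[interior] <- 2 * amp[interior]
  power[interior] <- 2 * power[interior]
  list(frequency = (idx - 1L) * burst$sampling_rate / n,
       amplitude = amp, power = power,
       resolution = burst$sampling_rate / n)
}

#' Single-sided amplitude spectrum of a burst
#'
#' Rectangular-window DFT with amplitude calibration: a pure tone of
#' amplitude A at a grid frequency appears as a bin of amplitude A.
#' Frequency resolution is `1 / duration` (100 Hz for a 10 ms burst).
#'
#' @param burst A [burst_recording()].
#' @return A tibble of class `cavi_spectrum` with columns `frequency` (Hz)
#'   and `amplitude` (volts).
#' @examples
#' sched <- treatment_schedule(total_duration = 2)
#' b <- synthesize_burst(emission_model(c("2" = 1)), sched, 0, seed = 1)
#' sp <- amplitude_spectrum(b)
#' sp[which.max(sp$amplitude), ]  # 2.2 MHz, ~1 V
#' @export
amplitude_spectrum <- function(burst) {
  stopifnot(inherits(burst, "burst_recording"))
  ft <- burst_fft(burst)
  out <- tibble(frequency = ft$frequency, amplitude = ft$amplitude)
  class(out) <- c("cavi_spectrum", class(out))
  out
}

# Shared band-Vrms kernel operating on a precomputed burst_fft.
band_vrms_fft <- function(ft, bands, multiplier, method) {
  center <- multiplier * bands$fundamental
  nyquist <- ft$frequency[length(ft$frequency)]
  if (center + bands$half_bandwidth > nyquist) {
    abort(sprintf("band %s (%g Hz) extends beyond Nyquist (%g Hz).",
                  band_label(multiplier), center, nyquist))
  }
  sel <- abs(ft$frequency - center) <= bands$half_bandwidth
  if (!any(sel)) abort("no spectral bins fall inside the requested band.")
  if (method == "peak") max(ft$amplitude[sel]) / sqrt(2)
  else sqrt(sum(ft$power[sel]))
}

broadband_mask <- function(ft, bands) {
  nyquist <- ft$frequency[length(ft$frequency)]
  if (bands$broadband_ceiling > nyquist) {
    abort(sprintf("broadband ceiling (%g Hz) exceeds Nyquist (%g Hz).",
                  bands$broadband_ceiling, nyquist))
  }
  mask <- ft$frequency >= bands$broadband_floor &
    ft$frequency <= bands$broadband_ceiling
  for (m in bands$multipliers) {
    mask <- mask &
      abs(ft$frequency - m * bands$fundamental) > bands$half_bandwidth
  }
  mask
}

#' Band-filtered Vrms of one burst
#'
#' Scores a narrowband emission: the spectrum is restricted to
#' `center +/- half_bandwidth` (the 200 Hz bandwidth filter) and the peak
#' single-sided spectral amplitude therein is converted to an RMS voltage by
#' dividing by sqrt(2) — the calibration under which a pure in-band tone of
#' amplitude A scores its true RMS, A/sqrt(2). `method = "rms"` instead
#' returns the time-domain RMS of the band-filtered signal (the square root
#' of total in-band power); the two coincide for a single in-band tone.
#'
#' @param burst A [burst_recording()].
#' @param bands A [spectral_bands()].
#' @param multiplier One of `bands$multipliers`.
#' @param method `"peak"` (default) or `"rms"`; see Details.
#' @return Vrms in volts (>= 0).
#' @examples
#' sched <- treatment_schedule(total_duration = 2)
#' b <- synthesize_burst(emission_model(c("2" = 1)), sched, 0, seed = 1)
#' band_vrms(b, spectral_bands(1.1e6), 2)  # 0.7071
#' @export
band_vrms <- function(burst, bands, multiplier, method = c("peak", "rms")) {
  stopifnot(inherits(burst, "burst_recording"), inherits(bands, "spectral_bands"))
  method <- match.arg(method)
  if (!multiplier %in% bands$multipliers) {
    abort(sprintf("multiplier %g is not in the band set.", multiplier))
  }
  band_vrms_fft(burst_fft(burst), bands, multiplier, method)
}

#' Broadband residual Vrms of one burst
#'
#' Scores inertial-cavitation emissions: every narrowband (all multipliers
#' `+/- half_bandwidth`) and everything outside
#' `[broadband_floor, broadband_ceiling]` is zeroed in the spectrum, and the
#' RMS of the residual — the square root of the summed residual power — is
#' returned. A noise continuum has no meaningful single peak, so the
#' residual is scored by total power rather than a peak amplitude. By
#' construction the result is insensitive to narrowband tone amplitudes.
#'
#' @inheritParams band_vrms
#' @return Residual RMS in volts (>= 0).
#' @export
broadband_vrms <- function(burst, bands) {
  stopifnot(inherits(burst, "burst_recording"), inherits(bands, "spectral_bands"))
  ft <- burst_fft(burst)
  sqrt(sum(ft$power[broadband_mask(ft, bands)]))
}

#' Per-burst band table for a whole treatment
#'
#' Applies [band_vrms()] (all multipliers) and [broadband_vrms()] to every
#' burst of a treatment recording, computing each burst's spectrum once.
#'
#' @param treatment A `treatment_recording` (see [synthesize_treatment()]),
#'   or a list of [burst_recording()]s.
#' @param bands A [spectral_bands()].
#' @param method Vrms estimator passed to the narrowband scorer.
#' @return A tibble with one row per burst and band: `burst_index`, `band`
#'   (labels `"0.5f"` ... `"4f"` and `"broadband"`), `vrms` (volts),
#'   `duration` (s). Empty treatments give a zero-row tibble.
#' @examples
#' sched <- treatment_schedule(total_duration = 4)
#' mod <- emission_model(c("1" = 0.5, "2" = 0.2))
#' tr <- synthesize_treatment(mod, sched, seed = 1)
#' analyze_treatment(tr, spectral_bands(1.1e6))
#' @export
analyze_treatment <- function(treatment, bands, method = c("peak", "rms")) {
  stopifnot(inherits(bands, "spectral_bands"))
  method <- match.arg(method)
  bursts <- if (inherits(treatment, "treatment_recording")) treatment$bursts
            else treatment
  labels <- c(band_label(bands$multipliers), "broadband")
  if (!length(bursts)) {
    return(tibble(burst_index = integer(),
                  band = factor(character(), levels = labels),
                  vrms = numeric(), duration = numeric()))
  }
  rows <- lapply(bursts, function(b) {
    stopifnot(inherits(b, "burst_recording"))
    ft <- burst_fft(b)
    v <- vapply(bands$multipliers,
                function(m) band_vrms_fft(ft, bands, m, method), numeric(1))
    bb <- sqrt(sum(ft$power[broadband_mask(ft, bands)]))
    list(burst_index = b$burst_index, vrms = c(v, bb), duration = b$duration)
  })
  tibble(
    burst_index = rep(vapply(rows, `[[`, integer(1), "burst_index"),
                      each = length(labels)),
    band = factor(rep(labels, length(rows)), levels = labels),
    vrms = unlist(lapply(rows, `[[`, "vrms"), use.names = FALSE),
    duration = rep(vapply(rows, `[[`, numeric(1), "duration"),
                   each = length(labels))
  )
}
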