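# Scaled-down study conditions shared across tests: a 100 kHz fundamental
# sampled at 2 MHz keeps all eight narrowbands (up to 4f = 400 kHz) and a
# 0.9 MHz broadband ceiling below Nyquist while bursts stay a few thousand
# samples long. Band centers (multiples of 50 kHz) sit on the DFT grid for
# any burst length that is a multiple of 40 samples.

fast_schedule <- function(total_duration = 4, prf = 0.5,
                          burst_duration = 0.002) {
  treatment_schedule(prf = prf, burst_duration = burst_duration,
                     total_duration = total_duration,
                     fundamental = 1e5, sampling_rate = 2e6)
}

fast_bands <- function() {
  spectral_bands(1e5, half_bandwidth = 100,
                 broadband_floor = 1e4, broadband_ceiling = 9e5)
}

fast_model <- function(amps = c("1" = 0.5, "2" = 0.2), noise = 0,
                       floor = 0, jitter = 0,
                       phases = c("zero", "random")) {
  emission_model(band_amplitudes = amps, broadband_noise_rms = noise,
                 noise_floor_rms = floor, amplitude_jitter_sigma = jitter,
                 phase_policy = match.arg(phases), broadband_ceiling = 9e5)
}

# Full-scale protocol (1.1 MHz, 25 MHz sampling) for calibration checks.
full_schedule <- function(total_duration = 120) {
  treatment_schedule(total_duration = total_duration)
}

all_band_amps <- function(a = 1) {
  setNames(rep(a, 8), c("0.5", "1", "1.5", "2", "2.5", "3", "3.5", "4"))
}

# Hand-rolled sine-burst constructor independent of the synthesizer.
make_tone_burst <- function(freqs, amps, fs, duration, phases = 0) {
  t <- (seq_len(round(fs * duration)) - 1) / fs
  if (length(phases) == 1) phases <- rep(phases, length(freqs))
  x <- numeric(length(t))
  for (i in seq_along(freqs)) {
    x <- x + amps[i] * sin(2 * pi * freqs[i] * t + phases[i])
  }
  burst_recording(x, fs)
}
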