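# Spectral scoring: amplitude calibration, band Vrms, broadband residual.

test_that("amplitude spectrum is tone-calibrated with 1/duration resolution", {
  b <- make_tone_burst(2.2e6, 1.0, fs = 25e6, duration = 0.010)
  sp <- amplitude_spectrum(b)
  expect_equal(sp$frequency[2] - sp$frequency[1], 100)
  peak <- sp[which.max(sp$amplitude), ]
  expect_equal(peak$frequency, 2.2e6)
  expect_equal(peak$amplitude, 1.0, tolerance = 1e-9)
})

test_that("all-zero burst has an all-zero spectrum", {
  b <- burst_recording(numeric(4000), 2e6)
  expect_true(all(amplitude_spectrum(b)$amplitude == 0))
})

test_that("two-tone spectrum resolves both peaks and satisfies Parseval", {
  b <- make_tone_burst(c(2.2e6, 3.3e6), c(0.5, 0.25), fs = 25e6,
                       duration = 0.010)
  sp <- amplitude_spectrum(b)
  expect_equal(sp$amplitude[sp$frequency == 2.2e6], 0.5, tolerance = 1e-9)
  expect_equal(sp$amplitude[sp$frequency == 3.3e6], 0.25, tolerance = 1e-9)
  # total spectral power equals time-domain power
  ft <- cavidose:::burst_fft(b)
  expect_equal(sum(ft$power), mean(b$samples^2), tolerance = 1e-12)
})

test_that("band Vrms matches the time-domain filtered-signal oracle", {
  bands <- spectral_bands(1.1e6)
  b <- make_tone_burst(c(2.2e6, 3.3e6), c(0.5, 0.25), fs = 25e6,
                       duration = 0.010)
  # oracle: frequency-mask the 3f band, invert, take the time-domain RMS
  x <- b$samples; n <- length(x)
  freq <- (seq_len(n) - 1) * 25e6 / n
  freq <- pmin(freq, 25e6 - freq)
  X <- fft(x); X[abs(freq - 3.3e6) > 100] <- 0
  oracle <- sqrt(mean(Re(fft(X, inverse = TRUE) / n)^2))
  expect_equal(oracle, 0.25 / sqrt(2), tolerance = 1e-6)
  expect_equal(band_vrms(b, bands, 3), oracle, tolerance = 1e-6)
  expect_equal(band_vrms(b, bands, 3, method = "rms"), oracle,
               tolerance = 1e-6)
  expect_equal(band_vrms(b, bands, 3), 0.1768, tolerance = 1e-3)
  # a band with no energy scores zero
  expect_equal(band_vrms(b, bands, 0.5), 0, tolerance = 1e-9)
})

test_that("broadband residual excludes narrowband tones completely", {
  bands <- fast_bands()
  sched <- fast_schedule(total_duration = 2)
  tones <- synthesize_burst(fast_model(amps = all_band_amps(1)), sched, 0,
                            seed = 1)
  tone_rms <- sqrt(mean(tones$samples^2))
  expect_lt(broadband_vrms(tones, bands), 1e-6 * tone_rms)

  noisy <- synthesize_burst(fast_model(amps = c("1" = 0), noise = 0.05),
                            sched, 0, seed = 2)
  with_tone <- burst_recording(noisy$samples + tones$samples, 2e6)
  expect_equal(broadband_vrms(with_tone, bands), broadband_vrms(noisy, bands),
               tolerance = 1e-6)
})

test_that("broadband Vrms of band-limited noise follows the Parseval prediction", {
  bands <- fast_bands()
  # construct noise strictly inside [floor, ceiling] by explicit masking
  n <- 4000; fs <- 2e6
  set.seed(5)
  x <- rnorm(n)
  freq <- pmin((seq_len(n) - 1) * fs / n, fs - (seq_len(n) - 1) * fs / n)
  keep <- freq >= bands$broadband_floor & freq <= bands$broadband_ceiling
  X <- fft(x); X[!keep] <- 0
  x <- Re(fft(X, inverse = TRUE)) / n
  b <- burst_recording(x, fs)
  sigma <- sqrt(mean(x^2))
  # fraction of in-band bins surviving the narrowband exclusion
  ft <- cavidose:::burst_fft(b)
  frac <- sum(ft$power[cavidose:::broadband_mask(ft, bands)]) /
    sum(ft$power)
  expect_equal(broadband_vrms(b, bands), sigma * sqrt(frac),
               tolerance = 1e-9)
  expect_equal(broadband_vrms(b, bands), sigma, tolerance = 0.01)
})

test_that("Vrms is linear in signal scale and bands are orthogonal", {
  bands <- fast_bands()
  sched <- fast_schedule(total_duration = 2)
  b <- synthesize_burst(fast_model(amps = all_band_amps(0.3), noise = 0.02),
                        sched, 0, seed = 9)
  b3 <- burst_recording(3.5 * b$samples, b$sampling_rate)
  for (m in bands$multipliers) {
    expect_equal(band_vrms(b3, bands, m), 3.5 * band_vrms(b, bands, m),
                 tolerance = 1e-12)
  }
  expect_equal(broadband_vrms(b3, bands), 3.5 * broadband_vrms(b, bands),
               tolerance = 1e-12)

  # injecting energy at 2f leaves every other band untouched
  base <- synthesize_burst(fast_model(amps = all_band_amps(0.3)), sched, 0,
                           seed = 9)
  spike <- make_tone_burst(2e5, 5, fs = 2e6, duration = 0.002)
  bumped <- burst_recording(base$samples + spike$samples, 2e6)
  for (m in setdiff(bands$multipliers, 2)) {
    expect_equal(band_vrms(bumped, bands, m), band_vrms(base, bands, m),
                 tolerance = 1e-6)
  }
})

test_that("analyze_treatment returns one record per burst in order", {
  sched <- fast_schedule(total_duration = 6)  # 3 bursts
  tr <- synthesize_treatment(fast_model(), sched, seed = 1)
  tab <- analyze_treatment(tr, fast_bands())
  expect_equal(nrow(tab), 3L * 9L)
  expect_equal(unique(tab$burst_index), 0:2)
  expect_equal(levels(tab$band),
               c("0.5f", "1f", "1.5f", "2f", "2.5f", "3f", "3.5f", "4f",
                 "broadband"))
  # noiseless constant amplitudes: all bursts identical
  wide <- tidyr::pivot_wider(tab, names_from = "band", values_from = "vrms")
  expect_equal(wide$`1f`, rep(wide$`1f`[1], 3))

  empty <- analyze_treatment(list(), fast_bands())
  expect_equal(nrow(empty), 0L)
  expect_s3_class(empty$band, "factor")
})

test_that("band and Nyquist violations raise errors", {
  bands <- spectral_bands(1.1e6)
  b <- make_tone_burst(2.2e6, 1, fs = 25e6, duration = 0.001)
  expect_error(band_vrms(b, bands, 1.7), "not in the band set")
  low_fs <- make_tone_burst(1e5, 1, fs = 4e6, duration = 0.002)
  expect_error(band_vrms(low_fs, bands, 4), "Nyquist")
  expect_error(broadband_vrms(low_fs, bands), "Nyquist")
  expect_error(spectral_bands(1e3, half_bandwidth = 400), "overlap")
  expect_error(spectral_bands(1e6, broadband_floor = 11e6), "below")
})
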