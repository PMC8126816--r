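# Dose accumulation, baseline normalization, group comparison plumbing.

make_records <- function(vrms, duration, band = "2f") {
  tibble::tibble(
    burst_index = seq_along(vrms) - 1L,
    band = factor(band, levels = unique(band)),
    vrms = vrms, duration = duration
  )
}

test_that("dose is the sum of Vrms times burst duration", {
  prof <- accumulate_dose(make_records(rep(0.1, 60), 0.01))
  expect_equal(prof$dose[prof$band == "2f"], 0.06)
  expect_equal(attr(prof, "n_bursts"), 60L)

  two <- accumulate_dose(make_records(c(0.2, 0.1), c(0.01, 0.02)))
  expect_equal(two$dose[two$band == "2f"], 0.004)
})

test_that("empty record tables give an all-zero profile over the band levels", {
  empty <- analyze_treatment(list(), fast_bands())
  prof <- accumulate_dose(empty)
  expect_equal(nrow(prof), 9L)
  expect_true(all(prof$dose == 0))
  expect_false(is_normalized(prof))
})

test_that("dose is additive over concatenated record lists", {
  sched <- fast_schedule(total_duration = 8)  # 4 bursts
  tr <- synthesize_treatment(fast_model(noise = 0.02, jitter = 0.1,
                                        phases = "random"), sched, seed = 3)
  tab <- analyze_treatment(tr, fast_bands())
  first <- dplyr::filter(tab, burst_index < 2)
  rest <- dplyr::filter(tab, burst_index >= 2)
  expect_equal(accumulate_dose(tab)$dose,
               accumulate_dose(first)$dose + accumulate_dose(rest)$dose)
})

test_that("normalization is a per-band ratio with an exact identity", {
  sched <- fast_schedule(total_duration = 4)
  bands <- fast_bands()
  trt <- synthesize_treatment(fast_model(noise = 0.02, floor = 1e-3),
                              sched, seed = 1) |>
    analyze_treatment(bands) |> accumulate_dose()
  norm_self <- normalize_dose(trt, trt)
  expect_true(is_normalized(norm_self))
  expect_equal(norm_self$dose, rep(1, 9))

  ratio <- normalize_dose(
    accumulate_dose(make_records(c(0.3, 0.3), c(0.01, 0.01))),  # 0.006
    accumulate_dose(make_records(c(0.1, 0.1), c(0.01, 0.01))))  # 0.002
  expect_equal(ratio$dose[ratio$band == "2f"], 3.0)
})

test_that("silent baselines and double normalization are refused", {
  a <- accumulate_dose(make_records(c(0.1), c(0.01)))
  zero <- accumulate_dose(make_records(c(0), c(0.01)))
  expect_error(normalize_dose(a, zero), "2f")
  n <- normalize_dose(a, a)
  expect_error(normalize_dose(n, a), "unnormalized")
  # band-set mismatch
  b9 <- analyze_treatment(
    synthesize_treatment(fast_model(floor = 1e-3),
                         fast_schedule(total_duration = 4), seed = 1),
    fast_bands()) |> accumulate_dose()
  expect_error(normalize_dose(a, b9), "band sets")
})

test_that("normalized dose is invariant under a common hydrophone rescale", {
  sched <- fast_schedule(total_duration = 4)
  bands <- fast_bands()
  trt <- synthesize_treatment(fast_model(noise = 0.02, floor = 1e-3),
                              sched, seed = 1)
  bl <- generate_baseline(sched, seed = 2)
  rescale <- function(tr, c) {
    tr$bursts <- lapply(tr$bursts, function(b) {
      b$samples <- c * b$samples; b
    })
    tr
  }
  norm1 <- normalize_dose(
    accumulate_dose(analyze_treatment(trt, bands)),
    accumulate_dose(analyze_treatment(bl, bands)))
  norm2 <- normalize_dose(
    accumulate_dose(analyze_treatment(rescale(trt, 7.3), bands)),
    accumulate_dose(analyze_treatment(rescale(bl, 7.3), bands)))
  expect_equal(norm1$dose, norm2$dose, tolerance = 1e-12)
})

test_that("broadband dose increases strictly with injected noise RMS", {
  sched <- fast_schedule(total_duration = 4)
  bands <- fast_bands()
  doses <- vapply(c(0.01, 0.02, 0.05), function(s) {
    tr <- synthesize_treatment(fast_model(noise = s), sched, seed = 4)
    prof <- accumulate_dose(analyze_treatment(tr, bands))
    prof$dose[prof$band == "broadband"]
  }, numeric(1))
  expect_true(all(diff(doses) > 0))
})

test_that("compare_emissions reports the exact test on normalized doses", {
  mk_table <- function(doses, group) {
    tidyr::expand_grid(
      subject = paste0(group, seq_along(doses)),
      band = c("2f", "3f", "4f", "broadband")
    ) |>
      dplyr::mutate(group = group,
                    dose = rep(doses, each = 4), normalized = TRUE)
  }
  tab <- dplyr::bind_rows(mk_table(c(5.1, 6.2, 5.8, 7.0), "Iso"),
                          mk_table(c(1.2, 1.9, 1.4, 2.2), "KD"))
  cmp <- compare_emissions(tab)
  expect_equal(nrow(cmp), 4L)
  expect_equal(cmp$p, rep(2 / 70, 4), tolerance = 1e-12)
  expect_equal(cmp$mean_a, rep(mean(c(5.1, 6.2, 5.8, 7.0)), 4))
  expect_equal(cmp$sem_a, rep(sd(c(5.1, 6.2, 5.8, 7.0)) / 2, 4))

  raw <- dplyr::mutate(tab, normalized = FALSE)
  expect_error(compare_emissions(raw), "normalized")
  expect_error(compare_emissions(tab, bands = "9f"), "not present")
})

test_that("study_dose_table runs the full per-subject pipeline", {
  sched <- fast_schedule(total_duration = 4)
  bands <- fast_bands()
  mod <- fast_model(noise = 0.02, floor = 1e-3, jitter = 0.15,
                    phases = "random")
  study <- generate_group_study(mod, mod, n_per_group = 2, schedule = sched,
                                seed = 8)
  bl <- generate_baseline(sched, seed = 99) |>
    analyze_treatment(bands) |> accumulate_dose()
  tab <- study_dose_table(study, bands, baseline = bl)
  expect_equal(nrow(tab), 4L * 9L)
  expect_true(all(tab$normalized))
  expect_true(all(tab$dose >= 0))
  cmp <- compare_emissions(tab)
  expect_true(all(cmp$p > 0 & cmp$p <= 1))
})
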