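# waveform-only harness: one synthetic sarcomere per frame plus a static
# fake geometry lets the feature extractor run without images
waveform_record <- function(params, seed = 1, ramp = "cosine") {
  wf <- generate_length_waveform(params, seed, ramp = ramp)
  n <- length(wf$t)
  sarc <- data.frame(frame = seq_len(n) - 1L, length_um = wf$length,
                     longitudinal = "center", transverse = "top")
  geom <- data.frame(frame = seq_len(n) - 1L, rect_long = 400,
                     rect_short = 120, rect_area = 48000, hull_area = 47000)
  sig <- structure(list(region = "whole", t = wf$t, raw = wf$length,
                        denoised = wf$clean, noise_level = sd(wf$length - wf$clean),
                        fps = params$fps), class = "length_signal")
  ev <- detect_phases(sig$denoised, sig$t, phase_config())
  extract_features(ev, sig, geom, sarc, um_per_px = 0.25, region = "whole")
}

test_that("all 35 feature-table metrics map to exactly one column", {
  sch <- feature_schema()
  expect_identical(nrow(sch), 35L)
  expect_identical(sch$column, sarcbundle:::FEATURE_COLUMNS)
  rec <- waveform_record(std_params(noise_sd = 0))
  expect_true(all(sch$column %in% names(rec)))
  expect_identical(ncol(rec), 36L)  # region + 35 metrics
})

test_that("a noiseless 5-cycle waveform recovers period, rate and amplitude", {
  rec <- waveform_record(waveform_params(resting_length = 2, amplitude = 0.4,
                                         period = 1, contraction_duration = 0.2,
                                         expansion_duration = 0.3,
                                         n_cycles = 5L, fps = 100, noise_sd = 0))
  expect_lt(abs(rec$contraction_period - 1.00), 0.02)
  expect_lt(abs(rec$contraction_frequency - 1.00), 0.02)
  expect_lt(abs(rec$shortening_amplitude - 0.40), 0.02)
  expect_equal(rec$contraction_frequency * rec$contraction_period, 1,
               tolerance = 1e-9)
  # peak shortening velocity: closed-form pi * A / (2 * d_c)
  v_true <- pi * 0.4 / (2 * 0.2)
  expect_lt(abs(rec$peak_shortening_velocity - v_true), 0.05 * v_true)
  # timing decompositions sum within one sample
  expect_lt(abs(rec$onset_to_half_contracted + rec$half_to_peak -
                rec$onset_to_peak), 0.01 + 1e-9)
  expect_lt(abs(rec$peak_to_half_relaxed + rec$half_relaxed_to_full -
                rec$peak_to_relaxation_end), 0.01 + 1e-9)
  expect_lt(abs(rec$onset_to_peak + rec$peak_to_relaxation_end -
                rec$onset_to_relaxation_end), 0.01 + 1e-9)
  # distributional stats are ordered
  expect_lte(rec$relaxed_SL_p25, rec$relaxed_SL_median)
  expect_lte(rec$relaxed_SL_median, rec$relaxed_SL_p75)
  # geometry pass-through with the um_per_px scaling
  expect_equal(rec$tissue_length_relaxed, 400 * 0.25)
  expect_equal(rec$tissue_area_rect_relaxed, 48000 * 0.25^2)
  expect_equal(rec$total_sarcomeres, 1)
})

test_that("zero or one complete event degrades gracefully", {
  # two recorded cycles leave no complete event (both are edge-truncated)
  p <- waveform_params(n_cycles = 2L, noise_sd = 0)
  expect_warning(rec0 <- waveform_record(p), "no complete")
  expect_identical(rec0$number_of_contractions, 0L)
  expect_true(is.na(rec0$contraction_period))
  expect_true(is.na(rec0$relaxed_SL_mean))
  expect_false(is.na(rec0$total_sarcomeres))
})

test_that("paired comparison reproduces the hand-computed toy example", {
  res <- paired_comparison(c(1.0, 2.0, 3.0), c(1.5, 2.6, 3.4))
  expect_equal(res$delta_pct, 25.0, tolerance = 1e-12)
  t_hand <- 0.5 / (sd(c(0.5, 0.6, 0.4)) / sqrt(3))
  expect_equal(res$t_statistic, t_hand, tolerance = 1e-6)
  expect_equal(res$p_value, 2 * pt(-t_hand, df = 2), tolerance = 1e-9)
  expect_identical(res$n, 3L)

  same <- suppressWarnings(paired_comparison(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$delta_pct, 0)
  expect_true(is.na(same$p_value))

  expect_error(paired_comparison(1, 2), "fewer than 2")
  # missing pairs are dropped, n reflects retained
  res2 <- paired_comparison(c(1, 2, NA, 3), c(1.5, 2.6, 9, 3.4))
  expect_identical(res2$n, 3L)
})
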