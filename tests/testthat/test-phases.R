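test_that("Savitzky-Golay derivative is exact on polynomials", {
  cfg <- phase_config(sg_window = 11L, sg_polyorder = 3L)
  expect_equal(smooth_derivative(rep(3, 60), cfg, fps = 100), rep(0, 60))
  t <- seq(0, 0.59, 0.01)
  ramp <- 1 + 0.5 * t
  d <- smooth_derivative(ramp, cfg, fps = 100)
  expect_lt(max(abs(d - 0.5)), 1e-6)  # everywhere, edges included
  expect_error(smooth_derivative(rep(1, 5), cfg, 100), "shorter")
})

test_that("Savitzky-Golay derivative matches the analytic cosine derivative", {
  A <- 0.4; Tp <- 1
  t <- seq(0, 3 - 0.01, 0.01)
  x <- 2 - (A / 2) * (1 - cos(2 * pi * t / Tp))
  d <- smooth_derivative(x, phase_config(), fps = 100)
  truth <- -(A / 2) * (2 * pi / Tp) * sin(2 * pi * t / Tp)
  interior <- 6:(length(t) - 5)
  expect_lt(max(abs(d[interior] - truth[interior])), 0.01 * max(abs(truth)))
})

test_that("a flat signal yields no events", {
  ev <- detect_phases(rep(2, 200), seq(0, 1.99, 0.01))
  expect_identical(nrow(ev), 0L)
})

test_that("linear-ramp cycles are recovered within 2 samples", {
  p <- std_params(noise_sd = 0)
  wf <- generate_length_waveform(p, 1, ramp = "linear")
  # ramp slope is A / d_c = 2 um/s; threshold strictly inside (0, 2)
  ev <- detect_phases(wf$clean, wf$t, phase_config(derivative_threshold = 0.1))
  tr <- wf$events
  matched <- ev[seq_len(nrow(tr)), ]
  dt <- 1 / p$fps + 1e-9
  expect_true(all(abs(matched$contraction_onset - tr$contraction_onset) <= 2 * dt))
  expect_true(all(abs(matched$relaxed_start - tr$relaxed_start) <= 2 * dt))
  expect_true(all(abs(matched$peak_contraction - tr$peak_contraction) <= 2 * dt,
                  na.rm = TRUE))
  # interior cycles are complete; count within the positive-block bound
  expect_identical(sum(ev$complete), nrow(tr) - 2L)
})

test_that("raised-cosine peaks land on the true descent ends", {
  p <- std_params(noise_sd = 0)
  wf <- generate_length_waveform(p, 1, ramp = "cosine")
  ev <- detect_phases(wf$clean, wf$t, phase_config())
  tr <- wf$events
  got <- ev$peak_contraction[seq_len(nrow(tr))]
  expect_true(all(abs(got - tr$peak_contraction) <= 1 / p$fps + 1e-9))
})

test_that("events are ordered, disjoint and monotone during contraction", {
  p <- std_params(noise_sd = 0)
  wf <- generate_length_waveform(p, 1)
  ev <- detect_phases(wf$clean, wf$t, phase_config())
  comp <- ev[ev$complete, ]
  expect_true(all(comp$relaxed_start <= comp$contraction_onset))
  expect_true(all(comp$contraction_onset < comp$peak_contraction))
  expect_true(all(comp$peak_contraction < comp$relaxation_end))
  if (nrow(comp) > 1) {
    expect_true(all(diff(comp$relaxed_start) > 0))
    expect_true(all(head(comp$relaxation_end, -1) <=
                    tail(comp$relaxed_start, -1) + 1e-9))
  }
  # net shortening between onset and peak is positive
  for (i in seq_len(nrow(comp))) {
    on <- which.min(abs(wf$t - comp$contraction_onset[i]))
    pk <- which.min(abs(wf$t - comp$peak_contraction[i]))
    expect_gt(wf$clean[on] - wf$clean[pk], 0)
  }
})

test_that("small pre-denoising noise moves detected times by <= 3 samples", {
  p0 <- std_params(noise_sd = 0)
  wf0 <- generate_length_waveform(p0, 1)
  ev0 <- detect_phases(wf0$clean, wf0$t, phase_config())
  p1 <- std_params(noise_sd = 0.02 * 0.4)  # sd = 2% of amplitude
  wf1 <- generate_length_waveform(p1, 5)
  sig <- structure(list(region = "whole", t = wf1$t, raw = wf1$length,
                        fps = 100), class = "length_signal")
  den <- gpr_denoise(sig)
  ev1 <- detect_phases(den$denoised, den$t, phase_config())
  shared <- intersect(which(ev0$complete), which(ev1$complete))
  expect_gt(length(shared), 0)
  dt <- 0.01
  for (col in c("relaxed_start", "contraction_onset", "peak_contraction",
                "relaxation_end")) {
    expect_true(all(abs(ev1[[col]][shared] - ev0[[col]][shared]) <= 3 * dt))
  }
})
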