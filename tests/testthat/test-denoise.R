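fake_labelled <- function(frames, lengths, longitudinal = "center",
                          transverse = "top") {
  data.frame(frame = as.integer(frames), length_um = lengths,
             longitudinal = longitudinal, transverse = transverse)
}

test_that("average_length_signal takes per-frame unweighted means", {
  s <- fake_labelled(c(0, 0, 0), c(1.8, 2.0, 2.2))
  sig <- average_length_signal(s, "whole", fps = 100, n_frames = 2L)
  expect_equal(sig$raw[1], 2.0)
  expect_true(is.na(sig$raw[2]))   # frame with no sarcomeres is missing
  expect_identical(sig$n, c(3L, 0L))
  s2 <- fake_labelled(0, 2.0)
  expect_equal(average_length_signal(s2, "whole", 100, 1L)$raw, 2.0)
  expect_error(average_length_signal(s, "right", 100, 2L), "empty")
})

test_that("region selectors filter on both labels", {
  s <- rbind(fake_labelled(0, 2.0, "left", "top"),
             fake_labelled(0, 3.0, "left", "bottom"),
             fake_labelled(0, 4.0, "right", "bottom"))
  expect_equal(average_length_signal(s, "left", 100, 1L)$raw, 2.5)
  expect_equal(average_length_signal(s, "bottom", 100, 1L)$raw, 3.5)
  expect_equal(average_length_signal(s, "left-bottom", 100, 1L)$raw, 3.0)
  expect_error(average_length_signal(s, "middle", 100, 1L), "unknown region")
})

test_that("GPR on a constant signal returns the constant with zero noise", {
  sig <- structure(list(region = "whole", t = seq(0, 0.99, 0.01),
                        raw = rep(2, 100), fps = 100),
                   class = "length_signal")
  den <- gpr_denoise(sig)
  expect_equal(den$denoised, rep(2, 100), tolerance = 1e-9)
  expect_equal(den$noise_level, 0)
})

test_that("GPR denoises a noisy cosine to well under the injected noise", {
  set.seed(21)
  t <- seq(0, 5 - 0.01, by = 0.01)
  truth <- 2.0 - 0.2 * (1 - cos(2 * pi * t))
  raw <- truth + rnorm(length(t), 0, 0.05)
  sig <- structure(list(region = "whole", t = t, raw = raw, fps = 100),
                   class = "length_signal")
  den <- gpr_denoise(sig, kernel_config())
  rmse <- sqrt(mean((den$denoised - truth)^2))
  expect_lt(rmse, 0.05)
  expect_gt(den$noise_level, 0.03)
  expect_lt(den$noise_level, 0.07)
  # definitional identity
  expect_equal(den$noise_level, sd(raw - den$denoised), tolerance = 1e-12)
  # denoising never increases roughness
  expect_lte(sd(diff(den$denoised)), sd(diff(raw)))
  # fitted periodic component recovers the 1 s period within 10%
  expect_lt(abs(den$hyperparameters[["period"]] - 1), 0.1)
})

test_that("missing frames are excluded from training and interpolated", {
  set.seed(22)
  t <- seq(0, 3 - 0.01, by = 0.01)
  truth <- 2.0 - 0.15 * (1 - cos(2 * pi * t))
  raw <- truth + rnorm(length(t), 0, 0.02)
  gaps <- c(40:45, 150:160)
  raw[gaps] <- NA
  sig <- structure(list(region = "whole", t = t, raw = raw, fps = 100),
                   class = "length_signal")
  den <- gpr_denoise(sig)
  expect_true(all(is.finite(den$denoised)))
  expect_lt(max(abs(den$denoised[gaps] - truth[gaps])), 0.05)
  expect_error(gpr_denoise(structure(list(t = t[1:20], raw = raw[1:20]),
                                     class = "length_signal")),
               "at least 50")
})
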