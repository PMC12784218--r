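test_that("waveform handles the zero-amplitude and noiseless cases", {
  p0 <- waveform_params(resting_length = 2.0, amplitude = 0, n_cycles = 3L)
  wf0 <- generate_length_waveform(p0, seed = 1)
  expect_true(all(wf0$length == 2.0))
  expect_identical(nrow(wf0$events), 0L)

  p <- std_params(noise_sd = 0)
  wf <- generate_length_waveform(p, seed = 1)
  expect_equal(min(wf$length), 1.6, tolerance = 1e-12)
  # the minimum is reached exactly at each cycle's descent end
  idx_min <- which(wf$length == min(wf$length))
  expect_equal(wf$t[idx_min], wf$events$peak_contraction)
})

test_that("raised-cosine descent has peak slope pi*A/(2*d_c)", {
  p <- waveform_params(amplitude = 0.4, contraction_duration = 0.2,
                       expansion_duration = 0.3, n_cycles = 2L,
                       fps = 2000, noise_sd = 0)  # fine grid for the oracle
  wf <- generate_length_waveform(p, seed = 1)
  slope <- diff(wf$clean) * p$fps            # finite-difference oracle
  expect_equal(max(abs(slope)), pi * 0.4 / (2 * 0.2), tolerance = 1e-3)
})

test_that("noiseless waveform is T-periodic and events count n_cycles", {
  for (Tp in c(0.8, 1.25)) {
    p <- waveform_params(period = Tp, n_cycles = 4L, noise_sd = 0)
    wf <- generate_length_waveform(p, seed = 1)
    shift <- round(Tp * p$fps)
    n <- length(wf$clean)
    expect_equal(wf$clean[seq_len(n - shift)],
                 wf$clean[(shift + 1):n], tolerance = 1e-12)
    expect_identical(nrow(wf$events), 4L)
  }
})

test_that("invalid waveform parameters error", {
  expect_error(waveform_params(amplitude = 2.5), "amplitude")
  expect_error(waveform_params(contraction_duration = 0.9,
                               expansion_duration = 0.3), "exceed")
  expect_error(waveform_params(fps = 0), "fps")
})

test_that("rendered movie is static for a constant waveform", {
  g <- geometry_preset("mini")
  fr <- render_movie(rep(2.0, 3), g, seed = 1, noise_sd = 0)
  expect_identical(fr[[1]], fr[[2]])
  expect_identical(fr[[2]], fr[[3]])
})

test_that("stripe count is floor(length / spacing) and rendering is seeded", {
  g <- geometry_preset("mini")  # 100 um at 2.0 um spacing
  fr <- render_movie(2.0, g, seed = 1, noise_sd = 10)
  expect_identical(attr(fr, "n_stripes"), 50L)
  fr2 <- render_movie(2.0, g, seed = 1, noise_sd = 10)
  expect_identical(fr[[1]], fr2[[1]])  # same seed, bit-identical
  fr3 <- render_movie(2.0, g, seed = 2, noise_sd = 10)
  expect_false(identical(fr[[1]], fr3[[1]]))
})

test_that("rendered stripe spacing matches the waveform value", {
  g <- geometry_preset("mini")
  for (sp_um in c(2.0, 1.7)) {
    fr <- render_movie(sp_um, g, seed = 1, noise_sd = 0)[[1]]
    sp_px <- oracle_stripe_spacing(fr, g$rotation)
    expect_lt(abs(sp_px - sp_um / g$um_per_px), 0.5)
  }
})

test_that("oversized tissue raises a geometry error", {
  g <- geometry_preset("mini", image_shape = c(60, 60))
  expect_error(render_movie(2.0, g, seed = 1), "exceeds image bounds")
})

test_that("simulate_movie writes a TIFF and a ground-truth sidecar", {
  dir <- withr::local_tempdir()
  p <- std_params(n_cycles = 1L)
  sim <- simulate_movie(p, geometry_preset("mini"), seed = 1,
                        out_dir = dir)
  expect_true(file.exists(sim$paths[["movie"]]))
  back <- read_tiff_stack(sim$paths[["movie"]])
  expect_length(back, length(sim$frames))
  expect_equal(back[[1]], round(sim$frames[[1]]), tolerance = 1e-12)
  truth <- jsonlite::read_json(sim$paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$length, sim$waveform$length, tolerance = 1e-9)
  expect_identical(nrow(truth$events), 1L)
})
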