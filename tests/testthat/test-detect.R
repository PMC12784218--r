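# helper: render isolated Gaussian blobs at given (row, col) centers
blob_frame <- function(centers, shape = c(100, 120), sigma = 2, amp = 500) {
  rows <- matrix(0:(shape[1] - 1), shape[1], shape[2])
  cols <- matrix(0:(shape[2] - 1), shape[1], shape[2], byrow = TRUE)
  img <- matrix(0, shape[1], shape[2])
  for (i in seq_len(nrow(centers))) {
    img <- img + amp * exp(-((rows - centers[i, 1])^2 +
                             (cols - centers[i, 2])^2) / (2 * sigma^2))
  }
  img
}

test_that("an all-zero frame yields no detections", {
  z <- detect_zdiscs(matrix(0, 50, 50), detect_config())
  expect_identical(nrow(z), 0L)
  expect_error(detect_zdiscs(matrix(NA_real_, 5, 5), detect_config()),
               "non-finite")
})

test_that("two isolated blobs are found at their true centroids", {
  frame <- blob_frame(rbind(c(50, 50), c(50, 80)))
  # isolated blobs are smaller than tissue stripes; relax the area gate
  z <- detect_zdiscs(frame, detect_config(min_zdisc_area = 10), frame_index = 7L)
  expect_identical(nrow(z), 2L)
  expect_true(all(z$frame == 7L))
  # brute-force oracle: intensity-weighted centroid over each blob's half
  oracle <- t(vapply(list(1:65, 66:120), function(cols) {
    sub <- frame[, cols]
    w <- sub / sum(sub)
    rows <- matrix(0:(nrow(sub) - 1), nrow(sub), ncol(sub))
    ccol <- matrix(cols - 1, nrow(sub), ncol(sub), byrow = TRUE)
    c(sum(w * rows), sum(w * ccol))
  }, numeric(2)))
  expect_lt(max(abs(sort(z$col) - sort(oracle[, 2]))), 0.5)
  expect_lt(max(abs(z$row - oracle[, 1])), 0.5)
})

test_that("a synthetic tissue frame yields one z-disc per rendered stripe", {
  g <- geometry_preset("mini")
  fr <- render_movie(2.0, g, seed = 2, noise_sd = 0)[[1]]
  z <- detect_zdiscs(fr, detect_config())
  expect_identical(nrow(z), attr(render_movie(2.0, g, seed = 2), "n_stripes"))
})

test_that("detection is translation-equivariant", {
  frame <- blob_frame(rbind(c(40, 40), c(40, 60), c(60, 50)))
  cfg <- detect_config(min_zdisc_area = 10)
  z0 <- detect_zdiscs(frame, cfg)
  dr <- 7L; dc <- -5L
  shifted <- matrix(0, nrow(frame), ncol(frame))
  shifted[(1 + dr):nrow(frame), 1:(ncol(frame) + dc)] <-
    frame[1:(nrow(frame) - dr), (1 - dc):ncol(frame)]
  z1 <- detect_zdiscs(shifted, cfg)
  expect_identical(nrow(z1), nrow(z0))
  o0 <- order(z0$col); o1 <- order(z1$col)  # match blobs by column order
  expect_lt(max(abs(z1$row[o1] - (z0$row[o0] + dr))), 0.05)
  expect_lt(max(abs(z1$col[o1] - (z0$col[o0] + dc))), 0.05)
})

test_that("pairing needs at least two discs and respects the length gate", {
  one <- data.frame(frame = 0L, row = 10, col = 10, area = 30,
                    orientation = 0)
  expect_identical(nrow(link_sarcomeres(one, detect_config(), 1)), 0L)
  two <- data.frame(frame = 0L, row = c(0, 0), col = c(0, 10), area = 30,
                    orientation = pi / 2)
  expect_identical(nrow(link_sarcomeres(two, detect_config(max_sarc_len = 3),
                                        um_per_px = 1)), 0L)
})

test_that("collinear discs at 2.0 um spacing pair into a chain", {
  n <- 10L
  discs <- data.frame(frame = 0L, row = rep(0, n),
                      col = seq(0, by = 2, length.out = n), area = 30,
                      orientation = pi / 2)  # stripes run along rows
  s <- link_sarcomeres(discs, detect_config(), um_per_px = 1)
  expect_identical(nrow(s), n - 1L)
  expect_true(all(abs(s$length_um - 2.0) < 1e-9))
  # every reported length respects the configured gate
  cfg <- detect_config(min_sarc_len = 1.0, max_sarc_len = 3.0)
  set.seed(11)
  rand <- data.frame(frame = 0L, row = runif(40, 0, 30),
                     col = runif(40, 0, 30), area = 30,
                     orientation = runif(40, -pi / 2, pi / 2))
  sr <- link_sarcomeres(rand, cfg, um_per_px = 1)
  if (nrow(sr) > 0) {
    expect_true(all(sr$length_um >= 1.0 & sr$length_um <= 3.0))
    # no pair reported twice
    expect_false(any(duplicated(sr[, c("a", "b")])))
  }
})

test_that("per-frame mean length tracks the generating waveform within 2%", {
  sim <- std_movie()
  cfg <- detect_config()
  idx <- seq(1, length(sim$frames), by = 25)
  err <- vapply(idx, function(i) {
    z <- detect_zdiscs(sim$frames[[i]], cfg)
    s <- link_sarcomeres(z, cfg, geometry_preset("mini")$um_per_px)
    abs(mean(s$length_um) - sim$waveform$length[i])
  }, 0)
  expect_lt(max(err), 0.02 * 2.0)
})
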