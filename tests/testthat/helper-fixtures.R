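# Shared fixtures, memoised so expensive simulations run once per session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# the standard scaled-down movie: L0 = 2.0 um, A = 0.4 um, T = 1.0 s,
# 5 cycles at 100 fps, moderate pixel noise; ~100 x 30 um tissue at
# 0.25 um/px rotated 10 degrees
std_params <- function(amplitude = 0.4, period = 1.0, n_cycles = 5L,
                       noise_sd = 0.01) {
  waveform_params(resting_length = 2.0, amplitude = amplitude,
                  period = period, contraction_duration = 0.2,
                  expansion_duration = 0.3, n_cycles = n_cycles,
                  fps = 100, noise_sd = noise_sd)
}

std_pixel_noise <- 45  # ~5% of the foreground level

std_movie <- function() {
  memo("std_movie", simulate_movie(std_params(), geometry_preset("mini"),
                                   seed = 3L, pixel_noise_sd = std_pixel_noise))
}

std_config <- function(regions = c("whole", "thirds")) {
  pipeline_config(um_per_px = 0.25, fps = 100, regions = regions, seed = 1L)
}

std_run <- function() {
  memo("std_run", run_pipeline(std_movie()$frames, std_config()))
}

# a single relaxed-state frame of the mini geometry, no noise
std_frame <- function() {
  memo("std_frame",
       render_movie(2.0, geometry_preset("mini"), seed = 5L, noise_sd = 0)[[1]])
}

# brute-force oracle: stripe spacing from a frame by intensity-profile peak
# finding along the long axis (independent of the detection module)
oracle_stripe_spacing <- function(frame, rotation_deg) {
  th <- rotation_deg * pi / 180
  nr <- nrow(frame); nc <- ncol(frame)
  cr <- (nr - 1) / 2; cc <- (nc - 1) / 2
  rows <- matrix(0:(nr - 1), nr, nc)
  cols <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  U <- (cols - cc) * cos(th) + (rows - cr) * sin(th)
  V <- -(cols - cc) * sin(th) + (rows - cr) * cos(th)
  sel <- abs(V) < 5
  bins <- round(U[sel])
  prof <- tapply(frame[sel], bins, mean)
  u <- as.numeric(names(prof))
  o <- order(u); u <- u[o]; prof <- as.numeric(prof)[o]
  peaks <- which(diff(sign(diff(prof))) == -2) + 1L
  peaks <- peaks[prof[peaks] > mean(prof)]
  mean(diff(u[peaks]))
}
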