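# Synthetic 2DMB movies and sarcomere-length waveforms with known ground
# truth. The generator emulates a rotated rectangular tissue of periodic
# bright stripes (z-discs) whose center-to-center spacing follows a
# prescribed contraction waveform, over a noisy background.

#' Waveform parameters for a synthetic contraction cycle
#'
#' Each cycle consists of a relaxed plateau at the resting length, a
#' shortening ramp down to `resting_length - amplitude`, and a
#' re-lengthening ramp back; plateau + contraction + expansion durations sum
#' to the period.
#'
#' @param resting_length resting sarcomere length L0 (um).
#' @param amplitude shortening amplitude A (um), `0 <= A < L0`.
#' @param period beat period T (s).
#' @param contraction_duration shortening ramp duration (s).
#' @param expansion_duration re-lengthening ramp duration (s).
#' @param n_cycles number of beats.
#' @param fps sampling rate (frames/s).
#' @param noise_sd i.i.d. Gaussian noise added to the sampled lengths (um).
#' @return an object of class `waveform_params`.
#' @export
waveform_params <- function(resting_length = 2.0, amplitude = 0.3,
                            period = 1.0, contraction_duration = 0.2,
                            expansion_duration = 0.3, n_cycles = 5L,
                            fps = 100, noise_sd = 0) {
  p <- list(resting_length = resting_length, amplitude = amplitude,
            period = period, contraction_duration = contraction_duration,
            expansion_duration = expansion_duration,
            plateau_duration = period - contraction_duration - expansion_duration,
            n_cycles = as.integer(n_cycles), fps = fps, noise_sd = noise_sd)
  if (!(resting_length > 0)) stop("waveform_params: resting_length must be > 0")
  if (amplitude < 0 || amplitude >= resting_length)
    stop("waveform_params: need 0 <= amplitude < resting_length")
  if (contraction_duration <= 0 || expansion_duration <= 0)
    stop("waveform_params: ramp durations must be > 0")
  if (p$plateau_duration < 0)
    stop("waveform_params: contraction + expansion durations exceed the period")
  if (fps <= 0) stop("waveform_params: fps must be > 0")
  if (noise_sd < 0) stop("waveform_params: noise_sd must be >= 0")
  if (p$n_cycles < 1L) stop("waveform_params: n_cycles must be >= 1")
  class(p) <- "waveform_params"
  p
}

#' Generate a sarcomere-length waveform with ground-truth phase boundaries
#'
#' Each cycle is a plateau at L0 for the plateau duration, a ramp down to
#' `L0 - A` over the contraction duration, and a ramp back up over the
#' expansion duration. Ramps are raised-cosine (C1-smooth) by default; a
#' linear-ramp variant is kept for analytic phase tests.
#'
#' @param params a [waveform_params()] object.
#' @param seed integer seed for the additive noise.
#' @param ramp `"cosine"` (default) or `"linear"`.
#' @return list with `t` (s), `length` (um, noisy), `clean` (noiseless), and
#'   `events`: a data.frame of per-cycle ground truth times
#'   (`relaxed_start`, `contraction_onset`, `peak_contraction`,
#'   `relaxation_end`, all s).
#' @export
generate_length_waveform <- function(params, seed = 1L,
                                     ramp = c("cosine", "linear")) {
  stopifnot(inherits(params, "waveform_params"))
  ramp <- match.arg(ramp)
  L0 <- params$resting_length; A <- params$amplitude
  Tp <- params$period; dc <- params$contraction_duration
  de <- params$expansion_duration; dr <- params$plateau_duration
  n <- round(params$n_cycles * Tp * params$fps)
  t <- (seq_len(n) - 1) / params$fps
  tau <- t %% Tp
  s <- rep(L0, n)
  in_c <- tau >= dr & tau < dr + dc
  in_e <- tau >= dr + dc
  if (ramp == "cosine") {
    s[in_c] <- L0 - A * (1 - cos(pi * (tau[in_c] - dr) / dc)) / 2
    s[in_e] <- L0 - A * (1 + cos(pi * (tau[in_e] - dr - dc) / de)) / 2
  } else {
    s[in_c] <- L0 - A * (tau[in_c] - dr) / dc
    s[in_e] <- L0 - A * (1 - (tau[in_e] - dr - dc) / de)
  }
  noisy <- s
  if (params$noise_sd > 0) {
    set.seed(as.integer(seed))
    noisy <- s + stats::rnorm(n, 0, params$noise_sd)
  }
  k <- seq_len(params$n_cycles) - 1
  events <- if (A > 0) {
    data.frame(cycle = k + 1L,
               relaxed_start = k * Tp,
               contraction_onset = k * Tp + dr,
               peak_contraction = k * Tp + dr + dc,
               relaxation_end = (k + 1) * Tp)
  } else {
    data.frame(cycle = integer(), relaxed_start = numeric(),
               contraction_onset = numeric(), peak_contraction = numeric(),
               relaxation_end = numeric())
  }
  list(t = t, length = noisy, clean = s, events = events, params = params)
}

#' Geometry of the synthetic rectangular tissue
#'
#' Defaults follow the 2DMB platform: a high-aspect-ratio rectangle of about
#' 308 um x 44 um with z-disc stripes perpendicular to the long axis.
#'
#' @param length,width tissue dimensions (um) in the relaxed state.
#' @param rotation long-axis angle from the image column axis (degrees).
#' @param stripe_spacing_relaxed relaxed z-disc spacing (um); this is the
#'   resting sarcomere length the renderer encodes.
#' @param stripe_width z-disc stripe width (um).
#' @param background_level,foreground_level image intensities (uint16 scale).
#' @param diffuse_level intensity of the tissue body between stripes;
#'   default 30% of the way from background to foreground.
#' @param image_shape `c(rows, cols)` in px, or `NULL` to auto-fit with a
#'   margin.
#' @param um_per_px spatial calibration (um/pixel).
#' @return an object of class `tissue_geometry`.
#' @export
tissue_geometry <- function(length = 308, width = 44, rotation = 15,
                            stripe_spacing_relaxed = 2.0, stripe_width = 0.6,
                            background_level = 100, foreground_level = 1000,
                            diffuse_level = NULL, image_shape = NULL,
                            um_per_px = 0.25) {
  if (!(length > width && width > 0))
    stop("tissue_geometry: need length > width > 0")
  if (!(stripe_spacing_relaxed > stripe_width && stripe_width > 0))
    stop("tissue_geometry: need stripe_spacing_relaxed > stripe_width > 0")
  if (!(foreground_level > background_level))
    stop("tissue_geometry: need foreground_level > background_level")
  if (um_per_px <= 0) stop("tissue_geometry: um_per_px must be > 0")
  if (is.null(diffuse_level))
    diffuse_level <- background_level + 0.3 * (foreground_level - background_level)
  g <- list(length = length, width = width, rotation = rotation,
            stripe_spacing_relaxed = stripe_spacing_relaxed,
            stripe_width = stripe_width,
            background_level = background_level,
            foreground_level = foreground_level,
            diffuse_level = diffuse_level,
            image_shape = image_shape, um_per_px = um_per_px)
  if (is.null(image_shape)) {
    th <- rotation * pi / 180
    lp <- length / um_per_px; wp <- width / um_per_px
    rows <- abs(lp * sin(th)) + abs(wp * cos(th)) + 24
    cols <- abs(lp * cos(th)) + abs(wp * sin(th)) + 24
    g$image_shape <- c(ceiling(rows), ceiling(cols))
  }
  class(g) <- "tissue_geometry"
  g
}

#' Preset geometries
#'
#' `"2dmb"` is the full-size platform geometry (~308 x 44 um at 0.5 um/px);
#' `"mini"` is a scaled-down tissue (100 x 30 um at 0.25 um/px) used to keep
#' end-to-end simulations fast.
#'
#' @param name preset name.
#' @param ... overrides passed to [tissue_geometry()].
#' @export
geometry_preset <- function(name = c("2dmb", "mini"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "2dmb" = list(length = 308, width = 44, rotation = 15, um_per_px = 0.25),
    "mini" = list(length = 100, width = 30, rotation = 10, um_per_px = 0.25))
  do.call(tissue_geometry, utils::modifyList(base, list(...)))
}

#' Render a synthetic 2DMB movie from a length waveform
#'
#' Each frame shows the rotated rectangular tissue with bright stripes
#' perpendicular to the long axis; the stripe center-to-center spacing
#' equals the waveform value at that frame, and the tissue shortens about
#' its centroid along the long axis as the spacing decreases (the width is
#' unchanged). Stripes have a Gaussian cross-section of about 1 px to avoid
#' aliasing at sub-pixel spacings.
#'
#' @param waveform output of [generate_length_waveform()], or a numeric
#'   vector of lengths (um).
#' @param geom a [tissue_geometry()] object.
#' @param seed integer seed for the pixel noise.
#' @param noise_sd Gaussian pixel noise standard deviation (intensity units).
#' @return list of numeric frame matrices with attributes `um_per_px` and
#'   `n_stripes`.
#' @export
render_movie <- function(waveform, geom, seed = 1L, noise_sd = 0) {
  stopifnot(inherits(geom, "tissue_geometry"))
  lengths_um <- if (is.list(waveform)) waveform$length else as.numeric(waveform)
  if (any(!is.finite(lengths_um)) || any(lengths_um <= 0))
    stop("render_movie: waveform lengths must be finite and > 0")
  shp <- geom$image_shape
  nr <- shp[1]; nc <- shp[2]
  th <- geom$rotation * pi / 180
  cr <- (nr - 1) / 2; cc <- (nc - 1) / 2
  # rotated tissue coordinates of every pixel (u along long axis, v across)
  rows <- matrix(0:(nr - 1), nr, nc)
  cols <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  U <- (cols - cc) * cos(th) + (rows - cr) * sin(th)
  V <- -(cols - cc) * sin(th) + (rows - cr) * cos(th)
  upx <- geom$um_per_px
  len_px0 <- geom$length / upx
  wid_px <- geom$width / upx
  n_str <- floor(geom$length / geom$stripe_spacing_relaxed)
  # geometry check at the largest extent reached by the waveform
  max_scale <- max(lengths_um) / geom$stripe_spacing_relaxed
  hl <- len_px0 * max_scale / 2; hw <- wid_px / 2
  ext_r <- abs(hl * sin(th)) + abs(hw * cos(th))
  ext_c <- abs(hl * cos(th)) + abs(hw * sin(th))
  if (cr - ext_r < 0 || cc - ext_c < 0 || cr + ext_r > nr - 1 || cc + ext_c > nc - 1)
    stop("render_movie: tissue rectangle exceeds image bounds")
  sigma_px <- max(1.0, geom$stripe_width / upx / 2)
  set.seed(as.integer(seed))
  frames <- vector("list", length(lengths_um))
  for (i in seq_along(lengths_um)) {
    spacing_px <- lengths_um[i] / upx
    scale <- lengths_um[i] / geom$stripe_spacing_relaxed
    half_len <- len_px0 * scale / 2
    inside <- abs(U) <= half_len & abs(V) <= hw
    u0 <- -(n_str - 1) / 2 * spacing_px
    idx <- pmin(pmax(round((U - u0) / spacing_px), 0), n_str - 1)
    d <- abs(U - (u0 + idx * spacing_px))
    stripe <- exp(-d^2 / (2 * sigma_px^2))
    img <- matrix(geom$background_level, nr, nc)
    img[inside] <- geom$diffuse_level +
      (geom$foreground_level - geom$diffuse_level) * stripe[inside]
    if (noise_sd > 0) img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
    frames[[i]] <- img
  }
  attr(frames, "um_per_px") <- upx
  attr(frames, "n_stripes") <- as.integer(n_str)
  frames
}

#' Simulate a complete synthetic movie with ground truth
#'
#' Convenience wrapper: waveform generation + rendering, optionally written
#' to disk as a multi-page 16-bit TIFF plus a JSON ground-truth sidecar
#' (waveform samples, event times, geometry).
#'
#' @param params a [waveform_params()] object.
#' @param geom a [tissue_geometry()] object.
#' @param seed integer seed (waveform noise and pixel noise derive from it).
#' @param pixel_noise_sd Gaussian pixel noise sd (intensity units).
#' @param out_dir if non-NULL, write `movie.tif` and `truth.json` there.
#' @param ramp ramp shape, see [generate_length_waveform()].
#' @return list with `frames`, `waveform`, `geom`, and (if written) `paths`.
#' @export
simulate_movie <- function(params = waveform_params(),
                           geom = geometry_preset("mini"),
                           seed = 1L, pixel_noise_sd = 0, out_dir = NULL,
                           ramp = "cosine") {
  wf <- generate_length_waveform(params, seed = seed, ramp = ramp)
  frames <- render_movie(wf, geom, seed = seed + 1L, noise_sd = pixel_noise_sd)
  out <- list(frames = frames, waveform = wf, geom = geom)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tif <- file.path(out_dir, "movie.tif")
    write_tiff_stack(frames, tif)
    truth <- list(t = wf$t, length = wf$length, clean = wf$clean,
                  events = wf$events,
                  geometry = unclass(geom), params = unclass(params),
                  n_stripes = attr(frames, "n_stripes"),
                  seed = seed, pixel_noise_sd = pixel_noise_sd)
    js <- file.path(out_dir, "truth.json")
    jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA, null = "null")
    out$paths <- c(movie = tif, truth = js)
  }
  out
}
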