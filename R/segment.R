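# Per-frame tissue segmentation: background-noise suppression, Gaussian
# blur, Otsu binarization, convex hull of the foreground, and the
# minimum-area rotated rectangle defining the tissue boundary.

#' Segmentation configuration
#'
#' @param noise_patch `c(row0, col0, rows, cols)` (0-based px) of the patch
#'   used to estimate background noise; default the top-left 20 x 20 corner.
#' @param noise_k suppression threshold multiplier: pixels below
#'   `mean + noise_k * sd` of the patch are zeroed before blurring.
#' @param blur_sigma Gaussian blur sd (px).
#' @return an object of class `segment_config`.
#' @export
segment_config <- function(noise_patch = c(0L, 0L, 20L, 20L), noise_k = 3,
                           blur_sigma = 2) {
  if (blur_sigma <= 0) stop("segment_config: blur_sigma must be > 0")
  if (length(noise_patch) != 4L || any(noise_patch[3:4] < 1))
    stop("segment_config: noise_patch must be c(row0, col0, rows, cols)")
  structure(list(noise_patch = as.integer(noise_patch), noise_k = noise_k,
                 blur_sigma = blur_sigma),
            class = "segment_config")
}

#' Estimate background noise from a small image region
#'
#' @param frame numeric matrix.
#' @param patch `c(row0, col0, rows, cols)`, 0-based.
#' @return list with `mean` and `sd` of the patch intensities.
#' @export
estimate_background_noise <- function(frame, patch = c(0L, 0L, 20L, 20L)) {
  r0 <- patch[1]; c0 <- patch[2]; nr <- patch[3]; nc <- patch[4]
  if (r0 < 0 || c0 < 0 || r0 + nr > nrow(frame) || c0 + nc > ncol(frame))
    stop("estimate_background_noise: patch out of bounds")
  if (nr * nc < 16) stop("estimate_background_noise: patch must cover >= 16 px")
  x <- frame[(r0 + 1):(r0 + nr), (c0 + 1):(c0 + nc)]
  list(mean = mean(x), sd = stats::sd(as.numeric(x)))
}

#' Segment the tissue in a single frame
#'
#' Noise-suppress (pixels below `mean + noise_k * sd` of the background
#' patch set to 0), Gaussian blur, Otsu threshold on the blurred image,
#' convex hull of the foreground pixels, minimum-area rotated rectangle of
#' the hull. Frames are processable independently (safe to parallelize).
#'
#' @param frame numeric matrix.
#' @param cfg a [segment_config()] object.
#' @param frame_index 0-based frame index carried in the result.
#' @return an object of class `tissue_mask`: list with `frame_index`,
#'   `foreground` (logical matrix), `hull_vertices` (matrix of 0-based
#'   (row, col)), `hull_area` (px^2), `rect_center` (row, col), `rect_dims`
#'   c(long, short) px, `rect_angle` degrees in (-90, 90], `rect_area` px^2.
#' @export
segment_tissue <- function(frame, cfg = segment_config(), frame_index = 0L) {
  if (any(!is.finite(frame))) stop("segment_tissue: non-finite pixels")
  bg <- estimate_background_noise(frame, cfg$noise_patch)
  thr_noise <- bg$mean + cfg$noise_k * bg$sd
  supp <- frame
  supp[supp < thr_noise] <- 0
  if (!any(frame > thr_noise)) {
    stop(structure(class = c("segmentation_failure", "error", "condition"),
                   list(message = sprintf(
                     "segment_tissue: no above-threshold pixels in frame %d",
                     frame_index), call = sys.call())))
  }
  blurred <- gaussian_blur(supp, cfg$blur_sigma)
  thr <- otsu_threshold(blurred)
  fg <- blurred > thr
  if (!any(fg)) {
    stop(structure(class = c("segmentation_failure", "error", "condition"),
                   list(message = sprintf(
                     "segment_tissue: empty foreground after Otsu in frame %d",
                     frame_index), call = sys.call())))
  }
  idx <- which(fg)
  pts <- cbind(row = (idx - 1L) %% nrow(fg), col = (idx - 1L) %/% nrow(fg))
  hull_idx <- grDevices::chull(pts[, 2], pts[, 1])
  hull <- pts[hull_idx, , drop = FALSE]
  rect <- min_area_rect(pts)
  structure(list(frame_index = as.integer(frame_index), foreground = fg,
                 hull_vertices = hull,
                 hull_area = convex_hull_area(pts),
                 rect_center = rect$center, rect_dims = rect$dims,
                 rect_angle = rect$angle_deg, rect_area = rect$area,
                 rect_corners = rect$corners,
                 noise_mean = bg$mean, noise_sd = bg$sd),
            class = "tissue_mask")
}
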