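# Frame-by-frame z-disc detection and z-disc pairing into sarcomeres.
# No temporal tracking: each frame is processed independently, which is
# robust to z-discs moving in and out of focus between frames.

#' Detection configuration
#'
#' @param band_sigma_narrow,band_sigma_wide difference-of-Gaussians scales
#'   (px); the band-pass is tuned to the z-disc stripe width.
#' @param zdisc_threshold_quantile quantile of the positive band-pass
#'   response used as the detection threshold.
#' @param min_zdisc_area minimum connected-component area (px^2).
#' @param min_sarc_len,max_sarc_len physiologic sarcomere length gate (um).
#' @param angle_tolerance maximum deviation (radians) of the pair vector
#'   from the perpendicular to each disc's stripe orientation.
#' @param max_zdiscs_per_frame hard cap used by QC flagging.
#' @return an object of class `detect_config`.
#' @export
detect_config <- function(band_sigma_narrow = 1.0, band_sigma_wide = 2.5,
                          zdisc_threshold_quantile = 0.6,
                          min_zdisc_area = 20,
                          min_sarc_len = 1.0, max_sarc_len = 3.0,
                          angle_tolerance = 30 * pi / 180,
                          max_zdiscs_per_frame = 1500L) {
  if (!(band_sigma_narrow < band_sigma_wide))
    stop("detect_config: band_sigma_narrow must be < band_sigma_wide")
  if (!(min_sarc_len > 0 && min_sarc_len < max_sarc_len))
    stop("detect_config: need 0 < min_sarc_len < max_sarc_len")
  if (zdisc_threshold_quantile <= 0 || zdisc_threshold_quantile >= 1)
    stop("detect_config: zdisc_threshold_quantile must be in (0, 1)")
  structure(list(band_sigma_narrow = band_sigma_narrow,
                 band_sigma_wide = band_sigma_wide,
                 zdisc_threshold_quantile = zdisc_threshold_quantile,
                 min_zdisc_area = min_zdisc_area,
                 min_sarc_len = min_sarc_len, max_sarc_len = max_sarc_len,
                 angle_tolerance = angle_tolerance,
                 max_zdiscs_per_frame = as.integer(max_zdiscs_per_frame)),
            class = "detect_config")
}

#' Detect z-discs in a single frame
#'
#' Difference-of-Gaussians band-pass at the z-disc scale, thresholded at a
#' quantile of the positive response, connected components (8-connected),
#' area filter, intensity-weighted centroids and second-moment orientations.
#'
#' @param frame numeric intensity matrix.
#' @param cfg a [detect_config()] object.
#' @param frame_index 0-based frame index stored in the output.
#' @return data.frame with columns `frame`, `row`, `col` (0-based px),
#'   `area` (px^2), `orientation` (radians, stripe major axis), sorted by
#'   (row, col).
#' @export
detect_zdiscs <- function(frame, cfg = detect_config(), frame_index = 0L) {
  if (!is.matrix(frame) || length(frame) == 0L)
    stop("detect_zdiscs: frame must be a non-empty matrix")
  if (any(!is.finite(frame)))
    stop("detect_zdiscs: frame contains non-finite pixels")
  resp <- dog_filter(frame, cfg$band_sigma_narrow, cfg$band_sigma_wide)
  pos <- resp[resp > 0]
  empty <- data.frame(frame = integer(), row = numeric(), col = numeric(),
                      area = numeric(), orientation = numeric())
  if (length(pos) == 0L) return(empty)
  thr <- stats::quantile(pos, cfg$zdisc_threshold_quantile, names = FALSE)
  mask <- resp > thr
  if (!any(mask)) return(empty)
  labels <- label_mask(mask)
  st <- component_stats(labels, resp)
  st <- st[st$area >= cfg$min_zdisc_area, , drop = FALSE]
  if (nrow(st) == 0L) return(empty)
  st <- st[order(st$row, st$col), , drop = FALSE]
  data.frame(frame = as.integer(frame_index), row = st$row, col = st$col,
             area = st$area, orientation = st$orientation)
}

#' Pair z-discs into sarcomeres
#'
#' Candidate pairs must have a length in the physiologic gate and a
#' connecting vector within `angle_tolerance` of the perpendicular to both
#' discs' stripe orientations. Each disc keeps at most its two best-scoring
#' partners (score: deviation from the median candidate length, penalized by
#' angular misalignment); mutually accepted pairs become sarcomeres. Ties
#' are broken toward the partner with the lower (row, col).
#'
#' @param zdiscs data.frame from [detect_zdiscs()] (one frame).
#' @param cfg a [detect_config()] object.
#' @param um_per_px spatial calibration.
#' @return data.frame with `frame`, `a`, `b` (row indices into `zdiscs`),
#'   `length_um`, `mid_row`, `mid_col` (px), `axis_angle` (radians).
#' @export
link_sarcomeres <- function(zdiscs, cfg = detect_config(), um_per_px = 1) {
  empty <- data.frame(frame = integer(), a = integer(), b = integer(),
                      length_um = numeric(), mid_row = numeric(),
                      mid_col = numeric(), axis_angle = numeric())
  n <- nrow(zdiscs)
  if (is.null(n) || n < 2L) return(empty)
  if (length(unique(zdiscs$frame)) > 1L)
    stop("link_sarcomeres: z-discs must come from a single frame")
  dr <- outer(zdiscs$row, zdiscs$row, "-")
  dc <- outer(zdiscs$col, zdiscs$col, "-")
  len <- sqrt(dr^2 + dc^2) * um_per_px
  pair_ang <- atan2(dr, dc)  # angle of the connecting vector, col axis = 0
  ok <- len >= cfg$min_sarc_len & len <= cfg$max_sarc_len
  ok[lower.tri(ok, diag = TRUE)] <- FALSE
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  # deviation of the pair vector from the perpendicular to a stripe
  # orientation, folded to [0, pi/2]
  perp_dev <- function(pair, stripe) {
    d <- abs((pair - (stripe + pi / 2)) %% pi)
    pmin(d, pi - d)
  }
  dev_a <- perp_dev(pair_ang[idx], zdiscs$orientation[idx[, 1]])
  dev_b <- perp_dev(pair_ang[idx], zdiscs$orientation[idx[, 2]])
  keep <- dev_a <= cfg$angle_tolerance & dev_b <= cfg$angle_tolerance
  idx <- idx[keep, , drop = FALSE]
  if (nrow(idx) == 0L) return(empty)
  plen <- len[idx]
  med <- stats::median(plen)
  misalign <- pmax(dev_a[keep], dev_b[keep])
  score <- abs(plen - med) + 0.5 * misalign  # um-scale penalty per radian
  # rank candidates per disc; keep each disc's two best
  cand <- rbind(
    data.frame(disc = idx[, 1], partner = idx[, 2], pair = seq_len(nrow(idx)),
               score = score),
    data.frame(disc = idx[, 2], partner = idx[, 1], pair = seq_len(nrow(idx)),
               score = score))
  ord <- order(cand$disc, cand$score, zdiscs$row[cand$partner],
               zdiscs$col[cand$partner])
  cand <- cand[ord, , drop = FALSE]
  rank_in_disc <- stats::ave(seq_len(nrow(cand)), cand$disc, FUN = seq_along)
  cand <- cand[rank_in_disc <= 2L, , drop = FALSE]
  accepted <- table(cand$pair)
  mutual <- as.integer(names(accepted)[accepted == 2L])
  if (length(mutual) == 0L) return(empty)
  i <- idx[mutual, 1]; j <- idx[mutual, 2]
  out <- data.frame(frame = zdiscs$frame[i], a = i, b = j,
                    length_um = plen[mutual],
                    mid_row = (zdiscs$row[i] + zdiscs$row[j]) / 2,
                    mid_col = (zdiscs$col[i] + zdiscs$col[j]) / 2,
                    axis_angle = pair_ang[cbind(i, j)])
  out[order(out$mid_row, out$mid_col), , drop = FALSE]
}
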