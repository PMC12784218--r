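# Regional labels: each sarcomere midpoint is projected into the tissue
# rectangle's frame and binned into a longitudinal third (left/center/right)
# and a transverse half (top/bottom). Both labels are independent, so
# analyses can use three longitudinal segments, two halves, or their 6-way
# product (e.g. "left-top").

#' Assign regional labels to sarcomeres
#'
#' The midpoint is rotated into the rectangle frame; the longitudinal
#' coordinate u in \[0, 1\] runs along the long axis and the transverse v
#' along the short axis. Binning is half-open with the last bin closed:
#' u < 1/3 left, < 2/3 center, else right; v < 1/2 top, else bottom. The
#' u = 0 end is anchored at the rectangle end with the smaller column
#' coordinate (smaller row breaks ties) so labels are stable across frames.
#' Sarcomeres outside the rectangle by more than `tol` (relative units) are
#' dropped and counted in the `n_dropped` attribute.
#'
#' @param sarcomeres data.frame from [link_sarcomeres()].
#' @param mask a `tissue_mask` for the same frame.
#' @param tol out-of-rectangle tolerance in u/v units (default 0.02).
#' @return `sarcomeres` with added columns `u`, `v`, `longitudinal`,
#'   `transverse`; dropped rows removed; attribute `n_dropped`.
#' @export
assign_regions <- function(sarcomeres, mask, tol = 0.02) {
  stopifnot(inherits(mask, "tissue_mask"))
  if (nrow(sarcomeres) > 0 &&
      any(sarcomeres$frame != mask$frame_index))
    stop("assign_regions: sarcomere/mask frame mismatch")
  if (nrow(sarcomeres) == 0L) {
    out <- cbind(sarcomeres, u = numeric(0), v = numeric(0),
                 longitudinal = character(0), transverse = character(0))
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  th <- mask$rect_angle * pi / 180
  axis_long <- c(sin(th), cos(th))   # (row, col) components
  # anchor u = 0 at the end with the smaller column (then row) coordinate
  half <- mask$rect_dims[1] / 2
  end1 <- mask$rect_center - half * axis_long
  end2 <- mask$rect_center + half * axis_long
  flip <- (end2[2] < end1[2]) ||
    (abs(end2[2] - end1[2]) < 1e-9 && end2[1] < end1[1])
  if (flip) axis_long <- -axis_long
  # short axis tied to the (possibly flipped) long axis so the top/bottom
  # side is stable across frames of the same movie
  axis_short <- c(axis_long[2], -axis_long[1])
  dr <- sarcomeres$mid_row - mask$rect_center[1]
  dc <- sarcomeres$mid_col - mask$rect_center[2]
  u <- (dr * axis_long[1] + dc * axis_long[2]) / mask$rect_dims[1] + 0.5
  v <- (dr * axis_short[1] + dc * axis_short[2]) / mask$rect_dims[2] + 0.5
  keep <- u >= -tol & u <= 1 + tol & v >= -tol & v <= 1 + tol
  n_dropped <- sum(!keep)
  u <- pmin(pmax(u[keep], 0), 1)
  v <- pmin(pmax(v[keep], 0), 1)
  out <- sarcomeres[keep, , drop = FALSE]
  out$u <- u
  out$v <- v
  out$longitudinal <- ifelse(u < 1 / 3, "left",
                             ifelse(u < 2 / 3, "center", "right"))
  out$transverse <- ifelse(v < 1 / 2, "top", "bottom")
  attr(out, "n_dropped") <- n_dropped
  out
}
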