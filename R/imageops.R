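# Low-level image operations shared by detection and segmentation.
# Images are numeric matrices indexed (row, col); coordinates reported by
# higher-level code are 0-based (row, col) with origin at the top-left pixel.

gaussian_kernel1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- seq.int(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Dense 1-D convolution operator with reflected (symmetric) boundary,
# as an n x n matrix; blur of an image is Kr %*% img %*% t(Kc).
conv_operator <- function(n, kernel) {
  radius <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (off in seq_along(kernel)) {
    j0 <- seq_len(n) + (off - 1L - radius)
    # reflect indices: ... 2 1 | 1 2 ... n | n n-1 ...
    j <- ifelse(j0 < 1L, 1L - j0, ifelse(j0 > n, 2L * n + 1L - j0, j0))
    j <- pmin(pmax(j, 1L), n)
    K[cbind(seq_len(n), j)] <- K[cbind(seq_len(n), j)] + kernel[off]
  }
  K
}

#' Separable Gaussian blur with reflected boundary
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels.
#' @return blurred matrix of the same shape.
#' @keywords internal
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel1d(sigma)
  Kr <- conv_operator(nrow(img), k)
  Kc <- conv_operator(ncol(img), k)
  Kr %*% img %*% t(Kc)
}

# Difference-of-Gaussians band-pass at the z-disc scale.
dog_filter <- function(img, sigma_narrow, sigma_wide) {
  gaussian_blur(img, sigma_narrow) - gaussian_blur(img, sigma_wide)
}

#' Otsu's threshold
#'
#' Maximizes the between-class variance over a 256-bin histogram of the
#' image's intensity range. Returns a threshold such that `img > thr` is
#' foreground; for a two-valued image the two values are separated exactly.
#'
#' @param img numeric matrix or vector of intensities.
#' @param n_bins number of histogram bins.
#' @return scalar threshold on the intensity scale.
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  x <- as.numeric(img)
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("otsu_threshold: no finite pixels")
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- as.numeric(
    tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins),
             nbins = n_bins))
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(h)
  w1 <- sum(h) - w0
  m0 <- cumsum(h * mids) / pmax(w0, 1)
  m1 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w1, 1)
  between <- w0 * w1 * (m0 - m1)^2
  between[w0 == 0 | w1 == 0] <- -Inf
  edges[which.max(between) + 1L]
}

label_mask <- function(mask) {
  storage.mode(mask) <- "logical"
  .label_components(mask)
}

# Per-component statistics from a label matrix and a weight image:
# area (px^2), intensity-weighted centroid (0-based row/col), and the
# orientation (radians, major axis of the second-moment ellipse, in
# (-pi/2, pi/2]).
component_stats <- function(labels, weights) {
  n <- attr(labels, "n_components")
  if (is.null(n)) n <- max(labels)
  if (n == 0L) {
    return(data.frame(label = integer(), area = numeric(), row = numeric(),
                      col = numeric(), orientation = numeric()))
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  w <- pmax(weights[idx], 0)
  nr <- nrow(labels)
  ri <- (idx - 1L) %% nr       # 0-based row
  ci <- (idx - 1L) %/% nr      # 0-based col
  area <- as.numeric(tabulate(lab, nbins = n))
  wsum <- rowsum_vec(w, lab, n)
  # guard all-zero weights within a component (flat response): fall back to 1
  zero <- wsum <= 0
  if (any(zero)) {
    w[lab %in% which(zero)] <- 1
    wsum <- rowsum_vec(w, lab, n)
  }
  mr <- rowsum_vec(w * ri, lab, n) / wsum
  mc <- rowsum_vec(w * ci, lab, n) / wsum
  dr <- ri - mr[lab]
  dc <- ci - mc[lab]
  mrr <- rowsum_vec(w * dr * dr, lab, n) / wsum
  mcc <- rowsum_vec(w * dc * dc, lab, n) / wsum
  mrc <- rowsum_vec(w * dr * dc, lab, n) / wsum
  # major-axis angle measured from the column (x) axis; row axis points down
  theta <- 0.5 * atan2(2 * mrc, mcc - mrr)
  theta <- ifelse(theta > pi / 2, theta - pi, ifelse(theta <= -pi / 2, theta + pi, theta))
  data.frame(label = seq_len(n), area = area, row = mr, col = mc,
             orientation = theta)
}

rowsum_vec <- function(x, group, n) {
  out <- numeric(n)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' Minimum-area bounding rectangle of a point set
#'
#' Rotating-calipers search over convex-hull edge directions. Points are
#' (row, col) pairs; the returned angle is the orientation of the rectangle's
#' LONG axis measured from the column axis, mapped to (-90, 90] degrees.
#'
#' @param pts two-column matrix of (row, col) coordinates.
#' @return list with `center` (row, col), `dims` c(long, short) in px,
#'   `angle_deg`, `area`, and the 4 `corners` (rows of (row, col)).
#' @export
min_area_rect <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 1L) stop("min_area_rect: empty point set")
  # work in (x, y) = (col, row)
  xy <- cbind(pts[, 2], pts[, 1])
  h <- grDevices::chull(xy)
  hull <- xy[h, , drop = FALSE]
  nh <- nrow(hull)
  if (nh == 1L) {
    return(list(center = c(pts[1, 1], pts[1, 2]), dims = c(0, 0),
                angle_deg = 0, area = 0,
                corners = matrix(rep(pts[1, ], 4), ncol = 2, byrow = TRUE)))
  }
  edges <- hull[c(seq_len(nh)[-1], 1L), , drop = FALSE] - hull
  ang <- atan2(edges[, 2], edges[, 1])
  best <- NULL
  for (a in unique(round(ang %% (pi / 2), 12))) {
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)  # rotate by -a
    rot <- hull %*% R
    xr <- range(rot[, 1]); yr <- range(rot[, 2])
    area <- diff(xr) * diff(yr)
    if (is.null(best) || area < best$area - 1e-12) {
      best <- list(a = a, xr = xr, yr = yr, area = area)
    }
  }
  a <- best$a
  w <- diff(best$xr); hgt <- diff(best$yr)
  ctr_rot <- c(mean(best$xr), mean(best$yr))
  Rinv <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)  # rotate by +a
  ctr <- as.numeric(ctr_rot %*% Rinv)      # (x, y)
  if (w >= hgt) {
    dims <- c(w, hgt); long_ang <- a
  } else {
    dims <- c(hgt, w); long_ang <- a + pi / 2
  }
  # corners in rotated frame, back-rotated
  cr <- rbind(c(best$xr[1], best$yr[1]), c(best$xr[2], best$yr[1]),
              c(best$xr[2], best$yr[2]), c(best$xr[1], best$yr[2]))
  corners_xy <- cr %*% Rinv
  deg <- (long_ang * 180 / pi) %% 180
  if (deg > 90) deg <- deg - 180
  if (deg <= -90) deg <- deg + 180
  list(center = c(ctr[2], ctr[1]), dims = dims, angle_deg = deg,
       area = best$area, corners = cbind(corners_xy[, 2], corners_xy[, 1]))
}

# Area of the convex hull of (row, col) points (shoelace on chull vertices).
convex_hull_area <- function(pts) {
  xy <- cbind(pts[, 2], pts[, 1])
  h <- grDevices::chull(xy)
  v <- xy[h, , drop = FALSE]
  n <- nrow(v)
  if (n < 3L) return(0)
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
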