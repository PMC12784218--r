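# Heuristic contractile-phase detection on a denoised sarcomere-length
# signal: mean-centre, take a Savitzky-Golay derivative, find the relaxed
# plateau inside each positive block (samples above 80% of the block peak,
# searched inward until the derivative flattens), and the minimum length
# inside the following negative block.

#' Phase-detection configuration
#'
#' @param sg_window Savitzky-Golay window (odd sample count).
#' @param sg_polyorder polynomial order (< window).
#' @param high_zone_fraction fraction of the block peak defining the
#'   high-value zone (default 0.80).
#' @param derivative_threshold plateau flatness threshold (um/s). The
#'   relaxed state spans where `|d length/dt|` is below this value.
#' @return an object of class `phase_config`.
#' @export
phase_config <- function(sg_window = 11L, sg_polyorder = 3L,
                         high_zone_fraction = 0.80,
                         derivative_threshold = 0.1) {
  if (sg_window %% 2L != 1L || sg_window < 3L)
    stop("phase_config: sg_window must be odd and >= 3")
  if (sg_polyorder >= sg_window)
    stop("phase_config: sg_polyorder must be < sg_window")
  if (high_zone_fraction <= 0 || high_zone_fraction >= 1)
    stop("phase_config: high_zone_fraction must be in (0, 1)")
  if (derivative_threshold <= 0)
    stop("phase_config: derivative_threshold must be > 0")
  structure(list(sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 high_zone_fraction = high_zone_fraction,
                 derivative_threshold = derivative_threshold),
            class = "phase_config")
}

# Savitzky-Golay convolution coefficients for the given derivative order,
# in sample units (multiply by fps^deriv for physical units).
savgol_coeffs <- function(window, polyorder, deriv = 0L) {
  k <- (window - 1L) %/% 2L
  A <- outer(seq.int(-k, k), 0:polyorder, "^")
  C <- solve(crossprod(A), t(A))      # (polyorder+1) x window
  C[deriv + 1L, ] * factorial(deriv)
}

#' Savitzky-Golay smooth derivative
#'
#' Local polynomial least-squares derivative; edges are handled by fitting
#' the polynomial to the first/last full window and evaluating its
#' derivative at the edge positions (polynomial exactness is preserved, so
#' a linear ramp yields its slope everywhere).
#'
#' @param x numeric signal (um).
#' @param cfg a [phase_config()] object.
#' @param fps sampling rate, converts the per-sample derivative to um/s.
#' @return derivative series (um/s), same length as `x`.
#' @export
smooth_derivative <- function(x, cfg = phase_config(), fps = 100) {
  n <- length(x)
  m <- cfg$sg_window
  if (n < m) stop("smooth_derivative: signal shorter than sg_window")
  k <- (m - 1L) %/% 2L
  coef <- savgol_coeffs(m, cfg$sg_polyorder, 1L)
  d <- numeric(n)
  # interior: convolution
  for (i in (k + 1L):(n - k)) d[i] <- sum(coef * x[(i - k):(i + k)])
  # edges: evaluate the first/last window's polynomial derivative
  edge_deriv <- function(xs, at) {
    A <- outer(seq.int(0, m - 1L), 0:cfg$sg_polyorder, "^")
    beta <- solve(crossprod(A), crossprod(A, xs))
    p <- seq_len(cfg$sg_polyorder)
    vapply(at, function(z) sum(beta[p + 1L] * p * z^(p - 1L)), 0)
  }
  d[1:k] <- edge_deriv(x[1:m], seq.int(0, k - 1L))
  d[(n - k + 1L):n] <- edge_deriv(x[(n - m + 1L):n], seq.int(m - k, m - 1L))
  d * fps
}

runs_of <- function(cond) {
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect contractile phases in a denoised signal
#'
#' Implements the block heuristic: (1) mean-centre the signal; (2) in each
#' positive block (maximal run above the mean) define the high-value zone
#' as samples above `high_zone_fraction` of the block peak, then search
#' inward from the zone boundaries until the absolute derivative falls
#' below `derivative_threshold` -- the two stopping points mark the relaxed
#' state's start and end (the end is the contraction onset); (3) in the
#' negative block following each onset, the minimum length is the peak
#' contraction; (4) the relaxation end is the next block's relaxed start.
#' Events missing any endpoint (signal edges) are returned with
#' `complete = FALSE` and are excluded from cycle statistics downstream.
#'
#' @param denoised numeric denoised length signal (um).
#' @param t time vector (s), same length.
#' @param cfg a [phase_config()] object.
#' @param derivative optional precomputed derivative (um/s); computed with
#'   [smooth_derivative()] when `NULL`.
#' @param fps sampling rate used when computing the derivative.
#' @return data.frame of events: `event`, `relaxed_start`,
#'   `contraction_onset`, `peak_contraction`, `relaxation_end` (s),
#'   `complete`, `fallback` (TRUE when the derivative threshold was never
#'   met inside a zone and the zone boundary was used).
#' @export
detect_phases <- function(denoised, t, cfg = phase_config(),
                          derivative = NULL, fps = NULL) {
  n <- length(denoised)
  stopifnot(length(t) == n)
  if (is.null(fps)) fps <- 1 / (t[2] - t[1])
  if (is.null(derivative)) derivative <- smooth_derivative(denoised, cfg, fps)
  empty <- data.frame(event = integer(), relaxed_start = numeric(),
                      contraction_onset = numeric(),
                      peak_contraction = numeric(),
                      relaxation_end = numeric(), complete = logical(),
                      fallback = logical())
  x <- denoised - mean(denoised)
  if (all(abs(x) < 1e-12)) return(empty)
  pos <- runs_of(x > 0)
  neg <- runs_of(x < 0)
  if (nrow(pos) == 0L || nrow(neg) == 0L) return(empty)
  flat <- abs(derivative) < cfg$derivative_threshold
  plateau <- matrix(NA_real_, nrow(pos), 2)  # sample indices (start, end)
  fallback <- logical(nrow(pos))
  for (b in seq_len(nrow(pos))) {
    s <- pos[b, 1]; e <- pos[b, 2]
    peak <- max(x[s:e])
    hi <- which(x[s:e] > cfg$high_zone_fraction * peak) + s - 1L
    z0 <- min(hi); z1 <- max(hi)
    left <- z0 + match(TRUE, flat[z0:z1]) - 1L
    right <- z1 - match(TRUE, rev(flat[z0:z1])) + 1L
    if (is.na(left)) { left <- z0; fallback[b] <- TRUE }
    if (is.na(right)) { right <- z1; fallback[b] <- TRUE }
    if (left > right) { left <- right <- as.integer(round((left + right) / 2)) }
    plateau[b, ] <- c(left, right)
  }
  events <- empty
  for (b in seq_len(nrow(pos))) {
    onset_i <- plateau[b, 2]
    # first negative block starting after this positive block
    nb <- which(neg[, 1] > pos[b, 2])
    peak_i <- NA_integer_
    trunc_peak <- FALSE
    if (length(nb) > 0L) {
      nb <- nb[1]
      seg <- neg[nb, 1]:neg[nb, 2]
      peak_i <- seg[which.min(denoised[seg])]
      trunc_peak <- neg[nb, 2] >= n  # minimum may lie past the recording
    }
    relax_end_i <- if (b < nrow(pos)) plateau[b + 1, 1] else NA_real_
    # the relaxation end must be confirmed by a full subsequent relaxed
    # plateau: if the next positive block runs into the recording edge the
    # plateau cannot be delimited, so the event stays incomplete
    relax_end_ok <- !is.na(relax_end_i) && pos[b + 1, 2] < n
    complete <- !is.na(peak_i) && relax_end_ok && !trunc_peak &&
      pos[b, 1] > 1L &&  # first block may have a truncated plateau start
      plateau[b, 1] <= onset_i && onset_i < peak_i && peak_i < relax_end_i
    events <- rbind(events, data.frame(
      event = b,
      relaxed_start = t[plateau[b, 1]],
      contraction_onset = t[onset_i],
      peak_contraction = if (is.na(peak_i)) NA_real_ else t[peak_i],
      relaxation_end = if (is.na(relax_end_i)) NA_real_ else t[relax_end_i],
      complete = complete, fallback = fallback[b]))
  }
  events
}
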