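# The structural / functional feature table: one record per (movie, region)
# with 35 metrics, plus the paired drug-effect comparison.

FEATURE_COLUMNS <- c(
  "number_of_contractions", "contraction_period", "contraction_frequency",
  "relaxed_SL_mean", "relaxed_SL_median", "relaxed_SL_p25", "relaxed_SL_p75",
  "relaxed_SL_sd",
  "peak_SL_mean", "peak_SL_median", "peak_SL_p25", "peak_SL_p75",
  "peak_SL_sd",
  "shortening_amplitude", "peak_shortening_velocity",
  "peak_lengthening_velocity",
  "onset_to_relaxation_end", "onset_to_peak", "onset_to_half_contracted",
  "half_to_peak", "peak_to_relaxation_end", "peak_to_half_relaxed",
  "half_relaxed_to_full",
  "tissue_length_relaxed", "tissue_length_peak",
  "tissue_width_relaxed", "tissue_width_peak",
  "tissue_area_hull_relaxed", "tissue_area_hull_peak",
  "tissue_area_rect_relaxed", "tissue_area_rect_peak",
  "total_sarcomeres", "sarcomere_density_hull", "sarcomere_density_rect",
  "noise_level")

#' Feature schema
#'
#' One row per feature column with its unit and a plain-language
#' description of how it is computed.
#'
#' @return data.frame with `column`, `unit`, `description`.
#' @export
feature_schema <- function() {
  d <- rbind(
    c("number_of_contractions", "count", "Total count of recorded full contraction events."),
    c("contraction_period", "s", "Average duration of a beating cycle (mean inter-onset interval of consecutive complete events)."),
    c("contraction_frequency", "Hz", "Average beating rate, 1 / contraction_period."),
    c("relaxed_SL_mean", "um", "Mean of individual sarcomere lengths pooled over all relaxed-phase frames."),
    c("relaxed_SL_median", "um", "Median of the pooled relaxed-state sarcomere lengths."),
    c("relaxed_SL_p25", "um", "25th percentile of the pooled relaxed-state sarcomere lengths."),
    c("relaxed_SL_p75", "um", "75th percentile of the pooled relaxed-state sarcomere lengths."),
    c("relaxed_SL_sd", "um", "Standard deviation of the pooled relaxed-state sarcomere lengths."),
    c("peak_SL_mean", "um", "Mean of individual sarcomere lengths pooled over the peak-contraction frames."),
    c("peak_SL_median", "um", "Median of the pooled peak-contraction sarcomere lengths."),
    c("peak_SL_p25", "um", "25th percentile of the pooled peak-contraction sarcomere lengths."),
    c("peak_SL_p75", "um", "75th percentile of the pooled peak-contraction sarcomere lengths."),
    c("peak_SL_sd", "um", "Standard deviation of the pooled peak-contraction sarcomere lengths."),
    c("shortening_amplitude", "um", "Relaxed minus peak-contracted average sarcomere length (from the denoised signal)."),
    c("peak_shortening_velocity", "um/s", "Maximum speed of length decrease during contraction phases."),
    c("peak_lengthening_velocity", "um/s", "Maximum speed of length increase during relaxation phases."),
    c("onset_to_relaxation_end", "s", "Contraction onset to end of relaxation."),
    c("onset_to_peak", "s", "Contraction onset to peak contraction."),
    c("onset_to_half_contracted", "s", "Contraction onset to 50% of maximal contraction (linear interpolation)."),
    c("half_to_peak", "s", "Half contraction to peak contraction."),
    c("peak_to_relaxation_end", "s", "Peak contraction to full relaxation."),
    c("peak_to_half_relaxed", "s", "Peak contraction to 50% relaxation (linear interpolation)."),
    c("half_relaxed_to_full", "s", "Half relaxation to full relaxation."),
    c("tissue_length_relaxed", "um", "Long rectangle dimension, median over relaxed-phase frames."),
    c("tissue_length_peak", "um", "Long rectangle dimension, mean over peak-contraction frames."),
    c("tissue_width_relaxed", "um", "Short rectangle dimension, median over relaxed-phase frames."),
    c("tissue_width_peak", "um", "Short rectangle dimension, mean over peak-contraction frames."),
    c("tissue_area_hull_relaxed", "um^2", "Convex-hull area, median over relaxed-phase frames."),
    c("tissue_area_hull_peak", "um^2", "Convex-hull area, mean over peak-contraction frames."),
    c("tissue_area_rect_relaxed", "um^2", "Bounding-rectangle area, median over relaxed-phase frames."),
    c("tissue_area_rect_peak", "um^2", "Bounding-rectangle area, mean over peak-contraction frames."),
    c("total_sarcomeres", "count", "Mean number of detected sarcomeres per frame."),
    c("sarcomere_density_hull", "1/um^2", "total_sarcomeres divided by the mean convex-hull area."),
    c("sarcomere_density_rect", "1/um^2", "total_sarcomeres divided by the mean bounding-rectangle area."),
    c("noise_level", "um", "Standard deviation of raw minus denoised length signal."))
  data.frame(column = d[, 1], unit = d[, 2], description = d[, 3])
}

masks_to_geometry <- function(masks) {
  do.call(rbind, lapply(masks, function(m) {
    data.frame(frame = m$frame_index, rect_long = m$rect_dims[1],
               rect_short = m$rect_dims[2], rect_area = m$rect_area,
               hull_area = m$hull_area)
  }))
}

# linear-interpolated crossing time of `level` between samples of `y`
# restricted to index window [i0, i1]; direction: "down" finds the first
# downward crossing, "up" the first upward crossing
crossing_time <- function(t, y, i0, i1, level, direction) {
  idx <- i0:i1
  hit <- if (direction == "down") which(y[idx] <= level) else which(y[idx] >= level)
  if (length(hit) == 0L) return(NA_real_)
  j <- idx[hit[1]]
  if (j == i0) return(t[j])
  y0 <- y[j - 1]; y1 <- y[j]
  if (y1 == y0) return(t[j])
  t[j - 1] + (level - y0) / (y1 - y0) * (t[j] - t[j - 1])
}

#' Extract the feature record for one (movie, region)
#'
#' @param events data.frame from [detect_phases()].
#' @param signal denoised `length_signal` (needs `denoised`, `raw`,
#'   `noise_level`).
#' @param masks list of `tissue_mask` objects (or a geometry data.frame
#'   from `masks_to_geometry`).
#' @param sarcomeres labelled sarcomere data.frame for the whole movie.
#' @param um_per_px spatial calibration.
#' @param region region selector (used to filter `sarcomeres`).
#' @param phase_cfg [phase_config()] used for the derivative.
#' @return one-row data.frame with `region` plus the 35 feature columns.
#' @export
extract_features <- function(events, signal, masks, sarcomeres,
                             um_per_px, region = "whole",
                             phase_cfg = phase_config()) {
  geom <- if (is.data.frame(masks)) masks else masks_to_geometry(masks)
  sarc <- sarcomeres[region_filter(sarcomeres, region), , drop = FALSE]
  t <- signal$t
  den <- signal$denoised
  fps <- signal$fps
  d <- smooth_derivative(den, phase_cfg, fps)
  out <- as.list(rep(NA_real_, length(FEATURE_COLUMNS)))
  names(out) <- FEATURE_COLUMNS
  comp <- events[which(events$complete), , drop = FALSE]
  out$number_of_contractions <- nrow(comp)
  if (nrow(comp) >= 2L) {
    consec <- diff(comp$event) == 1L
    ioi <- diff(comp$contraction_onset)[consec]
    if (length(ioi) > 0L) {
      out$contraction_period <- mean(ioi)
      out$contraction_frequency <- 1 / out$contraction_period
    }
  }
  frame_of <- function(ts) vapply(ts, function(s) which.min(abs(t - s)), 0L)
  if (nrow(comp) >= 1L) {
    relaxed_frames <- unlist(lapply(seq_len(nrow(comp)), function(i) {
      which(t >= comp$relaxed_start[i] & t <= comp$contraction_onset[i])
    }))
    peak_frames <- frame_of(comp$peak_contraction)
    pool_stats <- function(frames, prefix) {
      lens <- sarc$length_um[sarc$frame %in% (frames - 1L)]
      if (length(lens) == 0L) return(NULL)
      q <- stats::quantile(lens, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      stats::setNames(
        list(mean(lens), q[2], q[1], q[3],
             if (length(lens) > 1) stats::sd(lens) else 0),
        paste0(prefix, c("_mean", "_median", "_p25", "_p75", "_sd")))
    }
    rs <- pool_stats(relaxed_frames, "relaxed_SL")
    ps <- pool_stats(peak_frames, "peak_SL")
    for (nm in names(rs)) out[[nm]] <- rs[[nm]]
    for (nm in names(ps)) out[[nm]] <- ps[[nm]]
    # amplitude from the averaged (denoised) signal
    out$shortening_amplitude <- mean(den[relaxed_frames]) - mean(den[peak_frames])
    onset_f <- frame_of(comp$contraction_onset)
    relax_f <- frame_of(comp$relaxation_end)
    contr_idx <- unlist(mapply(seq, onset_f, peak_frames, SIMPLIFY = FALSE))
    expan_idx <- unlist(mapply(seq, peak_frames, relax_f, SIMPLIFY = FALSE))
    out$peak_shortening_velocity <- max(-d[contr_idx])
    out$peak_lengthening_velocity <- max(d[expan_idx])
    # timing decomposition with interpolated half-crossings
    tim <- vapply(seq_len(nrow(comp)), function(i) {
      i_on <- onset_f[i]; i_pk <- peak_frames[i]; i_re <- relax_f[i]
      lvl_c <- (den[i_on] + den[i_pk]) / 2
      lvl_r <- (den[i_pk] + den[i_re]) / 2
      th_c <- crossing_time(t, den, i_on, i_pk, lvl_c, "down")
      th_r <- crossing_time(t, den, i_pk, i_re, lvl_r, "up")
      c(o2r = comp$relaxation_end[i] - comp$contraction_onset[i],
        o2p = comp$peak_contraction[i] - comp$contraction_onset[i],
        o2h = th_c - comp$contraction_onset[i],
        h2p = comp$peak_contraction[i] - th_c,
        p2r = comp$relaxation_end[i] - comp$peak_contraction[i],
        p2h = th_r - comp$peak_contraction[i],
        h2f = comp$relaxation_end[i] - th_r)
    }, numeric(7))
    tm <- rowMeans(tim)
    out$onset_to_relaxation_end <- tm["o2r"]
    out$onset_to_peak <- tm["o2p"]
    out$onset_to_half_contracted <- tm["o2h"]
    out$half_to_peak <- tm["h2p"]
    out$peak_to_relaxation_end <- tm["p2r"]
    out$peak_to_half_relaxed <- tm["p2h"]
    out$half_relaxed_to_full <- tm["h2f"]
    # tissue geometry at the relaxed and peak states
    g_rel <- geom[geom$frame %in% (relaxed_frames - 1L), , drop = FALSE]
    g_pk <- geom[geom$frame %in% (peak_frames - 1L), , drop = FALSE]
    if (nrow(g_rel) > 0L) {
      out$tissue_length_relaxed <- stats::median(g_rel$rect_long) * um_per_px
      out$tissue_width_relaxed <- stats::median(g_rel$rect_short) * um_per_px
      out$tissue_area_hull_relaxed <- stats::median(g_rel$hull_area) * um_per_px^2
      out$tissue_area_rect_relaxed <- stats::median(g_rel$rect_area) * um_per_px^2
    }
    if (nrow(g_pk) > 0L) {
      out$tissue_length_peak <- mean(g_pk$rect_long) * um_per_px
      out$tissue_width_peak <- mean(g_pk$rect_short) * um_per_px
      out$tissue_area_hull_peak <- mean(g_pk$hull_area) * um_per_px^2
      out$tissue_area_rect_peak <- mean(g_pk$rect_area) * um_per_px^2
    }
  } else {
    warning("extract_features: no complete contraction events; functional metrics are missing")
  }
  n_frames <- length(t)
  out$total_sarcomeres <- nrow(sarc) / n_frames
  mean_hull_um2 <- mean(geom$hull_area) * um_per_px^2
  mean_rect_um2 <- mean(geom$rect_area) * um_per_px^2
  out$sarcomere_density_hull <- out$total_sarcomeres / mean_hull_um2
  out$sarcomere_density_rect <- out$total_sarcomeres / mean_rect_um2
  out$noise_level <- if (is.null(signal$noise_level)) NA_real_ else signal$noise_level
  cbind(data.frame(region = region), as.data.frame(out))
}

#' Paired baseline-vs-treated comparison of one feature
#'
#' Percent change in the group mean and a two-sided paired t-test on the
#' per-sample differences.
#'
#' @param baseline,treated equal-length numeric vectors (pairs with any
#'   missing value are dropped).
#' @return list with `delta_pct`, `t_statistic`, `p_value`, `n`, `df`.
#' @export
paired_comparison <- function(baseline, treated) {
  if (length(baseline) != length(treated))
    stop("paired_comparison: baseline and treated must have equal length")
  keep <- is.finite(baseline) & is.finite(treated)
  baseline <- baseline[keep]; treated <- treated[keep]
  n <- length(baseline)
  if (n < 2L) stop("paired_comparison: fewer than 2 complete pairs")
  delta_pct <- 100 * (mean(treated) - mean(baseline)) / mean(baseline)
  d <- treated - baseline
  sdd <- stats::sd(d)
  if (sdd == 0) {
    warning("paired_comparison: zero-variance differences; p-value undefined")
    return(list(delta_pct = delta_pct, t_statistic = NA_real_,
                p_value = NA_real_, n = n, df = n - 1L))
  }
  tstat <- mean(d) / (sdd / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  list(delta_pct = delta_pct, t_statistic = tstat, p_value = p, n = n,
       df = n - 1L)
}
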