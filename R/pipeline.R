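# Orchestration: movie -> per-frame detections and masks -> regional labels
# -> average-length signals -> GP denoising -> phase detection -> feature
# table, with QC flagging, JSON config round-trip, logging and CLI helpers.

#' Pipeline configuration
#'
#' @param um_per_px spatial calibration (um/pixel), required.
#' @param fps frame rate (default 100 frames/s).
#' @param regions any of `"whole"`, `"thirds"`, `"halves"`, `"sixths"`.
#' @param detect,segment,kernel,phase stage configurations.
#' @param max_zdiscs_per_frame QC cap on per-frame z-disc counts; the
#'   known failure mode registers noise as several thousand false
#'   positives, orders of magnitude above the expected count.
#' @param max_count_cv QC cap on the frame-to-frame coefficient of
#'   variation of z-disc counts.
#' @param seed integer seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(um_per_px, fps = 100,
                            regions = c("whole", "thirds"),
                            detect = detect_config(),
                            segment = segment_config(),
                            kernel = kernel_config(),
                            phase = phase_config(),
                            max_zdiscs_per_frame = 1500L,
                            max_count_cv = 0.5, seed = 1L) {
  if (missing(um_per_px) || !is.numeric(um_per_px) || um_per_px <= 0)
    stop("pipeline_config: um_per_px must be a positive number")
  if (fps <= 0) stop("pipeline_config: fps must be > 0")
  bad <- setdiff(regions, c("whole", "thirds", "halves", "sixths"))
  if (length(bad) > 0)
    stop("pipeline_config: unknown region selections: ",
         paste(bad, collapse = ", "))
  structure(list(um_per_px = um_per_px, fps = fps, regions = regions,
                 detect = detect, segment = segment, kernel = kernel,
                 phase = phase,
                 max_zdiscs_per_frame = as.integer(max_zdiscs_per_frame),
                 max_count_cv = max_count_cv, seed = as.integer(seed)),
            class = "pipeline_config")
}

region_names <- function(selections) {
  out <- character(0)
  if ("whole" %in% selections) out <- c(out, "whole")
  if ("thirds" %in% selections) out <- c(out, "left", "center", "right")
  if ("halves" %in% selections) out <- c(out, "top", "bottom")
  if ("sixths" %in% selections)
    out <- c(out, as.vector(outer(c("left", "center", "right"),
                                  c("top", "bottom"), paste, sep = "-")))
  unique(out)
}

#' Write / read a pipeline configuration as JSON
#'
#' The file round-trips to the exact `pipeline_config` schema.
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  unclass_deep <- function(x) {
    if (is.list(x)) lapply(unclass(x), unclass_deep) else x
  }
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    um_per_px = x$um_per_px, fps = x$fps, regions = x$regions,
    detect = do.call(detect_config, x$detect),
    segment = do.call(segment_config, x$segment),
    kernel = do.call(kernel_config, x$kernel),
    phase = do.call(phase_config, x$phase),
    max_zdiscs_per_frame = x$max_zdiscs_per_frame,
    max_count_cv = x$max_count_cv, seed = x$seed)
}

#' Read a movie from disk
#'
#' Accepts a multi-page TIFF or a directory of per-frame images
#' (lexicographic order); ND2 is not supported (convert upstream).
#'
#' @param path movie file or directory.
#' @return list of numeric frame matrices.
#' @export
read_movie <- function(path) {
  if (!file.exists(path)) stop("read_movie: no such file: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L)
      stop("read_movie: directory contains no TIFF frames: ", path)
    frames <- unlist(lapply(files, read_tiff_stack), recursive = FALSE)
  } else {
    frames <- read_tiff_stack(path)
  }
  if (length(frames) == 0L) stop("read_movie: empty movie: ", path)
  frames
}

#' QC check on per-frame detections and segmentation outcomes
#'
#' Flags the z-disc flood failure mode (a frame with far more detections
#' than a tissue can contain), unstable frame-to-frame detection counts,
#' and widespread segmentation failures. A movie with any flag raised is
#' excluded from paired comparisons, but the report is always produced.
#'
#' @param zdisc_counts integer vector of per-frame z-disc counts.
#' @param n_seg_failures number of frames where segmentation failed.
#' @param config a [pipeline_config()].
#' @return list: `counts`, `flags` (named logical), `excluded`, `reasons`.
#' @export
qc_check <- function(zdisc_counts, n_seg_failures = 0L, config) {
  n <- length(zdisc_counts)
  stopifnot(n >= 1L)
  flood <- any(zdisc_counts > config$max_zdiscs_per_frame)
  cv <- if (mean(zdisc_counts) > 0)
    stats::sd(zdisc_counts) / mean(zdisc_counts) else Inf
  instab <- is.finite(cv) && cv > config$max_count_cv || !is.finite(cv)
  segfail <- n_seg_failures > 0.10 * n
  flags <- c(zdisc_flood = flood, count_instability = instab,
             segmentation_failures = segfail)
  reasons <- c(
    if (flood) sprintf("frame z-disc count exceeds %d",
                       config$max_zdiscs_per_frame),
    if (instab) sprintf("z-disc count CV %.2f exceeds %.2f", cv,
                        config$max_count_cv),
    if (segfail) sprintf("segmentation failed on %d frames", n_seg_failures))
  list(counts = zdisc_counts, count_cv = cv, flags = flags,
       excluded = any(flags),
       reasons = if (length(reasons)) reasons else "clean")
}

#' Run the full analysis pipeline on one movie
#'
#' Executes segmentation, detection and partitioning on every frame, builds
#' the average-length signal for each requested region, denoises it with
#' the composite-kernel GP, detects contractile phases, and extracts the
#' feature record per region. Deterministic given the config seed.
#'
#' @param movie a path (TIFF stack / frame directory) or a list of frame
#'   matrices.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, writes
#'   `detections.csv`, `geometry.csv`, `signals/<region>.csv`,
#'   `events.csv`, `features.csv`, `qc.json` and `run.log`.
#' @return list with `features` (data.frame, one row per region),
#'   `signals`, `events` (named by region), `masks`, `sarcomeres`
#'   (labelled), `qc`.
#' @export
run_pipeline <- function(movie, config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  frames <- if (is.character(movie)) read_movie(movie) else as_frame_list(movie)
  n_frames <- length(frames)
  set.seed(config$seed)
  masks <- vector("list", n_frames)
  sarc_list <- vector("list", n_frames)
  counts <- integer(n_frames)
  seg_failures <- integer(0)
  for (i in seq_len(n_frames)) {
    fi <- i - 1L
    m <- tryCatch(segment_tissue(frames[[i]], config$segment, fi),
                  segmentation_failure = function(e) NULL)
    z <- detect_zdiscs(frames[[i]], config$detect, fi)
    counts[i] <- nrow(z)
    if (is.null(m)) {
      seg_failures <- c(seg_failures, fi)
      next
    }
    masks[[i]] <- m
    s <- link_sarcomeres(z, config$detect, config$um_per_px)
    if (nrow(s) > 0L) sarc_list[[i]] <- assign_regions(s, m)
  }
  masks <- masks[!vapply(masks, is.null, TRUE)]
  if (length(masks) == 0L)
    stop("run_pipeline: segmentation failed on every frame")
  sarcomeres <- do.call(rbind, sarc_list)
  if (is.null(sarcomeres) || nrow(sarcomeres) == 0L)
    stop("run_pipeline: no sarcomeres detected in any frame")
  qc <- qc_check(counts, length(seg_failures), config)
  geom <- masks_to_geometry(masks)
  regions <- region_names(config$regions)
  signals <- list(); events <- list(); feats <- list()
  for (rg in regions) {
    sig <- tryCatch(
      average_length_signal(sarcomeres, rg, config$fps, n_frames),
      error = function(e) NULL)
    if (is.null(sig)) next
    sig <- gpr_denoise(sig, config$kernel)
    ev <- detect_phases(sig$denoised, sig$t, config$phase, fps = config$fps)
    signals[[rg]] <- sig
    events[[rg]] <- ev
    feats[[rg]] <- extract_features(ev, sig, geom, sarcomeres,
                                    config$um_per_px, rg, config$phase)
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  res <- list(features = features, signals = signals, events = events,
              masks = masks, sarcomeres = sarcomeres, geometry = geom,
              qc = qc)
  if (!is.null(out_dir)) write_pipeline_outputs(res, config, out_dir)
  res
}

write_pipeline_outputs <- function(res, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$sarcomeres, file.path(out_dir, "detections.csv"),
                   row.names = FALSE)
  utils::write.csv(res$geometry, file.path(out_dir, "geometry.csv"),
                   row.names = FALSE)
  dir.create(file.path(out_dir, "signals"), showWarnings = FALSE)
  for (rg in names(res$signals)) {
    s <- res$signals[[rg]]
    utils::write.csv(
      data.frame(frame = seq_along(s$t) - 1L, t_s = s$t, raw_um = s$raw,
                 denoised_um = s$denoised),
      file.path(out_dir, "signals", paste0(rg, ".csv")), row.names = FALSE)
  }
  ev <- do.call(rbind, lapply(names(res$events), function(rg) {
    e <- res$events[[rg]]
    if (nrow(e) == 0L) return(NULL)
    cbind(region = rg, e)
  }))
  if (!is.null(ev))
    utils::write.csv(ev, file.path(out_dir, "events.csv"), row.names = FALSE)
  utils::write.csv(res$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$qc[c("flags", "excluded", "reasons", "count_cv")],
                       file.path(out_dir, "qc.json"), auto_unbox = TRUE,
                       digits = NA)
  writeLines(c(sprintf("sarcbundle %s",
                       as.character(utils::packageVersion("sarcbundle"))),
               sprintf("R %s", as.character(getRversion())),
               sprintf("seed %d", config$seed),
               sprintf("config_hash %s", config_hash(config)),
               sprintf("date %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
             file.path(out_dir, "run.log"))
  invisible(out_dir)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  write_pipeline_config(config, f)
  unname(tools::md5sum(f))
}
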