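#' Read and write spot/track tables
#'
#' Spot tables are plain CSV with at least `frame`, `x_um`, `y_um`
#' (spots) plus `track_id` (tracks); extra columns — intensities, nucleus
#' labels, conditions from other tools — are preserved verbatim, so
#' externally produced tables in the same schema drop straight into the
#' pipeline. Violations are reported with the offending column and row.
#'
#' @param path CSV path.
#' @param x Tibble to write.
#' @return The validated tibble (readers); the path, invisibly (writers).
#' @name spot_io
NULL

#' @rdname spot_io
#' @export
read_spot_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  validate_table(x, c("frame", "x_um", "y_um"), path)
  x
}

#' @rdname spot_io
#' @export
write_spot_table <- function(x, path) {
  validate_table(x, c("frame", "x_um", "y_um"), "input")
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname spot_io
#' @export
read_track_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  validate_table(x, c("track_id", "frame", "x_um", "y_um"), path)
  x
}

#' @rdname spot_io
#' @export
write_track_table <- function(x, path) {
  validate_table(x, c("track_id", "frame", "x_um", "y_um"), "input")
  readr::write_csv(x, path)
  invisible(path)
}

validate_table <- function(x, required, where) {
  miss <- setdiff(required, names(x))
  if (length(miss) > 0) {
    abort(paste0("table ", where, " is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  for (cl in required) {
    bad <- which(!is.finite(x[[cl]]))
    if (length(bad) > 0) {
      abort(paste0("non-finite `", cl, "` in ", where, " at row(s) ",
                   paste(head(bad, 5), collapse = ", ")))
    }
  }
  invisible(x)
}

#' Read and write label masks as 16-bit TIFF
#'
#' @param mask Integer matrix (labels 0..65535).
#' @param path TIFF path.
#' @return The label matrix (reader); the path, invisibly (writer).
#' @name mask_io
NULL

#' @rdname mask_io
#' @export
write_mask <- function(mask, path) {
  if (max(mask) > 65535) abort("labels exceed 16-bit range.")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname mask_io
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write a movie as per-channel multi-page TIFF plus a YAML sidecar
#'
#' @param movie A `bt_movie`.
#' @param dir Output directory (created if needed).
#' @param name Base name of the files.
#' @return The sidecar path, invisibly.
#' @export
write_movie_tiff <- function(movie, dir, name = "movie") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scale <- max(unlist(lapply(movie$channels, max)), 1)
  files <- list()
  for (ch in names(movie$channels)) {
    arr <- movie$channels[[ch]]
    pages <- lapply(seq_len(dim(arr)[3]), function(f) {
      pmin(pmax(arr[, , f] / scale, 0), 1)
    })
    f <- file.path(dir, paste0(name, "_", ch, ".tif"))
    tiff::writeTIFF(pages, f, bits.per.sample = 16L)
    files[[ch]] <- basename(f)
  }
  sidecar <- file.path(dir, paste0(name, ".yaml"))
  yaml::write_yaml(list(
    channels = files,
    pixel_size_um = movie$cfg$pixel_size_um,
    frame_interval_s = movie$cfg$frame_interval_s,
    n_frames = movie$cfg$n_frames,
    intensity_scale = scale
  ), sidecar)
  invisible(sidecar)
}

#' Run the burst-movie pipeline end to end
#'
#' The reproducible driver tying the stages together on one movie:
#' per-frame nucleus segmentation, per-nucleus extranuclear suppression
#' and DoG burst calling, spot linking, burst-event assembly, and burst
#' statistics. Every output table carries the configuration hash so runs
#' are auditable; identical configuration and seed give identical output.
#'
#' @param movie A `bt_movie` (e.g. from [render_movie()]).
#' @param params Named list of stage parameters; recognised entries:
#'   `nucleus_size_range`, `dog_radii`, `burst_offset`, `burst_slope`,
#'   `max_link_um`, `max_gap_frames`, `max_close_um`, `min_spots`.
#' @param out_dir Optional directory; when given, spot/track/event CSVs
#'   are written there.
#' @return List with `spots`, `tracks`, `events`, `stats`, `config_hash`.
#' @export
run_burst_pipeline <- function(movie, params = list(), out_dir = NULL) {
  p <- utils::modifyList(list(
    nucleus_size_range = c(40, 200), area_scale = 1,
    blur_sigma = 10, rolling_radius = 500,
    dog_radii = c(6, 12), burst_offset = 5, burst_slope = 0.55,
    max_link_um = 0.4, max_gap_frames = 3L, max_close_um = 0.6,
    min_spots = 5L
  ), params)
  cfg <- movie$cfg
  hash <- rlang::hash(list(p, cfg))
  nf <- cfg$n_frames
  seg <- function(frame) {
    segment_nuclei_burst_movie(frame, blur_sigma = p$blur_sigma,
                               rolling_radius = p$rolling_radius,
                               size_range = p$nucleus_size_range,
                               area_scale = p$area_scale)
  }
  # nuclei are labelled per frame by the watershed, whose numbering is
  # arbitrary; harmonize every frame's labels against the first frame so a
  # nucleus keeps one identity through the movie
  ref_mask <- seg(movie$channels$rna[, , 1])
  spots <- purrr::map_dfr(seq_len(nf), function(f) {
    frame <- movie$channels$rna[, , f]
    mask <- harmonize_labels(seg(frame), ref_mask)
    purrr::map_dfr(mask$stats$nucleus_label, function(lb) {
      med <- mask$stats$median_intensity[mask$stats$nucleus_label == lb]
      sup <- suppress_extranuclear(frame, mask, lb)
      call_bursts_in_nucleus(sup, med, radii = p$dog_radii,
                             offset = p$burst_offset, slope = p$burst_slope,
                             pixel_size_um = cfg$pixel_size_um,
                             frame_index = f - 1L) %>%
        mutate(nucleus_label = lb)
    })
  })
  tracks <- link_spots(spots, max_link_um = p$max_link_um,
                       max_gap_frames = p$max_gap_frames,
                       max_close_um = p$max_close_um,
                       min_spots = p$min_spots)
  events <- assemble_bursts(tracks, cfg$frame_interval_s)
  stats <- burst_statistics(events, cfg$frame_interval_s, nf)
  out <- list(spots = spots, tracks = tracks, events = events,
              stats = stats, nucleus_mask = ref_mask, config_hash = hash)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_spot_table(spots, file.path(out_dir, "spots.csv"))
    write_track_table(tracks, file.path(out_dir, "tracks.csv"))
    readr::write_csv(events, file.path(out_dir, "events.csv"))
    readr::write_csv(stats, file.path(out_dir, "burst_stats.csv"))
    yaml::write_yaml(c(p, list(config_hash = hash)),
                     file.path(out_dir, "run_config.yaml"))
  }
  out
}
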