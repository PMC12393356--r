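#' Assemble linked RNA spots into burst events
#'
#' Each linked RNA-focus track becomes one burst event spanning its first
#' to last frame (half-open interval), with the event intensity averaged
#' over member spots. Events inherit the majority nucleus label of their
#' spots; a track whose spots span several nuclei is assigned to the
#' majority nucleus with a warning.
#'
#' @param rna_tracks Linked spot tibble from the burst channel
#'   (`track_id`, `frame`, and optionally `peak_intensity`/`intensity`,
#'   `nucleus_label`).
#' @param frame_interval_s Frame interval in seconds.
#' @return Tibble of burst events: `nucleus_id`, `start_frame`,
#'   `end_frame`, `duration_s`, `mean_intensity`, `frames_observed`.
#' @export
assemble_bursts <- function(rna_tracks, frame_interval_s) {
  if (nrow(rna_tracks) == 0) {
    return(tibble(nucleus_id = integer(), start_frame = integer(),
                  end_frame = integer(), duration_s = numeric(),
                  mean_intensity = numeric(), frames_observed = integer()))
  }
  int_col <- intersect(c("peak_intensity", "intensity"), names(rna_tracks))[1]
  has_nuc <- "nucleus_label" %in% names(rna_tracks)
  out <- rna_tracks %>%
    group_by(.data$track_id) %>%
    summarise(
      nucleus_id = if (has_nuc) majority_label(.data$nucleus_label) else NA_integer_,
      n_nuclei = if (has_nuc) dplyr::n_distinct(.data$nucleus_label) else 1L,
      start_frame = min(.data$frame),
      end_frame = max(.data$frame) + 1L,
      mean_intensity = if (is.na(int_col)) NA_real_ else mean(.data[[int_col]]),
      frames_observed = n(),
      .groups = "drop"
    ) %>%
    mutate(duration_s = (.data$end_frame - .data$start_frame) * frame_interval_s)
  if (any(out$n_nuclei > 1)) {
    warn(paste0(sum(out$n_nuclei > 1),
                " burst track(s) spanned multiple nuclei; assigned to majority."))
  }
  out %>%
    select("nucleus_id", "start_frame", "end_frame", "duration_s",
           "mean_intensity", "frames_observed") %>%
    arrange(.data$nucleus_id, .data$start_frame)
}

majority_label <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

#' Burst frequency and duration statistics
#'
#' Per phase: burst rate normalised per nucleus-hour observed, mean on
#' duration, and mean off duration. Off durations are measured between the
#' end of one event and the start of the next within the same nucleus and
#' phase. Events are assigned to the phase containing their start frame.
#' Empty phases yield `NA` statistics, never zeros.
#'
#' @param events Burst-event tibble from [assemble_bursts()].
#' @param frame_interval_s Frame interval (s).
#' @param observed_frames Total frames observed per nucleus.
#' @param n_nuclei Number of nuclei observed (defaults to the number of
#'   distinct `nucleus_id` in `events`; pass explicitly when silent nuclei
#'   were observed).
#' @param phase_windows Optional named list of half-open frame intervals
#'   `c(start, end)`; default one window spanning the recording.
#' @return Tibble: `phase`, `n_events`, `burst_rate_per_nucleus_hour`,
#'   `mean_on_duration_s`, `mean_off_duration_s`.
#' @export
burst_statistics <- function(events, frame_interval_s, observed_frames,
                             n_nuclei = NULL,
                             phase_windows = NULL) {
  if (is.null(phase_windows)) {
    phase_windows <- list(all = c(0L, observed_frames))
  }
  n_nuclei <- n_nuclei %||% max(1L, dplyr::n_distinct(events$nucleus_id))
  purrr::imap_dfr(phase_windows, function(w, nm) {
    ev <- events %>%
      filter(.data$start_frame >= w[1], .data$start_frame < w[2]) %>%
      arrange(.data$nucleus_id, .data$start_frame)
    hours <- (min(w[2], observed_frames) - w[1]) * frame_interval_s / 3600
    if (nrow(ev) == 0) {
      return(tibble(phase = nm, n_events = 0L,
                    burst_rate_per_nucleus_hour = NA_real_,
                    mean_on_duration_s = NA_real_,
                    mean_off_duration_s = NA_real_))
    }
    offs <- ev %>%
      group_by(.data$nucleus_id) %>%
      summarise(off = list((.data$start_frame[-1] - .data$end_frame[-n()]) *
                             frame_interval_s), .groups = "drop") %>%
      tidyr::unnest("off")
    tibble(
      phase = nm,
      n_events = nrow(ev),
      burst_rate_per_nucleus_hour = nrow(ev) / (n_nuclei * hours),
      mean_on_duration_s = mean(ev$duration_s),
      mean_off_duration_s = if (nrow(offs) == 0) NA_real_ else mean(offs$off)
    )
  })
}
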