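#' Phase window definitions
#'
#' Time windows (minutes relative to stimulation) used to segment
#' recordings into pre-stimulation, acute, and chronic phases. The default
#' follows the acute = 0-120 min, chronic = beyond 160 min convention; the
#' `"bursting"` preset uses the empirically observed high-bursting window
#' 24-132 min as the acute phase. Neither is silently preferred; choose
#' per analysis.
#'
#' @param preset `"methods"` (acute 0-120, chronic >160) or `"bursting"`
#'   (acute 24-132, chronic >160).
#' @return Named list of `c(start_min, end_min)` windows (`pre`, `acute`,
#'   `chronic`), half-open, relative to stimulation at minute 0.
#' @export
phase_windows <- function(preset = c("methods", "bursting")) {
  preset <- match.arg(preset)
  acute <- if (preset == "methods") c(0, 120) else c(24, 132)
  list(pre = c(-Inf, 0), acute = acute, chronic = c(160, Inf))
}

#' Segment DNA-locus tracks by transcriptional burst state
#'
#' Labels every frame of each locus track `burst` if it falls inside an
#' on-interval of a burst event of the same nucleus, `nonburst`
#' otherwise; maximal runs of equal label become segments. Segments
#' shorter than `min_segment_frames` are kept but flagged unusable for
#' displacement statistics. Tracks without a nucleus shared with the burst
#' table are skipped with a warning.
#'
#' @param dna_tracks Linked locus tibble (`track_id`, `frame`, `x_um`,
#'   `y_um`, `nucleus_id`).
#' @param bursts Burst events (`nucleus_id`, `start_frame`, `end_frame`).
#' @param min_segment_frames Minimum usable segment length (default 3).
#' @return A segment tibble: `track_id`, `nucleus_id`, `state`,
#'   `start_frame`, `end_frame` (half-open), `n_frames`, `n_disp`,
#'   `mean_disp_um`, `usable`.
#' @export
segment_by_bursts <- function(dna_tracks, bursts, min_segment_frames = 3L) {
  if (!"nucleus_id" %in% names(dna_tracks)) {
    if ("nucleus_label" %in% names(dna_tracks)) {
      dna_tracks$nucleus_id <- dna_tracks$nucleus_label
    } else abort("`dna_tracks` needs a `nucleus_id` column.")
  }
  known <- unique(bursts$nucleus_id)
  skipped <- dna_tracks %>%
    filter(!.data$nucleus_id %in% known) %>% pull("track_id") %>% unique()
  if (length(skipped) > 0 && nrow(bursts) > 0) {
    warn(paste0(length(skipped),
                " track(s) in nuclei without burst data treated as non-burst."))
  }
  label_frame <- function(nuc, fr) {
    b <- bursts[bursts$nucleus_id == nuc, ]
    if (nrow(b) == 0) return(rep("nonburst", length(fr)))
    on <- vapply(fr, function(f) any(b$start_frame <= f & f < b$end_frame),
                 logical(1))
    ifelse(on, "burst", "nonburst")
  }
  segment_tracks_by_label(dna_tracks, label_frame, min_segment_frames)
}

#' Segment tracks by stimulation phase
#'
#' Maps frames to `pre` / `acute` / `chronic` via [phase_windows()]
#' relative to the stimulation frame; frames falling in no window (e.g.
#' the 120-160 min transition) are left unlabeled and form no segment.
#'
#' @param tracks Linked tibble (`track_id`, `frame`, `x_um`, `y_um`,
#'   optionally `nucleus_id`).
#' @param windows A [phase_windows()] list.
#' @param t0_frame Stimulation frame (may be <= 0 if stimulation preceded
#'   the recording).
#' @param frame_interval_s Frame interval (s).
#' @param min_segment_frames Minimum usable segment length.
#' @return Segment tibble as in [segment_by_bursts()].
#' @export
segment_by_phase <- function(tracks, windows, t0_frame, frame_interval_s,
                             min_segment_frames = 3L) {
  if (!"nucleus_id" %in% names(tracks)) tracks$nucleus_id <- NA_integer_
  label_frame <- function(nuc, fr) {
    mins <- (fr - t0_frame) * frame_interval_s / 60
    lab <- rep(NA_character_, length(fr))
    for (nm in names(windows)) {
      w <- windows[[nm]]
      lab[mins >= w[1] & mins < w[2]] <- nm
    }
    lab
  }
  segment_tracks_by_label(tracks, label_frame, min_segment_frames)
}

# shared run-length segmentation machinery: label each frame, split runs
segment_tracks_by_label <- function(tracks, label_frame, min_segment_frames) {
  tracks %>%
    group_by(.data$track_id) %>%
    dplyr::group_modify(function(tr, key) {
      tr <- arrange(tr, .data$frame)
      lab <- label_frame(tr$nucleus_id[1], tr$frame)
      keep <- !is.na(lab)
      if (!any(keep)) return(tibble())
      tr <- tr[keep, ]; lab <- lab[keep]
      runs <- rle(lab)
      ends <- cumsum(runs$lengths)
      starts <- c(1L, head(ends, -1) + 1L)
      purrr::map_dfr(seq_along(runs$values), function(i) {
        seg <- tr[starts[i]:ends[i], ]
        disp <- single_frame_displacements(seg)
        tibble(
          nucleus_id = tr$nucleus_id[1],
          state = runs$values[i],
          start_frame = seg$frame[1],
          end_frame = seg$frame[nrow(seg)] + 1L,
          n_frames = nrow(seg),
          n_disp = nrow(disp),
          mean_disp_um = if (nrow(disp)) mean(disp$disp_um) else NA_real_,
          usable = nrow(seg) >= min_segment_frames
        )
      })
    }) %>%
    ungroup()
}

#' Per-segment anomalous exponent
#'
#' Adds an `alpha` column to a segment table by fitting the log-log MSD
#' slope of each usable segment (requires the parent tracks).
#'
#' @param segments Segment tibble.
#' @param tracks The tracks the segments were cut from.
#' @param frame_interval_s Frame interval (s).
#' @param min_frames Minimum segment length for a fit (default 10).
#' @return `segments` with an `alpha` column (`NA` where unfittable).
#' @export
segment_alpha <- function(segments, tracks, frame_interval_s,
                          min_frames = 10L) {
  segments$alpha <- purrr::pmap_dbl(
    segments[, c("track_id", "start_frame", "end_frame", "n_frames")],
    function(track_id, start_frame, end_frame, n_frames) {
      if (n_frames < min_frames) return(NA_real_)
      seg <- tracks %>%
        filter(.data$track_id == !!track_id,
               .data$frame >= start_frame, .data$frame < end_frame)
      fit_alpha_diffusion(compute_msd(seg, frame_interval_s))$alpha
    })
  segments
}

#' Compare locus mobility between states
#'
#' Aggregates single-frame displacement (or segment alpha) per cell and
#' state, then tests each state pair: a paired two-tailed t-test across
#' cells when both states are observed in the same cells, an unpaired
#' two-tailed t-test otherwise. Significance markers follow the
#' conventional scale (* p<0.05, ** p<0.01, *** p<0.001, **** p<0.0001).
#'
#' @param segments Segment tibble (from [segment_by_bursts()] /
#'   [segment_by_phase()]); per-cell grouping uses `nucleus_id`.
#' @param metric `"mean_disp_um"` or `"alpha"` (requires
#'   [segment_alpha()] first).
#' @return A `bt_mobility_report`: list with `per_cell` (cell x state
#'   means) and `comparisons` (tibble: `state_a`, `state_b`, means, `n`,
#'   `test`, `p_value`, `signif`).
#' @export
compare_mobility <- function(segments, metric = "mean_disp_um") {
  seg <- segments %>%
    filter(.data$usable, !is.na(.data[[metric]]))
  if (dplyr::n_distinct(seg$state) < 2) {
    abort("need at least two states with usable segments.")
  }
  wcol <- if (metric == "mean_disp_um") "n_disp" else "n_frames"
  per_cell <- seg %>%
    group_by(cell = .data$nucleus_id, .data$state) %>%
    summarise(value = sum(.data[[metric]] * .data[[wcol]]) /
                sum(.data[[wcol]]), .groups = "drop")
  states <- sort(unique(per_cell$state))
  comparisons <- purrr::map_dfr(utils::combn(states, 2, simplify = FALSE),
    function(pr) {
      a <- per_cell %>% filter(.data$state == pr[1])
      b <- per_cell %>% filter(.data$state == pr[2])
      both <- intersect(a$cell, b$cell)
      if (length(both) >= 2) {
        av <- a$value[match(both, a$cell)]
        bv <- b$value[match(both, b$cell)]
        ht <- if (sd(av - bv) == 0) {
          list(p.value = if (mean(av - bv) == 0) 1 else 0)
        } else {
          t.test(av, bv, paired = TRUE)
        }
        test <- "paired t"
        n <- length(both)
      } else if (nrow(a) >= 2 && nrow(b) >= 2) {
        ht <- t.test(a$value, b$value)
        test <- "unpaired t"
        n <- min(nrow(a), nrow(b))
      } else {
        return(tibble(state_a = pr[1], state_b = pr[2],
                      mean_a = mean(a$value), mean_b = mean(b$value),
                      n = min(nrow(a), nrow(b)), test = "none",
                      p_value = NA_real_, signif = NA_character_))
      }
      tibble(state_a = pr[1], state_b = pr[2],
             mean_a = mean(a$value), mean_b = mean(b$value),
             n = n, test = test, p_value = ht$p.value,
             signif = p_stars(ht$p.value))
    })
  structure(list(per_cell = per_cell, comparisons = comparisons,
                 metric = metric),
            class = "bt_mobility_report")
}

p_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
}

#' Normalized displacement time course
#'
#' Bins single-frame locus displacements in time and divides each bin's
#' mean by the pre-stimulation mean (or the first bin when no
#' pre-stimulation frames exist), producing the normalized mobility
#' trajectory through stimulation. Bins fed by fewer than `min_loci` loci
#' are flagged.
#'
#' @param tracks Linked locus tibble.
#' @param t0_frame Stimulation frame.
#' @param frame_interval_s Frame interval (s).
#' @param bin_s Bin width in seconds.
#' @param anchor `"pre"` or `"first_bin"`.
#' @param min_loci Minimum loci per trusted bin.
#' @return Tibble: `t_mid_s` (bin midpoint relative to stimulation),
#'   `mean_disp_um`, `norm_disp`, `n_loci`, `flagged`.
#' @export
normalized_displacement_timecourse <- function(tracks, t0_frame,
                                               frame_interval_s, bin_s,
                                               anchor = c("pre", "first_bin"),
                                               min_loci = 3L) {
  anchor <- match.arg(anchor)
  disp <- tracks %>%
    group_by(.data$track_id) %>%
    dplyr::group_modify(~ single_frame_displacements(.x)) %>%
    ungroup() %>%
    mutate(t_s = (.data$frame - t0_frame) * frame_interval_s)
  pre <- disp %>% filter(.data$t_s < 0)
  if (anchor == "pre" && nrow(pre) == 0) {
    abort("no pre-stimulation displacements; use anchor = \"first_bin\".")
  }
  binned <- disp %>%
    mutate(bin = floor(.data$t_s / bin_s)) %>%
    group_by(.data$bin) %>%
    summarise(t_mid_s = (first(.data$bin) + 0.5) * bin_s,
              mean_disp_um = mean(.data$disp_um),
              n_loci = dplyr::n_distinct(.data$track_id),
              .groups = "drop")
  anchor_val <- if (anchor == "pre") mean(pre$disp_um) else
    binned$mean_disp_um[1]
  binned %>%
    mutate(norm_disp = .data$mean_disp_um / anchor_val,
           flagged = .data$n_loci < min_loci) %>%
    select("t_mid_s", "mean_disp_um", "norm_disp", "n_loci", "flagged")
}
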