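#' Link spot detections into tracks
#'
#' Frame-to-frame linking by optimal bipartite assignment (Hungarian
#' algorithm) on squared displacements, with links farther than
#' `max_link_um` forbidden, followed by a gap-closing pass that joins a
#' track end to a later track start when the frame difference is at most
#' `max_gap_frames` and the end-to-start distance at most `max_close_um`.
#' Gap candidates are considered in order of time difference then
#' distance. Tracks shorter than `min_spots` are dropped. The defaults are
#' the single-molecule tracking settings (0.4 um link, 0.6 um close, frame
#' gap 3, minimum 5 spots); locus movies pass movie-appropriate distances.
#'
#' @param spots Tibble with at least `frame`, `x_um`, `y_um`; additional
#'   columns are preserved.
#' @param max_link_um Maximum frame-to-frame linking distance (um).
#' @param max_gap_frames Maximum frame difference bridged by gap closing.
#' @param max_close_um Maximum gap-closing distance (um).
#' @param min_spots Minimum spots per retained track.
#' @param min_frame Spots before this frame are discarded before linking
#'   (photobleaching settle-in filter; 500 for single-molecule movies).
#' @return The spot tibble with a `track_id` column, ordered by track and
#'   frame; only retained tracks appear.
#' @export
link_spots <- function(spots, max_link_um = 0.4, max_gap_frames = 3L,
                       max_close_um = 0.6, min_spots = 5L,
                       min_frame = 0L) {
  spots <- as_tibble(spots)
  if (nrow(spots) == 0) return(mutate(spots, track_id = integer()))
  spots <- spots %>%
    filter(.data$frame >= min_frame) %>%
    arrange(.data$frame, .data$x_um, .data$y_um)
  if (nrow(spots) == 0) return(mutate(spots, track_id = integer()))

  n <- nrow(spots)
  tid <- integer(n)
  next_id <- 0L
  frames <- sort(unique(spots$frame))
  idx_by_frame <- split(seq_len(n), spots$frame)

  prev_idx <- idx_by_frame[[as.character(frames[1])]]
  tid[prev_idx] <- next_id + seq_along(prev_idx)
  next_id <- next_id + length(prev_idx)

  for (fi in seq_along(frames)[-1]) {
    cur_idx <- idx_by_frame[[as.character(frames[fi])]]
    consecutive <- frames[fi] - frames[fi - 1] == 1
    if (consecutive && length(prev_idx) > 0) {
      d2 <- outer(spots$x_um[prev_idx], spots$x_um[cur_idx], `-`)^2 +
        outer(spots$y_um[prev_idx], spots$y_um[cur_idx], `-`)^2
      assn <- lap_assign(d2, max_link_um^2)
      linked_cur <- rep(FALSE, length(cur_idx))
      for (i in seq_along(prev_idx)) {
        j <- assn[i]
        if (!is.na(j)) {
          tid[cur_idx[j]] <- tid[prev_idx[i]]
          linked_cur[j] <- TRUE
        }
      }
      newborn <- cur_idx[!linked_cur]
    } else {
      newborn <- cur_idx
    }
    if (length(newborn) > 0) {
      tid[newborn] <- next_id + seq_along(newborn)
      next_id <- next_id + length(newborn)
    }
    prev_idx <- cur_idx
  }
  spots$track_id <- tid

  spots <- close_gaps(spots, max_gap_frames, max_close_um)

  spots %>%
    group_by(.data$track_id) %>%
    filter(n() >= min_spots) %>%
    ungroup() %>%
    mutate(track_id = as.integer(factor(.data$track_id))) %>%
    arrange(.data$track_id, .data$frame)
}

# Optimal assignment with a per-link feasibility threshold. Returns, for
# each row, the assigned column index or NA. Infeasible links carry a
# prohibitive cost; dummy columns (one per row) model "no link" at a cost
# just above the feasibility bound so any feasible link is preferred.
lap_assign <- function(cost2, max_cost2) {
  n1 <- nrow(cost2); n2 <- ncol(cost2)
  big <- max_cost2 * 1e6 + 1
  cost2[cost2 > max_cost2] <- big
  full <- cbind(cost2, matrix(max_cost2 * (1 + 1e-9), n1, n1))
  sol <- clue::solve_LSAP(full)
  out <- as.integer(sol)
  out[out > n2] <- NA_integer_
  feasible <- !is.na(out) & cost2[cbind(seq_len(n1), ifelse(is.na(out), 1L, out))] <= max_cost2
  out[!feasible] <- NA_integer_
  out
}

# second pass: join track ends to later track starts across small gaps
close_gaps <- function(spots, max_gap_frames, max_close_um) {
  ends <- spots %>%
    group_by(.data$track_id) %>%
    summarise(frame = max(.data$frame),
              x_um = .data$x_um[which.max(.data$frame)],
              y_um = .data$y_um[which.max(.data$frame)], .groups = "drop")
  starts <- spots %>%
    group_by(.data$track_id) %>%
    summarise(frame = min(.data$frame),
              x_um = .data$x_um[which.min(.data$frame)],
              y_um = .data$y_um[which.min(.data$frame)], .groups = "drop")
  cand <- tidyr::expand_grid(e = seq_len(nrow(ends)), s = seq_len(nrow(starts))) %>%
    mutate(
      id_e = ends$track_id[.data$e], id_s = starts$track_id[.data$s],
      dt = starts$frame[.data$s] - ends$frame[.data$e],
      d = sqrt((starts$x_um[.data$s] - ends$x_um[.data$e])^2 +
                 (starts$y_um[.data$s] - ends$y_um[.data$e])^2)
    ) %>%
    filter(.data$id_e != .data$id_s, .data$dt >= 2,
           .data$dt <= max_gap_frames, .data$d <= max_close_um) %>%
    arrange(.data$dt, .data$d)
  if (nrow(cand) == 0) return(spots)
  used_end <- used_start <- integer()
  remap <- setNames(unique(spots$track_id), unique(spots$track_id))
  resolve <- function(id) { while (remap[[as.character(id)]] != id) id <- remap[[as.character(id)]]; id }
  for (i in seq_len(nrow(cand))) {
    ide <- cand$id_e[i]; ids <- cand$id_s[i]
    if (ide %in% used_end || ids %in% used_start) next
    root_e <- resolve(ide)
    if (resolve(ids) == root_e) next
    remap[[as.character(ids)]] <- root_e
    used_end <- c(used_end, ide)
    used_start <- c(used_start, ids)
  }
  spots$track_id <- vapply(spots$track_id, resolve, numeric(1))
  spots
}

#' Missing frames of each track
#'
#' @param tracks Linked spot tibble (with `track_id`, `frame`).
#' @return Tibble `track_id`, `gap_frame` listing frames absent from the
#'   interior of each track.
#' @export
track_gaps <- function(tracks) {
  tracks %>%
    group_by(.data$track_id) %>%
    summarise(gap_frame = list(setdiff(seq(min(.data$frame), max(.data$frame)),
                                       .data$frame)), .groups = "drop") %>%
    tidyr::unnest("gap_frame")
}
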