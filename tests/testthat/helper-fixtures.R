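# Shared fixtures and independent brute-force oracles.

# O(n^2) pair-enumeration MSD oracle: enumerates every ordered spot pair
# (one loop over start spots, all partners at once), buckets squared
# displacements by frame difference, applies the >= min_pairs lag filter.
# Stays independent of the gap-aware position-array implementation.
msd_oracle <- function(track, dt, min_pairs = 3L) {
  n <- nrow(track)
  lag_all <- integer(0); d2_all <- numeric(0)
  for (i in seq_len(n)) {
    k <- track$frame - track$frame[i]
    keep <- k > 0
    d2 <- (track$x_um - track$x_um[i])^2 + (track$y_um - track$y_um[i])^2
    lag_all <- c(lag_all, k[keep])
    d2_all <- c(d2_all, d2[keep])
  }
  m <- tapply(d2_all, lag_all, mean)
  cnt <- tapply(d2_all, lag_all, length)
  ks <- as.integer(names(m))
  ord <- order(ks)
  out <- tibble::tibble(lag_frames = ks[ord], dT_s = ks[ord] * dt,
                        msd_um2 = as.numeric(m)[ord],
                        n_pairs = as.integer(cnt)[ord])
  out[out$n_pairs >= min_pairs, , drop = FALSE]
}

# brute-force signed distance: +min distance to inside pixel centres for
# outside points, -min distance to outside pixel centres for inside points
signed_dist_oracle <- function(mask, x_px, y_px, pixel_size_um) {
  inside <- which(mask, arr.ind = TRUE) - 1      # (row, col) 0-based
  outside <- which(!mask, arr.ind = TRUE) - 1
  vapply(seq_along(x_px), function(i) {
    r <- round(y_px[i]); c <- round(x_px[i])
    if (mask[r + 1, c + 1]) {
      -min(sqrt((outside[, 1] - r)^2 + (outside[, 2] - c)^2))
    } else {
      min(sqrt((inside[, 1] - r)^2 + (inside[, 2] - c)^2))
    }
  }, numeric(1)) * pixel_size_um
}

# random gappy track for oracle comparisons
random_gappy_track <- function(n_spots, drop_frac = 0.2) {
  frames <- sort(sample(0:(n_spots * 2), n_spots))
  tibble::tibble(frame = frames,
                 x_um = cumsum(rnorm(n_spots, sd = 0.05)),
                 y_um = cumsum(rnorm(n_spots, sd = 0.05)))
}

# grid of non-overlapping elliptical nuclei for rendering
nuclei_grid <- function(n, shape, rx = 14, ry = 10) {
  per_row <- ceiling(sqrt(n))
  step_c <- shape[2] / per_row
  step_r <- shape[1] / ceiling(n / per_row)
  tibble::tibble(
    nucleus_id = seq_len(n),
    cx_px = ((seq_len(n) - 1) %% per_row + 0.5) * step_c,
    cy_px = ((seq_len(n) - 1) %/% per_row + 0.5) * step_r,
    rx_px = rx, ry_px = ry
  )
}

# synthetic burst movie: one confined locus per nucleus, telegraph-like
# scheduled bursts, returns the rendered movie with ground truth
make_burst_movie <- function(n_nuclei = 4, n_frames = 60, snr = 10,
                             shape = c(96L, 96L) * as.integer(ceiling(sqrt(n_nuclei) / 2)),
                             frame_interval_s = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- sim_config(pixel_size_um = 0.1, frame_interval_s = frame_interval_s,
                    n_frames = n_frames, image_shape = shape,
                    localization_noise_um = 0, psf_sigma_px = 1.5,
                    background_level = 100, snr = snr)
  nuc <- nuclei_grid(n_nuclei, shape)
  specs <- lapply(seq_len(n_nuclei), function(i) {
    walker_spec("confined", D_um2_s = 2e-4, Rc_um = 0.3,
                start_xy_um = c(nuc$cx_px[i], nuc$cy_px[i]) * cfg$pixel_size_um,
                lifetime_frames = n_frames)
  })
  tracks <- simulate_tracks(specs, cfg)
  tracks$nucleus_id <- tracks$track_id
  bursts <- purrr::map_dfr(seq_len(n_nuclei), function(i) {
    iv <- simulate_telegraph(n_frames, frame_interval_s,
                             k_on = 1 / (20 * frame_interval_s),
                             k_off = 1 / (10 * frame_interval_s))
    if (nrow(iv) == 0) return(tibble::tibble())
    dplyr::mutate(iv, nucleus_id = i, track_id = i)
  })
  if (!"end_frame" %in% names(bursts)) {
    bursts <- tibble::tibble(nucleus_id = integer(), track_id = integer(),
                             start_frame = integer(), end_frame = integer())
  }
  # keep only events long enough to be observable (>= 2 frames)
  bursts <- dplyr::filter(bursts, end_frame - start_frame >= 2)
  movie <- render_movie(tracks, cfg, nuc, bursts = bursts)
  movie
}

# match recovered events to ground-truth schedule by interval overlap;
# returns per-truth-event the best-overlap recovered event (or NA)
match_events <- function(truth, recovered) {
  purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    t <- truth[i, ]
    if (nrow(recovered) == 0) {
      return(tibble::tibble(truth_row = i, rec_row = NA_integer_,
                            overlap = 0))
    }
    ov <- pmin(recovered$end_frame, t$end_frame) -
      pmax(recovered$start_frame, t$start_frame)
    same_nuc <- recovered$nucleus_id == t$nucleus_id
    ov[!same_nuc] <- 0
    best <- which.max(ov)
    tibble::tibble(truth_row = i,
                   rec_row = ifelse(ov[best] > 0, best, NA_integer_),
                   overlap = max(ov[best], 0))
  })
}
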