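# locus tracks with piecewise diffusion: D per frame chosen by a state
# sequence; used to test burst/phase segmentation end to end
make_state_tracks <- function(n_cells, n_frames, dt, D_of_state, bursts_per_cell,
                              seed = 1) {
  set.seed(seed)
  tracks <- list(); bursts <- list()
  for (cell in seq_len(n_cells)) {
    b <- bursts_per_cell(cell)
    on <- rep(FALSE, n_frames)
    for (j in seq_len(nrow(b))) {
      on[(b$start_frame[j] + 1):b$end_frame[j]] <- TRUE
    }
    D <- D_of_state(on)
    steps <- matrix(rnorm(2 * (n_frames - 1)), ncol = 2) *
      sqrt(2 * D[-1] * dt)
    pos <- rbind(c(0, 0), apply(steps, 2, cumsum))
    tracks[[cell]] <- tibble::tibble(
      track_id = cell, nucleus_id = cell, frame = 0:(n_frames - 1),
      x_um = pos[, 1], y_um = pos[, 2]
    )
    if (nrow(b) > 0) bursts[[cell]] <- dplyr::mutate(b, nucleus_id = cell)
  }
  list(tracks = dplyr::bind_rows(tracks), bursts = dplyr::bind_rows(bursts))
}

test_that("burst segmentation partitions track frames by the schedule", {
  trk <- tibble::tibble(track_id = 1L, nucleus_id = 1L, frame = 0:29,
                        x_um = 0, y_um = 0)
  ev <- tibble::tibble(nucleus_id = 1L, start_frame = 10L, end_frame = 20L)
  seg <- segment_by_bursts(trk, ev)
  expect_equal(seg$state, c("nonburst", "burst", "nonburst"))
  expect_equal(seg$start_frame, c(0L, 10L, 20L))
  expect_equal(seg$end_frame, c(10L, 20L, 30L))
  # partition: no frame in two segments, all frames covered
  expect_equal(sum(seg$n_frames), 30)

  # no bursts -> single nonburst segment
  seg0 <- segment_by_bursts(trk, ev[0, ])
  expect_equal(nrow(seg0), 1)
  expect_equal(seg0$state, "nonburst")
})

test_that("every burst-labeled frame lies inside a same-nucleus event", {
  set.seed(30)
  sim <- make_state_tracks(
    n_cells = 6, n_frames = 80, dt = 15,
    D_of_state = function(on) ifelse(on, 1e-4, 4e-4),
    bursts_per_cell = function(cell) {
      tibble::tibble(start_frame = c(10L, 50L) + cell,
                     end_frame = c(25L, 65L) + cell)
    })
  seg <- segment_by_bursts(sim$tracks, sim$bursts)
  for (i in which(seg$state == "burst")) {
    b <- sim$bursts[sim$bursts$nucleus_id == seg$nucleus_id[i], ]
    inside <- any(b$start_frame <= seg$start_frame[i] &
                    seg$end_frame[i] <= b$end_frame)
    expect_true(inside)
  }
})

test_that("phase segmentation maps frames through the stimulation windows", {
  # 15 s frames; t0 at frame 40 (10 min pre-roll)
  trk <- tibble::tibble(track_id = 1L, nucleus_id = 1L, frame = 0:800,
                        x_um = 0, y_um = 0)
  seg <- segment_by_phase(trk, phase_windows("methods"), t0_frame = 40,
                          frame_interval_s = 15)
  expect_equal(seg$state[1], "pre")
  expect_equal(seg$end_frame[seg$state == "pre"], 40L)
  # acute covers [0, 120) min = frames 40..519
  expect_equal(seg$start_frame[seg$state == "acute"], 40L)
  expect_equal(seg$end_frame[seg$state == "acute"], 520L)
  # frame at minute 130 (frame 560) is in the 120-160 min gap -> unlabeled
  expect_false(any(seg$start_frame <= 560 & 560 < seg$end_frame))
  # chronic starts at minute 160 = frame 680
  expect_equal(seg$start_frame[seg$state == "chronic"], 680L)

  # bursting preset uses the 24-132 min acute window
  segb <- segment_by_phase(trk, phase_windows("bursting"), t0_frame = 40,
                           frame_interval_s = 15)
  expect_equal(segb$start_frame[segb$state == "acute"],
               40L + 24L * 4L)
})

test_that("mobility comparison detects a constructed paired effect", {
  set.seed(31)
  # burst displacement exactly 0.8x of nonburst in every cell
  segs <- purrr::map_dfr(1:10, function(cell) {
    base <- runif(1, 0.2, 0.4)
    tibble::tibble(track_id = cell, nucleus_id = cell,
                   state = c("burst", "nonburst"),
                   start_frame = c(0L, 50L), end_frame = c(50L, 100L),
                   n_frames = 50L, n_disp = 49L,
                   mean_disp_um = c(0.8 * base, base), usable = TRUE)
  })
  rep <- compare_mobility(segs)
  cmp <- tidy(rep)
  expect_equal(cmp$test, "paired t")
  expect_lt(cmp$p_value, 0.05)
  expect_lt(cmp$mean_a, cmp$mean_b)  # burst < nonburst

  # identical groups -> mean difference 0, p ~ 1
  same <- dplyr::mutate(segs, mean_disp_um = rep(0.3, 20))
  rep2 <- compare_mobility(same)
  expect_equal(tidy(rep2)$mean_a, tidy(rep2)$mean_b)
  expect_gt(tidy(rep2)$p_value, 0.9)
})

test_that("burst-state mobility reduction is recovered from simulated cells", {
  sim <- make_state_tracks(
    n_cells = 50, n_frames = 120, dt = 15,
    D_of_state = function(on) ifelse(on, 2e-4, 4e-4),  # slower during bursts
    bursts_per_cell = function(cell) {
      tibble::tibble(start_frame = c(20L, 80L), end_frame = c(45L, 105L))
    },
    seed = 32)
  seg <- segment_by_bursts(sim$tracks, sim$bursts)
  rep <- compare_mobility(seg)
  cmp <- tidy(rep)
  expect_lt(cmp$mean_a[cmp$state_a == "burst"],
            cmp$mean_b[cmp$state_a == "burst"])
  expect_lt(cmp$p_value, 0.01)
})

test_that("per-phase displacement ordering is recovered in a three-state design", {
  # pre slower than acute, chronic fastest: D 1e-4 / 2.5e-4 / 4e-4
  set.seed(33)
  dt <- 15
  t0 <- 40L
  n_frames <- 1000L
  tracks <- purrr::map_dfr(1:12, function(cell) {
    mins <- ((0:(n_frames - 1)) - t0) * dt / 60
    D <- ifelse(mins < 0, 1e-4, ifelse(mins < 120, 2.5e-4,
                                       ifelse(mins >= 160, 4e-4, 3e-4)))
    steps <- matrix(rnorm(2 * (n_frames - 1)), ncol = 2) *
      sqrt(2 * D[-1] * dt)
    pos <- rbind(c(0, 0), apply(steps, 2, cumsum))
    tibble::tibble(track_id = cell, nucleus_id = cell,
                   frame = 0:(n_frames - 1), x_um = pos[, 1], y_um = pos[, 2])
  })
  seg <- segment_by_phase(tracks, phase_windows(), t0, dt)
  rep <- compare_mobility(seg)
  means <- rep$per_cell %>%
    dplyr::group_by(state) %>%
    dplyr::summarise(m = mean(value))
  expect_lt(means$m[means$state == "pre"], means$m[means$state == "acute"])
  expect_lt(means$m[means$state == "acute"], means$m[means$state == "chronic"])
})

test_that("segment alpha distinguishes on/off anomalous exponents", {
  set.seed(34)
  dt <- 0.005
  # two-state fbm-like tracks approximated by stitching fbm pieces
  cfg <- sim_config(frame_interval_s = dt, localization_noise_um = 0)
  on_tracks <- simulate_tracks(
    replicate(40, walker_spec("fbm", D_um2_s = 0.1, alpha = 0.5,
                              lifetime_frames = 60L), simplify = FALSE), cfg)
  off_tracks <- simulate_tracks(
    replicate(40, walker_spec("fbm", D_um2_s = 0.1, alpha = 0.9,
                              lifetime_frames = 60L), simplify = FALSE), cfg)
  on_tracks <- dplyr::mutate(on_tracks, nucleus_id = track_id)
  off_tracks <- dplyr::mutate(off_tracks, nucleus_id = track_id + 1000L,
                              track_id = track_id + 1000L)
  tracks <- dplyr::bind_rows(on_tracks, off_tracks)
  bursts <- tibble::tibble(nucleus_id = unique(on_tracks$nucleus_id),
                           start_frame = 0L, end_frame = 60L)
  # the off-tracks' nuclei have no burst rows: expect the non-burst warning
  expect_warning(seg <- segment_by_bursts(tracks, bursts), "non-burst")
  seg <- segment_alpha(seg, tracks, dt)
  med <- seg %>%
    dplyr::filter(!is.na(alpha)) %>%
    dplyr::group_by(state) %>%
    dplyr::summarise(m = median(alpha))
  expect_lt(med$m[med$state == "burst"], med$m[med$state == "nonburst"])
})

test_that("normalized timecourse shows the sqrt(2) step for doubled D", {
  set.seed(35)
  dt <- 15; t0 <- 100L; n_frames <- 400L
  tracks <- purrr::map_dfr(1:40, function(cell) {
    D <- ifelse(0:(n_frames - 1) < t0, 2e-4, 4e-4)
    steps <- matrix(rnorm(2 * (n_frames - 1)), ncol = 2) *
      sqrt(2 * D[-1] * dt)
    pos <- rbind(c(0, 0), apply(steps, 2, cumsum))
    tibble::tibble(track_id = cell, frame = 0:(n_frames - 1),
                   x_um = pos[, 1], y_um = pos[, 2])
  })
  tc <- normalized_displacement_timecourse(tracks, t0, dt, bin_s = 600)
  pre <- tc$norm_disp[tc$t_mid_s < 0]
  post <- tc$norm_disp[tc$t_mid_s > 0]
  expect_equal(mean(pre), 1, tolerance = 0.05)
  expect_equal(mean(post), sqrt(2), tolerance = 0.05)
  expect_false(any(tc$flagged))
})
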