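test_that("nucleus segmentation recovers disjoint bright ellipses", {
  set.seed(2)
  cfg <- sim_config(n_frames = 2, image_shape = c(128L, 128L), snr = 10)
  nuc <- nuclei_grid(3, c(128L, 128L), rx = 13, ry = 9)
  mv <- render_movie(NULL, cfg, nuc)
  frame <- mv$channels$rna[, , 1]
  mask <- segment_nuclei_burst_movie(frame, blur_sigma = 4,
                                     size_range = c(100, 3000))
  expect_equal(nrow(mask$stats), 3)
  # each ground-truth ellipse >= 90% covered by exactly one label
  for (i in 1:3) {
    gt <- mv$truth$nucleus_mask == i
    labs <- mask$labels[gt]
    best <- as.integer(names(sort(table(labs[labs > 0]),
                                  decreasing = TRUE))[1])
    expect_gte(mean(mask$labels[gt] == best), 0.9)
  }
})

test_that("size selection removes undersized objects; constant frames error", {
  set.seed(4)
  frame <- matrix(10 + rnorm(64 * 64), 64, 64)
  frame[30:33, 30:33] <- 200      # 16 px object, below min size 100
  mask <- segment_nuclei_burst_movie(frame, blur_sigma = 1,
                                     size_range = c(100, 3000))
  expect_equal(nrow(mask$stats), 0)
  expect_error(segment_nuclei_burst_movie(matrix(5, 32, 32)), "constant")
})

test_that("extranuclear suppression follows the 90%-of-median rule and is idempotent", {
  frame <- matrix(100, 32, 32)
  frame[1, 1] <- 500
  labels <- matrix(0L, 32, 32); labels[10:20, 10:20] <- 1L
  mask <- structure(list(labels = labels,
                         stats = tibble::tibble(nucleus_label = 1L,
                                                area_px = 121L,
                                                median_intensity = 100)),
                    class = "bt_nucleus_mask")
  sup <- suppress_extranuclear(frame, mask, 1L)
  expect_equal(sup[1, 1], 90)                       # outside -> 0.9 * median
  expect_equal(sup[10:20, 10:20], frame[10:20, 10:20])  # inside untouched
  expect_equal(suppress_extranuclear(sup, mask, 1L), sup) # idempotent
  expect_error(suppress_extranuclear(frame, mask, 7L), "not in mask")
})

test_that("burst threshold is exactly 5 + 0.55 * median", {
  set.seed(6)
  meds <- runif(100, 0, 5000)
  expect_identical(burst_threshold(meds), 5 + 0.55 * meds)
})

test_that("flat frames give no burst spots; rendered bursts are localized to 1 px", {
  flat <- matrix(50, 64, 64)
  expect_equal(nrow(call_bursts_in_nucleus(flat, 50)), 0)

  set.seed(9)
  cfg <- sim_config(n_frames = 2, image_shape = c(96L, 96L), snr = 10,
                    localization_noise_um = 0)
  nuc <- tibble::tibble(nucleus_id = 1L, cx_px = 48, cy_px = 48,
                        rx_px = 30, ry_px = 24)
  tr <- tibble::tibble(track_id = 1L, frame = 0:1, x_um = 4.8, y_um = 4.8)
  b <- tibble::tibble(nucleus_id = 1L, track_id = 1L, start_frame = 0L,
                      end_frame = 2L)
  mv <- render_movie(tr, cfg, nuc, bursts = b)
  frame <- mv$channels$rna[, , 1]
  mask <- segment_nuclei_burst_movie(frame, blur_sigma = 4,
                                     size_range = c(500, 5000))
  med <- mask$stats$median_intensity[1]
  sup <- suppress_extranuclear(frame, mask, 1L)
  spots <- call_bursts_in_nucleus(sup, med, radii = c(2, 4),
                                  pixel_size_um = 0.1)
  expect_equal(nrow(spots), 1)
  expect_lt(sqrt((spots$x_px - 48)^2 + (spots$y_px - 48)^2), 1)
})

test_that("FISH nucleus segmentation projects, splits touching nuclei, fills holes", {
  set.seed(12)
  base <- matrix(10 + rnorm(128 * 128), 128, 128)
  cc <- matrix(rep(0:127, each = 128), 128, 128)
  rr <- matrix(rep(0:127, 128), 128, 128)
  # two touching discs
  d1 <- (cc - 48)^2 + (rr - 64)^2 <= 15^2
  d2 <- (cc - 77)^2 + (rr - 64)^2 <= 15^2
  img <- base + 100 * (d1 | d2)
  img[64, 48] <- 10                       # a hole inside nucleus 1
  stack <- array(rep(img / 2, 2), c(128, 128, 2))
  stack[, , 1] <- img                     # max projection recovers img
  mask <- segment_nuclei_fish(stack, rolling_radius = 60, blur_sigma = 2,
                              min_size = 20, watershed_tolerance = 6)
  expect_equal(nrow(mask$stats), 2)
  expect_gt(mask$labels[65, 49], 0)       # hole filled
})

test_that("FISH segmentation drops sub-minimum particles", {
  set.seed(13)
  img <- matrix(10 + rnorm(64 * 64), 64, 64)
  img[30:32, 30:32] <- 300                # 9 px < 20 px minimum
  mask <- segment_nuclei_fish(img, rolling_radius = 30, blur_sigma = 1)
  expect_equal(nrow(mask$stats), 0)
})

test_that("DoG spot thresholds follow the per-mode rules", {
  set.seed(14)
  frame <- matrix(rnorm(64 * 64, sd = 10), 64, 64)
  # dna_track: threshold k * sd(channel); with k = 3 and sd ~10 -> ~30;
  # no DoG value can reach it on pure noise of this sd after band-passing
  expect_equal(nrow(segment_spots_dog(frame, "dna_track", k = 30)), 0)
  expect_error(segment_spots_dog(frame, "rna_track"), "abs_threshold")
  flat <- matrix(0, 64, 64)
  flat[32, 32] <- 1e-9
  expect_equal(nrow(segment_spots_dog(flat, "dna_track", k = 3)), 0)

  # a bright rendered spot is found within 1 px in dna mode
  spotted <- matrix(100, 64, 64)
  spotted <- spotted + 80 * outer(exp(-((0:63) - 20)^2 / 8),
                                  exp(-((0:63) - 40)^2 / 8))
  sp <- segment_spots_dog(spotted + matrix(rnorm(64 * 64), 64, 64),
                          "dna_track", k = 3)
  expect_equal(nrow(sp), 1)
  expect_lt(abs(sp$y_px[1] - 20), 1)
  expect_lt(abs(sp$x_px[1] - 40), 1)
})

test_that("locus spot detected within 1 px in >=99% of frames at SNR >= 8", {
  set.seed(15)
  cfg <- sim_config(n_frames = 40, frame_interval_s = 15,
                    image_shape = c(64L, 64L), snr = 8,
                    localization_noise_um = 0)
  nuc <- tibble::tibble(nucleus_id = 1L, cx_px = 32, cy_px = 32,
                        rx_px = 24, ry_px = 20)
  tr <- simulate_tracks(walker_spec("confined", D_um2_s = 1e-4, Rc_um = 0.3,
                                    start_xy_um = c(3.2, 3.2),
                                    lifetime_frames = 40L), cfg)
  mv <- render_movie(tr, cfg, nuc)
  hits <- vapply(1:40, function(f) {
    frame <- mv$channels$dna[, , f]
    msk <- segment_nuclei_burst_movie(frame, blur_sigma = 4,
                                      size_range = c(500, 5000))
    sup <- suppress_extranuclear(frame, msk, 1L)
    sp <- segment_spots_dog(sup, "dna_track",
                            radii = c(1.5, 3), k = 1,
                            pixel_size_um = 0.1, frame_index = f - 1L)
    if (nrow(sp) == 0) return(FALSE)
    truth <- tr[tr$frame == f - 1L, ]
    any(sqrt((sp$x_um - truth$x_true_um)^2 +
               (sp$y_um - truth$y_true_um)^2) < 0.1)
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("organelle distance maps are exact and mutually exclusive", {
  mask <- matrix(FALSE, 16, 16)
  mask[6, 6] <- TRUE                       # 0-based (5,5)
  om <- build_organelle_distance_maps(mask, 0.1)
  expect_equal(om$external_um[6, 9], 0.3)  # 3 px away -> 0.3 um
  expect_equal(om$external_um[6, 7], 0.1)  # boundary-adjacent outside px
  expect_true(all(om$internal_um * om$external_um == 0))
  expect_error(build_organelle_distance_maps(matrix(TRUE, 4, 4), 0.1))
  expect_error(build_organelle_distance_maps(matrix(FALSE, 4, 4), 0.1))
})

test_that("SMT nuclear QC measures means over the thresholded nucleus", {
  red <- matrix(1, 64, 64); blue <- matrix(4, 64, 64)
  cc <- matrix(rep(0:63, each = 64), 64, 64)
  rr <- matrix(rep(0:63, 64), 64, 64)
  disc <- (cc - 32)^2 + (rr - 32)^2 <= 20^2
  red[disc] <- 10
  qc <- smt_nuclear_qc(red, blue)
  expect_equal(qc$mean_red, 10)
  expect_equal(qc$mean_blue, 4)
  expect_lt(abs(qc$area_px - sum(disc)) / sum(disc), 0.1)
  expect_error(smt_nuclear_qc(matrix(0, 8, 8), matrix(0, 8, 8)), "constant")
})

test_that("auto-threshold methods separate a clear bimodal image", {
  set.seed(16)
  truth <- rep(c(FALSE, TRUE), each = 500)
  v <- matrix(c(rnorm(500, 10, 1), rnorm(500, 100, 5)), 50, 20)
  for (m in c("mean", "isodata", "huang")) {
    thr <- auto_threshold(v, m)
    expect_gte(mean((as.numeric(v) > thr) == truth), 0.99)
  }
})
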