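#' Render a synthetic multi-channel movie from ground-truth tracks
#'
#' Draws calibrated image stacks the segmentation and tracking stages can be
#' validated against: elliptical nuclei on a textured background, tracked
#' loci as Gaussian spots in a DNA channel, MS2-like burst foci visible only
#' during their scheduled on-intervals in an RNA channel, and optional
#' speckle-like organelle blobs. Spots are rendered at a peak amplitude of
#' four times the background level by default (MS2-like foci are
#' several-fold brighter than the nucleoplasm); per-pixel Gaussian noise
#' with standard deviation `peak / snr` is added to every channel, plus
#' Poisson shot noise on the signal.
#'
#' @param tracks Tibble of walker positions (`track_id`, `frame`, `x_um`,
#'   `y_um`) as produced by [simulate_tracks()]; rendered into the `"dna"`
#'   channel. Tracks may carry a `nucleus_id` column.
#' @param cfg A [sim_config()].
#' @param nuclei Tibble of ellipse parameters: `nucleus_id`, `cx_px`,
#'   `cy_px`, `rx_px`, `ry_px` (centres and semi-axes, 0-based pixels).
#'   Ellipses must not overlap.
#' @param bursts Optional tibble of burst schedules: `nucleus_id`,
#'   `track_id` (the focus walker whose position the burst is rendered at),
#'   `start_frame`, `end_frame` (half-open). Rendered into the `"rna"`
#'   channel only during on-intervals.
#' @param organelles Optional binary matrix (rows x cols) of organelle
#'   pixels, rendered as a bright `"organelle"` channel.
#' @param spot_amplitude Peak intensity of rendered spots above background;
#'   default `cfg$snr` times the background noise sd.
#' @return A `bt_movie`: list with `channels` (named list of rows x cols x
#'   frames arrays), `cfg`, and `truth` (tracks, bursts, nucleus label
#'   matrix, organelle mask).
#' @export
render_movie <- function(tracks, cfg, nuclei, bursts = NULL,
                         organelles = NULL, spot_amplitude = NULL) {
  stopifnot(inherits(cfg, "bt_sim_config"))
  shp <- cfg$image_shape
  nr <- shp[1]; nc <- shp[2]
  nf <- cfg$n_frames
  px <- cfg$pixel_size_um
  # MS2-like foci are several-fold brighter than the nucleoplasm; the snr
  # knob then sets the background noise as peak / snr
  amp <- spot_amplitude %||% (4 * cfg$background_level)
  noise_sd <- amp / cfg$snr

  if (!is.null(tracks) && nrow(tracks) > 0) {
    xo <- tracks$x_um / px; yo <- tracks$y_um / px
    if (any(xo < 1 | xo > nc - 2 | yo < 1 | yo > nr - 2)) {
      abort("tracks exit the image; enlarge `image_shape` or re-centre.")
    }
  }

  nuc_mask <- matrix(0L, nr, nc)
  cc <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  rr <- matrix(rep(0:(nr - 1), nc), nr, nc)
  for (i in seq_len(nrow(nuclei))) {
    e <- nuclei[i, ]
    inside <- ((cc - e$cx_px) / e$rx_px)^2 + ((rr - e$cy_px) / e$ry_px)^2 <= 1
    if (any(nuc_mask[inside] != 0L)) abort("nuclei overlap.")
    nuc_mask[inside] <- as.integer(e$nucleus_id)
  }

  # static low-frequency texture inside nuclei (10% modulation)
  texture <- gblur_safe(matrix(rnorm(nr * nc), nr, nc), 8)
  texture <- texture / max(abs(texture)) * 0.1
  base <- cfg$background_level *
    ifelse(nuc_mask > 0L, 1 + texture, 0.2)

  channels <- list(
    dna = array(0, c(nr, nc, nf)),
    rna = array(0, c(nr, nc, nf))
  )
  if (!is.null(organelles)) channels$organelle <- array(0, c(nr, nc, nf))

  for (f in seq_len(nf) - 1L) {
    fr_dna <- base
    fr_rna <- base
    if (!is.null(tracks) && nrow(tracks) > 0) {
      sel <- tracks$frame == f
      if (any(sel)) {
        fr_dna <- add_gaussian_spots(fr_dna, tracks$x_um[sel] / px,
                                     tracks$y_um[sel] / px,
                                     amp, cfg$psf_sigma_px)
      }
    }
    if (!is.null(bursts) && nrow(bursts) > 0) {
      on <- bursts$start_frame <= f & f < bursts$end_frame
      if (any(on)) {
        for (b in which(on)) {
          tr <- tracks[tracks$track_id == bursts$track_id[b] &
                         tracks$frame == f, ]
          if (nrow(tr) == 1) {
            fr_rna <- add_gaussian_spots(fr_rna, tr$x_um / px, tr$y_um / px,
                                         amp, cfg$psf_sigma_px)
          }
        }
      }
    }
    channels$dna[, , f + 1L] <- add_camera_noise(fr_dna, noise_sd)
    channels$rna[, , f + 1L] <- add_camera_noise(fr_rna, noise_sd)
    if (!is.null(organelles)) {
      fr_org <- base + amp * gblur_safe(organelles * 1, 1)
      channels$organelle[, , f + 1L] <- add_camera_noise(fr_org, noise_sd)
    }
  }

  structure(
    list(
      channels = channels,
      cfg = cfg,
      truth = list(
        tracks = tracks,
        bursts = if (is.null(bursts)) NULL else
          dplyr::select(bursts, dplyr::any_of(
            c("nucleus_id", "track_id", "start_frame", "end_frame"))),
        nucleus_mask = nuc_mask,
        organelle_mask = organelles,
        drift = NULL
      )
    ),
    class = "bt_movie"
  )
}

# additive Gaussian spots, evaluated on a local window for speed
add_gaussian_spots <- function(frame, x_px, y_px, amp, sigma) {
  nr <- nrow(frame); nc <- ncol(frame)
  w <- ceiling(4 * sigma)
  for (i in seq_along(x_px)) {
    c0 <- round(x_px[i]); r0 <- round(y_px[i])
    rs <- max(0, r0 - w):min(nr - 1, r0 + w)
    cs <- max(0, c0 - w):min(nc - 1, c0 + w)
    g <- outer(
      exp(-(rs - y_px[i])^2 / (2 * sigma^2)),
      exp(-(cs - x_px[i])^2 / (2 * sigma^2))
    )
    frame[rs + 1, cs + 1] <- frame[rs + 1, cs + 1] + amp * g
  }
  frame
}

# Poisson shot noise on the (scaled) signal plus Gaussian read noise
add_camera_noise <- function(frame, read_sd) {
  shot <- rpois(length(frame), lambda = pmax(frame, 0))
  matrix(shot, nrow(frame), ncol(frame)) +
    matrix(rnorm(length(frame), sd = read_sd), nrow(frame), ncol(frame))
}

#' Generate a speckle-like organelle mask
#'
#' Random blobs (discs smoothed and thresholded) confined to nucleus
#' interiors, emulating interchromatin-granule-like bodies.
#'
#' @param shape `c(rows, cols)` in pixels.
#' @param n_blobs Number of seed discs.
#' @param radius_px Mean blob radius in pixels.
#' @param within Optional binary/integer matrix; blob centres are drawn
#'   from its positive pixels.
#' @return A logical matrix.
#' @export
organelle_blobs <- function(shape, n_blobs = 10, radius_px = 4,
                            within = NULL) {
  nr <- shape[1]; nc <- shape[2]
  mask <- matrix(0, nr, nc)
  if (is.null(within)) {
    centres <- cbind(runif(n_blobs, 1, nr), runif(n_blobs, 1, nc))
  } else {
    idx <- which(within > 0)
    if (length(idx) == 0) abort("`within` has no positive pixels.")
    pick <- sample(idx, n_blobs, replace = TRUE)
    centres <- cbind((pick - 1) %% nr + 1, (pick - 1) %/% nr + 1)
  }
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  rr <- matrix(rep(seq_len(nr), nc), nr, nc)
  for (i in seq_len(n_blobs)) {
    r_i <- radius_px * runif(1, 0.6, 1.4)
    mask <- mask | ((rr - centres[i, 1])^2 + (cc - centres[i, 2])^2 <= r_i^2)
  }
  mask
}

#' Inject rigid-body stage drift into a movie
#'
#' Each frame is rigidly transformed about the image centre: rotated by
#' `dtheta_deg` then translated by (`dx_px`, `dy_px`). Used to exercise the
#' drift-correction stage in a closed loop with known ground truth.
#'
#' @param movie A `bt_movie`.
#' @param drift Tibble or data frame with one row per frame and columns
#'   `dx_px`, `dy_px`, `dtheta_deg`.
#' @return The drifted `bt_movie`; `truth$drift` records the applied
#'   transforms.
#' @export
inject_drift <- function(movie, drift) {
  stopifnot(inherits(movie, "bt_movie"))
  drift <- as_tibble(drift)
  nf <- movie$cfg$n_frames
  if (nrow(drift) != nf) abort("`drift` must have one row per frame.")
  for (ch in names(movie$channels)) {
    for (f in seq_len(nf)) {
      movie$channels[[ch]][, , f] <- rigid_warp(
        movie$channels[[ch]][, , f],
        drift$dx_px[f], drift$dy_px[f], drift$dtheta_deg[f]
      )
    }
  }
  movie$truth$drift <- drift
  movie
}

# Rigid warp of one frame: content rotated by theta about the image centre,
# then shifted by (dx, dy) (x = column, y = row, 0-based). Bilinear
# interpolation; out-of-frame pixels take the frame median.
rigid_warp <- function(frame, dx, dy, theta_deg) {
  nr <- nrow(frame); nc <- ncol(frame)
  th <- theta_deg * pi / 180
  cx <- (nc - 1) / 2; cy <- (nr - 1) / 2
  cc <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  rr <- matrix(rep(0:(nr - 1), nc), nr, nc)
  # inverse map: source = R(-theta) * (dest - c - t) + c
  xd <- cc - cx - dx; yd <- rr - cy - dy
  xs <- cos(th) * xd + sin(th) * yd + cx
  ys <- -sin(th) * xd + cos(th) * yd + cy
  bilinear_sample(frame, xs, ys, fill = median(frame))
}

bilinear_sample <- function(frame, xs, ys, fill = 0) {
  nr <- nrow(frame); nc <- ncol(frame)
  ok <- xs >= 0 & xs <= nc - 1 & ys >= 0 & ys <= nr - 1
  x0 <- pmin(floor(xs), nc - 2); y0 <- pmin(floor(ys), nr - 2)
  fx <- xs - x0; fy <- ys - y0
  out <- matrix(fill, nr, nc)
  i00 <- (x0[ok]) * nr + y0[ok] + 1
  v <- (1 - fx[ok]) * (1 - fy[ok]) * frame[i00] +
    fx[ok] * (1 - fy[ok]) * frame[i00 + nr] +
    (1 - fx[ok]) * fy[ok] * frame[i00 + 1] +
    fx[ok] * fy[ok] * frame[i00 + nr + 1]
  out[ok] <- v
  out
}
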