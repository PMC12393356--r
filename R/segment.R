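#' Auto-threshold methods
#'
#' Histogram thresholds implemented from their published definitions:
#' `"mean"` is the mean of all pixels; `"isodata"` the iterative
#' intermeans method (the classic "Default" method of most image tools);
#' `"huang"` minimises Huang's fuzzy-entropy measure. Thresholds are
#' applied strictly-greater throughout the package.
#'
#' @param x Numeric matrix (one frame).
#' @param method One of `"mean"`, `"isodata"`, `"huang"`.
#' @param n_bins Histogram bins for `"isodata"`/`"huang"`.
#' @return The threshold value, on the intensity scale of `x`.
#' @export
auto_threshold <- function(x, method = c("mean", "isodata", "huang"),
                           n_bins = 256L) {
  method <- match.arg(method)
  v <- as.numeric(x)
  if (diff(range(v)) == 0) abort("cannot threshold a constant image.")
  switch(method,
    mean = mean(v),
    isodata = threshold_isodata(v, n_bins),
    huang = threshold_huang(v, n_bins)
  )
}

threshold_isodata <- function(v, n_bins) {
  t_old <- mean(v)
  for (i in 1:100) {
    lo <- v[v <= t_old]; hi <- v[v > t_old]
    if (length(lo) == 0 || length(hi) == 0) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t_old) < 1e-8 * diff(range(v))) return(t_new)
    t_old <- t_new
  }
  t_old
}

threshold_huang <- function(v, n_bins) {
  rng <- range(v)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  C <- rng[2] - rng[1]
  csum <- cumsum(h); cmu <- cumsum(h * mids)
  tot <- csum[n_bins]; totmu <- cmu[n_bins]
  best_t <- mids[1]; best_s <- Inf
  shannon <- function(u) {
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
    -u * log(u) - (1 - u) * log(1 - u)
  }
  for (ti in seq_len(n_bins - 1L)) {
    n0 <- csum[ti]; n1 <- tot - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- cmu[ti] / n0
    mu1 <- (totmu - cmu[ti]) / n1
    u <- ifelse(seq_len(n_bins) <= ti,
                1 / (1 + abs(mids - mu0) / C),
                1 / (1 + abs(mids - mu1) / C))
    s <- sum(h * shannon(u))
    if (s < best_s) { best_s <- s; best_t <- mids[ti] }
  }
  best_t
}

# Gaussian blur that tolerates kernels larger than the frame: the image is
# replicate-padded to fit the kernel, blurred, and cropped back.
gblur_safe <- function(x, sigma) {
  need <- 2L * ceiling(3 * sigma) + 2L
  pad <- max(0L, ceiling((need - min(dim(x))) / 2) + 1L)
  if (pad == 0L) return(EBImage::gblur(x, sigma = sigma))
  nr <- nrow(x); nc <- ncol(x)
  ri <- c(rep(1L, pad), seq_len(nr), rep(nr, pad))
  ci <- c(rep(1L, pad), seq_len(nc), rep(nc, pad))
  big <- EBImage::gblur(x[ri, ci], sigma = sigma)
  big[pad + seq_len(nr), pad + seq_len(nc)]
}

# Rolling-ball style background subtraction: grayscale top-hat with a disc
# structuring element. The disc is capped at the largest odd size that fits
# the frame; at the quoted radii (200-500 px) this removes only structure
# larger than any nucleus.
rolling_ball_subtract <- function(x, radius) {
  size <- min(2L * as.integer(radius) + 1L, min(dim(x)) - 1L)
  if (size %% 2L == 0L) size <- size - 1L
  if (size < 3L) return(x - min(x))
  brush <- EBImage::makeBrush(size, shape = "disc")
  bg <- EBImage::opening(x, brush)
  x - bg
}

# Difference-of-Gaussians band-pass: small-sigma blur minus large-sigma
# blur. Radii are used as sigmas directly (the sigma = radius convention);
# both are exposed wherever this is called.
dog_filter <- function(x, radius_small, radius_large) {
  gblur_safe(x, radius_small) -
    gblur_safe(x, radius_large)
}

#' Segment nuclei in a burst-movie frame
#'
#' Per-frame nucleus detection from the diffuse (non-focal) signal of the
#' RNA reporter channel: Gaussian blur, rolling-ball background
#' subtraction, mean auto-threshold, watershed separation, and size
#' selection. Per-label median intensities are measured on the unprocessed
#' frame, since the burst statistic is defined relative to the cell median.
#'
#' @param frame Numeric matrix, one channel of one frame.
#' @param blur_sigma Gaussian blur sigma in px (default 10).
#' @param rolling_radius Rolling-ball radius in px (default 500).
#' @param size_range Retained label area range `c(min, max)`, in px^2 at
#'   the reference magnification (default `c(40, 200)`).
#' @param area_scale Multiplier applied to `size_range` to re-express the
#'   bounds at a different pixel size (use `(ref_px / px)^2`).
#' @param watershed_tolerance Minimum object-height separation for the
#'   watershed split of touching nuclei.
#' @return A `bt_nucleus_mask`: list with `labels` (integer matrix),
#'   `stats` (tibble: `nucleus_label`, `area_px`, `median_intensity`).
#' @export
segment_nuclei_burst_movie <- function(frame, blur_sigma = 10,
                                       rolling_radius = 500,
                                       size_range = c(40, 200),
                                       area_scale = 1,
                                       watershed_tolerance = 1) {
  if (diff(range(frame)) == 0) abort("frame is constant; nothing to segment.")
  g <- gblur_safe(frame, blur_sigma)
  g <- rolling_ball_subtract(g, rolling_radius)
  thr <- auto_threshold(g, "mean")
  binary <- g > thr
  labels <- split_touching(binary, watershed_tolerance)
  keep_range <- size_range * area_scale
  finalize_nucleus_mask(labels, frame, keep_range)
}

# watershed split of a binary mask on its distance map
split_touching <- function(binary, tolerance) {
  if (!any(binary)) return(matrix(0L, nrow(binary), ncol(binary)))
  dm <- EBImage::distmap(EBImage::Image(binary * 1))
  lab <- EBImage::watershed(dm, tolerance = tolerance, ext = 1)
  matrix(as.integer(EBImage::imageData(lab)), nrow(binary), ncol(binary))
}

# size-filter, relabel 1..n, and collect per-label stats
finalize_nucleus_mask <- function(labels, frame, keep_range) {
  if (all(labels == 0L)) {
    return(structure(list(labels = labels,
                          stats = tibble(nucleus_label = integer(),
                                         area_px = integer(),
                                         median_intensity = numeric())),
                     class = "bt_nucleus_mask"))
  }
  areas <- tabulate(labels[labels > 0L])
  keep <- which(areas >= keep_range[1] & areas <= keep_range[2])
  new_lab <- integer(length(areas))
  new_lab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  pos <- labels > 0L
  out[pos] <- new_lab[labels[pos]]
  st <- purrr::map_dfr(seq_along(keep), function(i) {
    px <- frame[out == i]
    tibble(nucleus_label = i, area_px = length(px),
           median_intensity = median(px))
  })
  structure(list(labels = out, stats = st), class = "bt_nucleus_mask")
}

#' Relabel a nucleus mask to match a reference mask
#'
#' Maps each label of `mask` to the reference label it overlaps most;
#' labels without any reference overlap are dropped. Used to keep nucleus
#' identities stable across the frames of a movie despite the per-frame
#' watershed's arbitrary numbering.
#'
#' @param mask,ref `bt_nucleus_mask` objects of identical geometry.
#' @return `mask` relabelled in the reference numbering.
#' @export
harmonize_labels <- function(mask, ref) {
  if (nrow(mask$stats) == 0) return(mask)
  out <- matrix(0L, nrow(mask$labels), ncol(mask$labels))
  new_stats <- list()
  for (lb in mask$stats$nucleus_label) {
    sel <- mask$labels == lb
    ov <- table(ref$labels[sel])
    ov <- ov[names(ov) != "0"]
    if (length(ov) == 0) next
    target <- as.integer(names(ov)[which.max(ov)])
    out[sel] <- target
    st <- mask$stats[mask$stats$nucleus_label == lb, ]
    st$nucleus_label <- target
    new_stats[[length(new_stats) + 1L]] <- st
  }
  stats <- if (length(new_stats)) {
    bind_rows(new_stats) %>%
      group_by(.data$nucleus_label) %>%
      slice(which.max(.data$area_px)) %>%
      ungroup()
  } else {
    mask$stats[0, ]
  }
  structure(list(labels = out, stats = stats), class = "bt_nucleus_mask")
}

#' Suppress extranuclear signal around one nucleus
#'
#' Clears everything outside the target nucleus to 90% of that nucleus'
#' median intensity, so the per-nucleus burst statistic cannot fire on
#' edge artefacts or neighbouring cells. Pixels inside the nucleus are
#' untouched; the operation is idempotent.
#'
#' @param frame Numeric matrix.
#' @param mask A `bt_nucleus_mask`.
#' @param target_label Integer label present in `mask`.
#' @param outside_fraction Fraction of the nucleus median used outside
#'   (default 0.9).
#' @return The suppressed frame.
#' @export
suppress_extranuclear <- function(frame, mask, target_label,
                                  outside_fraction = 0.9) {
  st <- mask$stats[mask$stats$nucleus_label == target_label, ]
  if (nrow(st) != 1) abort(paste0("label ", target_label, " not in mask."))
  frame[mask$labels != target_label] <-
    outside_fraction * st$median_intensity
  frame
}

#' Burst-spot threshold
#'
#' The per-nucleus burst acceptance level on the DoG response:
#' `offset + slope * median_intensity`, default `5 + 0.55 * median`.
#'
#' @param median_intensity Nucleus median intensity.
#' @param offset,slope Affine threshold parameters.
#' @return The threshold.
#' @export
burst_threshold <- function(median_intensity, offset = 5, slope = 0.55) {
  offset + slope * median_intensity
}

#' Call transcriptional bursts within one nucleus
#'
#' Applies the difference-of-Gaussians band-pass (small radius 6, large
#' radius 12 by default) to an extranuclear-suppressed frame and returns
#' 8-connected strict local maxima whose DoG value exceeds
#' `5 + 0.55 * median_intensity`. Spot positions are the intensity-weighted
#' centroid of the above-threshold DoG patch around each maximum
#' (sub-pixel), reported in both pixels and micrometres.
#'
#' @param frame Suppressed frame (see [suppress_extranuclear()]).
#' @param median_intensity Nucleus median used in the threshold.
#' @param radii DoG radii `c(small, large)` in px.
#' @param offset,slope Threshold parameters, see [burst_threshold()].
#' @param pixel_size_um Pixel size for um coordinates.
#' @param frame_index Optional frame number attached to the output.
#' @return Tibble of spot records: `x_px`, `y_px`, `x_um`, `y_um`,
#'   `dog_value`, `peak_intensity`, `frame`.
#' @export
call_bursts_in_nucleus <- function(frame, median_intensity,
                                   radii = c(6, 12), offset = 5,
                                   slope = 0.55, pixel_size_um = 1,
                                   frame_index = NA_integer_) {
  dog <- dog_filter(frame, radii[1], radii[2])
  thr <- burst_threshold(median_intensity, offset, slope)
  dog_local_maxima(dog, thr, frame, pixel_size_um, frame_index)
}

# strict 8-connected local maxima of `dog` above `thr`, with sub-pixel
# centroid over the above-threshold connected patch
dog_local_maxima <- function(dog, thr, raw = NULL, pixel_size_um = 1,
                             frame_index = NA_integer_) {
  nr <- nrow(dog); nc <- ncol(dog)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- dog
  ctr <- pad[2:(nr + 1), 2:(nc + 1)]
  is_max <- ctr > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (ctr > pad[2:(nr + 1) + dr, 2:(nc + 1) + dc])
  }
  idx <- which(is_max)
  if (length(idx) == 0) {
    return(tibble(x_px = numeric(), y_px = numeric(), x_um = numeric(),
                  y_um = numeric(), dog_value = numeric(),
                  peak_intensity = numeric(), frame = integer()))
  }
  above <- dog > thr
  lab <- matrix(as.integer(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(above * 1)))), nr, nc)
  purrr::map_dfr(idx, function(i) {
    r0 <- (i - 1) %% nr + 1; c0 <- (i - 1) %/% nr + 1
    comp <- lab[r0, c0]
    sel <- which(lab == comp)
    wts <- dog[sel] - thr
    rsel <- (sel - 1) %% nr; csel <- (sel - 1) %/% nr
    yc <- sum(rsel * wts) / sum(wts)
    xc <- sum(csel * wts) / sum(wts)
    tibble(x_px = xc, y_px = yc,
           x_um = xc * pixel_size_um, y_um = yc * pixel_size_um,
           dog_value = dog[r0, c0],
           peak_intensity = if (is.null(raw)) dog[r0, c0] else raw[r0, c0],
           frame = frame_index)
  }) %>%
    distinct(.data$x_px, .data$y_px, .keep_all = TRUE)
}

#' Segment nuclei in a DAPI z-stack (FISH images)
#'
#' Maximum z-projection followed by rolling-ball background subtraction
#' (radius 200), Gaussian blur (sigma 4), Huang auto-threshold, removal of
#' particles below the minimum size, hole filling, and a tolerance-6
#' watershed to separate touching nuclei.
#'
#' @param stack 3D numeric array (rows x cols x z) or a single matrix.
#' @param rolling_radius,blur_sigma,min_size,watershed_tolerance Stage
#'   parameters; defaults follow the pipeline described above.
#' @return A `bt_nucleus_mask`.
#' @export
segment_nuclei_fish <- function(stack, rolling_radius = 200,
                                blur_sigma = 4, min_size = 20,
                                watershed_tolerance = 6) {
  proj <- if (length(dim(stack)) == 3) apply(stack, c(1, 2), max) else stack
  if (diff(range(proj)) == 0) abort("projection is constant.")
  g <- rolling_ball_subtract(proj, rolling_radius)
  g <- gblur_safe(g, blur_sigma)
  thr <- auto_threshold(g, "huang")
  binary <- g > thr
  binary <- matrix(as.integer(EBImage::imageData(
    EBImage::fillHull(EBImage::Image(binary * 1)))) > 0,
    nrow(binary), ncol(binary))
  labels <- split_touching(binary, watershed_tolerance)
  finalize_nucleus_mask(labels, proj, c(min_size, Inf))
}

#' Detect punctate spots by DoG filtering
#'
#' Spot detection for the locus-tracking movies. Thresholding depends on
#' the channel: `"dna_track"` uses `k` times the standard deviation of the
#' raw channel on the DoG response; `"rna_track"` a fixed absolute
#' threshold; `"organelle"` an isodata auto-threshold of the DoG response.
#'
#' @param frame Numeric matrix.
#' @param mode `"dna_track"`, `"rna_track"`, or `"organelle"`.
#' @param radii DoG radii `c(small, large)` in px.
#' @param k SD multiplier for `"dna_track"`.
#' @param abs_threshold Fixed threshold for `"rna_track"`.
#' @param pixel_size_um,frame_index Calibration/annotation of the output.
#' @return Tibble of spot records (see [call_bursts_in_nucleus()]).
#' @export
segment_spots_dog <- function(frame,
                              mode = c("dna_track", "rna_track", "organelle"),
                              radii = c(2, 4), k = 3, abs_threshold = NULL,
                              pixel_size_um = 1,
                              frame_index = NA_integer_) {
  mode <- match.arg(mode)
  dog <- dog_filter(frame, radii[1], radii[2])
  thr <- switch(mode,
    dna_track = k * sd(as.numeric(frame)),
    rna_track = {
      if (is.null(abs_threshold)) abort("`abs_threshold` required for rna_track.")
      abs_threshold
    },
    organelle = auto_threshold(dog, "isodata")
  )
  dog_local_maxima(dog, thr, frame, pixel_size_um, frame_index)
}

#' Segment an organelle mask by DoG + auto-threshold
#'
#' @param frame Numeric matrix (organelle channel).
#' @param radii DoG radii `c(small, large)` in px.
#' @return Logical matrix of organelle pixels.
#' @export
segment_organelle_mask <- function(frame, radii = c(2, 4)) {
  dog <- dog_filter(frame, radii[1], radii[2])
  dog > auto_threshold(dog, "isodata")
}

#' Internal/external organelle distance maps
#'
#' Euclidean distance transforms of the organelle mask and its inversion:
#' `internal_um` is, for inside pixels, the distance to the nearest outside
#' pixel (0 elsewhere); `external_um` is, for outside pixels, the distance
#' to the nearest inside pixel. Their pointwise product is identically 0.
#'
#' @param mask Logical or 0/1 matrix.
#' @param pixel_size_um Pixel size.
#' @return A `bt_organelle_mask`: list with `mask`, `internal_um`,
#'   `external_um`, `pixel_size_um`.
#' @export
build_organelle_distance_maps <- function(mask, pixel_size_um) {
  mask <- mask > 0
  if (all(mask) || !any(mask)) {
    abort("mask must contain both inside and outside pixels.")
  }
  internal <- matrix(as.numeric(EBImage::imageData(
    EBImage::distmap(EBImage::Image(mask * 1)))), nrow(mask), ncol(mask))
  external <- matrix(as.numeric(EBImage::imageData(
    EBImage::distmap(EBImage::Image((!mask) * 1)))), nrow(mask), ncol(mask))
  structure(
    list(mask = mask,
         internal_um = internal * pixel_size_um,
         external_um = external * pixel_size_um,
         pixel_size_um = pixel_size_um),
    class = "bt_organelle_mask"
  )
}

#' Nuclear QC for single-molecule movies
#'
#' Auto-thresholds the single-molecule (red) channel with the isodata
#' ("Default") method to delineate the nucleus, then reports its area and
#' the mean red and blue intensities over that area — the cross-condition
#' expression-level check run before tracking.
#'
#' @param red_frame,blue_frame Co-registered numeric matrices.
#' @return Tibble with `area_px`, `mean_red`, `mean_blue`.
#' @export
smt_nuclear_qc <- function(red_frame, blue_frame) {
  stopifnot(all(dim(red_frame) == dim(blue_frame)))
  if (diff(range(red_frame)) == 0) abort("red channel is constant.")
  thr <- auto_threshold(red_frame, "isodata")
  sel <- red_frame > thr
  if (!any(sel)) abort("thresholded nuclear area is empty.")
  tibble(area_px = sum(sel),
         mean_red = mean(red_frame[sel]),
         mean_blue = mean(blue_frame[sel]))
}
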