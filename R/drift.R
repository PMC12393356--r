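#' Rigid-body drift correction of a movie
#'
#' Estimates, per frame, the rigid transform (rotation about the image
#' centre plus translation) that maps the frame onto the reference frame,
#' using a drift-template derived from the nucleus: the template channel is
#' Gaussian-blurred, Huang auto-thresholded, the nuclear bounds dilated,
#' and outlier pixels moderated toward the region medians so focal signal
#' inside the nucleus cannot bias the registration. Registration is
#' phase correlation for translation combined with a 1D angular search.
#' Transforms are applied to all channels (resampled movie) and are meant
#' to be applied to spot coordinates via [apply_drift_to_spots()] for
#' kinetics, avoiding interpolation blur.
#'
#' @param movie A `bt_movie`.
#' @param template_channel Channel name used for registration.
#' @param angle_range,angle_step Angular search half-range and step (deg).
#' @param blur_sigma Template blur sigma (px).
#' @param reference_frame Frame (1-based) everything is registered to.
#' @return List with `movie` (corrected `bt_movie`) and `transforms`
#'   (tibble `frame`, `dx_px`, `dy_px`, `dtheta_deg` of the *estimated
#'   drift* of each frame relative to the reference).
#' @export
correct_drift <- function(movie, template_channel = "dna",
                          angle_range = 2, angle_step = 0.05,
                          blur_sigma = 4, reference_frame = 1L) {
  stopifnot(inherits(movie, "bt_movie"))
  ch <- movie$channels[[template_channel]]
  if (is.null(ch)) abort(paste0("no channel `", template_channel, "`."))
  nf <- dim(ch)[3]
  tmpl <- lapply(seq_len(nf), function(f) drift_template(ch[, , f], blur_sigma))
  ref <- tmpl[[reference_frame]]
  Fref <- stats::fft(ref - mean(ref))

  angles <- if (angle_range > 0) seq(-angle_range, angle_range, by = angle_step) else 0
  est <- purrr::map_dfr(seq_len(nf), function(f) {
    if (f == reference_frame) {
      return(tibble(frame = f - 1L, dx_px = 0, dy_px = 0, dtheta_deg = 0))
    }
    best <- list(score = -Inf)
    for (th in angles) {
      derot <- rigid_warp(tmpl[[f]], 0, 0, -th)
      pc <- phase_correlate(Fref, derot)
      if (pc$score > best$score) best <- c(pc, theta = th)
    }
    if (best$score < 0.01) {
      abort(paste0("registration failed at frame ", f,
                   " (no correlation peak)."))
    }
    # derotated frame = ref shifted by s = R(-theta) t  =>  t = R(theta) s
    thr <- best$theta * pi / 180
    dx <- cos(thr) * best$sx - sin(thr) * best$sy
    dy <- sin(thr) * best$sx + cos(thr) * best$sy
    tibble(frame = f - 1L, dx_px = dx, dy_px = dy, dtheta_deg = best$theta)
  })

  corrected <- movie
  for (nm in names(movie$channels)) {
    for (f in seq_len(nf)) {
      tr <- est[f, ]
      if (tr$dx_px == 0 && tr$dy_px == 0 && tr$dtheta_deg == 0) next
      # undo content = translate(t) . rotate(theta): apply the inverse rigid
      th <- -tr$dtheta_deg * pi / 180
      idx <- -(cos(th) * tr$dx_px - sin(th) * tr$dy_px)
      idy <- -(sin(th) * tr$dx_px + cos(th) * tr$dy_px)
      corrected$channels[[nm]][, , f] <-
        rigid_warp(movie$channels[[nm]][, , f], idx, idy, -tr$dtheta_deg)
    }
  }
  list(movie = corrected, transforms = est)
}

# nucleus-contrast drift template: blur, Huang threshold, dilate, moderate
# outliers toward region medians
drift_template <- function(frame, blur_sigma) {
  g <- gblur_safe(frame, blur_sigma)
  thr <- tryCatch(auto_threshold(g, "huang"), error = function(e) mean(g))
  mask <- g > thr
  if (any(mask) && !all(mask)) {
    mask <- matrix(as.integer(EBImage::imageData(EBImage::dilate(
      EBImage::Image(mask * 1), EBImage::makeBrush(7, "disc")))) > 0,
      nrow(frame), ncol(frame))
    med_in <- median(frame[mask]); med_out <- median(frame[!mask])
    hi <- stats::quantile(frame[mask], 0.975)
    out <- frame
    out[mask & frame > hi] <- med_in
    out[!mask] <- med_out
    gblur_safe(out, blur_sigma)
  } else {
    g
  }
}

# translation by normalised phase correlation with parabolic sub-pixel peak
# interpolation; returns the shift of `img` relative to the reference whose
# FFT is `Fref` (positive = content moved toward larger x/y)
phase_correlate <- function(Fref, img) {
  nr <- nrow(img); nc <- ncol(img)
  Fimg <- stats::fft(img - mean(img))
  cross <- Fref * Conj(Fimg)
  denom <- Mod(cross); denom[denom < 1e-12] <- 1e-12
  r <- Re(stats::fft(cross / denom, inverse = TRUE)) / (nr * nc)
  pk <- which.max(r)
  pr <- (pk - 1) %% nr; pc <- (pk - 1) %/% nr
  subpix <- function(vm1, v0, vp1) {
    den <- vm1 - 2 * v0 + vp1
    if (abs(den) < 1e-12) 0 else 0.5 * (vm1 - vp1) / den
  }
  rp <- r[(pr + c(-1, 0, 1)) %% nr + 1, pc + 1]
  cp <- r[pr + 1, (pc + c(-1, 0, 1)) %% nc + 1]
  dr <- pr + subpix(rp[1], rp[2], rp[3])
  dc <- pc + subpix(cp[1], cp[2], cp[3])
  if (dr > nr / 2) dr <- dr - nr
  if (dc > nc / 2) dc <- dc - nc
  # peak at (dr, dc) means ref(x) ~ img(x - shift): img shifted by -(dr,dc)
  list(sx = -dc, sy = -dr, score = max(r))
}

#' Map spot coordinates back to the drift-free reference frame
#'
#' Applies the inverse of the estimated per-frame rigid drift to spot
#' positions (in um), the preferred route for kinetics since it involves no
#' pixel interpolation.
#'
#' @param spots Tibble with `frame`, `x_um`, `y_um`.
#' @param transforms Transform tibble from [correct_drift()].
#' @param cfg The movie's [sim_config()] (for pixel size and image centre).
#' @return `spots` with corrected `x_um`, `y_um`.
#' @export
apply_drift_to_spots <- function(spots, transforms, cfg) {
  px <- cfg$pixel_size_um
  cx <- (cfg$image_shape[2] - 1) / 2
  cy <- (cfg$image_shape[1] - 1) / 2
  spots %>%
    left_join(transforms, by = "frame") %>%
    mutate(
      dx_px = tidyr::replace_na(.data$dx_px, 0),
      dy_px = tidyr::replace_na(.data$dy_px, 0),
      dtheta_deg = tidyr::replace_na(.data$dtheta_deg, 0),
      th = -.data$dtheta_deg * pi / 180,
      xr = .data$x_um / px - cx - .data$dx_px,
      yr = .data$y_um / px - cy - .data$dy_px,
      x_um = (cos(.data$th) * .data$xr - sin(.data$th) * .data$yr + cx) * px,
      y_um = (sin(.data$th) * .data$xr + cos(.data$th) * .data$yr + cy) * px
    ) %>%
    select(-"dx_px", -"dy_px", -"dtheta_deg", -"th", -"xr", -"yr")
}
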