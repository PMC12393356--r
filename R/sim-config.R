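#' Simulation configuration
#'
#' Bundles the acquisition constants shared by every simulator: spatial and
#' temporal calibration, movie geometry, and the imaging-noise model. The
#' defaults mirror a fast single-molecule acquisition (5 ms frame interval,
#' i.e. 200 fps HILO imaging); locus-tracking movies are typically acquired
#' at 15 or 30 s intervals and pass `frame_interval_s` accordingly.
#'
#' @param pixel_size_um Pixel size in micrometres per pixel; must be > 0.
#' @param frame_interval_s Time between consecutive frames in seconds; > 0.
#' @param n_frames Number of frames in the simulated movie (>= 2).
#' @param image_shape Integer vector `c(rows, cols)` of the frame in pixels.
#' @param localization_noise_um Standard deviation of the Gaussian
#'   localization error added independently per frame and axis, in um.
#'   Models camera/fitting error, not motion, so it is applied after any
#'   confinement reflection.
#' @param psf_sigma_px Gaussian sigma, in pixels, used to render point
#'   emitters into images.
#' @param background_level Mean background intensity inside nuclei
#'   (arbitrary camera units).
#' @param snr Peak spot amplitude divided by the background noise standard
#'   deviation; controls rendering noise.
#'
#' @return An object of class `bt_sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(n_frames = 10)
#' cfg$frame_interval_s
sim_config <- function(pixel_size_um = 0.1,
                       frame_interval_s = 0.005,
                       n_frames = 100L,
                       image_shape = c(128L, 128L),
                       localization_noise_um = 0.02,
                       psf_sigma_px = 1.5,
                       background_level = 100,
                       snr = 10) {
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be a positive number.")
  }
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0) {
    abort("`frame_interval_s` must be a positive number.")
  }
  if (!is.numeric(n_frames) || n_frames < 2) {
    abort("`n_frames` must be at least 2.")
  }
  if (length(image_shape) != 2L || any(image_shape < 8)) {
    abort("`image_shape` must be c(rows, cols) with both >= 8.")
  }
  structure(
    list(
      pixel_size_um = pixel_size_um,
      frame_interval_s = frame_interval_s,
      n_frames = as.integer(n_frames),
      image_shape = as.integer(image_shape),
      localization_noise_um = localization_noise_um,
      psf_sigma_px = psf_sigma_px,
      background_level = background_level,
      snr = snr
    ),
    class = "bt_sim_config"
  )
}

#' Walker specification for track simulation
#'
#' Describes one simulated particle: its motion model and the generative
#' parameters the downstream biophysics module tries to recover.
#'
#' @param model One of `"brownian"`, `"confined"` (Brownian steps reflected
#'   at a disc of radius `Rc_um` about the start point), or `"fbm"`
#'   (fractional Brownian motion with stationary increments and
#'   `E[MSD(dT)] = 4 D dT^alpha`).
#' @param D_um2_s Diffusion coefficient in um^2/s (>= 0).
#' @param alpha Anomalous exponent, used by `"fbm"` only; must lie in (0, 2].
#' @param Rc_um Confinement radius in um, used by `"confined"` only (> 0).
#' @param start_xy_um Numeric length-2 start position in um.
#' @param lifetime_frames Number of frames the walker is observed
#'   (photobleaching-limited duration, deterministic).
#'
#' @return A `bt_walker_spec` list.
#' @export
walker_spec <- function(model = c("brownian", "confined", "fbm"),
                        D_um2_s = 0.1,
                        alpha = 1,
                        Rc_um = NA_real_,
                        start_xy_um = c(0, 0),
                        lifetime_frames = 50L) {
  model <- match.arg(model)
  if (D_um2_s < 0) abort("`D_um2_s` must be >= 0.")
  if (model == "fbm" && (alpha <= 0 || alpha > 2)) {
    abort("`alpha` must lie in (0, 2] for fbm walkers.")
  }
  if (model == "confined" && (!is.finite(Rc_um) || Rc_um <= 0)) {
    abort("`Rc_um` must be > 0 for confined walkers.")
  }
  if (lifetime_frames < 1) abort("`lifetime_frames` must be positive.")
  structure(
    list(model = model, D_um2_s = D_um2_s, alpha = alpha, Rc_um = Rc_um,
         start_xy_um = as.numeric(start_xy_um),
         lifetime_frames = as.integer(lifetime_frames)),
    class = "bt_walker_spec"
  )
}
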