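#' Mean squared displacement of one track
#'
#' For each integer lag `k`, averages `|r(i+k) - r(i)|^2` over every
#' ordered pair of spots whose frame difference is exactly `k`; pairs
#' spanning missing frames are simply absent, so gaps contribute to longer
#' lags but never fabricate displacements. Lags with fewer than
#' `min_pairs` calculable displacements (default 3) are dropped.
#'
#' @param track Tibble with `frame`, `x_um`, `y_um` for a single track.
#' @param frame_interval_s Frame interval (s).
#' @param min_pairs Minimum displacements averaged per retained lag.
#' @return Tibble (`bt_msd`): `lag_frames`, `dT_s`, `msd_um2`, `n_pairs`.
#' @export
compute_msd <- function(track, frame_interval_s, min_pairs = 3L) {
  n <- nrow(track)
  empty <- tibble(lag_frames = integer(), dT_s = numeric(),
                  msd_um2 = numeric(), n_pairs = integer())
  if (n < 2) return(empty)
  fr <- track$frame
  maxf <- max(fr) - min(fr)
  x <- rep(NA_real_, maxf + 1L); y <- rep(NA_real_, maxf + 1L)
  x[fr - min(fr) + 1L] <- track$x_um
  y[fr - min(fr) + 1L] <- track$y_um
  msd <- numeric(maxf); np <- integer(maxf)
  for (k in seq_len(maxf)) {
    i <- seq_len(maxf + 1L - k)
    d2 <- (x[i + k] - x[i])^2 + (y[i + k] - y[i])^2
    d2 <- d2[!is.na(d2)]
    np[k] <- length(d2)
    msd[k] <- if (np[k]) mean(d2) else NA_real_
  }
  keep <- np >= min_pairs
  tibble(lag_frames = which(keep),
         dT_s = which(keep) * frame_interval_s,
         msd_um2 = msd[keep], n_pairs = np[keep])
}

#' Anomalous exponent and diffusion coefficient from an MSD curve
#'
#' Ordinary least squares of `log(MSD)` on `log(dT)` over all retained
#' lags with positive MSD: the slope is the anomalous exponent alpha and
#' the diffusion coefficient follows the 2D convention
#' `MSD = 4 D dT^alpha`, i.e. `D = exp(intercept) / 4`.
#'
#' @param curve MSD tibble from [compute_msd()].
#' @return Tibble with `alpha`, `D_um2_s`, `n_lags_used`; `NA`s when fewer
#'   than two usable lags remain.
#' @export
fit_alpha_diffusion <- function(curve) {
  use <- curve %>% filter(.data$msd_um2 > 0)
  if (nrow(use) < 2) {
    return(tibble(alpha = NA_real_, D_um2_s = NA_real_,
                  n_lags_used = nrow(use)))
  }
  fit <- lm(log(msd_um2) ~ log(dT_s), data = use)
  co <- coef(fit)
  tibble(alpha = unname(co[2]), D_um2_s = exp(unname(co[1])) / 4,
         n_lags_used = nrow(use))
}

#' Confined-diffusion fit of an MSD curve
#'
#' Nonlinear least squares of the confined model
#' `MSD(dT) = Rc^2 (1 - exp(-4 Dr dT / Rc^2))`, whose plateau is the
#' squared confinement radius. Fitting is performed in linear MSD space by
#' default, weighted by the number of displacements per lag; a log-space
#' variant is available. Initialisation: `Rc0 = sqrt(max MSD)`, `Dr0` from
#' the slope of the first two lags. Non-convergence yields `NA`s with a
#' flag rather than an error.
#'
#' @param curve MSD tibble from [compute_msd()].
#' @param fit_space `"linear"` (default) or `"log"`.
#' @param tol Convergence tolerance on parameters.
#' @return Tibble with `Rc_um`, `Dr_um2_s`, `converged`.
#' @export
fit_confined <- function(curve, fit_space = c("linear", "log"), tol = 1e-8) {
  fit_space <- match.arg(fit_space)
  use <- curve %>% filter(.data$msd_um2 > 0)
  if (nrow(use) < 4) {
    return(tibble(Rc_um = NA_real_, Dr_um2_s = NA_real_, converged = FALSE))
  }
  rc0 <- sqrt(max(use$msd_um2))
  dr0 <- max((use$msd_um2[2] - use$msd_um2[1]) /
               (use$dT_s[2] - use$dT_s[1]) / 4, 1e-6)
  w <- if ("n_pairs" %in% names(use)) use$n_pairs else rep(1, nrow(use))
  fit <- tryCatch(
    if (fit_space == "linear") {
      minpack.lm::nlsLM(
        msd_um2 ~ rc^2 * (1 - exp(-4 * dr * dT_s / rc^2)),
        data = use, start = list(rc = rc0, dr = dr0), weights = w,
        lower = c(1e-6, 1e-9),
        control = minpack.lm::nls.lm.control(ftol = tol, ptol = tol,
                                             maxiter = 200)
      )
    } else {
      minpack.lm::nlsLM(
        log(msd_um2) ~ log(rc^2 * (1 - exp(-4 * dr * dT_s / rc^2))),
        data = use, start = list(rc = rc0, dr = dr0),
        lower = c(1e-6, 1e-9),
        control = minpack.lm::nls.lm.control(ftol = tol, ptol = tol,
                                             maxiter = 200)
      )
    },
    error = function(e) NULL
  )
  if (is.null(fit) || any(!is.finite(coef(fit)))) {
    return(tibble(Rc_um = NA_real_, Dr_um2_s = NA_real_, converged = FALSE))
  }
  co <- coef(fit)
  tibble(Rc_um = unname(co["rc"]), Dr_um2_s = unname(co["dr"]),
         converged = TRUE)
}

#' Residence durations near the track origin
#'
#' Time each track remains within 0.25 um and 0.5 um of its starting
#' point: `(frame offset of the first spot beyond the radius) * dt`, or
#' the full observed duration if the radius is never exceeded.
#'
#' @param track Tibble with `frame`, `x_um`, `y_um`.
#' @param frame_interval_s Frame interval (s).
#' @param radii_um Radii in um (default `c(0.25, 0.5)`).
#' @return Tibble `radius_um`, `residence_s`.
#' @export
residence_durations <- function(track, frame_interval_s,
                                radii_um = c(0.25, 0.5)) {
  r <- sqrt((track$x_um - track$x_um[1])^2 +
              (track$y_um - track$y_um[1])^2)
  full <- (max(track$frame) - min(track$frame) + 1L) * frame_interval_s
  purrr::map_dfr(radii_um, function(rad) {
    beyond <- which(r > rad)
    dur <- if (length(beyond) == 0) full else
      (track$frame[beyond[1]] - track$frame[1]) * frame_interval_s
    tibble(radius_um = rad, residence_s = dur)
  })
}

#' Single-frame displacements of a track
#'
#' `|r(i+1) - r(i)|` for strictly consecutive frames; pairs spanning a gap
#' are excluded.
#'
#' @param track Tibble with `frame`, `x_um`, `y_um`.
#' @return Tibble `frame` (of the first spot of the pair), `disp_um`.
#' @export
single_frame_displacements <- function(track) {
  if (nrow(track) < 2) return(tibble(frame = integer(), disp_um = numeric()))
  track <- arrange(track, .data$frame)
  ok <- diff(track$frame) == 1L
  d <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  tibble(frame = track$frame[-nrow(track)][ok], disp_um = d[ok])
}

#' Per-track biophysical feature table
#'
#' Computes, for every track in a linked table, the six clustering
#' features: diffusion coefficient, anomalous exponent, confinement
#' radius, radial diffusion coefficient, MSD at one frame interval, and
#' residence duration within 0.25 um of the start (the 0.5 um residence
#' travels along as QC). Tracks whose confined fit fails or with fewer
#' than two usable MSD lags carry `NA`s and are flagged incomplete;
#' clustering operates on complete cases.
#'
#' @param tracks Linked spot tibble (`track_id`, `frame`, `x_um`, `y_um`,
#'   optionally `condition`).
#' @param frame_interval_s Frame interval (s).
#' @param min_frame Spots before this frame are dropped first
#'   (photobleaching settle-in; 1000 for single-molecule movies).
#' @param min_pairs Per-lag displacement minimum for the MSD.
#' @return Tibble (`bt_track_features`): one row per track with columns
#'   `track_id`, `condition`, `n_spots`, `D_um2_s`, `alpha`, `Rc_um`,
#'   `Dr_um2_s`, `msd_dt1_um2`, `res_025_s`, `res_050_s`, `complete`.
#' @export
track_features <- function(tracks, frame_interval_s, min_frame = 0L,
                           min_pairs = 3L) {
  tracks <- tracks %>% filter(.data$frame >= min_frame)
  has_cond <- "condition" %in% names(tracks)
  out <- tracks %>%
    group_by(.data$track_id) %>%
    dplyr::group_modify(function(tr, key) {
      curve <- compute_msd(tr, frame_interval_s, min_pairs)
      ad <- fit_alpha_diffusion(curve)
      cf <- fit_confined(curve)
      res <- residence_durations(tr, frame_interval_s)
      msd1 <- curve$msd_um2[curve$lag_frames == 1L]
      tibble(
        condition = if (has_cond) tr$condition[1] else NA_character_,
        n_spots = nrow(tr),
        D_um2_s = ad$D_um2_s, alpha = ad$alpha,
        Rc_um = cf$Rc_um, Dr_um2_s = cf$Dr_um2_s,
        msd_dt1_um2 = if (length(msd1)) msd1 else NA_real_,
        res_025_s = res$residence_s[1], res_050_s = res$residence_s[2]
      )
    }) %>%
    ungroup() %>%
    mutate(complete = complete.cases(
      select(., "D_um2_s", "alpha", "Rc_um", "Dr_um2_s",
             "msd_dt1_um2", "res_025_s")))
  class(out) <- c("bt_track_features", class(out))
  out
}

bt_feature_cols <- c("D_um2_s", "alpha", "Rc_um", "Dr_um2_s",
                     "msd_dt1_um2", "res_025_s")
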