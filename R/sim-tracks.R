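#' Simulate particle tracks with known ground truth
#'
#' Generates 2D trajectories for a list of walker specifications at the
#' configured frame interval. Brownian walkers take independent Gaussian
#' steps with per-axis variance `2 D dt`; confined walkers take the same
#' steps but are reflected at the circle of radius `Rc_um` about their start
#' point (so the noiseless path never leaves the disc); fractional Brownian
#' walkers have exactly stationary correlated increments such that
#' `E[MSD(dT)] = 4 D dT^alpha`. Gaussian localization noise of the
#' configured sigma is added independently per frame and axis *after* any
#' reflection, modelling camera error rather than motion.
#'
#' @param specs A list of [walker_spec()] objects (or a single one).
#' @param cfg A [sim_config()].
#' @param start_frame Integer frame index of the first spot of every track.
#' @return A tibble with columns `track_id`, `frame`, `x_um`, `y_um`,
#'   `model`, plus the noiseless coordinates `x_true_um`, `y_true_um`.
#' @export
#' @examples
#' cfg <- sim_config(n_frames = 20, localization_noise_um = 0)
#' tr <- simulate_tracks(list(walker_spec("brownian", D_um2_s = 0.05,
#'                                        lifetime_frames = 20)), cfg)
#' head(tr)
simulate_tracks <- function(specs, cfg, start_frame = 0L) {
  if (inherits(specs, "bt_walker_spec")) specs <- list(specs)
  if (length(specs) == 0) abort("`specs` must be non-empty.")
  stopifnot(inherits(cfg, "bt_sim_config"))
  dt <- cfg$frame_interval_s
  noise <- cfg$localization_noise_um
  purrr::imap_dfr(specs, function(sp, i) {
    n <- sp$lifetime_frames
    xy <- switch(sp$model,
      brownian = sim_brownian_path(n, sp$D_um2_s, dt),
      confined = sim_confined_path(n, sp$D_um2_s, dt, sp$Rc_um),
      fbm      = sim_fbm_path(n, sp$D_um2_s, dt, sp$alpha)
    )
    xy <- sweep(xy, 2, sp$start_xy_um, `+`)
    obs <- xy
    if (noise > 0) obs <- obs + matrix(rnorm(2L * n, sd = noise), ncol = 2)
    tibble(
      track_id = i,
      frame = start_frame + seq_len(n) - 1L,
      x_um = obs[, 1], y_um = obs[, 2],
      model = sp$model,
      x_true_um = xy[, 1], y_true_um = xy[, 2]
    )
  })
}

# Pure Brownian path starting at the origin; per-axis step sd sqrt(2 D dt).
sim_brownian_path <- function(n, D, dt) {
  if (n == 1L || D == 0) return(matrix(0, n, 2))
  steps <- matrix(rnorm(2L * (n - 1L), sd = sqrt(2 * D * dt)), ncol = 2)
  rbind(c(0, 0), apply(steps, 2, cumsum))
}

# Brownian steps reflected at the disc of radius Rc about the origin.
# Reflection is radial: a point at radius r > Rc maps to radius 2*Rc - r on
# the same ray, iterated in the rare case a step overshoots twice.
sim_confined_path <- function(n, D, dt, Rc) {
  xy <- matrix(0, n, 2)
  if (n == 1L || D == 0) return(xy)
  pos <- c(0, 0)
  sdv <- sqrt(2 * D * dt)
  for (i in 2:n) {
    cand <- pos + rnorm(2, sd = sdv)
    r <- sqrt(sum(cand^2))
    while (r > Rc) {
      cand <- cand * (2 * Rc - r) / r
      r <- abs(2 * Rc - r)
    }
    pos <- cand
    xy[i, ] <- pos
  }
  xy
}

# Exact fractional Gaussian noise via Cholesky factorisation of the unit-lag
# increment covariance rho(k) = (|k+1|^a - 2|k|^a + |k-1|^a) / 2. The factor
# is cached per (n, alpha) because every walker of one spec shares it.
.fgn_cache <- new.env(parent = emptyenv())

fgn_cholesky <- function(m, alpha) {
  key <- paste0(m, "_", format(alpha, digits = 12))
  got <- get0(key, envir = .fgn_cache)
  if (!is.null(got)) return(got)
  k <- 0:(m - 1)
  rho <- (abs(k + 1)^alpha - 2 * abs(k)^alpha + abs(k - 1)^alpha) / 2
  L <- chol(stats::toeplitz(rho))
  assign(key, L, envir = .fgn_cache)
  L
}

# fBm path with Var[X(t)] = 2 D t^alpha per axis (2D MSD = 4 D t^alpha).
sim_fbm_path <- function(n, D, dt, alpha) {
  if (n == 1L || D == 0) return(matrix(0, n, 2))
  m <- n - 1L
  L <- fgn_cholesky(m, alpha)
  z <- matrix(rnorm(2L * m), nrow = m)
  incr <- crossprod(L, z) * sqrt(2 * D * dt^alpha)
  rbind(c(0, 0), apply(incr, 2, cumsum))
}

#' Simulate a telegraph (two-state) burst schedule
#'
#' Draws alternating exponential off/on intervals with rates `k_on` (off ->
#' on switching) and `k_off` (on -> off), discretised to frames; the
#' generative counterpart of a gene cycling between transcriptional bursts
#' and silent periods.
#'
#' @param n_frames Number of frames in the movie.
#' @param frame_interval_s Frame interval in seconds.
#' @param k_on,k_off Switching rates in 1/s (off->on and on->off).
#' @param start_state `"off"` or `"on"` at frame 0.
#' @return A tibble of half-open on-intervals: `start_frame`, `end_frame`.
#' @export
simulate_telegraph <- function(n_frames, frame_interval_s, k_on, k_off,
                               start_state = "off") {
  t_total <- n_frames * frame_interval_s
  t <- 0
  state <- match.arg(start_state, c("off", "on"))
  on_start <- if (state == "on") 0 else NA_real_
  out <- list()
  while (t < t_total) {
    rate <- if (state == "off") k_on else k_off
    t <- t + stats::rexp(1, rate)
    if (state == "off") {
      if (t < t_total) on_start <- t
      state <- "on"
    } else {
      if (!is.na(on_start)) {
        s <- floor(on_start / frame_interval_s)
        e <- min(ceiling(min(t, t_total) / frame_interval_s), n_frames)
        if (e > s) out[[length(out) + 1L]] <- c(s, e)
      }
      on_start <- NA_real_
      state <- "off"
    }
  }
  if (state == "on" && !is.na(on_start) && on_start < t_total) {
    s <- floor(on_start / frame_interval_s)
    if (n_frames > s) out[[length(out) + 1L]] <- c(s, n_frames)
  }
  if (length(out) == 0) {
    return(tibble(start_frame = integer(), end_frame = integer()))
  }
  m <- do.call(rbind, out)
  # merge intervals that abut after frame discretisation
  res <- list(m[1, ])
  if (nrow(m) > 1) for (i in 2:nrow(m)) {
    lastv <- res[[length(res)]]
    if (m[i, 1] <= lastv[2]) {
      res[[length(res)]] <- c(lastv[1], max(lastv[2], m[i, 2]))
    } else res[[length(res) + 1L]] <- m[i, ]
  }
  m <- do.call(rbind, res)
  tibble(start_frame = as.integer(m[, 1]), end_frame = as.integer(m[, 2]))
}
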