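#' Signed distance of spots to an organelle boundary
#'
#' For each spot, evaluates the external minus the internal distance
#' transform at the pixel nearest its (sub-pixel) centroid: positive
#' values lie outside the organelle, negative values inside, and the
#' magnitude is the Euclidean distance to the boundary in um.
#'
#' @param spots Tibble with `x_px`, `y_px` (0-based pixel coordinates) or
#'   `x_um`, `y_um` (converted via the mask's pixel size).
#' @param om A `bt_organelle_mask` from [build_organelle_distance_maps()].
#' @return `spots` with a `signed_dist_um` column.
#' @export
signed_distance <- function(spots, om) {
  stopifnot(inherits(om, "bt_organelle_mask"))
  nr <- nrow(om$mask); nc <- ncol(om$mask)
  if (!all(c("x_px", "y_px") %in% names(spots))) {
    spots$x_px <- spots$x_um / om$pixel_size_um
    spots$y_px <- spots$y_um / om$pixel_size_um
  }
  cc <- round(spots$x_px); rr <- round(spots$y_px)
  if (any(cc < 0 | cc >= nc | rr < 0 | rr >= nr)) {
    abort("spot outside the image.")
  }
  idx <- cbind(rr + 1L, cc + 1L)
  spots$signed_dist_um <- om$external_um[idx] - om$internal_um[idx]
  spots
}

#' Compare signed-distance distributions between conditions
#'
#' Per-condition medians/means of the signed distance plus all pairwise
#' two-tailed t-tests, the convention used for condition-level proximity
#' comparisons; dot counts are reported alongside.
#'
#' @param records Tibble with `signed_dist_um` and `condition`.
#' @return List with `summary` (per condition: `n`, `median_um`,
#'   `mean_um`) and `tests` (pairwise `p_value` with significance stars).
#' @export
proximity_by_condition <- function(records) {
  conds <- unique(records$condition)
  if (length(conds) < 2) abort("need >= 2 conditions.")
  if (any(table(records$condition) == 0)) abort("empty condition.")
  summary <- records %>%
    group_by(.data$condition) %>%
    summarise(n = n(), median_um = median(.data$signed_dist_um),
              mean_um = mean(.data$signed_dist_um), .groups = "drop")
  tests <- purrr::map_dfr(utils::combn(conds, 2, simplify = FALSE),
    function(pr) {
      a <- records$signed_dist_um[records$condition == pr[1]]
      b <- records$signed_dist_um[records$condition == pr[2]]
      ht <- t.test(a, b)
      tibble(cond_a = pr[1], cond_b = pr[2],
             mean_diff_um = mean(a) - mean(b),
             p_value = ht$p.value, signif = p_stars(ht$p.value))
    })
  list(summary = summary, tests = tests)
}

#' Correlation between organelle proximity and bursting / mobility
#'
#' Per cell, computes (a) Pearson and Spearman correlations of
#' single-frame displacement against signed organelle distance and (b)
#' the point-biserial correlation of the burst indicator against signed
#' distance. Because both series are autocorrelated in time, the null is
#' calibrated by circular permutation of the distance series within each
#' cell (which preserves each series' autocorrelation), yielding a
#' permutation p-value per cell and pooled (per-cell weighted) overall
#' estimates. Constant series are flagged undefined.
#'
#' @param frames Tibble with one row per tracked frame: `cell`, `frame`,
#'   `signed_dist_um`, and `disp_um` and/or `burst` (logical).
#' @param n_perm Circular permutations per cell (default 200).
#' @param seed Permutation seed.
#' @return List with `per_cell` (correlations and permutation p-values)
#'   and `pooled` (weighted mean correlations).
#' @export
proximity_burst_correlation <- function(frames, n_perm = 200L, seed = 1L) {
  set.seed(seed)
  per_cell <- frames %>%
    group_by(.data$cell) %>%
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$frame)
      d <- df$signed_dist_um
      out <- tibble(n_frames = nrow(df))
      if (sd(d) == 0) {
        out$flag <- "constant distance"
        return(out)
      }
      out$flag <- NA_character_
      if ("disp_um" %in% names(df)) {
        ok <- !is.na(df$disp_um)
        if (sum(ok) > 3 && sd(df$disp_um[ok]) > 0) {
          out$r_disp_pearson <- cor(df$disp_um[ok], d[ok])
          out$r_disp_spearman <- cor(df$disp_um[ok], d[ok],
                                     method = "spearman")
          out$p_disp_perm <- circular_perm_p(df$disp_um[ok], d[ok], n_perm)
        }
      }
      if ("burst" %in% names(df)) {
        b <- as.numeric(df$burst)
        if (sd(b) > 0) {
          out$r_burst_pb <- cor(b, d)
          out$p_burst_perm <- circular_perm_p(b, d, n_perm)
        } else {
          out$flag <- "constant burst state"
        }
      }
      out
    }) %>%
    ungroup()
  num <- per_cell %>% filter(is.na(.data$flag))
  pooled <- tibble(
    n_cells = nrow(num),
    r_disp_pearson = pooled_mean(num, "r_disp_pearson"),
    r_burst_pb = pooled_mean(num, "r_burst_pb")
  )
  list(per_cell = per_cell, pooled = pooled)
}

pooled_mean <- function(df, col) {
  if (!col %in% names(df)) return(NA_real_)
  v <- df[[col]]; w <- df$n_frames
  ok <- !is.na(v)
  if (!any(ok)) return(NA_real_)
  sum(v[ok] * w[ok]) / sum(w[ok])
}

# two-sided permutation p-value for cor(x, y) under circular shifts of y;
# uses every non-zero shift when there are at most n_perm of them
circular_perm_p <- function(x, y, n_perm) {
  n <- length(y)
  obs <- abs(cor(x, y))
  shifts <- if (n - 1L <= n_perm) seq_len(n - 1L) else
    sample(n - 1L, n_perm)
  null <- vapply(shifts, function(s) {
    abs(cor(x, y[(seq_len(n) + s - 1L) %% n + 1L]))
  }, numeric(1))
  (1 + sum(null >= obs)) / (1 + length(null))
}

#' Shell enrichment at the organelle periphery
#'
#' Fraction of records whose signed distance falls inside a thin shell
#' just outside the organelle boundary (default 0 to 0.3 um), the
#' "periphery association" readout, per condition.
#'
#' @param records Tibble with `signed_dist_um` and `condition`.
#' @param shell_um `c(lo, hi)` signed-distance bounds of the shell.
#' @return Tibble: `condition`, `n`, `frac_in_shell`.
#' @export
periphery_enrichment <- function(records, shell_um = c(0, 0.3)) {
  records %>%
    group_by(.data$condition) %>%
    summarise(n = n(),
              frac_in_shell = mean(.data$signed_dist_um >= shell_um[1] &
                                     .data$signed_dist_um <= shell_um[2]),
              .groups = "drop")
}
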