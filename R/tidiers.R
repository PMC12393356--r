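#' Tidy a fitted state model
#'
#' One row per mixture component / cluster with its weight and mean
#' feature values (on the clustering scale, i.e. log for the skewed
#' features when log-transformed).
#'
#' @param x A `bt_state_model`.
#' @param ... Unused.
#' @return A tibble, one row per cluster.
#' @exportS3Method generics::tidy
tidy.bt_state_model <- function(x, ...) {
  if (x$kind == "gmm") {
    m <- t(x$means)
    colnames(m) <- x$feature_names
    dplyr::bind_cols(tibble(cluster = seq_len(x$k), weight = x$weights),
                     as_tibble(m))
  } else {
    tibble(cluster = seq_len(x$k),
           n_train = tabulate(x$train_labels, x$k))
  }
}

#' @rdname tidy.bt_state_model
#' @exportS3Method generics::glance
glance.bt_state_model <- function(x, ...) {
  tibble(kind = x$kind, k = x$k,
         loglik = if (x$kind == "gmm") tail(x$loglik_trace, 1) else NA_real_,
         em_iterations = if (x$kind == "gmm") length(x$loglik_trace)
                         else NA_integer_,
         seed = x$seed)
}

#' Tidy a mobility comparison report
#'
#' @param x A `bt_mobility_report`.
#' @param ... Unused.
#' @return The pairwise comparison tibble.
#' @exportS3Method generics::tidy
tidy.bt_mobility_report <- function(x, ...) x$comparisons

#' @rdname tidy.bt_mobility_report
#' @exportS3Method generics::glance
glance.bt_mobility_report <- function(x, ...) {
  tibble(metric = x$metric,
         n_states = dplyr::n_distinct(x$per_cell$state),
         n_cells = dplyr::n_distinct(x$per_cell$cell),
         min_p = min(x$comparisons$p_value, na.rm = TRUE))
}

#' Plot an MSD curve with its model fits
#'
#' @param curve Tibble from [compute_msd()].
#' @param fits Optional list with elements `alpha_d` (from
#'   [fit_alpha_diffusion()]) and/or `confined` (from [fit_confined()]).
#' @return A ggplot.
#' @export
plot_msd <- function(curve, fits = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(.data$dT_s, .data$msd_um2)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag time (s)", y = expression(MSD~(mu*m^2)))
  if (!is.null(fits$alpha_d) && is.finite(fits$alpha_d$alpha)) {
    ad <- fits$alpha_d
    p <- p + ggplot2::geom_line(
      data = tibble(dT_s = curve$dT_s,
                    msd_um2 = 4 * ad$D_um2_s * curve$dT_s^ad$alpha),
      colour = "steelblue")
  }
  if (!is.null(fits$confined) && isTRUE(fits$confined$converged)) {
    cf <- fits$confined
    p <- p + ggplot2::geom_line(
      data = tibble(dT_s = curve$dT_s,
                    msd_um2 = cf$Rc_um^2 *
                      (1 - exp(-4 * cf$Dr_um2_s * curve$dT_s / cf$Rc_um^2))),
      colour = "firebrick")
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.bt_cluster_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(factor(.data$cluster), .data$fold_change)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.3) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "cluster (decreasing mean D)",
                  y = "fold change of cluster fraction")
}

#' @exportS3Method ggplot2::autoplot
autoplot.bt_mobility_report <- function(object, ...) {
  ggplot2::ggplot(object$per_cell,
                  ggplot2::aes(.data$state, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL,
                  y = if (object$metric == "mean_disp_um")
                    expression(mean~single-frame~displacement~(mu*m))
                  else "segment alpha")
}

#' Plot a normalized displacement time course
#'
#' @param tc Tibble from [normalized_displacement_timecourse()].
#' @return A ggplot.
#' @export
plot_timecourse <- function(tc) {
  ggplot2::ggplot(tc, ggplot2::aes(.data$t_mid_s / 60, .data$norm_disp)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$flagged)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "time from stimulation (min)",
                  y = "normalized displacement")
}
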