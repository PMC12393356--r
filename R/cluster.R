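#' Build a balanced training set for state clustering
#'
#' Draws an equal number of complete-case tracks per condition under a
#' fixed seed, mirroring training-set construction balanced evenly across
#' hormone conditions (e.g. E2-, 1 h E2, 17 h E2).
#'
#' @param features A [track_features()] tibble with a `condition` column.
#' @param n_per_condition Tracks drawn per condition.
#' @param seed Integer seed making the draw reproducible.
#' @param conditions Conditions to include (default all present).
#' @return A `bt_training_set`: list with `features` (balanced tibble) and
#'   `balancing` (counts drawn per condition).
#' @export
build_training_set <- function(features, n_per_condition, seed = 1L,
                               conditions = NULL) {
  conditions <- conditions %||% unique(features$condition)
  cc <- features %>%
    filter(.data$complete, .data$condition %in% conditions)
  counts <- cc %>% count(.data$condition)
  missing <- setdiff(conditions, counts$condition)
  short <- counts$condition[counts$n < n_per_condition]
  bad <- c(missing, short)
  if (length(bad) > 0) {
    abort(paste0("insufficient complete-case tracks for condition(s): ",
                 paste(bad, collapse = ", ")))
  }
  set.seed(seed)
  picked <- cc %>%
    group_by(.data$condition) %>%
    slice(sample(n(), n_per_condition)) %>%
    ungroup()
  structure(
    list(features = picked,
         balancing = picked %>% count(.data$condition),
         seed = seed),
    class = "bt_training_set"
  )
}

# feature matrix on the clustering scale: heavily skewed magnitudes
# (D, Rc, MSD at lag 1) are log-transformed when `log_transform`
feature_matrix <- function(features, log_transform = TRUE) {
  X <- as.matrix(features[, bt_feature_cols])
  if (log_transform) {
    for (cl in c("D_um2_s", "Rc_um", "msd_dt1_um2")) {
      X[, cl] <- log(pmax(X[, cl], 1e-12))
    }
  }
  X
}

#' Fit a Gaussian-mixture state model
#'
#' Full-covariance Gaussian mixture over the six-feature space, fitted by
#' expectation-maximisation: initialisation draws several random subsets
#' as seeded k-means starts (at most `km_iter` iterations each, best
#' within-SS solution kept), followed by at most `em_iter` EM iterations. The log-likelihood trace is recorded (EM is
#' monotone). A component whose covariance turns singular is
#' ridge-regularised (1e-6 of its trace) with a warning. Components are
#' canonicalised by decreasing mean diffusion coefficient, so the last
#' cluster is always the slowest, most confined state.
#'
#' @param train A `bt_training_set` or feature tibble.
#' @param k Number of mixture components (default 6).
#' @param seed Seed for the k-means initialisation.
#' @param km_iter,em_iter Iteration caps for initialisation and EM.
#' @param log_transform Log-transform skewed features (see
#'   [feature_matrix()] behaviour); default `TRUE`.
#' @return A `bt_state_model` of kind `"gmm"`.
#' @export
fit_gmm <- function(train, k = 6L, seed = 1L, km_iter = 20L, em_iter = 20L,
                    log_transform = TRUE) {
  feats <- if (inherits(train, "bt_training_set")) train$features else train
  X <- feature_matrix(feats, log_transform)
  if (nrow(X) < 10 * k) abort("need at least 10*k training tracks.")
  set.seed(seed)
  # random-subset seeding: several candidate starts, keep the best k-means
  # solution (lowest within-cluster SS) before EM
  km <- NULL
  for (s in 1:10) {
    init_centers <- X[sample(nrow(X), k), , drop = FALSE]
    cand <- tryCatch(
      suppressWarnings(kmeans(X, centers = init_centers, iter.max = km_iter)),
      error = function(e) NULL)
    if (is.null(cand)) next
    if (is.null(km) || cand$tot.withinss < km$tot.withinss) km <- cand
  }
  if (is.null(km)) abort("k-means initialisation failed.")
  z <- matrix(0, nrow(X), k)
  z[cbind(seq_len(nrow(X)), km$cluster)] <- 1

  loglik <- numeric(0)
  params <- NULL
  for (it in seq_len(em_iter)) {
    ms <- mclust::mstepVVV(data = X, z = z)
    ms$parameters <- regularize_covariances(ms$parameters)
    es <- mclust::estepVVV(data = X, parameters = ms$parameters)
    if (!is.finite(es$loglik)) break
    loglik <- c(loglik, es$loglik)
    z <- es$z
    params <- ms$parameters
    if (it > 1 && abs(diff(tail(loglik, 2))) < 1e-10 * abs(es$loglik)) break
  }
  if (is.null(params)) abort("EM failed to produce finite parameters.")

  ord <- order(params$mean[match("D_um2_s", bt_feature_cols), ],
               decreasing = TRUE)
  model <- structure(
    list(kind = "gmm", k = k,
         means = params$mean[, ord, drop = FALSE],
         sigmas = lapply(ord, function(j) params$variance$sigma[, , j]),
         weights = params$pro[ord] / sum(params$pro),
         loglik_trace = loglik,
         log_transform = log_transform,
         feature_names = bt_feature_cols,
         seed = seed),
    class = "bt_state_model"
  )
  model
}

regularize_covariances <- function(parameters) {
  sig <- parameters$variance$sigma
  for (j in seq_len(dim(sig)[3])) {
    S <- sig[, , j]
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    if (!ok || !all(is.finite(S))) {
      warn("singular component covariance; ridge-regularised.")
      S[!is.finite(S)] <- 0
      sig[, , j] <- S + diag(1e-6 * max(sum(diag(S)), 1e-6) / nrow(S),
                             nrow(S))
    }
  }
  parameters$variance$sigma <- sig
  parameters
}

# per-component Gaussian log-densities, n x k
gmm_log_dens <- function(model, X) {
  ld <- vapply(seq_len(model$k), function(j) {
    mu <- model$means[, j]
    L <- chol(model$sigmas[[j]])
    d <- forwardsolve(t(L), t(X) - mu)
    -0.5 * colSums(d^2) - sum(log(diag(L))) -
      0.5 * ncol(X) * log(2 * pi) + log(model$weights[j])
  }, numeric(nrow(X)))
  matrix(ld, nrow = nrow(X), ncol = model$k)
}

#' Fit a Ward + kernel-SVM state model
#'
#' Agglomerative (Ward) clustering of z-scored features cut at `k`
#' clusters, followed by a multi-class Laplacian-kernel support-vector
#' classifier (spoc-svc, C = 8) trained on the cluster labels so
#' subsequent experiments can be classified consistently. Clusters are
#' canonicalised by decreasing mean diffusion coefficient.
#'
#' @param train A `bt_training_set` or feature tibble.
#' @param k Number of clusters (default 6).
#' @param C Soft-margin cost of the SVM (default 8).
#' @param seed Seed (kernel-width estimation subsamples the data).
#' @param svm_subsample Optional number of rows used to train the SVM
#'   (default all).
#' @param log_transform As in [fit_gmm()].
#' @return A `bt_state_model` of kind `"ward_svm"`.
#' @export
fit_ward_svm <- function(train, k = 6L, C = 8, seed = 1L,
                         svm_subsample = NULL, log_transform = TRUE) {
  feats <- if (inherits(train, "bt_training_set")) train$features else train
  X <- feature_matrix(feats, log_transform)
  if (nrow(X) < 10 * k) abort("need at least 10*k training tracks.")
  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  ag <- cluster::agnes(Xs, method = "ward")
  lab <- cutree(stats::as.hclust(ag), k = k)
  sizes <- tabulate(lab, k)
  if (any(sizes < 2)) abort("degenerate Ward cluster with < 2 members.")
  # canonical order by decreasing mean D (first feature column)
  mean_d <- tapply(X[, 1], lab, mean)
  ord <- order(mean_d, decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  lab <- relabel[lab]
  set.seed(seed)
  idx <- if (is.null(svm_subsample)) seq_len(nrow(Xs)) else
    sample(nrow(Xs), min(svm_subsample, nrow(Xs)))
  svm <- kernlab::ksvm(Xs[idx, , drop = FALSE], factor(lab[idx],
                                                       levels = seq_len(k)),
                       type = "spoc-svc", kernel = "laplacedot",
                       kpar = "automatic", C = C, scaled = FALSE)
  structure(
    list(kind = "ward_svm", k = k, svm = svm,
         center = ctr, scale = scl,
         train_labels = lab,
         log_transform = log_transform,
         feature_names = bt_feature_cols,
         seed = seed),
    class = "bt_state_model"
  )
}

#' Classify tracks with a fitted state model
#'
#' Deterministic assignment of feature rows to mobility states:
#' maximum-posterior component for a GMM, support-vector prediction for a
#' Ward+SVM model. Incomplete rows are returned unclassified (`NA`).
#'
#' @param model A `bt_state_model`.
#' @param features A [track_features()] tibble (or `bt_training_set`).
#' @return The feature tibble with a `cluster` column (integer, 1..k).
#' @export
classify_tracks <- function(model, features) {
  feats <- if (inherits(features, "bt_training_set")) features$features
           else features
  if (!"complete" %in% names(feats)) {
    feats$complete <- complete.cases(feats[, model$feature_names])
  }
  out <- feats
  out$cluster <- NA_integer_
  if (!any(feats$complete)) return(out)
  X <- feature_matrix(feats[feats$complete, ], model$log_transform)
  cl <- if (model$kind == "gmm") {
    max.col(gmm_log_dens(model, X), ties.method = "first")
  } else {
    Xs <- scale(X, center = model$center, scale = model$scale)
    pred <- methods::getMethod("predict", "ksvm")(model$svm, Xs)
    as.integer(as.character(pred))
  }
  out$cluster[out$complete] <- cl
  out
}

#' Per-cluster condition fractions and fold changes
#'
#' Computes the fraction of classified tracks in each cluster per
#' condition, the fold change `fraction_b / fraction_a` per cluster with a
#' percentile bootstrap CI over tracks, and — when per-cell labels are
#' available — a two-tailed two-sample t-test on per-cell cluster
#' fractions. A cluster empty in the denominator condition reports a
#' missing fold change, never an infinite one.
#'
#' @param assignments Tibble from [classify_tracks()] with `condition` and
#'   `cluster` (optionally a `cell` column).
#' @param cond_a,cond_b Denominator and numerator conditions.
#' @param k Number of clusters (default max observed).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Bootstrap seed.
#' @return A `bt_cluster_summary` tibble: `cluster`, `frac_a`, `frac_b`,
#'   `fold_change`, `ci_lo`, `ci_hi`, and `p_value` when per-cell data
#'   allow it.
#' @export
cluster_fold_changes <- function(assignments, cond_a, cond_b, k = NULL,
                                 n_boot = 1000L, seed = 1L) {
  asg <- assignments %>% filter(!is.na(.data$cluster))
  if (!all(c(cond_a, cond_b) %in% asg$condition)) {
    abort("both conditions must have classified tracks.")
  }
  k <- k %||% max(asg$cluster)
  frac_of <- function(cl) tabulate(cl, k) / length(cl)
  cl_a <- asg$cluster[asg$condition == cond_a]
  cl_b <- asg$cluster[asg$condition == cond_b]
  fa <- frac_of(cl_a); fb <- frac_of(cl_b)
  fold <- ifelse(fa > 0, fb / fa, NA_real_)

  set.seed(seed)
  boots <- replicate(n_boot, {
    ba <- frac_of(sample(cl_a, replace = TRUE))
    bb <- frac_of(sample(cl_b, replace = TRUE))
    ifelse(ba > 0, bb / ba, NA_real_)
  })
  ci <- apply(boots, 1, quantile, probs = c(0.025, 0.975), na.rm = TRUE)

  out <- tibble(cluster = seq_len(k), frac_a = fa, frac_b = fb,
                fold_change = fold, ci_lo = ci[1, ], ci_hi = ci[2, ])

  if ("cell" %in% names(asg)) {
    per_cell <- asg %>%
      filter(.data$condition %in% c(cond_a, cond_b)) %>%
      group_by(.data$condition, .data$cell) %>%
      summarise(frac = list(frac_of(.data$cluster)), .groups = "drop")
    out$p_value <- vapply(seq_len(k), function(cl) {
      a <- vapply(per_cell$frac[per_cell$condition == cond_a],
                  `[`, numeric(1), cl)
      b <- vapply(per_cell$frac[per_cell$condition == cond_b],
                  `[`, numeric(1), cl)
      if (length(a) < 2 || length(b) < 2) return(NA_real_)
      tryCatch(t.test(a, b)$p.value, error = function(e) NA_real_)
    }, numeric(1))
  }
  class(out) <- c("bt_cluster_summary", class(out))
  out
}

#' Cluster-count selection report
#'
#' For a range of k, reports the average silhouette width of the Ward
#' solution and the between-condition divergence (maximum absolute
#' difference in cluster fractions between two named conditions) — the
#' criterion used to motivate six clusters. k is never auto-chosen.
#'
#' @param train A `bt_training_set`.
#' @param k_range Candidate cluster counts.
#' @param cond_a,cond_b Conditions whose fraction divergence is reported.
#' @param log_transform As in [fit_gmm()].
#' @return Tibble: `k`, `avg_silhouette`, `max_fraction_divergence`.
#' @export
cluster_selection_report <- function(train, k_range = 2:8,
                                     cond_a, cond_b,
                                     log_transform = TRUE) {
  feats <- train$features
  X <- feature_matrix(feats, log_transform)
  Xs <- scale(X)
  ag <- cluster::agnes(Xs, method = "ward")
  hc <- stats::as.hclust(ag)
  d <- dist(Xs)
  purrr::map_dfr(k_range, function(kk) {
    lab <- cutree(hc, k = kk)
    sil <- mean(cluster::silhouette(lab, d)[, 3])
    fa <- tabulate(lab[feats$condition == cond_a], kk) /
      sum(feats$condition == cond_a)
    fb <- tabulate(lab[feats$condition == cond_b], kk) /
      sum(feats$condition == cond_b)
    tibble(k = kk, avg_silhouette = sil,
           max_fraction_divergence = max(abs(fa - fb)))
  })
}
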