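# three well-separated synthetic feature populations with known labels;
# separation >= 5 sd in several coordinates
make_populations <- function(n_per, seed = 1) {
  set.seed(seed)
  pop <- function(n, D, alpha, Rc, Dr, msd1, res, label, cond) {
    tibble::tibble(
      track_id = seq_len(n),
      condition = cond,
      n_spots = 50L,
      D_um2_s = exp(rnorm(n, log(D), 0.1)),
      alpha = rnorm(n, alpha, 0.05),
      Rc_um = exp(rnorm(n, log(Rc), 0.1)),
      Dr_um2_s = exp(rnorm(n, log(Dr), 0.1)),
      msd_dt1_um2 = exp(rnorm(n, log(msd1), 0.1)),
      res_025_s = rnorm(n, res, 0.02),
      res_050_s = rnorm(n, res * 2, 0.02),
      complete = TRUE,
      truth = label
    )
  }
  dplyr::bind_rows(
    pop(n_per, 1.0, 1.0, 0.8, 0.5, 0.02, 0.1, 1L, "a"),
    pop(n_per, 0.05, 0.7, 0.25, 0.03, 0.002, 0.5, 2L, "b"),
    pop(n_per, 0.002, 0.4, 0.08, 0.001, 2e-4, 1.5, 3L, "c")
  ) %>%
    dplyr::mutate(track_id = dplyr::row_number())
}

# best label-matching accuracy between truth and predicted clusterings
match_accuracy <- function(truth, pred) {
  k <- max(truth)
  perms <- combinat_perms(k)
  best <- 0
  for (p in perms) best <- max(best, mean(p[pred] == truth))
  best
}
combinat_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(k - 1)) {
    for (i in 0:(k - 1)) {
      out[[length(out) + 1L]] <- append(p, k, after = i)
    }
  }
  out
}

test_that("balanced training sets are reproducible and correctly sized", {
  feats <- make_populations(300)
  ts <- build_training_set(feats, n_per_condition = 200, seed = 5)
  expect_equal(nrow(ts$features), 600)
  expect_true(all(ts$balancing$n == 200))
  ts2 <- build_training_set(feats, n_per_condition = 200, seed = 5)
  expect_identical(ts$features, ts2$features)
  ts3 <- build_training_set(feats, n_per_condition = 200, seed = 6)
  expect_false(identical(ts$features$track_id, ts3$features$track_id))
  expect_error(build_training_set(feats, n_per_condition = 400, seed = 1),
               "insufficient")
})

test_that("GMM recovers well-separated populations and EM is monotone", {
  feats <- make_populations(150, seed = 2)
  model <- fit_gmm(feats, k = 3, seed = 3)
  expect_s3_class(model, "bt_state_model")
  asg <- classify_tracks(model, feats)
  expect_gte(match_accuracy(feats$truth, asg$cluster), 0.98)
  # log-likelihood trace non-decreasing
  expect_true(all(diff(model$loglik_trace) > -1e-6))
  # canonical ordering: cluster 1 fastest, cluster 3 slowest
  td <- tidy(model)
  expect_true(all(diff(td$D_um2_s) < 0))
})

test_that("k = 1 GMM reduces to the sample moments", {
  feats <- make_populations(60, seed = 4) %>% dplyr::filter(truth == 1)
  model <- fit_gmm(feats, k = 1, seed = 1)
  X <- bursttrack:::feature_matrix(feats, TRUE)
  expect_equal(as.numeric(model$means), unname(colMeans(X)), tolerance = 1e-6)
  expect_equal(model$weights, 1)
})

test_that("fixed seeds give bit-identical state models", {
  feats <- make_populations(100, seed = 6)
  a <- fit_gmm(feats, k = 3, seed = 11)
  b <- fit_gmm(feats, k = 3, seed = 11)
  expect_identical(a, b)
  c <- fit_ward_svm(feats, k = 3, seed = 11)
  d <- fit_ward_svm(feats, k = 3, seed = 11)
  expect_identical(c$train_labels, d$train_labels)
  expect_identical(classify_tracks(c, feats)$cluster,
                   classify_tracks(d, feats)$cluster)
})

test_that("Ward + SVM recovers the populations and re-predicts its training labels", {
  feats <- make_populations(120, seed = 7)
  model <- fit_ward_svm(feats, k = 3, seed = 8)
  expect_gte(match_accuracy(feats$truth, model$train_labels), 0.98)
  asg <- classify_tracks(model, feats)
  expect_gte(mean(asg$cluster == model$train_labels), 0.95)
})

test_that("GMM classification is deterministic and fit-consistent", {
  feats <- make_populations(100, seed = 9)
  model <- fit_gmm(feats, k = 3, seed = 2)
  a1 <- classify_tracks(model, feats)
  a2 <- classify_tracks(model, feats)
  expect_identical(a1, a2)
  # a point placed exactly at a component mean goes to that component
  X0 <- model$means[, 2]
  probe <- feats[1, ]
  vals <- X0
  vals[c(1, 3, 5)] <- exp(vals[c(1, 3, 5)])   # undo log transform
  probe[, bursttrack:::bt_feature_cols] <- as.list(vals)
  expect_equal(classify_tracks(model, probe)$cluster, 2L)
})

test_that("held-out classification stays accurate", {
  feats <- make_populations(200, seed = 10)
  train_idx <- unlist(lapply(split(seq_len(nrow(feats)), feats$truth),
                             head, 100))
  model <- fit_gmm(feats[train_idx, ], k = 3, seed = 1)
  held <- feats[-train_idx, ]
  asg <- classify_tracks(model, held)
  expect_gte(match_accuracy(held$truth, asg$cluster), 0.95)
})

test_that("fold changes are exact on constructed counts and handle empties", {
  asg <- dplyr::bind_rows(
    tibble::tibble(condition = "a",
                   cluster = rep(1:3, times = c(400, 300, 300))),
    tibble::tibble(condition = "b",
                   cluster = rep(1:3, times = c(200, 400, 400)))
  )
  fc <- cluster_fold_changes(asg, "a", "b", n_boot = 50, seed = 1)
  expect_equal(fc$fold_change[1], 0.5)
  expect_equal(sum(fc$frac_a), 1, tolerance = 1e-12)
  expect_equal(sum(fc$frac_b), 1, tolerance = 1e-12)

  # identical assignments -> all fold changes 1
  same <- dplyr::bind_rows(
    tibble::tibble(condition = "a", cluster = rep(1:3, 100)),
    tibble::tibble(condition = "b", cluster = rep(1:3, 100))
  )
  fc2 <- cluster_fold_changes(same, "a", "b", n_boot = 50, seed = 1)
  expect_true(all(fc2$fold_change == 1))

  # empty denominator cluster -> missing, not infinite
  miss <- dplyr::bind_rows(
    tibble::tibble(condition = "a", cluster = rep(1:2, 100)),
    tibble::tibble(condition = "b", cluster = rep(1:3, 100))
  )
  fc3 <- cluster_fold_changes(miss, "a", "b", k = 3, n_boot = 50, seed = 1)
  expect_true(is.na(fc3$fold_change[3]))
})

test_that("bootstrap CI covers the true fold change in most replicates", {
  set.seed(12)
  cover <- vapply(1:60, function(i) {
    cl_a <- sample(1:3, 400, replace = TRUE, prob = c(0.4, 0.3, 0.3))
    cl_b <- sample(1:3, 400, replace = TRUE, prob = c(0.2, 0.4, 0.4))
    asg <- dplyr::bind_rows(tibble::tibble(condition = "a", cluster = cl_a),
                            tibble::tibble(condition = "b", cluster = cl_b))
    fc <- cluster_fold_changes(asg, "a", "b", k = 3, n_boot = 200,
                               seed = i)
    fc$ci_lo[1] <= 0.5 && 0.5 <= fc$ci_hi[1]
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("an acute-only slow population is flagged as the depleted cluster", {
  # condition A carries an extra slow/confined population at 8%; B lacks it
  set.seed(13)
  base <- make_populations(500, seed = 13) %>%
    dplyr::filter(truth %in% 1:2)
  slow <- make_populations(500, seed = 14) %>%
    dplyr::filter(truth == 3) %>% dplyr::slice(1:80)   # 8% of condition A
  feats <- dplyr::bind_rows(
    base %>% dplyr::mutate(condition = rep(c("A", "B"), length.out = dplyr::n())),
    slow %>% dplyr::mutate(condition = "A")
  ) %>% dplyr::mutate(track_id = dplyr::row_number())
  model <- fit_gmm(feats, k = 3, seed = 5)
  asg <- classify_tracks(model, feats)
  fc <- cluster_fold_changes(asg, "A", "B", n_boot = 100, seed = 2)
  # the slowest canonical cluster (highest index) is the most depleted in B
  expect_equal(which.min(fc$fold_change), 3L)
})

test_that("cluster-count report covers the requested range", {
  feats <- make_populations(80, seed = 15)
  ts <- build_training_set(feats, n_per_condition = 60, seed = 1)
  rep <- cluster_selection_report(ts, k_range = 2:4,
                                  cond_a = "a", cond_b = "c")
  expect_equal(rep$k, 2:4)
  expect_true(all(is.finite(rep$avg_silhouette)))
})

test_that("model tidiers expose components and fit summaries", {
  feats <- make_populations(80, seed = 16)
  model <- fit_gmm(feats, k = 3, seed = 1)
  td <- tidy(model)
  expect_equal(nrow(td), 3)
  expect_equal(sum(td$weight), 1, tolerance = 1e-9)
  gl <- glance(model)
  expect_equal(gl$k, 3)
  expect_true(is.finite(gl$loglik))
})
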