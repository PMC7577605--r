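# Sample preparation, leave-one-run-out SVM decoding and group inference.

test_that("prepare_samples labels, detrends and z-scores correctly", {
  cfg <- tiny_config(shape = c(4, 4, 2), noise_sd = 0.1, drift_amplitude = 0,
                     visual_amplitude = 0)
  # single 8-s block at t = 10: labelled volumes start after the HRF delay
  ev1 <- data.frame(onset = 10, duration = 8, trial_type = "CF")
  set.seed(1)
  Y <- matrix(rnorm(75 * 4), 75, 4)
  s1 <- prepare_samples(Y, ev1, 3.2, run = 1)
  lab_idx <- which(!is.na(s1$labels))
  expect_true(all(s1$labels[lab_idx] == "CF"))
  expect_gte(min(lab_idx), ceiling(10 / 3.2) + 1 + 1)  # >= 1 volume after onset
  expect_gte(length(lab_idx), 2)
  expect_lte(length(lab_idx), 4)
  # z-scored per voxel
  expect_equal(unname(colMeans(s1$x)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(apply(s1$x, 2, sd)), rep(1, 4), tolerance = 1e-10)
  # a pure linear-trend voxel is zero after detrending
  Yt <- Y; Yt[, 2] <- seq_len(75) * 2 + 5
  s2 <- prepare_samples(Yt, ev1, 3.2)
  expect_lt(max(abs(s2$x[, 2])), 1e-8)

  cfg2 <- tiny_config()
  ev <- simulate_design(cfg2, seed = 2)
  s3 <- prepare_samples(matrix(rnorm(75 * 3), 75, 3), ev, 3.2)
  # every condition contributes labelled volumes; transitions unlabelled
  expect_setequal(unique(na.omit(s3$labels)), c("CF", "CO", "HeF", "HeO"))
  expect_gt(sum(is.na(s3$labels)), 0)
})

test_that("leave-one-run-out folds partition the runs", {
  folds <- loro_cv_splits(1:6)
  expect_length(folds, 6)
  expect_setequal(vapply(folds, `[[`, numeric(1), "test"), 1:6)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), 1:6)
  }
  expect_length(loro_cv_splits(c("a", "b")), 2)
  expect_error(loro_cv_splits(1), "at least 2")
})

test_that("the linear SVM separates separable data and is at chance otherwise", {
  # linearly separable 2-voxel toy
  tr_x <- rbind(matrix(rnorm(40, -2, 0.1), 20), matrix(rnorm(40, 2, 0.1), 20))
  tr_y <- rep(c("neg", "pos"), each = 20)
  expect_equal(train_test_lsvm(tr_x, tr_y, tr_x, tr_y), 1.0)

  # shuffled labels -> chance
  set.seed(8)
  n <- 1000
  X <- matrix(rnorm(n * 4), n)
  y <- sample(rep(c("neg", "pos"), n / 2))
  acc <- train_test_lsvm(X[1:500, ], y[1:500], X[501:n, ], y[501:n])
  expect_lt(abs(acc - 0.5), 0.06)
  expect_error(train_test_lsvm(X[1:10, ], rep("pos", 10), X, y), "single class")

  # task pooling
  lab <- c("CF", "HeF", "CO", "HeO", NA)
  expect_equal(as.character(pool_task_labels(lab, "FvsO")),
               c("pos", "pos", "neg", "neg", NA))
  expect_equal(as.character(pool_task_labels(lab, "CvsHe")),
               c("pos", "neg", "pos", "neg", NA))
})

test_that("searchlight accuracy is elevated only near the seeded region", {
  cfg <- tiny_config(n_subjects = c(A = 1, B = 1), shape = c(8, 8, 2),
                     n_runs = 3, species_effect = 1, main_region_fraction = 0.4)
  gt <- ground_truth_maps(cfg$grid_A, "A", cfg)
  sched <- lapply(1:3, function(r) simulate_design(cfg, seed = 60 + r))
  samples <- lapply(1:3, function(r) {
    sim <- simulate_bold_run(sched[[r]], gt$amplitude, cfg$grid_A, cfg, seed = 70 + r)
    prepare_samples(sim$bold, sched[[r]], cfg$tr_s, run = r)
  })
  am <- searchlight_accuracy(samples, cfg$grid_A, radius_mm = 4, task = "CvsHe")
  expect_equal(attr(am, "n_folds"), 3)
  vals <- as.numeric(am$values)
  expect_true(all(vals >= 0 & vals <= 1, na.rm = TRUE))
  in_region <- mean(vals[gt$regions$species_pref], na.rm = TRUE)
  far <- setdiff(seq_along(vals), unique(unlist(
    lapply(gt$regions$species_pref, function(v) {
      ctr <- index_to_mm(cfg$grid_A, xspecfmri:::.vox_unlinear(v, cfg$grid_A$shape))
      attr(sphere_voxels(cfg$grid_A, ctr, 6), "linear")
    }))))
  expect_gt(in_region, 0.8)
  expect_lt(mean(vals[far], na.rm = TRUE), in_region - 0.2)

  # accuracy is invariant to voxel order within the sphere (order-blind SVM)
  X <- do.call(rbind, lapply(samples, `[[`, "x"))
  y <- pool_task_labels(unlist(lapply(samples, `[[`, "labels")), "CvsHe")
  runs <- unlist(lapply(samples, function(s) rep(s$run, nrow(s$x))))
  folds <- loro_cv_splits(unique(runs))
  cols <- gt$regions$species_pref[1:5]
  a1 <- xspecfmri:::.cv_accuracy(X, y, runs, cols, folds)
  a2 <- xspecfmri:::.cv_accuracy(X, y, runs, rev(cols), folds)
  expect_equal(a1, a2)

  # radius 0 with min_voxels 1 gives a single-voxel decoding map
  am0 <- searchlight_accuracy(samples, cfg$grid_A, radius_mm = 0,
                              task = "CvsHe", min_voxels = 1L)
  expect_false(anyNA(am0$values))
})

test_that("group accuracy inference is calibrated around chance and recovers seeds", {
  g <- volume_grid(c(8, 8, 4))
  nv <- prod(g$shape)
  set.seed(31)
  # chance maps: binomial accuracies around 0.5
  M <- matrix(rbinom(8 * nv, 40, 0.5) / 40, 8)
  res <- group_accuracy_inference(M, g, n_perm = 200, seed = 4)
  expect_lt(abs(mean(res$mean) - 0.5), 0.02)
  # seeded decodable region
  region <- 1:30
  M2 <- M; M2[, region] <- M2[, region] + 0.4
  res2 <- group_accuracy_inference(M2, g, n_perm = 200, seed = 4)
  expect_true(any(res2$clusters$survives))
  surv_cols <- unlist(lapply(which(res2$clusters$survives),
                             function(ci) res2$cluster_voxels[[ci]]$mask_cols))
  expect_gt(length(intersect(surv_cols, region)) / length(region), 0.8)
  expect_error(group_accuracy_inference(M, g, voxel_p = 1e-6, n_perm = 100),
               "unattainable")

  # shuffled labels leave the training untouched by test-run content
  lab <- c(rep("CF", 5), rep("CO", 5))
  s <- list(x = matrix(rnorm(100), 10), labels = lab, run = 1)
  sh <- shuffle_sample_labels(list(s), seed = 2)[[1]]
  expect_setequal(sh$labels, lab)
})
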