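# HRF, design matrix, OLS fitting, contrasts, group stats, ANOVA,
# parametric modulation and the motion rule.

test_that("canonical HRF has the standard double-gamma shape", {
  k <- canonical_hrf(0.1)
  tt <- attr(k, "times")
  expect_equal(tt[which.max(k)], 5.0)           # mode of the double-gamma
  expect_equal(k[1], 0)                          # zero at t = 0
  expect_equal(max(k), 1, tolerance = 1e-4)      # peak-normalized
  late <- k[tt > 12 & tt < 25]
  expect_true(any(late < 0))                     # undershoot lobe
  expect_gt(sum(k) * 0.1, 0)                     # net positive integral
})

test_that("design matrix has conditions, DCT drift, motion and intercept", {
  cfg <- tiny_config()
  ev <- simulate_design(cfg, seed = 1)
  motion <- matrix(rnorm(75 * 6), 75, 6)
  X <- build_design_matrix(ev, 75, 3.2, motion = motion)
  # floor(2 * 240 / 128) = 3 drift columns
  expect_equal(sum(grepl("^dct_", colnames(X))), 3)
  expect_equal(sum(colnames(X) == "intercept"), 1)
  expect_equal(unname(colSums(abs(sweep(X[, grepl("motion", colnames(X))], 2,
                                        colMeans(X[, grepl("motion", colnames(X))]))))) > 0,
               rep(TRUE, 6))
  expect_setequal(attr(X, "conditions"), c("CF", "CO", "HeF", "HeO"))

  # missing condition is dropped and flagged
  ev2 <- ev[ev$trial_type != "CF", ]
  X2 <- build_design_matrix(ev2, 75, 3.2)
  expect_false("CF" %in% colnames(X2))
  expect_equal(attr(X2, "missing_conditions"), "CF")

  expect_error(build_design_matrix(data.frame(onset = 300, duration = 8,
                                              trial_type = "CF"), 75, 3.2),
               "beyond")
  expect_error(build_design_matrix(data.frame(onset = 10, duration = -1,
                                              trial_type = "CF"), 75, 3.2),
               "negative")

  # condition column follows the HRF: zero before onset, positive after delay
  ev1 <- data.frame(onset = 10, duration = 8, trial_type = "CF")
  X1 <- build_design_matrix(ev1, 75, 3.2)
  vol_before <- which((0:74) * 3.2 < 10)
  expect_true(all(abs(X1[vol_before, "CF"]) < 1e-9))
  expect_gt(max(X1[, "CF"]), 0)
})

test_that("fit_glm equals the pseudo-inverse oracle and recovers beta exactly", {
  set.seed(1)
  cfg <- tiny_config()
  ev <- simulate_design(cfg, seed = 2)
  X <- build_design_matrix(ev, 75, 3.2)
  # OLS identity: noise-free Y = X beta0 recovers beta0
  beta0 <- matrix(rnorm(ncol(X) * 5), ncol(X), 5)
  Y <- unclass(X) %*% beta0
  fit <- fit_glm(Y, X)
  expect_equal(unname(fit$beta), unname(beta0), tolerance = 1e-10)
  expect_equal(fit$df, 75 - ncol(X))

  # random problems vs MASS::ginv
  for (i in 1:5) {
    Yr <- matrix(rnorm(75 * 20), 75, 20)
    fr <- fit_glm(Yr, X)
    expect_equal(unname(fr$beta), unname(MASS::ginv(unclass(X)) %*% Yr),
                 tolerance = 1e-8)
  }

  # linear trend data is mostly absorbed by the drift columns: condition
  # betas stay below 0.1% of the trend range
  Yt <- matrix(seq_len(75), 75, 3) * rep(c(1, -2, 0.5), each = 75)
  ft <- fit_glm(Yt, X)
  expect_lt(max(abs(ft$beta[c("CF", "CO", "HeF", "HeO"), ])), 0.15)

  # duplicated condition column errors with the column named
  Xd <- cbind(unclass(X), CF2 = unclass(X)[, "CF"])
  expect_error(fit_glm(Yr, Xd), "rank deficient")
})

test_that("contrasts evaluate c'beta with a hand-computable t", {
  cfg <- tiny_config()
  ev <- simulate_design(cfg, seed = 3)
  X <- build_design_matrix(ev, 75, 3.2)
  beta0 <- matrix(0, ncol(X), 1, dimnames = list(colnames(X), NULL))
  beta0["CF", ] <- 2; beta0["CO", ] <- 1
  fit <- fit_glm(unclass(X) %*% beta0, X)
  expect_equal(unname(compute_contrast(fit, c(CF = 1, CO = -1))$con), 1,
               tolerance = 1e-10)
  expect_equal(unname(compute_contrast(fit, c(HeF = 1, HeO = -1))$con), 0,
               tolerance = 1e-10)
  expect_error(compute_contrast(fit, c(nope = 1)), "unknown")

  # toy 2-regressor design with closed-form (X'X)^-1
  X2 <- cbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1))
  attr(X2, "tr_s") <- 1
  y2 <- matrix(c(1, 3, 2, 2), 4, 1)
  f2 <- fit_glm(y2, X2)
  # beta = (2, 2); residuals (-1, 1, 0, 0); sigma2 = 2/2 = 1
  # var(c'beta) for c = (1, -1): sigma2 * (1/2 + 1/2) = 1 -> t = 0
  ct <- compute_contrast(f2, c(a = 1, b = -1))
  expect_equal(unname(ct$con), 0)
  # c = (1, 0): se = sqrt(1 * 1/2); t = 2 / sqrt(0.5)
  ca <- compute_contrast(f2, c(a = 1))
  expect_equal(unname(ca$t), 2 / sqrt(0.5), tolerance = 1e-12)
})

test_that("group one-sample t matches the hand formula", {
  M <- rbind(c(1, -1, 0), c(2, 0, 0), c(3, 1, 0))
  res <- group_onesample_t(M)
  expect_equal(res$t[1], 2 / (1 / sqrt(3)), tolerance = 1e-12)  # 3.464
  expect_equal(res$t[2], 0)
  expect_true(is.nan(res$t[3]))                                  # zero variance
  expect_error(group_onesample_t(M[1, , drop = FALSE]), "2 subjects")
})

test_that("cluster FWE permutation flags seeded clusters and guards inputs", {
  g <- volume_grid(c(8, 8, 4))
  set.seed(21)
  n <- 8
  M <- matrix(rnorm(n * prod(g$shape)), n)
  # seed a strong 3x3x2 effect
  idx <- as.matrix(expand.grid(2:4, 2:4, 1:2))
  lin <- 1 + idx[, 1] + 8 * (idx[, 2] + 8 * idx[, 3])
  M[, lin] <- M[, lin] + 3
  res <- cluster_fwe_permutation(M, g, n_perm = 200, seed = 5)
  expect_s3_class(res, "group_stat_map")
  expect_true(any(res$clusters$survives))
  top <- res$cluster_voxels[[1]]
  expect_gte(top$size, 12)
  expect_error(cluster_fwe_permutation(M, g, n_perm = 0), "n_perm")

  # the surviving map reconstructs on the grid
  vm <- group_map_volume(res, surviving_only = TRUE)
  expect_equal(dim(vm$values), g$shape)
  expect_gt(sum(vm$values != 0, na.rm = TRUE), 0)
})

test_that("ROI factorial ANOVA matches the sums-of-squares oracle", {
  # all cell means equal (with within-cell spread) -> F = 0 exactly
  d0 <- expand.grid(face = c("F", "O"), species = c("C", "He"), rep = 1:4)
  d0$beta <- 5 + ifelse(d0$rep <= 2, 0.1, -0.1)
  a0 <- roi_factorial_anova(d0, c("face", "species"))
  expect_true(all(a0$F < 1e-20))

  # hand-computable 2x2 with n = 2 per cell
  d1 <- data.frame(face = rep(c("F", "F", "O", "O"), 2),
                   species = rep(c("C", "He"), each = 4),
                   beta = c(3, 5, 1, 3, 6, 8, 2, 4))
  a1 <- roi_factorial_anova(d1, c("face", "species"))
  oracle <- ss_anova_2x2(d1$beta, d1$face, d1$species)
  expect_equal(a1$F[a1$effect == "face"], oracle$F_a, tolerance = 1e-8)
  expect_equal(a1$F[a1$effect == "species"], oracle$F_b, tolerance = 1e-8)
  expect_equal(a1$F[a1$effect == "face:species"], oracle$F_ab, tolerance = 1e-8)

  # additive construction: interaction F ~ 0, main effects > 0
  set.seed(3)
  d2 <- expand.grid(face = c("F", "O"), species = c("C", "He"), rep = 1:6)
  d2$beta <- 2 * (d2$face == "F") + 1 * (d2$species == "C")
  d2$beta <- d2$beta + rep(rnorm(6, 0, 1e-6), each = 4)
  a2 <- roi_factorial_anova(d2, c("face", "species"))
  expect_gt(a2$F[a2$effect == "face"], 100)
  expect_lt(a2$F[a2$effect == "face:species"], 1)

  # relabeling factor levels consistently leaves F unchanged
  d3 <- d1; d3$face <- ifelse(d1$face == "F", "zz", "aa")
  a3 <- roi_factorial_anova(d3, c("face", "species"))
  expect_equal(a3$F, a1$F, tolerance = 1e-12)

  expect_error(roi_factorial_anova(d1[d1$species == "C", ], c("face", "species")),
               "empty")
})

test_that("parametric modulation recovers a property-driven slope", {
  cfg <- tiny_config()
  ev <- simulate_design(cfg, seed = 4)
  prop <- rnorm(nrow(ev))
  centered <- prop - mean(prop)
  # construct data whose amplitude varies with the property
  sig <- numeric(75)
  for (b in seq_len(nrow(ev)))
    sig <- sig + (1 + 0.5 * centered[b]) *
      xspecfmri:::.convolve_events(ev$onset[b], ev$duration[b], 75, 3.2)
  Y <- matrix(sig + rnorm(75, 0, 0.01), 75, 1)
  pm <- parametric_modulation(Y, ev, prop, 75, 3.2)
  expect_false(pm$flagged)
  expect_equal(unname(pm$beta_mod), 0.5, tolerance = 0.05)

  # constant property -> flagged zero betas
  pm0 <- parametric_modulation(Y, ev, rep(2, nrow(ev)), 75, 3.2)
  expect_true(pm0$flagged)
  expect_equal(unname(pm0$beta_mod), 0)
  expect_error(parametric_modulation(Y, ev, 1:3, 75, 3.2), "one property value")
})

test_that("BH correction matches the step-up rule", {
  p <- c(0.001, 0.008, 0.012, 0.04, 0.5, 0.7, 0.9)
  set.seed(9)
  # embed as group test: construct beta columns whose t-test p are irrelevant;
  # check p.adjust path against a hand step-up on the same p vector
  m <- length(p)
  hand <- numeric(m)
  o <- order(p)
  cummin_rev <- rev(cummin(rev(p[o] * m / seq_len(m))))
  hand[o] <- pmin(1, cummin_rev)
  expect_equal(stats::p.adjust(p, "BH"), hand, tolerance = 1e-12)
  # and the modulation group test uses exactly that correction
  B <- matrix(rnorm(10 * 3), 10, 3)
  res <- modulation_group_test(B)
  expect_equal(res$p_bh, stats::p.adjust(res$p, "BH"))
})

test_that("motion exclusion is strict at 3 mm", {
  base <- matrix(0, 20, 6)
  expect_true(motion_exclusion_check(base)$keep)
  m1 <- base; m1[10, 1] <- 3.1
  expect_false(motion_exclusion_check(m1)$keep)
  m2 <- base; m2[10, 2] <- 3.0
  expect_true(motion_exclusion_check(m2)$keep)      # exactly 3.0 keeps
  m3 <- base; m3[, 4] <- 10                          # rotations don't count
  expect_true(motion_exclusion_check(m3)$keep)
  expect_error(motion_exclusion_check(base[, 1:4]), "6 columns")
})
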