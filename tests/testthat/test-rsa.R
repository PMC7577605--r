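# RDMs, noise normalization, cross-species matching, chance model and
# condition-pair effects.

make_items <- function(n_runs = 6) {
  data.frame(condition = rep(c("CF", "CO", "HeF", "HeO"), n_runs),
             run = rep(seq_len(n_runs), each = 4))
}

test_that("noise normalization rescales by baseline SD with a floored guard", {
  X <- matrix(c(2, 4, 6, 8, 1, 1, 1, 1), 4, 2)
  B <- rbind(c(2, 5), c(6, 5), c(4, 5))   # SDs: 2, 0
  expect_warning(out <- noise_normalize(X, B), "floored")
  expect_equal(out[, 1], X[, 1] / 2)
  # baseline SD 1 everywhere -> identity
  B1 <- matrix(rnorm(200), 100, 2)
  B1 <- sweep(sweep(B1, 2, colMeans(B1)), 2, apply(B1, 2, sd), "/")
  expect_equal(unname(noise_normalize(X, B1)[, 1]), X[, 1], tolerance = 1e-10)
  expect_error(noise_normalize(X, B[1, , drop = FALSE]), "at least 2")
})

test_that("RDMs are symmetric correlation distances with hand-checked entries", {
  items <- data.frame(condition = c("CF", "CO"), run = c(1, 1))
  expect_equal(compute_rdm(rbind(c(1, 2, 3), c(1, 2, 3)), items)$matrix[1, 2], 0)
  expect_equal(compute_rdm(rbind(c(1, 2, 3), c(3, 2, 1)), items)$matrix[1, 2], 2)

  set.seed(5)
  pats <- matrix(rnorm(24 * 10), 24)
  rdm <- compute_rdm(pats, make_items())
  expect_equal(dim(rdm$matrix), c(24, 24))
  expect_equal(rdm$matrix, t(rdm$matrix))
  expect_equal(unname(diag(rdm$matrix)), rep(0, 24))
  expect_true(all(rdm$matrix >= 0 & rdm$matrix <= 2))

  # Pearson invariance: shifting or positively scaling patterns changes nothing
  rdm2 <- compute_rdm(pats * 3 + 7, make_items())
  expect_equal(rdm2$matrix, rdm$matrix, tolerance = 1e-12)

  # zero-variance pattern flags its item as NA
  pats[3, ] <- 5
  rdm3 <- compute_rdm(pats, make_items())
  expect_equal(attr(rdm3, "flagged_items"), 3)
  expect_true(all(is.na(rdm3$matrix[3, -3])))
  expect_error(compute_rdm(pats[, 1, drop = FALSE], make_items()), "2 voxels")
})

test_that("RDM correlation respects the matching scheme", {
  set.seed(6)
  pats <- matrix(rnorm(24 * 8), 24)
  rdm_a <- compute_rdm(pats, make_items())
  # identical RDMs, identity (functional) mapping -> rho = 1
  expect_equal(rdm_correlation(rdm_a, rdm_a, matching_scheme("functional")), 1)

  # B built from A with conspecific/heterospecific labels swapped:
  # functional rho on the swapped data < 1, direct rho = 1
  items_sw <- make_items()
  swap <- c(CF = "HeF", CO = "HeO", HeF = "CF", HeO = "CO")
  items_sw$condition <- swap[items_sw$condition]
  rdm_b <- compute_rdm(pats, items_sw)
  expect_equal(rdm_correlation(rdm_a, rdm_b, matching_scheme("direct")), 1)
  expect_lt(rdm_correlation(rdm_a, rdm_b, matching_scheme("functional")), 0.999)

  # independent random RDMs: rho centred at 0
  rhos <- replicate(300, {
    ra <- compute_rdm(matrix(rnorm(24 * 6), 24), make_items())
    rb <- compute_rdm(matrix(rnorm(24 * 6), 24), make_items())
    rdm_correlation(ra, rb, matching_scheme("functional"))
  })
  expect_lt(abs(mean(rhos)), 3 * sd(rhos) / sqrt(300))
})

test_that("functional vs direct alignment is recovered from simulated pairs", {
  cfg <- tiny_config(n_subjects = c(A = 3, B = 3), shape = c(6, 6, 2), n_runs = 3)
  for (al in c("functional", "direct")) {
    pair <- simulate_cross_species_pair(cfg, alignment = al, seed = 21)
    rdms <- lapply(c("A", "B"), function(arm_name) {
      arm <- pair$arms[[arm_name]]
      lapply(arm$subjects, function(sub) {
        it <- extract_item_patterns(sub, arm$grid, arm$region, cfg$tr_s, cfg$n_volumes)
        compute_rdm(it$patterns, it$items)
      })
    })
    rho <- sapply(c("functional", "direct"), function(sc) {
      sch <- matching_scheme(sc)
      mean(outer(1:3, 1:3, Vectorize(function(a, b)
        rdm_correlation(rdms[[1]][[a]], rdms[[2]][[b]], sch))))
    })
    if (al == "functional") expect_gt(rho[["functional"]], rho[["direct"]])
    else expect_gt(rho[["direct"]], rho[["functional"]])
  }
})

test_that("searchlight similarity is elevated only in the seeded region", {
  cfg <- tiny_config(n_subjects = c(A = 1, B = 1), shape = c(6, 6, 2), n_runs = 3)
  pair <- simulate_cross_species_pair(cfg, alignment = "functional", seed = 31)
  armA <- pair$arms$A; armB <- pair$arms$B
  itA <- extract_item_patterns(armA$subjects[[1]], armA$grid, armA$region,
                               cfg$tr_s, cfg$n_volumes)
  ref <- compute_rdm(itA$patterns, itA$items)
  itB <- extract_item_patterns(armB$subjects[[1]], armB$grid,
                               seq_len(prod(armB$grid$shape)),
                               cfg$tr_s, cfg$n_volumes)
  sm <- searchlight_rsa(itB, ref, matching_scheme("functional"), armB$grid,
                        radius_mm = 2)
  vals <- as.numeric(sm$values)
  expect_true(all(vals >= -1 & vals <= 1, na.rm = TRUE))
  expect_gt(mean(vals[armB$region], na.rm = TRUE),
            mean(vals[-armB$region], na.rm = TRUE) + 0.1)

  # all-equal reference RDM -> NaN map with a warning
  ref0 <- ref; ref0$matrix[] <- 1; diag(ref0$matrix) <- 0
  ref0$matrix[upper.tri(ref0$matrix)] <- 1
  expect_warning(sm0 <- searchlight_rsa(itB, ref0, matching_scheme("functional"),
                                        armB$grid, radius_mm = 2),
                 "zero dissimilarity variance")
  expect_true(all(is.na(sm0$values)))
})

test_that("random-coordinate chance model is seeded and centred near zero", {
  cfg <- tiny_config(n_subjects = c(A = 1, B = 1), shape = c(6, 6, 2), n_runs = 3)
  pair <- simulate_cross_species_pair(cfg, alignment = "none", seed = 41)
  armA <- pair$arms$A; armB <- pair$arms$B
  itA <- extract_item_patterns(armA$subjects[[1]], armA$grid, armA$region,
                               cfg$tr_s, cfg$n_volumes)
  ref <- compute_rdm(itA$patterns, itA$items)
  itB <- extract_item_patterns(armB$subjects[[1]], armB$grid,
                               seq_len(prod(armB$grid$shape)),
                               cfg$tr_s, cfg$n_volumes)
  null1 <- chance_distribution_random_coordinates(itB, ref,
                                                  matching_scheme("functional"),
                                                  armB$grid, radius_mm = 2,
                                                  n = 50, seed = 5)
  null2 <- chance_distribution_random_coordinates(itB, ref,
                                                  matching_scheme("functional"),
                                                  armB$grid, radius_mm = 2,
                                                  n = 50, seed = 5)
  expect_identical(null1$sample, null2$sample)
  expect_lt(abs(null1$mean), 3 * null1$sd / sqrt(sum(!is.na(null1$sample))) + 0.1)
  expect_error(chance_distribution_random_coordinates(itB, ref,
                                                      matching_scheme("functional"),
                                                      armB$grid, n = 0), "n must be")
})

test_that("Cohen's d and condition-pair effects behave on constructed cases", {
  # d formula on tabulated toys
  expect_equal(cohens_d(c(0, 0.5, 1), 0), mean(c(0, 0.5, 1)) / sd(c(0, 0.5, 1)))
  obs <- c(0, 0.5, 1)   # mean 0.5, sd 0.5
  expect_equal(cohens_d(obs, rep(0, 3)), 1.0, tolerance = 1e-12)

  # identical dissimilarities across conditions: label swaps change nothing,
  # so observed ~ expected and d ~ 0
  set.seed(9)
  items <- make_items(4)
  # patterns depend only on run, not condition
  run_pat <- matrix(rnorm(4 * 6), 4)
  pats <- run_pat[items$run, ] + matrix(rnorm(16 * 6, 0, 1e-6), 16)
  rdms_a <- lapply(1:3, function(i) compute_rdm(pats + rnorm(96, 0, 1e-6), items))
  rdms_b <- lapply(1:3, function(i) compute_rdm(pats + rnorm(96, 0, 1e-6), items))
  tab <- condition_pair_effects(rdms_a, rdms_b, matching_scheme("functional"),
                                n_swaps = 30, seed = 2)
  expect_s3_class(tab, "pairwise_effect_table")
  expect_setequal(tab$pair, c("CF-CO", "HeF-HeO", "HeF-CF", "HeO-CO"))
  expect_lt(max(abs(tab$observed_mean_rho - tab$expected_mean_rho)), 0.2)
  expect_error(condition_pair_effects(rdms_a, rdms_b, n_swaps = 0), "n_swaps")
})
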