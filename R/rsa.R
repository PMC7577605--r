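# Across-species representational similarity analysis: correlation-distance
# RDMs over (condition, run) items, univariate noise normalization, direct
# versus functional condition matching, searchlight similarity maps with a
# random-coordinate chance model, and condition-pair follow-up effects.

#' Univariate noise normalization
#'
#' Rescales each voxel by the SD of its activity during baseline (fixation)
#' volumes, flooring zero-variance voxels at `eps` with a warning.
#'
#' @param x Volumes x voxels matrix (patterns or time series).
#' @param baseline Either a logical/integer vector selecting baseline
#'   volumes of `x`, or a volumes x voxels matrix of baseline data.
#' @param eps Variance floor (default 1e-6).
#' @return Matrix of the same shape as `x`, with attribute `"baseline_sd"`.
#' @export
noise_normalize <- function(x, baseline, eps = 1e-6) {
  x <- as.matrix(x)
  B <- if (is.matrix(baseline)) baseline else x[baseline, , drop = FALSE]
  if (nrow(B) < 2L) stop("need at least 2 baseline volumes")
  sdv <- apply(B, 2L, stats::sd)
  if (any(sdv < eps)) {
    warning(sum(sdv < eps), " zero-variance baseline voxel(s) floored")
    sdv <- pmax(sdv, eps)
  }
  out <- sweep(x, 2L, sdv, "/")
  attr(out, "baseline_sd") <- sdv
  out
}

#' Baseline (fixation) volume selector
#'
#' Marks volumes whose acquisition time falls in the pre-block fixation
#' windows of the schedule.
#'
#' @param events Run events.
#' @param n_volumes,tr_s Run geometry.
#' @param fixation_s Fixation window length before each block.
#' @return Logical vector over volumes.
#' @export
baseline_volumes <- function(events, n_volumes, tr_s, fixation_s = 10) {
  times <- (seq_len(n_volumes) - 1L) * tr_s
  out <- rep(FALSE, n_volumes)
  starts <- c(events$onset - fixation_s, max(events$onset + events$duration))
  ends <- c(events$onset, max(events$onset + events$duration) + fixation_s)
  for (i in seq_along(starts))
    out <- out | (times >= starts[i] & times < ends[i])
  out
}

#' Representational dissimilarity matrix
#'
#' Entry (i, j) is the correlation distance 1 - Pearson r between the
#' activity patterns of items i and j; symmetric with zero diagonal, entries
#' in [0, 2]. Items are (condition, run) pairs (24 at the default design).
#'
#' @param patterns Items x voxels matrix (>= 2 voxels).
#' @param items Data frame with `condition` and `run` per row of `patterns`.
#' @return Object of class `rdm`: `matrix`, `items`. Zero-variance patterns
#'   yield NA rows/columns and are recorded in `attr(, "flagged_items")`.
#' @export
compute_rdm <- function(patterns, items) {
  patterns <- as.matrix(patterns)
  if (ncol(patterns) < 2L) stop("need at least 2 voxels")
  if (nrow(patterns) != nrow(items)) stop("one item row per pattern row")
  sdv <- apply(patterns, 1L, stats::sd)
  flagged <- which(sdv == 0 | !is.finite(sdv))
  suppressWarnings(cmat <- stats::cor(t(patterns)))
  d <- 1 - cmat
  diag(d) <- 0
  if (length(flagged)) {
    d[flagged, ] <- NA_real_
    d[, flagged] <- NA_real_
    diag(d)[flagged] <- 0
  }
  structure(list(matrix = d, items = as.data.frame(items)),
            class = "rdm", flagged_items = flagged)
}

#' Across-species condition matching schemes
#'
#' Conditions are stored species-neutrally (conspecific-relative). Functional
#' matching aligns by conspecificity, i.e. the identity map on labels;
#' direct matching aligns by stimulus identity, i.e. swaps conspecific and
#' heterospecific between the two species.
#'
#' @param name `"functional"` or `"direct"`.
#' @return Object of class `matching_scheme`: named character bijection from
#'   reference-arm labels to partner-arm labels.
#' @export
matching_scheme <- function(name = c("functional", "direct")) {
  name <- match.arg(name)
  map <- if (name == "functional")
    c(CF = "CF", CO = "CO", HeF = "HeF", HeO = "HeO")
  else
    c(CF = "HeF", CO = "HeO", HeF = "CF", HeO = "CO")
  structure(list(name = name, map = map), class = "matching_scheme")
}

# Row order that aligns rdm_b's items with rdm_a's under the scheme.
.align_items <- function(rdm_a, rdm_b, scheme) {
  key_a <- paste(scheme$map[rdm_a$items$condition], rdm_a$items$run)
  key_b <- paste(rdm_b$items$condition, rdm_b$items$run)
  ord <- match(key_a, key_b)
  if (anyNA(ord)) stop("item mismatch after condition mapping")
  ord
}

#' Correlate two RDMs under a matching scheme
#'
#' Reorders the second RDM's items by the scheme's condition bijection (runs
#' matched by index) and returns the Pearson correlation over the upper
#' triangles (diagonal excluded).
#'
#' @param rdm_a,rdm_b [compute_rdm()] results with the same item structure.
#' @param scheme A [matching_scheme()] (default functional).
#' @return Pearson rho.
#' @export
rdm_correlation <- function(rdm_a, rdm_b, scheme = matching_scheme("functional")) {
  ord <- .align_items(rdm_a, rdm_b, scheme)
  mb <- rdm_b$matrix[ord, ord]
  ut <- upper.tri(rdm_a$matrix)
  stats::cor(rdm_a$matrix[ut], mb[ut], use = "complete.obs")
}

#' Extract (condition, run) item patterns via run-wise GLMs
#'
#' Fits the first-level GLM per run and returns the condition betas over the
#' requested voxels as 4 x n_runs = 24 item patterns, optionally rescaled by
#' each voxel's fixation-period SD (univariate noise normalization).
#'
#' @param subject One subject of a `synthetic_study` arm (list of `runs`).
#' @param grid The arm's grid.
#' @param voxels Linear voxel indices of the sphere/region.
#' @param tr_s,n_volumes Run geometry.
#' @param noise_normalize Rescale betas by baseline SD (default TRUE).
#' @return List: `patterns` (items x voxels), `items` data frame.
#' @export
extract_item_patterns <- function(subject, grid, voxels, tr_s, n_volumes,
                                  noise_normalize = TRUE) {
  pats <- list()
  items <- list()
  for (r in seq_along(subject$runs)) {
    run <- subject$runs[[r]]
    Y <- .bold_matrix(run$bold, voxels)
    X <- build_design_matrix(run$events, n_volumes, tr_s, motion = run$motion)
    fit <- fit_glm(Y, X)
    beta <- fit$beta[.CONDITIONS, , drop = FALSE]
    if (noise_normalize) {
      bl <- baseline_volumes(run$events, n_volumes, tr_s)
      sdv <- apply(Y[bl, , drop = FALSE], 2L, stats::sd)
      beta <- sweep(beta, 2L, pmax(sdv, 1e-6), "/")
    }
    pats[[r]] <- beta
    items[[r]] <- data.frame(condition = .CONDITIONS, run = r)
  }
  list(patterns = do.call(rbind, pats), items = do.call(rbind, items))
}

#' Searchlight similarity map against a reference RDM
#'
#' For every in-mask center, computes the local sphere RDM from the
#' subject's item patterns and correlates it with the reference RDM under
#' the matching scheme, projecting rho back to the center. A reference RDM
#' with zero dissimilarity variance yields an all-NA map with a warning.
#'
#' @param item_data [extract_item_patterns()]-style list covering the whole
#'   mask (`patterns` items x n-mask-voxels, `items`).
#' @param reference_rdm The fixed reference [compute_rdm()].
#' @param scheme A [matching_scheme()].
#' @param grid,mask Volume geometry; pattern columns = in-mask voxels in
#'   linear order.
#' @param radius_mm Searchlight radius (mm).
#' @param min_voxels Minimum sphere size (default 2).
#' @return A [volume_map()] of rho values.
#' @export
searchlight_rsa <- function(item_data, reference_rdm, scheme, grid,
                            mask = NULL, radius_mm = 4, min_voxels = 2L) {
  if (is.null(mask)) mask <- array(TRUE, grid$shape)
  mask <- array(as.logical(mask), grid$shape)
  mask_lin <- which(mask)
  if (!length(mask_lin)) stop("empty mask")
  ut <- upper.tri(reference_rdm$matrix)
  ref_vec_full <- reference_rdm$matrix
  if (stats::sd(ref_vec_full[ut], na.rm = TRUE) == 0 ||
      all(is.na(ref_vec_full[ut]))) {
    warning("reference RDM has zero dissimilarity variance; similarity undefined")
    return(volume_map(rep(NA_real_, prod(grid$shape)), grid))
  }
  col_of <- integer(prod(grid$shape))
  col_of[mask_lin] <- seq_along(mask_lin)
  center_mm <- index_to_mm(grid, .vox_unlinear(mask_lin, grid$shape))
  vals <- rep(NA_real_, prod(grid$shape))
  for (ci in seq_along(mask_lin)) {
    sph <- sphere_voxels(grid, center_mm[ci, ], radius_mm, mask)
    cols <- col_of[attr(sph, "linear")]
    if (length(cols) < min_voxels) next
    local <- compute_rdm(item_data$patterns[, cols, drop = FALSE],
                         item_data$items)
    vals[mask_lin[ci]] <- rdm_correlation(reference_rdm, local, scheme)
  }
  volume_map(vals, grid)
}

#' Chance similarity distribution from random coordinates
#'
#' Draws `n` sphere centers uniformly from the in-mask voxels, computes the
#' local-RDM similarity to the reference exactly as the searchlight does,
#' and returns the null sample with its mean and SD.
#'
#' @inheritParams searchlight_rsa
#' @param n Number of random draws (>= 1).
#' @param seed RNG seed (fixed seed gives an identical draw sequence).
#' @return List with `sample`, `mean`, `sd`.
#' @export
chance_distribution_random_coordinates <- function(item_data, reference_rdm,
                                                   scheme, grid, mask = NULL,
                                                   radius_mm = 4, n = 1000,
                                                   seed = 1L, min_voxels = 2L) {
  if (n < 1) stop("n must be >= 1")
  if (is.null(mask)) mask <- array(TRUE, grid$shape)
  mask <- array(as.logical(mask), grid$shape)
  mask_lin <- which(mask)
  if (!length(mask_lin)) stop("mask is empty")
  col_of <- integer(prod(grid$shape))
  col_of[mask_lin] <- seq_along(mask_lin)
  set.seed(seed)
  draws <- sample(mask_lin, n, replace = TRUE)
  mm <- index_to_mm(grid, .vox_unlinear(draws, grid$shape))
  out <- vapply(seq_len(n), function(i) {
    sph <- sphere_voxels(grid, mm[i, ], radius_mm, mask)
    cols <- col_of[attr(sph, "linear")]
    if (length(cols) < min_voxels) return(NA_real_)
    local <- compute_rdm(item_data$patterns[, cols, drop = FALSE],
                         item_data$items)
    rdm_correlation(reference_rdm, local, scheme)
  }, numeric(1))
  list(sample = out, mean = mean(out, na.rm = TRUE),
       sd = stats::sd(out, na.rm = TRUE))
}

#' Group test of similarity maps
#'
#' One-tailed one-sample t of per-subject rho maps against the chance mean,
#' with sign-flip cluster-extent FWE correction (the shared group-inference
#' machinery).
#'
#' @param subject_maps Subjects x voxels matrix of rho values over the mask.
#' @param null_mean Chance-level mean rho (scalar, e.g. from
#'   [chance_distribution_random_coordinates()]).
#' @param grid,mask,voxel_p,cluster_alpha,n_perm,connectivity,seed Passed to
#'   [cluster_fwe_permutation()].
#' @return A `group_stat_map`.
#' @export
group_similarity_test <- function(subject_maps, null_mean = 0, grid,
                                  mask = NULL, voxel_p = 0.001,
                                  cluster_alpha = 0.05, n_perm = 1000,
                                  connectivity = 18L, seed = 1L) {
  cluster_fwe_permutation(subject_maps, grid, mask, voxel_p, cluster_alpha,
                          n_perm, connectivity, tail = "greater",
                          mu = null_mean, seed = seed)
}

#' Cohen's d for observed versus expected means
#'
#' `(mean(observed) - mean(expected)) / sd(observed)`.
#'
#' @param observed,expected Numeric vectors (expected may be scalar).
#' @return Cohen's d.
#' @export
cohens_d <- function(observed, expected) {
  (mean(observed) - mean(expected)) / stats::sd(observed)
}

.PAIRS <- list(`CF-CO` = c("CF", "CO"), `HeF-HeO` = c("HeF", "HeO"),
               `HeF-CF` = c("HeF", "CF"), `HeO-CO` = c("HeO", "CO"))

# rho between A and scheme-aligned B restricted to items of two conditions.
.pair_rho <- function(ma, mb_aligned, items_a, conds) {
  rows <- items_a$condition %in% conds
  sub_a <- ma[rows, rows]
  sub_b <- mb_aligned[rows, rows]
  ut <- upper.tri(sub_a)
  suppressWarnings(stats::cor(sub_a[ut], sub_b[ut], use = "complete.obs"))
}

#' Condition-pair follow-up effects with Cohen's d
#'
#' For each condition pair (CF-CO: face sensitivity for conspecifics;
#' HeF-HeO: face sensitivity for heterospecifics; HeF-CF: species
#' sensitivity for faces; HeO-CO: species sensitivity for occiputs),
#' computes the cross-species sub-RDM correlation for every arm-A x arm-B
#' subject pair, averages per arm-B participant, and compares against the
#' chance mean obtained by randomly permuting condition labels within run
#' (`n_swaps` resamples). One-sample t of observed minus expected per
#' participant; Cohen's d = (mean_obs - mean_exp) / SD_obs.
#'
#' @param rdms_a,rdms_b Lists of [compute_rdm()] results (one per subject).
#' @param scheme A [matching_scheme()].
#' @param n_swaps Label-swap resamples (default 10000).
#' @param seed RNG seed.
#' @return Data frame (class `pairwise_effect_table`) with one row per pair:
#'   `pair`, `observed_mean_rho`, `expected_mean_rho`, `t`, `p`, `cohens_d`.
#' @export
condition_pair_effects <- function(rdms_a, rdms_b,
                                   scheme = matching_scheme("functional"),
                                   n_swaps = 10000, seed = 1L) {
  if (n_swaps < 1) stop("n_swaps must be >= 1")
  set.seed(seed)
  pair_names <- names(.PAIRS)
  nb <- length(rdms_b)
  obs <- matrix(0, nb, length(.PAIRS), dimnames = list(NULL, pair_names))
  expd <- matrix(0, nb, length(.PAIRS), dimnames = list(NULL, pair_names))
  for (bi in seq_len(nb)) {
    rb <- rdms_b[[bi]]
    obs_acc <- numeric(length(.PAIRS))
    exp_acc <- numeric(length(.PAIRS))
    for (ai in seq_along(rdms_a)) {
      ra <- rdms_a[[ai]]
      ord <- .align_items(ra, rb, scheme)
      mb <- rb$matrix[ord, ord]
      obs_acc <- obs_acc + vapply(.PAIRS, function(cp)
        .pair_rho(ra$matrix, mb, ra$items, cp), numeric(1))
      runs <- unique(ra$items$run)
      swap_acc <- numeric(length(.PAIRS))
      for (s in seq_len(n_swaps)) {
        perm_items <- ra$items
        for (r in runs) {
          rows <- which(perm_items$run == r)
          perm_items$condition[rows] <- sample(perm_items$condition[rows])
        }
        swap_acc <- swap_acc + vapply(.PAIRS, function(cp)
          .pair_rho(ra$matrix, mb, perm_items, cp), numeric(1))
      }
      exp_acc <- exp_acc + swap_acc / n_swaps
    }
    obs[bi, ] <- obs_acc / length(rdms_a)
    expd[bi, ] <- exp_acc / length(rdms_a)
  }
  rows <- lapply(pair_names, function(pn) {
    d <- obs[, pn] - expd[, pn]
    tt <- if (nb >= 2 && stats::sd(d) > 0)
      stats::t.test(d, alternative = "greater") else list(statistic = NA, p.value = NA)
    data.frame(pair = pn,
               observed_mean_rho = mean(obs[, pn]),
               expected_mean_rho = mean(expd[, pn]),
               t = as.numeric(tt$statistic), p = tt$p.value,
               cohens_d = cohens_d(obs[, pn], expd[, pn]))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pairwise_effect_table", "data.frame")
  out
}
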