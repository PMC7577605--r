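# First-level GLM and group random-effects inference for the four-condition
# block design. Estimation is ordinary least squares (no prewhitening); group
# inference uses sign-flip permutation with cluster-extent FWE correction.

.HRF_PEAK <- local({
  td <- seq(0, 32, by = 0.001)
  max(stats::dgamma(td, shape = 6, rate = 1) -
      stats::dgamma(td, shape = 16, rate = 1) / 6)
})

.hrf_value <- function(t) {
  (stats::dgamma(t, shape = 6, rate = 1) -
   stats::dgamma(t, shape = 16, rate = 1) / 6) / .HRF_PEAK
}

#' Canonical double-gamma haemodynamic response kernel
#'
#' Standard double-gamma HRF (response gamma with shape 6, undershoot gamma
#' with shape 16, undershoot ratio 1/6, both rate 1), peak-normalized so the
#' continuous kernel has maximum 1 (attained at t = 5 s), sampled from 0 to
#' `duration_s` in steps of `tr_s`.
#'
#' @param tr_s Sampling interval, seconds (> 0).
#' @param duration_s Kernel length in seconds (default 32).
#' @return Numeric vector of kernel samples; `attr(, "times")` gives the
#'   sample times.
#' @export
canonical_hrf <- function(tr_s, duration_s = 32) {
  stopifnot(tr_s > 0)
  times <- seq(0, duration_s, by = tr_s)
  k <- .hrf_value(times)
  attr(k, "times") <- times
  k
}

# HRF-convolved boxcar regressor sampled at volume onsets. Shared by the
# simulator and the design-matrix builder so that amplitude recovery is
# exact. Results are memoized: block-design timing repeats across runs and
# subjects, so identical (onsets, durations, geometry) keys recur constantly.
.conv_cache <- new.env(parent = emptyenv())

.convolve_events <- function(onsets, durations, n_volumes, tr_s, dt = 0.1) {
  key <- paste(c(onsets, durations, n_volumes, tr_s, dt), collapse = ",")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- .convolve_events_impl(onsets, durations, n_volumes, tr_s, dt)
  assign(key, out, envir = .conv_cache)
  out
}

.convolve_events_impl <- function(onsets, durations, n_volumes, tr_s, dt = 0.1) {
  total_s <- n_volumes * tr_s
  nt <- as.integer(ceiling(total_s / dt)) + 1L
  u <- numeric(nt)
  for (b in seq_along(onsets)) {
    i0 <- as.integer(floor(onsets[b] / dt)) + 1L
    i1 <- as.integer(ceiling((onsets[b] + durations[b]) / dt))
    if (i1 >= i0) u[i0:min(i1, nt)] <- 1
  }
  h <- .hrf_value(seq(0, 32, by = dt))
  conv <- stats::convolve(u, rev(h), type = "open")[seq_len(nt)] * dt
  vol_idx <- as.integer(round((seq_len(n_volumes) - 1L) * tr_s / dt)) + 1L
  conv[vol_idx]
}

.dct_basis <- function(n_volumes, k) {
  if (k < 1L) return(NULL)
  v <- seq_len(n_volumes) - 1L
  sapply(seq_len(k), function(r) cos(pi * (2 * v + 1) * r / (2 * n_volumes)))
}

#' Build a first-level design matrix
#'
#' One HRF-convolved boxcar column per condition, `floor(2 * T / highpass_s)`
#' discrete-cosine drift columns (T = run length in seconds, 128-s cutoff by
#' default), mean-centered motion nuisance columns, and an intercept.
#'
#' @param events Data frame with `onset`, `duration` (seconds) and
#'   `trial_type`.
#' @param n_volumes Number of volumes in the run.
#' @param tr_s Repetition time, seconds.
#' @param motion Optional numeric matrix (n_volumes x 6) of motion parameters.
#' @param highpass_s High-pass cutoff in seconds (default 128).
#' @param conditions Condition labels defining the condition columns; labels
#'   with no events are dropped and recorded in `attr(, "missing_conditions")`.
#' @return Numeric matrix of class `design_matrix` with named columns and
#'   attributes `tr_s`, `conditions`, `missing_conditions`.
#' @export
build_design_matrix <- function(events, n_volumes, tr_s, motion = NULL,
                                highpass_s = 128, conditions = .CONDITIONS) {
  if (any(events$duration < 0)) stop("negative event duration")
  if (any(events$onset + events$duration > n_volumes * tr_s + 1e-9))
    stop("event extends beyond the end of the run")
  cols <- list()
  present <- character(0)
  for (cond in conditions) {
    rows <- events$trial_type == cond
    if (!any(rows)) next
    cols[[cond]] <- .convolve_events(events$onset[rows], events$duration[rows],
                                     n_volumes, tr_s)
    present <- c(present, cond)
  }
  k <- as.integer(floor(2 * n_volumes * tr_s / highpass_s))
  dct <- .dct_basis(n_volumes, k)
  if (!is.null(dct)) colnames(dct) <- paste0("dct_", seq_len(k))
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_volumes) stop("motion table must have one row per volume")
    motion <- sweep(motion, 2L, colMeans(motion), "-")
    colnames(motion) <- paste0("motion_", seq_len(ncol(motion)))
  }
  X <- cbind(do.call(cbind, cols), dct, motion, intercept = rep(1, n_volumes))
  colnames(X)[seq_along(present)] <- present
  structure(X, class = c("design_matrix", class(X)), tr_s = tr_s,
            conditions = present,
            missing_conditions = setdiff(conditions, present))
}

#' Fit a voxel-wise ordinary least squares GLM
#'
#' @param y A `bold_run`, or a volumes x voxels numeric matrix.
#' @param design A [build_design_matrix()] result (full column rank).
#' @param mask Optional logical array restricting the fit; voxel order in the
#'   output follows the in-mask linear indices.
#' @return Object of class `beta_maps`: `beta` (regressors x voxels),
#'   `sigma2` (residual variance per voxel), `df`, `xtx_inv`, `mask_lin`,
#'   `grid` (when available).
#' @export
fit_glm <- function(y, design, mask = NULL) {
  grid <- NULL
  if (inherits(y, "bold_run")) {
    grid <- y$grid
    mask_lin <- if (is.null(mask)) seq_len(prod(grid$shape)) else which(as.logical(mask))
    Y <- .bold_matrix(y, mask_lin)
  } else {
    Y <- as.matrix(y)
    mask_lin <- seq_len(ncol(Y))
  }
  X <- unclass(design)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qrx, Y)
  res <- qr.resid(qrx, Y)
  df <- nrow(X) - qrx$rank
  if (df <= 0) stop("no residual degrees of freedom")
  sigma2 <- colSums(res^2) / df
  rownames(beta) <- colnames(X)
  structure(list(beta = beta, sigma2 = sigma2, df = df,
                 xtx_inv = chol2inv(chol(crossprod(X))),
                 colnames = colnames(X), mask_lin = mask_lin, grid = grid),
            class = "beta_maps")
}

#' Evaluate a linear contrast of GLM betas
#'
#' @param fit A `beta_maps` object from [fit_glm()].
#' @param weights Named numeric vector of contrast weights over design
#'   columns (e.g. `c(CF = 1, CO = 1, HeF = -1, HeO = -1)` for
#'   conspecific > heterospecific).
#' @param name Optional contrast name.
#' @return List with `con` (contrast value per voxel), `t` (t statistic),
#'   `df`, `name`.
#' @export
compute_contrast <- function(fit, weights, name = NULL) {
  unknown <- setdiff(names(weights), fit$colnames)
  if (length(unknown))
    stop("unknown design columns in contrast: ", paste(unknown, collapse = ", "))
  cvec <- numeric(length(fit$colnames))
  names(cvec) <- fit$colnames
  cvec[names(weights)] <- weights
  con <- drop(cvec %*% fit$beta)
  cvc <- drop(t(cvec) %*% fit$xtx_inv %*% cvec)
  se <- sqrt(fit$sigma2 * cvc)
  tval <- ifelse(se > 0, con / se, NaN)
  list(con = con, t = tval, df = fit$df, name = name)
}

#' Standard contrasts of the four-condition design
#'
#' `C>He` is (CF + CO) - (HeF + HeO); `F>O` is (CF + HeF) - (CO + HeO);
#' `interaction` is (CF - CO) - (HeF - HeO).
#'
#' @param name One of `"C>He"`, `"He>C"`, `"F>O"`, `"O>F"`, `"interaction"`.
#' @return Named weight vector for [compute_contrast()].
#' @export
contrast_spec <- function(name = c("C>He", "He>C", "F>O", "O>F", "interaction")) {
  name <- match.arg(name)
  switch(name,
    "C>He" = c(CF = 1, CO = 1, HeF = -1, HeO = -1),
    "He>C" = c(CF = -1, CO = -1, HeF = 1, HeO = 1),
    "F>O"  = c(CF = 1, CO = -1, HeF = 1, HeO = -1),
    "O>F"  = c(CF = -1, CO = 1, HeF = -1, HeO = 1),
    "interaction" = c(CF = 1, CO = -1, HeF = -1, HeO = 1))
}

#' Voxel-wise one-sample t test across subjects
#'
#' @param subject_maps Numeric subjects x voxels matrix (one row per subject).
#' @param mu Null mean (scalar or per-voxel vector).
#' @param tail `"two"` (default), `"greater"` or `"less"`.
#' @return List with `t`, `p`, `df`, `mean`. Voxels with zero variance give
#'   NaN t and NA p.
#' @export
group_onesample_t <- function(subject_maps, mu = 0, tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  M <- as.matrix(subject_maps)
  n <- nrow(M)
  if (n < 2L) stop("at least 2 subjects are required")
  D <- sweep(M, 2L, mu)
  m <- colMeans(D)
  s2 <- (colSums(D^2) - n * m^2) / (n - 1)
  s2[s2 < 0] <- 0
  se <- sqrt(s2 / n)
  tval <- ifelse(se > 0, m / se, NaN)
  df <- n - 1L
  p <- switch(tail,
    two = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
    greater = stats::pt(tval, df, lower.tail = FALSE),
    less = stats::pt(tval, df))
  list(t = tval, p = p, df = df, mean = m)
}

# Sign-flip t statistics for all permutations at once.
# M: subjects x voxels (already centered under H0); S: n_perm x subjects of +-1.
.signflip_t <- function(M, S) {
  n <- nrow(M)
  ss <- colSums(M^2)
  mean_p <- (S %*% M) / n
  var_p <- sweep(-n * mean_p^2, 2L, ss, "+") / (n - 1)
  var_p[var_p < 0] <- 0
  se <- sqrt(var_p / n)
  tmat <- mean_p / se
  tmat[se == 0] <- NaN
  tmat
}

#' Cluster-extent FWE correction by sign-flip permutation
#'
#' Per-voxel one-sample t maps are thresholded at the t quantile matching
#' `voxel_p`; suprathreshold voxels are clustered; the null distribution of
#' the maximum cluster size is built by randomly flipping the sign of each
#' subject's (mean-zero under H0) map. A cluster survives when
#' `(1 + #\{null >= size\}) / (n_perm + 1) <= cluster_alpha`.
#'
#' @param subject_maps Subjects x voxels matrix of contrast values (voxels =
#'   in-mask voxels in linear order).
#' @param grid A [volume_grid()] describing the full volume.
#' @param mask Optional logical array; defaults to the whole grid. `ncol`
#'   of `subject_maps` must equal the mask size.
#' @param voxel_p Cluster-forming voxel threshold as a p-value (default 0.001).
#' @param cluster_alpha FWE level for cluster extent (default 0.05).
#' @param n_perm Number of sign-flip resamples (>= 1; < 100 warns).
#' @param connectivity Cluster connectivity (default 18).
#' @param tail `"greater"` (default, positive effects) or `"two"`.
#' @param mu Null mean subtracted from the maps before testing.
#' @param seed RNG seed for the sign flips.
#' @return Object of class `group_stat_map`: `t` (vector over mask voxels),
#'   `df`, `t_threshold`, `clusters` data frame (`size`, `p_fwe`,
#'   `survives`, `peak_stat`, peak mm coordinates), `null_max_sizes`, plus
#'   the grid/mask needed to rebuild full maps via [group_map_volume()].
#' @export
cluster_fwe_permutation <- function(subject_maps, grid, mask = NULL,
                                    voxel_p = 0.001, cluster_alpha = 0.05,
                                    n_perm = 1000, connectivity = 18L,
                                    tail = c("greater", "two"), mu = 0,
                                    seed = 1L) {
  tail <- match.arg(tail)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (n_perm < 100) warning("n_perm < 100 gives a coarse null distribution")
  M <- sweep(as.matrix(subject_maps), 2L, mu)
  n <- nrow(M)
  if (n < 2L) stop("at least 2 subjects are required")
  if (n_perm > 2^n)
    warning("n_perm exceeds the number of distinct sign-flips (2^n)")
  mask_lin <- if (is.null(mask)) seq_len(prod(grid$shape)) else which(as.logical(mask))
  if (ncol(M) != length(mask_lin))
    stop("subject_maps columns must match the mask size")
  df <- n - 1L
  thr <- if (tail == "greater") stats::qt(1 - voxel_p, df) else stats::qt(1 - voxel_p / 2, df)
  stat_of <- function(tmat) if (tail == "greater") tmat else abs(tmat)
  t_obs <- .signflip_t(M, matrix(1, 1L, n))[1L, ]
  s_obs <- stat_of(t_obs)
  supra <- which(!is.na(s_obs) & s_obs > thr)
  obs_clusters <- list()
  if (length(supra)) {
    idx <- .vox_unlinear(mask_lin[supra], grid$shape)
    lab <- .connected_components(idx, grid$shape, connectivity)
    for (l in seq_len(max(lab))) {
      rows <- which(lab == l)
      pk <- rows[which.max(s_obs[supra[rows]])]
      obs_clusters[[l]] <- list(size = length(rows),
                                voxels = idx[rows, , drop = FALSE],
                                mask_cols = supra[rows],
                                peak_stat = t_obs[supra[pk]],
                                peak_mm = index_to_mm(grid, idx[pk, , drop = FALSE]))
    }
  }
  set.seed(seed)
  null_max <- integer(n_perm)
  block <- 200L
  done <- 0L
  while (done < n_perm) {
    b <- min(block, n_perm - done)
    S <- matrix(sample(c(-1, 1), b * n, replace = TRUE), b, n)
    tperm <- stat_of(.signflip_t(M, S))
    supra_mat <- !is.na(tperm) & tperm > thr
    supra_list <- lapply(seq_len(b), function(r) mask_lin[supra_mat[r, ]])
    null_max[done + seq_len(b)] <- .null_max_sizes(supra_list, grid$shape,
                                                   connectivity)
    done <- done + b
  }
  if (length(obs_clusters)) {
    sizes <- vapply(obs_clusters, `[[`, numeric(1), "size")
    p_fwe <- vapply(sizes, function(s) (1 + sum(null_max >= s)) / (n_perm + 1), numeric(1))
    clusters <- data.frame(
      cluster = seq_along(sizes), size = sizes, p_fwe = p_fwe,
      survives = p_fwe <= cluster_alpha,
      peak_stat = vapply(obs_clusters, `[[`, numeric(1), "peak_stat"),
      x_mm = vapply(obs_clusters, function(cl) cl$peak_mm[1], numeric(1)),
      y_mm = vapply(obs_clusters, function(cl) cl$peak_mm[2], numeric(1)),
      z_mm = vapply(obs_clusters, function(cl) cl$peak_mm[3], numeric(1)))
    ord <- order(-clusters$size, clusters$cluster)
    clusters <- clusters[ord, ]
    obs_clusters <- obs_clusters[ord]
    clusters$cluster <- seq_len(nrow(clusters))
  } else {
    clusters <- data.frame(cluster = integer(0), size = integer(0),
                           p_fwe = numeric(0), survives = logical(0),
                           peak_stat = numeric(0), x_mm = numeric(0),
                           y_mm = numeric(0), z_mm = numeric(0))
  }
  structure(list(t = t_obs, df = df, t_threshold = thr, tail = tail,
                 clusters = clusters, cluster_voxels = obs_clusters,
                 null_max_sizes = null_max, n_perm = n_perm,
                 voxel_p = voxel_p, cluster_alpha = cluster_alpha,
                 grid = grid, mask_lin = mask_lin),
            class = "group_stat_map")
}

#' @export
print.group_stat_map <- function(x, ...) {
  cat("group_stat_map: df =", x$df, ", voxel p <", x$voxel_p,
      "(t >", signif(x$t_threshold, 4), "),", nrow(x$clusters), "clusters,",
      sum(x$clusters$survives), "surviving at cluster alpha", x$cluster_alpha, "\n")
  invisible(x)
}

#' Rebuild a full-volume map from a masked group result
#'
#' @param x A `group_stat_map` (or any list with `grid`, `mask_lin`).
#' @param values Values over mask voxels (defaults to the t map).
#' @param surviving_only If TRUE, zero out voxels outside surviving clusters.
#' @return A [volume_map()].
#' @export
group_map_volume <- function(x, values = x$t, surviving_only = FALSE) {
  vals <- rep(NA_real_, prod(x$grid$shape))
  vals[x$mask_lin] <- values
  if (surviving_only) {
    keep <- rep(FALSE, prod(x$grid$shape))
    surv <- which(x$clusters$survives)
    for (ci in surv)
      keep[x$mask_lin[x$cluster_voxels[[ci]]$mask_cols]] <- TRUE
    vals[!keep] <- 0
    vals[setdiff(seq_along(vals), x$mask_lin)] <- NA_real_
  }
  volume_map(vals, x$grid)
}

#' Factorial ANOVA on ROI betas
#'
#' Fits a fully crossed fixed-effects factorial linear model of mean ROI beta
#' on the supplied factors (face x species, optionally x side) and returns
#' the F test for every main effect and interaction.
#'
#' @param data Data frame with a numeric `beta` column and factor columns.
#' @param factors Character vector of factor column names (2 or 3 of
#'   `"face"`, `"species"`, `"side"`).
#' @return Data frame with `effect`, `df1`, `df2`, `F`, `p`.
#' @export
roi_factorial_anova <- function(data, factors = c("face", "species")) {
  if (!all(factors %in% names(data))) stop("missing factor columns")
  for (f in factors) data[[f]] <- factor(data[[f]])
  cells <- table(data[factors])
  if (any(cells == 0) || any(vapply(data[factors], nlevels, 1L) < 2L))
    stop("empty design cells")
  if (length(unique(as.vector(cells))) != 1L)
    warning("unbalanced design cells; Type I sums of squares in model order")
  form <- stats::as.formula(paste("beta ~", paste(factors, collapse = " * ")))
  fit <- stats::aov(form, data = data)
  tab <- summary(fit)[[1]]
  effects <- trimws(rownames(tab))
  keep <- effects != "Residuals"
  data.frame(effect = effects[keep],
             df1 = tab$Df[keep],
             df2 = tab$Df[!keep],
             F = tab$`F value`[keep],
             p = tab$`Pr(>F)`[keep])
}

#' Parametric modulation analysis
#'
#' Adds a per-block parametric modulator to the first-level design: block
#' boxcars scaled by the mean-centered property value, HRF-convolved, and
#' orthogonalized against the parent (unmodulated) block regressor. Returns
#' the modulator beta per voxel.
#'
#' @param y A `bold_run` or volumes x voxels matrix.
#' @param events Block events (one row per block).
#' @param property Numeric vector, one value per event row.
#' @param n_volumes,tr_s Run geometry.
#' @param motion,highpass_s Passed to [build_design_matrix()].
#' @param mask Optional mask (for `bold_run` input).
#' @return List with `beta_mod` (modulator beta per voxel), `flagged`
#'   (TRUE when the centered property is constant, in which case betas are 0),
#'   and the `fit`.
#' @export
parametric_modulation <- function(y, events, property, n_volumes, tr_s,
                                  motion = NULL, highpass_s = 128, mask = NULL) {
  if (length(property) != nrow(events))
    stop("need exactly one property value per block")
  X <- build_design_matrix(events, n_volumes, tr_s, motion = motion,
                           highpass_s = highpass_s)
  centered <- property - mean(property)
  if (all(abs(centered) < 1e-12)) {
    nvox <- if (inherits(y, "bold_run")) {
      if (is.null(mask)) prod(y$grid$shape) else sum(mask)
    } else ncol(y)
    return(list(beta_mod = rep(0, nvox), flagged = TRUE, fit = NULL))
  }
  mod <- numeric(n_volumes)
  for (b in seq_len(nrow(events)))
    mod <- mod + centered[b] *
      .convolve_events(events$onset[b], events$duration[b], n_volumes, tr_s)
  parent <- .convolve_events(events$onset, events$duration, n_volumes, tr_s)
  mod <- mod - parent * sum(mod * parent) / sum(parent^2)
  Xm <- cbind(unclass(X), modulator = mod)
  attr(Xm, "tr_s") <- tr_s
  fit <- fit_glm(y, Xm, mask = mask)
  list(beta_mod = fit$beta["modulator", ], flagged = FALSE, fit = fit)
}

#' Group test of modulator betas with Benjamini-Hochberg correction
#'
#' One-sample t test of mean modulator beta against zero per planned test,
#' with step-up false-discovery-rate correction across tests (the design
#' calls for 23 planned region-by-property tests).
#'
#' @param beta_matrix Subjects x tests matrix of mean modulator betas.
#' @param alpha FDR level (default 0.05).
#' @return Data frame with `test`, `t`, `p`, `p_bh`, `significant`.
#' @export
modulation_group_test <- function(beta_matrix, alpha = 0.05) {
  beta_matrix <- as.matrix(beta_matrix)
  res <- group_onesample_t(beta_matrix, mu = 0, tail = "two")
  p_bh <- stats::p.adjust(res$p, method = "BH")
  data.frame(test = colnames(beta_matrix) %||% paste0("test_", seq_along(res$p)),
             t = res$t, p = res$p, p_bh = p_bh, significant = p_bh <= alpha)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Motion exclusion rule
#'
#' A run is excluded when the range (max minus min) of any translation
#' column strictly exceeds `limit_mm`; a range of exactly `limit_mm` keeps
#' the run.
#'
#' @param motion Numeric matrix with >= 6 columns (translations in mm first).
#' @param limit_mm Exclusion limit in mm (default 3).
#' @return List with `keep` (logical) and `max_range_mm`.
#' @export
motion_exclusion_check <- function(motion, limit_mm = 3) {
  motion <- as.matrix(motion)
  if (ncol(motion) < 6L || !is.numeric(motion) || anyNA(motion))
    stop("motion table must be a numeric matrix with 6 columns")
  trans <- motion[, 1:3, drop = FALSE]
  ranges <- apply(trans, 2L, function(x) diff(range(x)))
  list(keep = max(ranges) <= limit_mm, max_range_mm = max(ranges))
}
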