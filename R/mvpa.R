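# Searchlight MVPA: volume labelling from HRF-convolved condition time
# courses, leave-one-run-out linear-SVM decoding of face-vs-occiput and
# conspecific-vs-heterospecific, and permutation-based group inference.

#' Prepare labelled, detrended, z-scored samples from one run
#'
#' Each condition's block onsets are convolved with the canonical HRF; a
#' volume is labelled with condition c when c's convolved value exceeds 50%
#' of its own maximum and strictly exceeds every other condition's value
#' (transition volumes stay unlabelled). Each voxel's time course is then
#' linearly detrended and z-scored over all volumes of the run.
#'
#' @param bold A `bold_run`, or a volumes x voxels matrix.
#' @param events Run events (`onset`, `duration`, `trial_type`).
#' @param tr_s Repetition time, seconds.
#' @param run Run identifier carried through to cross-validation.
#' @param mask Optional logical array (for `bold_run` input).
#' @return Object of class `labeled_ts`: `x` (volumes x voxels), `labels`
#'   (character, NA = unlabelled), `run`.
#' @export
prepare_samples <- function(bold, events, tr_s, run = 1L, mask = NULL) {
  if (inherits(bold, "bold_run")) {
    mask_lin <- if (is.null(mask)) seq_len(prod(bold$grid$shape)) else which(as.logical(mask))
    X <- .bold_matrix(bold, mask_lin)
  } else X <- as.matrix(bold)
  n <- nrow(X)
  conv <- sapply(.CONDITIONS, function(cond) {
    rows <- events$trial_type == cond
    if (!any(rows)) return(rep(-Inf, n))
    .convolve_events(events$onset[rows], events$duration[rows], n, tr_s)
  })
  labels <- rep(NA_character_, n)
  top <- max.col(conv, ties.method = "first")
  for (v in seq_len(n)) {
    cnd <- top[v]
    val <- conv[v, cnd]
    if (!is.finite(val)) next
    others <- conv[v, -cnd]
    if (val > 0.5 * max(conv[, cnd]) && all(val > others))
      labels[v] <- .CONDITIONS[cnd]
  }
  if (!any(!is.na(labels))) stop("no volume could be labelled (degenerate timing)")
  tt <- cbind(1, seq_len(n))
  X <- X - tt %*% solve(crossprod(tt), crossprod(tt, X))  # linear detrend
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2L, mu)^2) * n / (n - 1))
  X <- sweep(X, 2L, mu)
  nz <- sdv > 1e-10          # flat/detrended-to-zero voxels stay at 0
  X[, !nz] <- 0
  X[, nz] <- sweep(X[, nz, drop = FALSE], 2L, sdv[nz], "/")
  structure(list(x = X, labels = labels, run = run), class = "labeled_ts")
}

#' Leave-one-run-out cross-validation folds
#'
#' @param runs Vector of run identifiers (>= 2 distinct).
#' @return List of folds, each `list(train = , test = )` of run ids; every
#'   run is the test set exactly once.
#' @export
loro_cv_splits <- function(runs) {
  u <- unique(runs)
  if (length(u) < 2L) stop("leave-one-run-out needs at least 2 runs")
  lapply(u, function(r) list(train = setdiff(u, r), test = r))
}

#' Pool the four conditions into a binary task
#'
#' `FvsO`: \{CF, HeF\} vs \{CO, HeO\}; `CvsHe`: \{CF, CO\} vs \{HeF, HeO\}.
#'
#' @param labels Character condition labels (NA allowed).
#' @param task `"FvsO"` or `"CvsHe"`.
#' @return Factor with levels `c("neg", "pos")` (NA where unlabelled).
#' @export
pool_task_labels <- function(labels, task = c("FvsO", "CvsHe")) {
  task <- match.arg(task)
  pos <- if (task == "FvsO") c("CF", "HeF") else c("CF", "CO")
  out <- rep(NA_character_, length(labels))
  out[labels %in% pos] <- "pos"
  out[!is.na(labels) & !(labels %in% pos)] <- "neg"
  factor(out, levels = c("neg", "pos"))
}

#' Train and test a linear support vector machine
#'
#' Linear maximum-margin classifier (libsvm C-classification, cost 1, no
#' internal rescaling) with class weights inversely proportional to training
#' class frequencies.
#'
#' @param train_x,train_y Training samples (matrix) and binary factor labels.
#' @param test_x,test_y Test samples and labels.
#' @return Fraction of correctly classified test samples.
#' @export
train_test_lsvm <- function(train_x, train_y, test_x, test_y) {
  train_y <- droplevels(factor(train_y))
  if (nlevels(train_y) < 2L) stop("training set contains a single class")
  wts <- 1 / table(train_y)
  wts <- wts / mean(wts)
  fit <- e1071::svm(x = as.matrix(train_x), y = train_y, kernel = "linear",
                    cost = 1, scale = FALSE, class.weights = wts)
  pred <- stats::predict(fit, as.matrix(test_x))
  mean(as.character(pred) == as.character(test_y))
}

# Cross-validated accuracy for one voxel subset.
.cv_accuracy <- function(X, y, runs, cols, folds) {
  acc <- vapply(folds, function(fold) {
    tr <- runs %in% fold$train & !is.na(y)
    te <- runs == fold$test & !is.na(y)
    if (!any(te) || length(unique(y[tr])) < 2L) return(NA_real_)
    train_test_lsvm(X[tr, cols, drop = FALSE], y[tr],
                    X[te, cols, drop = FALSE], y[te])
  }, numeric(1))
  mean(acc, na.rm = TRUE)
}

#' Searchlight decoding accuracy map
#'
#' For every in-mask voxel, trains and tests the linear SVM on the voxels of
#' a surrounding mm sphere (clipped to the mask) with leave-one-run-out
#' cross-validation, projecting the mean accuracy back to the center.
#' Centers whose sphere holds fewer than `min_voxels` voxels get NA.
#'
#' @param samples List of `labeled_ts`, one per run (see
#'   [prepare_samples()]); voxel columns must correspond to `mask`'s
#'   in-mask voxels in linear order.
#' @param grid The arm's [volume_grid()].
#' @param mask Logical array (the visually-responsive search space);
#'   defaults to the full grid.
#' @param radius_mm Searchlight radius in mm.
#' @param task `"FvsO"` or `"CvsHe"`.
#' @param min_voxels Minimum sphere size (default 2; radius 0 with
#'   `min_voxels = 1` gives single-voxel decoding).
#' @return A [volume_map()] of accuracies with attributes `n_folds`, `task`.
#' @export
searchlight_accuracy <- function(samples, grid, mask = NULL, radius_mm = 4,
                                 task = c("FvsO", "CvsHe"), min_voxels = 2L) {
  task <- match.arg(task)
  if (is.null(mask)) mask <- array(TRUE, grid$shape)
  mask <- array(as.logical(mask), grid$shape)
  mask_lin <- which(mask)
  if (!length(mask_lin)) stop("empty mask")
  X <- do.call(rbind, lapply(samples, `[[`, "x"))
  labels <- unlist(lapply(samples, `[[`, "labels"))
  runs <- unlist(lapply(samples, function(s) rep(s$run, nrow(s$x))))
  if (ncol(X) != length(mask_lin))
    stop("sample columns must match the mask size")
  y <- pool_task_labels(labels, task)
  folds <- loro_cv_splits(unique(runs))
  col_of <- integer(prod(grid$shape))
  col_of[mask_lin] <- seq_along(mask_lin)
  centers <- .vox_unlinear(mask_lin, grid$shape)
  center_mm <- index_to_mm(grid, centers)
  vals <- rep(NA_real_, prod(grid$shape))
  for (ci in seq_along(mask_lin)) {
    sph <- sphere_voxels(grid, center_mm[ci, ], radius_mm, mask)
    cols <- col_of[attr(sph, "linear")]
    if (length(cols) < min_voxels) next
    vals[mask_lin[ci]] <- .cv_accuracy(X, y, runs, cols, folds)
  }
  out <- volume_map(vals, grid, mask = NULL)
  attr(out, "n_folds") <- length(folds)
  attr(out, "task") <- task
  out
}

#' Shuffle condition labels within runs (chance-level control)
#'
#' Returns the sample list with block-condition labels randomly permuted
#' within each run, preserving per-condition counts.
#'
#' @param samples List of `labeled_ts`.
#' @param seed RNG seed.
#' @export
shuffle_sample_labels <- function(samples, seed = 1L) {
  set.seed(seed)
  lapply(samples, function(s) {
    lab <- s$labels
    idx <- which(!is.na(lab))
    s$labels[idx] <- sample(lab[idx])
    s
  })
}

#' Group inference on searchlight accuracy maps
#'
#' The group map is the voxel-wise mean accuracy across subjects. The null
#' is built by sign-flipping each subject's deviation from chance (0.5),
#' which is exact when chance-level accuracy deviations are symmetric.
#' Voxel-level significance uses per-voxel permutation quantiles of the
#' group mean; cluster extents are compared against the maximum cluster
#' size of the thresholded null maps.
#'
#' @param subject_maps Subjects x voxels matrix of accuracies over the mask
#'   (NA centers allowed), or a list of accuracy `volume_map`s.
#' @param grid,mask Volume geometry.
#' @param chance Chance accuracy (default 0.5).
#' @param voxel_p Voxel-level threshold on the permutation p (default 0.01;
#'   must be attainable, i.e. >= 1/(n_perm+1)).
#' @param cluster_alpha Cluster-extent FWE level.
#' @param n_perm Number of sign-flip resamples (< 100 warns).
#' @param connectivity Cluster connectivity.
#' @param seed RNG seed.
#' @return Object of class `group_accuracy_map`: `mean` (group map over
#'   mask), `voxel_p_map`, `clusters` data frame, `null_max_sizes`,
#'   `grid`, `mask_lin`.
#' @export
group_accuracy_inference <- function(subject_maps, grid, mask = NULL,
                                     chance = 0.5, voxel_p = 0.01,
                                     cluster_alpha = 0.05, n_perm = 1000,
                                     connectivity = 18L, seed = 1L) {
  if (is.list(subject_maps) && inherits(subject_maps[[1]], "volume_map")) {
    mask_lin0 <- if (is.null(mask)) seq_len(prod(grid$shape)) else which(as.logical(mask))
    subject_maps <- t(vapply(subject_maps,
                             function(m) as.numeric(m$values)[mask_lin0],
                             numeric(length(mask_lin0))))
  }
  M <- as.matrix(subject_maps) - chance
  n <- nrow(M)
  if (n < 2L) stop("at least 2 subjects are required")
  if (n_perm < 100) warning("n_perm < 100 gives a coarse null distribution")
  if (voxel_p < 1 / (n_perm + 1))
    stop("voxel_p is unattainable with this n_perm")
  mask_lin <- if (is.null(mask)) seq_len(prod(grid$shape)) else which(as.logical(mask))
  if (ncol(M) != length(mask_lin))
    stop("subject_maps columns must match the mask size")
  n_per_voxel <- colSums(!is.na(M))
  M0 <- M; M0[is.na(M0)] <- 0
  usable <- n_per_voxel >= 2L
  obs <- colSums(M0) / pmax(n_per_voxel, 1L)
  obs[!usable] <- NA_real_
  set.seed(seed)
  S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  null_means <- sweep(S %*% M0, 2L, pmax(n_per_voxel, 1L), "/")
  null_means[, !usable] <- NA_real_
  k <- max(1L, floor(voxel_p * (n_perm + 1)))
  thr <- apply(null_means, 2L, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(Inf)
    -sort(-x, partial = min(k, length(x)))[min(k, length(x))]
  })
  exceed <- sweep(null_means, 2L, obs, ">=")
  voxel_p_map <- (1 + colSums(exceed, na.rm = TRUE)) / (n_perm + 1)
  voxel_p_map[is.na(obs)] <- NA_real_
  supra_obs <- which(!is.na(obs) & obs > thr)
  obs_clusters <- list()
  if (length(supra_obs)) {
    idx <- .vox_unlinear(mask_lin[supra_obs], grid$shape)
    lab <- .connected_components(idx, grid$shape, connectivity)
    for (l in seq_len(max(lab))) {
      rows <- which(lab == l)
      pk <- rows[which.max(obs[supra_obs[rows]])]
      obs_clusters[[l]] <- list(size = length(rows),
                                mask_cols = supra_obs[rows],
                                voxels = idx[rows, , drop = FALSE],
                                peak_acc = obs[supra_obs[pk]] + chance,
                                peak_mm = index_to_mm(grid, idx[pk, , drop = FALSE]))
    }
  }
  null_supra <- sweep(null_means, 2L, thr, ">")
  null_supra[is.na(null_supra)] <- FALSE
  supra_list <- lapply(seq_len(n_perm), function(r) mask_lin[null_supra[r, ]])
  null_max <- .null_max_sizes(supra_list, grid$shape, connectivity)
  if (length(obs_clusters)) {
    sizes <- vapply(obs_clusters, `[[`, numeric(1), "size")
    p_fwe <- vapply(sizes, function(s) (1 + sum(null_max >= s)) / (n_perm + 1), numeric(1))
    clusters <- data.frame(
      cluster = seq_along(sizes), size = sizes, p_fwe = p_fwe,
      survives = p_fwe <= cluster_alpha,
      peak_accuracy = vapply(obs_clusters, `[[`, numeric(1), "peak_acc"),
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
                           peak_accuracy = numeric(0), x_mm = numeric(0),
                           y_mm = numeric(0), z_mm = numeric(0))
  }
  structure(list(mean = obs + chance, voxel_p_map = voxel_p_map,
                 clusters = clusters, cluster_voxels = obs_clusters,
                 null_max_sizes = null_max, n_perm = n_perm, chance = chance,
                 voxel_p = voxel_p, cluster_alpha = cluster_alpha,
                 n_subjects_per_voxel = n_per_voxel,
                 grid = grid, mask_lin = mask_lin),
            class = "group_accuracy_map")
}

#' @export
print.group_accuracy_map <- function(x, ...) {
  cat("group_accuracy_map: mean accuracy",
      signif(mean(x$mean, na.rm = TRUE), 3), "over", length(x$mask_lin),
      "voxels;", nrow(x$clusters), "clusters,", sum(x$clusters$survives),
      "surviving\n")
  invisible(x)
}

#' Per-cluster accuracy histogram data
#'
#' Subject accuracies at each surviving cluster's peak voxel (the per-cluster
#' distribution usually shown as histograms alongside group maps).
#'
#' @param result A `group_accuracy_map`.
#' @param subject_maps The subjects x voxels accuracy matrix used for the
#'   inference.
#' @return Data frame with `cluster`, `subject`, `accuracy`.
#' @export
cluster_accuracy_histograms <- function(result, subject_maps) {
  surv <- which(result$clusters$survives)
  if (!length(surv)) return(data.frame(cluster = integer(0),
                                       subject = integer(0),
                                       accuracy = numeric(0)))
  do.call(rbind, lapply(surv, function(ci) {
    cols <- result$cluster_voxels[[ci]]$mask_cols
    peak_col <- cols[which.max(result$mean[cols])]
    data.frame(cluster = ci, subject = seq_len(nrow(subject_maps)),
               accuracy = subject_maps[, peak_col])
  }))
}
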