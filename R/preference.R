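# Conspecific-preference versus face-preference analysis: per-voxel labels,
# the global proportion statistic a/(a+b), block-relabelling permutation
# inference, and nonparametric group tests on binary preference maps.

.C_WEIGHTS <- c(CF = 1, CO = 1, HeF = -1, HeO = -1)  # C > He
.F_WEIGHTS <- c(CF = 1, CO = -1, HeF = 1, HeO = -1)  # F > O

#' Per-voxel preference labels
#'
#' +1 where the conspecific>heterospecific beta is positive and exceeds the
#' face>occiput beta; -1 where the face>occiput beta is positive and exceeds
#' the conspecific beta; 0 otherwise (including ties of positive betas).
#' Swapping the two maps exchanges +1 and -1 and fixes 0.
#'
#' @param beta_c,beta_f Numeric vectors/arrays (same length) of the C>He and
#'   F>O contrast values.
#' @param mask Optional logical vector; out-of-mask voxels get NA.
#' @return Integer vector in \{-1, 0, +1\} (NA outside mask).
#' @export
voxel_preference_labels <- function(beta_c, beta_f, mask = NULL) {
  if (length(beta_c) != length(beta_f)) stop("contrast map lengths differ")
  lab <- integer(length(beta_c))
  lab[beta_c > 0 & beta_c > beta_f] <- 1L
  lab[beta_f > 0 & beta_f > beta_c] <- -1L
  if (!is.null(mask)) lab[!as.logical(mask)] <- NA_integer_
  lab
}

#' Preference proportion from group-level contrast maps
#'
#' Counts conspecific-preferring voxels (a) and face-preferring voxels (b)
#' by the labelling rule and returns the proportion a/(a+b).
#'
#' @inheritParams voxel_preference_labels
#' @return List with `a`, `b`, `proportion`.
#' @export
preference_proportion <- function(beta_c, beta_f, mask = NULL) {
  lab <- voxel_preference_labels(beta_c, beta_f, mask)
  a <- sum(lab == 1L, na.rm = TRUE)
  b <- sum(lab == -1L, na.rm = TRUE)
  if (a + b == 0L) stop("no preferring voxels: a + b = 0")
  list(a = a, b = b, proportion = a / (a + b))
}

# Precompute, per subject x run, everything needed to re-estimate condition
# betas under arbitrary block labels: nuisance-residualized per-block
# regressors and data. Condition betas for an assignment matrix A (blocks x 4)
# are then solve(crossprod(Bt %*% A)) %*% t(Bt %*% A) %*% Yt.
.relabel_machinery <- function(arm, config, mask_lin = NULL) {
  n <- config$n_volumes
  tr <- config$tr_s
  if (is.null(mask_lin)) mask_lin <- seq_len(prod(arm$grid$shape))
  lapply(arm$subjects, function(sub) {
    lapply(sub$runs, function(run) {
      ev <- run$events
      nb <- nrow(ev)
      B <- sapply(seq_len(nb), function(b)
        .convolve_events(ev$onset[b], ev$duration[b], n, tr))
      k <- as.integer(floor(2 * n * tr / 128))
      N <- cbind(.dct_basis(n, k), run$motion, 1)
      qn <- qr(N)
      Bt <- qr.resid(qn, B)
      Yt <- qr.resid(qn, .bold_matrix(run$bold, mask_lin))
      A_true <- outer(ev$trial_type, .CONDITIONS, "==") * 1
      # precomputed cross-products make a relabelled refit O(blocks^2) only
      list(BtB = crossprod(Bt), BtY = crossprod(Bt, Yt),
           A_true = A_true, n_blocks = nb, n_voxels = ncol(Yt))
    })
  })
}

# Group-level C>He and F>O contrast maps for one labelling of every run.
# `assign_fun(run_mach)` returns the blocks x 4 assignment matrix to use.
.group_contrasts <- function(mach, assign_fun) {
  con_c <- NULL; con_f <- NULL
  nsub <- length(mach)
  for (sub in mach) {
    sub_c <- NULL; sub_f <- NULL
    for (run in sub) {
      A <- assign_fun(run)
      G <- solve(t(A) %*% run$BtB %*% A, t(A) %*% run$BtY)  # 4 x voxels betas
      cc <- drop(.C_WEIGHTS %*% G)
      cf <- drop(.F_WEIGHTS %*% G)
      sub_c <- if (is.null(sub_c)) cc else sub_c + cc
      sub_f <- if (is.null(sub_f)) cf else sub_f + cf
    }
    nr <- length(sub)
    con_c <- if (is.null(con_c)) sub_c / nr else con_c + sub_c / nr
    con_f <- if (is.null(con_f)) sub_f / nr else con_f + sub_f / nr
  }
  list(beta_c = con_c / nsub, beta_f = con_f / nsub)
}

.random_assignment <- function(n_blocks) {
  conds <- sample(rep(.CONDITIONS, n_blocks / 4L))
  outer(conds, .CONDITIONS, "==") * 1
}

#' Permutation test of the preference proportion
#'
#' Recomputes the group-level preference proportion under `n_perm` random
#' relabellings of the stimulus blocks (labels permuted within each run,
#' preserving the balanced 3-per-condition design, with first-level betas
#' refitted each time) and compares the observed proportion against this
#' "no signal" null. Two-sided p uses distance from 0.5; the one-sided p
#' (conspecific direction) is also returned.
#'
#' @param arm One arm of a [simulate_group()] study (or any list with
#'   `subjects` carrying `runs` of `bold`, `events`, `motion`, plus `grid`).
#' @param config The study's [sim_config()].
#' @param mask Optional logical array over the arm's grid.
#' @param n_perm Number of resamples (default 10000).
#' @param seed RNG seed.
#' @return List of class `proportion_result`: `a`, `b`, `proportion`,
#'   `p_two`, `p_one`, `n_perm`, `seed`, `null_proportions`.
#' @export
proportion_permutation_test <- function(arm, config, mask = NULL,
                                        n_perm = 10000, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  mask_lin <- if (is.null(mask)) NULL else which(as.logical(mask))
  mach <- .relabel_machinery(arm, config, mask_lin)
  obs_maps <- .group_contrasts(mach, function(run) run$A_true)
  obs <- preference_proportion(obs_maps$beta_c, obs_maps$beta_f)
  set.seed(seed)
  null_prop <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    maps <- .group_contrasts(mach, function(run) .random_assignment(run$n_blocks))
    lab <- voxel_preference_labels(maps$beta_c, maps$beta_f)
    a <- sum(lab == 1L); b <- sum(lab == -1L)
    null_prop[p] <- if (a + b > 0L) a / (a + b) else 0.5
  }
  p_two <- (1 + sum(abs(null_prop - 0.5) >= abs(obs$proportion - 0.5) - 1e-12)) /
    (n_perm + 1)
  p_one <- (1 + sum(null_prop >= obs$proportion - 1e-12)) / (n_perm + 1)
  structure(list(a = obs$a, b = obs$b, proportion = obs$proportion,
                 p_two = p_two, p_one = p_one, n_perm = n_perm, seed = seed,
                 null_proportions = null_prop),
            class = "proportion_result")
}

#' @export
print.proportion_result <- function(x, ...) {
  cat(sprintf("preference proportion a/(a+b) = %d/(%d+%d) = %.3f; two-sided p = %.4g (one-sided %.4g), %d resamples\n",
              x$a, x$a, x$b, x$proportion, x$p_two, x$p_one, x$n_perm))
  invisible(x)
}

#' Per-subject preference label maps
#'
#' @inheritParams proportion_permutation_test
#' @return Subjects x voxels integer matrix of labels.
#' @export
subject_preference_labels <- function(arm, config, mask = NULL) {
  mask_lin <- if (is.null(mask)) NULL else which(as.logical(mask))
  mach <- .relabel_machinery(arm, config, mask_lin)
  t(vapply(mach, function(sub) {
    maps <- .group_contrasts(list(sub), function(run) run$A_true)
    as.numeric(voxel_preference_labels(maps$beta_c, maps$beta_f))
  }, numeric(mach[[1]][[1]]$n_voxels)))
}

#' Null mean of preference labels under block relabelling
#'
#' Empirical mean of each subject's label map over `m` within-subject random
#' block relabellings; the reference the group preference test compares
#' against.
#'
#' @inheritParams proportion_permutation_test
#' @param m Number of relabellings (default 100).
#' @return Subjects x voxels matrix of null label means.
#' @export
preference_null_mean <- function(arm, config, mask = NULL, m = 100, seed = 1L) {
  mask_lin <- if (is.null(mask)) NULL else which(as.logical(mask))
  mach <- .relabel_machinery(arm, config, mask_lin)
  set.seed(seed)
  t(vapply(mach, function(sub) {
    acc <- numeric(sub[[1]]$n_voxels)
    for (i in seq_len(m)) {
      maps <- .group_contrasts(list(sub), function(run) .random_assignment(run$n_blocks))
      acc <- acc + voxel_preference_labels(maps$beta_c, maps$beta_f)
    }
    acc / m
  }, numeric(mach[[1]][[1]]$n_voxels)))
}

#' Group inference on preference maps
#'
#' One-tailed one-sample t tests of subject preference labels against the
#' permutation-derived null mean, run separately for the conspecific (+1)
#' and face (-1) directions, each with sign-flip cluster-extent FWE
#' correction.
#'
#' @param subject_labels Subjects x voxels matrix from
#'   [subject_preference_labels()].
#' @param null_mean Scalar or subjects x voxels matrix from
#'   [preference_null_mean()] (default 0).
#' @param grid,mask Volume geometry (see [cluster_fwe_permutation()]).
#' @param voxel_p,cluster_alpha,n_perm,connectivity,seed Passed through.
#' @return List with elements `conspecific` and `face`, each a
#'   `group_stat_map`.
#' @export
group_preference_map <- function(subject_labels, null_mean = 0, grid,
                                 mask = NULL, voxel_p = 0.005,
                                 cluster_alpha = 0.05, n_perm = 1000,
                                 connectivity = 18L, seed = 1L) {
  D <- as.matrix(subject_labels) - null_mean
  if (nrow(D) < 2L) stop("at least 2 subjects are required")
  list(
    conspecific = cluster_fwe_permutation(D, grid, mask, voxel_p, cluster_alpha,
                                          n_perm, connectivity, "greater",
                                          seed = seed),
    face = cluster_fwe_permutation(-D, grid, mask, voxel_p, cluster_alpha,
                                   n_perm, connectivity, "greater",
                                   seed = seed + 1L))
}
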