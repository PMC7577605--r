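# Shared small-scale fixtures, built in code at test time.

tiny_config <- function(n_subjects = c(A = 3, B = 3),
                        shape = c(8, 8, 4), n_runs = 2, ...) {
  sim_config(n_subjects = n_subjects,
             grid_A = volume_grid(shape), grid_B = volume_grid(shape),
             n_runs = n_runs, ...)
}

# Brute-force sphere membership over all in-mask voxels (independent oracle).
brute_sphere <- function(grid, center_mm, radius_mm, mask = NULL) {
  all_idx <- as.matrix(expand.grid(i = 0:(grid$shape[1] - 1),
                                   j = 0:(grid$shape[2] - 1),
                                   k = 0:(grid$shape[3] - 1)))
  mm <- index_to_mm(grid, all_idx)
  d <- sqrt(rowSums(sweep(mm, 2, center_mm)^2))
  keep <- d <= radius_mm + 1e-9
  if (!is.null(mask)) {
    lin <- 1 + all_idx[, 1] + grid$shape[1] * (all_idx[, 2] + grid$shape[2] * all_idx[, 3])
    keep <- keep & as.logical(mask)[lin]
  }
  all_idx[keep, , drop = FALSE]
}

# Hand sums-of-squares two-way ANOVA oracle (balanced designs).
ss_anova_2x2 <- function(value, f1, f2) {
  f1 <- factor(f1); f2 <- factor(f2)
  gm <- mean(value)
  ss_a <- sum(tapply(value, f1, length) * (tapply(value, f1, mean) - gm)^2)
  ss_b <- sum(tapply(value, f2, length) * (tapply(value, f2, mean) - gm)^2)
  cellm <- tapply(value, list(f1, f2), mean)
  celln <- tapply(value, list(f1, f2), length)
  am <- tapply(value, f1, mean); bm <- tapply(value, f2, mean)
  ss_ab <- sum(celln * (cellm - outer(am, rep(1, nlevels(f2))) -
                          outer(rep(1, nlevels(f1)), bm) + gm)^2)
  fit <- value - cellm[cbind(f1, f2)]
  ss_e <- sum(fit^2)
  df_a <- nlevels(f1) - 1; df_b <- nlevels(f2) - 1
  df_ab <- df_a * df_b
  df_e <- length(value) - nlevels(f1) * nlevels(f2)
  list(F_a = (ss_a / df_a) / (ss_e / df_e),
       F_b = (ss_b / df_b) / (ss_e / df_e),
       F_ab = (ss_ab / df_ab) / (ss_e / df_e))
}

# Uniform solid-colour test frame.
solid_frame <- function(rgb, h = 4, w = 4) {
  arr <- array(0, c(h, w, 3))
  for (c in 1:3) arr[, , c] <- rgb[c]
  arr
}
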