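# Synthetic two-arm study generator. Arm A mirrors a population whose visual
# cortex is dominated by conspecific-preference (no face effect); arm B a
# population with widespread face-preference. Every generator is a pure
# function of (config, seed).

#' Simulation configuration
#'
#' Defaults encode the block-design study the package targets: 4 conditions x
#' 12 blocks/run x 6 runs, blocks of four 2-s stimuli preceded by 10-s
#' fixation (226-s schedule), 75 volumes at TR 3.2 s, with arm sizes 20 (A)
#' and 30 (B). Grids stand in for a visually-responsive cortical patch at
#' 2 mm resolution, not a whole brain.
#'
#' @param n_subjects Named vector `c(A = , B = )`.
#' @param grid_A,grid_B Per-arm [volume_grid()]s.
#' @param n_runs,n_blocks_per_run,stimuli_per_block Number of runs, blocks
#'   per run (divisible by 4), stimuli per block.
#' @param stimulus_duration_s,fixation_s,tr_s Timing parameters, seconds.
#' @param n_volumes Volumes per run; `n_volumes * tr_s` must cover the
#'   scheduled run length.
#' @param baseline Mean BOLD baseline (arbitrary units).
#' @param noise_sd Marginal SD of the AR(1) Gaussian noise.
#' @param ar1 AR(1) coefficient of the noise (default 0.3).
#' @param drift_amplitude SD of the random linear + slow-cosine drift
#'   coefficients (same units as `noise_sd`).
#' @param visual_amplitude Response amplitude of all conditions across the
#'   whole mask (makes the mask "visually responsive").
#' @param species_effect Extra amplitude for conspecific conditions (CF, CO)
#'   inside the species-preference region.
#' @param face_effect Extra amplitude for face conditions (CF, HeF) inside
#'   the face-preference region.
#' @param main_region_fraction Fraction of the x-extent covered by the
#'   dominant preference region (default 0.9, matching the near-total
#'   dominance the analyses are designed to detect).
#' @param motion_amplitude_mm Innovation SD of the random-walk motion
#'   parameters.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_subjects = c(A = 20, B = 30),
                       grid_A = volume_grid(c(16, 16, 10)),
                       grid_B = volume_grid(c(24, 24, 12)),
                       n_runs = 6, n_blocks_per_run = 12, stimuli_per_block = 4,
                       stimulus_duration_s = 2, fixation_s = 10,
                       tr_s = 3.2, n_volumes = 75,
                       baseline = 100, noise_sd = 1, ar1 = 0.3,
                       drift_amplitude = 1,
                       visual_amplitude = 0.6,
                       species_effect = 0.2, face_effect = 0.2,
                       main_region_fraction = 0.9,
                       motion_amplitude_mm = 0.05) {
  cfg <- as.list(environment())
  if (cfg$n_blocks_per_run %% 4 != 0)
    stop("n_blocks_per_run must be divisible by 4 for balanced conditions")
  block_s <- cfg$stimuli_per_block * cfg$stimulus_duration_s
  total_s <- cfg$n_blocks_per_run * (cfg$fixation_s + block_s) + cfg$fixation_s
  if (cfg$n_volumes * cfg$tr_s < total_s - cfg$fixation_s)
    stop("n_volumes * tr_s must cover the scheduled run")
  cfg$block_s <- block_s
  cfg$total_s <- total_s
  structure(cfg, class = "sim_config")
}

.child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1299721) %% 2147483629)
}

# Block-order constraints: within each window of 4 blocks each condition at
# most once, and no immediate repeats anywhere.
.order_valid <- function(conds) {
  n <- length(conds)
  for (w in seq(1L, n, by = 4L))
    if (anyDuplicated(conds[w:min(w + 3L, n)])) return(FALSE)
  !any(conds[-1L] == conds[-n])
}

#' Validate a run's event table against the design constraints
#'
#' Checks balanced condition counts, the window constraint (no condition
#' twice within blocks 1-4, 5-8, 9-12) and the no-immediate-repeat
#' constraint.
#'
#' @param events Events data frame for one run.
#' @param config A [sim_config()].
#' @return TRUE invisibly, or a character vector of violated constraints
#'   with attribute; use [validate_inputs()] for diagnostics.
#' @export
design_constraints_ok <- function(events, config = sim_config()) {
  conds <- events$trial_type[order(events$onset)]
  counts <- table(factor(conds, levels = .CONDITIONS))
  balanced <- all(counts == config$n_blocks_per_run / 4)
  balanced && .order_valid(conds)
}

#' Simulate one run's block schedule
#'
#' Draws a pseudo-random order of the 12 blocks (3 per condition) satisfying
#' both randomization constraints, and lays blocks out as 10-s fixation +
#' 8-s stimulation, with a trailing 10-s fixation (226-s schedule at the
#' defaults).
#'
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @param max_tries Bounded rejection-sampling attempts before erroring.
#' @return Events data frame (`onset`, `duration`, `trial_type`, `block`)
#'   with attribute `total_s`.
#' @export
simulate_design <- function(config = sim_config(), seed = 1L, max_tries = 10000L) {
  set.seed(seed)
  per <- config$n_blocks_per_run / 4L
  pool <- rep(.CONDITIONS, per)
  conds <- NULL
  for (i in seq_len(max_tries)) {
    cand <- sample(pool)
    if (.order_valid(cand)) { conds <- cand; break }
  }
  if (is.null(conds)) stop("could not satisfy randomization constraints")
  onsets <- config$fixation_s +
    (seq_len(config$n_blocks_per_run) - 1L) * (config$fixation_s + config$block_s)
  ev <- data.frame(onset = onsets, duration = config$block_s,
                   trial_type = conds, block = seq_len(config$n_blocks_per_run))
  attr(ev, "total_s") <- config$total_s
  ev
}

# One of six fixed randomization schedules per seed, assigned round-robin to
# subjects; each schedule is a list of n_runs event tables.
.six_schedules <- function(config, seed) {
  lapply(1:6, function(s)
    lapply(seq_len(config$n_runs), function(r)
      simulate_design(config, seed = .child_seed(seed, s * 101L + r))))
}

#' Ground-truth effect maps for one species arm
#'
#' The analysis mask is the full grid ("visually-responsive patch"); all
#' in-mask voxels respond to every condition with `visual_amplitude`. A
#' dominant slab along x (fraction `main_region_fraction`) carries the arm's
#' preference effect: conspecific (CF, CO) amplitude boost in arm A, face
#' (CF, HeF) boost in arm B. A small disjoint slab is reserved as the
#' opposite-preference candidate region (no effect), the remainder is null.
#'
#' @param grid The arm's [volume_grid()].
#' @param arm `"A"` or `"B"`.
#' @param config A [sim_config()].
#' @return List of class `ground_truth`: `amplitude` (voxels x 4 conditions),
#'   `regions` (linear indices: `species_pref`, `face_pref`, `null`),
#'   `mask_lin`, `grid`, `arm`.
#' @export
ground_truth_maps <- function(grid, arm = c("A", "B"), config = sim_config()) {
  arm <- match.arg(arm)
  shape <- grid$shape
  nv <- prod(shape)
  idx <- .vox_unlinear(seq_len(nv), shape)
  cut_main <- ceiling(config$main_region_fraction * shape[1]) - 1L
  main <- idx[, 1] <= cut_main
  small <- !main & idx[, 2] < floor(shape[2] / 2)
  amp <- matrix(config$visual_amplitude, nv, 4L,
                dimnames = list(NULL, .CONDITIONS))
  if (arm == "A") {
    amp[main, c("CF", "CO")] <- amp[main, c("CF", "CO")] + config$species_effect
    regions <- list(species_pref = which(main), face_pref = which(small),
                    null = which(!main & !small))
  } else {
    amp[main, c("CF", "HeF")] <- amp[main, c("CF", "HeF")] + config$face_effect
    regions <- list(species_pref = which(small), face_pref = which(main),
                    null = which(!main & !small))
  }
  structure(list(amplitude = amp, regions = regions,
                 mask_lin = seq_len(nv), grid = grid, arm = arm),
            class = "ground_truth")
}

#' Simulate one BOLD run from a block schedule and amplitude map
#'
#' Forward model: per condition, amplitude times the HRF-convolved block
#' boxcar (the same convolution the design matrix uses), plus a random
#' linear + slow-cosine drift and AR(1) Gaussian noise; a 6-column
#' random-walk motion table is generated alongside. Deterministic given the
#' seed.
#'
#' @param events Run schedule from [simulate_design()].
#' @param amplitude Voxels x 4 matrix (columns CF, CO, HeF, HeO), or a
#'   voxels x 4 x n-th run slice for run-varying amplitudes.
#' @param grid The arm's [volume_grid()].
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @return List with `bold` (a [bold_run()]) and `motion` (n_volumes x 6).
#' @export
simulate_bold_run <- function(events, amplitude, grid, config = sim_config(),
                              seed = 1L) {
  set.seed(seed)
  n <- config$n_volumes
  nv <- prod(grid$shape)
  stopifnot(nrow(amplitude) == nv)
  reg <- sapply(.CONDITIONS, function(cond) {
    rows <- events$trial_type == cond
    if (!any(rows)) return(numeric(n))
    .convolve_events(events$onset[rows], events$duration[rows], n, config$tr_s)
  })
  Y <- reg %*% t(amplitude[, .CONDITIONS, drop = FALSE])
  if (config$drift_amplitude > 0) {
    tt <- seq_len(n) / n - 0.5
    lin <- stats::rnorm(nv, 0, config$drift_amplitude)
    cosf <- stats::rnorm(nv, 0, config$drift_amplitude)
    Y <- Y + cbind(tt, cos(pi * tt)) %*% rbind(lin, cosf)
  }
  if (config$noise_sd > 0) {
    innov_sd <- config$noise_sd * sqrt(1 - config$ar1^2)
    eps <- matrix(stats::rnorm(n * nv, 0, innov_sd), n, nv)
    if (config$ar1 != 0) {
      for (t in 2:n) eps[t, ] <- eps[t, ] + config$ar1 * eps[t - 1L, ]
    }
    Y <- Y + eps
  }
  Y <- Y + config$baseline
  motion <- apply(matrix(stats::rnorm(n * 6L, 0, config$motion_amplitude_mm),
                         n, 6L), 2L, cumsum)
  motion[, 4:6] <- motion[, 4:6] * 0.01
  colnames(motion) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  list(bold = bold_run(array(t(Y), dim = c(grid$shape, n)), grid, config$tr_s),
       motion = motion)
}

#' Simulate a complete two-arm study
#'
#' Generates, per arm: ground-truth amplitude maps, one of six fixed block
#' randomization schedules per subject (round-robin), per-run BOLD data and
#' motion tables, and a per-arm stimulus-property table.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed; all content is a pure function of (config, seed).
#' @param arms Which arms to generate (default both).
#' @return Object of class `synthetic_study`: `arms$A`/`arms$B` each with
#'   `grid`, `ground_truth`, `subjects` (list of `runs`, each with `bold`,
#'   `events`, `motion`), `properties`; plus `config`, `seed`.
#' @export
simulate_group <- function(config = sim_config(), seed = 1L, arms = c("A", "B")) {
  schedules <- .six_schedules(config, seed)
  out <- list()
  ctr <- 0L
  for (arm in arms) {
    grid <- if (arm == "A") config$grid_A else config$grid_B
    n_sub <- config$n_subjects[[arm]]
    gt <- ground_truth_maps(grid, arm, config)
    subjects <- lapply(seq_len(n_sub), function(s) {
      sched <- schedules[[((s - 1L) %% 6L) + 1L]]
      runs <- lapply(seq_len(config$n_runs), function(r) {
        ctr <<- ctr + 1L
        sim <- simulate_bold_run(sched[[r]], gt$amplitude, grid, config,
                                 seed = .child_seed(seed, 7919L * ctr))
        list(bold = sim$bold, events = sched[[r]], motion = sim$motion)
      })
      list(runs = runs)
    })
    props <- simulate_stimulus_properties(config,
                                          seed = .child_seed(seed, if (arm == "A") 11L else 13L))
    out[[arm]] <- list(grid = grid, ground_truth = gt, subjects = subjects,
                       properties = props)
  }
  structure(list(arms = out, config = config, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  for (arm in names(x$arms)) {
    a <- x$arms[[arm]]
    cat("arm", arm, ":", length(a$subjects), "subjects,",
        x$config$n_runs, "runs on", paste(a$grid$shape, collapse = "x"), "grid\n")
  }
  invisible(x)
}

.PROP_NAMES <- c("brightness", "contrast", "hue", "saturation", "motion")

# Deviant-mode shifts touch every condition on every ranked property, so the
# amplified deviant block is strictly max-rank for all four conditions.
.deviant_condition_shifts <- function() {
  list(brightness = c(CF = 0.04, CO = -0.04, HeF = 0.04, HeO = -0.04),
       contrast   = c(CF = -0.03, CO = -0.03, HeF = 0.03, HeO = 0.03),
       hue        = c(CF = -8, CO = -8, HeF = 8, HeO = 8),
       saturation = c(CF = 0.03, CO = -0.03, HeF = 0.03, HeO = -0.03),
       motion     = c(CF = 0, CO = 0, HeF = 0, HeO = 0))
}

.default_condition_shifts <- function() {
  # Faces brighter than occiputs; heterospecific stimuli shifted in contrast,
  # hue and saturation (the pattern the stimulus-control analyses probe).
  list(brightness = c(CF = 0.04, CO = 0, HeF = 0.04, HeO = 0),
       contrast   = c(CF = 0, CO = 0, HeF = 0.03, HeO = 0.03),
       hue        = c(CF = 0, CO = 0, HeF = 8, HeO = 8),
       saturation = c(CF = 0, CO = 0, HeF = 0.03, HeO = 0.03),
       motion     = c(CF = 0, CO = 0, HeF = 0, HeO = 0))
}

#' Simulate per-block stimulus-property tables
#'
#' Property values per block are drawn from condition-specific normal
#' distributions. In `deviant_mode`, per-block baselines are yoked across
#' conditions within a run and one designated block per condition and run
#' carries the entire between-condition shift, so that removing it restores
#' exact balance.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @param condition_shifts Named list (per property) of per-condition mean
#'   shifts; `NULL` uses package defaults, `"none"` gives zero shifts.
#' @param deviant_mode Concentrate each condition's shift on one block per
#'   run (default FALSE).
#' @param noise_sd Named per-property within-condition SD.
#' @return Data frame (`run`, `block`, `condition`, and the five properties)
#'   with attribute `deviants` in deviant mode.
#' @export
simulate_stimulus_properties <- function(config = sim_config(), seed = 1L,
                                         condition_shifts = NULL,
                                         deviant_mode = FALSE,
                                         noise_sd = c(brightness = 0.02,
                                                      contrast = 0.015,
                                                      hue = 4,
                                                      saturation = 0.015,
                                                      motion = 0.3)) {
  set.seed(seed)
  if (is.null(condition_shifts))
    condition_shifts <- if (deviant_mode) .deviant_condition_shifts()
                        else .default_condition_shifts()
  if (identical(condition_shifts, "none"))
    condition_shifts <- lapply(.default_condition_shifts(), function(x) x * 0)
  base <- c(brightness = 0.5, contrast = 0.2, hue = 60, saturation = 0.4,
            motion = 2)
  per <- config$n_blocks_per_run / 4L
  rows <- list()
  deviants <- list()
  for (r in seq_len(config$n_runs)) {
    sched <- simulate_design(config, seed = .child_seed(seed, 37L * r))
    conds <- sched$trial_type
    slot <- stats::ave(seq_along(conds), conds, FUN = seq_along)
    df <- data.frame(run = r, block = seq_along(conds), condition = conds)
    for (p in .PROP_NAMES) {
      shift <- condition_shifts[[p]][conds]
      if (deviant_mode) {
        slot_base <- stats::rnorm(per, 0, noise_sd[[p]])
        val <- base[[p]] + slot_base[slot] + ifelse(slot == 1L, per * shift, 0)
      } else {
        val <- base[[p]] + shift + stats::rnorm(length(conds), 0, noise_sd[[p]])
      }
      df[[p]] <- as.numeric(val)
    }
    rows[[r]] <- df
    if (deviant_mode)
      deviants[[r]] <- df[slot == 1L, c("run", "block", "condition")]
  }
  out <- do.call(rbind, rows)
  if (deviant_mode) attr(out, "deviants") <- do.call(rbind, deviants)
  out
}

#' Simulate a cross-species pair study with controlled RDM alignment
#'
#' Both arms share a seeded region whose condition-level representational
#' geometry is drawn from a common latent space. Under
#' `alignment = "functional"` the geometry is indexed by conspecific-relative
#' labels (own-species to own-species); under `"direct"` by stimulus
#' identity (labels swapped between arms); under `"none"` the arms are
#' independent.
#'
#' @param config A [sim_config()]; `n_subjects`, grids, and run geometry are
#'   honoured.
#' @param alignment `"functional"`, `"direct"` or `"none"`.
#' @param seed RNG seed.
#' @param pattern_scale Amplitude SD of the latent condition patterns.
#' @param run_jitter SD of per-run jitter in latent space (makes run pairs
#'   informative).
#' @return A `synthetic_study` whose arms carry `region` (linear voxel
#'   indices of the seeded region) and attribute `alignment`.
#' @export
simulate_cross_species_pair <- function(config = sim_config(),
                                        alignment = c("functional", "direct", "none"),
                                        seed = 1L, pattern_scale = 1,
                                        run_jitter = 0.3) {
  alignment <- match.arg(alignment)
  # Strongly swap-asymmetric angles: correlation-distance RDMs only see
  # pattern angles, so the conspecific pair (165 deg apart) and the
  # heterospecific pair (50 deg) — and the two cross pairs (30 vs 145 deg) —
  # must subtend clearly different angles for the two matching schemes to be
  # distinguishable from finite, noisy data.
  deg <- function(a) c(cos(a * pi / 180), sin(a * pi / 180))
  latent <- rbind(CF = deg(0), CO = deg(165), HeF = deg(20), HeO = deg(-30))
  swap <- c(CF = "HeF", CO = "HeO", HeF = "CF", HeO = "CO")
  schedules <- .six_schedules(config, seed)
  ctr <- 0L
  arms <- list()
  for (arm in c("A", "B")) {
    grid <- if (arm == "A") config$grid_A else config$grid_B
    n_sub <- config$n_subjects[[arm]]
    shape <- grid$shape
    ctr_box <- lapply(shape, function(s) {
      half <- max(1L, floor(s / 4L))
      mid <- floor(s / 2L)
      seq(mid - half, mid + half - 1L)
    })
    idx <- as.matrix(expand.grid(i = ctr_box[[1]], j = ctr_box[[2]], k = ctr_box[[3]]))
    region <- sort(.vox_linear(idx, shape))
    nv <- prod(shape)
    q <- switch(alignment,
      functional = latent,
      direct = {
        qq <- latent[swap[.CONDITIONS], , drop = FALSE]
        rownames(qq) <- .CONDITIONS  # label c carries the swapped geometry
        qq
      },
      none = NULL)
    if (arm == "A") q <- latent  # arm A always carries the reference geometry
    subjects <- lapply(seq_len(n_sub), function(s) {
      set.seed(.child_seed(seed, 997L * s + match(arm, c("A", "B"))))
      qs <- if (is.null(q)) matrix(stats::rnorm(8), 4, 2,
                                   dimnames = list(.CONDITIONS, NULL)) else q
      basis <- matrix(stats::rnorm(length(region) * 2L), length(region), 2L)
      amp_runs <- lapply(seq_len(config$n_runs), function(r) {
        amp <- matrix(config$visual_amplitude, nv, 4L,
                      dimnames = list(NULL, .CONDITIONS))
        for (cond in .CONDITIONS) {
          z <- qs[cond, ] + stats::rnorm(2L, 0, run_jitter)
          amp[region, cond] <- amp[region, cond] + pattern_scale * drop(basis %*% z)
        }
        amp
      })
      sched <- schedules[[((s - 1L) %% 6L) + 1L]]
      runs <- lapply(seq_len(config$n_runs), function(r) {
        ctr <<- ctr + 1L
        sim <- simulate_bold_run(sched[[r]], amp_runs[[r]], grid, config,
                                 seed = .child_seed(seed, 104729L + ctr))
        list(bold = sim$bold, events = sched[[r]], motion = sim$motion)
      })
      list(runs = runs)
    })
    arms[[arm]] <- list(grid = grid, subjects = subjects, region = region)
  }
  structure(list(arms = arms, config = config, seed = seed),
            class = "synthetic_study", alignment = alignment)
}
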