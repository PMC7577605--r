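# End-to-end orchestration of the two-arm study: simulate -> GLM ->
# preference -> MVPA -> RSA -> report, under one config and one seed.

#' Pipeline configuration
#'
#' Collects the simulation config and per-arm analysis settings. Defaults
#' follow the per-species settings the analyses are designed around: arm A
#' (the smaller-brained species) voxel p < 0.001 with 4-mm spheres, arm B
#' voxel p < 1e-6 with 8-mm spheres; preference-map thresholds p < 0.005 /
#' p < 1e-4. Permutation counts default to desk-scale values and are fully
#' configurable.
#'
#' @param sim A [sim_config()].
#' @param voxel_p,pref_voxel_p,cluster_alpha Named per-arm thresholds.
#' @param radius_mm Named per-arm sphere/searchlight radii (mm).
#' @param n_perm Permutation count for cluster inference.
#' @param n_perm_proportion Resamples for the proportion permutation test.
#' @param n_null_relabel Relabellings for the preference-map null mean.
#' @param mvpa_voxel_p Voxel threshold for accuracy inference.
#' @param run_mvpa,run_rsa Stage toggles (searchlight stages dominate run
#'   time).
#' @param seed Global seed; per-stage child seeds are derived by fixed
#'   offsets.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            voxel_p = c(A = 0.001, B = 1e-6),
                            pref_voxel_p = c(A = 0.005, B = 1e-4),
                            cluster_alpha = c(A = 0.05, B = 0.001),
                            radius_mm = c(A = 4, B = 8),
                            n_perm = 500,
                            n_perm_proportion = 1000,
                            n_null_relabel = 50,
                            mvpa_voxel_p = 0.01,
                            run_mvpa = TRUE, run_rsa = TRUE,
                            seed = 1L) {
  stopifnot(all(radius_mm > 0), all(voxel_p > 0 & voxel_p < 1),
            all(cluster_alpha > 0 & cluster_alpha < 1))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read / write a pipeline config as YAML
#'
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  for (g in c("grid_A", "grid_B"))
    if (!is.null(sim_args[[g]]))
      sim_args[[g]] <- do.call(volume_grid, sim_args[[g]])
  if (!is.null(sim_args$n_subjects)) sim_args$n_subjects <- unlist(sim_args$n_subjects)
  y$sim <- do.call(sim_config, sim_args)
  for (nm in c("voxel_p", "pref_voxel_p", "cluster_alpha", "radius_mm"))
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  for (nm in c("voxel_p", "pref_voxel_p", "cluster_alpha", "radius_mm"))
    y[[nm]] <- as.list(y[[nm]])          # keep names through YAML
  y$sim <- unclass(y$sim)
  y$sim$n_subjects <- as.list(y$sim$n_subjects)
  for (g in c("grid_A", "grid_B"))
    y$sim[[g]] <- list(shape = y$sim[[g]]$shape,
                       voxel_size = y$sim[[g]]$voxel_size,
                       origin = y$sim[[g]]$origin)
  y$sim$block_s <- NULL; y$sim$total_s <- NULL
  yaml::write_yaml(y, path)
  invisible(path)
}

.log_stage <- function(log, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  c(log, line)
}

#' Run the full two-arm analysis pipeline
#'
#' Simulates the study, then per arm: first-level GLM contrasts with group
#' cluster-corrected maps and peak tables; the preference proportion with
#' permutation p and the group preference map; searchlight MVPA with group
#' accuracy inference; and across-arm RSA (region RDMs, functional vs direct
#' matching, condition-pair effects). Writes NIfTI/TSV/JSON outputs under
#' `out_dir` and returns the report.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips file
#'   output.
#' @return Report list (also written as `report.json`), with one block per
#'   stage and the seeds used.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  t0 <- Sys.time()
  log <- character(0)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  seed <- config$seed
  report <- list(seed = seed,
                 package_version = as.character(utils::packageVersion("xspecfmri")))
  log <- .log_stage(log, "simulate", sprintf("seed %d", seed))
  study <- simulate_group(config$sim, seed = .child_seed(seed, 1L))
  report$simulate <- list(
    arms = lapply(study$arms, function(a)
      list(n_subjects = length(a$subjects), grid = a$grid$shape)),
    n_runs = config$sim$n_runs, total_run_s = config$sim$total_s)

  report$glm <- list(); report$preference <- list(); report$mvpa <- list()
  for (arm_name in names(study$arms)) {
    arm <- study$arms[[arm_name]]
    nvox <- prod(arm$grid$shape)
    log <- .log_stage(log, "glm", sprintf("arm %s: %d subjects, %d voxels",
                                          arm_name, length(arm$subjects), nvox))
    mach <- .relabel_machinery(arm, config$sim)
    subj_c <- t(vapply(mach, function(sub)
      .group_contrasts(list(sub), function(run) run$A_true)$beta_c, numeric(nvox)))
    subj_f <- t(vapply(mach, function(sub)
      .group_contrasts(list(sub), function(run) run$A_true)$beta_f, numeric(nvox)))
    gcl_c <- cluster_fwe_permutation(subj_c, arm$grid,
                                     voxel_p = config$voxel_p[[arm_name]],
                                     cluster_alpha = config$cluster_alpha[[arm_name]],
                                     n_perm = config$n_perm,
                                     seed = .child_seed(seed, 21L))
    gcl_f <- cluster_fwe_permutation(subj_f, arm$grid,
                                     voxel_p = config$voxel_p[[arm_name]],
                                     cluster_alpha = config$cluster_alpha[[arm_name]],
                                     n_perm = config$n_perm,
                                     seed = .child_seed(seed, 22L))
    peaks_c <- select_peaks(group_map_volume(gcl_c), gcl_c$t_threshold, 16)
    if (!is.null(out_dir)) {
      write_volume(group_map_volume(gcl_c), file.path(out_dir, sprintf("glm_%s_CgtHe_t.nii.gz", arm_name)))
      write_volume(group_map_volume(gcl_f), file.path(out_dir, sprintf("glm_%s_FgtO_t.nii.gz", arm_name)))
      write_peaks(peaks_c, file.path(out_dir, sprintf("glm_%s_CgtHe_peaks.tsv", arm_name)))
    }
    report$glm[[arm_name]] <- list(
      conspecific_clusters = nrow(gcl_c$clusters),
      conspecific_surviving = sum(gcl_c$clusters$survives),
      face_clusters = nrow(gcl_f$clusters),
      face_surviving = sum(gcl_f$clusters$survives),
      n_peaks = nrow(peaks_c))

    log <- .log_stage(log, "prefs", sprintf("arm %s", arm_name))
    prop <- proportion_permutation_test(arm, config$sim,
                                        n_perm = config$n_perm_proportion,
                                        seed = .child_seed(seed, 31L))
    labels <- subject_preference_labels(arm, config$sim)
    null_mean <- preference_null_mean(arm, config$sim,
                                      m = config$n_null_relabel,
                                      seed = .child_seed(seed, 32L))
    pref_map <- group_preference_map(labels, null_mean, arm$grid,
                                     voxel_p = config$pref_voxel_p[[arm_name]],
                                     cluster_alpha = config$cluster_alpha[[arm_name]],
                                     n_perm = config$n_perm,
                                     seed = .child_seed(seed, 33L))
    report$preference[[arm_name]] <- list(
      a = prop$a, b = prop$b, proportion = prop$proportion,
      p_two = prop$p_two, p_one = prop$p_one, n_perm = prop$n_perm,
      conspecific_surviving = sum(pref_map$conspecific$clusters$survives),
      face_surviving = sum(pref_map$face$clusters$survives))
    if (!is.null(out_dir)) {
      jsonlite::write_json(report$preference[[arm_name]],
                           file.path(out_dir, sprintf("preference_%s.json", arm_name)),
                           auto_unbox = TRUE, digits = NA)
      group_lab <- voxel_preference_labels(colMeans(subj_c), colMeans(subj_f))
      write_volume(volume_map(as.numeric(group_lab), arm$grid),
                   file.path(out_dir, sprintf("preference_%s_labels.nii.gz", arm_name)))
    }

    if (config$run_mvpa) {
      task <- if (arm_name == "A") "CvsHe" else "FvsO"
      log <- .log_stage(log, "mvpa", sprintf("arm %s task %s", arm_name, task))
      acc_maps <- t(vapply(seq_along(arm$subjects), function(s) {
        samples <- lapply(seq_len(config$sim$n_runs), function(r) {
          run <- arm$subjects[[s]]$runs[[r]]
          prepare_samples(run$bold, run$events, config$sim$tr_s, run = r)
        })
        as.numeric(searchlight_accuracy(samples, arm$grid,
                                        radius_mm = config$radius_mm[[arm_name]],
                                        task = task)$values)
      }, numeric(nvox)))
      ginf <- group_accuracy_inference(acc_maps, arm$grid,
                                       voxel_p = config$mvpa_voxel_p,
                                       cluster_alpha = config$cluster_alpha[[arm_name]],
                                       n_perm = config$n_perm,
                                       seed = .child_seed(seed, 41L))
      report$mvpa[[arm_name]] <- list(
        task = task,
        mean_accuracy = mean(ginf$mean, na.rm = TRUE),
        peak_accuracy = if (nrow(ginf$clusters)) max(ginf$clusters$peak_accuracy) else NA,
        surviving_clusters = sum(ginf$clusters$survives))
      if (!is.null(out_dir)) {
        write_volume(volume_map(ginf$mean, arm$grid),
                     file.path(out_dir, sprintf("mvpa_%s_%s_accuracy.nii.gz", arm_name, task)))
        utils::write.table(ginf$clusters,
                           file.path(out_dir, sprintf("mvpa_%s_%s_clusters.tsv", arm_name, task)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        hist_df <- cluster_accuracy_histograms(ginf, acc_maps)
        utils::write.csv(hist_df,
                         file.path(out_dir, sprintf("mvpa_%s_%s_histograms.csv", arm_name, task)),
                         row.names = FALSE)
      }
    }
  }

  if (config$run_rsa) {
    log <- .log_stage(log, "rsa", "cross-arm condition matching")
    pair <- simulate_cross_species_pair(config$sim, alignment = "functional",
                                        seed = .child_seed(seed, 51L))
    rdms <- lapply(c("A", "B"), function(arm_name) {
      arm <- pair$arms[[arm_name]]
      lapply(arm$subjects, function(sub) {
        it <- extract_item_patterns(sub, arm$grid, arm$region,
                                    config$sim$tr_s, config$sim$n_volumes)
        compute_rdm(it$patterns, it$items)
      })
    })
    names(rdms) <- c("A", "B")
    rho <- sapply(c("functional", "direct"), function(sc) {
      sch <- matching_scheme(sc)
      mean(outer(seq_along(rdms$A), seq_along(rdms$B),
                 Vectorize(function(a, b) rdm_correlation(rdms$A[[a]], rdms$B[[b]], sch))))
    })
    pair_tab <- condition_pair_effects(rdms$A, rdms$B,
                                       matching_scheme("functional"),
                                       n_swaps = 200,
                                       seed = .child_seed(seed, 52L))
    report$rsa <- list(functional_mean_rho = rho[["functional"]],
                       direct_mean_rho = rho[["direct"]],
                       pair_effects = pair_tab)
    if (!is.null(out_dir))
      utils::write.table(pair_tab, file.path(out_dir, "rsa_pair_effects.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  report$log <- log
  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  report
}

#' Validate study inputs
#'
#' Checks event, motion and geometry conformance of a `synthetic_study` (or
#' a single arm) and returns a machine-readable issue list rather than
#' raising.
#'
#' @param study A `synthetic_study`, or one arm of one.
#' @param config The study's [sim_config()] (defaults to the study's own).
#' @return Data frame with `code`, `where`, `message` (zero rows when clean).
#' @export
validate_inputs <- function(study, config = NULL) {
  issues <- list()
  add <- function(code, where, msg)
    issues[[length(issues) + 1L]] <<- data.frame(code = code, where = where,
                                                 message = msg)
  arms <- if (!is.null(study$arms)) study$arms else list(arm = study)
  if (is.null(config)) config <- study$config
  run_s <- config$n_volumes * config$tr_s
  for (arm_name in names(arms)) {
    arm <- arms[[arm_name]]
    for (s in seq_along(arm$subjects)) {
      for (r in seq_along(arm$subjects[[s]]$runs)) {
        run <- arm$subjects[[s]]$runs[[r]]
        where <- sprintf("%s/sub-%02d/run-%02d", arm_name, s, r)
        ev <- run$events
        if (any(ev$onset + ev$duration > run_s + 1e-9))
          add("event_overrun", where, "event extends beyond run end")
        if (!all(ev$trial_type %in% .CONDITIONS))
          add("bad_condition", where, "unknown condition label")
        else if (!design_constraints_ok(ev, config))
          add("unbalanced_design", where, "condition counts or ordering constraints violated")
        if (!is.null(run$motion)) {
          chk <- tryCatch(motion_exclusion_check(run$motion),
                          error = function(e) NULL)
          if (is.null(chk)) add("bad_motion_table", where, "malformed motion table")
          else if (!chk$keep)
            add("motion_exclusion", where,
                sprintf("translation range %.2f mm exceeds 3 mm", chk$max_range_mm))
          if (!is.null(run$bold) && nrow(run$motion) != dim(run$bold$data)[4])
            add("motion_length_mismatch", where, "motion rows != volumes")
        }
        if (!is.null(run$bold) && !is.null(arm$grid) &&
            !all(dim(run$bold$data)[1:3] == arm$grid$shape))
          add("grid_mismatch", where, "BOLD grid differs from arm grid")
      }
    }
  }
  if (!length(issues))
    return(data.frame(code = character(0), where = character(0),
                      message = character(0)))
  do.call(rbind, issues)
}
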