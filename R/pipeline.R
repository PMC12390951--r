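# End-to-end pipeline -----------------------------------------------------
#
# One configuration object drives stimulus design -> cohort simulation ->
# preprocessing -> statistics, with optional CSV outputs per stage. Every
# stage is also callable on its own; this wrapper exists so a whole study
# reproduces from a single seed.

#' Pipeline configuration
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_participants Cohort size (default 11).
#' @param effect "default" (condition effect on right sensorimotor / left
#'   premotor channels) or "null".
#' @param n_blocks Blocks per session (default 60).
#' @param sr Audio sampling rate for the stimulus stage.
#' @param include_stimuli Render and validate the audio stimulus set
#'   (TRUE for a full study; the simulation itself only needs the
#'   protocol timing).
#' @param n_permutations Permutations for the cluster tests.
#' @param noise A `noise_config`.
#' @param preprocess A `preprocess_config`.
#' @return A `run_config`.
#' @export
run_config <- function(seed = 1L, n_participants = 11L,
                       effect = c("default", "null"),
                       n_blocks = 60L, sr = 44100,
                       include_stimuli = TRUE,
                       n_permutations = 5000L,
                       noise = noise_config(),
                       preprocess = preprocess_config()) {
  structure(list(seed = as.integer(seed),
                 n_participants = as.integer(n_participants),
                 effect = match.arg(effect),
                 n_blocks = as.integer(n_blocks), sr = sr,
                 include_stimuli = include_stimuli,
                 n_permutations = as.integer(n_permutations),
                 noise = noise, preprocess = preprocess),
            class = "run_config")
}

#' Run the whole study pipeline
#'
#' @param config A `run_config`.
#' @param out_dir Optional directory for CSV outputs (protocols, QC, ROI
#'   table, cluster and ANOVA tables).
#' @return List with `stimuli` (validation summary, when included),
#'   `montage`, `averages`, `retained`, `slopes`, `spatial` (slope
#'   cluster result), `temporal` (per-channel baseline contrasts for both
#'   conditions, group-retained channels only), `roi_table`, `anova`,
#'   `qc` (per-participant rule counts / exclusions).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  montage <- build_montage()
  ccfg <- cluster_config(n_permutations = config$n_permutations,
                         seed = config$seed)
  stim_summary <- NULL
  if (config$include_stimuli) {
    ss <- generate_stimulus_set(config$seed, sr = config$sr)
    stim_summary <- list(
      n_rhythmic = length(ss$rhythmic),
      durations = range(vapply(ss$rhythmic, function(s) s$duration_s, 0)),
      p_duration = ss$validation$p_duration,
      p_power = ss$validation$p_power)
  }
  cohort <- simulate_cohort(config$n_participants, config$effect,
                            seed = config$seed, n_blocks = config$n_blocks,
                            montage = montage, noise = config$noise)
  averages <- lapply(cohort, preprocess_session, config = config$preprocess)
  retained <- group_retained_channels(averages, config$preprocess)
  slopes <- cohort_slopes(averages)
  spatial <- spatial_cluster_test(
    slopes$rhythmic, slopes$arrhythmic, montage, ccfg,
    min_n = config$preprocess$min_participants_per_channel)

  # per-channel baseline contrast of the averaged response, per condition
  temporal <- lapply(stats::setNames(nm = c("rhythmic", "arrhythmic")),
                     function(cond) {
    ci <- match(cond, c("rhythmic", "arrhythmic"))
    chans <- which(retained[, ci])
    res <- lapply(chans, function(ch) {
      x <- do.call(rbind, lapply(averages, function(a) a$mean_hbo[ch, ci, ]))
      ok <- rowSums(is.na(x)) == 0
      if (sum(ok) < 2) return(NULL)
      temporal_cluster_test(x[ok, , drop = FALSE], config = ccfg)
    })
    names(res) <- chans
    res[!vapply(res, is.null, TRUE)]
  })

  roi_table <- roi_aggregate(averages, montage, retained)
  anova <- anova_suite(roi_table)
  qc <- lapply(averages, `[[`, "qc")

  out <- list(stimuli = stim_summary, montage = montage,
              averages = averages, retained = retained, slopes = slopes,
              spatial = spatial, temporal = temporal,
              roi_table = roi_table, anova = anova, qc = qc,
              config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  invisible(out)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  utils::write.csv(result$montage$channels, p("montage_channels.csv"),
                   row.names = FALSE)
  utils::write.csv(result$roi_table, p("roi_table.csv"), row.names = FALSE)
  utils::write.csv(result$anova$threeway$effects, p("anova_threeway.csv"),
                   row.names = FALSE)
  cl <- result$spatial$clusters
  if (nrow(cl)) {
    cl$members <- vapply(cl$members, paste, "", collapse = ";")
    utils::write.csv(cl, p("spatial_clusters.csv"), row.names = FALSE)
  }
  qc <- do.call(rbind, lapply(seq_along(result$qc), function(i) {
    q <- result$qc[[i]]
    data.frame(participant = i,
               n_excluded_rhythmic = q$n_excluded[1],
               n_excluded_arrhythmic = q$n_excluded[2],
               mask_fraction = q$mask_fraction)
  }))
  utils::write.csv(qc, p("qc_summary.csv"), row.names = FALSE)
  invisible(out_dir)
}
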