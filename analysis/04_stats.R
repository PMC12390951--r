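#!/usr/bin/env Rscript
# Stage 4 — group statistics.
#
# Regenerates and preprocesses the seeded cohort, then runs the group
# analyses: per-channel temporal cluster tests against baseline, the
# spatial cluster test on rising slopes (rhythmic vs arrhythmic), the
# 8-12 s ROI table, and the repeated-measures ANOVA suite with
# Tukey-Kramer post-hocs. Tables go to results/stats/.

library(neorhythm)

seed <- 1
out <- "results/stats"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

montage <- build_montage()
cohort <- simulate_cohort(11, "default", seed = seed, n_blocks = 60,
                          montage = montage)
averages <- lapply(cohort, preprocess_session)
retained <- group_retained_channels(averages)
ccfg <- cluster_config(n_permutations = 5000, seed = seed)

# rising slopes and the spatial cluster contrast
slopes <- cohort_slopes(averages)
sp <- spatial_cluster_test(slopes$rhythmic, slopes$arrhythmic, montage,
                           ccfg)
cl <- sp$clusters
if (nrow(cl)) {
  cl$members <- vapply(cl$members, paste, "", collapse = ";")
  write.csv(cl, file.path(out, "spatial_slope_clusters.csv"),
            row.names = FALSE)
}
sig <- significant_clusters(sp)
eff <- ground_truth_map(montage)$effect_channels
cat(sprintf(
  "Spatial slope contrast: %d cluster(s), %d significant; significant clusters cover %d/%d ground-truth effect channels.\n",
  nrow(sp$clusters), nrow(sig),
  length(intersect(unlist(significant_clusters(sp)$members), eff)),
  length(eff)))

# per-channel temporal clusters against baseline
tcl <- do.call(rbind, lapply(c("rhythmic", "arrhythmic"), function(cond) {
  ci <- match(cond, c("rhythmic", "arrhythmic"))
  do.call(rbind, lapply(which(retained[, ci]), function(ch) {
    x <- do.call(rbind, lapply(averages, function(a) a$mean_hbo[ch, ci, ]))
    x <- x[rowSums(is.na(x)) == 0, , drop = FALSE]
    if (nrow(x) < 2) return(NULL)
    res <- temporal_cluster_test(x, config = ccfg)
    s <- significant_clusters(res)
    if (nrow(s) == 0) return(NULL)
    data.frame(condition = cond, channel = ch, start_s = s$start - 6,
               end_s = s$end - 6, t_sum = s$t_sum, p = s$p)
  }))
}))
write.csv(tcl, file.path(out, "temporal_baseline_clusters.csv"),
          row.names = FALSE)
cat(sprintf(
  "Temporal baseline contrasts: %d / %d retained channels show a significant rhythmic response; %d / %d arrhythmic.\n",
  length(unique(tcl$channel[tcl$condition == "rhythmic"])),
  sum(retained[, 1]),
  length(unique(tcl$channel[tcl$condition == "arrhythmic"])),
  sum(retained[, 2])))

# ROI table and the rANOVA suite
roi <- roi_aggregate(averages, montage, retained)
write.csv(roi, file.path(out, "roi_table.csv"), row.names = FALSE)
suite <- anova_suite(roi)
write.csv(suite$threeway$effects, file.path(out, "anova_threeway.csv"),
          row.names = FALSE)
for (cond in names(suite$by_condition))
  write.csv(suite$by_condition[[cond]]$effects,
            file.path(out, sprintf("anova_%s.csv", cond)),
            row.names = FALSE)
for (rr in names(suite$by_roi))
  write.csv(suite$by_roi[[rr]]$effects,
            file.path(out, sprintf("anova_roi_%s.csv", rr)),
            row.names = FALSE)
for (cond in names(suite$posthoc_roi))
  write.csv(suite$posthoc_roi[[cond]],
            file.path(out, sprintf("tukey_roi_%s.csv", cond)),
            row.names = FALSE)

ef <- suite$threeway$effects
show <- function(name) {
  r <- ef[ef$effect == name, ]
  sprintf("%s: F(%d, %d) = %.3f, p = %.4f, pes = %.3f",
          name, r$df_num, r$df_den, r$F, r$p, r$pes)
}
cat("Three-way rANOVA:\n  ", show("condition"), "\n  ",
    show("roi"), "\n  ", show("condition x roi x hemisphere"), "\n")
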