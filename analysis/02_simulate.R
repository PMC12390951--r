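#!/usr/bin/env Rscript
# Stage 2 — synthetic cohort.
#
# Simulates the 11-participant study (60 blocks per session, default
# effect map: rhythmic > arrhythmic over right sensorimotor and left
# premotor channels) and writes the montage, per-participant protocols
# and artifact logs under results/sessions/. Raw intensity arrays are
# large and fully reproducible from the seed, so they are regenerated by
# later stages rather than serialized.

library(neorhythm)

seed <- 1
out <- "results/sessions"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

montage <- build_montage()
write.csv(montage$channels, file.path(out, "montage_channels.csv"),
          row.names = FALSE)
write.csv(montage$optodes, file.path(out, "montage_optodes.csv"),
          row.names = FALSE)

cohort <- simulate_cohort(11, "default", seed = seed, n_blocks = 60,
                          montage = montage)

for (i in seq_along(cohort)) {
  s <- cohort[[i]]
  write.table(s$events,
              file.path(out, sprintf("%s_events.tsv", s$participant_id)),
              sep = "\t", row.names = FALSE, quote = FALSE)
  lg <- s$artifact_log
  if (nrow(lg)) {
    lg$channels <- vapply(lg$channels, paste, "", collapse = ";")
    write.csv(lg, file.path(out, sprintf("%s_artifacts.csv",
                                         s$participant_id)),
              row.names = FALSE)
  }
}

dur_min <- vapply(cohort, function(s)
  (max(s$events$onset_s) + 30) / 60, 0)
n_art <- vapply(cohort, function(s) nrow(s$artifact_log), 0L)
cat(sprintf(
  "Simulated %d sessions of %d blocks (%.0f-%.0f min, fs = %.4f Hz, %d channels).\n",
  length(cohort), 60, min(dur_min), max(dur_min), cohort[[1]]$fs,
  nrow(montage$channels)))
cat(sprintf("Motion artifacts per session: %s (spikes + step shifts).\n",
            paste(n_art, collapse = ", ")))
cat("Events, artifact logs and montage written under", out, "\n")
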