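#!/usr/bin/env Rscript
# Stage 1 — stimulus design.
#
# Builds the five beat-based sequences, derives matched arrhythmic
# counterparts, renders all 60 stimuli at 44.1 kHz, verifies the
# duration/envelope-power equivalence, and writes the design tables
# (and, optionally, the WAV files) under results/stimuli/.

library(neorhythm)

seed <- 1
out <- "results/stimuli"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
write_wavs <- nzchar(Sys.getenv("NEORHYTHM_WRITE_WAVS"))

set <- generate_stimulus_set(seed = seed, sr = 44100)

seq_tab <- do.call(rbind, lapply(set$bases, function(b)
  data.frame(base_id = b$base_id, n_tones = b$n_tones,
             total_units = sum(b$intervals),
             beat_alignment = beat_alignment(b),
             intervals = paste(b$intervals, collapse = " "))))
write.csv(seq_tab, file.path(out, "base_sequences.csv"), row.names = FALSE)

stim_tab <- do.call(rbind, lapply(c(set$rhythmic, set$arrhythmic),
                                  function(s) {
  sp <- envelope_power(s)
  data.frame(condition = s$condition, base_id = s$base_id,
             tempo_ms = s$tempo_unit_ms, pitch_hz = s$pitch_hz,
             duration_s = s$duration_s, n_tones = length(s$onsets_s),
             beat_hz = beat_frequency(s),
             beat_power = power_at(sp, beat_frequency(s)),
             mean_power_0_10 = sp$mean_power_0_10)
}))
write.csv(stim_tab, file.path(out, "stimuli.csv"), row.names = FALSE)

if (write_wavs) {
  for (s in c(set$rhythmic, set$arrhythmic)) {
    write_stimulus_wav(s, file.path(out, sprintf("%s_base%d_%dms_%dHz.wav",
                                                 s$condition, s$base_id,
                                                 s$tempo_unit_ms,
                                                 s$pitch_hz)))
  }
}

v <- set$validation
cat(sprintf(
  "Built %d rhythmic + %d arrhythmic stimuli (durations %.2f-%.2f s).\n",
  length(set$rhythmic), length(set$arrhythmic),
  min(stim_tab$duration_s), max(stim_tab$duration_s)))
cat(sprintf(
  "Matched-pair tests: duration p = %.3f, 0-10 Hz envelope power p = %.3f (both > 0.05: sets are equivalent).\n",
  v$p_duration, v$p_power))
by_cond <- tapply(stim_tab$beat_power, stim_tab$condition, median)
cat(sprintf(
  "Median beat-frequency envelope power: rhythmic %.2e vs arrhythmic %.2e.\n",
  by_cond["rhythmic"], by_cond["arrhythmic"]))
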