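# Shared fixtures, built once per test run. Audio fixtures use an 8 kHz
# rate: every analysed envelope frequency is far below 4 kHz and the
# rendering arithmetic is rate-independent.

.fixtures <- new.env(parent = emptyenv())

fixture_stimset <- function() {
  if (is.null(.fixtures$stimset))
    .fixtures$stimset <- generate_stimulus_set(seed = 1, sr = 8000)
  .fixtures$stimset
}

fixture_montage <- function() {
  if (is.null(.fixtures$montage)) .fixtures$montage <- build_montage()
  .fixtures$montage
}

# a hand-made rendered_stimulus wrapping an arbitrary waveform
manual_stimulus <- function(waveform, sr = 8000, condition = "rhythmic") {
  structure(list(condition = condition, base_id = 1L, tempo_unit_ms = 140,
                 pitch_hz = 440, onsets_s = 0, waveform = waveform, sr = sr,
                 duration_s = length(waveform) / sr),
            class = "rendered_stimulus")
}

# a hand-made 1 Hz condition_average with given per-condition time courses
manual_average <- function(rhythmic, arrhythmic, time_s = -5:24) {
  nch <- nrow(rhythmic)
  mean_hbo <- array(NA_real_, c(nch, 2, length(time_s)),
                    dimnames = list(NULL, c("rhythmic", "arrhythmic"), NULL))
  mean_hbo[, 1, ] <- rhythmic
  mean_hbo[, 2, ] <- arrhythmic
  structure(list(mean_hbo = mean_hbo, time_s = time_s,
                 n_trials = matrix(10L, nch, 2),
                 excluded = matrix(FALSE, nch, 2,
                                   dimnames = list(NULL,
                                                   c("rhythmic",
                                                     "arrhythmic")))),
            class = "condition_average")
}

# a balanced within-subject ROI table built from a cell-mean function
manual_roi_table <- function(n_participants, cell_fun) {
  grid <- expand.grid(participant = seq_len(n_participants),
                      condition = c("rhythmic", "arrhythmic"),
                      roi = c("sensorimotor", "auditory", "premotor"),
                      hemisphere = c("left", "right"),
                      stringsAsFactors = FALSE)
  grid$hbo <- mapply(cell_fun, grid$participant, grid$condition, grid$roi,
                     grid$hemisphere)
  grid
}
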