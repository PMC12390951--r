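# Stimulus design -------------------------------------------------------
#
# Rhythmic (beat-based) sequences are built from an inventory of four
# onset-to-onset intervals: the fastest interval is 1 time unit and the
# others are 2, 3 and 4 units. Sequences are assembled from two-beat and
# four-beat cells so that most tone onsets fall on an isochronous 2-unit
# beat grid; arrhythmic controls keep the interval inventory but destroy
# the grid.

TEMPI_MS <- c(140, 185, 230)
PITCHES_HZ <- c(880, 440)

#' Compose the five beat-based base sequences
#'
#' Builds five rhythmic sequences of 42--45 intervals drawn from
#' \{1, 2, 3, 4\} time units, with an even total of 94--102 units so that
#' every rendering at the three tempi (1 unit = 140, 185, 230 ms) lasts
#' between 13 and 24 s. Sequences are assembled from cells that each span
#' a whole number of 2-unit beats, so at least 80% of beat-grid points
#' coincide with a tone onset.
#'
#' @param seed Integer seed; the same seed always yields the same five
#'   sequences.
#' @return A list of 5 objects of class `rhythm_sequence`, each with
#'   fields `base_id`, `intervals` and `n_tones`.
#' @export
compose_rhythmic_bases <- function(seed = 1L) {
  set.seed(seed)
  lapply(1:5, function(id) {
    repeat {
      n <- sample(42:45, 1)                   # intervals
      total <- sample(seq(94L, 102L, 2L), 1)  # time units (even: beat grid)
      c4 <- sample(1:8, 1)                    # [4] cells
      d4 <- sample(1:4, 1)                    # [3,1]/[1,3] cells
      a <- n + c4 - total %/% 2               # [1,1] cells
      b <- total - n - 3L * c4 - 2L * d4      # [2] cells
      if (a < 0 || b < 0) next
      # each 4-unit cell misses one interior beat
      if ((c4 + d4) / (total / 2) > 0.2) next
      cells <- c(replicate(a, c(1L, 1L), simplify = FALSE),
                 replicate(b, 2L, simplify = FALSE),
                 replicate(c4, 4L, simplify = FALSE),
                 replicate(d4, sample(list(c(3L, 1L), c(1L, 3L)), 1)[[1]],
                           simplify = FALSE))
      intervals <- unlist(cells[sample.int(length(cells))])
      stopifnot(length(intervals) == n, sum(intervals) == total)
      return(new_rhythm_sequence(id, intervals))
    }
  })
}

new_rhythm_sequence <- function(base_id, intervals) {
  structure(list(base_id = as.integer(base_id),
                 intervals = intervals,
                 n_tones = length(intervals) + 1L),
            class = "rhythm_sequence")
}

#' Fraction of 2-unit beat-grid points carrying a tone onset
#' @param seq A `rhythm_sequence`.
#' @return Scalar in [0, 1].
#' @export
beat_alignment <- function(seq) {
  onsets <- cumsum(c(0, seq$intervals))
  beats <- seq.int(0, max(onsets), by = 2)
  mean(beats %in% onsets)
}

#' Derive the matched arrhythmic control of a rhythmic sequence
#'
#' Within each interval category (1, 2, 3, 4 units) present in the source,
#' a random third of the intervals is shortened by 20%, 25% or 33%, a third
#' is kept, and a third is lengthened by 20%, 25% or 33%; remainders when a
#' category size is not divisible by 3 are spread randomly over the three
#' labels. All intervals are then randomly shuffled, which removes the beat
#' grid while preserving the interval count and, in expectation, the total
#' duration.
#'
#' @param seq A `rhythm_sequence`.
#' @param seed Integer seed.
#' @return An `arrhythmic_sequence` with real-valued `intervals` and a
#'   `perturbation_log` data frame (one row per interval in final order:
#'   `label` in shortened/same/lengthened, `factor`, `source_units`).
#' @export
make_arrhythmic <- function(seq, seed = 1L) {
  stopifnot(inherits(seq, "rhythm_sequence"))
  set.seed(seed)
  iv <- seq$intervals
  n <- length(iv)
  label <- character(n)
  fac <- rep(NA_real_, n)
  for (v in sort(unique(iv))) {
    idx <- which(iv == v)
    idx <- idx[sample.int(length(idx))]    # random order within category
    nk <- length(idx)
    sizes <- rep(nk %/% 3L, 3L)
    rem <- nk %% 3L
    if (rem > 0) {
      extra <- sample(1:3, rem)
      sizes[extra] <- sizes[extra] + 1L
    }
    grp <- rep(c("shortened", "same", "lengthened"), times = sizes)
    label[idx] <- grp
  }
  perturbed <- which(label != "same")
  fac[perturbed] <- sample(c(0.20, 0.25, 0.33), length(perturbed),
                           replace = TRUE)
  out <- ifelse(label == "shortened", iv * (1 - fac),
                ifelse(label == "lengthened", iv * (1 + fac), iv))
  ord <- sample.int(n)
  structure(list(source_base_id = seq$base_id,
                 intervals = out[ord],
                 perturbation_log = data.frame(label = label[ord],
                                               factor = fac[ord],
                                               source_units = iv[ord])),
            class = "arrhythmic_sequence")
}

# Audio rendering -------------------------------------------------------

#' Render a sequence as audio
#'
#' Each tone is a decaying sinusoid (5 ms linear attack, 60 ms exponential
#' decay) at the requested pitch; onsets follow the cumulative interval sums
#' at the requested tempo. The stimulus duration is the last onset plus a
#' fixed 0.5 s tail, applied identically to rhythmic and arrhythmic
#' sequences.
#'
#' @param seq A `rhythm_sequence` or `arrhythmic_sequence`.
#' @param tempo_unit_ms Duration of 1 time unit; one of 140, 185, 230.
#' @param pitch_hz Tone frequency; one of 440, 880.
#' @param sr Sampling rate in Hz (default 44100).
#' @return A `rendered_stimulus`: `condition`, `base_id`, `tempo_unit_ms`,
#'   `pitch_hz`, `onsets_s`, `waveform`, `sr`, `duration_s`.
#' @export
render_stimulus <- function(seq, tempo_unit_ms, pitch_hz, sr = 44100) {
  if (!tempo_unit_ms %in% TEMPI_MS)
    stop("tempo_unit_ms must be one of ", paste(TEMPI_MS, collapse = ", "))
  if (!pitch_hz %in% PITCHES_HZ)
    stop("pitch_hz must be one of ", paste(PITCHES_HZ, collapse = ", "))
  condition <- if (inherits(seq, "rhythm_sequence")) "rhythmic"
               else if (inherits(seq, "arrhythmic_sequence")) "arrhythmic"
               else stop("seq must be a rhythm_sequence or arrhythmic_sequence")
  onsets <- cumsum(c(0, seq$intervals)) * tempo_unit_ms / 1000
  duration <- max(onsets) + 0.5
  n <- round(duration * sr)
  wave <- numeric(n)
  tone <- percussive_tone(pitch_hz, sr)
  for (t0 in onsets) {
    i0 <- round(t0 * sr) + 1L
    i1 <- min(n, i0 + length(tone) - 1L)
    wave[i0:i1] <- wave[i0:i1] + tone[seq_len(i1 - i0 + 1L)]
  }
  # fixed gain, NOT peak normalisation: per-stimulus peak normalisation
  # rescales the whole envelope by the (condition-dependent) amount of
  # tone overlap and would bias the envelope-power comparison
  wave <- wave * 0.25
  structure(list(condition = condition,
                 base_id = if (condition == "rhythmic") seq$base_id
                           else seq$source_base_id,
                 tempo_unit_ms = tempo_unit_ms,
                 pitch_hz = pitch_hz,
                 onsets_s = onsets,
                 waveform = wave,
                 sr = sr,
                 duration_s = duration),
            class = "rendered_stimulus")
}

# 5 ms attack, tau = 60 ms decay; 0.35 s support covers > 5 decay constants
percussive_tone <- function(pitch_hz, sr, tau = 0.06, attack = 0.005,
                            length_s = 0.35) {
  t <- seq(0, length_s, by = 1 / sr)
  env <- exp(-t / tau) * pmin(1, t / attack)
  env * sin(2 * pi * pitch_hz * t)
}

#' Beat frequency of a rendering
#'
#' The underlying beat spans 2 time units, so the beat rate is
#' 1 / (2 x tempo unit).
#' @param stim A `rendered_stimulus`.
#' @return Frequency in Hz.
#' @export
beat_frequency <- function(stim) 1000 / (2 * stim$tempo_unit_ms)

# Envelope spectrum -----------------------------------------------------

# smallest 5-smooth integer >= n; keeps R's mixed-radix FFT O(n log n)
next_fast_len <- function(n) {
  if (n <= 6) return(as.integer(n))
  m <- n
  repeat {
    k <- m
    for (p in c(2L, 3L, 5L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(as.integer(m))
    m <- m + 1L
  }
}

# analytic signal via the FFT half-spectrum construction; the signal is
# zero-padded to an FFT-friendly length and truncated back, which leaves
# only negligible edge ringing in the envelope
analytic_signal <- function(x) {
  n0 <- length(x)
  n <- next_fast_len(n0)
  if (n > n0) x <- c(x, numeric(n - n0))
  f <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else if (n > 1) {
    h[2:((n + 1) / 2)] <- 2
  }
  (stats::fft(f * h, inverse = TRUE) / n)[seq_len(n0)]
}

#' Amplitude-envelope spectrum of a stimulus
#'
#' Computes the magnitude envelope as the absolute value of the analytic
#' signal (Hilbert transform), then its power spectrum on a fixed grid:
#' the envelope is zero-padded so frequency resolution is `df_hz`
#' regardless of stimulus duration, which makes the 0--10 Hz average
#' comparable across stimuli of unequal length.
#'
#' @param stim A `rendered_stimulus`.
#' @param df_hz Frequency resolution of the padded grid (default 0.1 Hz).
#' @return An `envelope_spectrum`: `freqs_hz` (0 to Nyquist), `power`
#'   (|FFT|^2 of the envelope, normalised by the squared sample count) and
#'   `mean_power_0_10` (mean power over [0, 10] Hz).
#' @export
envelope_power <- function(stim, df_hz = 0.1) {
  x <- stim$waveform
  stopifnot(length(x) > 0)
  sr <- stim$sr
  nfft <- next_fast_len(max(length(x), ceiling(sr / df_hz)))
  if (all(x == 0)) {
    env <- numeric(length(x))
  } else {
    env <- Mod(analytic_signal(x))
  }
  f <- stats::fft(c(env, numeric(nfft - length(env))))
  keep <- seq_len(floor(nfft / 2) + 1L)
  freqs <- (keep - 1L) * sr / nfft
  power <- (Mod(f[keep]) / length(x))^2
  structure(list(freqs_hz = freqs, power = power,
                 mean_power_0_10 = mean(power[freqs <= 10])),
            class = "envelope_spectrum")
}

#' Envelope power near a frequency
#' @param spec An `envelope_spectrum`.
#' @param f_hz Centre frequency in Hz.
#' @param halfwidth_hz Half-width of the search band (default 0.15 Hz).
#' @return Maximum power within the band.
#' @export
power_at <- function(spec, f_hz, halfwidth_hz = 0.15) {
  sel <- abs(spec$freqs_hz - f_hz) <= halfwidth_hz
  if (!any(sel)) stop("no frequency bin within band")
  max(spec$power[sel])
}

# Stimulus-set construction and validation ------------------------------

#' Generate the full matched stimulus set
#'
#' Five beat-based sequences and their arrhythmic counterparts, each
#' rendered at 3 tempi x 2 pitches: 30 rhythmic and 30 matched arrhythmic
#' stimuli, paired by (base, tempo, pitch).
#'
#' Because the random perturbation is drawn per base (five independent
#' draws replicated over six renderings each), an unlucky draw can leave
#' the sets systematically mismatched in duration or envelope power. As in
#' standard matched-stimulus construction, the generator therefore verifies
#' its own equivalence criterion (paired t-tests, p > 0.05 on duration and
#' on 0--10 Hz envelope power) and redraws the arrhythmic perturbations
#' until it holds.
#'
#' @param seed Integer seed.
#' @param sr Sampling rate for rendering (default 44100).
#' @param max_redraw Cap on arrhythmic redraws (default 50).
#' @return A list with `bases`, `arrhythmic_seqs`, `rhythmic`,
#'   `arrhythmic` (parallel lists of 30 renderings) and `validation`
#'   (the accepted [validate_stimulus_sets()] result).
#' @export
generate_stimulus_set <- function(seed = 1L, sr = 44100, max_redraw = 50L) {
  bases <- compose_rhythmic_bases(seed)
  grid <- expand.grid(base = 1:5, tempo = TEMPI_MS, pitch = PITCHES_HZ)
  rhythmic <- lapply(seq_len(nrow(grid)), function(i)
    render_stimulus(bases[[grid$base[i]]], grid$tempo[i], grid$pitch[i], sr))
  for (attempt in seq_len(max_redraw)) {
    arr <- lapply(bases, function(b)
      make_arrhythmic(b, seed = seed + 1000L * attempt + b$base_id))
    # durations are free to compute; screen them before rendering audio
    dur_a <- vapply(seq_len(nrow(grid)), function(i)
      sum(arr[[grid$base[i]]]$intervals) * grid$tempo[i] / 1000 + 0.5, 0)
    dur_r <- vapply(rhythmic, function(s) s$duration_s, 0)
    if (paired_t_p(dur_r, dur_a)$p <= 0.05) next
    arrhythmic <- lapply(seq_len(nrow(grid)), function(i)
      render_stimulus(arr[[grid$base[i]]], grid$tempo[i], grid$pitch[i], sr))
    v <- validate_stimulus_sets(rhythmic, arrhythmic)
    if (v$p_duration > 0.05 && v$p_power > 0.05)
      return(list(bases = bases, arrhythmic_seqs = arr,
                  rhythmic = rhythmic, arrhythmic = arrhythmic,
                  validation = v))
  }
  stop("could not construct a matched arrhythmic set in ", max_redraw,
       " redraws")
}

# paired t that tolerates zero-variance differences
paired_t_p <- function(x, y) {
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1))
    return(list(t = sign(mean(d)) * Inf, p = 0))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Check duration and envelope-power equivalence of the matched sets
#'
#' Paired t-tests across the 30 matched pairs on (a) stimulus duration and
#' (b) mean envelope power over 0--10 Hz. A well-matched design gives
#' p > 0.05 on both.
#'
#' @param rhythmic,arrhythmic Parallel lists of `rendered_stimulus`,
#'   paired by (base, tempo, pitch).
#' @param df_hz Envelope-spectrum resolution passed to [envelope_power()].
#' @return List with `p_duration`, `p_power`, `t_duration`, `t_power`,
#'   `durations` and `powers` (2-column matrices, rhythmic first).
#' @export
validate_stimulus_sets <- function(rhythmic, arrhythmic, df_hz = 0.1) {
  if (length(rhythmic) != length(arrhythmic))
    stop("rhythmic and arrhythmic lists must have equal length")
  key <- function(s) paste(s$base_id, s$tempo_unit_ms, s$pitch_hz)
  if (!identical(vapply(rhythmic, key, ""), vapply(arrhythmic, key, "")))
    stop("lists are not paired by (base, tempo, pitch)")
  dur <- cbind(vapply(rhythmic, function(s) s$duration_s, 0),
               vapply(arrhythmic, function(s) s$duration_s, 0))
  pow <- cbind(vapply(rhythmic,
                      function(s) envelope_power(s, df_hz)$mean_power_0_10, 0),
               vapply(arrhythmic,
                      function(s) envelope_power(s, df_hz)$mean_power_0_10, 0))
  td <- paired_t_p(dur[, 1], dur[, 2])
  tp <- paired_t_p(pow[, 1], pow[, 2])
  list(p_duration = td$p, p_power = tp$p,
       t_duration = td$t, t_power = tp$t,
       durations = dur, powers = pow)
}

# Block protocol --------------------------------------------------------

#' Order the 60 stimuli into a block protocol
#'
#' Randomises block order under two constraints: no more than two blocks of
#' the same condition in a row, and no two consecutive blocks from the same
#' base sequence with a different tempo or pitch. Blocks are separated by a
#' silent inter-stimulus interval jittered uniformly in 25--35 s. Order is
#' found by seeded constrained sequential sampling with restart.
#'
#' @param stimuli List of `rendered_stimulus`, half rhythmic and half
#'   arrhythmic.
#' @param seed Integer seed.
#' @param isi_range ISI bounds in seconds (default c(25, 35)).
#' @param lead_in_s Silence before the first block (default 10 s; leaves
#'   room for the pre-stimulus baseline).
#' @param max_retry Restart cap for the constraint sampler.
#' @return A `block_protocol` data frame: `block_index`, `condition`,
#'   `base_id`, `tempo_ms`, `pitch_hz`, `onset_s`, `duration_s`, `isi_s`
#'   (gap following the block; NA for the last).
#' @export
build_protocol <- function(stimuli, seed = 1L, isi_range = c(25, 35),
                           lead_in_s = 10, max_retry = 10000L) {
  conds <- vapply(stimuli, function(s) s$condition, "")
  n <- length(stimuli)
  if (sum(conds == "rhythmic") != n / 2)
    stop("need equally many rhythmic and arrhythmic stimuli")
  set.seed(seed)
  for (try in seq_len(max_retry)) {
    remaining <- seq_len(n)
    order_idx <- integer(0)
    ok <- TRUE
    for (k in seq_len(n)) {
      cand <- remaining
      # condition-run constraint
      if (length(order_idx) >= 2) {
        last2 <- conds[utils::tail(order_idx, 2)]
        if (last2[1] == last2[2])
          cand <- cand[conds[cand] != last2[1]]
      }
      # same-base different-rendering constraint
      if (length(order_idx) >= 1) {
        prev <- stimuli[[utils::tail(order_idx, 1)]]
        bad <- vapply(cand, function(i) {
          s <- stimuli[[i]]
          s$base_id == prev$base_id &&
            (s$tempo_unit_ms != prev$tempo_unit_ms ||
             s$pitch_hz != prev$pitch_hz)
        }, TRUE)
        cand <- cand[!bad]
      }
      if (length(cand) == 0) { ok <- FALSE; break }
      pick <- if (length(cand) == 1) cand else sample(cand, 1)
      order_idx <- c(order_idx, pick)
      remaining <- setdiff(remaining, pick)
    }
    if (ok) {
      isi <- stats::runif(n - 1, isi_range[1], isi_range[2])
      dur <- vapply(stimuli[order_idx], function(s) s$duration_s, 0)
      onset <- lead_in_s + cumsum(c(0, dur[-n] + isi))
      proto <- data.frame(
        block_index = seq_len(n),
        condition = conds[order_idx],
        base_id = vapply(stimuli[order_idx], function(s) s$base_id, 0L),
        tempo_ms = vapply(stimuli[order_idx],
                          function(s) s$tempo_unit_ms, 0),
        pitch_hz = vapply(stimuli[order_idx], function(s) s$pitch_hz, 0),
        onset_s = onset,
        duration_s = dur,
        isi_s = c(isi, NA))
      class(proto) <- c("block_protocol", "data.frame")
      return(proto)
    }
  }
  stop("could not satisfy protocol constraints within ", max_retry,
       " restarts")
}

#' Longest run of a single condition in a protocol
#' @param protocol A `block_protocol`.
#' @return Integer run length.
#' @export
max_condition_run <- function(protocol) {
  max(rle(protocol$condition)$lengths)
}

#' Write a stimulus waveform as a 16-bit PCM WAV file
#' @param stim A `rendered_stimulus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stimulus_wav <- function(stim, path) {
  pcm <- as.integer(round(pmax(-1, pmin(1, stim$waveform)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")        # PCM, mono
  writeBin(as.integer(stim$sr), con, size = 4, endian = "little")
  writeBin(as.integer(stim$sr * 2L), con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
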