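# Synthetic neonatal fNIRS sessions --------------------------------------
#
# Forward model mirroring the analysis chain in reverse: ground-truth
# hemodynamics (canonical neonatal HRF scaled by channel x condition
# amplitudes) + physiological noise + motion artifacts, converted to
# optical density by the modified Beer-Lambert law and then to raw
# dual-wavelength intensities (I = I0 10^-OD, I0 = 1).

FS_DEFAULT <- 10.1215
WAVELENGTHS_NM <- c(690, 830)

#' Canonical neonatal hemodynamic response
#'
#' A gamma-shaped HbO impulse response peaking at `peak_s` (default 10 s,
#' as observed in premature neonates), effectively returned to baseline by
#' 25 s; HbR is the scaled negative mirror (typical neurovascular coupling:
#' HbO increase, HbR decrease).
#'
#' @param amplitude Peak HbO amplitude (micromolar).
#' @param peak_s Time to peak in seconds.
#' @param fs Sampling rate in Hz.
#' @param duration_s Support of the returned kernel (default 25 s).
#' @param hbr_ratio |HbR|/HbO amplitude ratio in (0, 1] (default 1/3).
#' @return List with `t_s`, `hbo`, `hbr` (micromolar).
#' @export
neonatal_hrf <- function(amplitude = 1, peak_s = 10, fs = FS_DEFAULT,
                         duration_s = 25, hbr_ratio = 1 / 3) {
  stopifnot(peak_s > 0, hbr_ratio > 0, hbr_ratio <= 1)
  t <- seq(0, duration_s, by = 1 / fs)
  shape <- 8
  rate <- (shape - 1) / peak_s       # gamma mode at peak_s
  h <- stats::dgamma(t, shape = shape, rate = rate)
  if (max(h) > 0) h <- h / max(h)
  hbo <- amplitude * h
  list(t_s = t, hbo = hbo, hbr = -hbr_ratio * hbo)
}

#' Ground-truth amplitude map for a cohort
#'
#' Baseline response amplitudes by ROI (auditory strongest), with a
#' rhythmic > arrhythmic difference injected on the designated effect
#' channels (by default the right sensorimotor and left premotor ROIs,
#' the regions where beat-based regularity modulates the response).
#'
#' @param montage An `fnirs_montage`.
#' @param effect "default" (condition difference on effect channels) or
#'   "null" (no condition difference anywhere).
#' @param base_uM Baseline HbO peak amplitude for non-auditory channels.
#' @param auditory_uM Baseline amplitude for auditory channels.
#' @param effect_rhythmic_uM,effect_arrhythmic_uM Amplitudes on effect
#'   channels under each condition.
#' @return A `ground_truth`: list with `amp` (channel x condition matrix,
#'   columns rhythmic/arrhythmic, micromolar), `effect_channels`,
#'   `peak_s`, `hbr_ratio`.
#' @export
ground_truth_map <- function(montage, effect = c("default", "null"),
                             base_uM = 1.0, auditory_uM = 1.3,
                             effect_rhythmic_uM = 1.5,
                             effect_arrhythmic_uM = 0.75) {
  effect <- match.arg(effect)
  ch <- montage$channels
  amp <- matrix(base_uM, nrow(ch), 2,
                dimnames = list(ch$channel, c("rhythmic", "arrhythmic")))
  amp[ch$roi == "auditory", ] <- auditory_uM
  eff <- c(roi_channels(montage, "sensorimotor", "right"),
           roi_channels(montage, "premotor", "left"))
  if (effect == "default") {
    amp[as.character(eff), "rhythmic"] <- effect_rhythmic_uM
    amp[as.character(eff), "arrhythmic"] <- effect_arrhythmic_uM
  }
  structure(list(amp = amp, effect_channels = eff,
                 peak_s = 10, hbr_ratio = 1 / 3),
            class = "ground_truth")
}

#' Default physiological-noise and artifact configuration
#'
#' Amplitudes are micromolar HbO. Oscillatory components: cardiac (~2.5 Hz),
#' respiratory (~1 Hz), Mayer waves (~0.1 Hz, inside the analysis band);
#' plus a slow random-walk drift and white measurement noise. Motion
#' artifacts: transient spikes (0.5--2 s) and step baseline shifts, with
#' amplitudes expressed as multiples of the 0.01 Molar x mm detection
#' threshold; `spike_rate`/`shift_rate` are expected events per session
#' (each event hits a contiguous group of channels).
#'
#' @param cardiac_uM,resp_uM,mayer_uM,drift_uM,white_uM Component amplitudes.
#' @param spike_rate,shift_rate Expected artifact events per session.
#' @param spike_mult Range of spike magnitude as a multiple of threshold.
#' @param shift_mult Range of step-shift magnitude (multiple of threshold;
#'   smaller than spikes, since the filtered step leaves a long tail).
#' @param n_global Channels affected by a "global" artifact (> 10 triggers
#'   the all-channel rejection rule).
#' @param global_prob Probability that a spike event is global.
#' @return List of class `noise_config`.
#' @export
noise_config <- function(cardiac_uM = 0.3, resp_uM = 0.2, mayer_uM = 0.3,
                         drift_uM = 0.1, white_uM = 0.05,
                         spike_rate = 2, shift_rate = 1,
                         spike_mult = c(4, 10), shift_mult = c(2, 4),
                         n_global = 12L, global_prob = 0.25) {
  cfg <- list(cardiac_uM = cardiac_uM, resp_uM = resp_uM, mayer_uM = mayer_uM,
              drift_uM = drift_uM, white_uM = white_uM,
              spike_rate = spike_rate, shift_rate = shift_rate,
              spike_mult = spike_mult, shift_mult = shift_mult,
              n_global = n_global, global_prob = global_prob)
  if (any(unlist(cfg[1:7]) < 0)) stop("noise amplitudes/rates must be >= 0")
  structure(cfg, class = "noise_config")
}

# zero noise everywhere; used for round-trip identities
noise_off <- function() {
  noise_config(0, 0, 0, 0, 0, spike_rate = 0, shift_rate = 0)
}

#' Simulate one raw session
#'
#' Per channel, the HbO time course is the sum over blocks of the
#' condition amplitude times the canonical HRF at the block onset
#' (event-related approximation, so noise-free trial averages reproduce
#' the injected HRF exactly), plus physiological noise and seeded motion
#' artifacts; HbR is the scaled negative mirror. Hb is pushed through the
#' Beer-Lambert forward model to optical density and raw intensity.
#'
#' @param montage An `fnirs_montage`.
#' @param truth A `ground_truth` (see [ground_truth_map()]).
#' @param protocol A `block_protocol`.
#' @param noise A `noise_config`.
#' @param seed Integer seed.
#' @param participant_id Identifier stored with the session.
#' @param fs Sampling rate (default 10.1215 Hz).
#' @return A `raw_session`: `intensities` (channel x time x wavelength),
#'   `fs`, `wavelengths_nm`, `events`, `montage`, `truth`,
#'   `artifact_log` (data frame of injected artifacts), `participant_id`,
#'   and `hb_true` (channel x time HbO, micromolar, noise included).
#' @export
simulate_session <- function(montage, truth, protocol, noise = noise_config(),
                             seed = 1L, participant_id = "sim01",
                             fs = FS_DEFAULT) {
  set.seed(seed)
  ch <- montage$channels
  nch <- nrow(ch)
  n <- ceiling((max(protocol$onset_s) + 30) * fs)
  t <- (seq_len(n) - 1) / fs

  # stimulus impulse trains per condition, convolved with the unit HRF
  hrf <- neonatal_hrf(1, truth$peak_s, fs, hbr_ratio = truth$hbr_ratio)
  resp <- matrix(0, 2, n, dimnames = list(c("rhythmic", "arrhythmic"), NULL))
  for (cond in rownames(resp)) {
    imp <- numeric(n)
    onsets <- protocol$onset_s[protocol$condition == cond]
    imp[pmin(n, round(onsets * fs) + 1L)] <- 1
    resp[cond, ] <- stats::convolve(imp, rev(hrf$hbo), type = "open")[seq_len(n)]
  }
  hbo <- truth$amp[, "rhythmic"] %o% resp["rhythmic", ] +
         truth$amp[, "arrhythmic"] %o% resp["arrhythmic", ]

  # physiological noise, independent per channel with jittered frequencies
  osc <- function(amp_uM, f0) {
    if (amp_uM == 0) return(0)
    f <- f0 * stats::runif(nch, 0.9, 1.1)
    ph <- stats::runif(nch, 0, 2 * pi)
    a <- amp_uM * stats::runif(nch, 0.7, 1.3)
    a * sin(outer(2 * pi * f, t) + ph)
  }
  noise_hbo <- osc(noise$cardiac_uM, 2.5) + osc(noise$resp_uM, 1.0) +
               osc(noise$mayer_uM, 0.1)
  if (noise$drift_uM > 0) {
    drift <- t(apply(matrix(stats::rnorm(nch * n, sd = noise$drift_uM / sqrt(n)),
                            nch, n), 1, cumsum))
    noise_hbo <- noise_hbo + drift
  }
  if (noise$white_uM > 0)
    noise_hbo <- noise_hbo + matrix(stats::rnorm(nch * n, sd = noise$white_uM),
                                    nch, n)
  hbo <- hbo + noise_hbo
  hbr <- -truth$hbr_ratio * hbo

  # motion artifacts: spikes and step shifts on contiguous channel groups
  thresh_uM <- 0.01 / ch$separation_mm * 1e6   # 0.01 M mm in micromolar
  log <- list()
  inject <- function(kind, n_events) {
    for (k in seq_len(n_events)) {
      global <- kind == "spike" && stats::runif(1) < noise$global_prob
      size <- if (global) noise$n_global
              else if (kind == "spike") sample(1:5, 1) else sample(1:3, 1)
      c0 <- sample(nch, 1)
      chans <- unique(pmin(nch, seq(c0, length.out = size)))
      t0 <- stats::runif(1, 5, max(6, n / fs - 5))
      mrange <- if (kind == "spike") noise$spike_mult else noise$shift_mult
      mult <- stats::runif(1, mrange[1], mrange[2])
      if (kind == "spike") {
        w <- stats::runif(1, 0.5, 2)
        sel <- which(t >= t0 & t <= t0 + w)
        shape <- sin(pi * seq_along(sel) / length(sel))^2
        for (cc in chans)
          hbo[cc, sel] <<- hbo[cc, sel] + sign(stats::runif(1) - 0.5) *
            mult * thresh_uM[cc] * shape
      } else {
        sel <- which(t >= t0)
        for (cc in chans)
          hbo[cc, sel] <<- hbo[cc, sel] + sign(stats::runif(1) - 0.5) *
            mult * thresh_uM[cc]
        w <- NA_real_
      }
      log[[length(log) + 1L]] <<- data.frame(kind = kind, t_s = t0,
                                             width_s = w, mult = mult,
                                             channels = I(list(chans)))
    }
  }
  inject("spike", stats::rpois(1, noise$spike_rate))
  inject("shift", stats::rpois(1, noise$shift_rate))
  hbr <- -truth$hbr_ratio * hbo   # artifacts hit both chromophores

  od <- hb_to_od(hbo * 1e-6, hbr * 1e-6, ch$separation_mm)
  intensities <- array(NA_real_, c(nch, n, 2),
                       dimnames = list(ch$channel, NULL, WAVELENGTHS_NM))
  intensities[, , 1] <- 10^(-od$od690)
  intensities[, , 2] <- 10^(-od$od830)

  structure(list(intensities = intensities, fs = fs,
                 wavelengths_nm = WAVELENGTHS_NM,
                 events = protocol, montage = montage, truth = truth,
                 artifact_log = if (length(log)) do.call(rbind, log)
                                else data.frame(),
                 participant_id = participant_id,
                 hb_true = hbo),
            class = "raw_session")
}

#' Design a block protocol without rendering audio
#'
#' Builds the base and arrhythmic sequences, computes rendering durations
#' analytically (total units x tempo + 0.5 s tail) and orders the blocks
#' under the usual constraints. With `n_blocks < 60` a balanced subset of
#' (base, tempo, pitch) combinations is used, the same combinations in
#' both conditions.
#'
#' @param seed Integer seed.
#' @param n_blocks Even total number of blocks (default 60).
#' @return A `block_protocol`.
#' @export
design_protocol <- function(seed = 1L, n_blocks = 60L) {
  stopifnot(n_blocks %% 2 == 0, n_blocks <= 60)
  set.seed(seed)
  bases <- compose_rhythmic_bases(seed)
  arr <- lapply(bases, function(b) make_arrhythmic(b, seed = seed + b$base_id))
  grid <- expand.grid(base = 1:5, tempo = TEMPI_MS, pitch = PITCHES_HZ)
  keep <- if (n_blocks < 60) sort(sample(nrow(grid), n_blocks / 2))
          else seq_len(nrow(grid))
  stub <- function(seq, cond, tempo, pitch, base_id) {
    structure(list(condition = cond, base_id = base_id,
                   tempo_unit_ms = tempo, pitch_hz = pitch,
                   duration_s = sum(seq$intervals) * tempo / 1000 + 0.5),
              class = "rendered_stimulus")
  }
  for (try in 1:10) {
    stims <- c(
      lapply(keep, function(i) stub(bases[[grid$base[i]]], "rhythmic",
                                    grid$tempo[i], grid$pitch[i],
                                    grid$base[i])),
      lapply(keep, function(i) stub(arr[[grid$base[i]]], "arrhythmic",
                                    grid$tempo[i], grid$pitch[i],
                                    grid$base[i])))
    proto <- tryCatch(build_protocol(stims, seed = seed + try - 1L),
                      error = function(e) NULL)
    if (!is.null(proto)) return(proto)
    # tiny subsets can be unorderable (e.g. one base at two renderings);
    # redraw the subset
    keep <- sort(sample(nrow(grid), n_blocks / 2))
  }
  stop("could not design an orderable protocol subset")
}

#' Simulate a cohort of sessions
#'
#' Each participant gets an individual block order and an individual
#' overall responsiveness drawn from a lognormal scale (sdlog
#' `between_sdlog`), applied to the shared ground-truth amplitude map;
#' per-channel lognormal jitter (`channel_sdlog`) adds local variability.
#'
#' @param n_participants Number of sessions (default 11).
#' @param effect Passed to [ground_truth_map()] ("default" or "null").
#' @param seed Integer seed.
#' @param n_blocks Blocks per session (default 60).
#' @param montage Montage shared by the cohort (default [build_montage()]).
#' @param noise A `noise_config`.
#' @param between_sdlog,channel_sdlog Lognormal sd of participant / channel
#'   amplitude scaling (defaults 0.25 / 0.10).
#' @param fs Sampling rate.
#' @return List of `raw_session`.
#' @export
simulate_cohort <- function(n_participants = 11L,
                            effect = c("default", "null"),
                            seed = 1L, n_blocks = 60L,
                            montage = build_montage(),
                            noise = noise_config(),
                            between_sdlog = 0.25, channel_sdlog = 0.10,
                            fs = FS_DEFAULT) {
  effect <- match.arg(effect)
  truth0 <- ground_truth_map(montage, effect)
  lapply(seq_len(n_participants), function(p) {
    pseed <- seed * 1009L + p
    set.seed(pseed)
    scale_p <- stats::rlnorm(1, 0, between_sdlog)
    scale_ch <- stats::rlnorm(nrow(truth0$amp), 0, channel_sdlog)
    truth <- truth0
    truth$amp <- truth0$amp * scale_p * scale_ch
    proto <- design_protocol(seed = pseed, n_blocks = n_blocks)
    simulate_session(montage, truth, proto, noise, seed = pseed + 500000L,
                     participant_id = sprintf("sim%02d", p), fs = fs)
  })
}

#' Write a session's intensities and events as plain-text files
#'
#' Writes `<prefix>_intensity_690.csv`, `<prefix>_intensity_830.csv`
#' (channels x time), `<prefix>_events.tsv` and `<prefix>_montage.csv`.
#'
#' @param session A `raw_session`.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_session_csv <- function(session, prefix) {
  utils::write.csv(session$intensities[, , 1],
                   paste0(prefix, "_intensity_690.csv"), row.names = FALSE)
  utils::write.csv(session$intensities[, , 2],
                   paste0(prefix, "_intensity_830.csv"), row.names = FALSE)
  utils::write.table(session$events, paste0(prefix, "_events.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(session$montage$channels, paste0(prefix, "_montage.csv"),
                   row.names = FALSE)
  invisible(prefix)
}
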