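# Preprocessing chain ----------------------------------------------------
#
# Raw intensities -> optical density -> band-pass (0.03-0.5 Hz, zero-phase
# Butterworth) -> modified Beer-Lambert law -> motion-artifact mask ->
# per-channel z-scoring -> 30 s epochs (-5..+25 s around onsets) with
# linear detrend + baseline correction -> four trial-rejection rules ->
# channel exclusion (> 80% rejected) -> per-condition averages at 1 Hz.

#' Preprocessing configuration
#'
#' Defaults follow standard neonatal fNIRS practice: analysis band 0.03--0.5 Hz;
#' motion artifacts where |Hb x distance| exceeds 0.01 Molar x mm, masked
#' over a 3 s window, globally when more than 10 channels exceed at once;
#' trial rejection on |z| > 3, on concentration gradients over 0.4 s steps
#' exceeding 1.5 (z units), on post-onset area under the curve below 10
#' (z s), and on artifact overlap; channels excluded per condition beyond
#' 80% rejected trials; epochs -5..+25 s; group channels need at least 4
#' contributing participants; analysis rate 1 Hz.
#'
#' @param band_hz Band-pass edges in Hz.
#' @param artifact_abs_threshold Motion threshold (Molar x mm).
#' @param artifact_window_s Mask window around an exceedance (s).
#' @param artifact_channel_count Channels above which a sample is masked
#'   everywhere.
#' @param z_reject Within-trial |z| rejection threshold.
#' @param gradient_step_s,gradient_threshold Step length (s) and gradient
#'   limit (z units) of the gradient rule.
#' @param auc_min Minimum post-onset area under the curve (z s).
#' @param max_rejected_fraction Per channel x condition exclusion threshold.
#' @param epoch_s Epoch window (s relative to onset), default c(-5, 25).
#' @param min_participants_per_channel Group-level retention threshold.
#' @param downsample_hz Analysis rate after averaging.
#' @param dpf,extinction Beer-Lambert parameters.
#' @param filter_order Butterworth order (applied forward-backward).
#' @return A `preprocess_config`.
#' @export
preprocess_config <- function(band_hz = c(0.03, 0.5),
                              artifact_abs_threshold = 0.01,
                              artifact_window_s = 3,
                              artifact_channel_count = 10L,
                              z_reject = 3,
                              gradient_step_s = 0.4,
                              gradient_threshold = 1.5,
                              auc_min = 10,
                              max_rejected_fraction = 0.80,
                              epoch_s = c(-5, 25),
                              min_participants_per_channel = 4L,
                              downsample_hz = 1,
                              dpf = dpf_defaults(),
                              extinction = extinction_defaults(),
                              filter_order = 3L) {
  stopifnot(band_hz[1] > 0, band_hz[1] < band_hz[2],
            artifact_abs_threshold > 0, z_reject > 0,
            gradient_threshold > 0, max_rejected_fraction > 0,
            epoch_s[1] < 0, epoch_s[2] > 0)
  structure(as.list(environment()), class = "preprocess_config")
}

#' Convert raw intensities to optical density
#'
#' OD = -log10(I / I_ref) with I_ref the per-channel temporal mean, per
#' wavelength.
#'
#' @param session A `raw_session`.
#' @return List of channel x time matrices `od690`, `od830`.
#' @export
intensity_to_od <- function(session) {
  conv <- function(w) {
    x <- session$intensities[, , w, drop = FALSE]
    dim(x) <- dim(x)[1:2]
    bad <- which(x <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("nonpositive intensity at channel %s, sample %s (%s nm)",
                   bad[1, 1], bad[1, 2], session$wavelengths_nm[w]))
    -log10(x / rowMeans(x))
  }
  list(od690 = conv(1), od830 = conv(2))
}

#' Zero-phase band-pass filter
#'
#' Butterworth of order `config$filter_order` applied forward and backward.
#' The two passes are realised as |H(w)|^2 in the frequency domain over all
#' channels at once, with odd-reflection padding longer than the high-pass
#' transient; away from the edges this matches `signal::filtfilt` of the
#' same design.
#'
#' @param od Channel x time matrix (or list of such matrices).
#' @param fs Sampling rate in Hz.
#' @param config A `preprocess_config`.
#' @return Filtered object of the same shape.
#' @export
bandpass <- function(od, fs, config = preprocess_config()) {
  if (is.list(od)) return(lapply(od, bandpass, fs = fs, config = config))
  bf <- signal::butter(config$filter_order, config$band_hz / (fs / 2),
                       type = "pass")
  b <- bf$b
  a <- bf$a
  n <- ncol(od)
  # odd-reflection padding longer than the high-pass transient
  pad <- min(n - 1L, as.integer(3 * ceiling(fs / config$band_hz[1])))
  y <- t(od)                                  # time x channels
  ext <- rbind(2 * rep(1, pad) %o% y[1, ] - y[(pad + 1):2, , drop = FALSE],
               y,
               2 * rep(1, pad) %o% y[n, ] - y[(n - 1):(n - pad), ,
                                              drop = FALSE])
  # forward-backward IIR filtering equals applying |H(w)|^2 with zero
  # phase; do that in the frequency domain over all channels at once
  n_ext <- nrow(ext)
  m <- next_fast_len(n_ext)
  if (m > n_ext) ext <- rbind(ext, matrix(0, m - n_ext, ncol(ext)))
  w <- 2 * pi * (seq_len(m) - 1) / m
  e <- exp(-1i * w)
  polyv <- function(cf) Reduce(function(acc, ck) acc * e + ck, cf)
  h2 <- Mod(polyv(b) / polyv(a))^2
  z <- Re(stats::mvfft(stats::mvfft(ext) * h2, inverse = TRUE)) / m
  t(z[(pad + 1):(pad + n), , drop = FALSE])
}

#' Optical density to hemoglobin concentration series
#'
#' Applies the inverse modified Beer-Lambert law per channel.
#'
#' @param od List with `od690`, `od830` (channel x time).
#' @param montage An `fnirs_montage` (channel separations).
#' @param config A `preprocess_config`.
#' @return An `hb_series`: `hbo`, `hbr` (channel x time, micromolar),
#'   `fs` unset until attached by the caller.
#' @export
od_to_hb_series <- function(od, montage, config = preprocess_config()) {
  hb <- od_to_hb(od$od690, od$od830, montage$channels$separation_mm,
                 dpf = config$dpf, extinction = config$extinction)
  structure(list(hbo = hb$hbo, hbr = hb$hbr), class = "hb_series")
}

#' Detect motion artifacts
#'
#' A sample is an exceedance when |Hb x separation| > the threshold
#' (Molar x mm) on either chromophore; a +-1.5 s window around each
#' exceedance is masked on that channel. Samples exceeding on more than
#' `artifact_channel_count` channels are masked on all channels.
#'
#' @param hb An `hb_series` (micromolar).
#' @param montage An `fnirs_montage`.
#' @param fs Sampling rate.
#' @param config A `preprocess_config`.
#' @return Logical channel x time mask (TRUE = artifact).
#' @export
detect_motion <- function(hb, montage, fs, config = preprocess_config()) {
  sep <- montage$channels$separation_mm
  prod_mm <- pmax(abs(hb$hbo), abs(hb$hbr)) * 1e-6 * sep  # Molar x mm
  exceed <- prod_mm > config$artifact_abs_threshold
  half <- round(config$artifact_window_s / 2 * fs)
  # global rule: sample bad on > K channels -> bad everywhere
  global <- colSums(exceed) > config$artifact_channel_count
  exceed[, global] <- TRUE
  mask <- matrix(FALSE, nrow(exceed), ncol(exceed))
  nt <- ncol(exceed)
  dilate <- function(v) {
    idx <- which(v)
    if (!length(idx)) return(v)
    # interval-stabbing via a difference array: O(n)
    delta <- integer(nt + 1L)
    lo <- pmax(1L, idx - half)
    hi <- pmin(nt, idx + half)
    for (k in seq_along(idx)) {
      delta[lo[k]] <- delta[lo[k]] + 1L
      delta[hi[k] + 1L] <- delta[hi[k] + 1L] - 1L
    }
    cumsum(delta[seq_len(nt)]) > 0
  }
  for (ch in seq_len(nrow(exceed))) mask[ch, ] <- dilate(exceed[ch, ])
  mask
}

#' Z-score each channel over the whole recording
#'
#' Mean and SD are computed over unmasked samples only; the transform is
#' applied to every sample.
#'
#' @param hb An `hb_series`.
#' @param mask Optional logical artifact mask (TRUE = exclude from stats).
#' @return An `hb_series` with standardized `hbo`/`hbr`.
#' @export
zscore_channels <- function(hb, mask = NULL) {
  zs <- function(m) {
    t(vapply(seq_len(nrow(m)), function(i) {
      x <- m[i, ]
      use <- if (is.null(mask)) rep(TRUE, length(x)) else !mask[i, ]
      (x - mean(x[use])) / stats::sd(x[use])
    }, numeric(ncol(m))))
  }
  structure(list(hbo = zs(hb$hbo), hbr = zs(hb$hbr)), class = "hb_series")
}

#' Cut 30 s epochs and apply the four trial-rejection rules
#'
#' Epochs span `config$epoch_s` (half-open, 0-based sample indexing)
#' around each block onset; each trial is linearly detrended over the
#' whole epoch and baseline-corrected by subtracting its pre-onset mean.
#' Rejection codes, evaluated in order per trial x channel:
#' `z_exceeded` (|z| > 3 anywhere in the trial), `gradient` (change over
#' 0.4 s steps > 1.5), `auc` (post-onset area under the curve < 10 z s),
#' `artifact_overlap` (any masked sample), else `kept`.
#'
#' @param z An `hb_series`, z-scored.
#' @param events A `block_protocol`.
#' @param mask Logical artifact mask from [detect_motion()].
#' @param fs Sampling rate.
#' @param config A `preprocess_config`.
#' @return An `epoch_set`: `epochs` (trial x channel x time HbO, detrended
#'   and baseline-corrected), `time_s`, `trials` (condition, tempo, pitch,
#'   onset), `rejection` (trial x channel character matrix), `fs`.
#' @export
epoch_and_clean <- function(z, events, mask, fs, config = preprocess_config()) {
  n <- ncol(z$hbo)
  nch <- nrow(z$hbo)
  n_ep <- round(diff(config$epoch_s) * fs)      # 30 s of samples
  rel_t <- config$epoch_s[1] + (seq_len(n_ep) - 1) / fs
  pre <- rel_t < 0
  post <- rel_t >= 0
  step <- round(config$gradient_step_s * fs)

  ok_events <- events$onset_s + config$epoch_s[2] <= n / fs &
               events$onset_s + config$epoch_s[1] >= 0
  if (any(!ok_events))
    warning(sum(!ok_events), " event(s) beyond the recording were skipped")
  ev <- events[ok_events, ]
  ntr <- nrow(ev)

  # residual-maker for the linear detrend, shared by all trials/channels
  X <- cbind(1, seq_len(n_ep))
  P <- diag(n_ep) - X %*% solve(crossprod(X), t(X))

  epochs <- array(NA_real_, c(ntr, nch, n_ep))
  rejection <- matrix("kept", ntr, nch)
  for (tr in seq_len(ntr)) {
    i0 <- round((ev$onset_s[tr] + config$epoch_s[1]) * fs)   # 0-based
    idx <- i0 + seq_len(n_ep)                                 # 1-based slice
    seg <- z$hbo[, idx, drop = FALSE]
    mseg <- mask[, idx, drop = FALSE]
    x <- seg %*% P                                # detrend
    x <- x - rowMeans(x[, pre, drop = FALSE])     # baseline-correct
    epochs[tr, , ] <- x
    z_bad <- apply(abs(seg), 1, max) > config$z_reject
    grad <- seg[, (step + 1):n_ep, drop = FALSE] -
            seg[, 1:(n_ep - step), drop = FALSE]
    g_bad <- apply(abs(grad), 1, max) > config$gradient_threshold
    # rectified area: a flat/quiet-trial screen. A z-scored trial of
    # session-typical variance integrates to ~ 0.8 * 25 = 20 z s; the
    # signed integral of a band-passed (zero-mean) signal would hover
    # near 0 and reject everything.
    a_bad <- rowSums(abs(x[, post, drop = FALSE])) / fs < config$auc_min
    m_bad <- rowSums(mseg) > 0
    code <- rep("kept", nch)
    code[m_bad] <- "artifact_overlap"
    code[a_bad] <- "auc"
    code[g_bad] <- "gradient"
    code[z_bad] <- "z_exceeded"                   # rule order: 1 wins
    rejection[tr, ] <- code
  }
  structure(list(epochs = epochs, time_s = rel_t,
                 trials = ev[, c("condition", "tempo_ms", "pitch_hz",
                                 "onset_s")],
                 rejection = rejection, fs = fs),
            class = "epoch_set")
}

#' Exclude over-rejected channels and average retained trials
#'
#' A channel is excluded for a condition when more than
#' `max_rejected_fraction` of its trials are rejected (strictly greater).
#' Retained trials are averaged over tempi and pitches per condition,
#' then decimated to `downsample_hz` by non-overlapping bin means (the
#' 0.5 Hz low-pass already prevents aliasing).
#'
#' @param epochs An `epoch_set`.
#' @param config A `preprocess_config`.
#' @return A `condition_average`: `mean_hbo` (channel x condition x time
#'   array at 1 Hz), `time_s` (bin start times), `n_trials`
#'   (channel x condition contributing counts), `excluded`
#'   (channel x condition logical), `participant_id` unset by default.
#' @export
exclude_and_average <- function(epochs, config = preprocess_config()) {
  conds <- c("rhythmic", "arrhythmic")
  nch <- dim(epochs$epochs)[2]
  fs <- epochs$fs
  # non-overlapping 1/downsample_hz s bins defined on the time axis, so a
  # non-integer samples-per-second rate cannot drift the grid
  bin_id <- floor((epochs$time_s - epochs$time_s[1]) * config$downsample_hz)
  n_bins <- max(bin_id) + 1L
  t_out <- epochs$time_s[1] + (seq_len(n_bins) - 1) / config$downsample_hz
  mean_hbo <- array(NA_real_, c(nch, 2, n_bins),
                    dimnames = list(NULL, conds, NULL))
  n_trials <- matrix(0L, nch, 2, dimnames = list(NULL, conds))
  excluded <- matrix(FALSE, nch, 2, dimnames = list(NULL, conds))
  for (ci in 1:2) {
    tr_sel <- which(epochs$trials$condition == conds[ci])
    for (ch in seq_len(nch)) {
      kept <- tr_sel[epochs$rejection[tr_sel, ch] == "kept"]
      frac_rej <- 1 - length(kept) / length(tr_sel)
      if (frac_rej > config$max_rejected_fraction || length(kept) == 0) {
        excluded[ch, ci] <- TRUE
        next
      }
      avg <- if (length(kept) == 1) epochs$epochs[kept, ch, ]
             else colMeans(epochs$epochs[kept, ch, , drop = FALSE][, 1, ])
      mean_hbo[ch, ci, ] <- as.numeric(tapply(avg, bin_id, mean))
      n_trials[ch, ci] <- length(kept)
    }
  }
  structure(list(mean_hbo = mean_hbo, time_s = t_out,
                 n_trials = n_trials, excluded = excluded),
            class = "condition_average")
}

#' Run the full chain on one session
#'
#' @param session A `raw_session`.
#' @param config A `preprocess_config`.
#' @return A `condition_average` with `participant_id` attached, plus a
#'   `qc` list (rejection counts per rule, excluded channels, mask
#'   fraction).
#' @export
preprocess_session <- function(session, config = preprocess_config()) {
  od <- intensity_to_od(session)
  od <- bandpass(od, session$fs, config)
  hb <- od_to_hb_series(od, session$montage, config)
  mask <- detect_motion(hb, session$montage, session$fs, config)
  z <- zscore_channels(hb, mask)
  ep <- epoch_and_clean(z, session$events, mask, session$fs, config)
  avg <- exclude_and_average(ep, config)
  avg$participant_id <- session$participant_id
  avg$qc <- list(rule_counts = table(ep$rejection),
                 n_excluded = colSums(avg$excluded),
                 mask_fraction = mean(mask))
  avg
}

#' Channels retained at group level
#'
#' A channel enters group statistics for a condition only when at least
#' `min_participants_per_channel` participants contribute an average.
#'
#' @param averages List of `condition_average` (one per participant).
#' @param config A `preprocess_config`.
#' @return Logical channel x condition matrix (TRUE = retained).
#' @export
group_retained_channels <- function(averages, config = preprocess_config()) {
  contrib <- Reduce(`+`, lapply(averages, function(a) !a$excluded))
  contrib >= config$min_participants_per_channel
}
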