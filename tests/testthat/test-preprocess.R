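# a minimal raw_session wrapper around given intensity arrays
manual_session <- function(intensities, fs = 10.1215, montage = NULL,
                           events = NULL) {
  structure(list(intensities = intensities, fs = fs,
                 wavelengths_nm = c(690, 830), events = events,
                 montage = montage, participant_id = "manual"),
            class = "raw_session")
}

test_that("optical density conversion references the temporal mean", {
  ints <- array(1, c(2, 100, 2))
  od <- intensity_to_od(manual_session(ints))
  expect_true(all(od$od690 == 0))
  # intensity at a tenth of its reference: OD = 1
  ints2 <- array(1, c(1, 10, 2))
  ints2[1, 1, ] <- 1 / 10
  ref <- mean(ints2[1, , 1])
  od2 <- intensity_to_od(manual_session(ints2))
  expect_equal(od2$od690[1, 1], -log10((1 / 10) / ref))
  ints3 <- ints
  ints3[2, 5, 1] <- 0
  expect_error(intensity_to_od(manual_session(ints3)), "channel 2, sample 5")
})

test_that("the band-pass has the specified frequency response", {
  fs <- 10.1215
  n <- 8000
  t <- (1:n) / fs
  mid <- 2000:6000
  gain <- function(f) {
    y <- bandpass(matrix(sin(2 * pi * f * t), 1), fs)
    max(abs(y[1, mid]))
  }
  expect_lt(gain(1e-9), 0.01)           # DC
  expect_gte(gain(0.1), 0.9)            # passband
  expect_lte(gain(0.1), 1.0 + 1e-6)
  expect_lt(gain(0.005), 0.1)           # >= 20 dB down
  expect_lt(gain(2), 0.1)
})

test_that("motion detection applies the window and the global rule", {
  m <- fixture_montage()
  fs <- 10.1215
  nch <- nrow(m$channels)
  n <- 600
  hb <- list(hbo = matrix(0, nch, n), hbr = matrix(0, nch, n))
  uM <- function(ch) 0.011 / m$channels$separation_mm[ch] * 1e6
  # single-channel spike: ~3 s masked on that channel only
  hb$hbo[5, 300] <- uM(5)
  mask <- detect_motion(structure(hb, class = "hb_series"), m, fs)
  expect_true(mask[5, 300])
  expect_equal(sum(mask[5, ]), 2 * round(1.5 * fs) + 1)
  expect_equal(sum(mask[-5, ]), 0)
  # sub-threshold stays clean
  hb$hbo[5, 300] <- 0.009 / m$channels$separation_mm[5] * 1e6
  expect_equal(sum(detect_motion(structure(hb, class = "hb_series"),
                                 m, fs)), 0)
  # spike on 11 channels: masked on every channel
  hb$hbo[, ] <- 0
  for (cc in 1:11) hb$hbo[cc, 100] <- uM(cc)
  mask2 <- detect_motion(structure(hb, class = "hb_series"), m, fs)
  expect_true(all(mask2[, 100]))
  # but on 10 channels it stays local
  hb$hbo[, ] <- 0
  for (cc in 1:10) hb$hbo[cc, 100] <- uM(cc)
  mask3 <- detect_motion(structure(hb, class = "hb_series"), m, fs)
  expect_true(all(mask3[1:10, 100]))
  expect_equal(sum(mask3[11:nch, ]), 0)
})

test_that("z-scoring standardizes per channel and honours the mask", {
  set.seed(3)
  hb <- structure(list(hbo = matrix(rnorm(3 * 500, mean = 4, sd = 9), 3),
                       hbr = matrix(rnorm(3 * 500), 3)),
                  class = "hb_series")
  z <- zscore_channels(hb)
  expect_equal(unname(rowMeans(z$hbo)), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(z$hbo, 1, sd), rep(1, 3), tolerance = 1e-12)
  # affine invariance
  hb2 <- hb
  hb2$hbo <- 5 * hb$hbo - 2
  expect_equal(zscore_channels(hb2)$hbo, z$hbo)
  # masked samples are excluded from the statistics: direct recomputation
  mask <- matrix(FALSE, 3, 500)
  mask[1, 1:50] <- TRUE
  zm <- zscore_channels(hb, mask)
  keep <- hb$hbo[1, -(1:50)]
  expect_equal(zm$hbo[1, ],
               (hb$hbo[1, ] - mean(keep)) / sd(keep))
})

test_that("epochs are 30 s long and the rejection rules fire individually", {
  fs <- 10.1215
  n <- 2000
  nch <- 3
  n_ep <- round(30 * fs)
  events <- data.frame(condition = c("rhythmic", "arrhythmic"),
                       tempo_ms = 140, pitch_hz = 440,
                       onset_s = c(40, 120))
  mk <- function(z_hbo, mask = matrix(FALSE, nch, n)) {
    z <- structure(list(hbo = z_hbo, hbr = -z_hbo / 3), class = "hb_series")
    epoch_and_clean(z, events, mask, fs)
  }
  # a wide positive bump after each onset keeps the AUC rule quiet
  base <- matrix(0, nch, n)
  t <- (seq_len(n) - 1) / fs
  for (o in events$onset_s)
    base <- base + rep(1.5 * exp(-(t - o - 10)^2 / 40), each = nch)
  ep <- mk(base)
  expect_equal(dim(ep$epochs), c(2, nch, n_ep))
  expect_equal(length(ep$time_s), n_ep)
  expect_equal(min(ep$time_s), -5)
  expect_lt(max(ep$time_s), 25)
  expect_true(all(ep$rejection == "kept"))
  # baseline of every retained epoch is ~ 0 after correction
  expect_lt(max(abs(rowMeans(ep$epochs[1, , ep$time_s < 0]))), 1e-10)

  # rule 1: one sample beyond |z| = 3
  x <- base
  x[2, round(50 * fs)] <- 3.2
  expect_equal(mk(x)$rejection[1, 2], "z_exceeded")
  # rule 2: a fast jump > 1.5 within 0.4 s (kept below |z| = 3)
  x <- base
  x[3, round(45 * fs) + 0:3] <- 0
  x[3, round(45 * fs) + 4:8] <- 1.8
  expect_equal(mk(x)$rejection[1, 3], "gradient")
  # rule 3: flat zero trial -> rectified AUC 0 < 10
  expect_equal(mk(matrix(0, nch, n))$rejection[1, 1], "auc")
  # rule 4: overlap with the motion mask
  mask <- matrix(FALSE, nch, n)
  mask[1, round(45 * fs)] <- TRUE
  expect_equal(mk(base, mask)$rejection[1, 1], "artifact_overlap")
  expect_equal(mk(base, mask)$rejection[1, 2], "kept")

  # events beyond the recording are skipped with a warning
  ev2 <- rbind(events, data.frame(condition = "rhythmic", tempo_ms = 140,
                                  pitch_hz = 440, onset_s = 500))
  z <- structure(list(hbo = base, hbr = -base / 3), class = "hb_series")
  expect_warning(ep2 <- epoch_and_clean(z, ev2, matrix(FALSE, nch, n), fs),
                 "skipped")
  expect_equal(dim(ep2$epochs)[1], 2)
})

test_that("channel exclusion respects the strict 80% rule and 1 Hz binning", {
  fs <- 10.1215
  n_ep <- round(30 * fs)
  n_tr <- 60
  set.seed(8)
  epochs <- array(rnorm(n_tr * 2 * n_ep), c(n_tr, 2, n_ep))
  time_s <- -5 + (seq_len(n_ep) - 1) / fs
  trials <- data.frame(condition = rep(c("rhythmic", "arrhythmic"), 30),
                       tempo_ms = 140, pitch_hz = 440, onset_s = 1:60)
  rejection <- matrix("kept", n_tr, 2)
  rhy <- which(trials$condition == "rhythmic")
  rejection[rhy[1:25], 1] <- "auc"       # 25/30 = 83% rejected
  rejection[rhy[1:24], 2] <- "auc"       # 24/30 = 80%: retained
  ep <- structure(list(epochs = epochs, time_s = time_s, trials = trials,
                       rejection = rejection, fs = fs),
                  class = "epoch_set")
  avg <- exclude_and_average(ep)
  expect_true(avg$excluded[1, "rhythmic"])
  expect_false(avg$excluded[2, "rhythmic"])
  expect_equal(unname(avg$n_trials[2, "rhythmic"]), 6L)
  expect_equal(avg$time_s, -5:24)
  # 1 Hz samples are means of the kept trials' 1 s bins
  kept <- rhy[25:30]
  bin0 <- time_s >= -5 & time_s < -4
  expect_equal(unname(avg$mean_hbo[2, 1, 1]),
               mean(colMeans(epochs[kept, 2, ])[bin0]))
})

test_that("the preprocessing chain is deterministic end to end", {
  m <- fixture_montage()
  s <- simulate_session(m, ground_truth_map(m),
                        design_protocol(seed = 6, n_blocks = 4),
                        noise_config(), seed = 13)
  a1 <- preprocess_session(s)
  a2 <- preprocess_session(s)
  expect_identical(a1$mean_hbo, a2$mean_hbo)
  expect_identical(a1$excluded, a2$excluded)
})

test_that("group retention needs at least 4 contributing participants", {
  mk_avg <- function(excluded_row1) {
    structure(list(excluded = rbind(excluded_row1,
                                    matrix(FALSE, 4, 2))),
              class = "condition_average")
  }
  avgs <- c(lapply(1:3, function(i) mk_avg(c(FALSE, FALSE))),
            lapply(1:4, function(i) mk_avg(c(TRUE, TRUE))))
  ret <- group_retained_channels(avgs)
  expect_false(ret[1, 1])    # only 3 participants contribute channel 1
  expect_true(all(ret[2:5, ]))
})
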