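test_that("base sequences satisfy the interval, length and beat constraints", {
  bases <- compose_rhythmic_bases(seed = 1)
  expect_length(bases, 5)
  for (b in bases) {
    expect_true(all(b$intervals %in% 1:4))
    expect_gte(length(b$intervals), 42)
    expect_lte(length(b$intervals), 45)
    expect_equal(b$n_tones, length(b$intervals) + 1L)
    expect_gte(sum(b$intervals), 93)
    expect_lte(sum(b$intervals), 104)
    expect_gte(beat_alignment(b), 0.8)
  }
  expect_identical(bases, compose_rhythmic_bases(seed = 1))
  expect_false(identical(bases, compose_rhythmic_bases(seed = 2)))
})

test_that("arrhythmic derivation balances labels within each interval category", {
  bases <- compose_rhythmic_bases(seed = 3)
  for (b in bases) {
    arr <- make_arrhythmic(b, seed = 11)
    expect_equal(length(arr$intervals), length(b$intervals))
    log <- arr$perturbation_log
    # per-category split as equal as integer division allows
    for (v in unique(log$source_units)) {
      cnt <- table(factor(log$label[log$source_units == v],
                          levels = c("shortened", "same", "lengthened")))
      expect_lte(max(cnt) - min(cnt), 1)
    }
    expect_true(all(stats::na.omit(log$factor) %in% c(0.20, 0.25, 0.33)))
    # perturbed intervals carry their factor exactly
    expect_equal(arr$intervals,
                 ifelse(log$label == "shortened",
                        log$source_units * (1 - log$factor),
                        ifelse(log$label == "lengthened",
                               log$source_units * (1 + log$factor),
                               log$source_units)))
  }
})

test_that("tiny categories get a best-effort one-of-each split", {
  seq3 <- structure(list(base_id = 1L, intervals = c(2L, 2L, 2L),
                         n_tones = 4L), class = "rhythm_sequence")
  arr <- make_arrhythmic(seq3, seed = 5)
  expect_setequal(arr$perturbation_log$label,
                  c("shortened", "same", "lengthened"))
})

test_that("arrhythmic total duration stays close to the source in expectation", {
  b <- compose_rhythmic_bases(seed = 1)[[1]]
  ratios <- vapply(1:300, function(k)
    sum(make_arrhythmic(b, seed = k)$intervals) / sum(b$intervals), 0)
  expect_gte(mean(ratios), 0.98)
  expect_lte(mean(ratios), 1.06)
})

test_that("rendering places onsets at cumulative interval sums", {
  seq12 <- structure(list(base_id = 1L, intervals = c(1L, 2L), n_tones = 3L),
                     class = "rhythm_sequence")
  st <- render_stimulus(seq12, 140, 440, sr = 8000)
  expect_equal(st$onsets_s, c(0, 0.140, 0.420))
  expect_equal(st$duration_s, 0.420 + 0.5)
  expect_true(all(diff(st$onsets_s) > 0))
  expect_error(render_stimulus(seq12, 150, 440), "tempo")
  expect_error(render_stimulus(seq12, 140, 500), "pitch")
})

test_that("the default set is 30 renderings per condition within 13-24 s", {
  ss <- fixture_stimset()
  expect_length(ss$rhythmic, 30)
  expect_length(ss$arrhythmic, 30)
  durs <- vapply(ss$rhythmic, function(s) s$duration_s, 0)
  expect_true(all(durs >= 13 & durs <= 24))
  tones <- vapply(ss$bases, function(b) b$n_tones, 0L)
  expect_true(all(tones >= 43 & tones <= 46))
})

test_that("envelope spectrum behaves like an analytic-signal envelope", {
  sr <- 8000
  t <- seq(0, 10, by = 1 / sr)
  # pure unmodulated tone: constant envelope, so power away from DC is
  # only finite-length spectral leakage
  pure <- manual_stimulus(sin(2 * pi * 440 * t), sr)
  sp <- envelope_power(pure)
  non_dc <- sp$power[sp$freqs_hz > 1 & sp$freqs_hz <= 10]
  expect_lt(max(non_dc) / sp$power[1], 1e-3)
  # 100% AM at 4 Hz: envelope peak exactly at the modulation frequency
  am <- manual_stimulus((1 + sin(2 * pi * 4 * t)) * sin(2 * pi * 440 * t), sr)
  sp_am <- envelope_power(am)
  in_band <- sp_am$freqs_hz > 1 & sp_am$freqs_hz <= 10
  peak_f <- sp_am$freqs_hz[in_band][which.max(sp_am$power[in_band])]
  expect_equal(peak_f, 4, tolerance = 0.05)
  # invariances: polarity flip exactly, global gain up to scale
  sp_neg <- envelope_power(manual_stimulus(-am$waveform, sr))
  expect_equal(sp_neg$power, sp_am$power)
  sp_gain <- envelope_power(manual_stimulus(3 * am$waveform, sr))
  expect_equal(sp_gain$power / 9, sp_am$power, tolerance = 1e-10)
  # silence: all-zero spectrum
  sp0 <- envelope_power(manual_stimulus(numeric(8000), sr))
  expect_true(all(sp0$power == 0))
  expect_equal(sp0$mean_power_0_10, 0)
  # mean_power_0_10 is the arithmetic mean over [0, 10] Hz
  expect_equal(sp_am$mean_power_0_10,
               mean(sp_am$power[sp_am$freqs_hz <= 10]))
})

test_that("every matched pair has more beat-frequency power when rhythmic", {
  ss <- fixture_stimset()
  wins <- mapply(function(r, a) {
    f <- beat_frequency(r)
    power_at(envelope_power(r), f) > power_at(envelope_power(a), f)
  }, ss$rhythmic, ss$arrhythmic)
  expect_true(all(wins))
})

test_that("stimulus-set validation does paired t-tests with guarded edge cases", {
  ss <- fixture_stimset()
  v <- ss$validation
  expect_gt(v$p_duration, 0.05)
  expect_gt(v$p_power, 0.05)
  # identical lists: zero differences -> t = 0, p = 1
  same <- validate_stimulus_sets(ss$rhythmic[1:5], ss$rhythmic[1:5])
  expect_equal(same$t_duration, 0)
  expect_equal(same$p_duration, 1)
  # constant +5 s offset with jitter, n = 10: cross-check vs stats::t.test
  set.seed(42)
  base <- ss$rhythmic[1:10]
  shifted <- lapply(base, function(s) {
    s$duration_s <- s$duration_s + 5 + stats::rnorm(1, 0, 0.05)
    s
  })
  v2 <- validate_stimulus_sets(shifted, base)
  d1 <- vapply(shifted, function(s) s$duration_s, 0)
  d0 <- vapply(base, function(s) s$duration_s, 0)
  ref <- stats::t.test(d1, d0, paired = TRUE)
  expect_equal(v2$p_duration, ref$p.value)
  expect_lt(v2$p_duration, 0.001)
  # unmatched pairing errors
  expect_error(validate_stimulus_sets(ss$rhythmic[1:3], ss$arrhythmic[3:1]),
               "paired")
})

test_that("block protocols satisfy the ordering and ISI constraints", {
  ss <- fixture_stimset()
  stims <- c(ss$rhythmic, ss$arrhythmic)
  proto <- build_protocol(stims, seed = 4)
  expect_equal(nrow(proto), 60)
  expect_equal(sum(proto$condition == "rhythmic"), 30)
  expect_lte(max_condition_run(proto), 2)
  isi <- proto$isi_s[!is.na(proto$isi_s)]
  expect_true(all(isi >= 25 & isi <= 35))
  # no consecutive same-base blocks with a different rendering
  same_base <- proto$base_id[-1] == proto$base_id[-60]
  diff_rend <- proto$tempo_ms[-1] != proto$tempo_ms[-60] |
               proto$pitch_hz[-1] != proto$pitch_hz[-60]
  expect_false(any(same_base & diff_rend))
  # onsets consistent with durations + gaps
  expect_equal(diff(proto$onset_s),
               proto$duration_s[-60] + isi)
  expect_identical(build_protocol(stims, seed = 4), proto)
})

test_that("design_protocol reproduces protocol constraints without audio", {
  proto <- design_protocol(seed = 5, n_blocks = 12)
  expect_equal(nrow(proto), 12)
  expect_equal(sum(proto$condition == "rhythmic"), 6)
  expect_lte(max_condition_run(proto), 2)
  # the same (base, tempo, pitch) combinations appear in both conditions
  key <- function(d) sort(paste(d$base_id, d$tempo_ms, d$pitch_hz))
  expect_identical(key(proto[proto$condition == "rhythmic", ]),
                   key(proto[proto$condition == "arrhythmic", ]))
})

test_that("the WAV writer emits a well-formed PCM16 header", {
  st <- render_stimulus(compose_rhythmic_bases(1)[[1]], 140, 440, sr = 8000)
  path <- withr::local_tempfile(fileext = ".wav")
  write_stimulus_wav(st, path)
  con <- file(path, "rb")
  on.exit(close(con))
  expect_identical(readChar(con, 4), "RIFF")
  invisible(readBin(con, integer(), 1, size = 4))
  expect_identical(readChar(con, 4), "WAVE")
  expect_equal(file.info(path)$size, 44 + 2 * length(st$waveform))
})
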