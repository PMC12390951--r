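test_that("rising slopes follow the peak-minus-onset definition", {
  # linear ramp 0 -> 2 z over 10 s, then flat
  ramp <- pmin(pmax(0:29 - 5, 0), 10) / 5    # on -5:24 grid: 0..2 at t=10
  avg <- manual_average(rhythmic = rbind(ramp),
                        arrhythmic = rbind(ramp / 2))
  sl <- rising_slope(avg)
  rc <- sl$slopes[sl$slopes$condition == "rhythmic", ]
  expect_equal(rc$hbo_onset, 0)
  expect_equal(rc$hbo_peak, 2)
  expect_equal(rc$time_peak_s, 10)
  expect_equal(rc$slope, 0.2)
  # Eq. 2: equal slopes -> 0; zero arrhythmic slope -> 1; antisymmetry
  same <- rising_slope(manual_average(rbind(ramp), rbind(ramp)))
  expect_equal(same$normalized$normalized_slope, 0)
  one <- rising_slope(manual_average(rbind(ramp), rbind(numeric(30) - 1e-9)))
  expect_equal(one$normalized$normalized_slope, 1, tolerance = 1e-6)
  swapped <- rising_slope(manual_average(rbind(ramp / 2), rbind(ramp)))
  orig <- rising_slope(manual_average(rbind(ramp), rbind(ramp / 2)))
  expect_equal(swapped$normalized$normalized_slope,
               -orig$normalized$normalized_slope)
  # degenerate denominator yields NA with a warning
  flat <- manual_average(rbind(numeric(30)), rbind(numeric(30)))
  expect_warning(nz <- rising_slope(flat), "undefined")
  expect_true(is.na(nz$normalized$normalized_slope))
})

test_that("ROI aggregation averages the 8-12 s window over ROI channels", {
  m <- fixture_montage()
  nch <- nrow(m$channels)
  rhy <- matrix(0, nch, 30)
  w <- -5:24 >= 8 & -5:24 <= 12
  sm_r <- roi_channels(m, "sensorimotor", "right")
  rhy[sm_r[1], w] <- 1
  rhy[sm_r[2], w] <- 3
  rhy[sm_r[-(1:2)], w] <- 2
  avg <- manual_average(rhy, rhy / 2)
  tab <- roi_aggregate(list(avg), m)
  row <- tab[tab$roi == "sensorimotor" & tab$hemisphere == "right" &
             tab$condition == "rhythmic", ]
  expect_equal(row$hbo, mean(c(1, 3, rep(2, length(sm_r) - 2))))
  const <- manual_average(matrix(1, nch, 30), matrix(1, nch, 30))
  tab2 <- roi_aggregate(list(const), m)
  expect_true(all(tab2$hbo == 1))
  # excluded channels do not contribute
  avg2 <- avg
  avg2$excluded[sm_r[2], "rhythmic"] <- TRUE
  tab3 <- roi_aggregate(list(avg2), m)
  row3 <- tab3[tab3$roi == "sensorimotor" & tab3$hemisphere == "right" &
               tab3$condition == "rhythmic", ]
  expect_equal(row3$hbo, mean(c(1, rep(2, length(sm_r) - 2))))
})

test_that("a null condition difference gives F = 0, p = 1", {
  # per-participant condition differences are nonzero but balance exactly,
  # so the condition SS is 0 while its error stratum keeps variance
  set.seed(20)
  base <- array(rnorm(8 * 3 * 2), c(8, 3, 2))
  tab <- manual_roi_table(8, function(p, cond, roi, hemi) {
    base[p, match(roi, c("sensorimotor", "auditory", "premotor")),
         match(hemi, c("left", "right"))] +
      (cond == "rhythmic") * 0.2 * ifelse(p %% 2 == 0, 1, -1)
  })
  res <- suppressWarnings(rm_anova(tab))
  cond <- res$effects[res$effects$effect == "condition", ]
  expect_equal(cond$F, 0, tolerance = 1e-20)
  expect_equal(cond$p, 1, tolerance = 1e-8)
})

test_that("a 2x2 within design matches hand-computed sums of squares", {
  # closed-form oracle: classical partitioning computed with explicit sums
  set.seed(10)
  n <- 6
  y <- array(rnorm(n * 4), c(n, 2, 2))
  y[, 2, ] <- y[, 2, ] + 0.8                 # condition effect
  y <- y + array(rnorm(n), c(n, 2, 2))       # participant offsets
  tab <- expand.grid(participant = 1:n, condition = c("a", "b"),
                     hemisphere = c("l", "r"), stringsAsFactors = FALSE)
  tab$hbo <- mapply(function(p, cc, hh)
    y[p, match(cc, c("a", "b")), match(hh, c("l", "r"))],
    tab$participant, tab$condition, tab$hemisphere)

  grand <- mean(tab$hbo)
  mc <- tapply(tab$hbo, tab$condition, mean)
  mp <- tapply(tab$hbo, tab$participant, mean)
  mpc <- tapply(tab$hbo, list(tab$participant, tab$condition), mean)
  ss_c <- 2 * n * sum((mc - grand)^2)
  ss_pc <- 2 * sum((mpc - outer(mp, mc, `+`) + grand)^2)
  f_c <- (ss_c / 1) / (ss_pc / (n - 1))

  res <- suppressWarnings(rm_anova(tab, within = c("condition",
                                                   "hemisphere")))
  got <- res$effects[res$effects$effect == "condition", ]
  expect_equal(got$F, f_c, tolerance = 1e-10)
  expect_equal(got$df_num, 1)
  expect_equal(got$df_den, n - 1)
  expect_equal(got$pes, ss_c / (ss_c + ss_pc), tolerance = 1e-10)
})

test_that("partial eta squared satisfies its F-identity on every effect", {
  set.seed(11)
  tab <- manual_roi_table(9, function(p, cond, roi, hemi)
    rnorm(1) + (cond == "rhythmic") * (roi == "sensorimotor") * 0.5)
  res <- suppressWarnings(rm_anova(tab))
  with(res$effects,
       expect_equal(pes, F * df_num / (F * df_num + df_den),
                    tolerance = 1e-10))
})

test_that("within-subject sums of squares add up to the total", {
  set.seed(12)
  tab <- manual_roi_table(7, function(p, cond, roi, hemi) rnorm(1))
  res <- suppressWarnings(rm_anova(tab))
  # reconstruct all SS from the fitted strata
  ss <- unlist(lapply(summary(res$fit), function(s)
    s[[1]][, "Sum Sq"]))
  total <- sum((tab$hbo - mean(tab$hbo))^2)
  expect_equal(sum(ss), total, tolerance = 1e-8)
})

test_that("sphericity corrections appear for multi-df within effects", {
  set.seed(13)
  tab <- manual_roi_table(10, function(p, cond, roi, hemi)
    rnorm(1) + (roi == "auditory") * 0.4)
  res <- suppressWarnings(rm_anova(tab))
  roi_row <- res$effects[res$effects$effect == "roi", ]
  expect_false(is.na(roi_row$gg_epsilon))
  expect_false(is.na(roi_row$p_gg))
  expect_false(is.na(roi_row$mauchly_p))
  expect_lte(roi_row$gg_epsilon, 1 + 1e-9)
  # two-level effects need no correction
  cond_row <- res$effects[res$effects$effect == "condition", ]
  expect_true(is.na(cond_row$gg_epsilon))
})

test_that("incomplete designs are rejected with named cells", {
  tab <- manual_roi_table(5, function(p, cond, roi, hemi) rnorm(1))
  expect_error(rm_anova(tab[-3, ]), "not complete")
  tab$hbo[4] <- NA
  expect_error(rm_anova(tab), "not complete")
})

test_that("the ANOVA suite runs the follow-ups and Tukey post-hocs", {
  set.seed(14)
  tab <- manual_roi_table(8, function(p, cond, roi, hemi)
    rnorm(1, sd = 0.2) + (cond == "rhythmic") * 0.5 +
      (roi == "auditory") * 0.4)
  suite <- suppressWarnings(anova_suite(tab))
  expect_named(suite$by_condition, c("rhythmic", "arrhythmic"))
  expect_named(suite$by_roi, c("sensorimotor", "auditory", "premotor"))
  ph <- suite$posthoc_roi$rhythmic
  expect_equal(nrow(ph), 3)            # three pairwise ROI contrasts
  expect_true(all(ph$p.value >= 0 & ph$p.value <= 1))
  cond_p <- suite$threeway$effects$p[
    suite$threeway$effects$effect == "condition"]
  expect_lt(cond_p, 0.01)
})
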