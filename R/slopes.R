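# Rising-slope metrics ----------------------------------------------------
#
# Slope = (HbO_peak - HbO_onset) / (t_peak - t_onset) on the 1 Hz
# condition average, peak searched over the post-onset window; the
# normalized slope contrasts conditions per channel:
# (Slope_RC - Slope_AC) / (Slope_RC + Slope_AC).

#' Rising slope of the average HbO response
#'
#' @param avg A `condition_average` (1 Hz).
#' @param window_s Post-onset search window for the peak (default c(0, 25));
#'   the peak is the maximum strictly after onset.
#' @return A `slope_result` data frame: channel, condition, hbo_onset,
#'   hbo_peak, time_peak_s, slope, plus per-channel `normalized` in a
#'   second data frame `normalized` (channel, slope_rhythmic,
#'   slope_arrhythmic, normalized_slope).
#' @export
rising_slope <- function(avg, window_s = c(0, 25)) {
  t <- avg$time_s
  i_on <- which.min(abs(t - 0))
  post <- which(t > 0 & t <= window_s[2])
  conds <- dimnames(avg$mean_hbo)[[2]]
  nch <- dim(avg$mean_hbo)[1]
  rows <- expand.grid(channel = seq_len(nch), condition = conds,
                      stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    ch <- rows$channel[i]
    y <- avg$mean_hbo[ch, rows$condition[i], ]
    if (anyNA(y)) {
      return(data.frame(channel = ch, condition = rows$condition[i],
                        hbo_onset = NA_real_, hbo_peak = NA_real_,
                        time_peak_s = NA_real_, slope = NA_real_))
    }
    k <- post[which.max(y[post])]
    data.frame(channel = ch, condition = rows$condition[i],
               hbo_onset = y[i_on], hbo_peak = y[k], time_peak_s = t[k],
               slope = (y[k] - y[i_on]) / (t[k] - 0))
  }))
  s_rc <- res$slope[res$condition == "rhythmic"]
  s_ac <- res$slope[res$condition == "arrhythmic"]
  denom <- s_rc + s_ac
  norm <- ifelse(is.na(denom) | denom == 0, NA_real_, (s_rc - s_ac) / denom)
  if (any(!is.na(denom) & denom == 0))
    warning("normalized slope undefined (Slope_RC + Slope_AC = 0) on ",
            sum(!is.na(denom) & denom == 0), " channel(s)")
  structure(list(slopes = res,
                 normalized = data.frame(channel = seq_len(nch),
                                         slope_rhythmic = s_rc,
                                         slope_arrhythmic = s_ac,
                                         normalized_slope = norm)),
            class = "slope_result")
}

#' Participant x channel slope matrices for a cohort
#'
#' @param averages List of `condition_average`.
#' @return List with matrices `rhythmic` and `arrhythmic`
#'   (participant x channel; NA where the channel was excluded).
#' @export
cohort_slopes <- function(averages) {
  per <- lapply(averages, function(a) rising_slope(a)$normalized)
  list(rhythmic = do.call(rbind, lapply(per, function(p) p$slope_rhythmic)),
       arrhythmic = do.call(rbind, lapply(per, function(p) p$slope_arrhythmic)))
}

# ROI aggregation ---------------------------------------------------------

#' Participant x condition x ROI x hemisphere response table
#'
#' Averages the 1 Hz HbO response over the 8--12 s window (inclusive; the
#' 4 s window around the ~10 s response peak) per channel, then over the
#' channels of each analysis ROI (auditory, sensorimotor, premotor) per
#' hemisphere. Channels excluded for a participant/condition, or dropped
#' at group level, do not contribute.
#'
#' @param averages List of `condition_average` (one per participant).
#' @param montage An `fnirs_montage`.
#' @param retained Optional channel x condition logical from
#'   [group_retained_channels()].
#' @param window_s Averaging window (default c(8, 12)).
#' @return An `roi_table` data frame: participant, condition, roi,
#'   hemisphere, hbo (NA when no channel contributed).
#' @export
roi_aggregate <- function(averages, montage, retained = NULL,
                          window_s = c(8, 12)) {
  rois <- c("sensorimotor", "auditory", "premotor")
  hemis <- c("left", "right")
  conds <- c("rhythmic", "arrhythmic")
  out <- expand.grid(participant = seq_along(averages), condition = conds,
                     roi = rois, hemisphere = hemis,
                     stringsAsFactors = FALSE)
  out$hbo <- NA_real_
  for (r in seq_len(nrow(out))) {
    a <- averages[[out$participant[r]]]
    w <- a$time_s >= window_s[1] & a$time_s <= window_s[2]
    chans <- roi_channels(montage, out$roi[r], out$hemisphere[r])
    ci <- match(out$condition[r], conds)
    use <- chans[!a$excluded[chans, ci]]
    if (!is.null(retained)) use <- use[retained[use, ci]]
    if (length(use) == 0) next
    per_ch <- rowMeans(a$mean_hbo[use, ci, w, drop = FALSE][, 1, ,
                                                            drop = FALSE])
    out$hbo[r] <- mean(per_ch)
  }
  structure(out, class = c("roi_table", "data.frame"))
}
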