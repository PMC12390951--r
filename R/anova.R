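# Repeated-measures ANOVA -------------------------------------------------
#
# Fully within-subject designs over the ROI response table: the three-way
# condition x ROI x hemisphere model plus the follow-up two-way models.
# Sums of squares come from the classical aov/Error decomposition;
# sphericity diagnostics (Mauchly) and Greenhouse-Geisser corrections
# from the multivariate route (car::Anova); Tukey-Kramer post-hocs from
# emmeans.

#' Repeated-measures ANOVA on a within-subject table
#'
#' @param data Data frame with a `participant` column, a numeric response
#'   column, and the within-subject factor columns.
#' @param response Name of the response column (default "hbo").
#' @param within Character vector of within-subject factor names.
#' @return An `anova_result`: `effects` data frame (effect, df_num,
#'   df_den, F, p, pes, gg_epsilon, p_gg, mauchly_p), the `aov` fit, and
#'   the data used.
#' @export
rm_anova <- function(data, response = "hbo",
                     within = c("condition", "roi", "hemisphere")) {
  df <- as.data.frame(data)
  df$participant <- factor(df$participant)
  for (f in within) df[[f]] <- factor(df[[f]])
  df$.y <- df[[response]]

  # completeness: one finite value per participant x cell
  cells <- do.call(interaction, c(df[within], drop = FALSE))
  tab <- table(df$participant, cells, useNA = "no")
  bad <- which(tab != 1, arr.ind = TRUE)
  miss <- df$participant[is.na(df$.y)]
  if (nrow(bad) > 0 || anyNA(df$.y)) {
    desc <- unique(c(
      if (nrow(bad) > 0)
        paste0("participant ", rownames(tab)[bad[, 1]], " cell ",
               colnames(tab)[bad[, 2]]),
      if (anyNA(df$.y))
        paste0("participant ", df$participant[is.na(df$.y)], " cell ",
               cells[is.na(df$.y)], " is NA")))
    stop("design is not complete/balanced: ",
         paste(utils::head(desc, 10), collapse = "; "))
  }

  fixed <- paste(within, collapse = " * ")
  form <- stats::as.formula(paste(".y ~", fixed,
                                  "+ Error(participant/(", fixed, "))"))
  # literal formula/data in the call so emmeans can recover the model frame
  fit <- do.call(stats::aov, list(form, data = df))

  effects <- data.frame()
  for (stratum in summary(fit)) {
    tab_s <- stratum[[1]]
    rn <- trimws(rownames(tab_s))
    res_row <- which(rn == "Residuals")
    ss_err <- tab_s[res_row, "Sum Sq"]
    for (r in setdiff(seq_len(nrow(tab_s)), res_row)) {
      effects <- rbind(effects, data.frame(
        effect = gsub(":", " x ", rn[r]),
        df_num = tab_s[r, "Df"], df_den = tab_s[res_row, "Df"],
        F = tab_s[r, "F value"], p = tab_s[r, "Pr(>F)"],
        pes = tab_s[r, "Sum Sq"] / (tab_s[r, "Sum Sq"] + ss_err)))
    }
  }

  # sphericity route: multivariate model on the wide response
  cell_levels <- levels(cells)
  Y <- matrix(NA_real_, nlevels(df$participant), length(cell_levels),
              dimnames = list(levels(df$participant), cell_levels))
  Y[cbind(as.integer(df$participant), as.integer(cells))] <- df$.y
  idata <- unique(df[order(cells), within, drop = FALSE])
  idata <- idata[match(cell_levels, do.call(interaction,
                                            c(idata[within], drop = FALSE))), ,
                 drop = FALSE]
  rownames(idata) <- NULL
  mlm <- stats::lm(Y ~ 1)
  caov <- car::Anova(mlm, idata = idata,
                     idesign = stats::as.formula(paste("~", fixed)),
                     type = 3)
  # "HF eps > 1 treated as 1" is routine for near-spherical data
  cs <- suppressWarnings(summary(caov, multivariate = FALSE))
  effects$gg_epsilon <- NA_real_
  effects$p_gg <- NA_real_
  effects$mauchly_p <- NA_real_
  adj <- cs$pval.adjustments
  sph <- cs$sphericity.tests
  norm_name <- function(x) gsub(":", " x ", x)
  if (!is.null(adj) && nrow(adj) > 0) {
    for (r in seq_len(nrow(adj))) {
      i <- match(norm_name(rownames(adj)[r]), effects$effect)
      if (!is.na(i)) {
        effects$gg_epsilon[i] <- adj[r, "GG eps"]
        effects$p_gg[i] <- adj[r, "Pr(>F[GG])"]
      }
    }
  }
  if (!is.null(sph) && nrow(sph) > 0) {
    for (r in seq_len(nrow(sph))) {
      i <- match(norm_name(rownames(sph)[r]), effects$effect)
      if (!is.na(i)) effects$mauchly_p[i] <- sph[r, "p-value"]
    }
  }
  rownames(effects) <- NULL
  structure(list(effects = effects, fit = fit, data = df),
            class = "anova_result")
}

#' Tukey-Kramer post-hoc comparisons on one factor
#'
#' @param result An `anova_result`.
#' @param factor_name Factor whose levels to compare (e.g. "roi").
#' @return Data frame of pairwise contrasts with Tukey-adjusted p values.
#' @export
tukey_posthoc <- function(result, factor_name = "roi") {
  emm <- emmeans::emmeans(result$fit,
                          stats::as.formula(paste("~", factor_name)))
  as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                  adjust = "tukey"))
}

#' The full ANOVA suite over an ROI table
#'
#' The three-way condition x ROI x hemisphere rANOVA; two follow-up
#' two-way (ROI x hemisphere) rANOVAs, one per condition; three follow-up
#' (condition x hemisphere) rANOVAs, one per ROI; and Tukey-Kramer ROI
#' post-hocs within each condition.
#'
#' @param roi_table An `roi_table` from [roi_aggregate()].
#' @return List: `threeway` (anova_result), `by_condition`, `by_roi`
#'   (named lists of anova_result), `posthoc_roi` (named list of Tukey
#'   tables).
#' @export
anova_suite <- function(roi_table) {
  threeway <- rm_anova(roi_table)
  by_condition <- lapply(stats::setNames(nm = unique(roi_table$condition)),
                         function(cc)
    rm_anova(roi_table[roi_table$condition == cc, ],
             within = c("roi", "hemisphere")))
  by_roi <- lapply(stats::setNames(nm = unique(roi_table$roi)), function(rr)
    rm_anova(roi_table[roi_table$roi == rr, ],
             within = c("condition", "hemisphere")))
  posthoc_roi <- lapply(by_condition, tukey_posthoc, factor_name = "roi")
  list(threeway = threeway, by_condition = by_condition, by_roi = by_roi,
       posthoc_roi = posthoc_roi)
}
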