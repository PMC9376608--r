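# Aggregation of explanation maps by face region / electrode group and time
# zone, and the fluency x zone ANOVA of attribution dynamics.

#' Region/zone mapping for attribution statistics
#'
#' @param au_regions named vector AU -> "upper"/"lower"
#' @param eeg_groups named vector channel -> group label
#' @param zones data.frame with `zone`, `start_ms`, `end_ms`; zones must be
#'   non-overlapping and cover 0-1,500 ms
#' @return list of class `ssml_region_map`
#' @export
region_map <- function(au_regions = au_region_map(),
                       eeg_groups = eeg_group_map(),
                       zones = time_zones()) {
  stopifnot(nrow(zones) >= 1, zones$start_ms[1] == 0,
            all(zones$start_ms[-1] == zones$end_ms[-nrow(zones)]),
            zones$end_ms[nrow(zones)] == 1500)
  structure(list(au_regions = au_regions, eeg_groups = eeg_groups,
                 zones = zones), class = "ssml_region_map")
}

zone_columns <- function(zones, n_cols, duration_ms = 1500) {
  lapply(seq_len(nrow(zones)), function(i) {
    a <- floor(zones$start_ms[i] / duration_ms * n_cols) + 1L
    b <- floor(zones$end_ms[i] / duration_ms * n_cols)
    a:b
  })
}

#' Aggregate attribution maps by region and time zone
#'
#' One row per (trial, modality, region, zone) holding the mean absolute
#' attribution over that block (and the signed mean for inspection). Zone
#' boundaries map to columns at 58 frames/s for AU maps (29/29/29 frames at
#' the default zones) and 128 Hz for EEG maps (64/64/64 samples).
#'
#' @param explanations list of `ssml_explanation` (e.g. from
#'   [explain_trialset()])
#' @param labels fluency label per explanation
#' @param regions an [region_map()]
#' @return long-format data.frame with columns `trial`, `modality`, `region`,
#'   `zone`, `fluency`, `mean_abs_phi`, `mean_phi`, `n_cells`
#' @export
aggregate_attributions <- function(explanations, labels,
                                   regions = region_map()) {
  stopifnot(length(explanations) == length(labels))
  zc_au <- zone_columns(regions$zones, N_AU_FRAMES)
  zc_eeg <- zone_columns(regions$zones, N_EEG_SAMPLES)
  out <- list()
  r <- 0L
  for (t in seq_along(explanations)) {
    ex <- explanations[[t]]
    unmapped <- setdiff(rownames(ex$e_au), names(regions$au_regions))
    if (length(unmapped)) stop("unmapped AU rows: ", paste(unmapped, collapse = ", "))
    unmapped <- setdiff(rownames(ex$e_eeg), names(regions$eeg_groups))
    if (length(unmapped)) stop("unmapped EEG channels: ", paste(unmapped, collapse = ", "))
    for (reg in unique(regions$au_regions)) {
      rows <- which(regions$au_regions[rownames(ex$e_au)] == reg)
      for (z in seq_len(nrow(regions$zones))) {
        blk <- ex$e_au[rows, zc_au[[z]], drop = FALSE]
        r <- r + 1L
        out[[r]] <- data.frame(trial = t, modality = "AU", region = reg,
                               zone = regions$zones$zone[z], fluency = labels[t],
                               mean_abs_phi = mean(abs(blk)),
                               mean_phi = mean(blk), n_cells = length(blk),
                               stringsAsFactors = FALSE)
      }
    }
    for (grp in unique(regions$eeg_groups)) {
      rows <- which(regions$eeg_groups[rownames(ex$e_eeg)] == grp)
      for (z in seq_len(nrow(regions$zones))) {
        blk <- ex$e_eeg[rows, zc_eeg[[z]], drop = FALSE]
        r <- r + 1L
        out[[r]] <- data.frame(trial = t, modality = "EEG", region = grp,
                               zone = regions$zones$zone[z], fluency = labels[t],
                               mean_abs_phi = mean(abs(blk)),
                               mean_phi = mean(blk), n_cells = length(blk),
                               stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' ANOVA of attribution dynamics (fluency x time zone)
#'
#' Per region/group, a two-factor split-plot ANOVA of the per-trial mean
#' absolute attribution: fluency is a between-trial factor and time zone a
#' within-trial (repeated-measures) factor, so the zone and fluency:zone
#' tests use the within-trial error stratum and remain calibrated despite
#' the correlation between the three zone values of one trial. The
#' interaction term carries the timing question: do fluent and stuttered
#' trials concentrate their attribution in different time zones?
#'
#' @param table long-format data.frame from [aggregate_attributions()]
#' @param response column to analyse (default `mean_abs_phi`)
#' @return data.frame of class `ssml_zone_stats` with one row per
#'   (modality, region, factor)
#' @export
attribution_anova <- function(table, response = "mean_abs_phi") {
  stopifnot(all(c("trial", "modality", "region", "zone", "fluency", response)
                %in% names(table)))
  if (length(unique(table$fluency)) < 2 || length(unique(table$zone)) < 2)
    stop("need at least 2 levels of fluency and zone")
  out <- list()
  for (mod in unique(table$modality)) {
    for (reg in unique(table$region[table$modality == mod])) {
      sub <- table[table$modality == mod & table$region == reg, ]
      counts <- stats::xtabs(~ fluency + zone, sub)
      if (any(counts < 2))
        stop("cells with fewer than 2 observations in region ", reg, ": ",
             paste(rownames(counts)[rowSums(counts < 2) > 0], collapse = ", "))
      sub$fluency <- factor(sub$fluency)
      sub$zone <- factor(sub$zone)
      sub$trial_f <- factor(sub$trial)
      y <- sub[[response]]
      if (stats::var(y) < 1e-12 * (mean(y)^2 + 1e-12))
        stop("degenerate input: zero variance in region ", reg)
      fml <- stats::as.formula(paste(response,
                                     "~ fluency * zone + Error(trial_f)"))
      fit <- summary(stats::aov(fml, data = sub))
      between <- fit[["Error: trial_f"]][[1]]
      within <- fit[["Error: Within"]][[1]]
      ms_res <- within["Residuals", "Mean Sq"]
      if (!is.finite(ms_res) || ms_res < 1e-12 * (mean(y)^2 + 1e-12))
        stop("degenerate input: zero residual variance in region ", reg)
      terms <- trimws(c(rownames(between), rownames(within)))
      tab2 <- rbind(between, within)
      keep <- terms != "Residuals"
      out[[paste(mod, reg)]] <- data.frame(
        modality = mod, region = reg, factor = terms[keep],
        F = tab2[keep, "F value"], p = tab2[keep, "Pr(>F)"],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ssml_zone_stats", "data.frame")
  res
}

# fast interaction F for permutation studies: the split-plot within-stratum
# test computed from two linear fits on within-trial-centred data
interaction_F <- function(values, fluency, zone, trial) {
  f <- factor(fluency); z <- factor(zone)
  yc <- values - stats::ave(values, trial)        # within-trial centering
  X0 <- stats::model.matrix(~ z)
  X1 <- stats::model.matrix(~ z * f)
  r0 <- stats::.lm.fit(X0, yc)$residuals
  r1 <- stats::.lm.fit(X1, yc)$residuals
  rss0 <- sum(r0^2); rss1 <- sum(r1^2)
  df1 <- (nlevels(f) - 1) * (nlevels(z) - 1)
  df2 <- (length(unique(trial)) - nlevels(f)) * (nlevels(z) - 1)
  Fv <- ((rss0 - rss1) / df1) / (rss1 / df2)
  list(F = Fv, p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}
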