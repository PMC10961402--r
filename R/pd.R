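#' DPP-4 inhibition relative to baseline
#'
#' `inhibition(t) = (1 - activity(t) / baseline) * 100`. Baseline is the
#' pre-dose activity measurement; values above baseline give negative
#' inhibition and are retained.
#'
#' @param times Sampling times (h).
#' @param activity DPP-4 activity values (substrate turnover units).
#' @param baseline Pre-dose activity (> 0).
#' @return A tibble `time`, `inhibition` (%), with attribute
#'   `baseline_activity`.
#' @export
#' @examples
#' dpp4_inhibition(c(0, 2), c(100, 20), baseline = 100)
dpp4_inhibition <- function(times, activity, baseline) {
  if (!is.finite(baseline) || baseline <= 0) {
    abort("baseline activity must be > 0")
  }
  out <- tibble::tibble(time = times,
                        inhibition = (1 - activity / baseline) * 100)
  attr(out, "baseline_activity") <- baseline
  out
}

#' Time above an inhibition threshold
#'
#' Piecewise-linear interpolation of the threshold crossings; returns the
#' summed length of all sub-intervals of `interval` where the series exceeds
#' `threshold`.
#'
#' @param times,values The effect series (must contain >= 2 points).
#' @param threshold Threshold on the value scale (default 80%).
#' @param interval Two-element window in h; defaults to the sampled range.
#' @return Duration in hours.
#' @export
#' @examples
#' duration_above(c(0, 2, 24), c(50, 90, 70), 80)  # 11.5
duration_above <- function(times, values, threshold = 80,
                           interval = range(times)) {
  if (length(times) < 2) abort("need >= 2 points")
  o <- order(times)
  times <- times[o]; values <- values[o]
  lo <- max(interval[1], times[1])
  hi <- min(interval[2], times[length(times)])
  if (hi <= lo) return(0)
  # refine the grid with interpolated points at the interval bounds
  vb <- stats::approx(times, values, xout = c(lo, hi))$y
  keep <- times > lo & times < hi
  tt <- c(lo, times[keep], hi)
  vv <- c(vb[1], values[keep], vb[2])
  total <- 0
  for (i in seq_len(length(tt) - 1)) {
    t1 <- tt[i]; t2 <- tt[i + 1]
    v1 <- vv[i]; v2 <- vv[i + 1]
    if (v1 > threshold && v2 > threshold) {
      total <- total + (t2 - t1)
    } else if (v1 > threshold || v2 > threshold) {
      tc <- t1 + (threshold - v1) / (v2 - v1) * (t2 - t1)
      total <- total + if (v1 > threshold) tc - t1 else t2 - tc
    }
  }
  total
}

#' Summary statistics of a DPP-4 inhibition series
#'
#' Rmax/TRmax come directly from the observed points (earliest time on
#' ties); the AUEC uses the linear trapezoid; `E24` is the value at the end
#' of the dosing interval, linearly interpolated (and flagged) when 24 h was
#' not sampled; `DUR80` integrates the time above the threshold over
#' `dur_interval` (the dosing interval on day 1, the full sampled extent on
#' day 14).
#'
#' @param times,inhibition The inhibition series (h, %).
#' @param interval Dosing interval for AUEC/E24, default `c(0, 24)`.
#' @param dur_interval Window for the time-above-threshold statistic;
#'   defaults to `interval`.
#' @param threshold DUR threshold (%), default 80.
#' @return One-row tibble: `r_max`, `t_rmax`, `r_min`, `auec_0_24`,
#'   `auec_0_t`, `e_24`, `e24_interpolated`, `dur_80`.
#' @export
inhibition_summary <- function(times, inhibition, interval = c(0, 24),
                               dur_interval = interval, threshold = 80) {
  keep <- !is.na(times) & !is.na(inhibition)
  times <- times[keep]; inhibition <- inhibition[keep]
  if (length(times) == 0) abort("empty inhibition series")
  o <- order(times)
  times <- times[o]; inhibition <- inhibition[o]
  in_int <- times >= interval[1] & times <= interval[2]
  i_max <- which(inhibition == max(inhibition[in_int]) & in_int)[1]
  e24_sampled <- any(abs(times - interval[2]) < 1e-9)
  e24 <- stats::approx(times, inhibition, xout = interval[2])$y
  tibble::tibble(
    r_max = inhibition[i_max],
    t_rmax = times[i_max],
    r_min = min(inhibition[in_int]),
    auec_0_24 = if (sum(in_int) >= 2)
      auc_linear(times, inhibition, interval[1], interval[2]) else NA_real_,
    auec_0_t = if (length(times) >= 2)
      auc_linear(times, inhibition, max(interval[1], times[1]),
                 max(times)) else NA_real_,
    e_24 = e24,
    e24_interpolated = !e24_sampled,
    dur_80 = duration_above(times, inhibition, threshold,
                            interval = dur_interval))
}

#' Change-from-predose GLP-1 series and summary
#'
#' `delta(t) = GLP1(t) - GLP1(0)` with the pre-dose value as t = 0.
#' Post-meal change scores are read 2 h after the 4 h lunch and the 10 h
#' dinner (t = 6 and 12 h); `Ravg = AUEC0-24 / 24`.
#'
#' @param times,values The GLP-1 series (h, pM) including the pre-dose point.
#' @return A list with `delta` (tibble `time`, `delta`) and `summary`
#'   (one-row tibble: `baseline`, `r_max`, `t_rmax`, `r_min`, `auec_0_24`,
#'   `auec_0_t`, `r_avg`, `delta_6h`, `delta_12h`).
#' @export
delta_glp1 <- function(times, values) {
  keep <- !is.na(times) & !is.na(values)
  times <- times[keep]; values <- values[keep]
  o <- order(times)
  times <- times[o]; values <- values[o]
  i0 <- which(abs(times) < 1e-9)
  if (length(i0) == 0) abort("pre-dose (t = 0) GLP-1 value is required")
  base <- values[i0[1]]
  delta <- values - base
  i_max <- which.max(delta)[1]
  auec24 <- if (max(times) >= 24) auc_linear(times, delta, 0, 24) else NA_real_
  at <- function(t) {
    if (t >= min(times) && t <= max(times)) {
      stats::approx(times, delta, xout = t)$y
    } else NA_real_
  }
  list(
    delta = tibble::tibble(time = times, delta = delta),
    summary = tibble::tibble(
      baseline = base,
      r_max = max(delta), t_rmax = times[i_max], r_min = min(delta),
      auec_0_24 = auec24,
      auec_0_t = auc_linear(times, delta, 0, max(times)),
      r_avg = auec24 / 24,
      delta_6h = at(6), delta_12h = at(12)))
}

#' OGTT effect areas
#'
#' Linear-trapezoid AUEC0-t for each analyte curve of an oral glucose
#' tolerance test (0-3 h sampling grid).
#'
#' @param ogtt A data frame with a `time` column and one column per analyte
#'   (e.g. `glucose`, `insulin`, `c_peptide`, `glucagon`).
#' @return One-row tibble of AUECs named after the analyte columns.
#' @export
ogtt_auec <- function(ogtt) {
  if (nrow(ogtt) < 2) abort("need >= 2 OGTT sampling points")
  analytes <- setdiff(names(ogtt), "time")
  vals <- lapply(analytes, function(a) {
    auc_linear(ogtt$time, ogtt[[a]])
  })
  tibble::as_tibble(setNames(vals, analytes))
}

#' Change in OGTT effect areas between occasions
#'
#' Per-subject AUEC0-t on the post-treatment OGTT day minus the baseline
#' day, then group means: the standard layout of an OGTT effect table.
#'
#' @param auec_post,auec_base Tibbles of per-subject AUECs with `ID`, `ARM`
#'   and one column per analyte (as from [ogtt_auec()] row-bound across
#'   subjects).
#' @return A tibble with one row per arm x analyte: `mean_change`,
#'   `sd_change`, `n`.
#' @export
ogtt_change_summary <- function(auec_post, auec_base) {
  analytes <- setdiff(intersect(names(auec_post), names(auec_base)),
                      c("ID", "ARM"))
  joined <- dplyr::inner_join(auec_post, auec_base, by = c("ID", "ARM"),
                              suffix = c("_post", "_base"))
  long <- purrr::map_dfr(analytes, function(a) {
    tibble::tibble(ID = joined$ID, ARM = joined$ARM, analyte = a,
                   change = joined[[paste0(a, "_post")]] -
                            joined[[paste0(a, "_base")]])
  })
  long %>%
    dplyr::group_by(.data$ARM, .data$analyte) %>%
    dplyr::summarise(n = dplyr::n(), mean_change = mean(.data$change),
                     sd_change = sd(.data$change), .groups = "drop")
}

#' OGTT analysis of a study dataset
#'
#' Extracts the day -1 and day 15 OGTT curves per subject, computes per-curve
#' AUEC0-t and the change-from-baseline group summary.
#'
#' @param ds A [study_dataset()].
#' @return List with `per_subject` (AUECs per subject and occasion) and
#'   `changes` (group summary from [ogtt_change_summary()]).
#' @export
run_ogtt <- function(ds) {
  kinds <- c("glucose", "insulin", "c_peptide", "glucagon")
  obs <- tibble::as_tibble(ds) %>%
    dplyr::filter(.data$EVID == 0L, .data$DVID %in% kinds,
                  .data$OCC %in% c("day-1", "day15"))
  per <- obs %>%
    dplyr::group_by(.data$ID, .data$ARM, .data$OCC, .data$DVID) %>%
    dplyr::arrange(.data$TIME, .by_group = TRUE) %>%
    dplyr::summarise(auec = auc_linear(.data$TIME - min(.data$TIME), .data$DV),
                     .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "DVID", values_from = "auec")
  base <- dplyr::filter(per, .data$OCC == "day-1") %>% dplyr::select(-"OCC")
  post <- dplyr::filter(per, .data$OCC == "day15") %>% dplyr::select(-"OCC")
  list(per_subject = per, changes = ogtt_change_summary(post, base))
}

#' Change-from-baseline efficacy summaries
#'
#' Glycaemic indices (fasting plasma glucose, 2-h postprandial glucose by
#' meal, HbA1c, glycated albumin) summarised as per-subject change from the
#' pre-treatment baseline day, then group mean and SD.
#'
#' @param ds A [study_dataset()].
#' @param baseline_occ Occasion label of the baseline measurements
#'   (default `"day-2"`).
#' @return A tibble with one row per arm x index x occasion:
#'   `mean_change`, `sd_change`, `n`. Subjects without a baseline value for
#'   an index are excluded with a warning.
#' @export
efficacy_changes <- function(ds, baseline_occ = "day-2") {
  kinds <- c("fpg", "ppg_2h", "hba1c", "ga")
  obs <- tibble::as_tibble(ds) %>%
    dplyr::filter(.data$EVID == 0L, .data$DVID %in% kinds, !is.na(.data$DV))
  # ppg_2h occasions carry a meal suffix (e.g. "day7:lunch"); the index key
  # is DVID plus the meal part so changes are within-meal comparisons
  obs$meal <- ifelse(grepl(":", obs$OCC),
                     sub("^[^:]*:", "", obs$OCC), "")
  obs$day <- sub(":.*$", "", obs$OCC)
  base <- obs %>%
    dplyr::filter(.data$day == baseline_occ) %>%
    dplyr::select("ID", "DVID", "meal", base = "DV")
  post <- obs %>% dplyr::filter(.data$day != baseline_occ)
  joined <- dplyr::left_join(post, base, by = c("ID", "DVID", "meal"))
  if (anyNA(joined$base)) {
    drop_ids <- unique(joined$ID[is.na(joined$base)])
    warn(paste0("subjects without baseline excluded: ",
                paste(drop_ids, collapse = ", ")))
    joined <- joined[!is.na(joined$base), ]
  }
  joined %>%
    dplyr::mutate(change = .data$DV - .data$base) %>%
    dplyr::group_by(.data$ARM, .data$DVID, .data$day, .data$meal) %>%
    dplyr::summarise(n = dplyr::n(), mean_change = mean(.data$change),
                     sd_change = sd(.data$change), .groups = "drop")
}

#' Fold change of a treated-arm mean over placebo
#'
#' Small aggregation helper used when comparing group-mean effect areas
#' (e.g. active GLP-1 AUEC0-24) against the placebo arm.
#'
#' @param treated,placebo Group-mean values.
#' @return `treated / placebo`.
#' @export
fold_vs_placebo <- function(treated, placebo) treated / placebo
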