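#' Linear-trapezoid area under the curve
#'
#' The single trapezoid code path used by every AUC/AUEC computation in the
#' package. Exact for piecewise-linear input; values are interpolated
#' linearly at `start`/`end` when these fall between sampled times.
#'
#' @param times Sampling times (h), sorted strictly increasing.
#' @param values Values at `times` (any concentration- or effect-like unit).
#'   Missing values inside the range are skipped with a warning.
#' @param start,end Integration bounds (h); default the sampled range.
#' @return The area in h x value-units.
#' @export
#' @examples
#' auc_linear(c(0, 1, 2), c(0, 2, 2))          # 3
#' auc_linear(c(0, 24), c(5, 5))               # 120
auc_linear <- function(times, values, start = min(times), end = max(times)) {
  if (length(times) != length(values)) {
    abort("times and values must have equal length")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    abort("times must be sorted strictly increasing")
  }
  if (anyNA(values)) {
    warn("missing values inside the integration range were skipped")
    keep <- !is.na(values)
    times <- times[keep]
    values <- values[keep]
  }
  if (length(times) < 2) abort("need at least 2 points for a trapezoid AUC")
  if (start >= end) abort("start must be < end")
  if (start < times[1] || end > times[length(times)]) {
    abort("[start, end] must lie within the sampled range")
  }
  v_start <- stats::approx(times, values, xout = start)$y
  v_end <- stats::approx(times, values, xout = end)$y
  inner <- times > start & times < end
  tt <- c(start, times[inner], end)
  vv <- c(v_start, values[inner], v_end)
  sum(diff(tt) * (head(vv, -1) + tail(vv, -1)) / 2)
}

#' Terminal-slope (lambda-z) regression
#'
#' Best-fit terminal elimination rate constant: for every candidate terminal
#' window (the last k points strictly after Tmax, k = 3 ... all), ordinary
#' least squares of log concentration on time is fitted and the window with
#' the largest adjusted R-squared wins; ties go to the window with more
#' points. Estimates spanning fewer than two half-lives are flagged
#' unreliable.
#'
#' @param times Sampling times (h).
#' @param concs Concentrations; only positive values after Tmax are usable.
#' @return A list of class `lambda_z_fit`: `lambda_z` (1/h), `t_half` (h),
#'   `n_points`, `adj_r2`, `t_first`, `t_last`, `span_halflives`,
#'   `reliable`, `estimable`.
#' @export
lambda_z_fit <- function(times, concs) {
  no_fit <- structure(
    list(lambda_z = NA_real_, t_half = NA_real_, n_points = NA_integer_,
         adj_r2 = NA_real_, t_first = NA_real_, t_last = NA_real_,
         span_halflives = NA_real_, reliable = FALSE, estimable = FALSE),
    class = "lambda_z_fit")
  ok <- !is.na(concs) & concs > 0
  times <- times[ok]
  concs <- concs[ok]
  if (length(times) == 0) return(no_fit)
  i_cmax <- which.max(concs)[1]          # earliest maximum
  post <- times > times[i_cmax]
  t_post <- times[post]
  c_post <- concs[post]
  m <- length(t_post)
  if (m < 3) return(no_fit)
  best <- NULL
  for (k in 3:m) {
    idx <- (m - k + 1):m
    x <- t_post[idx]
    y <- log(c_post[idx])
    fit <- stats::lm.fit(cbind(1, x), y)
    slope <- fit$coefficients[2]
    if (!is.finite(slope) || slope >= 0) next
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    if (tss <= 0) next
    r2 <- 1 - rss / tss
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    # ties (to within numerical noise) resolved in favour of more points;
    # iterating k upward and accepting >= implements exactly that
    if (is.null(best) || adj >= best$adj_r2 - 1e-12) {
      if (is.null(best) || adj > best$adj_r2 + 1e-12 || k > best$n_points) {
        best <- list(lambda_z = -slope, adj_r2 = max(min(adj, 1), 0),
                     n_points = k, t_first = x[1], t_last = x[k])
      }
    }
  }
  if (is.null(best)) return(no_fit)
  span <- (best$t_last - best$t_first) * best$lambda_z / log(2)
  structure(
    list(lambda_z = unname(best$lambda_z),
         t_half = unname(log(2) / best$lambda_z),
         n_points = best$n_points,
         adj_r2 = unname(best$adj_r2),
         t_first = best$t_first, t_last = best$t_last,
         span_halflives = unname(span),
         reliable = span >= 2, estimable = TRUE),
    class = "lambda_z_fit")
}

#' @export
print.lambda_z_fit <- function(x, ...) {
  if (!x$estimable) {
    cat("lambda-z: not estimable\n")
  } else {
    cat(sprintf(
      "lambda-z %.5g 1/h (t1/2 %.4g h), %d points, adj R2 %.4f, span %.2f t1/2%s\n",
      x$lambda_z, x$t_half, x$n_points, x$adj_r2, x$span_halflives,
      if (x$reliable) "" else " [unreliable]"))
  }
  invisible(x)
}

empty_nca_row <- function(reason = NA_character_) {
  tibble::tibble(
    cmax = NA_real_, tmax = NA_real_, auc_0_24 = NA_real_, auc_0_t = NA_real_,
    auc_0_inf = NA_real_, lambda_z = NA_real_, t_half = NA_real_,
    cav_ss = NA_real_, cl_f = NA_real_, clss_f = NA_real_, vz_f = NA_real_,
    span_halflives = NA_real_, lambda_reliable = NA, reason = reason)
}

# mg dose over h*ng/mL AUC -> L/h  (mg -> ng is 1e6; ng/mL -> ng/L is 1e3)
.cl_from_auc <- function(dose_mg, auc) dose_mg * 1000 / auc

#' Single-dose non-compartmental PK parameters
#'
#' Cmax and Tmax are read directly off the observed points (earliest time on
#' ties); AUC0-24 uses the linear trapezoid; AUC0-inf adds the
#' last-concentration tail `C_t / lambda_z` when the terminal slope is
#' estimable. BLQ handling: pre-Tmax BLQ values are set to zero, post-Tmax
#' BLQ points are excluded.
#'
#' @param times,concs Day-1 concentration profile (h, ng/mL).
#' @param dose Dose in mg.
#' @param blq Optional logical/0-1 vector flagging BLQ observations.
#' @return One-row tibble with `cmax`, `tmax`, `auc_0_24`, `auc_0_t`,
#'   `auc_0_inf`, `lambda_z`, `t_half`, `cl_f` and terminal-fit diagnostics.
#' @export
nca_single_dose <- function(times, concs, dose, blq = NULL) {
  prof <- .prepare_profile(times, concs, blq)
  if (nrow(prof) == 0) return(empty_nca_row("all observations BLQ or missing"))
  times <- prof$time
  concs <- prof$conc
  i_cmax <- which.max(concs)[1]
  out <- empty_nca_row()
  out$cmax <- concs[i_cmax]
  out$tmax <- times[i_cmax]
  lam <- lambda_z_fit(times, concs)
  if (lam$estimable) {
    out$lambda_z <- lam$lambda_z
    out$t_half <- lam$t_half
    out$span_halflives <- lam$span_halflives
    out$lambda_reliable <- lam$reliable
  }
  if (length(times) >= 2) {
    if (min(times) <= 0 && max(times) >= 24) {
      out$auc_0_24 <- auc_linear(times, concs, 0, 24)
    }
    start0 <- if (min(times) <= 0) 0 else min(times)
    out$auc_0_t <- auc_linear(times, concs, start0, max(times))
    if (lam$estimable) {
      c_last <- concs[length(concs)]
      out$auc_0_inf <- out$auc_0_t + c_last / lam$lambda_z
      out$cl_f <- .cl_from_auc(dose, out$auc_0_inf)
    }
  }
  out
}

.prepare_profile <- function(times, concs, blq = NULL) {
  keep <- !is.na(times) & !is.na(concs)
  times <- times[keep]
  concs <- concs[keep]
  if (!is.null(blq)) {
    blq <- as.logical(blq[keep])
    if (any(blq)) {
      i_cmax <- if (any(!blq)) which.max(ifelse(blq, -Inf, concs))[1] else 0L
      pre <- blq & seq_along(times) < i_cmax
      concs[pre] <- 0                      # BLQ before Tmax counted as zero
      drop <- blq & seq_along(times) >= i_cmax  # BLQ from Tmax on excluded
      times <- times[!drop]
      concs <- concs[!drop]
    }
  }
  o <- order(times)
  tibble::tibble(time = times[o], conc = concs[o])
}

#' Steady-state non-compartmental PK parameters
#'
#' Computed over a day-14 dosing interval: `Cav,ss = AUC0-tau / tau`,
#' `CLss/F = Dose / AUC0-tau` and `Vz,ss/F = CLss/F / lambda_z`. The
#' single-dose definition `CL/F = Dose / AUC0-inf` is also reported as
#' `cl_f`; the steady-state table statistic is `clss_f`.
#'
#' @param times,concs Day-14 profile with times in hours since the day-14
#'   dose (0 to 120 h for the test drug).
#' @param dose Dose in mg.
#' @param tau Dosing interval (h), default 24.
#' @param blq Optional BLQ flags.
#' @return One-row tibble with the single-dose fields plus `cav_ss`,
#'   `clss_f`, `vz_f`.
#' @export
nca_steady_state <- function(times, concs, dose, tau = 24, blq = NULL) {
  if (tau <= 0) abort("tau must be > 0")
  if (dose <= 0) abort("dose must be > 0")
  out <- nca_single_dose(times, concs, dose, blq)
  if (!is.na(out$auc_0_24) && tau == 24) {
    auc_tau <- out$auc_0_24
  } else {
    prof <- .prepare_profile(times, concs, blq)
    auc_tau <- if (nrow(prof) >= 2 && min(prof$time) <= 0 &&
                   max(prof$time) >= tau) {
      auc_linear(prof$time, prof$conc, 0, tau)
    } else NA_real_
  }
  if (!is.na(auc_tau)) {
    out$cav_ss <- auc_tau / tau
    out$clss_f <- .cl_from_auc(dose, auc_tau)
    if (!is.na(out$lambda_z)) out$vz_f <- out$clss_f / out$lambda_z
  }
  out
}

#' Accumulation ratios
#'
#' `R_Cmax = Cmax(day 14) / Cmax(day 1)` and
#' `R_AUC = AUC0-tau(day 14) / AUC0-24(day 1)`.
#'
#' @param day1,day14 One-row NCA tibbles from [nca_single_dose()] /
#'   [nca_steady_state()] (or anything carrying `cmax` and `auc_0_24`).
#' @return One-row tibble `r_cmax`, `r_auc`; a zero or missing denominator
#'   yields `NA`.
#' @export
#' @examples
#' accumulation_ratios(tibble::tibble(cmax = 80.5, auc_0_24 = 717),
#'                     tibble::tibble(cmax = 162, auc_0_24 = 1530))
accumulation_ratios <- function(day1, day14) {
  ratio <- function(num, den) {
    if (is.null(num) || is.null(den) || is.na(num) || is.na(den) || den == 0) {
      NA_real_
    } else num / den
  }
  tibble::tibble(
    r_cmax = ratio(day14$cmax, day1$cmax),
    r_auc = ratio(day14$auc_0_24, day1$auc_0_24))
}

#' Per-subject non-compartmental analysis of a study dataset
#'
#' Runs day-1 and day-14 NCA for every non-placebo subject and joins the
#' accumulation ratios. Day-14 times are re-referenced to the day-14 dose.
#'
#' @param ds A [study_dataset()].
#' @return A tibble, one row per subject x occasion, with an extra
#'   `occasion` column (`"day1"` / `"day14"`) and ratio columns on the
#'   day-14 rows.
#' @export
run_nca <- function(ds) {
  tau <- dataset_metadata(ds)$tau
  subs <- subject_records(ds, dvid = "drug_concentration")
  rows <- list()
  for (s in subs) {
    if (identical(s$arm, "placebo") || nrow(s$obs) == 0) next
    dose <- s$dose_amt[1]
    t14 <- max(s$dose_t)
    d1 <- s$obs[s$obs$OCC == "day1", ]
    d14 <- s$obs[s$obs$OCC == "day14", ]
    r1 <- if (nrow(d1) > 0) {
      nca_single_dose(d1$TIME, d1$DV, dose, d1$BLQ)
    } else empty_nca_row("no day-1 observations")
    r14 <- if (nrow(d14) > 0) {
      nca_steady_state(d14$TIME - t14, d14$DV, dose, tau, d14$BLQ)
    } else empty_nca_row("no day-14 observations")
    rat <- accumulation_ratios(r1, r14)
    r1 <- dplyr::mutate(r1, ID = s$id, ARM = s$arm, occasion = "day1",
                        r_cmax = NA_real_, r_auc = NA_real_)
    r14 <- dplyr::mutate(r14, ID = s$id, ARM = s$arm, occasion = "day14",
                         r_cmax = rat$r_cmax, r_auc = rat$r_auc)
    rows[[length(rows) + 1]] <- dplyr::bind_rows(r1, r14)
  }
  out <- dplyr::bind_rows(rows)
  dplyr::select(out, "ID", "ARM", "occasion", dplyr::everything())
}

#' Group summary of NCA parameters
#'
#' Arithmetic mean and SD per arm and occasion (median and range for Tmax),
#' the layout of a standard multiple-dose PK summary table.
#'
#' @param nca_tbl Output of [run_nca()].
#' @return A tibble with one row per arm x occasion x parameter.
#' @export
nca_summary <- function(nca_tbl) {
  long <- tidyr::pivot_longer(
    nca_tbl,
    cols = c("cmax", "tmax", "auc_0_24", "auc_0_t", "auc_0_inf", "t_half",
             "cav_ss", "clss_f", "vz_f", "r_cmax", "r_auc"),
    names_to = "parameter", values_to = "value")
  long %>%
    dplyr::filter(!is.na(.data$value)) %>%
    dplyr::group_by(.data$ARM, .data$occasion, .data$parameter) %>%
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = sd(.data$value),
      median = median(.data$value),
      min = min(.data$value),
      max = max(.data$value),
      .groups = "drop")
}
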