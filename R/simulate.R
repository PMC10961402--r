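#' Virtual-trial simulation configuration
#'
#' Defines the design and the true data-generating process of a simulated
#' 14-day once-daily multiple-dose trial: 32 subjects in two 16-subject dose
#' groups randomised 10:2:4 (active : placebo : comparator), rich PK/PD
#' sampling on days 1 and 14, trough samples on days 7 and 10, and oral
#' glucose tolerance tests on day -1 and day 15.
#'
#' The default true PK parameters were chosen so that noiseless group-level
#' non-compartmental summaries of the simulated active arms land on the
#' magnitudes reported for this dose range (day-14 Cmax around 150/300
#' ng/mL and AUC over a dosing interval around 1530/3120 h*ng/mL at 50/100
#' mg), and the DPP-4 link parameters reproduce inhibition summaries
#' (AUEC0-24h near 2010/2090 h*%, time above 80% inhibition near 22/32 h).
#'
#' @param seed Integer seed; a fixed seed reproduces the trial bit-for-bit.
#' @param n_per_arm Named integer vector of arm sizes.
#' @param true_theta Named list of typical two-compartment PK parameters for
#'   the active drug (`cl`, `v1`, `q`, `v2`, `ka`).
#' @param omega2 Named between-subject variances (lognormal) for `cl`, `v1`,
#'   `v2`.
#' @param sigma_prop Proportional residual CV for concentrations.
#' @param emax_true DPP-4 link parameters for the active drug:
#'   `emax` (%), `ec50` (ng/mL), `gamma`, `iiv_ec50` (variance).
#' @param emax_comparator Same for the comparator arm.
#' @param comparator_theta One-compartment parameters for the comparator
#'   (`cl`, `v`, `ka`).
#' @param tbil_covariate List `exponent` (power of TBIL on `v2`),
#'   `median`, `cv` of the lognormal TBIL distribution (stand-in values;
#'   no cohort distribution is published).
#' @param dpp4_baseline Mean and SD of pre-dose DPP-4 activity (arbitrary
#'   substrate-turnover units).
#' @param dpp4_noise_sd Proportional SD of the activity residual.
#' @param glp1 List: `baseline` (pM), `amplitude` (pM per meal pulse),
#'   `k` (inhibition amplification), `noise_sd` (pM).
#' @param ogtt List: per-analyte baseline and excursion parameters plus
#'   `noise_cv`; `multiplier` is a named per-arm treatment-effect factor.
#' @param efficacy List of per-arm mean shifts for the glycaemic indices;
#'   `ppg_supper_day14` holds the planted 2-h postprandial effect.
#' @param schedules Named list of sampling-time vectors (hours post first
#'   dose unless noted); override to thin the design in small studies.
#' @param n_days Number of dosing days (default 14).
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1,
    n_per_arm = c(cetagliptin50 = 10, cetagliptin100 = 10,
                  sitagliptin100 = 8, placebo = 4),
    true_theta = list(cl = 34.7, v1 = 30, q = 320, v2 = 788, ka = 6.1),
    omega2 = c(cl = 0.04, v1 = 0.06, v2 = 0.05),
    sigma_prop = 0.15,
    emax_true = list(emax = 92.47, ec50 = 5.37, gamma = 0.89,
                     iiv_ec50 = 0.04),
    emax_comparator = list(emax = 91.68, ec50 = 6.73, gamma = 0.89,
                           iiv_ec50 = 0.04),
    comparator_theta = list(cl = 26.6, v = 280, ka = 0.9),
    tbil_covariate = list(exponent = 0.5, median = 12, cv = 0.30),
    dpp4_baseline = c(mean = 20, sd = 3),
    dpp4_noise_sd = 0.015,
    glp1 = list(baseline = 0.45, amplitude = 3, k = 1.4, noise_sd = 0.3),
    ogtt = list(
      glucose = c(base = 7.5, peak = 6, tpeak = 0.75, shape = 2),
      insulin = c(base = 80, peak = 350, tpeak = 0.9, shape = 2),
      c_peptide = c(base = 1300, peak = 1500, tpeak = 1, shape = 2),
      glucagon = c(base = 160, peak = -40, tpeak = 0.8, shape = 2),
      noise_cv = 0.08,
      multiplier = c(cetagliptin50 = 1.35, cetagliptin100 = 1.25,
                     sitagliptin100 = 1.12, placebo = 1)),
    efficacy = list(
      fpg_base = 7.5, fpg_sd = 0.6,
      ppg_base = 11, ppg_sd = 1.5,
      hba1c_base = 8, hba1c_sd = 0.4,
      ga_base = 21, ga_sd = 1.5,
      ppg_supper_day14 = c(cetagliptin50 = -2.64, cetagliptin100 = 0,
                           sitagliptin100 = 0, placebo = 0)),
    schedules = NULL,
    n_days = 14) {
  if (sum(n_per_arm) <= 0) abort("at least one arm must have subjects")
  if (any(n_per_arm < 0)) abort("arm sizes must be non-negative")
  if (any(omega2 < 0) || sigma_prop < 0) abort("variances must be >= 0")
  last_dose <- 24 * (n_days - 1)
  default_schedules <- list(
    pk_day1 = c(0, 0.5, 1, 2, 3, 4, 5, 6, 8, 12, 24),
    pk_troughs = c(24 * 6, 24 * 9),                    # pre-dose days 7, 10
    pk_day14 = last_dose + c(0, 0.5, 1, 2, 3, 4, 5, 6, 8, 12, 24, 48, 72,
                             96, 120),
    pk_day14_comparator = last_dose + c(0, 0.5, 1, 2, 3, 4, 5, 6, 8, 12,
                                        24, 48),
    glp1_day1 = c(0, 0.5, 1, 2, 3, 4, 5, 6, 8, 12, 24),
    glp1_day14 = last_dose + c(0, 0.5, 1, 2, 3, 4, 5, 6, 8, 12, 24),
    ogtt = c(0, 0.167, 0.5, 1, 1.5, 2, 3),             # relative to glucose
    meal_times = c(4, 10))                             # post-dose, days 1/14
  structure(
    list(seed = seed, n_per_arm = n_per_arm, true_theta = true_theta,
         omega2 = omega2, sigma_prop = sigma_prop, emax_true = emax_true,
         emax_comparator = emax_comparator,
         comparator_theta = comparator_theta,
         tbil_covariate = tbil_covariate, dpp4_baseline = dpp4_baseline,
         dpp4_noise_sd = dpp4_noise_sd, glp1 = glp1, ogtt = ogtt,
         efficacy = efficacy,
         schedules = modifyList(default_schedules, schedules %||% list()),
         n_days = n_days),
    class = "sim_config")
}

#' Noiseless individual PK profile
#'
#' Superposition of closed-form single-dose solutions over a dose history;
#' delegates to [twocomp_oral_conc()] (or [onecomp_oral_conc()] for
#' three-parameter inputs).
#'
#' @param params Named individual PK parameters (`cl`, `v1`, `q`, `v2`,
#'   `ka`, or `cl`, `v`, `ka` for a one-compartment subject).
#' @param dose_t,dose_amt Dose times (h) and amounts (mg).
#' @param times Evaluation times (h).
#' @return Concentrations (ng/mL); zero before the first dose.
#' @export
simulate_pk_profile <- function(params, dose_t, dose_amt, times) {
  if (length(dose_t) == 0) return(rep(0, length(times)))
  if (!is.null(params[["v1"]])) {
    twocomp_oral_conc(params, dose_t, dose_amt, times)
  } else {
    onecomp_oral_conc(params, dose_t, dose_amt, times)
  }
}

sigmoid_emax <- function(conc, emax, ec50, gamma = 1) {
  out <- numeric(length(conc))
  pos <- conc > 0
  cg <- conc[pos]^gamma
  out[pos] <- emax * cg / (ec50^gamma + cg)
  out
}

#' Simulate DPP-4 activity from a concentration series
#'
#' Direct-effect link: `activity(t) = baseline * (1 - E(t)/100) * (1 + eps)`
#' with `E` the sigmoid-Emax inhibition and `eps` proportional Gaussian
#' noise; activity is floored at zero.
#'
#' @param conc Concentration series (ng/mL).
#' @param emax_params List `emax`, `ec50`, `gamma`.
#' @param baseline Subject's pre-dose activity (> 0).
#' @param noise_sd Proportional noise SD (0 for the noiseless truth).
#' @return Activity series, same length as `conc`.
#' @export
simulate_dpp4_activity <- function(conc, emax_params, baseline,
                                   noise_sd = 0) {
  if (baseline <= 0) abort("baseline activity must be > 0")
  E <- sigmoid_emax(conc, emax_params$emax, emax_params$ec50,
                    emax_params$gamma %||% 1)
  eps <- if (noise_sd > 0) rnorm(length(conc), 0, noise_sd) else 0
  pmax(baseline * (1 - E / 100) * (1 + eps), 0)
}

#' Simulate a meal-driven active GLP-1 series
#'
#' Phenomenological shape, not a mechanistic claim: each meal adds a pulse
#' with a triangular rise over 1 h and an exponential decay (half-life
#' 0.5 h), scaled by `1 + k * I(t)/100` where `I` is the concurrent DPP-4
#' inhibition.
#'
#' @param times Sampling times (h).
#' @param inhibition DPP-4 inhibition (%) at `times` (same length), or a
#'   single value.
#' @param meal_times Meal times (h).
#' @param baseline Pre-dose GLP-1 (pM).
#' @param amplitude Pulse peak height (pM) before inhibition scaling.
#' @param k Inhibition amplification factor.
#' @param noise_sd Additive Gaussian noise SD (pM).
#' @return GLP-1 series (pM), floored at zero.
#' @export
simulate_glp1 <- function(times, inhibition, meal_times, baseline,
                          amplitude, k = 1.4, noise_sd = 0) {
  if (amplitude < 0) abort("amplitude must be >= 0")
  inhibition <- rep_len(inhibition, length(times))
  pulse <- numeric(length(times))
  for (mt in meal_times) {
    dt <- times - mt
    rise <- dt >= 0 & dt < 1
    decay <- dt >= 1
    pulse[rise] <- pulse[rise] + amplitude * dt[rise]
    pulse[decay] <- pulse[decay] +
      amplitude * exp(-(dt[decay] - 1) * log(2) / 0.5)
  }
  y <- baseline + pulse * (1 + k * pmax(inhibition, 0) / 100)
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  pmax(y, 0)
}

gamma_excursion <- function(t, peak, tpeak, shape) {
  # unit-peak gamma-like bump: (t/tpeak)^shape * exp(shape*(1 - t/tpeak))
  x <- pmax(t, 0) / tpeak
  peak * x^shape * exp(shape * (1 - x))
}

#' Simulate OGTT analyte curves
#'
#' Fixed curve shapes (baseline plus a gamma-shaped excursion) with a
#' treatment-effect multiplier: glucose and glucagon excursions shrink,
#' insulin and C-peptide excursions grow, as the multiplier rises above 1.
#'
#' @param multiplier Treatment-effect factor (> 0; 1 = no effect).
#' @param cfg_ogtt The `ogtt` block of a [sim_config()].
#' @param times Sampling grid (h after the glucose dose).
#' @param noise_cv Proportional noise CV (0 for noiseless curves).
#' @return Tibble `time`, `glucose`, `insulin`, `c_peptide`, `glucagon`;
#'   all values non-negative.
#' @export
simulate_ogtt <- function(multiplier, cfg_ogtt = sim_config()$ogtt,
                          times = c(0, 0.167, 0.5, 1, 1.5, 2, 3),
                          noise_cv = cfg_ogtt$noise_cv) {
  if (multiplier <= 0) abort("multiplier must be > 0")
  shape_of <- function(name, eff) {
    p <- cfg_ogtt[[name]]
    y <- p[["base"]] + gamma_excursion(times, p[["peak"]], p[["tpeak"]],
                                       p[["shape"]]) * eff
    if (noise_cv > 0) y <- y * (1 + rnorm(length(y), 0, noise_cv))
    pmax(y, 0)
  }
  tibble::tibble(
    time = times,
    glucose = shape_of("glucose", 1 / multiplier),
    insulin = shape_of("insulin", multiplier),
    c_peptide = shape_of("c_peptide", multiplier),
    glucagon = shape_of("glucagon", 1 / multiplier))
}

#' Simulate a complete virtual trial
#'
#' Draws individual PK/PD parameters and covariates, simulates every
#' scheduled observation of the trial design and assembles a
#' [study_dataset()] together with the ground truth needed for
#' parameter-recovery tests.
#'
#' @param cfg A [sim_config()].
#' @return List with `dataset` (a [study_dataset()]) and `truth` (list:
#'   `subjects` tibble of realised individual parameters and baselines,
#'   `config` the generating configuration).
#' @export
simulate_trial <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  sch <- cfg$schedules
  last_dose <- 24 * (cfg$n_days - 1)
  dose_t <- seq(0, last_dose, by = 24)
  arms <- rep(names(cfg$n_per_arm), cfg$n_per_arm)
  n <- length(arms)
  tb <- cfg$tbil_covariate
  sdlog_tbil <- sqrt(log(1 + tb$cv^2))
  rows <- list()
  truth_rows <- list()
  for (i in seq_len(n)) {
    arm <- arms[i]
    dose <- switch(arm, cetagliptin50 = 50, cetagliptin100 = 100,
                   sitagliptin100 = 100, placebo = 0)
    tbil <- rlnorm(1, log(tb$median), sdlog_tbil)
    base_act <- max(rnorm(1, cfg$dpp4_baseline[["mean"]],
                          cfg$dpp4_baseline[["sd"]]), 1)
    # individual PK parameters
    if (arm %in% c("cetagliptin50", "cetagliptin100")) {
      eta <- rnorm(3) * sqrt(cfg$omega2[c("cl", "v1", "v2")])
      p_i <- list(
        cl = cfg$true_theta$cl * exp(eta[1]),
        v1 = cfg$true_theta$v1 * exp(eta[2]),
        q = cfg$true_theta$q,
        v2 = cfg$true_theta$v2 * (tbil / tb$median)^tb$exponent *
          exp(eta[3]),
        ka = cfg$true_theta$ka)
      link <- cfg$emax_true
    } else if (arm == "sitagliptin100") {
      eta <- rnorm(2) * sqrt(cfg$omega2[c("cl", "v1")])
      p_i <- list(cl = cfg$comparator_theta$cl * exp(eta[1]),
                  v = cfg$comparator_theta$v * exp(eta[2]),
                  ka = cfg$comparator_theta$ka)
      link <- cfg$emax_comparator
    } else {
      p_i <- NULL
      link <- list(emax = 0, ec50 = 1, gamma = 1)
    }
    eta_ec50 <- rnorm(1) * sqrt(link$iiv_ec50 %||% 0)
    ec50_i <- link$ec50 * exp(eta_ec50)
    link_i <- list(emax = link$emax, ec50 = ec50_i,
                   gamma = link$gamma %||% 1)

    pk_times <- sort(unique(c(sch$pk_day1, sch$pk_troughs,
                              if (arm == "sitagliptin100")
                                sch$pk_day14_comparator else sch$pk_day14)))
    conc_true <- if (is.null(p_i)) rep(0, length(pk_times)) else
      simulate_pk_profile(p_i, dose_t, rep(dose, length(dose_t)), pk_times)
    conc_obs <- conc_true *
      (1 + rnorm(length(conc_true), 0, cfg$sigma_prop))
    conc_obs <- pmax(conc_obs, 0)
    lloq <- default_metadata()$lloq$drug_concentration
    blq <- conc_obs < lloq
    conc_obs[blq] <- lloq

    act_true <- simulate_dpp4_activity(conc_true, link_i, base_act, 0)
    act_obs <- simulate_dpp4_activity(conc_true, link_i, base_act,
                                      cfg$dpp4_noise_sd)
    inh_true <- (1 - act_true / base_act) * 100

    glp_times <- sort(unique(c(sch$glp1_day1, sch$glp1_day14)))
    inh_glp <- stats::approx(pk_times, inh_true, xout = glp_times,
                             rule = 2)$y
    meal_abs <- c(sch$meal_times, last_dose + sch$meal_times)
    glp_obs <- simulate_glp1(glp_times, inh_glp, meal_abs,
                             cfg$glp1$baseline, cfg$glp1$amplitude,
                             cfg$glp1$k, cfg$glp1$noise_sd)

    occ_of <- function(t) {
      dplyr::case_when(t < 0 ~ "baseline",
                       t <= 24 ~ "day1",
                       t < last_dose ~ paste0("day", floor(t / 24) + 1),
                       TRUE ~ "day14")
    }
    ev <- list()
    push <- function(x) ev[[length(ev) + 1]] <<- x
    if (dose > 0) {
      push(tibble::tibble(TIME = dose_t, EVID = 1L, AMT = dose,
                          DV = NA_real_, DVID = NA_character_, MDV = 1L,
                          BLQ = 0L, OCC = occ_of(dose_t)))
    }
    push(tibble::tibble(TIME = pk_times, EVID = 0L, AMT = NA_real_,
                        DV = conc_obs, DVID = "drug_concentration",
                        MDV = 0L, BLQ = as.integer(blq),
                        OCC = occ_of(pk_times)))
    push(tibble::tibble(TIME = pk_times, EVID = 0L, AMT = NA_real_,
                        DV = act_obs, DVID = "dpp4_activity", MDV = 0L,
                        BLQ = 0L, OCC = occ_of(pk_times)))
    push(tibble::tibble(TIME = glp_times, EVID = 0L, AMT = NA_real_,
                        DV = glp_obs, DVID = "glp1_active", MDV = 0L,
                        BLQ = 0L, OCC = occ_of(glp_times)))
    # OGTT on day -1 and day 15
    mult <- cfg$ogtt$multiplier[[arm]]
    for (occ in c("day-1", "day15")) {
      m_eff <- if (occ == "day-1") 1 else mult
      curves <- simulate_ogtt(m_eff, cfg$ogtt, sch$ogtt, cfg$ogtt$noise_cv)
      t0 <- if (occ == "day-1") -24 else last_dose + 24
      long <- tidyr::pivot_longer(curves, -"time", names_to = "DVID",
                                  values_to = "DV")
      push(tibble::tibble(TIME = t0 + long$time, EVID = 0L, AMT = NA_real_,
                          DV = long$DV, DVID = long$DVID, MDV = 0L,
                          BLQ = 0L, OCC = occ))
    }
    # glycaemic indices: baseline day -2 and on-treatment days
    eff <- cfg$efficacy
    fpg0 <- rnorm(1, eff$fpg_base, eff$fpg_sd)
    push(tibble::tibble(
      TIME = c(-48, 24 * 6, last_dose),
      EVID = 0L, AMT = NA_real_,
      DV = pmax(fpg0 + rnorm(3, 0, 0.3), 0.1),
      DVID = "fpg", MDV = 0L, BLQ = 0L,
      OCC = c("day-2", "day7", "day14")))
    supper_shift <- eff$ppg_supper_day14[[arm]] %||% 0
    ppg0 <- rnorm(1, eff$ppg_base, eff$ppg_sd)
    ppg_spec <- tibble::tibble(
      day = c("day-2", "day-2", "day7", "day7", "day14", "day14"),
      meal = c("lunch", "supper", "lunch", "supper", "lunch", "supper"),
      shift = c(0, 0, 0, 0, 0, supper_shift))
    ppg_time <- c(-42, -36, 24 * 6 + 6, 24 * 6 + 12, last_dose + 6,
                  last_dose + 12)
    push(tibble::tibble(
      TIME = ppg_time, EVID = 0L, AMT = NA_real_,
      DV = pmax(ppg0 + ppg_spec$shift + rnorm(6, 0, 0.5), 0.1),
      DVID = "ppg_2h", MDV = 0L, BLQ = 0L,
      OCC = paste0(ppg_spec$day, ":", ppg_spec$meal)))
    for (idx in c("hba1c", "ga")) {
      v0 <- rnorm(1, eff[[paste0(idx, "_base")]], eff[[paste0(idx, "_sd")]])
      push(tibble::tibble(
        TIME = c(-48, last_dose), EVID = 0L, AMT = NA_real_,
        DV = pmax(v0 + c(0, rnorm(1, 0, 0.2)), 0.1),
        DVID = idx, MDV = 0L, BLQ = 0L, OCC = c("day-2", "day14")))
    }
    sub <- dplyr::bind_rows(ev)
    sub$ID <- i
    sub$ARM <- arm
    sub$TBIL <- tbil
    rows[[i]] <- sub
    truth_rows[[i]] <- tibble::tibble(
      ID = i, ARM = arm, TBIL = tbil, dose = dose,
      cl = p_i$cl %||% NA_real_, v1 = p_i$v1 %||% p_i$v %||% NA_real_,
      q = p_i$q %||% NA_real_, v2 = p_i$v2 %||% NA_real_,
      ka = p_i$ka %||% NA_real_,
      dpp4_baseline = base_act, ec50 = ec50_i,
      emax = link_i$emax, gamma = link_i$gamma)
  }
  events <- dplyr::bind_rows(rows) %>%
    dplyr::arrange(.data$ID, .data$TIME, dplyr::desc(.data$EVID))
  ds <- study_dataset(events)
  list(dataset = ds,
       truth = list(subjects = dplyr::bind_rows(truth_rows), config = cfg))
}
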