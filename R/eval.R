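#' Update a model's initial estimates from a fitted object
#'
#' Convenience for warm-started refits (bootstrap replicates, sensitivity
#' re-runs): returns the model with initial values set to the fit's final
#' estimates.
#'
#' @param model A [pop_model()].
#' @param fit A `pop_model_fit` of the same model.
#' @return The updated `pop_model`.
#' @export
update_inits <- function(model, fit) {
  est <- setNames(fit$theta$estimate, fit$theta$parameter)
  model$params$init <- ifelse(model$params$name %in% names(est),
                              est[model$params$name], model$params$init)
  if (length(model$iiv) > 0) {
    om <- setNames(fit$omega$omega2, fit$omega$parameter)
    model$iiv[names(model$iiv)] <- om[names(model$iiv)]
  }
  model$error$add <- fit$sigma_hat$add
  model$error$prop <- fit$sigma_hat$prop
  model
}

#' Nonparametric bootstrap of a population model
#'
#' Resamples subjects (whole-subject blocks) with replacement, stratified
#' by arm when requested, refits each replicate dataset and summarises the
#' replicate estimates by their median and 2.5/97.5 percentiles.
#' Non-converged replicates are excluded and counted, never imputed.
#' Deterministic given `seed`.
#'
#' @param data A [study_dataset()] or prepared subject list.
#' @param model A [pop_model()] (typically with inits at the original
#'   estimates via [update_inits()]).
#' @param B Number of bootstrap datasets.
#' @param seed Integer seed.
#' @param stratify_by_arm Preserve arm sizes when resampling (default TRUE).
#' @param control Fit control (SEs and diagnostics are off by default).
#' @return List of class `bootstrap_result`: `summary` (tibble term,
#'   median, lower, upper), `replicates` (per-replicate estimates),
#'   `n_requested`, `n_converged`.
#' @export
bootstrap_model <- function(data, model, B = 1000, seed = 1,
                            stratify_by_arm = TRUE, control = list()) {
  if (B < 1) abort("B must be >= 1")
  subjects <- prepare_subjects(data, model)
  ctl <- modifyList(list(se = FALSE, diagnostics = FALSE), control)
  arms <- vapply(subjects, function(s) s$arm %||% "all", character(1))
  groups <- if (stratify_by_arm) split(seq_along(subjects), arms) else
    list(all = seq_along(subjects))
  set.seed(seed)
  reps <- vector("list", B)
  n_conv <- 0L
  for (b in seq_len(B)) {
    idx <- unlist(lapply(groups, function(g) {
      sample(g, length(g), replace = TRUE)
    }), use.names = FALSE)
    boot_sub <- subjects[idx]
    # re-key ids so resampled duplicates stay distinct subjects
    for (j in seq_along(boot_sub)) boot_sub[[j]]$id <- j
    fit <- tryCatch(fit_population(boot_sub, model, ctl),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$convergence$converged || !is.finite(fit$ofv)) {
      next
    }
    n_conv <- n_conv + 1L
    td <- tidy(fit)
    reps[[b]] <- tibble::tibble(replicate = b, term = td$term,
                                estimate = td$estimate)
  }
  replicates <- dplyr::bind_rows(reps)
  summary <- replicates %>%
    dplyr::group_by(.data$term) %>%
    dplyr::summarise(
      median = median(.data$estimate),
      lower = quantile(.data$estimate, 0.025, names = FALSE),
      upper = quantile(.data$estimate, 0.975, names = FALSE),
      .groups = "drop")
  structure(list(summary = summary, replicates = replicates,
                 n_requested = B, n_converged = n_conv),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap: %d/%d replicates converged\n", x$n_converged,
              x$n_requested))
  print(x$summary)
  invisible(x)
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets under the fitted model with the
#' original design (doses, times, covariates) and fresh draws of the random
#' effects and residual errors; per time bin it reports the observed
#' 5th/50th/95th percentiles against the corresponding simulated
#' percentiles with their 90% confidence bands. Bins default to the nominal
#' scheduled sampling times. Deterministic given `seed`.
#'
#' @param fit A `pop_model_fit`.
#' @param n_sim Number of simulated replicates.
#' @param seed Integer seed.
#' @param bins Optional vector of bin edges; by default each distinct
#'   sampling time is its own bin.
#' @param probs Percentiles to track (default `c(0.05, 0.5, 0.95)`).
#' @return A tibble of class `vpc_result`: one row per bin x percentile
#'   with `observed`, `sim_median`, `sim_lower`, `sim_upper`, `n_obs`.
#' @export
vpc <- function(fit, n_sim = 1000, seed = 1, bins = NULL,
                probs = c(0.05, 0.5, 0.95)) {
  model <- fit$model
  subjects <- fit$subjects
  q <- length(fit$omega2_hat)
  sg <- .sigma_pair(model, fit$sigma_hat)
  base <- .base_param_matrix(model, subjects, fit$theta_hat)
  pos <- if (q > 0) match(names(fit$omega2_hat), colnames(base)) else
    integer()
  all_t <- unlist(lapply(subjects, function(s) s$t))
  all_y <- unlist(lapply(subjects, function(s) s$y))
  bin_of <- function(t) {
    if (is.null(bins)) t else bins[pmax(findInterval(t, bins), 1)]
  }
  bin_id <- bin_of(all_t)
  set.seed(seed)
  n_obs_total <- length(all_y)
  sim_stats <- array(NA_real_, dim = c(n_sim, length(unique(bin_id)),
                                       length(probs)))
  ubins <- sort(unique(bin_id))
  for (r in seq_len(n_sim)) {
    ysim <- numeric(n_obs_total)
    off <- 0
    for (i in seq_along(subjects)) {
      s <- subjects[[i]]
      ni <- length(s$y)
      par_i <- base[i, ]
      if (q > 0) {
        eta <- rnorm(q) * sqrt(fit$omega2_hat)
        par_i <- .apply_eta(par_i, pos, eta,
                            model$eta_transform %||% "lognormal")
      }
      f <- predict_subject(model, par_i, s)
      eps_p <- if (sg[2] > 0) rnorm(ni, 0, sg[2]) else 0
      eps_a <- if (sg[1] > 0) rnorm(ni, 0, sg[1]) else 0
      ysim[off + seq_len(ni)] <- f * (1 + eps_p) + eps_a
      off <- off + ni
    }
    for (bi in seq_along(ubins)) {
      sel <- bin_id == ubins[bi]
      sim_stats[r, bi, ] <- quantile(ysim[sel], probs, names = FALSE)
    }
  }
  rows <- list()
  for (bi in seq_along(ubins)) {
    sel <- bin_id == ubins[bi]
    obs_q <- quantile(all_y[sel], probs, names = FALSE)
    for (pi in seq_along(probs)) {
      sims <- sim_stats[, bi, pi]
      rows[[length(rows) + 1]] <- tibble::tibble(
        bin = ubins[bi], percentile = 100 * probs[pi],
        observed = obs_q[pi],
        sim_median = median(sims),
        sim_lower = quantile(sims, 0.05, names = FALSE),
        sim_upper = quantile(sims, 0.95, names = FALSE),
        n_obs = sum(sel))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("vpc_result", class(out))
  out
}

#' Goodness-of-fit tables
#'
#' One row per non-excluded observation (ID, TIME, DV, PRED, IPRED, CWRES)
#' plus a summary of the conditional-weighted-residual distribution and the
#' count of potential outliers.
#'
#' @param fit A `pop_model_fit`.
#' @param outlier_threshold CWRES magnitude flagged as outlying (default 5).
#' @return List with `table` and one-row `summary` (cwres mean, variance,
#'   `n_outliers`, `n_obs`).
#' @export
gof_tables <- function(fit, outlier_threshold = 5) {
  tab <- cwres(fit)
  list(table = tab,
       summary = tibble::tibble(
         cwres_mean = mean(tab$CWRES),
         cwres_var = var(tab$CWRES),
         n_outliers = sum(abs(tab$CWRES) > outlier_threshold),
         n_obs = nrow(tab)))
}
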