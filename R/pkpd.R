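#' Build the sequential PK/PD dataset
#'
#' Implements the IPP (individual PK parameters) sequential approach: the
#' population PK fit is frozen, concentration observations with
#' `|CWRES| > exclusion` are flagged as outliers, and each DPP-4 inhibition
#' observation is paired with the subject's model-predicted concentration at
#' its time (from the empirical Bayes PK parameters).
#'
#' @param pk_fit A converged `pop_model_fit` of the concentration data.
#' @param ds The [study_dataset()] holding the DPP-4 activity observations.
#' @param exclusion CWRES magnitude threshold (default 5; must be > 0).
#' @return List of class `pkpd_dataset`: `subjects` (prepared list with
#'   inhibition `y` and predicted-concentration `x`), `exclusions` (flagged
#'   concentration records), `n_excluded`, `pk_fit`.
#' @export
build_pkpd_dataset <- function(pk_fit, ds, exclusion = 5) {
  if (!is.finite(exclusion) && !is.infinite(exclusion)) {
    abort("exclusion threshold must be numeric")
  }
  if (exclusion <= 0) abort("exclusion threshold must be > 0")
  diag <- cwres(pk_fit)
  excl <- diag[abs(diag$CWRES) > exclusion, , drop = FALSE]
  # inhibition observations on the PK-sampled occasions
  act <- tibble::as_tibble(ds) %>%
    dplyr::filter(.data$EVID == 0L, .data$DVID == "dpp4_activity")
  pk_ids <- vapply(pk_fit$subjects, function(s) s$id, numeric(1))
  subjects <- list()
  for (i in seq_along(pk_fit$subjects)) {
    s <- pk_fit$subjects[[i]]
    a <- act[act$ID == s$id, ]
    if (nrow(a) == 0) next
    base <- a$DV[which.min(a$TIME)]
    inh <- (1 - a$DV / base) * 100
    par_i <- .individual_params(pk_fit, i)
    conc_pred <- predict_subject(pk_fit$model, par_i, s, times = a$TIME)
    subjects[[length(subjects) + 1]] <- list(
      id = s$id, arm = s$arm, y = inh, t = a$TIME,
      dose_t = s$dose_t, dose_amt = s$dose_amt,
      x = conc_pred, covariates = s$covariates)
  }
  structure(list(subjects = subjects, exclusions = excl,
                 n_excluded = nrow(excl), pk_fit = pk_fit),
            class = "pkpd_dataset")
}

#' Default sigmoid-Emax population PK/PD model
#'
#' Sigmoid-Emax direct effect on the individually predicted concentration,
#' lognormal variability on EC50 and combined (additive + proportional)
#' residual error.
#'
#' @param inits Named overrides for `emax`, `ec50`, `gamma`.
#' @param iiv Named initial variances (default EC50 only).
#' @param error Residual error spec.
#' @return A `pop_model`.
#' @export
pkpd_emax_model <- function(inits = c(),
                            iiv = c(ec50 = 0.1),
                            error = list(model = "combined", add = 2,
                                         prop = 0.05)) {
  base <- c(emax = 90, ec50 = 6, gamma = 1)
  base[names(inits)] <- inits
  pop_model(
    "emax",
    tibble::tibble(name = names(base), init = unname(base),
                   transform = c("logit100", "log", "log")),
    iiv = iiv, error = error, dvid = "dpp4_activity")
}

#' Fit the sequential population PK/PD model
#'
#' Maximum-likelihood (Laplace) fit of the sigmoid-Emax model to the
#' inhibition data of a [build_pkpd_dataset()]; the PK side stays frozen.
#'
#' @param pkpd A `pkpd_dataset`.
#' @param model A [pop_model()], default [pkpd_emax_model()].
#' @param control Passed to [fit_population()].
#' @return A `pop_model_fit` over (Emax, EC50, gamma).
#' @export
fit_pkpd <- function(pkpd, model = pkpd_emax_model(), control = list()) {
  stopifnot(inherits(pkpd, "pkpd_dataset"))
  fit_population(pkpd$subjects, model, control)
}

#' Predict individual DPP-4 inhibition over time
#'
#' Direct effect, no delay: `E(t) = Emax * C_i(t)^gamma /
#' (EC50_i^gamma + C_i(t)^gamma)` with `C_i` from the frozen individual PK
#' parameters and `EC50_i` from the subject's PD empirical Bayes estimate.
#'
#' @param pd_fit A `pop_model_fit` from [fit_pkpd()].
#' @param pkpd The `pkpd_dataset` used for the fit.
#' @param id Subject identifier.
#' @param times Prediction times (h).
#' @return Tibble `time`, `conc`, `inhibition`.
#' @export
predict_inhibition <- function(pd_fit, pkpd, id, times) {
  idx_pd <- which(vapply(pd_fit$subjects, function(s) s$id, numeric(1)) == id)
  if (length(idx_pd) == 0) abort(paste0("unknown subject: ", id))
  pk_fit <- pkpd$pk_fit
  idx_pk <- which(vapply(pk_fit$subjects, function(s) s$id,
                         numeric(1)) == id)
  conc <- if (length(idx_pk) == 1) {
    par_pk <- .individual_params(pk_fit, idx_pk)
    predict_subject(pk_fit$model, par_pk, pk_fit$subjects[[idx_pk]],
                    times = times)
  } else {
    rep(0, length(times))
  }
  par_pd <- .individual_params(pd_fit, idx_pd)
  tibble::tibble(
    time = times, conc = conc,
    inhibition = sigmoid_emax(conc, par_pd[["emax"]], par_pd[["ec50"]],
                              par_pd[["gamma"]]))
}
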