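#' Two-compartment oral concentration, closed form
#'
#' Tri-exponential single-dose solution (macro rates alpha, beta derived
#' from CL, V1, Q, V2 plus the absorption rate Ka), superposed over the dose
#' history. All parameters are apparent (/F); bioavailability is fixed at 1.
#' Rate collisions (Ka equal to a macro rate) are handled by a continuous
#' limit branch, never NaN.
#'
#' @param params Named list/vector with `cl` (L/h), `v1` (L), `q` (L/h),
#'   `v2` (L), `ka` (1/h).
#' @param dose_t,dose_amt Dose times (h) and amounts (mg).
#' @param times Times at which to evaluate (h); times before the first dose
#'   return 0.
#' @return Concentrations in ng/mL.
#' @export
#' @examples
#' p <- list(cl = 33, v1 = 120, q = 9.6, v2 = 384, ka = 1.5)
#' twocomp_oral_conc(p, dose_t = 0, dose_amt = 50, times = c(0, 1, 2, 24))
twocomp_oral_conc <- function(params, dose_t, dose_amt, times) {
  p <- as.numeric(c(params[["cl"]], params[["v1"]], params[["q"]],
                    params[["v2"]], params[["ka"]]))
  if (any(!is.finite(p)) || any(p <= 0)) abort("all PK parameters must be > 0")
  pred_pk_cpp(p, as.numeric(times), as.numeric(dose_t),
              rep_len(as.numeric(dose_amt), length(dose_t)), 1L)
}

#' One-compartment oral concentration (Bateman), closed form
#'
#' @param params Named list/vector with `cl` (L/h), `v` (L), `ka` (1/h).
#' @inheritParams twocomp_oral_conc
#' @return Concentrations in ng/mL.
#' @export
onecomp_oral_conc <- function(params, dose_t, dose_amt, times) {
  p <- as.numeric(c(params[["cl"]], params[["v"]], params[["ka"]]))
  if (any(!is.finite(p)) || any(p <= 0)) abort("all PK parameters must be > 0")
  pred_pk_cpp(p, as.numeric(times), as.numeric(dose_t),
              rep_len(as.numeric(dose_amt), length(dose_t)), 2L)
}

#' Apply covariate effects to structural parameters
#'
#' Power form normalised to a reference value:
#' `param_i = theta_param * (cov_i / reference) ^ exponent`. Composes
#' multiplicatively with the lognormal between-subject effects
#' `exp(eta)`.
#'
#' @param theta Named numeric vector of typical parameter values.
#' @param effects List of covariate effects, each a list with `parameter`,
#'   `covariate`, `exponent`, `reference`.
#' @param covariates Named list/vector of the subject's covariate values.
#' @return Named numeric vector of individual structural parameters.
#' @export
#' @examples
#' apply_covariates(c(v2 = 400), list(list(parameter = "v2",
#'   covariate = "TBIL", exponent = 0.5, reference = 12)),
#'   c(TBIL = 48))  # doubled
apply_covariates <- function(theta, effects, covariates) {
  out <- theta
  covariates <- as.list(covariates)
  for (ef in effects) {
    cov_val <- covariates[[ef$covariate]]
    if (is.null(cov_val) || is.na(cov_val)) {
      abort(paste0("missing covariate ", ef$covariate,
                   " required for parameter ", ef$parameter))
    }
    if (cov_val <= 0 || ef$reference <= 0) {
      abort("power-form covariates require positive values and reference")
    }
    out[[ef$parameter]] <- out[[ef$parameter]] *
      (cov_val / ef$reference)^ef$exponent
  }
  out
}
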