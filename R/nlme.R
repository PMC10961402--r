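#' Define a population (nonlinear mixed-effects) model
#'
#' A declarative model specification consumed by [fit_population()], [ofv()]
#' and the model-evaluation tools. Individual parameters follow
#' `P_i = P_pop * covariate factors * exp(eta_i)` with diagonal lognormal
#' between-subject variability, and the residual error is additive,
#' proportional or combined.
#'
#' @param structural One of `"twocomp_oral"` (parameters `cl`, `v1`, `q`,
#'   `v2`, `ka`), `"onecomp_oral"` (`cl`, `v`, `ka`), `"emax"` (`emax`,
#'   `ec50`, `gamma`; driven by a per-observation input `x`), `"linear"`
#'   (`intercept`, `slope`; driven by `x`), or an R function
#'   `f(params_ind, subject)` returning the prediction vector for one
#'   subject.
#' @param params Tibble with columns `name`, `init` and optionally
#'   `transform` (`"log"` default, `"identity"`, `"logit100"`) and `fixed`.
#' @param iiv Named numeric vector of initial variances (omega^2) for the
#'   parameters carrying between-subject variability. A zero/absent entry
#'   means no random effect on that parameter.
#' @param error List: `model` (`"additive"`, `"proportional"`, `"combined"`),
#'   `add` (SD, DV units), `prop` (fraction).
#' @param covariate_effects List of power-form covariate effects, each
#'   `list(parameter =, covariate =, exponent =, reference =, fixed =)`.
#'   A non-fixed exponent is estimated as an extra fixed effect named
#'   `<parameter>_<covariate>`.
#' @param dvid Observation kind modelled (default drug concentration).
#' @param arms Treatment arms included in the fit.
#' @param eta_transform How random effects enter the individual parameters:
#'   `"lognormal"` (`P_i = P * exp(eta)`, the default) or `"additive"`
#'   (`P_i = P + eta`; supported for function structurals, used e.g. by
#'   linear-Gaussian reference models).
#'
#' @return An object of class `pop_model`.
#' @export
pop_model <- function(structural, params, iiv = numeric(),
                      error = list(model = "proportional", prop = 0.15),
                      covariate_effects = list(),
                      dvid = "drug_concentration",
                      arms = c("cetagliptin50", "cetagliptin100"),
                      eta_transform = c("lognormal", "additive")) {
  eta_transform <- match.arg(eta_transform)
  if (eta_transform == "additive" && !is.function(structural)) {
    abort("additive random effects require a function structural model")
  }
  params <- tibble::as_tibble(params)
  if (!"transform" %in% names(params)) params$transform <- "log"
  if (!"fixed" %in% names(params)) params$fixed <- FALSE
  stopifnot(!anyDuplicated(params$name))
  if (length(iiv) > 0) {
    stopifnot(all(names(iiv) %in% params$name), all(iiv >= 0))
    iiv <- iiv[iiv > 0]
  }
  err_model <- match.arg(error$model,
                         c("additive", "proportional", "combined"))
  structure(list(structural = structural, params = params, iiv = iiv,
                 error = list(model = err_model,
                              add = error$add %||% 0,
                              prop = error$prop %||% 0),
                 covariate_effects = covariate_effects,
                 dvid = dvid, arms = arms, eta_transform = eta_transform),
            class = "pop_model")
}

# apply random effects to a parameter vector
.apply_eta <- function(par, pos, eta, transform = "lognormal") {
  if (length(pos) == 0) return(par)
  if (transform == "additive") {
    par[pos] <- par[pos] + eta
  } else {
    par[pos] <- par[pos] * exp(eta)
  }
  par
}

#' Standard two-compartment population PK model
#'
#' The default structural configuration for the test drug: two-compartment
#' oral absorption, lognormal variability on `cl`, `v1` and `v2` (sparse
#' absorption-phase sampling leaves `ka` without a random effect), and
#' proportional residual error. With the first post-dose sample at 0.5 h
#' the absorption rate constant is not estimable and is fixed by default
#' (`ka_fixed = TRUE`); the remaining disposition parameters are estimated.
#'
#' @param inits Named overrides of the typical-value initial estimates.
#' @param iiv Named initial omega^2 values.
#' @param error Residual error spec, as in [pop_model()].
#' @param covariate_effects As in [pop_model()].
#' @param arms Arms included in the fit.
#' @param ka_fixed Keep the absorption rate constant fixed at its initial
#'   value (default TRUE).
#' @return A `pop_model`.
#' @export
pk_twocomp_model <- function(inits = c(), iiv = c(cl = 0.1, v1 = 0.1, v2 = 0.1),
                             error = list(model = "proportional", prop = 0.15),
                             covariate_effects = list(),
                             arms = c("cetagliptin50", "cetagliptin100"),
                             ka_fixed = TRUE) {
  base <- c(cl = 30, v1 = 50, q = 200, v2 = 600, ka = 6)
  base[names(inits)] <- inits
  pop_model("twocomp_oral",
            tibble::tibble(name = names(base), init = unname(base),
                           transform = "log",
                           fixed = c(FALSE, FALSE, FALSE, FALSE, ka_fixed)),
            iiv = iiv, error = error, covariate_effects = covariate_effects,
            arms = arms)
}

structural_model_id <- function(structural) {
  if (is.function(structural)) return(0L)
  switch(structural, twocomp_oral = 1L, onecomp_oral = 2L, emax = 3L,
         linear = 4L,
         abort(paste0("unknown structural model: ", structural)))
}

#' Prepare per-subject fitting data
#'
#' Extracts the observation vectors a [pop_model()] needs from a
#' [study_dataset()] (or passes through an already-prepared list). BLQ
#' observations are excluded from likelihood evaluation.
#'
#' @param ds A [study_dataset()] or a prepared subject list.
#' @param model A [pop_model()].
#' @return List of subjects, each `list(id, arm, y, t, dose_t, dose_amt, x,
#'   covariates)`.
#' @export
prepare_subjects <- function(ds, model) {
  if (!inherits(ds, "study_dataset")) return(ds)
  recs <- subject_records(ds, dvid = model$dvid, drop_blq = TRUE)
  recs <- Filter(function(s) s$arm %in% model$arms, recs)
  lapply(recs, function(s) {
    keep <- !is.na(s$obs$DV)
    list(id = s$id, arm = s$arm,
         y = s$obs$DV[keep], t = s$obs$TIME[keep],
         dose_t = s$dose_t, dose_amt = s$dose_amt,
         x = numeric(0), covariates = s$covariates)
  })
}

# individual base parameters (typical values x covariate factors), one row
# per subject, columns in model$params$name order (exponent thetas dropped)
.base_param_matrix <- function(model, subjects, theta) {
  struct_names <- .structural_param_names(model)
  n <- length(subjects)
  mat <- matrix(rep(theta[struct_names], each = n), nrow = n,
                dimnames = list(NULL, struct_names))
  for (ef in model$covariate_effects) {
    expo <- if (isTRUE(ef$fixed)) ef$exponent else
      theta[[paste0(ef$parameter, "_", ef$covariate)]]
    for (i in seq_len(n)) {
      cov_val <- subjects[[i]]$covariates[[ef$covariate]]
      if (is.null(cov_val) || is.na(cov_val)) {
        abort(paste0("subject ", subjects[[i]]$id, " is missing covariate ",
                     ef$covariate))
      }
      mat[i, ef$parameter] <- mat[i, ef$parameter] *
        (cov_val / ef$reference)^expo
    }
  }
  mat
}

.structural_param_names <- function(model) {
  cov_names <- vapply(model$covariate_effects, function(ef) {
    if (isTRUE(ef$fixed)) NA_character_ else
      paste0(ef$parameter, "_", ef$covariate)
  }, character(1))
  setdiff(model$params$name, cov_names[!is.na(cov_names)])
}

.sigma_pair <- function(model, sigma) {
  switch(model$error$model,
         additive = c(sigma[["add"]], 0),
         proportional = c(0, sigma[["prop"]]),
         combined = c(sigma[["add"]], sigma[["prop"]]))
}

.subject_payload <- function(subjects) {
  lapply(subjects, function(s) {
    list(y = as.numeric(s$y), t = as.numeric(s$t),
         dose_t = as.numeric(s$dose_t),
         dose_amt = rep_len(as.numeric(s$dose_amt), length(s$dose_t)),
         x = as.numeric(s$x %||% numeric(0)))
  })
}

.engine_call <- function(model, subjects, theta, omega2, sigma, eta_start,
                         payload = NULL) {
  base <- .base_param_matrix(model, subjects, theta)
  iiv_idx <- match(names(omega2), colnames(base))
  sg <- .sigma_pair(model, sigma)
  subj_payload <- payload %||% .subject_payload(subjects)
  rfun <- NULL
  if (is.function(model$structural)) {
    iiv_pos <- match(names(omega2), colnames(base))
    tfm <- model$eta_transform %||% "lognormal"
    rfun <- function(i, eta) {
      par <- .apply_eta(base[i, ], iiv_pos, eta, tfm)
      model$structural(par, subjects[[i]])
    }
  }
  ofv_laplace_cpp(subj_payload, base, as.integer(iiv_idx),
                  as.numeric(omega2), sg[1], sg[2],
                  structural_model_id(model$structural), eta_start,
                  rfun)
}

#' Marginal -2 log-likelihood (Laplace approximation)
#'
#' Sum over subjects of the -2 log marginal likelihood, each subject's
#' integral over its random effects approximated by Laplace at the
#' posterior mode. Exact for linear-Gaussian models. A zero-length `omega2`
#' gives the pure fixed-effects -2LL.
#'
#' @param data A [study_dataset()] or prepared subject list.
#' @param model A [pop_model()].
#' @param theta Named numeric vector of fixed effects (natural scale).
#' @param omega2 Named numeric vector of between-subject variances.
#' @param sigma Named list/vector with `add` and/or `prop`.
#' @return List with `ofv`, per-subject `ofv_i` and the `eta` modes.
#' @export
ofv <- function(data, model, theta, omega2 = model$iiv,
                sigma = c(add = model$error$add, prop = model$error$prop)) {
  subjects <- prepare_subjects(data, model)
  sigma <- as.list(sigma)
  eta0 <- matrix(0, length(subjects), max(length(omega2), 1))
  res <- .engine_call(model, subjects, theta, omega2, sigma, eta0)
  list(ofv = res$ofv, ofv_i = as.numeric(res$ofv_i), eta = res$eta)
}

# --- packing of the outer optimisation vector -----------------------------

.pack <- function(model) {
  free <- !model$params$fixed
  th <- model$params[free, ]
  pk <- list(theta_names = th$name, theta_transform = th$transform,
             omega_names = names(model$iiv) %||% character(0),
             err = model$error$model)
  start <- c(
    vapply(seq_len(nrow(th)), function(i) {
      .to_unconstrained(th$init[i], th$transform[i])
    }, numeric(1)),
    log(unname(model$iiv)),
    switch(model$error$model,
           additive = log(model$error$add),
           proportional = log(model$error$prop),
           combined = c(log(model$error$add), log(model$error$prop))))
  omega_labels <- if (length(pk$omega_names) > 0) {
    paste0("omega2_", pk$omega_names)
  } else character(0)
  names(start) <- c(th$name, omega_labels,
                    switch(model$error$model, additive = "sigma_add",
                           proportional = "sigma_prop",
                           combined = c("sigma_add", "sigma_prop")))
  pk$start <- start
  pk
}

.to_unconstrained <- function(x, transform) {
  switch(transform, log = log(x), identity = x,
         logit100 = stats::qlogis(x / 100))
}
.from_unconstrained <- function(x, transform) {
  switch(transform, log = exp(x), identity = x,
         logit100 = 100 * stats::plogis(x))
}

.unpack <- function(par, pk, model) {
  nth <- length(pk$theta_names)
  theta <- vapply(seq_len(nth), function(i) {
    .from_unconstrained(par[i], pk$theta_transform[i])
  }, numeric(1))
  names(theta) <- pk$theta_names
  fixed <- model$params[model$params$fixed, ]
  if (nrow(fixed) > 0) {
    th_fixed <- setNames(fixed$init, fixed$name)
    theta <- c(theta, th_fixed)
  }
  nom <- length(pk$omega_names)
  omega2 <- exp(par[nth + seq_len(nom)])
  names(omega2) <- pk$omega_names
  rest <- if (nth + nom > 0) par[-(seq_len(nth + nom))] else par
  sigma <- switch(pk$err,
                  additive = list(add = exp(rest[1]), prop = 0),
                  proportional = list(add = 0, prop = exp(rest[1])),
                  combined = list(add = exp(rest[1]), prop = exp(rest[2])))
  list(theta = theta, omega2 = omega2, sigma = sigma)
}

#' Fit a population model by maximum likelihood (Laplace)
#'
#' Minimises the Laplace [ofv()] over fixed effects, log-variances and
#' log-sigmas with a quasi-Newton outer optimiser and nested per-subject
#' posterior-mode finding. Deterministic given data and initial estimates.
#'
#' @param data A [study_dataset()] or prepared subject list.
#' @param model A [pop_model()].
#' @param control List: `se` (compute standard errors, default TRUE),
#'   `diagnostics` (compute PRED/IPRED/CWRES, default TRUE), `iter.max`,
#'   `eval.max`, `rel.tol` passed to [stats::nlminb()], `warm_eta` optional
#'   starting matrix of random-effect modes.
#'
#' @return A `pop_model_fit`: tibbles of fixed effects (`theta`) with RSE%,
#'   variance components (`omega`), residual error (`sigma`), `ofv`, `aic`,
#'   per-subject empirical Bayes estimates (`eta`), per-observation
#'   `diagnostics` (ID, TIME, DV, PRED, IPRED, CWRES) and a convergence
#'   report.
#' @export
fit_population <- function(data, model, control = list()) {
  subjects <- prepare_subjects(data, model)
  if (length(subjects) == 0) abort("no subjects to fit")
  ctl <- modifyList(list(se = TRUE, diagnostics = TRUE, iter.max = 400,
                         eval.max = 1000, rel.tol = 1e-6, warm_eta = NULL),
                    control)
  pk <- .pack(model)
  q <- length(pk$omega_names)
  n <- length(subjects)
  ew <- new.env(parent = emptyenv())
  ew$eta <- ctl$warm_eta %||% matrix(0, n, max(q, 1))
  payload <- .subject_payload(subjects)
  objective <- function(par) {
    if (any(!is.finite(par))) return(1e10)
    up <- .unpack(par, pk, model)
    res <- .engine_call(model, subjects, up$theta, up$omega2, up$sigma,
                        ew$eta, payload)
    if (q > 0) ew$eta <- res$eta
    if (!is.finite(res$ofv)) return(1e10)
    res$ofv
  }
  # box the packed parameters: wide enough for any plausible estimate,
  # tight enough that exploratory steps cannot reach degenerate regions
  nth <- length(pk$theta_names)
  nom <- length(pk$omega_names)
  nsg <- length(pk$start) - nth - nom
  lower <- c(pk$start[seq_len(nth)] - 6, rep(-12, nom), rep(-10, nsg))
  upper <- c(pk$start[seq_len(nth)] + 6, rep(3, nom), rep(2, nsg))
  opt <- nlminb(pk$start, objective, lower = lower, upper = upper,
                control = list(iter.max = ctl$iter.max,
                               eval.max = ctl$eval.max,
                               rel.tol = ctl$rel.tol))
  # a stalled start ("false convergence" after very few iterations) is
  # retried from the best point found, where the warm random-effect modes
  # now give a cleaner surface
  for (retry in 1:2) {
    if (opt$convergence == 0 || opt$iterations > 5) break
    opt2 <- nlminb(opt$par, objective, lower = lower, upper = upper,
                   control = list(iter.max = ctl$iter.max,
                                  eval.max = ctl$eval.max,
                                  rel.tol = ctl$rel.tol))
    if (opt2$objective <= opt$objective) opt <- opt2 else break
  }
  up <- .unpack(opt$par, pk, model)
  final <- .engine_call(model, subjects, up$theta, up$omega2, up$sigma,
                        ew$eta, payload)
  eta_hat <- final$eta
  p_est <- length(opt$par)
  # standard errors from the curvature of the objective
  se_packed <- rep(NA_real_, p_est)
  se_ok <- FALSE
  if (isTRUE(ctl$se)) {
    H <- tryCatch(pracma::hessian(objective, opt$par), error = function(e) NULL)
    if (!is.null(H)) {
      cov_try <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(cov_try) && all(is.finite(diag(cov_try))) &&
          all(diag(cov_try) > 0)) {
        se_packed <- sqrt(diag(cov_try))
        se_ok <- TRUE
      }
    }
  }
  theta_tbl <- .theta_table(model, pk, opt$par, se_packed)
  omega_tbl <- tibble::tibble(
    parameter = pk$omega_names,
    omega2 = unname(up$omega2),
    cv_percent = 100 * sqrt(exp(unname(up$omega2)) - 1),
    boundary = log(unname(up$omega2)) < -10)
  sigma_tbl <- tibble::tibble(
    component = c("additive", "proportional"),
    value = c(up$sigma$add, up$sigma$prop))
  converged <- opt$convergence == 0 ||
    grepl("relative convergence|X-convergence|singular convergence",
          opt$message %||% "")
  fit <- structure(list(
    model = model, subjects = subjects,
    theta = theta_tbl, omega = omega_tbl, sigma = sigma_tbl,
    theta_hat = up$theta, omega2_hat = up$omega2, sigma_hat = up$sigma,
    ofv = final$ofv, aic = final$ofv + 2 * p_est, n_params = p_est,
    eta_hat = eta_hat,
    convergence = list(converged = converged,
                       message = opt$message,
                       iterations = opt$iterations,
                       se_available = se_ok),
    packed = list(par = opt$par, pk = pk)),
    class = "pop_model_fit")
  if (isTRUE(ctl$diagnostics)) {
    fit$diagnostics <- .fit_diagnostics(fit)
  }
  fit
}

.theta_table <- function(model, pk, par, se_packed) {
  nth <- length(pk$theta_names)
  rows <- lapply(seq_len(nth), function(i) {
    est <- .from_unconstrained(par[i], pk$theta_transform[i])
    se_u <- se_packed[i]
    rse <- if (is.na(se_u)) NA_real_ else {
      se_nat <- switch(pk$theta_transform[i],
                       log = est * se_u,
                       identity = se_u,
                       logit100 = se_u * est * (1 - est / 100))
      100 * se_nat / abs(est)
    }
    tibble::tibble(parameter = pk$theta_names[i], estimate = unname(est),
                   rse_percent = unname(rse), fixed = FALSE)
  })
  fixed <- model$params[model$params$fixed, ]
  if (nrow(fixed) > 0) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      parameter = fixed$name, estimate = fixed$init,
      rse_percent = NA_real_, fixed = TRUE)
  }
  dplyr::bind_rows(rows)
}

# per-observation structural prediction for one subject
predict_subject <- function(model, params_ind, subj, times = subj$t,
                            x = subj$x) {
  id <- structural_model_id(model$structural)
  if (id == 1L) {
    pred_pk_cpp(as.numeric(params_ind[c("cl", "v1", "q", "v2", "ka")]),
                times, subj$dose_t, subj$dose_amt, 1L)
  } else if (id == 2L) {
    pred_pk_cpp(as.numeric(params_ind[c("cl", "v", "ka")]),
                times, subj$dose_t, subj$dose_amt, 2L)
  } else if (id == 3L) {
    predict_emax(list(emax = params_ind[["emax"]], ec50 = params_ind[["ec50"]],
                      gamma = params_ind[["gamma"]]), x)
  } else if (id == 4L) {
    params_ind[["intercept"]] + params_ind[["slope"]] * x
  } else {
    model$structural(params_ind, subj)
  }
}

.individual_params <- function(fit, i, eta = fit$eta_hat[i, ]) {
  base <- .base_param_matrix(fit$model, fit$subjects, fit$theta_hat)
  par <- base[i, ]
  if (length(fit$omega2_hat) > 0) {
    pos <- match(names(fit$omega2_hat), colnames(base))
    par <- .apply_eta(par, pos, eta[seq_along(pos)],
                      fit$model$eta_transform %||% "lognormal")
  }
  par
}

.fit_diagnostics <- function(fit) {
  model <- fit$model
  subjects <- fit$subjects
  omega2 <- fit$omega2_hat
  q <- length(omega2)
  sg <- .sigma_pair(model, fit$sigma_hat)
  base <- .base_param_matrix(model, subjects, fit$theta_hat)
  pos <- if (q > 0) match(names(omega2), colnames(base)) else integer()
  rows <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    ni <- length(s$y)
    if (ni == 0) return(NULL)
    par0 <- base[i, ]
    pred <- predict_subject(model, par0, s)
    eta_i <- if (q > 0) fit$eta_hat[i, seq_len(q)] else numeric(0)
    tfm <- model$eta_transform %||% "lognormal"
    par_i <- .apply_eta(par0, pos, eta_i, tfm)
    ipred <- predict_subject(model, par_i, s)
    if (q > 0) {
      # FOCE linearisation about the posterior mode
      J <- matrix(0, ni, q)
      h <- 1e-4
      for (k in seq_len(q)) {
        ep <- eta_i; ep[k] <- ep[k] + h
        em <- eta_i; em[k] <- em[k] - h
        pp <- .apply_eta(par0, pos, ep, tfm)
        pm <- .apply_eta(par0, pos, em, tfm)
        J[, k] <- (predict_subject(model, pp, s) -
                   predict_subject(model, pm, s)) / (2 * h)
      }
      mean_lin <- ipred - drop(J %*% eta_i)
      v <- sg[1]^2 + sg[2]^2 * ipred^2
      cov <- J %*% (diag(omega2, q) %*% t(J)) + diag(v, ni)
      ee <- eigen(cov, symmetric = TRUE)
      if (any(ee$values <= 0)) {
        abort(paste0("non-invertible residual covariance for subject ",
                     s$id))
      }
      inv_sqrt <- ee$vectors %*% diag(1 / sqrt(ee$values), ni) %*%
        t(ee$vectors)
      cw <- drop(inv_sqrt %*% (s$y - mean_lin))
    } else {
      v <- sg[1]^2 + sg[2]^2 * pred^2
      cw <- (s$y - pred) / sqrt(v)
    }
    tibble::tibble(ID = s$id, ARM = s$arm %||% NA_character_, TIME = s$t,
                   DV = s$y, PRED = pred, IPRED = ipred, CWRES = cw)
  })
  dplyr::bind_rows(rows)
}

#' Empirical Bayes estimates of the random effects
#'
#' Posterior modes of each subject's random effects at the final population
#' estimates. A subject with no observations sits at the prior mode (0).
#'
#' @param fit A `pop_model_fit`.
#' @return Tibble: `ID`, one column per random effect (`eta_<param>`).
#' @export
empirical_bayes <- function(fit) {
  q <- length(fit$omega2_hat)
  ids <- vapply(fit$subjects, function(s) s$id, numeric(1))
  if (q == 0) return(tibble::tibble(ID = ids))
  eta <- fit$eta_hat[, seq_len(q), drop = FALSE]
  colnames(eta) <- paste0("eta_", names(fit$omega2_hat))
  dplyr::bind_cols(tibble::tibble(ID = ids), tibble::as_tibble(eta))
}

#' Conditional weighted residuals
#'
#' First-order-conditional linearisation about each subject's posterior
#' mode: the residual vector is decorrelated by the inverse square root of
#' the linearised covariance `J Omega J' + V`. With all variances on the
#' boundary this reduces to `(DV - PRED) / sigma`.
#'
#' @param fit A `pop_model_fit`.
#' @return The per-observation diagnostics tibble (ID, TIME, DV, PRED,
#'   IPRED, CWRES).
#' @export
cwres <- function(fit) {
  fit$diagnostics %||% .fit_diagnostics(fit)
}

#' @export
print.pop_model_fit <- function(x, ...) {
  cat("Population model fit (Laplace)\n")
  cat(sprintf("  subjects: %d   observations: %d\n", length(x$subjects),
              sum(vapply(x$subjects, function(s) length(s$y), numeric(1)))))
  cat(sprintf("  OFV: %.3f   AIC: %.3f   converged: %s\n", x$ofv, x$aic,
              x$convergence$converged))
  cat("Fixed effects:\n")
  print(x$theta)
  if (nrow(x$omega) > 0) {
    cat("Between-subject variability:\n")
    print(x$omega)
  }
  cat("Residual error:\n")
  print(x$sigma)
  invisible(x)
}

#' @export
tidy.pop_model_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$theta, type = "theta", .before = 1) %>%
      rename(term = "parameter"),
    tibble::tibble(type = "omega2", term = paste0("omega2_", x$omega$parameter),
                   estimate = x$omega$omega2, rse_percent = NA_real_,
                   fixed = FALSE),
    tibble::tibble(type = "sigma",
                   term = paste0("sigma_", x$sigma$component),
                   estimate = x$sigma$value, rse_percent = NA_real_,
                   fixed = FALSE) %>%
      dplyr::filter(.data$estimate > 0))
}

#' @export
glance.pop_model_fit <- function(x, ...) {
  tibble::tibble(
    ofv = x$ofv, aic = x$aic, n_params = x$n_params,
    n_subjects = length(x$subjects),
    n_obs = sum(vapply(x$subjects, function(s) length(s$y), numeric(1))),
    converged = x$convergence$converged)
}

#' @export
augment.pop_model_fit <- function(x, ...) cwres(x)
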