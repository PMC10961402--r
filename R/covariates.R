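#' Stepwise covariate search (forward inclusion / backward elimination)
#'
#' Forward step: every candidate `(parameter, covariate)` pair is added to
#' the current model as a power effect normalised to the cohort median and
#' refitted; the candidate with the largest drop in the objective function
#' joins the model if the drop reaches `forward_dofv` (3.84, p ~ 0.05 at
#' 1 df). Repeats until no candidate qualifies. Backward step: each
#' included effect is removed in turn; an effect whose deletion raises the
#' objective by less than `backward_dofv` (6.63, p ~ 0.01) is dropped.
#' Candidate fits that fail to converge are skipped and logged, never
#' accepted.
#'
#' @param data A [study_dataset()] or prepared subject list.
#' @param base_model A [pop_model()] without the candidate effects.
#' @param candidates List of `list(parameter =, covariate =)` pairs.
#' @param forward_dofv,backward_dofv Inclusion/retention thresholds on the
#'   -2 log-likelihood scale.
#' @param control Fit control passed to [fit_population()]; standard errors
#'   and diagnostics are disabled during the search.
#' @return List of class `covariate_search`: `final` (fitted final model),
#'   `selected` (list of retained effects), `log` (tibble of every tested
#'   step with its delta-OFV).
#' @export
stepwise_covariate_search <- function(data, base_model, candidates,
                                      forward_dofv = 3.84,
                                      backward_dofv = 6.63,
                                      control = list()) {
  subjects <- prepare_subjects(data, base_model)
  ctl <- modifyList(list(se = FALSE, diagnostics = FALSE), control)
  log_rows <- list()
  log_step <- function(phase, par, cov, dofv, action) {
    log_rows[[length(log_rows) + 1]] <<- tibble::tibble(
      phase = phase, parameter = par, covariate = cov, dofv = dofv,
      action = action)
  }
  ref_of <- function(cov) {
    vals <- vapply(subjects, function(s) as.numeric(s$covariates[[cov]]),
                   numeric(1))
    stats::median(vals)
  }
  with_effects <- function(effects, warm = NULL) {
    m <- base_model
    m$covariate_effects <- effects
    extra <- vapply(effects, function(ef) {
      paste0(ef$parameter, "_", ef$covariate)
    }, character(1))
    if (length(extra) > 0) {
      inits <- vapply(effects, function(ef) ef$init %||% 0.1, numeric(1))
      m$params <- dplyr::bind_rows(
        m$params,
        tibble::tibble(name = extra, init = inits,
                       transform = "identity", fixed = FALSE))
    }
    if (!is.null(warm)) {
      est <- setNames(warm$theta$estimate, warm$theta$parameter)
      shared <- intersect(m$params$name, names(est))
      m$params$init[match(shared, m$params$name)] <- est[shared]
      om <- setNames(warm$omega$omega2, warm$omega$parameter)
      m$iiv[names(m$iiv)] <- pmax(om[names(m$iiv)], 1e-6)
      m$error$add <- warm$sigma_hat$add
      m$error$prop <- warm$sigma_hat$prop
    }
    fit_population(subjects, m, ctl)
  }
  base_fit <- with_effects(list())
  current <- list()
  current_fit <- base_fit

  # forward inclusion
  remaining <- candidates
  repeat {
    if (length(remaining) == 0) break
    best <- NULL
    for (j in seq_along(remaining)) {
      cand <- remaining[[j]]
      cand$reference <- ref_of(cand$covariate)
      trial_fit <- tryCatch(
        with_effects(c(current, list(cand)), warm = current_fit),
        error = function(e) NULL)
      if (is.null(trial_fit) || !is.finite(trial_fit$ofv)) {
        log_step("forward", cand$parameter, cand$covariate, NA_real_,
                 "skipped (fit failed)")
        next
      }
      dofv <- current_fit$ofv - trial_fit$ofv
      log_step("forward", cand$parameter, cand$covariate, dofv, "tested")
      if (dofv >= forward_dofv &&
          (is.null(best) || dofv > best$dofv)) {
        best <- list(j = j, cand = cand, fit = trial_fit, dofv = dofv)
      }
    }
    if (is.null(best)) break
    log_step("forward", best$cand$parameter, best$cand$covariate,
             best$dofv, "included")
    current <- c(current, list(best$cand))
    current_fit <- best$fit
    remaining <- remaining[-best$j]
  }

  # backward elimination
  repeat {
    if (length(current) == 0) break
    dropped <- FALSE
    for (j in seq_along(current)) {
      reduced_fit <- if (length(current) == 1) base_fit else tryCatch(
        with_effects(current[-j], warm = current_fit),
        error = function(e) NULL)
      if (is.null(reduced_fit)) next
      dofv <- reduced_fit$ofv - current_fit$ofv
      ef <- current[[j]]
      log_step("backward", ef$parameter, ef$covariate, dofv, "tested")
      if (dofv < backward_dofv) {
        log_step("backward", ef$parameter, ef$covariate, dofv, "removed")
        current <- current[-j]
        current_fit <- reduced_fit
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }

  structure(list(final = current_fit, selected = current,
                 base_ofv = base_fit$ofv,
                 log = if (length(log_rows) > 0) dplyr::bind_rows(log_rows)
                       else tibble::tibble(phase = character(),
                                           parameter = character(),
                                           covariate = character(),
                                           dofv = numeric(),
                                           action = character())),
            class = "covariate_search")
}

#' @export
print.covariate_search <- function(x, ...) {
  cat("Stepwise covariate search\n")
  if (length(x$selected) == 0) {
    cat("  no covariate retained\n")
  } else {
    for (ef in x$selected) {
      cat(sprintf("  retained: %s on %s\n", ef$covariate, ef$parameter))
    }
  }
  cat(sprintf("  base OFV %.2f -> final OFV %.2f\n", x$base_ofv,
              x$final$ofv))
  invisible(x)
}
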