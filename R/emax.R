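#' Predict inhibition from the Emax model
#'
#' `E(c) = Emax * c^gamma / (EC50^gamma + c^gamma)`: 0 at `c = 0`,
#' approaching `Emax` as `c` grows; `c = EC50` gives exactly `Emax / 2` for
#' any `gamma`.
#'
#' @param p List/vector with `emax` (%), `ec50` (ng/mL) and optionally
#'   `gamma` (default 1).
#' @param conc Concentrations (>= 0).
#' @return Predicted inhibition (%).
#' @export
#' @examples
#' predict_emax(list(emax = 92.47, ec50 = 5.37), 5.37)  # 46.235
predict_emax <- function(p, conc) {
  if (any(conc < 0, na.rm = TRUE)) abort("concentrations must be >= 0")
  sigmoid_emax(conc, p[["emax"]], p[["ec50"]], p[["gamma"]] %||% 1)
}

#' Fit the pooled concentration-inhibition Emax model
#'
#' Ordinary (unweighted) least squares on pooled pairs of plasma
#' concentration and DPP-4 inhibition, one curve per drug: the
#' concentration-effect analysis behind a classic inhibition-vs-exposure
#' plot. The Hill coefficient is fixed at 1 by default (the pooled analysis
#' reports only Emax and EC50); set `gamma_fixed = NA` to estimate it.
#' Initialisation is by multistart: `Emax` from \{max observed, 100\} and
#' `EC50` over a log-grid spanning the observed concentration range; the
#' best converged objective wins.
#'
#' @param conc,inhibition Paired observations (ng/mL, %).
#' @param gamma_fixed Fixed Hill coefficient (default 1), or `NA` to
#'   estimate.
#' @return An object of class `emax_fit`: `params` (list `emax`, `ec50`,
#'   `gamma`), `se` (asymptotic), `sigma` (residual SD), `rss`, `n`,
#'   `fitted`, `data`.
#' @export
fit_emax <- function(conc, inhibition, gamma_fixed = 1) {
  keep <- !is.na(conc) & !is.na(inhibition)
  conc <- conc[keep]
  inhibition <- inhibition[keep]
  if (length(unique(conc)) < 3) {
    abort("Emax model is not identifiable: need >= 3 distinct concentrations")
  }
  pos <- conc[conc > 0]
  if (length(pos) < 2) abort("need positive concentrations to place EC50")
  estimate_gamma <- is.na(gamma_fixed)
  grid_ec50 <- exp(seq(log(max(min(pos), 1e-6)), log(max(pos)),
                       length.out = 8))
  starts <- expand.grid(emax = c(max(inhibition), 100), ec50 = grid_ec50)
  best <- NULL
  df <- data.frame(conc = conc, inh = inhibition)
  for (s in seq_len(nrow(starts))) {
    st <- list(emax = starts$emax[s], ec50 = starts$ec50[s])
    if (estimate_gamma) st$gamma <- 1
    form <- if (estimate_gamma) {
      inh ~ emax * conc^gamma / (ec50^gamma + conc^gamma)
    } else {
      substitute(inh ~ emax * conc^g / (ec50^g + conc^g),
                 list(g = gamma_fixed))
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(stats::as.formula(form), data = df, start = st,
                        lower = rep(1e-8, length(st)),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) abort("Emax fit failed from every start")
  cf <- coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, length(cf)),
                                              names(cf)))
  n <- length(conc)
  p <- length(cf)
  structure(list(
    params = list(emax = unname(cf[["emax"]]), ec50 = unname(cf[["ec50"]]),
                  gamma = if (estimate_gamma) unname(cf[["gamma"]])
                          else gamma_fixed),
    se = as.list(se),
    sigma = sqrt(best$rss / max(n - p, 1)),
    rss = best$rss, n = n,
    fitted = stats::fitted(best$fit),
    data = tibble::tibble(conc = conc, inhibition = inhibition)),
    class = "emax_fit")
}

#' @export
print.emax_fit <- function(x, ...) {
  cat(sprintf(
    "Emax model fit (n = %d): Emax %.2f%%, EC50 %.3f ng/mL, gamma %.3g, residual SD %.2f\n",
    x$n, x$params$emax, x$params$ec50, x$params$gamma, x$sigma))
  invisible(x)
}

#' @export
tidy.emax_fit <- function(x, ...) {
  terms <- c("emax", "ec50", "gamma")
  tibble::tibble(
    term = terms,
    estimate = unlist(x$params[terms]),
    std.error = vapply(terms, function(t) x$se[[t]] %||% NA_real_,
                       numeric(1)))
}

#' @export
glance.emax_fit <- function(x, ...) {
  tibble::tibble(sigma = x$sigma, rss = x$rss, nobs = x$n)
}

#' Extract pooled concentration-inhibition pairs from a dataset
#'
#' Matches DPP-4 inhibition (computed against each subject's pre-dose
#' activity) with the drug concentration observed at the same nominal time.
#'
#' @param ds A [study_dataset()].
#' @param arms Arms to pool (default the active-drug arms).
#' @param occasions Occasions pooled (default day 1 and day 14).
#' @return Tibble `ID`, `ARM`, `TIME`, `conc`, `inhibition`.
#' @export
emax_pairs <- function(ds, arms = c("cetagliptin50", "cetagliptin100"),
                       occasions = c("day1", "day14")) {
  tab <- tibble::as_tibble(ds) %>%
    dplyr::filter(.data$EVID == 0L, .data$ARM %in% arms)
  act <- tab %>% dplyr::filter(.data$DVID == "dpp4_activity")
  conc <- tab %>% dplyr::filter(.data$DVID == "drug_concentration",
                                .data$BLQ == 0L)
  base <- act %>%
    dplyr::group_by(.data$ID) %>%
    dplyr::summarise(base = .data$DV[which.min(.data$TIME)],
                     .groups = "drop")
  act %>%
    dplyr::filter(.data$OCC %in% occasions) %>%
    dplyr::left_join(base, by = "ID") %>%
    dplyr::mutate(inhibition = (1 - .data$DV / .data$base) * 100) %>%
    dplyr::inner_join(
      conc %>% dplyr::select("ID", "TIME", conc = "DV"),
      by = c("ID", "TIME")) %>%
    dplyr::select("ID", "ARM", "TIME", "conc", "inhibition")
}
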