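# small in-code fixtures shared across test files

# a minimal valid three-subject event table
make_small_dataset <- function() {
  mk_sub <- function(id, arm, dose) {
    doses <- if (dose > 0) {
      tibble::tibble(TIME = c(0, 24), EVID = 1L, AMT = dose,
                     DV = NA_real_, DVID = NA_character_, MDV = 1L,
                     BLQ = 0L, OCC = c("day1", "day2"))
    } else NULL
    obs <- tibble::tibble(
      TIME = c(0, 1, 2, 24), EVID = 0L, AMT = NA_real_,
      DV = c(0.5, 40, 35, 12) * max(dose, 1) / 50,
      DVID = "drug_concentration", MDV = 0L,
      BLQ = c(1L, 0L, 0L, 0L), OCC = "day1")
    if (dose == 0) {
      obs$DV <- 0.5
      obs$BLQ <- 1L
    }
    out <- dplyr::bind_rows(doses, obs)
    out <- out[order(out$TIME, -out$EVID), ]
    out$ID <- id
    out$ARM <- arm
    out$TBIL <- 10 + id
    out
  }
  study_dataset(dplyr::bind_rows(
    mk_sub(1L, "cetagliptin50", 50),
    mk_sub(2L, "cetagliptin100", 100),
    mk_sub(3L, "placebo", 0)))
}

# deterministic mono-exponential profile
mono_profile <- function(c0 = 100, ke = 0.1,
                         times = c(24, 48, 72, 96, 120)) {
  list(times = times, concs = c0 * exp(-ke * times))
}

# quick small trial for pipeline-level tests: two active arms only,
# thinned sampling
small_trial_cfg <- function(seed = 42,
                            n = c(cetagliptin50 = 4, cetagliptin100 = 4,
                                  sitagliptin100 = 0, placebo = 0)) {
  sim_config(seed = seed, n_per_arm = n)
}

# one shared (dataset, PK fit) fixture for the sequential PK/PD tests;
# built lazily and cached for the session
.fixture_cache <- new.env(parent = emptyenv())
cached_pk_fixture <- function() {
  if (is.null(.fixture_cache$pk)) {
    sim <- simulate_trial(sim_config(
      seed = 555, n_per_arm = c(cetagliptin50 = 6, cetagliptin100 = 6,
                                sitagliptin100 = 0, placebo = 0)))
    fit <- fit_population(sim$dataset, pk_twocomp_model(),
                          control = list(se = FALSE))
    .fixture_cache$pk <- list(sim = sim, fit = fit)
  }
  .fixture_cache$pk
}

# linear random-intercept data: y_ij = mu + eta_i + eps_ij
make_linear_subjects <- function(n = 10, ni = 4, mu = 5, om2 = 0.8,
                                 s2 = 0.25, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    eta <- rnorm(1, 0, sqrt(om2))
    list(id = i, arm = "all", y = mu + eta + rnorm(ni, 0, sqrt(s2)),
         t = seq_len(ni), dose_t = numeric(0), dose_amt = numeric(0),
         x = rep(0, ni), covariates = list())
  })
}

linear_model_spec <- function(mu = 5, om2 = 0.8, s2 = 0.25) {
  pop_model(
    structural = function(par, subj) rep(par[["mu"]], length(subj$y)),
    params = tibble::tibble(name = "mu", init = mu,
                            transform = "identity"),
    iiv = c(mu = om2), error = list(model = "additive", add = sqrt(s2)),
    arms = "all", eta_transform = "additive")
}

# exact marginal -2 log-likelihood under compound symmetry
linear_closed_form_m2ll <- function(subjects, mu, om2, s2) {
  tot <- 0
  for (s in subjects) {
    ni <- length(s$y)
    Sig <- diag(s2, ni) + matrix(om2, ni, ni)
    r <- s$y - mu
    tot <- tot + ni * log(2 * pi) +
      as.numeric(determinant(Sig)$modulus) + drop(t(r) %*% solve(Sig, r))
  }
  tot
}
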