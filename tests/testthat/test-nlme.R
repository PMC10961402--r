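test_that("Laplace OFV equals the closed-form Gaussian marginal -2LL", {
  subj <- make_linear_subjects(seed = 1)
  m <- linear_model_spec()
  for (mu in c(4.2, 5, 6.1)) {
    lap <- ofv(subj, m, theta = c(mu = mu))
    expect_equal(lap$ofv, linear_closed_form_m2ll(subj, mu, 0.8, 0.25),
                 tolerance = 1e-8)
  }
})

test_that("omega = 0 reduces to the fixed-effects -2LL", {
  subj <- make_linear_subjects(seed = 2)
  m <- pop_model(
    structural = function(par, s) rep(par[["mu"]], length(s$y)),
    params = tibble::tibble(name = "mu", init = 5, transform = "identity"),
    iiv = numeric(), error = list(model = "additive", add = 0.5),
    arms = "all")
  got <- ofv(subj, m, theta = c(mu = 5))$ofv
  direct <- sum(vapply(subj, function(s) {
    sum((s$y - 5)^2 / 0.25 + log(2 * pi * 0.25))
  }, numeric(1)))
  expect_equal(got, direct, tolerance = 1e-10)
})

test_that("OFV is additive over duplicated subjects and order-invariant", {
  subj <- make_linear_subjects(seed = 3)
  m <- linear_model_spec()
  one <- ofv(subj, m, theta = c(mu = 5))$ofv
  two <- ofv(c(subj, subj), m, theta = c(mu = 5))$ofv
  expect_equal(two, 2 * one, tolerance = 1e-8)
  shuffled <- ofv(rev(subj), m, theta = c(mu = 5))$ofv
  expect_equal(shuffled, one, tolerance = 1e-10)
})

test_that("rescaling DV with matching sigma shifts OFV by the Jacobian only", {
  subj <- make_linear_subjects(seed = 4)
  k <- 3.7
  scaled <- lapply(subj, function(s) { s$y <- k * s$y; s })
  m1 <- linear_model_spec()
  m2 <- pop_model(
    structural = function(par, s) rep(par[["mu"]], length(s$y)),
    params = tibble::tibble(name = "mu", init = 5 * k,
                            transform = "identity"),
    iiv = c(mu = 0.8 * k^2),
    error = list(model = "additive", add = sqrt(0.25) * k),
    arms = "all", eta_transform = "additive")
  n_obs <- sum(vapply(subj, function(s) length(s$y), numeric(1)))
  expect_equal(ofv(scaled, m2, theta = c(mu = 5 * k))$ofv,
               ofv(subj, m1, theta = c(mu = 5))$ofv + 2 * n_obs * log(k),
               tolerance = 1e-8)
})

test_that("fitting recovers the linear model and reports AIC = OFV + 2p", {
  subj <- make_linear_subjects(n = 40, ni = 6, seed = 5)
  fit <- fit_population(subj, linear_model_spec(mu = 3, om2 = 0.3,
                                                s2 = 0.5),
                        control = list(diagnostics = FALSE))
  expect_true(fit$convergence$converged)
  expect_equal(fit$theta$estimate[1], 5, tolerance = 0.35)
  expect_equal(fit$aic, fit$ofv + 2 * 3)
  # refit from the optimum moves the OFV by less than 0.01
  m2 <- update_inits(linear_model_spec(), fit)
  fit2 <- fit_population(subj, m2, control = list(diagnostics = FALSE,
                                                  se = FALSE))
  expect_lt(abs(fit2$ofv - fit$ofv), 0.01)
})

test_that("zero-noise zero-IIV data drive omega to the boundary", {
  subj <- lapply(1:8, function(i) {
    list(id = i, arm = "all", y = rep(5, 4), t = 1:4,
         dose_t = numeric(0), dose_amt = numeric(0), x = rep(0, 4),
         covariates = list())
  })
  fit <- fit_population(subj, linear_model_spec(mu = 4, om2 = 0.2,
                                                s2 = 0.3),
                        control = list(se = FALSE, diagnostics = FALSE))
  expect_equal(fit$theta$estimate[1], 5, tolerance = 1e-4)
  expect_true(fit$omega$boundary[1] || fit$omega$omega2[1] < 1e-4)
})

test_that("empirical Bayes estimates shrink correctly", {
  subj <- make_linear_subjects(n = 6, ni = 8, seed = 6)
  # subject with no observations sits at the prior mode
  subj[[7]] <- list(id = 7, arm = "all", y = numeric(0), t = numeric(0),
                    dose_t = numeric(0), dose_amt = numeric(0),
                    x = numeric(0), covariates = list())
  fit <- fit_population(subj, linear_model_spec(),
                        control = list(se = FALSE, diagnostics = FALSE))
  eb <- empirical_bayes(fit)
  expect_equal(eb$eta_mu[eb$ID == 7], 0)
  # tiny omega shrinks every eta to zero
  m_small <- linear_model_spec(om2 = 1e-8)
  o <- ofv(subj, m_small, theta = c(mu = 5), omega2 = c(mu = 1e-8))
  expect_true(all(abs(o$eta) < 1e-3))
})

test_that("empirical Bayes estimates track the true eta on rich data", {
  set.seed(8)
  true_eta <- rnorm(12, 0, 0.3)
  p <- list(cl = 20, v = 100, ka = 1.2)
  tt <- c(0.5, 1, 2, 4, 8, 12, 16, 24)
  subj <- lapply(1:12, function(i) {
    cc <- onecomp_oral_conc(list(cl = 20 * exp(true_eta[i]), v = 100,
                                 ka = 1.2), 0, 100, tt)
    list(id = i, arm = "all", y = cc * (1 + rnorm(8, 0, 0.01)), t = tt,
         dose_t = 0, dose_amt = 100, x = numeric(0), covariates = list())
  })
  m <- pop_model("onecomp_oral",
                 tibble::tibble(name = c("cl", "v", "ka"),
                                init = c(20, 100, 1.2),
                                fixed = c(FALSE, TRUE, TRUE)),
                 iiv = c(cl = 0.09),
                 error = list(model = "proportional", prop = 0.01),
                 arms = "all")
  fit <- fit_population(subj, m, control = list(se = FALSE,
                                                diagnostics = FALSE))
  eb <- empirical_bayes(fit)
  # individual clearances are recovered within 5% (the eta scale itself is
  # only defined relative to the fitted population value)
  cl_hat <- fit$theta$estimate[fit$theta$parameter == "cl"] * exp(eb$eta_cl)
  expect_lt(max(abs(cl_hat - 20 * exp(true_eta)) / (20 * exp(true_eta))),
            0.05)
})

test_that("CWRES reduces to scaled residuals without random effects", {
  subj <- make_linear_subjects(seed = 9)
  m <- pop_model(
    structural = function(par, s) rep(par[["mu"]], length(s$y)),
    params = tibble::tibble(name = "mu", init = 5, transform = "identity",
                            fixed = TRUE),
    iiv = numeric(), error = list(model = "additive", add = 0.5),
    arms = "all")
  fit <- fit_population(subj, m, control = list(se = FALSE))
  d <- cwres(fit)
  expect_equal(d$CWRES, (d$DV - d$PRED) / fit$sigma_hat$add,
               tolerance = 1e-9)
})

test_that("CWRES is standardised under the true model and flags outliers", {
  subj <- make_linear_subjects(n = 100, ni = 5, seed = 10)
  fit <- fit_population(subj, linear_model_spec(),
                        control = list(se = FALSE))
  d <- cwres(fit)
  expect_lt(abs(mean(d$CWRES)), 0.1)
  expect_lt(abs(var(d$CWRES) - 1), 0.2)
  # perturb one observation by 10 residual SDs
  subj2 <- subj
  subj2[[3]]$y[2] <- subj2[[3]]$y[2] + 10 * sqrt(0.25)
  fit2 <- fit_population(subj2, linear_model_spec(),
                         control = list(se = FALSE))
  d2 <- cwres(fit2)
  hit <- d2[d2$ID == 3, ][2, ]
  expect_gt(abs(hit$CWRES), 5)
})

test_that("standard errors are reported as RSE percentages", {
  subj <- make_linear_subjects(n = 30, ni = 5, seed = 11)
  fit <- fit_population(subj, linear_model_spec(mu = 4),
                        control = list(diagnostics = FALSE))
  expect_true(fit$convergence$se_available)
  expect_true(is.finite(fit$theta$rse_percent[1]))
  td <- tidy(fit)
  expect_true(all(c("mu", "omega2_mu", "sigma_additive") %in% td$term))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 150)
})
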