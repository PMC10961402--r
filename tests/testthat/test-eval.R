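# a cheap one-compartment population model for resampling machinery tests
make_onecomp_pop <- function(n = 20, seed = 1, om2 = 0.06, prop = 0.10,
                             cl = 10) {
  set.seed(seed)
  tt <- c(0.5, 1, 2, 6, 12, 24)
  subj <- lapply(seq_len(n), function(i) {
    cli <- cl * exp(rnorm(1, 0, sqrt(om2)))
    cc <- onecomp_oral_conc(list(cl = cli, v = 80, ka = 1.5), 0, 100, tt)
    list(id = i, arm = "all", y = cc * (1 + rnorm(6, 0, prop)), t = tt,
         dose_t = 0, dose_amt = 100, x = numeric(0), covariates = list())
  })
  model <- pop_model("onecomp_oral",
                     tibble::tibble(name = c("cl", "v", "ka"),
                                    init = c(cl, 80, 1.5),
                                    fixed = c(FALSE, TRUE, TRUE)),
                     iiv = c(cl = om2),
                     error = list(model = "proportional", prop = prop),
                     arms = "all")
  list(subjects = subj, model = model)
}

test_that("a degenerate bootstrap of one repeated subject has zero width", {
  pop <- make_onecomp_pop(n = 1, seed = 2)
  subjects <- rep(pop$subjects, 16)
  for (j in seq_along(subjects)) subjects[[j]]$id <- j
  bt <- bootstrap_model(subjects, pop$model, B = 10, seed = 3,
                        stratify_by_arm = FALSE)
  expect_equal(bt$n_converged, 10)
  expect_equal(bt$summary$lower, bt$summary$upper, tolerance = 1e-8)
})

test_that("the bootstrap is deterministic under a fixed seed", {
  pop <- make_onecomp_pop(n = 10, seed = 4)
  b1 <- bootstrap_model(pop$subjects, pop$model, B = 5, seed = 11)
  b2 <- bootstrap_model(pop$subjects, pop$model, B = 5, seed = 11)
  expect_identical(b1$summary, b2$summary)
})

test_that("bootstrap medians approach the original fit as noise shrinks", {
  pop <- make_onecomp_pop(n = 24, seed = 6, om2 = 0.02, prop = 0.02)
  fit <- fit_population(pop$subjects, pop$model,
                        control = list(se = FALSE, diagnostics = FALSE))
  bt <- bootstrap_model(pop$subjects, update_inits(pop$model, fit),
                        B = 40, seed = 7, stratify_by_arm = FALSE)
  cl_hat <- fit$theta$estimate[fit$theta$parameter == "cl"]
  cl_med <- bt$summary$median[bt$summary$term == "cl"]
  expect_lt(abs(cl_med - cl_hat) / cl_hat, 0.05)
})

test_that("a degenerate VPC collapses onto the model prediction", {
  pop <- make_onecomp_pop(n = 6, seed = 8)
  fake_fit <- structure(list(
    model = pop$model, subjects = pop$subjects,
    theta_hat = c(cl = 10, v = 80, ka = 1.5),
    omega2_hat = setNames(numeric(0), character(0)),
    sigma_hat = list(add = 0, prop = 0)), class = "pop_model_fit")
  v <- vpc(fake_fit, n_sim = 20, seed = 9)
  pred1 <- onecomp_oral_conc(list(cl = 10, v = 80, ka = 1.5), 0, 100,
                             c(0.5, 1, 2, 6, 12, 24))
  for (i in seq_along(pred1)) {
    row <- v[v$bin == c(0.5, 1, 2, 6, 12, 24)[i] & v$percentile == 50, ]
    expect_equal(row$sim_median, pred1[i], tolerance = 1e-10)
    expect_equal(row$sim_lower, row$sim_upper, tolerance = 1e-10)
  }
})

test_that("the VPC is seed-deterministic and its bands widen with omega", {
  pop <- make_onecomp_pop(n = 12, seed = 10)
  mk_fit <- function(om2) {
    structure(list(
      model = pop$model, subjects = pop$subjects,
      theta_hat = c(cl = 10, v = 80, ka = 1.5),
      omega2_hat = c(cl = om2),
      sigma_hat = list(add = 0, prop = 0.1)), class = "pop_model_fit")
  }
  v1 <- vpc(mk_fit(0.05), n_sim = 60, seed = 12)
  v1b <- vpc(mk_fit(0.05), n_sim = 60, seed = 12)
  expect_identical(v1, v1b)
  widths <- vapply(c(0.01, 0.09, 0.36), function(om2) {
    v <- vpc(mk_fit(om2), n_sim = 60, seed = 12)
    mean(v$sim_upper - v$sim_lower)
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("goodness-of-fit tables mirror the observations", {
  # zero noise, zero IIV: individual predictions reproduce the data
  tt <- c(0.5, 1, 2, 6, 12, 24)
  subj <- lapply(1:5, function(i) {
    cc <- onecomp_oral_conc(list(cl = 10, v = 80, ka = 1.5), 0, 100, tt)
    list(id = i, arm = "all", y = cc, t = tt, dose_t = 0, dose_amt = 100,
         x = numeric(0), covariates = list())
  })
  model <- pop_model("onecomp_oral",
                     tibble::tibble(name = c("cl", "v", "ka"),
                                    init = c(10, 80, 1.5),
                                    fixed = c(TRUE, TRUE, TRUE)),
                     iiv = numeric(),
                     error = list(model = "proportional", prop = 0.05),
                     arms = "all")
  fit <- fit_population(subj, model, control = list(se = FALSE))
  g <- gof_tables(fit)
  expect_equal(g$table$IPRED, g$table$DV, tolerance = 1e-9)
  expect_equal(g$summary$n_obs, 30)
  expect_equal(g$summary$n_outliers, 0)
})

test_that("well-specified fits produce no CWRES outliers at trial size", {
  fx <- cached_pk_fixture()
  g <- gof_tables(fx$fit)
  expect_equal(g$summary$n_outliers, 0)
  expect_equal(nrow(g$table),
               sum(vapply(fx$fit$subjects, function(s) length(s$y),
                          numeric(1))))
})
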