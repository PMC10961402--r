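# independent symbolic oracle: area of a piecewise-linear function as a sum
# of exact trapezoid formulas evaluated segment-by-segment with rational
# arithmetic on the segment means
piecewise_linear_area <- function(times, values, a, b) {
  total <- 0
  for (i in seq_len(length(times) - 1)) {
    lo <- max(times[i], a)
    hi <- min(times[i + 1], b)
    if (hi <= lo) next
    slope <- (values[i + 1] - values[i]) / (times[i + 1] - times[i])
    v_lo <- values[i] + slope * (lo - times[i])
    v_hi <- values[i] + slope * (hi - times[i])
    total <- total + (hi - lo) * (v_lo + v_hi) / 2
  }
  total
}

test_that("trapezoid AUC matches simple closed forms", {
  expect_equal(auc_linear(c(0, 1, 2), c(0, 2, 2)), 3)
  expect_equal(auc_linear(c(0, 24), c(7, 7)), 24 * 7)
  # interpolated bounds
  expect_equal(auc_linear(c(0, 2), c(0, 2), 0.5, 1.5), 1)
})

test_that("trapezoid AUC equals the symbolic piecewise-linear oracle", {
  set.seed(4)
  for (rep in 1:20) {
    tt <- sort(runif(10, 0, 48))
    vv <- runif(10, 0, 100)
    a <- runif(1, tt[1], tt[4])
    b <- runif(1, tt[6], tt[10])
    expect_equal(auc_linear(tt, vv, a, b),
                 piecewise_linear_area(tt, vv, a, b), tolerance = 1e-12)
  }
})

test_that("AUC is additive over adjacent intervals to 1e-12", {
  set.seed(5)
  tt <- sort(runif(12, 0, 24))
  vv <- runif(12, 0, 50)
  a <- tt[2]; b <- tt[6]; cc <- tt[11]
  expect_equal(auc_linear(tt, vv, a, b) + auc_linear(tt, vv, b, cc),
               auc_linear(tt, vv, a, cc), tolerance = 1e-12)
})

test_that("AUC errors on unsorted times and skips missing values", {
  expect_error(auc_linear(c(1, 0, 2), c(1, 1, 1)), "sorted")
  expect_warning(
    out <- auc_linear(c(0, 1, 2, 3), c(1, NA, 1, 1)),
    "skipped")
  expect_equal(out, 3)
})

test_that("lambda-z on exact mono-exponential data recovers the rate", {
  prof <- mono_profile(100, 0.1)
  fit <- lambda_z_fit(prof$times, prof$concs)
  expect_equal(fit$lambda_z, 0.1, tolerance = 1e-10)
  expect_equal(fit$t_half, log(2) / 0.1, tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-9)
})

test_that("lambda-z is not estimable from flat or sparse data", {
  expect_false(lambda_z_fit(c(1, 2, 3, 4), rep(5, 4))$estimable)
  expect_false(lambda_z_fit(c(1, 2), c(10, 5))$estimable)
})

test_that("lambda-z recovers the slow phase of a biexponential profile", {
  tt <- c(0.5, 1, 2, 3, 4, 5, 6, 8, 12, 24, 48, 72, 96, 120)
  cc <- 80 * exp(-0.25 * tt) + 40 * exp(-0.0180 * tt)
  fit <- lambda_z_fit(tt, cc)
  expect_true(fit$estimable)
  expect_lt(abs(fit$lambda_z - 0.0180) / 0.0180, 0.10)
})

test_that("single-dose NCA handles a single quantifiable point", {
  out <- nca_single_dose(times = 1, concs = 25, dose = 50)
  expect_equal(out$cmax, 25)
  expect_equal(out$tmax, 1)
  expect_true(is.na(out$auc_0_24))
  expect_true(is.na(out$auc_0_inf))
})

test_that("an all-BLQ profile yields an empty result with a reason", {
  out <- nca_single_dose(c(0, 1, 2), c(0.5, 0.5, 0.5), 50,
                         blq = c(1, 1, 1))
  expect_true(is.na(out$cmax))
  expect_match(out$reason, "BLQ")
})

test_that("AUC0-inf of a Bateman profile is close to F*D/CL", {
  cl <- 5; v <- 50; ka <- 1.2; dose <- 100
  tt <- c(0, 0.25, 0.5, 1, 2, 3, 4, 6, 8, 12, 16, seq(24, 120, by = 8))
  cc <- onecomp_oral_conc(list(cl = cl, v = v, ka = ka), 0, dose, tt)
  out <- nca_single_dose(tt, cc, dose)
  true_auc <- dose * 1000 / cl     # h*ng/mL
  expect_lt(abs(out$auc_0_inf - true_auc) / true_auc, 0.02)
  expect_lt(abs(out$cl_f - cl) / cl, 0.02)
})

test_that("steady-state parameters follow their defining ratios", {
  # Cav,ss = AUC0-tau / tau on a profile with known area
  tt <- seq(0, 24, by = 2)
  cc <- rep(130, length(tt))
  out <- nca_steady_state(tt, cc, dose = 100)
  expect_equal(out$cav_ss, 130)
  expect_equal(out$clss_f, 100 * 1000 / (130 * 24))
})

test_that("steady-state clearance and volume reproduce printed-scale arithmetic", {
  # dose 100 mg over AUC0-tau 3120 h*ng/mL -> CLss/F = 32.05 L/h,
  # and Cav,ss = 130 ng/mL
  tt <- c(0, 12, 24)
  cc <- rep(3120 / 24, 3)
  out <- nca_steady_state(tt, cc, dose = 100)
  expect_equal(out$cav_ss, 130, tolerance = 1e-12)
  expect_equal(out$clss_f, 32.05, tolerance = 1e-3)
  # CLss/F = 32.7 with lambda_z = ln2/41.9 gives Vz,ss/F ~ 1977 L
  expect_equal(32.7 / (log(2) / 41.9), 1976.7, tolerance = 1e-3)
})

test_that("accumulation ratios reproduce the group-mean arithmetic", {
  d1 <- tibble::tibble(cmax = 80.5, auc_0_24 = 717)
  d14 <- tibble::tibble(cmax = 162, auc_0_24 = 1530)
  r <- accumulation_ratios(d1, d14)
  expect_equal(r$r_auc, 2.134, tolerance = 1e-3)
  expect_equal(r$r_cmax, 2.012, tolerance = 1e-3)
  # identical occasions give unit ratios
  expect_equal(unlist(accumulation_ratios(d1, d1)), c(r_cmax = 1, r_auc = 1))
  # zero denominators give missing ratios
  r0 <- accumulation_ratios(tibble::tibble(cmax = 0, auc_0_24 = NA), d14)
  expect_true(is.na(r0$r_cmax) && is.na(r0$r_auc))
})

test_that("NCA scales linearly in concentration, invariantly in time", {
  tt <- c(0, 0.5, 1, 2, 4, 8, 12, 24, 48, 72, 96, 120)
  cc <- twocomp_oral_conc(list(cl = 30, v1 = 100, q = 20, v2 = 500,
                               ka = 1.5), 0, 50, tt)
  a <- nca_single_dose(tt, cc, 50)
  b <- nca_single_dose(tt, 3 * cc, 50)
  expect_equal(b$cmax, 3 * a$cmax)
  expect_equal(b$auc_0_24, 3 * a$auc_0_24)
  expect_equal(b$tmax, a$tmax)
  expect_equal(b$lambda_z, a$lambda_z, tolerance = 1e-9)
})

test_that("NCA CL/F converges to true CL/F as sampling extends", {
  cl <- 4; v <- 60; ka <- 1
  errs <- vapply(c(48, 96, 192), function(horizon) {
    tt <- sort(unique(c(seq(0, 24, 2), seq(24, horizon, 12))))
    cc <- onecomp_oral_conc(list(cl = cl, v = v, ka = ka), 0, 100, tt)
    out <- nca_single_dose(tt, cc, 100)
    abs(out$cl_f - cl) / cl
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.01)
})
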