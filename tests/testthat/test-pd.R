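test_that("inhibition is the relative drop from baseline activity", {
  out <- dpp4_inhibition(c(0, 1, 2), c(100, 20, 120), baseline = 100)
  expect_equal(out$inhibition, c(0, 80, -20))
  expect_error(dpp4_inhibition(0, 10, baseline = 0), "baseline")
})

test_that("duration above threshold interpolates crossings", {
  expect_equal(duration_above(c(0, 2, 24), c(50, 90, 70), 80), 11.5)
  expect_equal(duration_above(c(0, 12, 24), c(10, 20, 30), 80), 0)
  expect_equal(duration_above(c(0, 12, 24), c(85, 90, 88), 80), 24)
})

test_that("duration above matches a dense brute-force scan", {
  set.seed(21)
  for (rep in 1:10) {
    tt <- sort(c(0, runif(8, 0, 24), 24))
    vv <- runif(10, 40, 100)
    grid <- seq(0, 24, by = 0.001)
    dense <- stats::approx(tt, vv, xout = grid)$y
    brute <- sum(dense > 80) * 0.001
    expect_lt(abs(duration_above(tt, vv, 80) - brute), 0.01)
  }
})

test_that("inhibition summaries follow their definitions", {
  s <- inhibition_summary(c(0, 6, 12, 18, 24), rep(90, 5))
  expect_equal(s$r_max, 90)
  expect_equal(s$auec_0_24, 2160)
  expect_equal(s$dur_80, 24)
  expect_equal(s$e_24, 90)
  expect_false(s$e24_interpolated)
  expect_error(inhibition_summary(numeric(0), numeric(0)), "empty")
  # E24 interpolated and flagged on a grid missing 24 h
  s2 <- inhibition_summary(c(0, 12, 36), c(80, 90, 70),
                           interval = c(0, 24))
  expect_true(s2$e24_interpolated)
  expect_equal(s2$e_24, 80)
})

test_that("noiseless simulated inhibition has Rmax equal to E(Cmax)", {
  p <- list(cl = 32.7, v1 = 30, q = 285, v2 = 816, ka = 6)
  link <- list(emax = 92.47, ec50 = 5.37, gamma = 0.884)
  tt <- c(0, 0.5, 1, 2, 3, 4, 6, 8, 12, 24)
  conc <- twocomp_oral_conc(p, 0, 50, tt)
  act <- simulate_dpp4_activity(conc, link, baseline = 20)
  inh <- dpp4_inhibition(tt, act, 20)
  s <- inhibition_summary(inh$time, inh$inhibition)
  expect_equal(s$r_max, predict_emax(link, max(conc)), tolerance = 1e-12)
  expect_equal(s$t_rmax, tt[which.max(conc)])
})

test_that("GLP-1 change scores and averages follow the printed arithmetic", {
  # flat series: all change scores zero
  flat <- delta_glp1(c(0, 6, 12, 24), rep(2, 4))
  expect_equal(flat$delta$delta, rep(0, 4))
  expect_equal(flat$summary$r_avg, 0)
  # a series whose change-score AUEC0-24 is 57.8 h*pM averages 2.408 pM
  d <- delta_glp1(c(0, 24), c(1, 1 + 57.8 / 12))
  expect_equal(d$summary$auec_0_24, 57.8, tolerance = 1e-12)
  expect_equal(d$summary$r_avg, 2.408, tolerance = 1e-3)
  expect_error(delta_glp1(c(1, 2), c(5, 6)), "pre-dose")
})

test_that("group-mean AUEC fold versus placebo matches the reported ratio", {
  expect_equal(fold_vs_placebo(57.8, 26.3), 2.20, tolerance = 2e-3)
})

test_that("OGTT effect areas integrate each analyte curve", {
  ogtt <- tibble::tibble(time = c(0, 0.5, 1, 2, 3),
                         glucose = rep(10, 5), insulin = c(0, 5, 10, 5, 0))
  a <- ogtt_auec(ogtt)
  expect_equal(a$glucose, 30)
  expect_equal(a$insulin, 15)
  expect_error(ogtt_auec(ogtt[1, ]), ">= 2")
})

test_that("OGTT change summaries reproduce the printed differences", {
  mk <- function(id, arm, glucose, insulin, glucagon) {
    tibble::tibble(ID = id, ARM = arm, glucose = glucose,
                   insulin = insulin, glucagon = glucagon)
  }
  base <- mk(1, "cetagliptin50", 48.65, 431.53, 469.51)
  post <- mk(1, "cetagliptin50", 43.68, 651.43, 396.81)
  ch <- ogtt_change_summary(post, base)
  expect_equal(ch$mean_change[ch$analyte == "glucose"], -4.97,
               tolerance = 1e-10)
  expect_equal(ch$mean_change[ch$analyte == "insulin"], 219.90,
               tolerance = 1e-10)
  expect_equal(ch$mean_change[ch$analyte == "glucagon"], -72.70,
               tolerance = 1e-10)
})

test_that("efficacy change tables recover a planted postprandial effect", {
  sim <- simulate_trial(sim_config(
    seed = 31, n_per_arm = c(cetagliptin50 = 10, cetagliptin100 = 0,
                             sitagliptin100 = 0, placebo = 10)))
  ch <- efficacy_changes(sim$dataset)
  planted <- ch[ch$ARM == "cetagliptin50" & ch$DVID == "ppg_2h" &
                  ch$day == "day14" & ch$meal == "supper", ]
  expect_equal(planted$mean_change, -2.64, tolerance = 0.8)
  placebo <- ch[ch$ARM == "placebo" & ch$DVID == "ppg_2h", ]
  expect_true(all(abs(placebo$mean_change) < 1))
  # identical baseline and post values give exactly zero changes
  ds0 <- sim$dataset
  hba <- ds0$EVID == 0L & ds0$DVID == "hba1c"
  ds0$DV[hba] <- 7
  ch0 <- efficacy_changes(ds0)
  expect_true(all(ch0$mean_change[ch0$DVID == "hba1c"] == 0))
})

test_that("run_ogtt summarises a simulated cohort by arm", {
  sim <- simulate_trial(small_trial_cfg(13))
  out <- run_ogtt(sim$dataset)
  expect_true(all(c("per_subject", "changes") %in% names(out)))
  expect_setequal(unique(out$changes$analyte),
                  c("glucose", "insulin", "c_peptide", "glucagon"))
  # treated glucose burden should fall on average (multiplier > 1)
  glu <- out$changes[out$changes$analyte == "glucose", ]
  expect_true(mean(glu$mean_change) < 0)
})
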