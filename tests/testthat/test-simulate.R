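test_that("a fixed seed reproduces the trial bit-for-bit", {
  a <- simulate_trial(small_trial_cfg(7))
  b <- simulate_trial(small_trial_cfg(7))
  expect_identical(a$dataset, b$dataset)
  expect_identical(a$truth$subjects, b$truth$subjects)
})

test_that("arm sizes and sampling schedules match the configuration", {
  cfg <- sim_config(seed = 2, n_per_arm = c(cetagliptin50 = 3,
                                            cetagliptin100 = 2,
                                            sitagliptin100 = 2,
                                            placebo = 1))
  sim <- simulate_trial(cfg)
  ds <- sim$dataset
  arms <- dplyr::distinct(tibble::as_tibble(ds), ID, ARM)
  expect_equal(as.integer(table(arms$ARM)[names(cfg$n_per_arm)]),
               as.integer(cfg$n_per_arm))
  # day-1 concentration times for subject 1 follow the schedule
  s1 <- ds[ds$ID == 1 & ds$EVID == 0 & ds$DVID == "drug_concentration" &
             ds$OCC == "day1", ]
  expect_equal(s1$TIME, cfg$schedules$pk_day1)
  # comparator day-14 sampling stops at 48 h post dose
  sita <- arms$ID[arms$ARM == "sitagliptin100"][1]
  st <- ds[ds$ID == sita & ds$EVID == 0 &
             ds$DVID == "drug_concentration", ]
  expect_equal(max(st$TIME), max(cfg$schedules$pk_day14_comparator))
})

test_that("placebo-only arms with zero variance give flat null responses", {
  cfg <- sim_config(seed = 1,
                    n_per_arm = c(cetagliptin50 = 0, cetagliptin100 = 0,
                                  sitagliptin100 = 0, placebo = 3),
                    omega2 = c(cl = 0, v1 = 0, v2 = 0), sigma_prop = 0,
                    dpp4_noise_sd = 0,
                    glp1 = list(baseline = 0.45, amplitude = 3, k = 1.4,
                                noise_sd = 0))
  sim <- simulate_trial(cfg)
  ds <- sim$dataset
  conc <- ds[ds$EVID == 0 & ds$DVID == "drug_concentration", ]
  expect_true(all(conc$BLQ == 1L))   # nothing above LLOQ
  act <- ds[ds$EVID == 0 & ds$DVID == "dpp4_activity", ]
  for (id in unique(act$ID)) {
    a <- act[act$ID == id, ]
    expect_equal(a$DV, rep(a$DV[1], nrow(a)))  # zero inhibition
  }
})

test_that("zero subjects in every arm is a configuration error", {
  expect_error(sim_config(n_per_arm = c(cetagliptin50 = 0,
                                        cetagliptin100 = 0,
                                        sitagliptin100 = 0, placebo = 0)),
               "at least one arm")
})

test_that("simulate_pk_profile with no doses returns zeros", {
  expect_equal(simulate_pk_profile(list(cl = 30, v1 = 100, q = 20,
                                        v2 = 500, ka = 1.5),
                                   numeric(0), numeric(0), c(0, 1, 2)),
               c(0, 0, 0))
})

test_that("the DPP-4 link has the right limits and inverts exactly", {
  link <- list(emax = 92.47, ec50 = 5.37, gamma = 0.884)
  expect_equal(simulate_dpp4_activity(0, link, baseline = 20), 20)
  high <- simulate_dpp4_activity(1e12, link, baseline = 20)
  expect_equal(high, 20 * (1 - 92.47 / 100), tolerance = 1e-6)
  # inhibition computed downstream returns the sigmoid exactly (noiseless)
  conc <- c(0, 1, 5.37, 20, 100)
  act <- simulate_dpp4_activity(conc, link, baseline = 18)
  inh <- dpp4_inhibition(seq_along(conc), act, baseline = 18)
  expect_equal(inh$inhibition, predict_emax(link, conc), tolerance = 1e-12)
  expect_equal(inh$inhibition[3], 92.47 / 2, tolerance = 1e-12)
})

test_that("GLP-1 pulses respond to meals and inhibition as specified", {
  tt <- seq(0, 24, by = 0.05)
  flat <- simulate_glp1(tt, 0, numeric(0), baseline = 0.5, amplitude = 3)
  expect_equal(flat, rep(0.5, length(tt)))
  lo <- simulate_glp1(tt, 0, c(4, 10), baseline = 0, amplitude = 3, k = 2)
  hi <- simulate_glp1(tt, 80, c(4, 10), baseline = 0, amplitude = 3, k = 2)
  expect_equal(max(hi) / max(lo), 2.6, tolerance = 1e-9)
  # peaks fall within 2 h after each meal
  for (mt in c(4, 10)) {
    win <- tt >= mt & tt <= mt + 2
    seg <- hi
    seg[!win] <- -Inf
    local_peak <- tt[which.max(seg)]
    expect_true(local_peak >= mt && local_peak <= mt + 2)
  }
})

test_that("OGTT curves scale with the treatment multiplier", {
  base <- simulate_ogtt(1, noise_cv = 0)
  again <- simulate_ogtt(1, noise_cv = 0)
  expect_identical(base, again)       # day -1 vs day 15 under no effect
  aucs <- vapply(c(1, 1.2, 1.5, 2), function(m) {
    ogtt_auec(simulate_ogtt(m, noise_cv = 0))$glucose
  }, numeric(1))
  expect_true(all(diff(aucs) < 0))    # glucose burden shrinks
  ins <- vapply(c(1, 1.5, 2), function(m) {
    ogtt_auec(simulate_ogtt(m, noise_cv = 0))$insulin
  }, numeric(1))
  expect_true(all(diff(ins) > 0))
  expect_true(all(as.matrix(simulate_ogtt(1.5, noise_cv = 0)[-1]) >= 0))
})

test_that("ground truth is stored alongside the dataset", {
  sim <- simulate_trial(small_trial_cfg(9))
  tr <- sim$truth$subjects
  expect_equal(nrow(tr), length(unique(sim$dataset$ID)))
  expect_true(all(c("cl", "v2", "ec50", "dpp4_baseline", "TBIL") %in%
                    names(tr)))
  expect_identical(sim$truth$config$seed, 9)
})
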