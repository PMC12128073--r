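test_that("sampled patients respect the cohort covariate boxes", {
  cfg <- cohort_config("A", n = 1000, seed = 3)
  p <- sample_patients(cfg)
  expect_true(all(p$pna < 50))
  expect_true(all(p$weight >= 0.7 & p$weight <= 4.2))
  expect_true(all(p$ga >= 25.4 & p$ga <= 41.0))
  expect_true(all(p$scr >= 15 & p$scr <= 81))
  expect_equal(p$pma, p$ga + p$pna / 7, tolerance = 0.1)
  dpk <- p$dose / p$weight
  expect_true(all(dpk >= 5.7 & dpk <= 27))  # rounding to 0.1 mg allowed
  expect_true(all(p$tau > p$tinf))
  expect_equal(p$daily_dose, p$dose * 24 / p$tau)

  cfgB <- cohort_config("B", n = 1000, seed = 3)
  pb <- sample_patients(cfgB)
  expect_true(all(pb$pna >= 50 & pb$pna <= 6273))
  expect_true(all(pb$weight >= 2.3 & pb$weight <= 74.6))
  expect_true(all(pb$scr >= 6 & pb$scr <= 103))
  expect_true(all(is.finite(pb$crcl) & pb$crcl > 0))
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- cohort_config("A", n = 25, seed = 17)
  m <- example_model("neo_wt_pma_scr")
  c1 <- simulate_cohort(m, cfg)
  c2 <- simulate_cohort(m, cfg)
  expect_identical(c1$patients, c2$patients)
  expect_identical(c1$observations, c2$observations)
  expect_identical(c1$truth, c2$truth)
  c3 <- simulate_cohort(m, cohort_config("A", n = 25, seed = 18))
  expect_false(identical(c1$observations, c3$observations))
})

test_that("noise-free, zero-IIV simulation reproduces the population profile", {
  m0 <- vanco_model(
    name = "gen0",
    parameters = example_model("neo_wt_pma_scr")$parameters,
    omega = matrix(0, 2, 2, dimnames = list(c("CL", "V1"), c("CL", "V1"))),
    residual = list(type = "additive", sigma_add = 1)
  )
  cfg <- cohort_config("A", n = 20, seed = 5,
                       residual = list(type = "additive", sigma_add = 1e-9))
  coh <- simulate_cohort(m0, cfg)
  for (i in seq_len(nrow(coh$patients))) {
    pat <- coh$patients[i, ]
    obs <- coh$observations[coh$observations$id == pat$id, ]
    f <- conc_ss(typical_params(m0, pat), ss_regimen(pat$dose, pat$tau, pat$tinf),
                 obs$time)
    expect_equal(obs$conc, f, tolerance = 1e-6)
  }
  expect_true(all(abs(coh$truth$eta_CL) < 1e-12))
})

test_that("simulated IIV matches the generating omega", {
  m <- example_model("neo_wt_pma_scr")
  cfg <- cohort_config("A", n = 1000, seed = 7)
  coh <- simulate_cohort(m, cfg)
  sd_cl <- sd(coh$truth$eta_CL)
  expect_lt(abs(sd_cl - sqrt(m$omega["CL", "CL"])) / sqrt(m$omega["CL", "CL"]), 0.1)
  # hidden truth is consistent: true AUC24 = daily dose / individual CL
  expect_equal(coh$truth$true_auc24,
               coh$patients$daily_dose / coh$truth$true_cl, tolerance = 1e-12)
})

test_that("simulated profiles look like post-distributional TDM data", {
  for (lab in c("A", "B")) {
    gen <- example_model(if (lab == "A") "neo_wt_pma_scr" else "ped_wt")
    cfg <- cohort_config(lab, n = 500, seed = 13)
    coh <- simulate_cohort(gen, cfg)
    wide <- tidyr::pivot_wider(coh$observations, id_cols = "id",
                               names_from = "label", values_from = "conc")
    # troughs fall below peaks almost surely
    expect_gte(mean(wide$trough < wide$peak), 0.99)
    # calibration against the observed plasma-concentration ranges
    troughs <- coh$observations$conc[coh$observations$label == "trough"]
    peaks <- coh$observations$conc[coh$observations$label == "peak"]
    expect_gte(mean(troughs >= 0.8 & troughs <= 48.5), 0.95)
    expect_gte(mean(peaks >= 13.2 & peaks <= 76.7), 0.95)
    # sampling times: peak shortly after infusion, trough near interval end
    times <- tidyr::pivot_wider(coh$observations, id_cols = "id",
                                names_from = "label", values_from = "time")
    expect_true(all(times$peak > coh$patients$tinf))
    expect_true(all(times$trough < coh$patients$tau))
    expect_true(all(times$peak < times$trough))
  }
})

test_that("the time-registration error mode perturbs recorded times only", {
  m <- example_model("neo_wt_pma_scr")
  cfg0 <- cohort_config("A", n = 30, seed = 9)
  cfg1 <- cohort_config("A", n = 30, seed = 9, time_error_sd = 5 / 60)
  c0 <- simulate_cohort(m, cfg0)
  c1 <- simulate_cohort(m, cfg1)
  expect_identical(c0$observations$conc, c1$observations$conc)
  dt <- c1$observations$time - c0$observations$time
  expect_true(any(dt != 0))
  expect_true(all(abs(dt) <= 5 / 60 + 1e-12))
})

test_that("cohort config validates its constraints", {
  expect_error(cohort_config("A", n = 0), "at least 1")
  expect_error(cohort_config("A", pna_range = c(3, 60)), "< 50")
  expect_error(cohort_config("B", pna_range = c(10, 600)), ">= 50")
})
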