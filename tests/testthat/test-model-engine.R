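test_that("covariate multipliers evaluate to their closed forms", {
  m <- allometric_ped_model()
  # reference-weight identity: all multipliers 1, theta recovered exactly
  tp <- typical_params(m, list(weight = 70))
  expect_identical(tp$CL, 4)
  expect_identical(tp$V1, 40)
  # direct arithmetic re-evaluation at 2.5 kg
  tp <- typical_params(m, list(weight = 2.5))
  expect_equal(tp$CL, 4 * (2.5 / 70)^0.75, tolerance = 1e-12)
  # half-maximum symmetry of the maturation term
  hill <- simple_1cmt(
    theta_cl = 2,
    terms_cl = list(list(kind = "hill_maturation", covariate = "pma",
                         tm50 = 33.3, gamma = 3.68)))
  tp <- typical_params(hill, list(pma = 33.3))
  expect_equal(tp$CL, 2 * 0.5, tolerance = 1e-12)
  # linear term
  lin <- simple_1cmt(
    theta_cl = 1,
    terms_cl = list(list(kind = "linear", covariate = "scr", ref = 29, slope = -0.005)))
  expect_equal(typical_params(lin, list(scr = 49))$CL, 1 * (1 - 0.005 * 20))
})

test_that("missing covariates fail with the covariate and model named", {
  m <- allometric_ped_model()
  expect_error(typical_params(m, list(scr = 30)), "weight")
  expect_error(typical_params(m, list(scr = 30)), "test_allo")
})

test_that("crcl is derived on demand for models that need it", {
  m <- simple_1cmt(
    theta_cl = 4,
    terms_cl = list(list(kind = "power", covariate = "crcl", ref = 120, exp = 0.4)))
  cov <- list(height = 140, scr = 19, pna = 2000)
  expect_equal(typical_params(m, cov)$CL,
               4 * (crcl_schwartz(140, 19) / 120)^0.4)
  # explicit crcl takes precedence
  expect_equal(typical_params(m, c(cov, crcl = 120))$CL, 4)
  expect_error(typical_params(m, list(scr = 19)), "crcl|height")
})

test_that("model constructor validates structure, omega and residual", {
  good <- simple_1cmt()
  expect_s3_class(good, "vanco_model")
  expect_error(simple_1cmt(omega = matrix(c(0.1, 0.2, 0, 0.1), 2,
                                          dimnames = list(c("CL", "V1"), NULL))),
               "symmetric")
  om <- matrix(c(0.1, 0.5, 0.5, 0.1), 2, dimnames = list(c("CL", "V1"), NULL))
  expect_error(simple_1cmt(omega = om), "semidefinite")
  expect_error(simple_1cmt(residual = list(type = "additive", sigma_add = 0)),
               "variance")
  expect_error(simple_1cmt(terms_cl = list(list(kind = "exponential",
                                                covariate = "weight"))),
               "unknown covariate term kind")
  expect_error(
    vanco_model("bad2", n_compartments = 2,
                parameters = list(CL = list(theta = 1), V1 = list(theta = 1)),
                omega = diag(c(CL = 0.1)),
                residual = list(type = "additive", sigma_add = 1)),
    "Q, V2")
})

test_that("models round-trip through their YAML representation", {
  for (m in example_models()) {
    path <- withr::local_tempfile(fileext = ".yaml")
    write_model(m, path)
    back <- read_model(path)
    expect_equal(back, m, tolerance = 0)
  }
  # and a model with long-decimal parameters survives at full precision
  m <- simple_1cmt(theta_cl = 1 / 3, theta_v = exp(1))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model(m, path)
  expect_equal(read_model(path)$parameters$CL$theta, 1 / 3, tolerance = 1e-15)
})

test_that("bundled example models load, are cohort-filtered and predict positive PK", {
  ms <- example_models()
  expect_gte(length(ms), 4)
  expect_setequal(names(example_models("A")), c("neo_wt_pma_scr", "neo_wt_pma_scr_alt"))
  neo_cov <- list(weight = 2.5, pma = 39.7, pna = 17, ga = 37.1,
                  height = 46, scr = 29)
  ped_cov <- list(weight = 12.2, pna = 671, height = 80, scr = 19)
  for (nm in names(ms)) {
    cov <- if (grepl("^neo", nm)) neo_cov else ped_cov
    tp <- typical_params(ms[[nm]], cov)
    expect_true(tp$CL > 0 && tp$V1 > 0, label = nm)
  }
  tp2 <- typical_params(ms$ped_wt_crcl_2cmt, ped_cov)
  expect_true(tp2$Q > 0 && tp2$V2 > 0)
})

test_that("renal function estimates follow their bedside formulas", {
  # constructed identity: k * height / (scr in mg/dL) with scr = k in mg/dL
  expect_equal(crcl_schwartz(height = 100, scr = 0.413 * 88.4), 100)
  expect_equal(crcl_schwartz(140, 19), 0.413 * 140 / (19 / 88.4))
  # inverse proportionality in creatinine
  expect_equal(crcl_schwartz(100, 60), 2 * crcl_schwartz(100, 120))
  # infant formula: positive over the whole neonatal covariate box
  grid <- expand.grid(height = c(30, 45, 60), scr = c(15, 40, 81),
                      pna = c(3, 17, 40))
  expect_true(all(crcl_boer(grid$height, grid$scr, grid$pna) > 0))
  # monotone decreasing in serum creatinine
  scr <- seq(15, 81, length.out = 20)
  expect_true(all(diff(crcl_boer(47, scr, 17)) < 0))
  # dispatch: infant formula below 365 days, Schwartz at and above
  expect_equal(crcl_estimate(100, 30, 364), crcl_boer(100, 30, 364))
  expect_equal(crcl_estimate(100, 30, 365), crcl_schwartz(100, 30))
  expect_error(crcl_schwartz(-1, 30), "positive")
  expect_error(crcl_boer(100, 30, 0), "positive")
})
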