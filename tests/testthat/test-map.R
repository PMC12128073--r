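reg8 <- ss_regimen(100, tau = 8, tinf = 1)

test_that("MAP objective has its documented closed-form special cases", {
  m <- simple_1cmt()
  # empty observations at the prior mode: both terms vanish
  expect_identical(map_objective(m, list(), reg8, NULL, c(0, 0)), 0)
  # zero residual at the prior mode leaves only ln sigma^2
  f0 <- conc_ss(typical_params(m, list()), reg8, 5)
  obs <- tibble::tibble(time = 5, conc = f0, label = "trough")
  m2 <- simple_1cmt(residual = list(type = "additive", sigma_add = 2))
  expect_equal(map_objective(m2, list(), reg8, obs, c(0, 0)), log(4),
               tolerance = 1e-12)
  # prior quadratic form alone when no data
  eta <- c(CL = 0.3, V1 = -0.2)
  expect_equal(map_objective(m, list(), reg8, obs[0, ], eta),
               drop(t(eta) %*% solve(m$omega) %*% eta), tolerance = 1e-12)
  expect_error(map_objective(m, list(), reg8, obs, 0.1), "length")
})

test_that("a priori fit is the prior mode with typical parameters", {
  m <- simple_1cmt()
  fit <- estimate_map(m, list(), reg8, NULL)
  expect_identical(unname(fit$eta), c(0, 0))
  expect_equal(fit$params$CL, 5)
  expect_equal(fit$params$V1, 10)
  expect_identical(fit$ofv, 0)
  expect_identical(fit$scenario, "a priori")
  expect_true(fit$converged)
})

test_that("the optimizer lands below 1000 random probes of the objective", {
  m <- simple_1cmt()
  obs <- tibble::tibble(time = c(1.5, 7.5), conc = c(16, 7),
                        label = c("peak", "trough"))
  fit <- estimate_map(m, list(), reg8, obs)
  probes <- withr::with_seed(5, matrix(rnorm(2000, 0, 1), ncol = 2))
  vals <- apply(probes, 1, function(e) map_objective(m, list(), reg8, obs, e))
  expect_true(all(vals >= fit$ofv - 1e-9))
  # objective equivalence: stored ofv is exactly the objective at eta_hat
  expect_identical(fit$ofv, map_objective(m, list(), reg8, obs, fit$eta))
})

test_that("1-D trough-only estimate matches a dense grid search", {
  m <- cl_only_model()
  obs <- tibble::tibble(time = 7.5, conc = 9, label = "trough")
  fit <- estimate_map(m, list(), reg8, obs)
  grid <- seq(-3, 3, length.out = 10001)
  vals <- vapply(grid, function(e) map_objective(m, list(), reg8, obs, e),
                 numeric(1))
  expect_equal(unname(fit$eta), grid[which.min(vals)], tolerance = 1e-3)
  expect_lte(fit$ofv, min(vals) + 1e-9)
})

test_that("noise-free observations from the fitting model recover eta", {
  m <- simple_1cmt(residual = list(type = "additive", sigma_add = 1e-3))
  eta_star <- c(CL = 0.35, V1 = -0.25)
  ind <- list(CL = 5 * exp(eta_star[["CL"]]), V1 = 10 * exp(eta_star[["V1"]]))
  obs <- tibble::tibble(time = c(1.5, 7.5),
                        conc = conc_ss(ind, reg8, c(1.5, 7.5)),
                        label = c("peak", "trough"))
  fit <- estimate_map(m, list(), reg8, obs)
  expect_equal(unname(fit$eta), unname(eta_star), tolerance = 1e-3)
})

test_that("shrinkage responds monotonically to residual information", {
  obs <- tibble::tibble(time = 7.5, conc = 9, label = "trough")
  # uninformative-data limit: huge residual SD drives eta to the prior mode
  m_flat <- simple_1cmt(residual = list(type = "additive", sigma_add = 1e6))
  fit_flat <- estimate_map(m_flat, list(), reg8, obs)
  expect_equal(unname(fit_flat$eta), c(0, 0), tolerance = 1e-4)
  # halving the residual SD (doubling the weight) can only reduce shrinkage
  fit_1 <- estimate_map(simple_1cmt(residual = list(type = "additive", sigma_add = 2)),
                        list(), reg8, obs)
  fit_2 <- estimate_map(simple_1cmt(residual = list(type = "additive", sigma_add = sqrt(2))),
                        list(), reg8, obs)
  expect_lte(sqrt(sum(fit_1$eta^2)), sqrt(sum(fit_2$eta^2)) + 1e-8)
})

test_that("estimation is deterministic and handles singular omega explicitly", {
  m <- simple_1cmt()
  obs <- tibble::tibble(time = c(1.5, 7.5), conc = c(16, 7),
                        label = c("peak", "trough"))
  f1 <- estimate_map(m, list(), reg8, obs)
  f2 <- estimate_map(m, list(), reg8, obs)
  expect_identical(f1, f2)
  sing <- simple_1cmt(omega = matrix(c(0.09, 0.09, 0.09, 0.09), 2,
                                     dimnames = list(c("CL", "V1"), NULL)))
  expect_error(estimate_map(sing, list(), reg8, obs), "pseudo-inverse")
  fit_p <- estimate_map(sing, list(), reg8, obs,
                        control = map_control(pseudo_inverse = TRUE))
  expect_true(fit_p$converged)
  expect_error(estimate_map(m, list(), reg8,
                            tibble::tibble(time = 5, conc = -1, label = "trough")),
               "positive")
})

test_that("fit accessors expose tidy summaries", {
  m <- simple_1cmt()
  obs <- tibble::tibble(time = 7.5, conc = 9, label = "trough")
  fit <- estimate_map(m, list(), reg8, obs)
  td <- tidy(fit)
  expect_equal(td$term, c("eta_CL", "eta_V1"))
  gl <- glance(fit)
  expect_equal(gl$scenario, "trough")
  expect_equal(gl$n_obs, 1L)
})
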