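#' MAP estimation settings
#'
#' Controls for the local optimisation behind [estimate_map()]. The objective
#' is smooth in `eta`, so a quasi-Newton search (BFGS with numerical
#' gradients) is run from the prior mode `eta = 0` plus `n_starts - 1`
#' jittered starting points drawn once from a fixed seed, making the whole
#' estimate deterministic. Ties in the objective (within `tie_tol`) are broken
#' toward the smallest `||eta||`.
#'
#' @param n_starts Total number of starts (>= 1; default 5: prior mode + 4
#'   jittered).
#' @param start_sd Standard deviation of the jittered starts on the log scale.
#' @param start_seed Seed for the jittered starts.
#' @param maxit,reltol Passed to [stats::optim()].
#' @param tie_tol Objective tolerance within which fits count as tied.
#' @param pseudo_inverse If `TRUE`, a singular IIV matrix is inverted with an
#'   eigenvalue pseudo-inverse instead of failing.
#' @return List of settings for [estimate_map()].
#' @export
map_control <- function(n_starts = 5L, start_sd = 0.5, start_seed = 101L,
                        maxit = 500L, reltol = 1e-12, tie_tol = 1e-8,
                        pseudo_inverse = FALSE) {
  list(n_starts = as.integer(n_starts), start_sd = start_sd,
       start_seed = as.integer(start_seed), maxit = as.integer(maxit),
       reltol = reltol, tie_tol = tie_tol, pseudo_inverse = pseudo_inverse)
}

SCENARIOS <- c("peak+trough", "peak", "trough", "a priori")

residual_sd <- function(residual, f) {
  switch(residual$type,
    additive = rep(residual$sigma_add, length(f)),
    proportional = residual$sigma_prop * abs(f),
    combined = sqrt(residual$sigma_add^2 + (residual$sigma_prop * f)^2)
  )
}

omega_inverse <- function(omega, pseudo_inverse = FALSE) {
  inv <- tryCatch(solve(omega), error = function(e) NULL)
  if (!is.null(inv) && all(is.finite(inv))) return(inv)
  if (!pseudo_inverse) {
    abort(paste0("IIV matrix omega is singular; set ",
                 "map_control(pseudo_inverse = TRUE) to use an eigenvalue ",
                 "pseudo-inverse."))
  }
  e <- eigen(omega, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-12
  e$vectors[, pos, drop = FALSE] %*%
    diag(1 / e$values[pos], sum(pos)) %*% t(e$vectors[, pos, drop = FALSE])
}

individual_params <- function(typ, omega_labels, eta) {
  ind <- as.list(typ)
  for (p in omega_labels) ind[[p]] <- ind[[p]] * exp(eta[[p]])
  tibble::tibble(CL = ind$CL, V1 = ind$V1,
                 Q = ind$Q %||% NA_real_, V2 = ind$V2 %||% NA_real_)
}

#' MAP objective function
#'
#' Extended-least-squares maximum a posteriori objective for individual
#' random effects `eta` given sparse steady-state observations:
#' `sum_j [ (y_j - f_j(eta))^2 / g_j^2 + ln g_j^2 ] + eta' Omega^-1 eta`,
#' where `f_j` is the model-predicted concentration at observation `j` and
#' `g_j` the residual standard deviation there (additive, proportional
#' `g = sigma_prop * f`, or combined). With no observations and `eta = 0` the
#' objective is exactly 0 (the prior mode).
#'
#' @param model A [vanco_model()].
#' @param covariates Patient covariates (see [typical_params()]).
#' @param regimen Steady-state regimen from [ss_regimen()].
#' @param obs Observation table: tibble/data frame with columns `time`
#'   (h after dose start), `conc` (mg/L) and optionally `label`
#'   (`"peak"`/`"trough"`); may have zero rows (a priori).
#' @param eta Named (or omega-ordered) numeric vector of random effects.
#' @param control [map_control()] settings (used for singular-omega policy).
#' @return The objective value (unitless).
#' @export
map_objective <- function(model, covariates, regimen, obs, eta,
                          control = map_control()) {
  labels <- rownames(model$omega)
  if (length(eta) != length(labels)) {
    abort(sprintf("`eta` must have length %d (random effects: %s).",
                  length(labels), paste(labels, collapse = ", ")))
  }
  eta <- setNames(as.numeric(eta), labels)
  typ <- typical_params(model, covariates)
  oinv <- omega_inverse(model$omega, control$pseudo_inverse)
  map_objective_impl(typ, labels, oinv, model$residual, regimen, obs, eta)
}

map_objective_impl <- function(typ, labels, oinv, residual, regimen, obs, eta) {
  prior <- drop(t(eta) %*% oinv %*% eta)
  if (is.null(obs) || nrow(obs) == 0L) return(prior)
  ind <- as.list(typ)
  for (i in seq_along(labels)) ind[[labels[i]]] <- ind[[labels[i]]] * exp(eta[i])
  f <- conc_ss(ind, regimen, obs$time)
  g2 <- residual_sd(residual, f)^2
  if (any(g2 <= 0)) return(Inf)
  sum((obs$conc - f)^2 / g2 + log(g2)) + prior
}

#' MAP Bayesian estimation of individual random effects
#'
#' Estimates the posterior mode of the individual random effects from 0, 1 or
#' 2 steady-state concentrations, by minimising [map_objective()] with a
#' deterministic multi-start quasi-Newton search. With an empty observation
#' set the fit is the a priori prediction (`eta = 0`) by construction.
#' Individual parameters are `typical * exp(eta_hat)`.
#'
#' @inheritParams map_objective
#' @param scenario Optional scenario label stored on the fit (one of
#'   `"peak+trough"`, `"peak"`, `"trough"`, `"a priori"`); inferred from the
#'   observation labels when omitted.
#' @return A `vanco_fit`: list with `eta` (named vector), `params` (one-row
#'   tibble of individual CL/V1/Q/V2), `ofv`, `converged`, `scenario`,
#'   `n_obs`, `model`. Supports [tidy()] and [glance()].
#' @examples
#' m <- example_model("ped_wt")
#' cov <- list(weight = 12.2)
#' reg <- ss_regimen(dose = 180, tau = 6, tinf = 1)
#' obs <- tibble::tibble(time = 5.5, conc = 12, label = "trough")
#' fit <- estimate_map(m, cov, reg, obs)
#' glance(fit)
#' @export
estimate_map <- function(model, covariates, regimen, obs = NULL,
                         scenario = NULL, control = map_control()) {
  labels <- rownames(model$omega)
  k <- length(labels)
  typ <- typical_params(model, covariates)
  scenario <- scenario %||% infer_scenario(obs)
  if (is.null(obs) || nrow(obs) == 0L) {
    eta <- setNames(numeric(k), labels)
    return(new_vanco_fit(eta, individual_params(typ, labels, eta), ofv = 0,
                         converged = TRUE, scenario = scenario, n_obs = 0L,
                         model = model$name))
  }
  if (any(!is.finite(obs$conc) | obs$conc <= 0)) {
    abort("observed concentrations must be positive.")
  }
  oinv <- omega_inverse(model$omega, control$pseudo_inverse)
  fn <- function(eta) {
    v <- map_objective_impl(typ, labels, oinv, model$residual, regimen, obs, eta)
    if (!is.finite(v)) 1e10 else v
  }
  starts <- rbind(
    numeric(k),
    withr::with_seed(control$start_seed,
      matrix(rnorm((control$n_starts - 1L) * k, 0, control$start_sd),
             ncol = k))
  )
  runs <- lapply(seq_len(nrow(starts)), function(i) {
    if (k == 1L) {
      # Brent on a bracket far wider than any plausible random effect
      return(tryCatch(
        optim(starts[i, ], fn, method = "Brent", lower = -15, upper = 15,
              control = list(maxit = control$maxit)),
        error = function(e) NULL))
    }
    res <- tryCatch(
      optim(starts[i, ], fn, method = "BFGS",
            control = list(maxit = control$maxit, reltol = control$reltol)),
      error = function(e) NULL)
    if (is.null(res)) {
      res <- tryCatch(
        optim(starts[i, ], fn, method = "Nelder-Mead",
              control = list(maxit = 2L * control$maxit)),
        error = function(e) NULL)
    }
    res
  })
  runs <- purrr::compact(runs)
  ok <- vapply(runs, function(r) is.finite(r$value) && r$convergence == 0L,
               logical(1))
  converged <- any(ok)
  pool <- if (converged) runs[ok] else runs
  if (!length(pool)) {
    eta <- setNames(numeric(k), labels)
    return(new_vanco_fit(eta, individual_params(typ, labels, eta), ofv = NA_real_,
                         converged = FALSE, scenario = scenario,
                         n_obs = nrow(obs), model = model$name))
  }
  vals <- vapply(pool, `[[`, numeric(1), "value")
  best_val <- min(vals)
  tied <- which(vals <= best_val + control$tie_tol)
  norms <- vapply(tied, function(i) sqrt(sum(pool[[i]]$par^2)), numeric(1))
  best <- pool[[tied[which.min(norms)]]]
  eta <- setNames(best$par, labels)
  ofv <- map_objective_impl(typ, labels, oinv, model$residual, regimen, obs, eta)
  new_vanco_fit(eta, individual_params(typ, labels, eta), ofv = ofv,
                converged = converged, scenario = scenario,
                n_obs = nrow(obs), model = model$name)
}

infer_scenario <- function(obs) {
  if (is.null(obs) || nrow(obs) == 0L) return("a priori")
  labs <- unique(obs$label %||% character())
  if (setequal(labs, c("peak", "trough"))) return("peak+trough")
  if (identical(labs, "peak")) return("peak")
  if (identical(labs, "trough")) return("trough")
  "peak+trough"
}

new_vanco_fit <- function(eta, params, ofv, converged, scenario, n_obs, model) {
  structure(
    list(eta = eta, params = params, ofv = ofv, converged = converged,
         scenario = scenario, n_obs = n_obs, model = model),
    class = "vanco_fit"
  )
}

#' @export
print.vanco_fit <- function(x, ...) {
  cat(sprintf("<vanco_fit> model %s, scenario '%s' (%d obs)\n",
              x$model, x$scenario, x$n_obs))
  cat("  eta:", paste(sprintf("%s = %.4f", names(x$eta), x$eta), collapse = ", "), "\n")
  cat(sprintf("  CL = %.4g L/h, V1 = %.4g L; ofv = %.4g; converged: %s\n",
              x$params$CL, x$params$V1, x$ofv, x$converged))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.vanco_fit <- function(x, ...) {
  tibble::tibble(term = paste0("eta_", names(x$eta)), estimate = unname(x$eta))
}

#' @exportS3Method generics::glance
glance.vanco_fit <- function(x, ...) {
  tibble::tibble(model = x$model, scenario = x$scenario, n_obs = x$n_obs,
                 CL = x$params$CL, V1 = x$params$V1, ofv = x$ofv,
                 converged = x$converged)
}
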