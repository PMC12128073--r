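#' Configuration for the synthetic cohort generator
#'
#' Describes the study conditions the generator emulates: two pediatric
#' cohorts on intermittent intravenous vancomycin with one peak and one trough
#' sample each, at steady state. Cohort `A` are neonates/young infants
#' (postnatal age < 50 days, including premature patients); cohort `B` are
#' older infants to adolescents (postnatal age >= 50 days). Default covariate
#' ranges, doses per kg and sampling-time windows follow the observed cohort
#' characteristics (weight 0.7-4.2 kg, gestational age 25.4-41.0 weeks, serum
#' creatinine 15-81 µmol/L, dose 5.8-26.9 mg/kg for A; weight 2.3-74.6 kg,
#' serum creatinine 6-103 µmol/L, dose 5.8-33.5 mg/kg for B); distribution
#' families within those ranges (truncated lognormal / uniform / triangular)
#' are generator choices and fully overridable here.
#'
#' @param cohort `"A"` or `"B"`.
#' @param n Number of patients (>= 1).
#' @param seed RNG seed; every random draw of the generator flows from it.
#' @param dose_per_kg_median,dose_per_kg_range Median and range (mg/kg) of the
#'   truncated-lognormal maintenance dose per kg.
#' @param tinf Infusion duration in h.
#' @param pna_range Postnatal age range in days (cohort constraint: `A` < 50,
#'   `B` >= 50).
#' @param ga_range,ga_mode Gestational-age triangular distribution (weeks),
#'   cohort A only.
#' @param weight_range Weight truncation range in kg.
#' @param scr_median,scr_range Serum creatinine lognormal median and
#'   truncation range (µmol/L).
#' @param peak_delay_median,peak_delay_sdlog,peak_delay_max Lognormal delay of
#'   the peak sample after the end of infusion (h).
#' @param trough_offset Range (h) before the end of the dosing interval at
#'   which the trough is drawn.
#' @param residual Residual error used to corrupt simulated samples. The
#'   default (`NULL`) is assay-level measurement error (combined, 0.5 mg/L
#'   additive + 10% proportional): a popPK model's fitted residual also
#'   absorbs model misspecification and is systematically larger than pure
#'   measurement noise, so it overstates sampling noise when used for data
#'   generation. Pass `"model"` to use the generating model's residual model
#'   instead, or any residual list as in [vanco_model()] (e.g.
#'   `list(type = "additive", sigma_add = 1e-9)` for a noise-free cohort).
#' @param time_error_sd Optional time-registration error: recorded sample
#'   times are perturbed by uniform noise of this half-width (h; e.g. `5/60`
#'   for the 5-minute registration-uncertainty mode). Concentrations are
#'   simulated at the true times; the recorded times carry the error. Default
#'   0 (off).
#' @return A `vanco_cohort_config` list.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(cohort = c("A", "B"), n = 100L, seed = 42L,
                          dose_per_kg_median = NULL, dose_per_kg_range = NULL,
                          tinf = 1,
                          pna_range = NULL, ga_range = c(25.4, 41.0),
                          ga_mode = 37, weight_range = NULL,
                          scr_median = NULL, scr_range = NULL,
                          peak_delay_median = 0.6, peak_delay_sdlog = 0.5,
                          peak_delay_max = 4,
                          trough_offset = c(0.1, 0.9),
                          residual = NULL, time_error_sd = 0) {
  cohort <- match.arg(cohort)
  if (n < 1L) abort("`n` must be at least 1.")
  defaults <- if (cohort == "A") {
    list(dose_per_kg_median = 12.0, dose_per_kg_range = c(5.8, 26.9),
         pna_range = c(3, 40), weight_range = c(0.7, 4.2),
         scr_median = 29, scr_range = c(15, 81))
  } else {
    list(dose_per_kg_median = 14.9, dose_per_kg_range = c(5.8, 33.5),
         pna_range = c(50, 6273), weight_range = c(2.3, 74.6),
         scr_median = 19, scr_range = c(6, 103))
  }
  cfg <- list(
    cohort = cohort, n = as.integer(n), seed = as.integer(seed),
    dose_per_kg_median = dose_per_kg_median %||% defaults$dose_per_kg_median,
    dose_per_kg_range = dose_per_kg_range %||% defaults$dose_per_kg_range,
    tinf = tinf,
    pna_range = pna_range %||% defaults$pna_range,
    ga_range = ga_range, ga_mode = ga_mode,
    weight_range = weight_range %||% defaults$weight_range,
    scr_median = scr_median %||% defaults$scr_median,
    scr_range = scr_range %||% defaults$scr_range,
    peak_delay_median = peak_delay_median,
    peak_delay_sdlog = peak_delay_sdlog,
    peak_delay_max = peak_delay_max,
    trough_offset = trough_offset,
    residual = residual, time_error_sd = time_error_sd
  )
  rng <- range(cfg$pna_range)
  if (cohort == "A" && rng[2] >= 50) abort("cohort A requires postnatal age < 50 days.")
  if (cohort == "B" && rng[1] < 50) abort("cohort B requires postnatal age >= 50 days.")
  structure(cfg, class = "vanco_cohort_config")
}

# exact inverse-CDF draws from a lognormal truncated to [lo, hi]
rlnorm_trunc <- function(n, median, sdlog, lo, hi) {
  meanlog <- log(median)
  p <- runif(n, stats::plnorm(lo, meanlog, sdlog), stats::plnorm(hi, meanlog, sdlog))
  stats::qlnorm(p, meanlog, sdlog)
}

rtriangular <- function(n, lo, hi, mode) {
  u <- runif(n)
  fc <- (mode - lo) / (hi - lo)
  ifelse(u < fc,
         lo + sqrt(u * (hi - lo) * (mode - lo)),
         hi - sqrt((1 - u) * (hi - lo) * (hi - mode)))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# interdose interval policy: cohort A by postmenstrual age, cohort B by age
tau_policy <- function(cohort, pma, age_years) {
  if (cohort == "A") ifelse(pma < 37, 12, 8) else ifelse(age_years < 12, 6, 8)
}

sample_patients_impl <- function(config) {
  n <- config$n
  if (config$cohort == "A") {
    pna <- runif(n, config$pna_range[1], config$pna_range[2])
    ga <- rtriangular(n, config$ga_range[1], config$ga_range[2], config$ga_mode)
    pma <- ga + pna / 7
    # birthweight tracks maturity; ~18% residual spread
    weight <- clamp(exp(log(2.5) + 0.09 * (pma - 39.7) + rnorm(n, 0, 0.18)),
                    config$weight_range[1], config$weight_range[2])
    height <- clamp(30 + 6.4 * weight + rnorm(n, 0, 1.5), 30, 62)
    scr <- rlnorm_trunc(n, config$scr_median, 0.35,
                        config$scr_range[1], config$scr_range[2])
    age_years <- pna / 365.25
  } else {
    pna <- rlnorm_trunc(n, 671, 1.1, config$pna_range[1], config$pna_range[2])
    age_years <- pna / 365.25
    ga <- rep(NA_real_, n)
    pma <- rep(NA_real_, n)
    wt_typ <- ifelse(age_years < 10, 2 * (age_years + 4), 3 * age_years + 7)
    weight <- clamp(wt_typ * exp(rnorm(n, 0, 0.2)),
                    config$weight_range[1], config$weight_range[2])
    ht_typ <- ifelse(age_years < 1, 52 + 23 * age_years,
                     ifelse(age_years < 12, 75 + 6.3 * (age_years - 1),
                            144 + 4 * (age_years - 12)))
    height <- clamp(ht_typ * exp(rnorm(n, 0, 0.05)), 45, 190)
    scr <- rlnorm_trunc(n, config$scr_median + 1.3 * pmin(age_years, 17), 0.35,
                        config$scr_range[1], config$scr_range[2])
  }
  sex <- ifelse(runif(n) < ifelse(config$cohort == "A", 0.571, 0.638),
                "female", "male")
  tau <- tau_policy(config$cohort, pma, age_years)
  dpk <- rlnorm_trunc(n, config$dose_per_kg_median, 0.3,
                      config$dose_per_kg_range[1], config$dose_per_kg_range[2])
  dose <- round(dpk * weight, 1)
  tibble::tibble(
    id = seq_len(n), cohort = config$cohort,
    weight = weight, pna = pna, ga = ga, pma = pma,
    height = height, sex = sex, scr = scr,
    crcl = crcl_estimate(height, scr, pna),
    dose = dose, tau = tau, tinf = config$tinf,
    daily_dose = dose * 24 / tau
  )
}

#' Sample virtual patients (covariates and regimens only)
#'
#' Draws `config$n` patients with covariates from the configured truncated
#' distributions and assigns a steady-state regimen (dose per kg times weight,
#' interval by a simple pediatric tau policy: 8-12 h by postmenstrual age in
#' cohort A, 6-8 h by age in cohort B). Deterministic given the config seed.
#'
#' @param config A [cohort_config()].
#' @return Tibble with one row per patient: covariates (`weight`, `pna`, `ga`,
#'   `pma`, `height`, `sex`, `scr`, `crcl`) and regimen (`dose` mg, `tau` h,
#'   `tinf` h, `daily_dose` mg/24 h).
#' @export
sample_patients <- function(config) {
  stopifnot(inherits(config, "vanco_cohort_config"))
  withr::with_seed(config$seed, sample_patients_impl(config))
}

simulate_observations_impl <- function(model, patients, config) {
  labels <- rownames(model$omega)
  resid <- if (is.null(config$residual)) {
    list(type = "combined", sigma_add = 0.5, sigma_prop = 0.10)
  } else if (identical(config$residual, "model")) {
    model$residual
  } else {
    validate_residual(config$residual, "cohort residual override")
  }
  n <- nrow(patients)
  # symmetric PSD square root (works for singular omega, e.g. zero IIV);
  # each patient consumes a fixed number of normal draws
  e <- eigen(model$omega, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(model$omega)) %*%
    t(e$vectors)
  obs <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    pat <- patients[i, ]
    typ <- typical_params(model, pat)
    eta <- setNames(drop(L %*% rnorm(length(labels))), labels)
    ind <- individual_params(typ, labels, eta)
    reg <- ss_regimen(pat$dose, pat$tau, pat$tinf)
    # peaks are post-distributional but early in the interval (well clear of
    # the trough window), as in clinical peak sampling shortly after infusion
    peak_delay <- min(exp(log(config$peak_delay_median) +
                            rnorm(1, 0, config$peak_delay_sdlog)),
                      config$peak_delay_max, 0.35 * (pat$tau - pat$tinf))
    t_peak <- pat$tinf + max(peak_delay, 0.05)
    t_trough <- pat$tau - runif(1, config$trough_offset[1], config$trough_offset[2])
    times <- c(t_peak, t_trough)
    f <- conc_ss(ind, reg, times)
    y <- pmax(f + rnorm(2, 0, residual_sd(resid, f)), 0.05)
    obs[[i]] <- tibble::tibble(id = pat$id, time = times, conc = y,
                               label = c("peak", "trough"))
    cl_eta <- if ("CL" %in% labels) eta[["CL"]] else 0
    truth[[i]] <- tibble::tibble(
      id = pat$id,
      !!!setNames(as.list(unname(eta)), paste0("eta_", labels)),
      true_cl = typ$CL * exp(cl_eta),
      true_auc24 = reg$daily_dose / (typ$CL * exp(cl_eta))
    )
  }
  observations <- dplyr::bind_rows(obs)
  # recorded-time perturbation is drawn after the concentration stream so
  # switching the mode on changes recorded times and nothing else
  if (config$time_error_sd > 0) {
    err <- runif(nrow(observations), -config$time_error_sd, config$time_error_sd)
    observations$time <- pmax(observations$time + err, 0.05)
  }
  list(observations = observations, truth = dplyr::bind_rows(truth))
}

#' Simulate steady-state TDM observations for sampled patients
#'
#' For each patient, draws individual random effects `eta ~ MVN(0, omega)`
#' from the generating model, computes the steady-state concentrations at a
#' sampled peak time (shortly after the end of infusion) and trough time
#' (shortly before the end of the interval), and adds residual noise per the
#' model's residual-error model (truncated below at 0.05 mg/L). The hidden
#' ground truth (`eta`, individual clearance, and the generator's
#' `true_auc24 = daily dose / individual CL`) is returned in a separate table
#' that the estimation code paths never see.
#'
#' @param model Generating [vanco_model()].
#' @param patients Patient tibble from [sample_patients()].
#' @param config The [cohort_config()] used to sample the patients.
#' @param seed RNG seed for the observation draws (defaults to
#'   `config$seed + 1` so patients and observations use distinct streams).
#' @return List with `observations` (tibble: `id`, `time`, `conc`, `label`)
#'   and `truth` (tibble: `id`, `eta_*`, `true_cl`, `true_auc24`).
#' @export
simulate_observations <- function(model, patients, config,
                                  seed = config$seed + 1L) {
  stopifnot(inherits(model, "vanco_model"))
  withr::with_seed(seed, simulate_observations_impl(model, patients, config))
}

#' Generate a complete synthetic cohort
#'
#' Chains [sample_patients()] and [simulate_observations()] into a
#' `vanco_cohort` object: the testable stand-in for a retrospective TDM
#' dataset with one peak and one trough per patient at steady state.
#'
#' @inheritParams simulate_observations
#' @param config A [cohort_config()].
#' @return A `vanco_cohort`: list with `patients`, `observations`, `truth`
#'   tibbles, the `config`, and the generating model name.
#' @examples
#' cfg <- cohort_config("A", n = 5, seed = 1)
#' cohort <- simulate_cohort(example_model("neo_wt_pma_scr"), cfg)
#' cohort$patients
#' @export
simulate_cohort <- function(model, config) {
  stopifnot(inherits(model, "vanco_model"),
            inherits(config, "vanco_cohort_config"))
  patients <- sample_patients(config)
  sim <- simulate_observations(model, patients, config)
  structure(
    list(patients = patients, observations = sim$observations,
         truth = sim$truth, config = config, model = model$name),
    class = "vanco_cohort"
  )
}

#' @export
print.vanco_cohort <- function(x, ...) {
  cat(sprintf("<vanco_cohort> cohort %s, %d patients, generated from model '%s'\n",
              x$config$cohort, nrow(x$patients), x$model))
  cat(sprintf("  weight %.1f-%.1f kg; %d observations (1 peak + 1 trough each)\n",
              min(x$patients$weight), max(x$patients$weight),
              nrow(x$observations)))
  invisible(x)
}
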