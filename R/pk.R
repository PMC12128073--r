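#' Dosing regimens
#'
#' `ss_regimen()` describes steady-state intermittent intravenous infusion:
#' a maintenance dose (mg) infused over `tinf` hours every `tau` hours.
#' `dose_events()` builds an explicit event table (one row per administered
#' dose) for non-steady-state superposition with [conc_profile()].
#'
#' @param dose Maintenance dose in mg (> 0).
#' @param tau Interdose interval in h (> `tinf`).
#' @param tinf Infusion duration in h (> 0).
#' @param amount,start,duration Vectors describing explicit dose events
#'   (mg, start time h, infusion duration h). Events must not overlap.
#' @return `ss_regimen()`: a list with `dose`, `tau`, `tinf` and derived
#'   `daily_dose` (mg/24 h); `dose_events()`: a tibble with one row per dose.
#' @examples
#' ss_regimen(dose = 100, tau = 8, tinf = 1)
#' dose_events(amount = c(100, 100), start = c(0, 8), duration = 1)
#' @export
ss_regimen <- function(dose, tau, tinf = 1) {
  if (!is.finite(dose) || dose <= 0) abort("`dose` must be positive.")
  if (!is.finite(tinf) || tinf <= 0) abort("`tinf` must be positive.")
  if (!is.finite(tau) || tau <= tinf) {
    abort("`tau` must exceed the infusion duration `tinf`.")
  }
  list(dose = dose, tau = tau, tinf = tinf, daily_dose = dose * 24 / tau)
}

#' @rdname ss_regimen
#' @export
dose_events <- function(amount, start, duration) {
  ev <- tibble::tibble(amount = amount, start = start, duration = duration)
  if (any(!is.finite(ev$amount) | ev$amount <= 0)) abort("dose amounts must be positive.")
  if (any(!is.finite(ev$duration) | ev$duration <= 0)) abort("infusion durations must be positive.")
  ev <- dplyr::arrange(ev, .data$start)
  if (nrow(ev) > 1L) {
    ends <- ev$start + ev$duration
    if (any(ends[-nrow(ev)] > ev$start[-1L] + 1e-9)) {
      abort("dose events overlap in time.")
    }
  }
  ev
}

# Exponential-mode decomposition of the unit-bolus disposition:
# C_bolus(t) = D * sum(coef_i * exp(-lambda_i * t)). One mode for a
# one-compartment model; two (alpha/beta macro constants) for two compartments.
pk_modes <- function(params) {
  p <- as.list(params)
  for (f in c("CL", "V1")) {
    if (is.null(p[[f]]) || !is.finite(p[[f]]) || p[[f]] <= 0) {
      abort(sprintf("structural parameter `%s` must be positive.", f))
    }
  }
  two_cmt <- !is.null(p$Q) && !is.na(p$Q) && p$Q > 0 &&
    !is.null(p$V2) && !is.na(p$V2) && p$V2 > 0
  if (!two_cmt) {
    return(list(lambda = p$CL / p$V1, coef = 1 / p$V1))
  }
  k10 <- p$CL / p$V1
  k12 <- p$Q / p$V1
  k21 <- p$Q / p$V2
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  A <- (alpha - k21) / (p$V1 * (alpha - beta))
  B <- (k21 - beta) / (p$V1 * (alpha - beta))
  list(lambda = c(alpha, beta), coef = c(A, B))
}

# Concentration contributed by one infusion (rate r0 over dur) at time u after
# its start; closed form valid during (u <= dur) and after the infusion.
conc_one_dose <- function(modes, r0, dur, u) {
  if (u <= 0) return(0)
  up <- min(u, dur)
  r0 * sum(modes$coef / modes$lambda *
             (1 - exp(-modes$lambda * up)) * exp(-modes$lambda * max(u - dur, 0)))
}

#' Concentration-time profile for explicit dose events
#'
#' Closed-form plasma concentration for linear compartmental kinetics under
#' intermittent intravenous infusion, by superposition of per-dose infusion
#' solutions. A one-compartment model uses the single-exponential solution;
#' a two-compartment model the bi-exponential macro-constant solution.
#' Times before the first dose return 0.
#'
#' @param params Structural parameters: named list or one-row data frame with
#'   `CL` (L/h), `V1` (L) and optionally `Q` (L/h), `V2` (L) for two
#'   compartments (as returned by [typical_params()]).
#' @param doses Dose-event table from [dose_events()].
#' @param times Times in h since the first possible dose (vectorised, >= 0
#'   not required; negative times return 0).
#' @return Numeric vector of concentrations in mg/L.
#' @export
conc_profile <- function(params, doses, times) {
  modes <- pk_modes(params)
  vapply(times, function(t) {
    sum(vapply(seq_len(nrow(doses)), function(i) {
      conc_one_dose(modes, doses$amount[i] / doses$duration[i],
                    doses$duration[i], t - doses$start[i])
    }, numeric(1)))
  }, numeric(1))
}

#' Steady-state concentration within a dosing interval
#'
#' Closed-form steady-state concentration for intermittent infusion every
#' `tau` h, at time `t` after the start of a dose. For `0 <= t < tau` this is
#' the periodic steady-state profile (the superposition of infinitely many
#' past doses, summed as a geometric series per exponential mode). Times
#' `t >= tau` are also accepted and give the concentration when the next dose
#' is held (late troughs drawn beyond the scheduled interval).
#'
#' @inheritParams conc_profile
#' @param regimen A steady-state regimen from [ss_regimen()].
#' @param times Time(s) after dose start, h (vectorised, >= 0).
#' @return Numeric vector of concentrations in mg/L.
#' @examples
#' p <- list(CL = 0.15, V1 = 1.5)
#' conc_ss(p, ss_regimen(30, tau = 8, tinf = 1), times = c(1.5, 7.9))
#' @export
conc_ss <- function(params, regimen, times) {
  modes <- pk_modes(params)
  r0 <- regimen$dose / regimen$tinf
  tinf <- regimen$tinf
  tau <- regimen$tau
  acc <- 1 - exp(-modes$lambda * tau)
  vapply(times, function(t) {
    if (t < 0) abort("steady-state times must be non-negative.")
    cur <- 0
    tail_t <- t
    if (t < tinf) {
      cur <- r0 * sum(modes$coef / modes$lambda * (1 - exp(-modes$lambda * t)))
      tail_t <- t + tau
    }
    prior <- r0 * sum(modes$coef / modes$lambda * (1 - exp(-modes$lambda * tinf)) *
                        exp(-modes$lambda * (tail_t - tinf)) / acc)
    cur + prior
  }, numeric(1))
}
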