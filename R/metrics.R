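#' Relative bias and relative root mean squared error
#'
#' Standard external-evaluation metrics for predicted versus reference
#' exposures, both in percent:
#' `rbias = 100 * mean((pred - true) / true)` (signed accuracy) and
#' `rrmse = 100 * sqrt(mean(((pred - true) / true)^2))` (precision).
#' A model is conventionally called clinically acceptable when rBias lies
#' within ±15% and precise when rRMSE is below 20%.
#'
#' @param predicted,true Equal-length numeric vectors (mg.h/L); `true` must be
#'   strictly positive.
#' @return The metric in percent.
#' @examples
#' rbias(c(110, 90), c(100, 100)) # 0
#' rrmse(c(110, 90), c(100, 100)) # 10
#' @export
rbias <- function(predicted, true) {
  check_pred_true(predicted, true)
  100 * mean((predicted - true) / true)
}

#' @rdname rbias
#' @export
rrmse <- function(predicted, true) {
  check_pred_true(predicted, true)
  100 * sqrt(mean(((predicted - true) / true)^2))
}

check_pred_true <- function(predicted, true) {
  if (length(predicted) != length(true) || length(true) < 1L) {
    abort("`predicted` and `true` must have equal length >= 1.")
  }
  if (any(!is.finite(true) | true <= 0)) {
    abort("`true` values must be positive and finite.")
  }
  invisible(NULL)
}

#' Median-consensus reference AUC24
#'
#' The reference ("true") exposure for one patient is the sample median of
#' the AUC24 values estimated by all candidate models from that patient's
#' peak and trough concentrations. With an even number of models this is the
#' mean of the two middle values.
#'
#' @param per_model_auc Numeric vector of per-model peak+trough AUC24 values
#'   (mg.h/L) for one patient; must be non-empty.
#' @return The consensus AUC24 (mg.h/L).
#' @examples
#' consensus_true_auc(c(400, 500, 900))      # 500
#' consensus_true_auc(c(400, 500, 600, 900)) # 550
#' @export
consensus_true_auc <- function(per_model_auc) {
  if (length(per_model_auc) < 1L) {
    abort("at least one contributing model AUC is required.")
  }
  median(per_model_auc)
}

#' Dosage-advice concordance between model and reference AUC24
#'
#' A model's advice is concordant with the reference when both AUC24 values
#' fall in the same band of the 400-600 mg.h/L target window: both below
#' (both advise a dose increase), both within (neither adjusts), or both
#' above (both advise a decrease).
#'
#' @param model_auc,true_auc Positive AUC24 values (vectorised).
#' @param window Target window, default `c(400, 600)`.
#' @return Logical vector: `TRUE` where advice is concordant.
#' @examples
#' dosage_advice_concordance(350, 380)  # TRUE (both advise increase)
#' dosage_advice_concordance(390, 610)  # FALSE
#' @export
dosage_advice_concordance <- function(model_auc, true_auc, window = c(400, 600)) {
  classify_target_attainment(model_auc, window) ==
    classify_target_attainment(true_auc, window)
}

# patient-level nonparametric bootstrap percentile CI for rbias;
# deterministic given `seed`
boot_rbias_ci <- function(predicted, true, n_boot = 2000L, seed = 1L,
                          conf = 0.95) {
  r <- (predicted - true) / true
  n <- length(r)
  means <- withr::with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    colMeans(matrix(r[idx], nrow = n))
  })
  a <- (1 - conf) / 2
  100 * quantile(means, c(a, 1 - a), names = FALSE, type = 7)
}
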