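#' Evaluation settings
#'
#' Thresholds and bootstrap settings for [run_evaluation()]. Defaults follow
#' the conventional acceptability criteria for external popPK evaluation:
#' rBias within ±15%, rRMSE below 20%, AUC24 target window 400-600 mg.h/L
#' (inclusive boundaries), and a patient-level nonparametric bootstrap
#' (percentile method) for the rBias 95% confidence interval.
#'
#' @param bias_limit Acceptable absolute rBias, percent.
#' @param precision_limit Acceptable rRMSE upper bound, percent.
#' @param auc_window AUC24 target window (mg.h/L).
#' @param n_boot Bootstrap resamples for the rBias CI.
#' @param seed Seed for the bootstrap (all other pipeline steps are
#'   deterministic).
#' @param map_control [map_control()] settings passed to every fit.
#' @return A `vanco_eval_config` list.
#' @export
eval_config <- function(bias_limit = 15, precision_limit = 20,
                        auc_window = c(400, 600), n_boot = 2000L, seed = 1L,
                        map_control = vancoauc::map_control()) {
  structure(
    list(bias_limit = bias_limit, precision_limit = precision_limit,
         auc_window = auc_window, n_boot = as.integer(n_boot),
         seed = as.integer(seed), map_control = map_control),
    class = "vanco_eval_config"
  )
}

scenario_obs <- function(obs, scenario) {
  switch(scenario,
    "peak+trough" = obs,
    "peak" = dplyr::filter(obs, .data$label == "peak"),
    "trough" = dplyr::filter(obs, .data$label == "trough"),
    "a priori" = obs[0, ]
  )
}

#' Run the four-scenario evaluation
#'
#' The full evaluation design: every candidate model is fitted to every
#' patient under four TDM scenarios (peak+trough, peak only, trough only, and
#' a priori from covariates alone), each fit yields a steady-state
#' `AUC24 = daily dose / individual CL`, the per-patient reference ("true")
#' AUC24 is the median across models of the peak+trough estimates, and each
#' model x scenario cell is scored against that reference with rBias
#' (bootstrap 95% CI), rRMSE, acceptability flags, and dosage-advice
#' concordance over the 400-600 mg.h/L window.
#'
#' Patients lacking a peak or trough observation are excluded with a log
#' entry; non-converged fits are excluded per model x scenario with `n`
#' reported.
#'
#' @param models A [vanco_model()] or list of them (the candidate ensemble).
#' @param cohort A `vanco_cohort` from [simulate_cohort()], or any list with
#'   `patients` and `observations` tibbles in the same layout (e.g. from
#'   [read_dataset()]). Hidden truth columns, if present, are never used.
#' @param config An [eval_config()].
#' @return A `vanco_eval`: list with
#'   * `scenario_table` — one row per patient x model x scenario with `auc24`;
#'   * `truth` — per-patient consensus `true_auc24` (with min/max of the
#'     contributing model values);
#'   * `metrics` — per model x scenario: `n`, `rbias`, `rbias_lo`, `rbias_hi`,
#'     `rrmse`, acceptability flags, `pct_concordant_advice`,
#'     `pct_no_adjustment`;
#'   * `scenario_summary` — median/IQR of AUC24 per scenario;
#'   * `log` — exclusion log (one record per excluded patient/fit);
#'   supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' \donttest{
#' cfg <- cohort_config("A", n = 10, seed = 7)
#' cohort <- simulate_cohort(example_model("neo_wt_pma_scr"), cfg)
#' ev <- run_evaluation(example_models("A"), cohort,
#'                      eval_config(n_boot = 200))
#' tidy(ev)
#' }
#' @export
run_evaluation <- function(models, cohort, config = eval_config()) {
  if (inherits(models, "vanco_model")) models <- list(models)
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, logical(1), "vanco_model")))
  names(models) <- vapply(models, `[[`, character(1), "name")
  patients <- dplyr::arrange(tibble::as_tibble(cohort$patients), .data$id)
  observations <- tibble::as_tibble(cohort$observations)
  log <- character()

  complete <- observations |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(ok = any(.data$label == "peak") & any(.data$label == "trough"),
                     .groups = "drop")
  bad_ids <- complete$id[!complete$ok]
  bad_ids <- union(bad_ids, setdiff(patients$id, complete$id))
  if (length(bad_ids)) {
    log <- c(log, sprintf("patient %s excluded: missing peak and/or trough observation",
                          bad_ids))
    patients <- dplyr::filter(patients, !.data$id %in% bad_ids)
  }
  if (nrow(patients) == 0L) abort("no patients with complete observations.")
  obs_by_id <- split(observations, observations$id)

  rows <- vector("list", nrow(patients) * length(models) * length(SCENARIOS))
  r <- 0L
  for (m in models) {
    for (i in seq_len(nrow(patients))) {
      pat <- patients[i, ]
      reg <- ss_regimen(pat$dose, pat$tau, pat$tinf)
      obs_full <- obs_by_id[[as.character(pat$id)]]
      for (sc in SCENARIOS) {
        fit <- estimate_map(m, pat, reg, scenario_obs(obs_full, sc),
                            scenario = sc, control = config$map_control)
        if (!fit$converged) {
          log <- c(log, sprintf("patient %d, model %s, scenario '%s': fit did not converge; excluded",
                                pat$id, m$name, sc))
        }
        r <- r + 1L
        rows[[r]] <- tibble::tibble(
          id = pat$id, model = m$name, scenario = sc,
          auc24 = reg$daily_dose / fit$params$CL,
          cl = fit$params$CL, ofv = fit$ofv, converged = fit$converged
        )
      }
    }
  }
  scenario_table <- dplyr::bind_rows(rows) |>
    dplyr::mutate(scenario = factor(.data$scenario, levels = SCENARIOS))
  if (length(log)) {
    warn(sprintf("%d exclusion(s) during evaluation; see $log.", length(log)))
  }
  ev <- build_eval(scenario_table, config)
  ev$log <- log
  ev
}

# consensus truth + metrics from an already-computed scenario table
build_eval <- function(scenario_table, config) {
  truth <- scenario_table |>
    dplyr::filter(.data$scenario == "peak+trough", .data$converged) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(true_auc24 = consensus_true_auc(.data$auc24),
                     n_models = dplyr::n(),
                     auc_min = min(.data$auc24), auc_max = max(.data$auc24),
                     .groups = "drop")

  scored <- scenario_table |>
    dplyr::filter(.data$converged) |>
    dplyr::inner_join(truth, by = "id") |>
    dplyr::arrange(.data$id)

  metrics <- scored |>
    dplyr::group_by(.data$model, .data$scenario) |>
    dplyr::group_modify(function(d, key) {
      ci <- boot_rbias_ci(d$auc24, d$true_auc24, config$n_boot, config$seed)
      concord <- dosage_advice_concordance(d$auc24, d$true_auc24, config$auc_window)
      both_within <- classify_target_attainment(d$auc24, config$auc_window) == "within" &
        classify_target_attainment(d$true_auc24, config$auc_window) == "within"
      tibble::tibble(
        n = nrow(d),
        rbias = rbias(d$auc24, d$true_auc24),
        rbias_lo = ci[1], rbias_hi = ci[2],
        rrmse = rrmse(d$auc24, d$true_auc24),
        pct_concordant_advice = 100 * mean(concord),
        pct_no_adjustment = 100 * mean(both_within)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      acceptable_bias = abs(.data$rbias) <= config$bias_limit,
      acceptable_precision = .data$rrmse < config$precision_limit
    )

  scenario_summary <- scored |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(
      n = dplyr::n(),
      auc_median = median(.data$auc24),
      auc_q25 = quantile(.data$auc24, 0.25, names = FALSE),
      auc_q75 = quantile(.data$auc24, 0.75, names = FALSE),
      .groups = "drop"
    )

  structure(
    list(scenario_table = scenario_table, truth = truth, metrics = metrics,
         scenario_summary = scenario_summary, config = config,
         log = character()),
    class = "vanco_eval"
  )
}

#' @export
print.vanco_eval <- function(x, ...) {
  cat(sprintf("<vanco_eval> %d patients x %d models x 4 scenarios\n",
              nrow(x$truth), length(unique(x$scenario_table$model))))
  cat(sprintf("  consensus true AUC24: median %.0f mg.h/L (IQR %.0f-%.0f)\n",
              median(x$truth$true_auc24),
              quantile(x$truth$true_auc24, 0.25),
              quantile(x$truth$true_auc24, 0.75)))
  print(x$metrics, n = Inf)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.vanco_eval <- function(x, ...) x$metrics

#' @exportS3Method generics::glance
glance.vanco_eval <- function(x, ...) {
  tibble::tibble(
    n_patients = nrow(x$truth),
    n_models = length(unique(x$scenario_table$model)),
    median_true_auc24 = median(x$truth$true_auc24),
    pct_fits_converged = 100 * mean(x$scenario_table$converged)
  )
}

#' Plot evaluation metrics per model and scenario
#'
#' Accuracy (rBias, with bootstrap 95% CI) and precision (rRMSE) per model
#' and sampling scenario, with the acceptability thresholds as dashed lines
#' (±15% for rBias, 20% for rRMSE by default).
#'
#' @param object A `vanco_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.vanco_eval <- function(object, ...) {
  cfg <- object$config
  long <- dplyr::bind_rows(
    object$metrics |>
      dplyr::transmute(.data$model, .data$scenario, metric = "rBias (%)",
                       value = .data$rbias, lo = .data$rbias_lo, hi = .data$rbias_hi),
    object$metrics |>
      dplyr::transmute(.data$model, .data$scenario, metric = "rRMSE (%)",
                       value = .data$rrmse, lo = NA_real_, hi = NA_real_)
  )
  thresholds <- tibble::tibble(
    metric = c("rBias (%)", "rBias (%)", "rRMSE (%)"),
    y = c(-cfg$bias_limit, cfg$bias_limit, cfg$precision_limit)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$scenario, y = .data$value,
                                     colour = .data$model, group = .data$model)) +
    ggplot2::geom_hline(data = thresholds, ggplot2::aes(yintercept = .data$y),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.15, na.rm = TRUE,
                           position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "TDM scenario", y = NULL, colour = "model") +
    ggplot2::theme_minimal()
}

#' Model versus reference AUC24 with target-window shading
#'
#' Scatter of model-estimated AUC24 (one scenario) against the consensus
#' reference AUC24, faceted by model, with the 400-600 mg.h/L target window
#' shaded on both axes. Points where dosage advice agrees (same band on both
#' axes) are drawn in green, discordant points in red.
#'
#' @param eval A `vanco_eval`.
#' @param scenario Scenario to display (default `"trough"`).
#' @return A ggplot object.
#' @export
plot_auc_concordance <- function(eval, scenario = "trough") {
  cfg <- eval$config
  w <- cfg$auc_window
  d <- eval$scenario_table |>
    dplyr::filter(.data$scenario == !!scenario, .data$converged) |>
    dplyr::inner_join(eval$truth, by = "id") |>
    dplyr::mutate(concordant = dosage_advice_concordance(
      .data$auc24, .data$true_auc24, w))
  bands <- tibble::tibble(lo = c(0, w[1], w[2]), hi = c(w[1], w[2], Inf))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$true_auc24, y = .data$auc24)) +
    ggplot2::geom_rect(data = bands, inherit.aes = FALSE,
                       ggplot2::aes(xmin = .data$lo, xmax = .data$hi,
                                    ymin = .data$lo, ymax = .data$hi),
                       fill = "grey85") +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$concordant), size = 1.5) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "forestgreen",
                                            `FALSE` = "firebrick"),
                                 labels = c(`TRUE` = "concordant",
                                            `FALSE` = "discordant")) +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "reference AUC24 (mg·h/L)",
                  y = sprintf("model AUC24, %s scenario (mg·h/L)", scenario),
                  colour = "dosage advice") +
    ggplot2::theme_minimal()
}
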