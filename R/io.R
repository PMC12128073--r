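#' Write and read rectangular TDM datasets
#'
#' Cohorts are exchanged as CSV files in a NONMEM-style rectangular layout:
#' one dose row per patient (`EVID = 1`, `AMT` mg, `RATE` mg/h, `DUR` h,
#' `II` = interdose interval h, `SS = 1` for steady state, `MDV = 1`) followed
#' by observation rows (`EVID = 0`, `DV` mg/L, `MDV = 0`), with covariate
#' columns (`WT` kg, `PNA` d, `GA` wk, `PMA` wk, `HT` cm, `SEX`, `SCR`
#' µmol/L, `CRCL`) repeated on every row. Times are hours from the first dose
#' of the steady-state day, so the observation "time after dose" equals
#' `TIME`.
#'
#' `read_dataset()` validates on load: missing mandatory columns fail with a
#' message listing them; observation rows with non-positive `DV` and patients
#' with overlapping infusion events are rejected with row-numbered log
#' messages (emitted as warnings) and excluded, mirroring explicit data
#' cleaning of mistaken entries.
#'
#' @param cohort A `vanco_cohort` (or list with `patients` and `observations`).
#' @param path CSV file path.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns a list with `patients` and `observations` tibbles in the layout
#'   of [simulate_cohort()], directly usable by [run_evaluation()].
#' @export
write_dataset <- function(cohort, path) {
  p <- cohort$patients
  sex_code <- ifelse(p$sex == "female", 0L, 1L)
  dose_rows <- tibble::tibble(
    ID = p$id, TIME = 0, EVID = 1L, AMT = p$dose, RATE = p$dose / p$tinf,
    DUR = p$tinf, II = p$tau, SS = 1L, DV = NA_real_, MDV = 1L,
    LABEL = NA_character_,
    WT = p$weight, PNA = p$pna, GA = p$ga, PMA = p$pma, HT = p$height,
    SEX = sex_code, SCR = p$scr, CRCL = p$crcl, COHORT = p$cohort
  )
  o <- dplyr::inner_join(cohort$observations,
                         dplyr::mutate(p, SEXC = sex_code), by = "id")
  obs_rows <- tibble::tibble(
    ID = o$id, TIME = o$time, EVID = 0L, AMT = NA_real_, RATE = NA_real_,
    DUR = NA_real_, II = NA_real_, SS = NA_integer_, DV = o$conc, MDV = 0L,
    LABEL = o$label,
    WT = o$weight, PNA = o$pna, GA = o$ga, PMA = o$pma, HT = o$height,
    SEX = o$SEXC, SCR = o$scr, CRCL = o$crcl, COHORT = o$cohort
  )
  rows <- dplyr::bind_rows(dose_rows, obs_rows) |>
    dplyr::arrange(.data$ID, .data$TIME, dplyr::desc(.data$EVID))
  readr::write_csv(rows, path, na = "")
  invisible(path)
}

DATASET_COLUMNS <- c("ID", "TIME", "EVID", "AMT", "DUR", "II", "DV", "MDV",
                     "WT", "PNA", "SCR")

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA", "."))
  missing_cols <- setdiff(DATASET_COLUMNS, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("dataset '%s' is missing mandatory column(s): %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  raw$row <- seq_len(nrow(raw)) + 1L  # file line numbers (header = line 1)
  log <- character()

  is_dose <- !is.na(raw$AMT) & raw$AMT > 0
  is_obs <- !is.na(raw$DV)
  conflict <- is_dose & is_obs
  if (any(conflict)) {
    log <- c(log, sprintf("row %d rejected: both AMT and DV present", raw$row[conflict]))
  }
  bad_dv <- is_obs & !conflict & raw$DV <= 0
  if (any(bad_dv)) {
    log <- c(log, sprintf("row %d rejected: non-positive DV", raw$row[bad_dv]))
  }
  neither <- !is_dose & !is_obs
  if (any(neither)) {
    log <- c(log, sprintf("row %d rejected: neither dose nor observation", raw$row[neither]))
  }
  keep <- !(conflict | bad_dv | neither)
  dat <- raw[keep, ]
  is_dose <- is_dose[keep]

  bad_ids <- integer()
  for (pid in unique(dat$ID)) {
    d <- dat[dat$ID == pid & is_dose, ]
    if (nrow(d) == 0L) {
      log <- c(log, sprintf("patient %s rejected: no dose row", pid))
      bad_ids <- c(bad_ids, pid)
      next
    }
    d <- d[order(d$TIME), ]
    if (any(is.na(d$DUR) | d$DUR <= 0)) {
      log <- c(log, sprintf("patient %s rejected: dose row without positive DUR", pid))
      bad_ids <- c(bad_ids, pid)
      next
    }
    if (nrow(d) > 1L &&
        any(d$TIME[-nrow(d)] + d$DUR[-nrow(d)] > d$TIME[-1L] + 1e-9)) {
      log <- c(log, sprintf("patient %s rejected: overlapping infusion events (rows %s)",
                            pid, paste(d$row, collapse = ",")))
      bad_ids <- c(bad_ids, pid)
    }
    if (any(is.na(d$II) | d$II <= d$DUR)) {
      log <- c(log, sprintf("patient %s rejected: missing or invalid interdose interval II",
                            pid))
      bad_ids <- c(bad_ids, pid)
    }
  }
  dat <- dat[!dat$ID %in% bad_ids, ]
  is_dose <- !is.na(dat$AMT) & dat$AMT > 0
  if (length(log)) {
    warn(paste0("dataset validation rejected rows/patients:\n  ",
                paste(log, collapse = "\n  ")))
  }
  if (nrow(dat) == 0L) abort(sprintf("dataset '%s' has no valid records.", path))

  doses <- dat[is_dose, ]
  first_dose <- doses[!duplicated(doses$ID), ]
  num_col <- function(col) {
    if (col %in% names(first_dose)) as.numeric(first_dose[[col]])
    else rep(NA_real_, nrow(first_dose))
  }
  patients <- tibble::tibble(
    id = first_dose$ID,
    cohort = if ("COHORT" %in% names(first_dose)) first_dose$COHORT else NA_character_,
    weight = as.numeric(first_dose$WT),
    pna = as.numeric(first_dose$PNA),
    ga = num_col("GA"),
    pma = num_col("PMA"),
    height = num_col("HT"),
    sex = if ("SEX" %in% names(first_dose)) {
      ifelse(first_dose$SEX == 0, "female", "male")
    } else NA_character_,
    scr = as.numeric(first_dose$SCR),
    crcl = num_col("CRCL"),
    dose = first_dose$AMT, tau = first_dose$II, tinf = first_dose$DUR,
    daily_dose = first_dose$AMT * 24 / first_dose$II
  )
  obs <- dat[!is_dose, ]
  observations <- tibble::tibble(
    id = obs$ID, time = obs$TIME, conc = obs$DV,
    label = if ("LABEL" %in% names(obs) && !all(is.na(obs$LABEL))) obs$LABEL
            else infer_obs_labels(obs, patients)
  )
  list(patients = patients, observations = observations, log = log)
}

# fall back to position within the interval when no explicit labels are stored
infer_obs_labels <- function(obs, patients) {
  tau <- patients$tau[match(obs$ID, patients$id)]
  ifelse(obs$TIME < tau / 2, "peak", "trough")
}

#' Write and read the hidden-truth sidecar table
#'
#' The generator's ground truth (individual random effects, clearance, and
#' AUC24) is kept out of the analysis dataset and exchanged as a separate CSV
#' keyed by patient id.
#'
#' @param cohort A `vanco_cohort`.
#' @param path CSV file path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` a tibble.
#' @export
write_truth <- function(cohort, path) {
  readr::write_csv(cohort$truth, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write the evaluation output tables
#'
#' Writes the tidy CSV outputs of a [run_evaluation()] result: the scenario
#' table, the consensus truth, the metrics table, and the per-scenario
#' summary.
#'
#' @param eval A `vanco_eval`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_eval <- function(eval, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    scenario_table = file.path(dir, "scenario_table.csv"),
    consensus_truth = file.path(dir, "consensus_truth.csv"),
    metrics = file.path(dir, "metrics.csv"),
    scenario_summary = file.path(dir, "scenario_summary.csv")
  )
  readr::write_csv(eval$scenario_table, files[["scenario_table"]])
  readr::write_csv(eval$truth, files[["consensus_truth"]])
  readr::write_csv(eval$metrics, files[["metrics"]])
  readr::write_csv(eval$scenario_summary, files[["scenario_summary"]])
  if (length(eval$log)) {
    writeLines(eval$log, file.path(dir, "exclusions.log"))
  }
  invisible(files)
}
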