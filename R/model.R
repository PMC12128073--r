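#' Define a population pharmacokinetic model
#'
#' A `vanco_model` describes one population PK model for intermittent
#' intravenous vancomycin: compartmental structure (1 or 2 compartments with
#' first-order elimination), fixed-effect typical values with multiplicative
#' covariate terms, a lognormal interindividual-variability (IIV) covariance
#' matrix, and a residual-error model. Models are plain declarative objects;
#' they can be written to and read from YAML files with [write_model()] /
#' [read_model()].
#'
#' Each structural parameter (CL in L/h, V1 in L, and for two-compartment
#' models Q in L/h and V2 in L) has a typical value `theta` and a list of
#' covariate terms. A term is a list with a `kind` and its parameters:
#'
#' * `power`: `(x / ref)^exp` — includes fixed-exponent allometric scaling
#'   (e.g. `exp = 0.75` on weight).
#' * `hill_maturation`: `x^gamma / (x^gamma + tm50^gamma)` — sigmoidal
#'   maturation, conventionally on postmenstrual age (`tm50` in weeks).
#' * `linear`: `1 + slope * (x - ref)`.
#'
#' The individual parameter model is `P_i = theta_P * prod(terms) * exp(eta_P)`
#' with `eta ~ MVN(0, omega)` for the parameters named in `omega`.
#'
#' @param name Model name (used in tables and file names).
#' @param n_compartments 1 or 2.
#' @param parameters Named list over structural parameters (`CL`, `V1`, and for
#'   2-compartment models `Q`, `V2`); each element a list with `theta` (typical
#'   value) and optionally `terms` (list of covariate terms, see Details).
#' @param omega IIV covariance matrix (lognormal scale) with dimnames naming
#'   the structural parameters carrying random effects; must be symmetric
#'   positive semidefinite. A named numeric vector of variances is accepted
#'   as shorthand for a diagonal matrix.
#' @param residual Residual-error model: list with `type` one of `"additive"`,
#'   `"proportional"`, `"combined"`, and `sigma_add` (mg/L) and/or
#'   `sigma_prop` (fraction) as required.
#' @param description Optional free-text description.
#' @return An object of class `vanco_model`.
#' @seealso [typical_params()], [read_model()], [example_models()]
#' @examples
#' m <- vanco_model(
#'   name = "demo",
#'   parameters = list(
#'     CL = list(theta = 4, terms = list(
#'       list(kind = "power", covariate = "weight", ref = 70, exp = 0.75)
#'     )),
#'     V1 = list(theta = 42, terms = list(
#'       list(kind = "power", covariate = "weight", ref = 70, exp = 1)
#'     ))
#'   ),
#'   omega = c(CL = 0.09, V1 = 0.09),
#'   residual = list(type = "proportional", sigma_prop = 0.2)
#' )
#' typical_params(m, list(weight = 2.5))
#' @export
vanco_model <- function(name, n_compartments = 1, parameters, omega, residual,
                        description = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a non-empty string.")
  }
  if (!n_compartments %in% c(1L, 2L)) {
    abort("`n_compartments` must be 1 or 2.")
  }
  required <- if (n_compartments == 2L) c("CL", "V1", "Q", "V2") else c("CL", "V1")
  missing_p <- setdiff(required, names(parameters))
  if (length(missing_p)) {
    abort(sprintf("model '%s': missing structural parameter(s): %s",
                  name, paste(missing_p, collapse = ", ")))
  }
  for (p in names(parameters)) {
    th <- parameters[[p]]$theta
    if (!is.numeric(th) || length(th) != 1L || !is.finite(th) || th <= 0) {
      abort(sprintf("model '%s': theta for %s must be a positive number.", name, p))
    }
    for (term in parameters[[p]]$terms %||% list()) {
      validate_term(term, name, p)
    }
  }
  if (is.vector(omega) && !is.null(names(omega))) {
    omega <- diag(omega, length(omega)) |>
      `dimnames<-`(list(names(omega), names(omega)))
  }
  omega <- as.matrix(omega)
  if (is.null(rownames(omega)) && !is.null(colnames(omega))) {
    rownames(omega) <- colnames(omega)
  }
  if (is.null(rownames(omega))) {
    abort(sprintf("model '%s': omega must carry dimnames naming the random effects.", name))
  }
  colnames(omega) <- rownames(omega)
  if (!isSymmetric(unname(omega), tol = 1e-8)) {
    abort(sprintf("model '%s': omega must be symmetric.", name))
  }
  if (min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    abort(sprintf("model '%s': omega must be positive semidefinite.", name))
  }
  bad <- setdiff(rownames(omega), names(parameters))
  if (length(bad)) {
    abort(sprintf("model '%s': omega names random effects on unknown parameters: %s",
                  name, paste(bad, collapse = ", ")))
  }
  residual <- validate_residual(residual, name)
  structure(
    list(name = name, n_compartments = as.integer(n_compartments),
         parameters = parameters, omega = omega, residual = residual,
         description = description),
    class = "vanco_model"
  )
}

KNOWN_COVARIATES <- c("weight", "pna", "ga", "pma", "height", "sex", "scr", "crcl")
TERM_KINDS <- c("power", "hill_maturation", "linear")

validate_term <- function(term, model, param) {
  kind <- term$kind
  if (is.null(kind) || !kind %in% TERM_KINDS) {
    abort(sprintf("model '%s' (%s): unknown covariate term kind '%s'.",
                  model, param, kind %||% "<missing>"))
  }
  if (is.null(term$covariate) || !term$covariate %in% KNOWN_COVARIATES) {
    abort(sprintf("model '%s' (%s): term references unknown covariate '%s'.",
                  model, param, term$covariate %||% "<missing>"))
  }
  need <- switch(kind,
    power = c("ref", "exp"),
    hill_maturation = c("tm50", "gamma"),
    linear = c("ref", "slope")
  )
  miss <- need[!vapply(need, function(f) is.numeric(term[[f]]) && is.finite(term[[f]]),
                       logical(1))]
  if (length(miss)) {
    abort(sprintf("model '%s' (%s): %s term needs numeric field(s): %s",
                  model, param, kind, paste(miss, collapse = ", ")))
  }
  invisible(term)
}

validate_residual <- function(residual, model) {
  type <- residual$type %||% "<missing>"
  if (!type %in% c("additive", "proportional", "combined")) {
    abort(sprintf("model '%s': residual type must be additive, proportional or combined.",
                  model))
  }
  sa <- residual$sigma_add %||% 0
  sp <- residual$sigma_prop %||% 0
  ok <- switch(type,
    additive = sa > 0,
    proportional = sp > 0,
    combined = sa >= 0 && sp >= 0 && (sa + sp) > 0
  )
  if (!isTRUE(ok)) {
    abort(sprintf("model '%s': residual standard deviations do not define a positive variance.",
                  model))
  }
  list(type = type, sigma_add = sa, sigma_prop = sp)
}

#' @export
print.vanco_model <- function(x, ...) {
  cat(sprintf("<vanco_model> %s (%d-compartment)\n", x$name, x$n_compartments))
  for (p in names(x$parameters)) {
    terms <- x$parameters[[p]]$terms %||% list()
    lbl <- if (length(terms)) {
      paste(vapply(terms, function(t) paste0(t$kind, "(", t$covariate, ")"),
                   character(1)), collapse = " * ")
    } else "-"
    cat(sprintf("  %-3s theta = %g, terms: %s\n", p, x$parameters[[p]]$theta, lbl))
  }
  cat(sprintf("  IIV on: %s; residual: %s (add %g mg/L, prop %g)\n",
              paste(rownames(x$omega), collapse = ", "),
              x$residual$type, x$residual$sigma_add, x$residual$sigma_prop))
  invisible(x)
}

cov_value <- function(covariates, name, model) {
  covariates <- as.list(covariates)
  x <- covariates[[name]]
  if (name == "crcl" && (is.null(x) || is.na(x))) {
    need <- c("height", "scr", "pna")
    have <- vapply(need, function(f) !is.null(covariates[[f]]) && !is.na(covariates[[f]]),
                   logical(1))
    if (!all(have)) {
      abort(sprintf(
        "model '%s' needs creatinine clearance, and covariate(s) %s required to derive it are missing.",
        model, paste(need[!have], collapse = ", ")))
    }
    return(crcl_estimate(covariates$height, covariates$scr, covariates$pna))
  }
  if (is.null(x) || is.na(x)) {
    abort(sprintf("model '%s' requires covariate '%s', which is missing.", model, name))
  }
  x
}

eval_term <- function(term, covariates, model) {
  x <- cov_value(covariates, term$covariate, model)
  m <- switch(term$kind,
    power = (x / term$ref)^term$exp,
    hill_maturation = x^term$gamma / (x^term$gamma + term$tm50^term$gamma),
    linear = 1 + term$slope * (x - term$ref)
  )
  if (!is.finite(m) || m <= 0) {
    abort(sprintf("model '%s': %s term on '%s' evaluated to a non-positive multiplier (%g).",
                  model, term$kind, term$covariate, m))
  }
  m
}

#' Typical (population) structural parameters for a patient
#'
#' Evaluates the fixed-effect part of a model for one patient:
#' `P = theta_P * prod(covariate-term multipliers)` for each structural
#' parameter. Random effects are not applied (equivalently, `eta = 0`).
#'
#' @param model A [vanco_model()].
#' @param covariates Named list or one-row data frame of patient covariates
#'   (`weight` kg, `pna` days, `ga` weeks, `pma` weeks, `height` cm, `scr`
#'   µmol/L, `crcl` mL/min/1.73 m^2). `crcl` is derived via [crcl_estimate()]
#'   when a model needs it and it is absent.
#' @return One-row tibble with columns `CL`, `V1` and, for two-compartment
#'   models, `Q` and `V2` (otherwise `NA`).
#' @export
typical_params <- function(model, covariates) {
  stopifnot(inherits(model, "vanco_model"))
  if (is.data.frame(covariates)) {
    stopifnot(nrow(covariates) == 1L)
    covariates <- as.list(covariates)
  }
  vals <- vapply(names(model$parameters), function(p) {
    spec <- model$parameters[[p]]
    mult <- prod(vapply(spec$terms %||% list(), eval_term, numeric(1),
                        covariates = covariates, model = model$name))
    spec$theta * mult
  }, numeric(1))
  tibble::tibble(
    CL = vals[["CL"]], V1 = vals[["V1"]],
    Q = if ("Q" %in% names(vals)) vals[["Q"]] else NA_real_,
    V2 = if ("V2" %in% names(vals)) vals[["V2"]] else NA_real_
  )
}

#' Read and write model files
#'
#' Models are stored as YAML documents, one model per file, mirroring the
#' fields of [vanco_model()]. `read_model()` validates on load and fails with
#' an informative message on schema violations; `write_model()` writes with
#' 15 significant digits so that a model round-trips through its file
#' representation exactly.
#'
#' @param path File path of a model YAML document.
#' @param model A [vanco_model()].
#' @return `read_model()` returns a `vanco_model`; `write_model()` returns
#'   `path` invisibly.
#' @export
read_model <- function(path) {
  doc <- yaml::read_yaml(path)
  need <- c("name", "n_compartments", "parameters", "omega", "residual")
  miss <- setdiff(need, names(doc))
  if (length(miss)) {
    abort(sprintf("model file '%s' is missing field(s): %s",
                  path, paste(miss, collapse = ", ")))
  }
  om <- doc$omega
  omega <- do.call(rbind, lapply(om$matrix, as.numeric))
  dimnames(omega) <- list(om$labels, om$labels)
  vanco_model(
    name = doc$name,
    n_compartments = doc$n_compartments,
    parameters = doc$parameters,
    omega = omega,
    residual = doc$residual,
    description = doc$description
  )
}

#' @rdname read_model
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "vanco_model"))
  doc <- list(
    name = model$name,
    description = model$description,
    n_compartments = model$n_compartments,
    parameters = model$parameters,
    omega = list(
      labels = rownames(model$omega),
      matrix = lapply(seq_len(nrow(model$omega)), function(i) unname(model$omega[i, ]))
    ),
    residual = model$residual
  )
  doc <- doc[!vapply(doc, is.null, logical(1))]
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' Bundled example models
#'
#' The package ships illustrative model files under
#' `system.file("models", package = "vancoauc")` mirroring the covariate
#' composition typical of published pediatric vancomycin models: neonatal
#' (cohort A) one-compartment models with weight, postmenstrual-age maturation
#' and serum creatinine on clearance, and pediatric (cohort B) models with
#' allometric weight (plus serum creatinine or creatinine clearance) on
#' clearance, one of them two-compartmental. Their parameter values are
#' illustrative, chosen to produce realistic pediatric vancomycin exposures;
#' they are not re-encodings of any published model.
#'
#' @param cohort Optional `"A"` or `"B"` to select the models suitable for one
#'   cohort; default returns all bundled models.
#' @return `example_models()`: named list of [vanco_model()] objects;
#'   `example_model()`: a single model by name.
#' @export
example_models <- function(cohort = NULL) {
  dir <- system.file("models", package = "vancoauc")
  paths <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  models <- lapply(paths, read_model)
  names(models) <- vapply(models, `[[`, character(1), "name")
  if (!is.null(cohort)) {
    cohort <- match.arg(cohort, c("A", "B"))
    keep <- if (cohort == "A") grepl("^neo_", names(models)) else grepl("^ped_", names(models))
    models <- models[keep]
  }
  models
}

#' @rdname example_models
#' @param name Name of a bundled model (file basename without extension).
#' @export
example_model <- function(name) {
  path <- system.file("models", paste0(name, ".yaml"), package = "vancoauc")
  if (!nzchar(path)) {
    abort(sprintf("no bundled model named '%s'; see example_models().", name))
  }
  read_model(path)
}
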