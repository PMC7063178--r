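#' @useDynLib erins, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif setNames
#' @importFrom utils read.csv write.csv head tail
NULL

SPECIES_ROLES <- c("stress_input_proxy", "upr_sensor", "upr_effector",
                   "inflammatory", "insulin_cascade", "lipid_second_messenger",
                   "readout_total", "readout_phospho")

TERM_SHAPES <- c("input_drive", "activation", "decay")

#' Construct a rate term
#'
#' A rate term is one additive contribution to a species' time derivative,
#' expressed in the three-shape grammar used throughout the package:
#'
#' * `input_drive`: `+k * u(driver)` — an external input feeding a species.
#' * `activation`: `+k * prod(factors) * prod(1 + F * accelerator)` — mass
#'   action in the listed factor species, optionally accelerated by
#'   `(1 + F x)` binding terms.
#' * `decay`: `-k * x(decay_of) * prod(factors) / prod(1 + F * inhibitor)` —
#'   first order consumption, optionally co-driven by extra factor species
#'   (mixed decay) and slowed by `(1 + F x)` feedback divisors.
#'
#' Rate (`k`) and binding (`F`) constants may be given as literal nonnegative
#' numbers or as names resolved against the model's parameter set.
#'
#' @param shape one of `"input_drive"`, `"activation"`, `"decay"`.
#' @param k rate constant (name or nonnegative number).
#' @param driver input name (`input_drive` only).
#' @param factors character vector of species multiplied into the rate.
#' @param accelerators list of `list(species=, F=)` multiplying as `(1+F*x)`.
#' @param decay_of species undergoing decay (`decay` only).
#' @param inhibitors list of `list(species=, F=)` dividing as `(1+F*x)`.
#' @return an object of class `erins_term`.
#' @export
rate_term <- function(shape, k, driver = NULL, factors = character(),
                      accelerators = list(), decay_of = NULL,
                      inhibitors = list()) {
  if (!shape %in% TERM_SHAPES)
    validation_error(sprintf("unknown term shape '%s' (expected one of %s)",
                             shape, cstr(TERM_SHAPES)))
  if (shape == "input_drive" && is.null(driver))
    validation_error("input_drive term needs a 'driver' input name")
  if (shape == "decay" && is.null(decay_of))
    validation_error("decay term needs a 'decay_of' species name")
  structure(list(shape = shape, k = k, driver = driver,
                 factors = as.character(factors),
                 accelerators = accelerators,
                 decay_of = decay_of, inhibitors = inhibitors),
            class = "erins_term")
}

#' @export
print.erins_term <- function(x, ...) {
  k <- if (is.character(x$k)) x$k else format(x$k)
  body <- switch(x$shape,
    input_drive = sprintf("+%s * u(%s)", k, x$driver),
    activation = {
      acc <- vapply(x$accelerators, function(a)
        sprintf("(1 + %s*%s)", if (is.character(a$F)) a$F else format(a$F),
                a$species), "")
      paste0("+", paste(c(k, x$factors, acc), collapse = " * "))
    },
    decay = {
      inh <- vapply(x$inhibitors, function(a)
        sprintf("(1 + %s*%s)", if (is.character(a$F)) a$F else format(a$F),
                a$species), "")
      num <- paste(c(k, x$decay_of, x$factors), collapse = " * ")
      if (length(inh)) sprintf("-%s / %s", num, paste(inh, collapse = " "))
      else paste0("-", num)
    })
  cat(body, "\n")
  invisible(x)
}

term_species_refs <- function(term) {
  unique(c(term$factors,
           vapply(term$accelerators, `[[`, "", "species"),
           term$decay_of %||% character(),
           vapply(term$inhibitors, `[[`, "", "species")))
}

resolve_const <- function(x, params, what = "constant") {
  if (is.character(x)) {
    v <- params$rate_constants[[x]] %||% params$binding_constants[[x]]
    if (is.null(v))
      lookup_error(sprintf("%s '%s' not found in parameter set", what, x))
    v
  } else {
    if (!is_scalar_number(x) || x < 0)
      validation_error(sprintf("%s must be a finite nonnegative number", what))
    x
  }
}

#' Parse and validate a declarative model specification
#'
#' Reads a structured configuration (a JSON file, JSON string, or an already
#' parsed list) declaring the species roster, the per-species rate terms,
#' the parameter set and the readout definitions, and returns a validated
#' `erins_model`.
#'
#' @param config path to a JSON document, a JSON string, or a list with
#'   elements `species`, `terms`, `parameters`, `inputs`, `readouts`.
#' @return an object of class `erins_model`.
#' @export
parse_model_spec <- function(config) {
  doc <- read_config(config)
  for (sec in c("species", "terms", "parameters"))
    if (is.null(doc[[sec]]))
      config_error(sprintf("model config is missing the '%s' section", sec))

  species <- do.call(rbind, lapply(doc$species, function(s) {
    data.frame(name = s$name, role = s$role %||% "insulin_cascade",
               initial = s$initial %||% 1.05,
               lower = s$lower %||% 0, upper = s$upper %||% 25,
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(species$name))
    validation_error(sprintf("duplicate species names: %s",
                             cstr(unique(species$name[duplicated(species$name)]))))
  bad_role <- setdiff(species$role, SPECIES_ROLES)
  if (length(bad_role))
    validation_error(sprintf("unknown species roles: %s", cstr(bad_role)))
  with(species, {
    if (any(lower > upper)) validation_error("species lower bound above upper bound")
    if (any(initial < lower | initial > upper))
      validation_error("species initial value outside its bounds")
  })

  params <- doc$parameters
  params$interval <- as.numeric(params$interval %||% c(0, 5))
  params$rate_constants <- lapply(params$rate_constants %||% list(), as.numeric)
  params$binding_constants <- lapply(params$binding_constants %||% list(), as.numeric)
  params$amplify1 <- params$amplify1 %||% 1.5
  params$amplify2 <- params$amplify2 %||% 1.0
  chk <- unlist(c(params$rate_constants, params$binding_constants))
  if (length(chk) && (any(!is.finite(chk)) || any(chk < params$interval[1]) ||
                      any(chk > params$interval[2])))
    validation_error(sprintf(
      "parameter(s) outside the configured interval [%g, %g]: %s",
      params$interval[1], params$interval[2],
      cstr(names(chk)[!is.finite(chk) | chk < params$interval[1] |
                        chk > params$interval[2]])))
  if (params$amplify1 <= 0 || params$amplify2 <= 0)
    validation_error("amplify factors must be positive")

  inputs <- unlist(doc$inputs %||% list("u1", "u2"))

  # a JSON round trip may collapse a single accelerator/inhibitor object out
  # of its enclosing array; re-wrap it
  norm_mods <- function(x) {
    x <- x %||% list()
    if (!is.null(x$species)) list(x) else x
  }
  terms <- lapply(doc$terms, function(tl)
    lapply(tl, function(t) {
      if (inherits(t, "erins_term")) t
      else rate_term(shape = t$shape, k = t$k, driver = t$driver,
                     factors = unlist(t$factors) %||% character(),
                     accelerators = norm_mods(t$accelerators),
                     decay_of = t$decay_of,
                     inhibitors = norm_mods(t$inhibitors))
    }))

  model <- structure(list(species = species, terms = terms, parameters = params,
                          inputs = inputs,
                          readouts = doc$readouts %||% list()),
                     class = "erins_model")
  validate_model(model)
  model
}

read_config <- function(config) {
  if (is.list(config)) return(config)
  if (is.character(config) && length(config) == 1L) {
    if (file.exists(config))
      return(jsonlite::fromJSON(config, simplifyVector = FALSE))
    if (grepl("^\\s*\\{", config))
      return(jsonlite::fromJSON(config, simplifyVector = FALSE))
    config_error(sprintf("config file not found: %s", config))
  }
  config_error("config must be a list, a JSON string or a path to a JSON file")
}

validate_model <- function(model) {
  sp <- model$species$name
  orphan <- setdiff(sp, names(model$terms))
  if (length(orphan))
    validation_error(sprintf("species without any rate term: %s", cstr(orphan)))
  extra <- setdiff(names(model$terms), sp)
  if (length(extra))
    validation_error(sprintf("terms declared for unknown species: %s", cstr(extra)))

  for (tgt in names(model$terms)) {
    tl <- model$terms[[tgt]]
    if (!length(tl))
      validation_error(sprintf("species '%s' has an empty term list", tgt))
    n_drive <- 0L
    for (i in seq_along(tl)) {
      term <- tl[[i]]
      refs <- term_species_refs(term)
      missing <- setdiff(refs, sp)
      if (length(missing))
        validation_error(sprintf(
          "term %d of species '%s' references undeclared species: %s",
          i, tgt, cstr(missing)), species = missing)
      if (term$shape == "input_drive") {
        n_drive <- n_drive + 1L
        if (!term$driver %in% model$inputs)
          validation_error(sprintf(
            "term %d of species '%s' references undeclared input '%s'",
            i, tgt, term$driver))
      }
      # constants must resolve and be admissible
      resolve_const(term$k, model$parameters, "rate constant")
      for (a in c(term$accelerators, term$inhibitors))
        resolve_const(a$F, model$parameters, "binding constant")
    }
    if (n_drive > 1L)
      validation_error(sprintf(
        "species '%s' has %d input_drive terms; at most one is supported",
        tgt, n_drive))
  }

  for (nm in names(model$readouts)) {
    def <- model$readouts[[nm]]
    refs <- switch(def$type %||% "species",
                   species = def$species,
                   pair_ratio = c(def$phospho, def$unphospho),
                   raw_ratio = c(def$numerator, def$denominator),
                   flux = character(),
                   config_error(sprintf("readout '%s' has unknown type '%s'",
                                        nm, def$type)))
    missing <- setdiff(refs, sp)
    if (length(missing))
      validation_error(sprintf("readout '%s' references unknown species: %s",
                               nm, cstr(missing)))
    if (identical(def$type, "flux") && !def$input %in% model$inputs)
      validation_error(sprintf("flux readout '%s' references unknown input '%s'",
                               nm, def$input))
  }
  invisible(model)
}

#' @export
print.erins_model <- function(x, ...) {
  cat(sprintf("<erins_model> %d species, %d terms, %d inputs, %d readouts\n",
              nrow(x$species), sum(lengths(x$terms)), length(x$inputs),
              length(x$readouts)))
  invisible(x)
}

#' Initial state vector of a model
#'
#' @param model an `erins_model`.
#' @return named numeric vector of initial abundances (AU).
#' @export
initial_state <- function(model) {
  setNames(model$species$initial, model$species$name)
}

#' Path to the bundled default model configuration
#'
#' The shipped roster reconstructs the integrated ER-stress/insulin network:
#' unfolded-protein load and chaperone pool, the three UPR sensor branches
#' (PERK/eIF2a/ATF4, IRE1a/XBP1, ATF6), the inflammatory relay
#' (TRAF2-ASK1, JNK, IKKb, IkBa, NF-kB) and the insulin cascade
#' (IR, IRS, PI3K, PIP3, AKT, FoxO1), with calibrated parameters.
#' @return file path.
#' @export
default_model_path <- function() {
  system.file("extdata", "model_default.json", package = "erins",
              mustWork = TRUE)
}

#' @rdname default_model_path
#' @export
default_scenarios_path <- function() {
  system.file("extdata", "scenarios_default.json", package = "erins",
              mustWork = TRUE)
}

#' @rdname default_model_path
#' @export
default_patterns_path <- function() {
  system.file("extdata", "patterns_dio_ncd.csv", package = "erins",
              mustWork = TRUE)
}
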