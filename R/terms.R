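#' Evaluate a single rate term
#'
#' Pure-R reference interpreter for the three-shape term grammar. Returns the
#' signed contribution of one term (decay terms are negative). The compiled
#' C++ evaluator used by the integrator is checked against this function in
#' the test suite; keep the two in lockstep.
#'
#' @param term an `erins_term`.
#' @param state named numeric vector of species abundances (AU).
#' @param inputs named numeric vector of input values (AU).
#' @param params parameter set (list with `rate_constants`,
#'   `binding_constants`).
#' @return signed rate (AU per time).
#' @export
evaluate_term <- function(term, state, inputs, params) {
  need <- term_species_refs(term)
  missing <- setdiff(need, names(state))
  if (length(missing))
    lookup_error(sprintf("state is missing species: %s", cstr(missing)))
  k <- resolve_const(term$k, params, "rate constant")
  switch(term$shape,
    input_drive = {
      if (!term$driver %in% names(inputs))
        lookup_error(sprintf("input '%s' not supplied", term$driver))
      k * inputs[[term$driver]]
    },
    activation = {
      v <- k * prod(vapply(term$factors, function(s) state[[s]], 0))
      for (a in term$accelerators)
        v <- v * (1 + resolve_const(a$F, params, "binding constant") *
                    state[[a$species]])
      v
    },
    decay = {
      v <- k * state[[term$decay_of]] *
        prod(vapply(term$factors, function(s) state[[s]], 0))
      den <- 1
      for (a in term$inhibitors)
        den <- den * (1 + resolve_const(a$F, params, "binding constant") *
                        state[[a$species]])
      -v / den
    })
}

# Compile a validated model plus a resolved input policy into the flat
# integer/double tables consumed by the C++ right-hand side.
#
# `imode` per input: 0 = fixed value (covers zero, frozen and
# controller-held inputs), 1 = steady-state amplified, re-derived at every
# RHS evaluation.
compile_model <- function(model, imode = NULL, ivalue = NULL, iamp = NULL) {
  sp <- model$species$name
  idx <- setNames(seq_along(sp), sp)
  iidx <- setNames(seq_along(model$inputs), model$inputs)
  p <- model$parameters

  target <- integer(); kind <- integer(); kval <- numeric()
  driver <- integer(); decayof <- integer()
  fct_ptr <- 0L; fct_idx <- integer()
  acc_ptr <- 0L; acc_idx <- integer(); acc_F <- numeric()
  inh_ptr <- 0L; inh_idx <- integer(); inh_F <- numeric()
  meta <- list()

  for (tgt in sp) {
    for (term in model$terms[[tgt]]) {
      target <- c(target, idx[[tgt]])
      kind <- c(kind, match(term$shape, TERM_SHAPES) - 1L)
      kval <- c(kval, resolve_const(term$k, p, "rate constant"))
      driver <- c(driver, if (term$shape == "input_drive") iidx[[term$driver]] else 0L)
      decayof <- c(decayof, if (term$shape == "decay") idx[[term$decay_of]] else 0L)
      fct_idx <- c(fct_idx, unname(idx[term$factors]))
      fct_ptr <- c(fct_ptr, length(fct_idx))
      for (a in term$accelerators) {
        acc_idx <- c(acc_idx, idx[[a$species]])
        acc_F <- c(acc_F, resolve_const(a$F, p, "binding constant"))
      }
      acc_ptr <- c(acc_ptr, length(acc_idx))
      for (a in term$inhibitors) {
        inh_idx <- c(inh_idx, idx[[a$species]])
        inh_F <- c(inh_F, resolve_const(a$F, p, "binding constant"))
      }
      inh_ptr <- c(inh_ptr, length(inh_idx))
      meta[[length(target)]] <- list(species = tgt, term = term)
    }
  }

  n_inputs <- length(model$inputs)
  if (is.null(imode)) imode <- rep(0L, n_inputs)
  if (is.null(ivalue)) ivalue <- rep(0, n_inputs)
  if (is.null(iamp)) iamp <- rep(1, n_inputs)
  drv_term <- vapply(seq_len(n_inputs), function(i) {
    w <- which(kind == 0L & driver == i)
    if (length(w)) w[1] else 0L
  }, 0L)
  if (any(imode == 1L & drv_term == 0L))
    validation_error("steady-state input mode set for an input with no drive term")

  list(target = target, kind = kind, k = kval, driver = driver,
       decayof = decayof,
       fct_ptr = fct_ptr, fct_idx = fct_idx,
       acc_ptr = acc_ptr, acc_idx = acc_idx, acc_F = acc_F,
       inh_ptr = inh_ptr, inh_idx = inh_idx, inh_F = inh_F,
       n_species = length(sp), n_terms = length(target), n_inputs = n_inputs,
       imode = as.integer(imode), drv_term = as.integer(drv_term),
       ivalue = as.numeric(ivalue), iamp = as.numeric(iamp),
       species = sp, input_names = model$inputs, meta = meta)
}

#' Build the ODE right-hand side of a model
#'
#' Compiles the model's rate terms and returns a derivative function
#' `f(t, x)` mapping a state vector to its derivative vector. The derivative
#' of each species is the sum of its terms; evaluation order has no effect.
#' Inputs are resolved according to `imode`/`ivalue`/`iamp` (all inputs fixed
#' at 0 by default); use [simulate()] for policy-aware integration.
#'
#' @param model an `erins_model`.
#' @param imode,ivalue,iamp optional per-input mode (0 fixed / 1 steady-state
#'   amplified), fixed values and amplification factors.
#' @return a function `f(t, x)` returning the named derivative vector.
#' @export
build_rhs <- function(model, imode = NULL, ivalue = NULL, iamp = NULL) {
  ct <- compile_model(model, imode, ivalue, iamp)
  function(t, x) setNames(.rhs_cpp(as.numeric(x), ct), ct$species)
}
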