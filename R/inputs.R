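# External inputs: the ER-stress drive (u1) and the insulin drive (u2) are
# derived from the equilibrium condition of the species they feed, then
# scaled by an amplification factor. With amplification 1 the derived input
# exactly nullifies the driven species' net derivative at the state it was
# derived from.

#' Derive the ER-stress input u1 from the equilibrium condition
#'
#' At equilibrium of the unfolded-protein load `x1` (production by `u1`
#' balancing chaperone-mediated clearance), the drive must satisfy
#' `u1 = amplify1 * k2 * x1 * x2 / k1`.
#'
#' @param state named numeric vector containing the unfolded-protein load and
#'   chaperone species.
#' @param params parameter set with rate constants `k1`, `k2` and the
#'   `amplify1` factor.
#' @param species names of the load and chaperone species in `state`
#'   (default `c("x1", "x2")`).
#' @return the derived input value (AU).
#' @export
derive_u1 <- function(state, params, species = c("x1", "x2")) {
  k1 <- resolve_const("k1", params, "rate constant")
  k2 <- resolve_const("k2", params, "rate constant")
  if (k1 <= 0)
    validation_error("invalid parameterization: k1 must be positive to derive u1")
  missing <- setdiff(species, names(state))
  if (length(missing))
    lookup_error(sprintf("state is missing species: %s", cstr(missing)))
  (params$amplify1 %||% 1) * k2 * state[[species[1]]] * state[[species[2]]] / k1
}

#' Derive the insulin input u2 from the equilibrium condition
#'
#' At equilibrium of the insulin receptor `x26` (synthesis driven by `u2`
#' balancing its feedback-modulated decay), the drive must satisfy
#' `u2 = amplify2 * (k52 / ((1 + F3 x30)(1 + F4 x32))) * x26 / k53`,
#' where `x30`/`x32` are the downstream cascade species whose abundance slows
#' receptor turnover.
#'
#' @param state named numeric vector containing the receptor and feedback
#'   species.
#' @param params parameter set with `k52`, `k53`, `F3`, `F4`, `amplify2`.
#' @param species names of the receptor and the two feedback species
#'   (default `c("x26", "x30", "x32")`).
#' @return the derived input value (AU).
#' @export
derive_u2 <- function(state, params, species = c("x26", "x30", "x32")) {
  k52 <- resolve_const("k52", params, "rate constant")
  k53 <- resolve_const("k53", params, "rate constant")
  F3 <- resolve_const("F3", params, "binding constant")
  F4 <- resolve_const("F4", params, "binding constant")
  if (k53 <= 0)
    validation_error("invalid parameterization: k53 must be positive to derive u2")
  missing <- setdiff(species, names(state))
  if (length(missing))
    lookup_error(sprintf("state is missing species: %s", cstr(missing)))
  (params$amplify2 %||% 1) * (k52 / ((1 + F3 * state[[species[2]]]) *
                                       (1 + F4 * state[[species[3]]]))) *
    state[[species[1]]] / k53
}

#' Derive a steady-state input for any model input
#'
#' Generalization of [derive_u1()]/[derive_u2()] to an arbitrary roster: the
#' input value that makes the driven species' net derivative zero at `state`,
#' times the input's amplification factor.
#'
#' @param model an `erins_model`.
#' @param input input name (e.g. `"u1"`).
#' @param state named state vector (defaults to the model's initial state).
#' @param amplify amplification factor.
#' @return derived input value (AU).
#' @export
derive_input <- function(model, input, state = initial_state(model),
                         amplify = 1) {
  i <- match(input, model$inputs)
  if (is.na(i)) lookup_error(sprintf("unknown input '%s'", input))
  imode <- rep(0L, length(model$inputs))
  iamp <- rep(1, length(model$inputs))
  imode[i] <- 1L
  iamp[i] <- amplify
  ct <- compile_model(model, imode = imode, ivalue = rep(0, length(model$inputs)),
                      iamp = iamp)
  .inputs_cpp(as.numeric(state[ct$species]), ct)[i]
}

#' Define the input policy for a scenario
#'
#' Each input runs in one of four modes:
#' * `"zero"` — held at 0 for all t (the NCD control for the stress drive);
#' * `"fixed"` — held at a supplied constant value;
#' * `"steady_state_amplified"` — derived from the equilibrium condition,
#'   either re-derived at every RHS evaluation (`schedule = "continuous"`,
#'   the DIO default for the stress drive) or computed once at the initial
#'   state and then frozen (`schedule = "frozen"`);
#' * `"controller"` — supplied by a PID control loop (see
#'   [closed_loop_simulate()]).
#'
#' @param ... one named entry per input, each a list with elements `mode` and
#'   optionally `value`, `amplify`, `schedule`.
#' @return an object of class `erins_input_policy`.
#' @export
input_policy <- function(...) {
  pol <- list(...)
  for (nm in names(pol)) {
    p <- pol[[nm]]
    p$mode <- match.arg(p$mode,
                        c("zero", "fixed", "steady_state_amplified", "controller"))
    p$schedule <- match.arg(p$schedule %||% "continuous", c("continuous", "frozen"))
    p$amplify <- p$amplify %||% 1
    p$value <- p$value %||% 0
    pol[[nm]] <- p
  }
  structure(pol, class = "erins_input_policy")
}

# Resolve a policy into compile-time input tables at a given initial state.
resolve_policy <- function(model, policy, x0) {
  n <- length(model$inputs)
  imode <- rep(0L, n); ivalue <- rep(0, n); iamp <- rep(1, n)
  for (i in seq_len(n)) {
    nm <- model$inputs[i]
    p <- policy[[nm]]
    if (is.null(p)) next  # default: held at 0
    switch(p$mode,
      zero = { },
      fixed = ivalue[i] <- p$value,
      controller = ivalue[i] <- p$value,
      steady_state_amplified = {
        if (p$schedule == "continuous") {
          imode[i] <- 1L
          iamp[i] <- p$amplify
        } else {
          ivalue[i] <- derive_input(model, nm, x0, amplify = p$amplify)
        }
      })
  }
  list(imode = imode, ivalue = ivalue, iamp = iamp)
}
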