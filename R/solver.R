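# Adaptive TR-BDF2 integrator (trapezoidal rule + second-order backward
# differentiation composite step; the method family of MATLAB's ode23tb).
# One-step, L-stable, with an embedded third-order error estimate built from
# the divided differences of the three stage derivatives, smoothed through
# the stage-2 iteration matrix to avoid overestimation on stiff components.

TRBDF2_GAMMA <- 2 - sqrt(2)
# leading local-error constant of TR-BDF2
TRBDF2_CERR <- abs((-3 * TRBDF2_GAMMA^2 + 4 * TRBDF2_GAMMA - 2) /
                     (12 * (2 - TRBDF2_GAMMA)))

# Integrate dx/dt = f(x) (autonomous; inputs are resolved inside the compiled
# tables) across an output time grid. States are recorded exactly at the grid
# nodes; the adaptive step never crosses a node. The C++ stepper carries the
# work; the pure-R twin below is retained as an independent reference and is
# cross-checked against it in the test suite.
trbdf2_grid <- function(ct, x0, times, rtol = 1e-5, atol = 1e-7,
                        clip = NULL, h0 = NULL) {
  out <- .trbdf2_cpp(as.numeric(x0), as.numeric(times), ct, rtol, atol,
                     if (!is.null(clip)) as.numeric(clip$lower),
                     if (!is.null(clip)) as.numeric(clip$upper),
                     h0 %||% -1)
  if (out$status == "underflow")
    integration_error(sprintf("step size underflow at t = %g", out$last_time),
                      last_time = out$last_time)
  if (out$status == "nonfinite") {
    bad <- ct$species[out$bad]
    numerical_error(sprintf("non-finite derivative for species: %s", cstr(bad)),
                    species = bad)
  }
  states <- out$states
  colnames(states) <- ct$species
  attr(states, "h_final") <- out$h_final
  states
}

trbdf2_grid_r <- function(ct, x0, times, rtol = 1e-5, atol = 1e-7,
                          clip = NULL, h0 = NULL) {
  n <- length(x0)
  np <- length(times)
  gam <- TRBDF2_GAMMA
  a1c <- gam / 2
  a2c <- (1 - gam) / (2 - gam)
  b1 <- 1 / (gam * (2 - gam))
  b0 <- (1 - gam)^2 / (gam * (2 - gam))
  I_n <- diag(n)

  states <- matrix(NA_real_, np, n)
  states[1, ] <- x0
  x <- as.numeric(x0)
  J <- NULL
  h <- h0 %||% (times[2] - times[1]) / 10

  fx <- function(x) {
    f <- .rhs_cpp(x, ct)
    if (any(!is.finite(f))) {
      bad <- ct$species[!is.finite(f)]
      numerical_error(sprintf("non-finite derivative for species: %s", cstr(bad)),
                      species = bad)
    }
    f
  }

  newton <- function(z, a, M_lu, cvec) {
    for (it in 1:10) {
      r <- z - a * .rhs_cpp(z, ct) - cvec
      dz <- solve(M_lu, r)
      z <- z - dz
      if (max(abs(dz) / (atol + rtol * pmax(abs(z), 1e-12))) < 0.05)
        return(list(z = z, ok = TRUE))
    }
    list(z = z, ok = FALSE)
  }

  for (seg in seq_len(np - 1)) {
    t <- times[seg]
    t_end <- times[seg + 1]
    hmin <- max(1e-12, 1e-10 * (t_end - times[1]))
    while (t < t_end - 1e-12 * max(1, abs(t_end))) {
      h <- min(h, t_end - t)
      if (h < hmin)
        integration_error(sprintf("step size underflow at t = %g", t),
                          last_time = t)
      f0 <- fx(x)
      if (is.null(J)) J <- .jac_cpp(x, ct)
      M1 <- I_n - (a1c * h) * J
      M2 <- I_n - (a2c * h) * J
      s1 <- newton(x + gam * h * f0, a1c * h, M1, x + (a1c * h) * f0)
      ok <- s1$ok
      s2 <- NULL
      if (ok) {
        z1 <- s1$z
        pred <- z1 + ((1 - gam) / gam) * (z1 - x)
        s2 <- newton(pred, a2c * h, M2, b1 * z1 - b0 * x)
        ok <- s2$ok
      }
      if (!ok) {
        J <- .jac_cpp(x, ct)  # refresh Jacobian, then retry with smaller step
        h <- h / 2
        next
      }
      z1 <- s1$z; z2 <- s2$z
      f1 <- .rhs_cpp(z1, ct); f2 <- .rhs_cpp(z2, ct)
      dd <- 2 * ((f2 - f1) / ((1 - gam) * h) - (f1 - f0) / (gam * h)) / h
      est <- solve(M2, TRBDF2_CERR * h^3 * dd)
      errnorm <- sqrt(mean((est / (atol + rtol * pmax(abs(x), abs(z2))))^2))
      if (is.finite(errnorm) && errnorm <= 1) {
        t <- t + h
        x <- z2
        if (!is.null(clip)) x <- pmin(pmax(x, clip$lower), clip$upper)
        J <- NULL  # refresh lazily at next step
        h <- h * min(3, max(0.3, 0.9 * errnorm^(-1 / 3)))
      } else {
        h <- h * max(0.1, 0.9 * (errnorm + 1e-16)^(-1 / 3))
      }
    }
    states[seg + 1, ] <- x
  }
  colnames(states) <- ct$species
  attr(states, "h_final") <- h
  states
}

#' Simulation configuration
#'
#' @param t_span numeric length-2, start and end of the canonical time axis
#'   (AU). The default horizon is 70000 AU, one AU per reported iteration.
#' @param n_points output grid size (>= 2).
#' @param rel_tol,abs_tol solver tolerances.
#' @param clip_states if `TRUE`, states are projected onto their configured
#'   bounds at every accepted solver step.
#' @param solver solver identifier; only `"trbdf2"` is provided.
#' @return an object of class `erins_sim_config`.
#' @export
sim_config <- function(t_span = c(0, 70000), n_points = 1401,
                       rel_tol = 1e-5, abs_tol = 1e-7,
                       clip_states = TRUE, solver = "trbdf2") {
  if (length(t_span) != 2 || t_span[2] <= t_span[1])
    config_error("t_span must be (start, end) with end > start")
  if (n_points < 2) config_error("n_points must be >= 2")
  if (rel_tol <= 0 || abs_tol <= 0) config_error("tolerances must be positive")
  if (!identical(solver, "trbdf2"))
    config_error(sprintf("unknown solver '%s'", solver))
  structure(list(t_span = as.numeric(t_span), n_points = as.integer(n_points),
                 rel_tol = rel_tol, abs_tol = abs_tol,
                 clip_states = isTRUE(clip_states), solver = solver),
            class = "erins_sim_config")
}

#' Integrate a model over time
#'
#' Solves the compiled ODE system with the TR-BDF2 stiff integrator, applying
#' the scenario's input policy, and returns the state, input and readout
#' trajectories on the output grid.
#'
#' @param model an `erins_model`.
#' @param policy an [input_policy()] (default: all inputs held at zero).
#' @param config an [sim_config()].
#' @param init named initial state (default: the model's initial values,
#'   1.05 AU for every species in the shipped roster).
#' @return an `erins_sim_result` with elements `times`, `states`, `inputs`,
#'   `readouts`.
#' @export
simulate <- function(model, policy = input_policy(),
                     config = sim_config(), init = initial_state(model)) {
  x0 <- as.numeric(init[model$species$name])
  if (any(is.na(x0)))
    lookup_error("initial state is missing species declared in the model")
  res <- resolve_policy(model, policy, setNames(x0, model$species$name))
  ct <- compile_model(model, res$imode, res$ivalue, res$iamp)
  times <- seq(config$t_span[1], config$t_span[2], length.out = config$n_points)
  clip <- if (config$clip_states)
    list(lower = model$species$lower, upper = model$species$upper)
  states <- trbdf2_grid(ct, x0, times, config$rel_tol, config$abs_tol, clip)
  inputs <- matrix(unlist(lapply(seq_len(nrow(states)), function(i)
    .inputs_cpp(states[i, ], ct))), nrow = nrow(states), byrow = TRUE,
    dimnames = list(NULL, model$inputs))
  out <- structure(list(times = times, states = states, inputs = inputs,
                        model = model, ct = ct, config = config),
                   class = "erins_sim_result")
  out$readouts <- compute_readouts(out, model$readouts)
  out
}

#' @export
print.erins_sim_result <- function(x, ...) {
  cat(sprintf("<erins_sim_result> %d points over t = [%g, %g], %d species\n",
              length(x$times), min(x$times), max(x$times), ncol(x$states)))
  invisible(x)
}

#' Compute readout trajectories from a simulation result
#'
#' Ratio readouts (`pair_ratio`) are pointwise phospho / (phospho +
#' unphosphorylated); `raw_ratio` readouts divide two species directly (the
#' blot-style phospho/total-band signal ratio, which may exceed 1); `flux`
#' readouts report the instantaneous input-drive term `k * u(t)` of the
#' flagged input; `species` readouts copy a trajectory. Zero denominators are
#' guarded with `eps` and flagged with a warning.
#'
#' @param result an `erins_sim_result`.
#' @param defs named list of readout definitions (see the bundled model
#'   config for the grammar).
#' @param eps denominator guard.
#' @return matrix of readout trajectories (one column per readout).
#' @export
compute_readouts <- function(result, defs, eps = 1e-9) {
  if (!length(defs)) return(matrix(numeric(), nrow = length(result$times), ncol = 0))
  st <- result$states
  guard <- FALSE
  cols <- lapply(names(defs), function(nm) {
    def <- defs[[nm]]
    need <- switch(def$type, species = def$species,
                   pair_ratio = c(def$phospho, def$unphospho),
                   raw_ratio = c(def$numerator, def$denominator),
                   flux = character())
    missing <- setdiff(need, colnames(st))
    if (length(missing))
      lookup_error(sprintf("readout '%s' needs missing species: %s",
                           nm, cstr(missing)))
    switch(def$type,
      species = st[, def$species],
      pair_ratio = {
        den <- st[, def$phospho] + st[, def$unphospho]
        if (any(den < eps)) guard <<- TRUE
        st[, def$phospho] / pmax(den, eps)
      },
      raw_ratio = {
        den <- st[, def$denominator]
        if (any(den < eps)) guard <<- TRUE
        st[, def$numerator] / pmax(den, eps)
      },
      flux = {
        i <- match(def$input, result$ct$input_names)
        kdrv <- result$ct$k[result$ct$drv_term[i]]
        kdrv * result$inputs[, def$input]
      })
  })
  if (guard)
    warning("zero total encountered in a ratio readout; epsilon guard applied",
            call. = FALSE)
  out <- do.call(cbind, cols)
  colnames(out) <- names(defs)
  out
}

# Single-state readout evaluation used by the control loops.
readout_at_state <- function(def, x, u, ct, eps = 1e-9) {
  switch(def$type,
    species = x[[def$species]],
    pair_ratio = {
      den <- x[[def$phospho]] + x[[def$unphospho]]
      x[[def$phospho]] / max(den, eps)
    },
    raw_ratio = x[[def$numerator]] / max(x[[def$denominator]], eps),
    flux = {
      i <- match(def$input, ct$input_names)
      ct$k[ct$drv_term[i]] * u[[i]]
    })
}

#' Steady value of a trajectory
#'
#' Operational definition of the "steady value" reported for a readout: the
#' mean over the final `tail_fraction` of the output grid. The spread
#' (max - min) of the tail is attached as a settledness diagnostic.
#'
#' @param trajectory numeric vector.
#' @param tail_fraction fraction of points in (0, 1] to average over.
#' @return the tail mean, with attribute `settle` (tail max - min).
#' @export
steady_value <- function(trajectory, tail_fraction = 0.1) {
  n <- length(trajectory)
  if (!n) validation_error("trajectory is empty")
  if (tail_fraction <= 0 || tail_fraction > 1)
    validation_error("tail_fraction must be in (0, 1]")
  m <- max(1L, ceiling(tail_fraction * n))
  tail_vals <- trajectory[(n - m + 1L):n]
  structure(mean(tail_vals), settle = max(tail_vals) - min(tail_vals))
}

#' Write a simulation result to CSV
#'
#' One row per time point; columns are time, states, inputs and readouts
#' (header names match the configuration names exactly). Controller traces,
#' if present, are appended as `error_<loop>` / `u_<loop>` columns.
#'
#' @param result an `erins_sim_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(result, path) {
  m <- cbind(time = result$times, result$states, result$inputs)
  if (!is.null(result$readouts) && ncol(result$readouts))
    m <- cbind(m, result$readouts)
  if (!is.null(result$controller_traces))
    m <- cbind(m, result$controller_traces)
  write.csv(as.data.frame(m, check.names = FALSE), path, row.names = FALSE)
  invisible(path)
}
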