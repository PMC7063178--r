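#' PID controller configuration
#'
#' Discrete proportional-integral-derivative law computing an external input
#' from the error between a reference and a measured readout:
#' `u = kp*e + ki*integral(e) + kd*de/dt`, sampled with a zero-order hold.
#' The error is `r - o` in `"signed"` mode (default; able to steer a readout
#' both ways) or `|r - o|` in `"absolute"` mode (directionless, retained for
#' replication). The derivative is taken on the measurement, not the error,
#' to avoid reference kick; negative `kd` is permitted.
#'
#' @param kp,ki,kd controller gains.
#' @param reference target readout value.
#' @param error_mode `"signed"` or `"absolute"`.
#' @param output_limits length-2 clamp on the control input; actuation is
#'   floored at 0 by default since a negative stress or insulin drive has no
#'   physical meaning.
#' @param anti_windup freeze the integral while the output is clamped and the
#'   error would push it further out.
#' @param sample_interval controller sampling period (AU time); `NULL` means
#'   the output-grid spacing.
#' @param initial_output preload of the controller output at t = 0 (realized
#'   through the integral term when `ki != 0`); used to start a loop at the
#'   operating drive it takes over from.
#' @return an object of class `erins_pid_config`.
#' @export
pid_config <- function(kp = 0, ki = 0, kd = 0, reference = 0,
                       error_mode = c("signed", "absolute"),
                       output_limits = c(0, Inf), anti_windup = TRUE,
                       sample_interval = NULL, initial_output = 0) {
  error_mode <- match.arg(error_mode)
  if (output_limits[1] > output_limits[2])
    config_error("output_limits must satisfy min <= max")
  if (!is.null(sample_interval) && sample_interval <= 0)
    config_error("sample_interval must be positive")
  structure(list(kp = kp, ki = ki, kd = kd, reference = reference,
                 error_mode = error_mode, output_limits = output_limits,
                 anti_windup = isTRUE(anti_windup),
                 sample_interval = sample_interval,
                 initial_output = initial_output),
            class = "erins_pid_config")
}

pid_init <- function(cfg) {
  list(integral = if (cfg$ki != 0) cfg$initial_output / cfg$ki else 0,
       prev_meas = NA_real_)
}

#' Advance a discrete PID controller by one sample
#'
#' @param cfg an [pid_config()].
#' @param state controller state as returned by a previous call (or `NULL`
#'   to start fresh).
#' @param measurement current readout value.
#' @param dt time since the previous sample (> 0).
#' @param reference target value (defaults to the configured reference).
#' @return list with `output` (clamped control input) and `state`.
#' @export
pid_step <- function(cfg, state = NULL, measurement, dt,
                     reference = cfg$reference) {
  if (dt <= 0) config_error("pid_step requires dt > 0")
  if (is.null(state)) state <- pid_init(cfg)
  e <- reference - measurement
  if (cfg$error_mode == "absolute") e <- abs(e)
  deriv <- if (is.na(state$prev_meas)) 0 else -(measurement - state$prev_meas) / dt
  integral_new <- state$integral + e * dt
  u_raw <- cfg$kp * e + cfg$ki * integral_new + cfg$kd * deriv
  lo <- cfg$output_limits[1]; hi <- cfg$output_limits[2]
  u <- min(max(u_raw, lo), hi)
  if (cfg$anti_windup && u != u_raw &&
      ((u_raw > hi && e > 0) || (u_raw < lo && e < 0))) {
    # clamped and winding further out: keep the previous integral
    integral_new <- state$integral
    u <- min(max(cfg$kp * e + cfg$ki * integral_new + cfg$kd * deriv, lo), hi)
  }
  list(output = u, error = e,
       state = list(integral = integral_new, prev_meas = measurement))
}

#' Define a control loop around the plant
#'
#' Pairs a sensed readout with an actuated input. In the network's standard
#' wiring, controller 1 senses a UPR-arm readout (the pPERK/PERK ratio) and
#' actuates the ER-stress drive `u1`; controller 2 senses an insulin-arm
#' readout (IRpY, IRSpY or the pAkt/Akt signal ratio) and actuates the
#' insulin drive `u2`.
#'
#' @param readout name of a model readout.
#' @param input name of the actuated input.
#' @param controller an [pid_config()].
#' @param name optional loop label used in trace column names.
#' @return an object of class `erins_control_loop`.
#' @export
control_loop <- function(readout, input, controller, name = readout) {
  structure(list(readout = readout, input = input, controller = controller,
                 name = name), class = "erins_control_loop")
}

#' Closed-loop simulation with discrete PID controllers
#'
#' Integrates the plant piecewise between controller samples: at each sample
#' the loops read their readouts from the current state, compute new control
#' inputs, and hold them (zero-order hold) until the next sample. Inputs not
#' actuated by any loop follow `policy`.
#'
#' @param model an `erins_model`.
#' @param loops list of [control_loop()]s (empty list reduces to
#'   [simulate()]).
#' @param config an [sim_config()].
#' @param policy [input_policy()] for the non-actuated inputs.
#' @param init named initial state.
#' @return an `erins_sim_result` with controller traces (`error_<loop>`,
#'   `u_<loop>` columns).
#' @export
closed_loop_simulate <- function(model, loops, config = sim_config(),
                                 policy = input_policy(),
                                 init = initial_state(model)) {
  if (!length(loops)) return(simulate(model, policy, config, init))
  times <- seq(config$t_span[1], config$t_span[2], length.out = config$n_points)
  dt_grid <- times[2] - times[1]
  for (lp in loops) {
    if (!lp$readout %in% names(model$readouts))
      config_error(sprintf("loop '%s' senses unknown readout '%s'",
                           lp$name, lp$readout))
    if (!lp$input %in% model$inputs)
      config_error(sprintf("loop '%s' actuates unknown input '%s'",
                           lp$name, lp$input))
    si <- lp$controller$sample_interval
    if (!is.null(si)) {
      m <- si / dt_grid
      if (abs(m - round(m)) > 1e-8 || round(m) < 1)
        config_error(sprintf(
          "sample_interval of loop '%s' must be a multiple of the grid spacing",
          lp$name))
    }
  }
  sample_every <- vapply(loops, function(lp) {
    si <- lp$controller$sample_interval
    if (is.null(si)) 1L else as.integer(round(si / dt_grid))
  }, 0L)

  x0 <- as.numeric(init[model$species$name])
  res <- resolve_policy(model, policy, setNames(x0, model$species$name))
  ct <- compile_model(model, res$imode, res$ivalue, res$iamp)
  iidx <- vapply(loops, function(lp) match(lp$input, model$inputs), 0L)
  cstate <- lapply(loops, function(lp) pid_init(lp$controller))
  clip <- if (config$clip_states)
    list(lower = model$species$lower, upper = model$species$upper)

  np <- config$n_points
  states <- matrix(NA_real_, np, length(x0),
                   dimnames = list(NULL, model$species$name))
  inputs <- matrix(NA_real_, np, length(model$inputs),
                   dimnames = list(NULL, model$inputs))
  traces <- matrix(NA_real_, np, 2 * length(loops))
  colnames(traces) <- c(vapply(loops, function(lp) paste0("error_", lp$name), ""),
                        vapply(loops, function(lp) paste0("u_", lp$name), ""))
  states[1, ] <- x0
  x <- x0
  h_carry <- dt_grid / 10

  for (k in seq_len(np)) {
    xs <- setNames(x, model$species$name)
    ucur <- .inputs_cpp(x, ct)
    for (j in seq_along(loops)) {
      lp <- loops[[j]]
      due <- ((k - 1L) %% sample_every[j]) == 0L
      meas <- readout_at_state(model$readouts[[lp$readout]], xs, ucur, ct)
      if (due) {
        dt_s <- dt_grid * sample_every[j]
        stp <- tryCatch(
          pid_step(lp$controller, cstate[[j]], meas, dt_s),
          error = function(e) integration_error(
            sprintf("controller '%s' failed at sample %d: %s",
                    lp$name, k, conditionMessage(e)), sample = k))
        cstate[[j]] <- stp$state
        ct$ivalue[iidx[j]] <- stp$output
        traces[k, paste0("u_", lp$name)] <- stp$output
        traces[k, paste0("error_", lp$name)] <- stp$error
      } else {
        traces[k, paste0("u_", lp$name)] <- ct$ivalue[iidx[j]]
        e <- lp$controller$reference - meas
        if (lp$controller$error_mode == "absolute") e <- abs(e)
        traces[k, paste0("error_", lp$name)] <- e
      }
    }
    inputs[k, ] <- .inputs_cpp(x, ct)
    if (k == np) break
    seg <- tryCatch(
      trbdf2_grid(ct, x, times[k:(k + 1L)], config$rel_tol, config$abs_tol,
                  clip, h0 = h_carry),
      erins_integration_error = function(e) integration_error(
        sprintf("integration failed in controller segment %d: %s",
                k, conditionMessage(e)), sample = k))
    h_carry <- min(attr(seg, "h_final"), dt_grid)
    x <- seg[2, ]
    states[k + 1L, ] <- x
  }

  out <- structure(list(times = times, states = states, inputs = inputs,
                        model = model, ct = ct, config = config,
                        controller_traces = traces),
                   class = "erins_sim_result")
  out$readouts <- compute_readouts(out, model$readouts)
  out
}
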