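# pid_control: discrete PID law and closed-loop simulation.

test_that("published gains reproduce the forced arithmetic", {
  # integral-only controller 1: unit error held for 1 AU -> ki * 1
  c1 <- pid_config(kp = 0, ki = 0.0691, kd = 0)
  s <- pid_step(c1, NULL, measurement = -1, dt = 1, reference = 0)
  expect_equal(s$output, 0.0691)
  # controller 2 kp/ki contribution: unit error held for 10 AU
  c2 <- pid_config(kp = 0.2134, ki = 0.10329, kd = 0)
  st <- NULL
  for (i in 1:10) {
    s <- pid_step(c2, st, measurement = -1, dt = 1, reference = 0)
    st <- s$state
  }
  expect_equal(s$output, 0.2134 + 1.0329, tolerance = 1e-12)
  # zero error everywhere -> zero output
  c0 <- pid_config(kp = 1, ki = 1, kd = 1)
  s0 <- pid_step(c0, NULL, measurement = 2, dt = 1, reference = 2)
  expect_equal(s0$output, 0)
})

test_that("derivative acts on the measurement and negative kd is honoured", {
  cfg <- pid_config(kp = 0, ki = 0, kd = -0.1082,
                    output_limits = c(-Inf, Inf))
  s1 <- pid_step(cfg, NULL, measurement = 1, dt = 2, reference = 5)
  expect_equal(s1$output, 0)  # no previous measurement: derivative 0
  s2 <- pid_step(cfg, s1$state, measurement = 2, dt = 2, reference = 5)
  # d(o)/dt = 0.5, derivative term = kd * (-0.5)
  expect_equal(s2$output, -0.1082 * -0.5)
})

test_that("outputs are clamped and the integral does not wind up", {
  cfg <- pid_config(kp = 0, ki = 1, output_limits = c(0, 2),
                    anti_windup = TRUE)
  st <- NULL
  for (i in 1:50) {
    s <- pid_step(cfg, st, measurement = 0, dt = 1, reference = 10)
    st <- s$state
    expect_lte(s$output, 2)
  }
  expect_lte(st$integral, 10 + 2)  # frozen once clamped, not growing by 10/step
  # after the reference drops, recovery is immediate rather than delayed
  s <- pid_step(cfg, st, measurement = 10, dt = 1, reference = 0)
  expect_equal(s$output, 0)
})

test_that("signed errors steer monotonically (sign coherence)", {
  cfg <- pid_config(kp = 1, ki = 0.5, output_limits = c(-Inf, Inf))
  above <- pid_step(cfg, NULL, measurement = 3, dt = 1, reference = 2)$output
  below <- pid_step(cfg, NULL, measurement = 1, dt = 1, reference = 2)$output
  expect_lt(above, below)
  # absolute mode is directionless
  cfga <- pid_config(kp = 1, ki = 0.5, error_mode = "absolute")
  ea <- pid_step(cfga, NULL, measurement = 3, dt = 1, reference = 2)
  eb <- pid_step(cfga, NULL, measurement = 1, dt = 1, reference = 2)
  expect_equal(ea$output, eb$output)
  expect_gte(ea$error, 0)
  expect_error(pid_step(cfg, NULL, 1, dt = 0), class = "erins_config_error")
})

test_that("integral control drives a first-order plant to its reference", {
  m <- scalar_plant()
  loop <- control_loop("x", "u1",
                       pid_config(kp = 0, ki = 0.0691, kd = 0,
                                  reference = 2.0))
  r <- closed_loop_simulate(m, list(loop),
                            sim_config(t_span = c(0, 2000), n_points = 401))
  sv <- as.numeric(steady_value(r$readouts[, "x"]))
  expect_equal(sv, 2.0, tolerance = 0.02)
  expect_lt(abs(as.numeric(steady_value(r$controller_traces[, "error_x"]))),
            0.02 * 2)
})

test_that("a reference at the open-loop steady point reproduces the open loop", {
  m <- scalar_plant()
  open <- simulate(m, input_policy(u1 = list(mode = "fixed", value = 1.5)),
                   sim_config(t_span = c(0, 1500), n_points = 301))
  x_inf <- as.numeric(steady_value(open$readouts[, "x"]))
  loop <- control_loop("x", "u1",
                       pid_config(kp = 0, ki = 0.0691, reference = x_inf,
                                  initial_output = 1.5))
  ctl <- closed_loop_simulate(m, list(loop),
                              sim_config(t_span = c(0, 1500), n_points = 301))
  expect_equal(as.numeric(steady_value(ctl$controller_traces[, "u_x"])),
               1.5, tolerance = 0.02)
  expect_lt(abs(as.numeric(steady_value(ctl$controller_traces[, "error_x"]))),
            0.01)
})

test_that("an empty loop list reduces to the open-loop simulator", {
  m <- tiny_pair_model()
  cfg <- sim_config(t_span = c(0, 50), n_points = 26)
  a <- closed_loop_simulate(m, list(), cfg)
  b <- simulate(m, input_policy(), cfg)
  expect_identical(a$states, b$states)
})

test_that("loop wiring is validated against the model", {
  m <- scalar_plant()
  expect_error(closed_loop_simulate(m, list(control_loop("nope", "u1",
                                                         pid_config(ki = 1)))),
               "nope", class = "erins_config_error")
  expect_error(closed_loop_simulate(m, list(control_loop("x", "u9",
                                                         pid_config(ki = 1)))),
               "u9", class = "erins_config_error")
  # sample interval must divide the output grid spacing (1 AU here)
  bad <- control_loop("x", "u1", pid_config(ki = 1, sample_interval = 3.3))
  expect_error(closed_loop_simulate(m, list(bad),
                                    sim_config(t_span = c(0, 10),
                                               n_points = 11)),
               "multiple", class = "erins_config_error")
})

test_that("all twelve controlled conditions track their references", {
  run <- battery_run()
  b <- run$battery
  span1 <- b$loop1$references$high - b$loop1$references$low
  for (cs in c("I", "II", "III"))
    for (cond in c("high_low", "high_high", "low_high", "low_low")) {
      r <- run$results[[paste("case", cs, cond, sep = "_")]]
      lev <- strsplit(cond, "_")[[1]]
      ref1 <- b$loop1$references[[lev[1]]]
      tail1 <- as.numeric(steady_value(r$readouts[, b$loop1$readout]))
      expect_lt(abs(tail1 - ref1), 0.05 * span1)
      refs2 <- b$cases[[cs]]$references
      ref2 <- refs2[[lev[2]]]
      span2 <- refs2$high - refs2$low
      tail2 <- as.numeric(steady_value(r$readouts[, b$cases[[cs]]$readout]))
      expect_lt(abs(tail2 - ref2), 0.05 * span2)
      # actuation respects the configured clamps
      expect_true(all(r$controller_traces[, "u_pPERK"] >= 0))
      expect_true(all(r$controller_traces[, "u_marker"] <=
                        b$controllers$insulin$output_limits[2]))
    }
})
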