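# Shared fixtures. Everything is built in code; the expensive full battery
# run on the shipped calibrated configuration is computed once per session
# and reused by the scenario, control and acceptance tests.

# Two-species stress core: dx1/dt = k1*u1 - k2*x1*x2 plus a buffered
# chaperone pool, the smallest model exercising all three term shapes.
tiny_pair_model <- function(k1 = 1, k2 = 1) {
  parse_model_spec(list(
    species = list(list(name = "x1", role = "stress_input_proxy"),
                   list(name = "x2", role = "upr_effector")),
    inputs = list("u1"),
    parameters = list(rate_constants = list(k1 = k1, k2 = k2,
                                            ks = 0.0525, kd = 0.05),
                      amplify1 = 1, amplify2 = 1),
    terms = list(
      x1 = list(list(shape = "input_drive", k = "k1", driver = "u1"),
                list(shape = "decay", k = "k2", decay_of = "x1",
                     factors = list("x2"))),
      x2 = list(list(shape = "activation", k = "ks"),
                list(shape = "decay", k = "kd", decay_of = "x2"))),
    readouts = list(x1 = list(type = "species", species = "x1"),
                    flux = list(type = "flux", input = "u1"))))
}

# Single first-order plant dx/dt = k_in*u1 - k_out*x, for control tests.
scalar_plant <- function(k_in = 1, k_out = 1) {
  parse_model_spec(list(
    species = list(list(name = "x", role = "insulin_cascade")),
    inputs = list("u1"),
    parameters = list(rate_constants = list(k_in = k_in, k_out = k_out)),
    terms = list(x = list(list(shape = "input_drive", k = "k_in", driver = "u1"),
                          list(shape = "decay", k = "k_out", decay_of = "x"))),
    readouts = list(x = list(type = "species", species = "x"))))
}

default_params <- function() {
  list(rate_constants = list(), binding_constants = list())
}

# A fake simulation result carrying constant readout trajectories, for
# pattern-check unit tests that need no integration.
fake_result <- function(values, n = 20) {
  ro <- matrix(rep(unlist(values), each = n), nrow = n,
               dimnames = list(NULL, names(values)))
  structure(list(times = seq_len(n), readouts = ro), class = "erins_sim_result")
}

# Session cache for the expensive shipped-configuration battery run.
.erins_cache <- new.env(parent = emptyenv())

default_model <- function() {
  if (is.null(.erins_cache$model))
    .erins_cache$model <- parse_model_spec(default_model_path())
  .erins_cache$model
}

battery_run <- function() {
  if (is.null(.erins_cache$run)) {
    .erins_cache$run <- run_battery(default_model(), load_battery(),
                                    load_pattern_table())
  }
  .erins_cache$run
}
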