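# model_core: term grammar, spec parsing/validation, compiled RHS.

test_that("parse_model_spec accepts the minimal stress-core document", {
  m <- tiny_pair_model()
  expect_s3_class(m, "erins_model")
  expect_equal(nrow(m$species), 2)
  expect_length(m$terms$x1, 2)
  expect_equal(m$terms$x1[[1]]$shape, "input_drive")
})

test_that("the bundled default roster parses and satisfies all invariants", {
  m <- parse_model_spec(default_model_path())
  expect_equal(nrow(m$species), 32)
  expect_true(all(lengths(m$terms) >= 1))
  expect_true(all(m$species$initial >= m$species$lower &
                    m$species$initial <= m$species$upper))
  # every readout the analysis needs is definable from the roster
  need <- c("pPERK_ratio", "pIRE1a_ratio", "peIF2a_ratio",
            "insulin_sensitivity", "flux_unfolded", "ATF6a", "pJNK",
            "pIKKb", "pNFkB", "IRpY", "IRSpY", "PIP3", "pFoxO1")
  expect_true(all(need %in% names(m$readouts)))
  ks <- unlist(c(m$parameters$rate_constants, m$parameters$binding_constants))
  expect_true(all(ks >= 0 & ks <= 5))
})

test_that("validation rejects malformed documents with informative errors", {
  base <- list(
    species = list(list(name = "x1", role = "stress_input_proxy")),
    inputs = list("u1"),
    parameters = list(rate_constants = list(k1 = 1)),
    terms = list(x1 = list(list(shape = "input_drive", k = "k1",
                                driver = "u1"))))
  # term referencing an undeclared species names it
  bad <- base
  bad$terms$x1[[2]] <- list(shape = "decay", k = "k1", decay_of = "x99")
  expect_error(parse_model_spec(bad), "x99",
               class = "erins_validation_error")
  # duplicate species
  bad <- base
  bad$species[[2]] <- list(name = "x1", role = "upr_sensor")
  expect_error(parse_model_spec(bad), "duplicate",
               class = "erins_validation_error")
  # parameter outside the sampling interval
  bad <- base
  bad$parameters$rate_constants$k1 <- 7
  expect_error(parse_model_spec(bad), "interval",
               class = "erins_validation_error")
  # unknown term shape
  bad <- base
  bad$terms$x1[[1]]$shape <- "sigmoid"
  expect_error(parse_model_spec(bad), "shape",
               class = "erins_validation_error")
  # orphan species (no rate term)
  bad <- base
  bad$species[[2]] <- list(name = "x2", role = "upr_effector")
  expect_error(parse_model_spec(bad), "x2",
               class = "erins_validation_error")
})

test_that("evaluate_term reproduces the three canonical term shapes", {
  p <- default_params()
  # input drive: k1 * u1
  t1 <- rate_term("input_drive", k = 1, driver = "u1")
  expect_equal(evaluate_term(t1, c(x1 = 1), c(u1 = 1.1025), p), 1.1025)
  # modulated activation: k40 * x19 * (1 + F2*x18) * x1 * x2
  t2 <- rate_term("activation", k = 1, factors = c("x19", "x1", "x2"),
                  accelerators = list(list(species = "x18", F = 1)))
  st <- c(x19 = 1, x18 = 1, x1 = 1, x2 = 1)
  expect_equal(evaluate_term(t2, st, c(), p), 2)
  # modulated decay: -k52 * x26 / ((1 + F3*x30)(1 + F4*x32))
  t3 <- rate_term("decay", k = 2, decay_of = "x26",
                  inhibitors = list(list(species = "x30", F = 1),
                                    list(species = "x32", F = 0)))
  expect_equal(evaluate_term(t3, c(x26 = 1, x30 = 1, x32 = 5), c(), p), -1)
  # missing species is a lookup error
  expect_error(evaluate_term(t3, c(x26 = 1), c(), p),
               class = "erins_lookup_error")
})

test_that("build_rhs sums terms and honours the steady-state construction", {
  m <- tiny_pair_model()
  x0 <- initial_state(m)
  # Eq-4-style input with amplify 1 nullifies the load derivative exactly
  f <- build_rhs(m, imode = 1L, iamp = 1)
  expect_identical(f(0, x0)[["x1"]], 0)
  # all rate constants zero -> zero derivative vector
  z <- tiny_pair_model(k1 = 0, k2 = 0)
  z$parameters$rate_constants[c("ks", "kd")] <- list(0, 0)
  fz <- build_rhs(z)
  expect_equal(unname(fz(0, initial_state(z))), c(0, 0))
  # worked arithmetic: dx20/dt = 2 - 1 = 1 at the unit state
  m2 <- parse_model_spec(list(
    species = lapply(c("x20", "x19", "x18", "x1", "x2"),
                     function(n) list(name = n, role = "upr_effector",
                                      initial = 1)),
    inputs = list(),
    parameters = list(rate_constants = list(k40 = 1, k41 = 1, one = 1),
                      binding_constants = list(F2 = 1)),
    terms = c(list(
      x20 = list(list(shape = "activation", k = "k40",
                      factors = list("x19", "x1", "x2"),
                      accelerators = list(list(species = "x18", F = "F2"))),
                 list(shape = "decay", k = "k41", decay_of = "x20"))),
      setNames(lapply(c("x19", "x18", "x1", "x2"), function(n)
        list(list(shape = "activation", k = "one", factors = list(n)),
             list(shape = "decay", k = "one", decay_of = n))),
        c("x19", "x18", "x1", "x2")))))
  f2 <- build_rhs(m2)
  expect_equal(f2(0, initial_state(m2))[["x20"]], 1)
})

test_that("compiled RHS equals the naive per-term interpreter (additivity)", {
  m <- parse_model_spec(default_model_path())
  ct <- erins:::compile_model(m, imode = c(0L, 0L), ivalue = c(2, 3))
  set.seed(42)
  for (rep in 1:5) {
    x <- runif(nrow(m$species), 0.1, 5)
    names(x) <- m$species$name
    fast <- erins:::.rhs_cpp(unname(x), ct)
    slow <- vapply(m$species$name, function(sp)
      sum(vapply(m$terms[[sp]], evaluate_term, 0, state = x,
                 inputs = c(u1 = 2, u2 = 3), params = m$parameters)), 0)
    expect_equal(unname(fast), unname(slow), tolerance = 1e-12)
  }
})

test_that("term contributions scale linearly in the rate constant", {
  p <- default_params()
  st <- c(a = 1.3, b = 0.7)
  set.seed(7)
  for (k in runif(5, 0, 5)) {
    tm <- rate_term("activation", k = k, factors = c("a", "b"))
    t1 <- rate_term("activation", k = 1, factors = c("a", "b"))
    expect_equal(evaluate_term(tm, st, c(), p),
                 k * evaluate_term(t1, st, c(), p))
    dm <- rate_term("decay", k = k, decay_of = "a",
                    inhibitors = list(list(species = "b", F = 2)))
    d1 <- rate_term("decay", k = 1, decay_of = "a",
                    inhibitors = list(list(species = "b", F = 2)))
    expect_equal(evaluate_term(dm, st, c(), p),
                 k * evaluate_term(d1, st, c(), p))
  }
})
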