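# Scenario battery: the two open-loop conditions (NCD control with the
# stress drive off; DIO with the amplified steady-state stress drive) and
# the twelve closed-loop "thought experiment" conditions (three marker
# pairings x four high/low reference combinations).

CASE_IDS <- c("I", "II", "III")
CONDITION_IDS <- c("high_high", "high_low", "low_high", "low_low")

# roman condition labels (i)-(iv) in the order used in the text:
# (i) high pPERK / low marker, (ii) high/high, (iii) low/high, (iv) low/low
ROMAN_CONDITIONS <- c(i = "high_low", ii = "high_high",
                      iii = "low_high", iv = "low_low")

normalize_condition <- function(condition) {
  condition <- gsub("/", "_", tolower(condition))
  if (condition %in% names(ROMAN_CONDITIONS))
    condition <- ROMAN_CONDITIONS[[condition]]
  if (!condition %in% CONDITION_IDS)
    config_error(sprintf(
      "unknown condition '%s' (expected one of %s, or i-iv)",
      condition, cstr(CONDITION_IDS)))
  condition
}

#' Load the scenario battery configuration
#'
#' The battery file defines the simulation grid, the open-loop input
#' policies for NCD and DIO, the two controller gain sets, the per-case
#' controlled readouts with their calibrated low/high reference values,
#' the low/high verdict thresholds, the expected verdict table and the
#' quantitative anchors used by calibration.
#'
#' @param path JSON battery configuration (default: the bundled calibrated
#'   battery).
#' @return list of class `erins_battery`.
#' @export
load_battery <- function(path = default_scenarios_path()) {
  doc <- read_config(path)
  for (sec in c("simulation", "open_loop", "controllers", "loop1", "cases"))
    if (is.null(doc[[sec]]))
      config_error(sprintf("battery config is missing the '%s' section", sec))
  doc$tail_fraction <- doc$tail_fraction %||% 0.1
  structure(doc, class = c("erins_battery", "list"))
}

battery_sim_config <- function(battery) {
  s <- battery$simulation
  sim_config(t_span = unlist(s$t_span), n_points = s$n_points,
             rel_tol = s$rel_tol %||% 1e-5, abs_tol = s$abs_tol %||% 1e-7)
}

policy_from_spec <- function(spec) {
  do.call(input_policy, lapply(spec, function(p) p))
}

scenario_names <- function() {
  c("NCD", "DIO",
    unlist(lapply(CASE_IDS, function(cs)
      paste("case", cs, CONDITION_IDS, sep = "_"))))
}

build_loops <- function(battery, case, condition) {
  parts <- strsplit(condition, "_")[[1]]
  lev_pperk <- parts[1]; lev_marker <- parts[2]
  g1 <- battery$controllers[[battery$loop1$controller %||% "upr"]]
  g2 <- battery$controllers[[battery$cases[[case]]$controller %||% "insulin"]]
  cdef <- battery$cases[[case]]
  list(
    control_loop(
      readout = battery$loop1$readout, input = battery$loop1$input %||% "u1",
      name = "pPERK",
      controller = pid_config(
        kp = g1$kp, ki = g1$ki, kd = g1$kd,
        reference = battery$loop1$references[[lev_pperk]],
        output_limits = unlist(g1$output_limits %||% c(0, Inf)),
        initial_output = battery$loop1$initial_output %||% 0)),
    control_loop(
      readout = cdef$readout, input = cdef$input %||% "u2",
      name = "marker",
      controller = pid_config(
        kp = g2$kp, ki = g2$ki, kd = g2$kd,
        reference = cdef$references[[lev_marker]],
        output_limits = unlist(g2$output_limits %||% c(0, Inf)),
        initial_output = cdef$initial_output %||% 0)))
}

#' Run a single named scenario
#'
#' @param model an `erins_model` (typically [parse_model_spec()] on the
#'   bundled calibrated config).
#' @param scenario scenario name: `"NCD"`, `"DIO"` or
#'   `"case_<I|II|III>_<pPERK level>_<marker level>"`.
#' @param battery an `erins_battery`.
#' @return an `erins_sim_result`; closed-loop scenarios carry the verdict in
#'   attribute `"verdict"`.
#' @export
run_scenario <- function(model, scenario, battery = load_battery()) {
  cfg <- battery_sim_config(battery)
  if (scenario %in% names(battery$open_loop)) {
    pol <- policy_from_spec(battery$open_loop[[scenario]])
    return(simulate(model, pol, cfg))
  }
  m <- regmatches(scenario,
                  regexec("^case_(I{1,3})_(high|low)_(high|low)$", scenario))[[1]]
  if (!length(m))
    config_error(sprintf("unknown scenario '%s'", scenario))
  run_thought_experiment(model, m[2], paste(m[3], m[4], sep = "_"), battery)
}

#' Run one closed-loop thought experiment
#'
#' Wires the two PID loops for the requested case (I: pPERK + IRpY,
#' II: pPERK + IRSpY, III: pPERK + pAKT signal ratio), with the pPERK and
#' marker references set to their configured low/high values, and simulates
#' the controlled plant. The result is classified low/high against the
#' battery's verdict thresholds.
#'
#' @param model an `erins_model`.
#' @param case `"I"`, `"II"` or `"III"`.
#' @param condition `"high_low"`, `"high_high"`, `"low_high"`, `"low_low"`
#'   (pPERK level first), `"high/low"` style, or roman `"i"`-`"iv"`.
#' @param battery an `erins_battery`.
#' @return an `erins_sim_result` with attribute `"verdict"` (see
#'   [classify_verdict()]).
#' @export
run_thought_experiment <- function(model, case, condition,
                                   battery = load_battery()) {
  if (!case %in% CASE_IDS)
    config_error(sprintf("unknown case '%s' (expected I, II or III)", case))
  condition <- normalize_condition(condition)
  loops <- build_loops(battery, case, condition)
  res <- closed_loop_simulate(model, loops, battery_sim_config(battery))
  attr(res, "scenario") <- paste("case", case, condition, sep = "_")
  attr(res, "verdict") <- classify_verdict(res, battery)
  res
}

#' Classify a run as low/high against the battery thresholds
#'
#' ER stress is judged from the steady unfolded-protein flux, insulin
#' sensitivity from the steady pAkt/Akt signal ratio, and the UPR arm from
#' the three phospho/total sensor ratios; each is compared against the
#' battery's per-readout threshold (the midpoint of the open-loop NCD and
#' DIO steady values).
#'
#' @param result an `erins_sim_result`.
#' @param battery an `erins_battery`.
#' @return list with `er_stress`, `insulin_sensitivity`, `upr` (overall UPR
#'   level), `upr_ratios` (per-ratio levels) and the underlying `values`.
#' @export
classify_verdict <- function(result, battery) {
  thr <- battery$verdict_thresholds
  tf <- battery$tail_fraction
  sv <- function(ro) {
    if (!ro %in% colnames(result$readouts))
      lookup_error(sprintf("verdict readout '%s' missing from result", ro))
    as.numeric(steady_value(result$readouts[, ro], tf))
  }
  lev <- function(v, t) if (v > t) "high" else "low"
  flux_ro <- battery$verdict_readouts$flux %||% "flux_unfolded"
  sens_ro <- battery$verdict_readouts$sensitivity %||% "insulin_sensitivity"
  upr_ros <- unlist(battery$verdict_readouts$upr %||%
                      c("pPERK_ratio", "pIRE1a_ratio", "peIF2a_ratio"))
  vals <- c(setNames(sv(flux_ro), flux_ro), setNames(sv(sens_ro), sens_ro),
            setNames(vapply(upr_ros, sv, 0), upr_ros))
  upr_levels <- vapply(upr_ros, function(ro) lev(vals[[ro]], thr[[ro]]), "")
  list(er_stress = lev(vals[[flux_ro]], thr[[flux_ro]]),
       insulin_sensitivity = lev(vals[[sens_ro]], thr[[sens_ro]]),
       upr = if (sum(upr_levels == "high") >= 2) "high" else "low",
       upr_ratios = upr_levels,
       values = vals)
}

#' Run the full scenario battery
#'
#' Runs NCD, DIO and all twelve thought-experiment conditions, checks the
#' qualitative pattern table on the open-loop pair, and compares every
#' closed-loop verdict against the expected verdict table.
#'
#' @param model an `erins_model`.
#' @param battery an `erins_battery`.
#' @param patterns an `erins_pattern_table` (or `NULL` to skip).
#' @return list of class `erins_battery_run` with `results` (named list),
#'   `pattern_check`, `verdicts` (data.frame), and `all_pass`.
#' @export
run_battery <- function(model, battery = load_battery(),
                        patterns = load_pattern_table()) {
  cases <- intersect(CASE_IDS, names(battery$cases))
  results <- list()
  for (nm in names(battery$open_loop))
    results[[nm]] <- run_scenario(model, nm, battery)
  for (cs in cases)
    for (cond in CONDITION_IDS) {
      nm <- paste("case", cs, cond, sep = "_")
      results[[nm]] <- run_thought_experiment(model, cs, cond, battery)
    }

  pattern_check <- if (!is.null(patterns))
    check_qualitative_patterns(results, patterns, battery$tail_fraction)

  verdict_rows <- list()
  for (cs in cases)
    for (cond in CONDITION_IDS) {
      nm <- paste("case", cs, cond, sep = "_")
      v <- attr(results[[nm]], "verdict")
      exp <- battery$expected_verdicts[[cs]][[cond]]
      verdict_rows[[nm]] <- data.frame(
        scenario = nm, case = cs, condition = cond,
        er_stress = v$er_stress, insulin_sensitivity = v$insulin_sensitivity,
        upr = v$upr,
        expected_er_stress = exp$er_stress %||% NA,
        expected_insulin_sensitivity = exp$insulin_sensitivity %||% NA,
        expected_upr = exp$upr %||% NA)
    }
  verdicts <- do.call(rbind, verdict_rows)
  if (!is.null(verdicts))
    verdicts$matched <- with(verdicts,
      er_stress == expected_er_stress &
      insulin_sensitivity == expected_insulin_sensitivity &
      upr == expected_upr)

  all_pass <- (is.null(pattern_check) || all(pattern_check$passed)) &&
    (is.null(verdicts) || all(verdicts$matched))
  structure(list(results = results, pattern_check = pattern_check,
                 verdicts = verdicts, all_pass = all_pass,
                 battery = battery),
            class = "erins_battery_run")
}

#' @export
print.erins_battery_run <- function(x, ...) {
  np <- if (!is.null(x$pattern_check))
    sprintf("%d/%d patterns", sum(x$pattern_check$passed),
            nrow(x$pattern_check)) else "no pattern table"
  cat(sprintf("<erins_battery_run> %d scenarios; %s; %d/%d verdicts matched\n",
              length(x$results), np, sum(x$verdicts$matched),
              max(NROW(x$verdicts), 0)))
  invisible(x)
}

# First grid time after which `traj` stays strictly below `frac` of its
# initial value; Inf if it never settles below.
flux_zero_time <- function(times, traj, frac = 0.01) {
  thr <- frac * traj[1]
  above <- which(traj >= thr)
  if (!length(above)) return(times[1])
  if (max(above) == length(traj)) return(Inf)
  times[max(above) + 1L]
}

# Evaluate one quantitative anchor against a set of scenario results.
anchor_value <- function(results, anchor, tail_fraction = 0.1) {
  res <- results[[anchor$scenario]]
  if (is.null(res))
    lookup_error(sprintf("anchor '%s' references missing scenario '%s'",
                         anchor$id, anchor$scenario))
  switch(anchor$type,
    steady = as.numeric(steady_value(res$readouts[, anchor$readout],
                                     tail_fraction)),
    steady_mean = mean(vapply(unlist(anchor$readouts), function(ro)
      as.numeric(steady_value(res$readouts[, ro], tail_fraction)), 0)),
    flux_zero_time = flux_zero_time(res$times, res$readouts[, anchor$readout],
                                    anchor$threshold %||% 0.01),
    config_error(sprintf("unknown anchor type '%s'", anchor$type)))
}
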