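#' Load a qualitative pattern table
#'
#' A pattern table encodes categorical contrasts between conditions
#' ("readout R is strictly higher in DIO than in NCD") as rows with columns
#' `id`, `readout`, `condition_a`, `condition_b`, `relation`
#' (`greater`/`less`, interpreted as condition_a vs condition_b) and a free
#' text `provenance`. The bundled table encodes the DIO-vs-NCD western-blot
#' and qPCR contrasts: stress markers up, insulin-signalling markers down.
#'
#' @param x path to a CSV file or a data.frame.
#' @return validated data.frame of class `erins_pattern_table`.
#' @export
load_pattern_table <- function(x = default_patterns_path()) {
  df <- if (is.data.frame(x)) x else read.csv(x, stringsAsFactors = FALSE)
  need <- c("id", "readout", "condition_a", "condition_b", "relation")
  missing <- setdiff(need, names(df))
  if (length(missing))
    config_error(sprintf("pattern table is missing columns: %s", cstr(missing)))
  if (!"provenance" %in% names(df)) df$provenance <- rep("", nrow(df))
  bad <- setdiff(df$relation, c("greater", "less"))
  if (length(bad))
    config_error(sprintf("unknown relations in pattern table: %s", cstr(bad)))
  if (any(df$condition_a == df$condition_b))
    config_error("pattern constraints must compare two distinct conditions")
  if (anyDuplicated(df$id))
    config_error("pattern ids must be unique")
  structure(df, class = c("erins_pattern_table", "data.frame"))
}

#' Check model outputs against a qualitative pattern table
#'
#' A constraint passes iff the steady value of its readout in condition A is
#' strictly greater (or less) than in condition B; ties fail, mirroring the
#' categorical higher/lower claims the table encodes.
#'
#' @param results named list of `erins_sim_result` objects, one per
#'   condition.
#' @param patterns an `erins_pattern_table`.
#' @param tail_fraction passed to [steady_value()].
#' @return data.frame with one row per constraint (`id`, `readout`,
#'   `value_a`, `value_b`, `passed`) and attribute `score` (fraction
#'   passed; 1 for an empty table).
#' @export
check_qualitative_patterns <- function(results, patterns,
                                       tail_fraction = 0.1) {
  if (!nrow(patterns)) {
    out <- data.frame(id = character(), readout = character(),
                      value_a = numeric(), value_b = numeric(),
                      passed = logical())
    attr(out, "score") <- 1.0
    return(out)
  }
  conds <- unique(c(patterns$condition_a, patterns$condition_b))
  missing <- setdiff(conds, names(results))
  if (length(missing))
    lookup_error(sprintf("no simulation result for condition(s): %s",
                         cstr(missing)))
  rows <- lapply(seq_len(nrow(patterns)), function(i) {
    p <- patterns[i, ]
    for (cond in c(p$condition_a, p$condition_b)) {
      if (!p$readout %in% colnames(results[[cond]]$readouts))
        lookup_error(sprintf("readout '%s' absent from condition '%s'",
                             p$readout, cond))
    }
    va <- as.numeric(steady_value(results[[p$condition_a]]$readouts[, p$readout],
                                  tail_fraction))
    vb <- as.numeric(steady_value(results[[p$condition_b]]$readouts[, p$readout],
                                  tail_fraction))
    ok <- if (p$relation == "greater") va > vb else va < vb
    data.frame(id = p$id, readout = p$readout, value_a = va, value_b = vb,
               passed = ok)
  })
  out <- do.call(rbind, rows)
  attr(out, "score") <- mean(out$passed)
  out
}

# Assign relative condition means per readout from the ordering constraints:
# level 0 for the lowest condition, each `greater` edge lifting the target by
# one fold-change. Cycles (contradictory constraints) are reported.
pattern_levels <- function(patterns) {
  out <- list()
  for (ro in unique(patterns$readout)) {
    sub <- patterns[patterns$readout == ro, ]
    # edge lo -> hi for every constraint
    lo <- ifelse(sub$relation == "greater", sub$condition_b, sub$condition_a)
    hi <- ifelse(sub$relation == "greater", sub$condition_a, sub$condition_b)
    nodes <- unique(c(lo, hi))
    lev <- setNames(rep(0, length(nodes)), nodes)
    for (pass in seq_len(length(nodes) + 1)) {
      changed <- FALSE
      for (e in seq_along(lo)) {
        if (lev[[hi[e]]] < lev[[lo[e]]] + 1) {
          lev[[hi[e]]] <- lev[[lo[e]]] + 1
          changed <- TRUE
        }
      }
      if (!changed) break
      if (pass > length(nodes))
        validation_error(sprintf(
          "contradictory ordering constraints for readout '%s' (cycle among: %s)",
          ro, cstr(nodes)), readout = ro)
    }
    out[[ro]] <- lev
  }
  out
}

#' Generate synthetic replicate densitometry observations
#'
#' Synthetic stand-in for replicate western-blot/qPCR measurements: for every
#' readout in the pattern table, condition means are separated by
#' `effect_size`-fold in the direction the constraints state, and `n`
#' positive replicates are drawn around each mean with multiplicative
#' lognormal noise (mean-corrected, so the expected replicate mean equals the
#' condition mean).
#'
#' @param patterns an `erins_pattern_table`.
#' @param effect_size fold-change between adjacent ordered conditions (> 1).
#' @param sigma lognormal noise standard deviation (log scale).
#' @param n replicates per condition (>= 2); densitometry panels in this
#'   design use n = 4.
#' @param seed integer seed; generation is fully reproducible.
#' @return tidy data.frame (`readout`, `condition`, `replicate`, `value`)
#'   of class `erins_synthetic_blots`.
#' @export
generate_synthetic_blots <- function(patterns, effect_size = 2, sigma = 0.2,
                                     n = 4, seed = 1) {
  if (effect_size <= 1) validation_error("effect_size must be > 1")
  if (n < 2) validation_error("n must be >= 2")
  levels <- pattern_levels(patterns)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rows <- list()
  for (ro in names(levels)) {
    for (cond in names(levels[[ro]])) {
      m <- effect_size^levels[[ro]][[cond]]
      vals <- m * exp(rnorm(n, mean = -sigma^2 / 2, sd = sigma))
      rows[[length(rows) + 1L]] <-
        data.frame(readout = ro, condition = cond, replicate = seq_len(n),
                   value = vals)
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("erins_synthetic_blots", "data.frame"),
            effect_size = effect_size, sigma = sigma, n = n, seed = seed)
}

# Condition means of a synthetic blot set, readout x condition.
blot_means <- function(blots) {
  agg <- stats::aggregate(value ~ readout + condition, data = blots, FUN = mean)
  agg
}

#' Check synthetic blots against their generating pattern table
#'
#' @param blots output of [generate_synthetic_blots()].
#' @param patterns the generating `erins_pattern_table`.
#' @return logical vector, one element per constraint (`TRUE` = replicate
#'   means satisfy the stated ordering).
#' @export
check_blots_against_patterns <- function(blots, patterns) {
  m <- blot_means(blots)
  key <- function(ro, cond) m$value[m$readout == ro & m$condition == cond]
  vapply(seq_len(nrow(patterns)), function(i) {
    p <- patterns[i, ]
    va <- key(p$readout, p$condition_a)
    vb <- key(p$readout, p$condition_b)
    if (p$relation == "greater") va > vb else va < vb
  }, TRUE)
}
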