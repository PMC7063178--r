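#' Export a model to SBML Level 3 (rate rules)
#'
#' Writes the compiled network as an SBML Level 3 Version 2 document: one
#' compartment, every species with its initial amount, all rate and binding
#' constants as parameters, the external inputs as constant parameters (at
#' their value for the given policy at the initial state), and one rate rule
#' per species carrying the summed term expressions as MathML.
#'
#' @param model an `erins_model`.
#' @param path output file.
#' @param policy an [input_policy()] used to value the input parameters.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(model, path, policy = input_policy()) {
  if (!requireNamespace("xml2", quietly = TRUE))
    config_error("SBML export requires the 'xml2' package")
  x0 <- initial_state(model)
  res <- resolve_policy(model, policy, x0)
  ct <- compile_model(model, res$imode, res$ivalue, res$iamp)
  uvals <- .inputs_cpp(as.numeric(x0), ct)

  ci <- function(x) sprintf("<ci> %s </ci>", x)
  cn <- function(x) sprintf("<cn> %s </cn>", format(x, digits = 15))
  times <- function(...) {
    args <- c(...)
    if (length(args) == 1) args
    else sprintf("<apply><times/>%s</apply>", paste(args, collapse = ""))
  }
  plus1 <- function(Fname, sp)
    sprintf("<apply><plus/><cn> 1 </cn>%s</apply>", times(ci(Fname), ci(sp)))
  pname <- function(k) if (is.character(k)) ci(k) else cn(k)

  term_math <- function(term) {
    switch(term$shape,
      input_drive = times(pname(term$k), ci(term$driver)),
      activation = times(pname(term$k),
                         vapply(term$factors, ci, ""),
                         vapply(term$accelerators, function(a)
                           plus1(if (is.character(a$F)) a$F else
                             format(a$F), a$species), "")),
      decay = {
        num <- times(pname(term$k), ci(term$decay_of),
                     vapply(term$factors, ci, ""))
        expr <- if (length(term$inhibitors)) {
          den <- times(vapply(term$inhibitors, function(a)
            plus1(if (is.character(a$F)) a$F else format(a$F), a$species), ""))
          sprintf("<apply><divide/>%s%s</apply>", num, den)
        } else num
        sprintf("<apply><minus/>%s</apply>", expr)
      })
  }

  species_xml <- paste(sprintf(
    '    <species id="%s" compartment="cell" initialAmount="%g" hasOnlySubstanceUnits="true" boundaryCondition="false" constant="false"/>',
    model$species$name, model$species$initial), collapse = "\n")
  pars <- c(model$parameters$rate_constants, model$parameters$binding_constants)
  par_xml <- paste(c(sprintf(
    '    <parameter id="%s" value="%g" constant="true"/>',
    names(pars), unlist(pars)),
    sprintf('    <parameter id="%s" value="%g" constant="true"/>',
            model$inputs, uvals)), collapse = "\n")
  rule_xml <- paste(vapply(model$species$name, function(sp) {
    maths <- vapply(model$terms[[sp]], term_math, "")
    body <- if (length(maths) == 1) maths
      else sprintf("<apply><plus/>%s</apply>", paste(maths, collapse = ""))
    sprintf(paste0(
      '    <rateRule variable="%s">\n',
      '      <math xmlns="http://www.w3.org/1998/Math/MathML">%s</math>\n',
      '    </rateRule>'), sp, body)
  }, ""), collapse = "\n")

  doc <- sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">\n',
    '<model id="erins_model">\n',
    '  <listOfCompartments>\n',
    '    <compartment id="cell" size="1" constant="true"/>\n',
    '  </listOfCompartments>\n',
    '  <listOfSpecies>\n%s\n  </listOfSpecies>\n',
    '  <listOfParameters>\n%s\n  </listOfParameters>\n',
    '  <listOfRules>\n%s\n  </listOfRules>\n',
    '</model>\n</sbml>\n'), species_xml, par_xml, rule_xml)
  # fail loudly on malformed output before writing
  xml2::read_xml(doc)
  writeLines(doc, path)
  invisible(path)
}
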