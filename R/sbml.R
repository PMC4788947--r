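# Minimal SBML Level 3 Version 1 writer for the reduced circuit model.
# The model is expressed exactly as simulated: nine species governed by
# rate rules plus the algebraic monomer M as an assignment rule.

# R expression -> MathML (content markup), recursively over the call tree.
.mathml <- function(e) {
  if (is.numeric(e)) return(paste0("<cn> ", format(e, digits = 17),
                                   " </cn>"))
  if (is.name(e)) return(paste0("<ci> ", as.character(e), " </ci>"))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    args <- as.list(e)[-1]
    if (op == "(") return(.mathml(args[[1]]))
    if (op == "-" && length(args) == 1)
      return(paste0("<apply><minus/>", .mathml(args[[1]]), "</apply>"))
    if (op == "sqrt")
      return(paste0("<apply><root/><degree><cn> 2 </cn></degree>",
                    .mathml(args[[1]]), "</apply>"))
    tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                  "/" = "divide", "^" = "power",
                  stop("unsupported operator in SBML math: ", op))
    return(paste0("<apply><", tag, "/>",
                  paste(vapply(args, .mathml, character(1)),
                        collapse = ""), "</apply>"))
  }
  stop("unsupported expression in SBML math")
}

.sbml_rules <- function() {
  # rate rules of the reduced model; M is the QSSA assignment
  list(
    M = quote(-(dAI + k_2) / (4 * k3) +
                sqrt((dAI + k_2)^2 + 8 * k3 * (k2 * x2 * x3 +
                                                 2 * k_3 * x4)) / (4 * k3)),
    x1 = quote(kmA_CgA - dmA * x1),
    x2 = quote(kpA * x1 - dA * x2 - k2 * x2 * x3 + k_2 * M),
    x3 = quote(-(k2 * x2 * x3) + k_2 * M + kd * (x9 - x3) - dI * x3),
    x4 = quote(k3 * M^2 - k_3 * x4 - dAI2 * x4),
    x5 = quote(kmB_CgB * (x4 / (gamma1 + x4)) - dmB * x5),
    x6 = quote(kpB * x5 - dB * x6),
    x7 = quote(kmC_CgC * ((x4 + beta1 * gamma4 * x6 +
                             beta2 * gamma5 * x4 * x6) /
                            (gamma2 + gamma3 * x4 + gamma4 * x6 +
                               gamma5 * x4 * x6)) - dmC * x7),
    x8 = quote(kpC * x7 - dC * x8),
    x9 = quote(Kcells * kd * (x3 - x9) - dIe * x9)
  )
}

#' Export the circuit model as SBML Level 3 Version 1
#'
#' Writes the reduced model as an SBML document: the ten model variables
#' (nine dynamic species plus the algebraic monomer M) in a single
#' compartment, every kinetic constant as a parameter, the nine ODEs as
#' rate rules and M as an assignment rule.  The document reflects exactly
#' the equations the package simulates.
#'
#' @param params [circuit_parameters()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(params = circuit_parameters(), path) {
  species <- c(paste0("x", 1:9), "M")
  consts <- setdiff(names(params), c("Vcell", "Ncells", "Vmedium"))
  vals <- c(setNames(lapply(consts, function(nm) params[[nm]]), consts),
            list(Kcells = compute_kcells(params$Vcell, params$Ncells,
                                         params$Vmedium)))
  rules <- .sbml_rules()
  sp <- paste(sprintf(
    '      <species id="%s" compartment="cell" initialConcentration="0" hasOnlySubstanceUnits="false" boundaryCondition="%s" constant="false"/>',
    species, ifelse(species == "M", "true", "false")), collapse = "\n")
  par <- paste(sprintf(
    '      <parameter id="%s" value="%s" constant="true"/>',
    names(vals), vapply(vals, function(v) format(v, digits = 17),
                        character(1))), collapse = "\n")
  rl <- vapply(names(rules), function(v) {
    tag <- if (v == "M") "assignmentRule" else "rateRule"
    sprintf(
      '      <%s variable="%s">\n        <math xmlns="http://www.w3.org/1998/Math/MathML">%s</math>\n      </%s>',
      tag, v, .mathml(rules[[v]]), tag)
  }, character(1))
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">\n',
    '  <model id="i1ffl_reduced" name="Reduced I1-FFL adaptation circuit" timeUnits="minute">\n',
    '    <listOfCompartments>\n',
    '      <compartment id="cell" spatialDimensions="3" size="1" constant="true"/>\n',
    '    </listOfCompartments>\n',
    '    <listOfSpecies>\n', sp, '\n    </listOfSpecies>\n',
    '    <listOfParameters>\n', par, '\n    </listOfParameters>\n',
    '    <listOfRules>\n', paste(rl, collapse = "\n"),
    '\n    </listOfRules>\n',
    '  </model>\n</sbml>\n')
  # validate well-formedness before writing
  parsed <- tryCatch(xml2::read_xml(doc), error = function(e)
    stop("export_sbml(): generated document is not well-formed: ",
         conditionMessage(e), call. = FALSE))
  ok <- tryCatch({
    writeLines(doc, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    stop("export_sbml(): cannot write to ", path, call. = FALSE)
  invisible(path)
}
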