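#' Import an SBML model as an ode_system
#'
#' Reads an SBML Level 2/3 file, assembles the stoichiometry-weighted right-
#' hand side from the reaction kinetic laws (MathML content markup), and
#' returns a symbolic [ode_system]. Species with `boundaryCondition` or
#' `constant` set become constant species (zero derivative). Local reaction
#' parameters are renamed `<reaction id>_<parameter id>` when they would
#' clash with a global identifier, so parameter names stay unique.
#'
#' Constructs outside the supported subset are rejected, not ignored:
#' rules, events, constraints, function definitions, and compartments with a
#' size other than 1 all raise an import error naming the construct.
#'
#' @param path path to an SBML XML file.
#' @return an [ode_system].
#' @export
#' @examples
#' path <- system.file("extdata", "t1-synthetic.xml", package = "teaps")
#' m <- import_sbml(path)
#' rhs_eval(m, c(1, 1, 1), c(k1 = 1, v2 = 2, km2 = 1, k3 = 1, k4 = 1))
import_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML import error: malformed XML (",
                                           conditionMessage(e), ")"))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "sb")
  model <- xml2::xml_find_first(doc, ".//sb:model", ns)
  if (inherits(model, "xml_missing"))
    stop("SBML import error: no <model> element")
  reject <- c(listOfRules = "rules", listOfEvents = "events",
              listOfConstraints = "constraints",
              listOfFunctionDefinitions = "function definitions",
              listOfInitialAssignments = "initial assignments")
  for (tag in names(reject)) {
    node <- xml2::xml_find_first(model, paste0("./sb:", tag), ns)
    if (!inherits(node, "xml_missing") &&
        length(xml2::xml_children(node)) > 0)
      stop("SBML import error: unsupported construct: ", reject[[tag]])
  }
  comps <- xml2::xml_find_all(model, ".//sb:listOfCompartments/sb:compartment",
                              ns)
  for (cp in comps) {
    size <- xml2::xml_attr(cp, "size")
    if (!is.na(size) && abs(as.numeric(size) - 1) > 0)
      stop("SBML import error: unsupported construct: compartment with size != 1")
  }
  sp_nodes <- xml2::xml_find_all(model, ".//sb:listOfSpecies/sb:species", ns)
  if (!length(sp_nodes)) stop("SBML import error: model has no species")
  species <- xml2::xml_attr(sp_nodes, "id")
  boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true" |
    xml2::xml_attr(sp_nodes, "constant") %in% "true"
  gp_nodes <- xml2::xml_find_all(model, "./sb:listOfParameters/sb:parameter",
                                 ns)
  params <- xml2::xml_attr(gp_nodes, "id")
  rxn_nodes <- xml2::xml_find_all(model, ".//sb:listOfReactions/sb:reaction",
                                  ns)
  net <- stats::setNames(vector("list", length(species)), species)
  for (s in species) net[[s]] <- list()
  reactions <- list()
  for (rx in rxn_nodes) {
    rid <- xml2::xml_attr(rx, "id")
    kl <- xml2::xml_find_first(rx, "./sb:kineticLaw", ns)
    if (inherits(kl, "xml_missing"))
      stop("SBML import error: reaction ", rid, " has no kinetic law")
    # local parameters, renamed on clash
    lp <- xml2::xml_find_all(
      kl, "./sb:listOfParameters/sb:parameter | ./sb:listOfLocalParameters/sb:localParameter",
      ns)
    rename <- character(0)
    for (p in lp) {
      pid <- xml2::xml_attr(p, "id")
      newid <- if (pid %in% c(params, species)) paste(rid, pid, sep = "_")
               else pid
      rename[pid] <- newid
      params <- c(params, newid)
    }
    math <- xml2::xml_find_first(kl, "./*[local-name()='math']/*")
    if (inherits(math, "xml_missing"))
      stop("SBML import error: reaction ", rid, " kinetic law has no math")
    expr <- mathml_to_expr(math, rename)
    reactions[[rid]] <- expr
    add_side <- function(xpath, sign) {
      refs <- xml2::xml_find_all(rx, xpath, ns)
      for (ref in refs) {
        sid <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        if (!sid %in% species)
          stop("SBML import error: unknown species ", sid, " in reaction ", rid)
        net[[sid]][[length(net[[sid]]) + 1L]] <<- list(sign * st, expr)
      }
    }
    add_side("./sb:listOfReactants/sb:speciesReference", -1)
    add_side("./sb:listOfProducts/sb:speciesReference", +1)
  }
  rhs <- lapply(species, function(s) {
    if (boundary[match(s, species)] || !length(net[[s]])) return(0)
    acc <- NULL
    for (term in net[[s]]) {
      piece <- if (term[[1]] == 1) term[[2]]
               else if (term[[1]] == -1) call("-", term[[2]])
               else call("*", term[[1]], term[[2]])
      if (is.null(acc)) acc <- piece
      else if (term[[1]] < 0 && !is.call(piece)) acc <- call("-", acc, term[[2]])
      else if (identical(piece[[1]], as.name("-")) && length(piece) == 2L)
        acc <- call("-", acc, piece[[2]])
      else acc <- call("+", acc, piece)
    }
    acc
  })
  ode_system(name = xml2::xml_attr(model, "id"),
             species = species, params = unique(params), rhs = rhs,
             reactions = reactions)
}

# Translate a MathML content-markup node to an R expression. Supported:
# apply with plus/minus/times/divide/power, ci, cn (plain and e-notation).
mathml_to_expr <- function(node, rename = character(0)) {
  name <- xml2::xml_name(node)
  if (name == "ci") {
    id <- trimws(xml2::xml_text(node))
    if (id %in% names(rename)) id <- rename[[id]]
    return(as.name(id))
  }
  if (name == "cn") {
    type <- xml2::xml_attr(node, "type")
    if (!is.na(type) && type == "e-notation") {
      parts <- xml2::xml_contents(node)
      nums <- trimws(xml2::xml_text(parts[xml2::xml_name(parts) != "sep"]))
      nums <- nums[nzchar(nums)]
      return(as.numeric(nums[1]) * 10^as.numeric(nums[2]))
    }
    return(as.numeric(trimws(xml2::xml_text(node))))
  }
  if (name == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- lapply(kids[-1], mathml_to_expr, rename = rename)
    fold <- function(f) Reduce(function(a, b) call(f, a, b), args)
    return(switch(
      op,
      plus = if (length(args) == 0) 0 else fold("+"),
      times = fold("*"),
      minus = if (length(args) == 1L) call("-", args[[1]]) else fold("-"),
      divide = fold("/"),
      power = fold("^"),
      exp = call("exp", args[[1]]),
      ln = call("log", args[[1]]),
      stop("SBML import error: unsupported MathML operator: ", op)))
  }
  stop("SBML import error: unsupported MathML node: ", name)
}

# R expression -> MathML content markup (the subset mathml_to_expr reads).
expr_to_mathml <- function(e) {
  if (is.numeric(e)) return(paste0("<cn> ", format(e, digits = 17), " </cn>"))
  if (is.name(e)) return(paste0("<ci> ", as.character(e), " </ci>"))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                  "/" = "divide", "^" = "power",
                  "(" = return(expr_to_mathml(e[[2]])),
                  stop("cannot export operator to MathML: ", op))
    inner <- paste(vapply(as.list(e)[-1], expr_to_mathml, character(1)),
                   collapse = "")
    return(paste0("<apply><", tag, "/>", inner, "</apply>"))
  }
  stop("cannot export expression to MathML: ", deparse1(e))
}

#' Export an ode_system to SBML (round-trip support)
#'
#' Writes a minimal SBML Level 2 document whose species derivatives are
#' expressed as one pseudo-reaction per dynamic species carrying the full
#' right-hand side as its kinetic law; constant species are written with
#' `boundaryCondition="true"`. [import_sbml] of the result reproduces a
#' symbolically equivalent system.
#'
#' @param model an [ode_system].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(model, path) {
  sp <- vapply(seq_along(model$species), function(i) {
    sprintf('      <species id="%s" compartment="cell" initialConcentration="1"%s/>',
            model$species[i],
            if (model$constant_mask[i]) ' boundaryCondition="true"' else "")
  }, character(1))
  pars <- vapply(model$params, function(p)
    sprintf('      <parameter id="%s" value="1"/>', p), character(1))
  rxns <- character(0)
  for (i in seq_along(model$species)) {
    if (model$constant_mask[i]) next
    rxns <- c(rxns, sprintf(paste0(
      '      <reaction id="net_%s" reversible="true">\n',
      '        <listOfProducts>\n',
      '          <speciesReference species="%s" stoichiometry="1"/>\n',
      '        </listOfProducts>\n',
      '        <kineticLaw>\n',
      '          <math xmlns="http://www.w3.org/1998/Math/MathML">%s</math>\n',
      '        </kineticLaw>\n',
      '      </reaction>'),
      model$species[i], model$species[i],
      expr_to_mathml(model$rhs[[i]])))
  }
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">\n',
    '  <model id="', model$name, '">\n',
    '    <listOfCompartments>\n',
    '      <compartment id="cell" size="1"/>\n',
    '    </listOfCompartments>\n',
    '    <listOfSpecies>\n', paste(sp, collapse = "\n"), '\n',
    '    </listOfSpecies>\n',
    '    <listOfParameters>\n', paste(pars, collapse = "\n"), '\n',
    '    </listOfParameters>\n',
    '    <listOfReactions>\n', paste(rxns, collapse = "\n"), '\n',
    '    </listOfReactions>\n',
    '  </model>\n',
    '</sbml>\n')
  writeLines(xml, path)
  invisible(path)
}
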