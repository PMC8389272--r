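# SBML Level 3 Version 1 Core interchange, built on xml2.
#
# Import maps species -> species symbols (boundary/constant -> pool),
# kineticLaw MathML -> custom rate expressions, assignmentRules -> rules,
# events -> event specs, all into ONE layer named after the model id (the
# format itself cannot carry layer information; partition_scheme() re-layers
# afterwards). Unsupported constructs (fast reactions, csymbol delay,
# dynamic stoichiometry, multiple piecewise, rate/algebraic rules, event
# delays/priorities, function definitions) abort with an error naming the
# feature rather than being skipped silently.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
DELAY_CSYMBOL <- "http://www.sbml.org/sbml/symbols/delay"
TIME_CSYMBOL <- "http://www.sbml.org/sbml/symbols/time"

# ---------------------------------------------------------------- MathML --

mathml_to_ast <- function(node) {
  name <- xml2::xml_name(node)
  kids <- xml2::xml_children(node)
  if (name == "math") {
    if (length(kids) != 1L)
      rxn_abort("MathML <math> must contain exactly one expression",
                "rxnsim_sbml_error")
    return(mathml_to_ast(kids[[1L]]))
  }
  if (name == "cn") {
    type <- xml2::xml_attr(node, "type")
    if (!is.na(type) && type == "rational") {
      parts <- as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]])
      return(list(type = "num", value = parts[[1L]] / parts[[2L]]))
    }
    if (!is.na(type) && type == "e-notation") {
      txt <- xml2::xml_text(node)
      parts <- as.numeric(strsplit(trimws(txt), "\\s+")[[1]])
      return(list(type = "num", value = parts[[1L]] * 10^parts[[2L]]))
    }
    return(list(type = "num", value = as.numeric(xml2::xml_text(node))))
  }
  if (name == "ci")
    return(list(type = "sym", name = trimws(xml2::xml_text(node))))
  if (name == "csymbol") {
    url <- xml2::xml_attr(node, "definitionURL")
    if (!is.na(url) && grepl("delay", url))
      rxn_abort("unsupported SBML feature: csymbol delay", "rxnsim_sbml_unsupported")
    if (!is.na(url) && grepl("time", url))
      return(list(type = "sym", name = "t"))
    rxn_abort(sprintf("unsupported SBML feature: csymbol %s", url),
              "rxnsim_sbml_unsupported")
  }
  if (name == "piecewise") {
    pieces <- kids[xml2::xml_name(kids) == "piece"]
    other <- kids[xml2::xml_name(kids) == "otherwise"]
    if (length(pieces) != 1L || length(other) != 1L)
      rxn_abort("unsupported SBML feature: multiple piecewise",
                "rxnsim_sbml_unsupported")
    pk <- xml2::xml_children(pieces[[1L]])
    return(list(type = "call", fn = "piecewise",
                args = list(mathml_to_ast(pk[[1L]]), mathml_to_ast(pk[[2L]]),
                            mathml_to_ast(xml2::xml_children(other[[1L]])[[1L]]))))
  }
  if (name != "apply")
    rxn_abort(sprintf("unsupported MathML element <%s>", name), "rxnsim_sbml_error")

  op <- kids[[1L]]
  opname <- xml2::xml_name(op)
  args <- lapply(kids[-1L], mathml_to_ast)
  nary <- function(o) Reduce(function(a, b) list(type = "binop", op = o, lhs = a, rhs = b), args)
  switch(opname,
    plus = if (length(args) == 0L) list(type = "num", value = 0)
           else if (length(args) == 1L) args[[1L]] else nary("+"),
    minus = if (length(args) == 1L) list(type = "unop", op = "neg", arg = args[[1L]])
            else nary("-"),
    times = if (length(args) == 0L) list(type = "num", value = 1)
            else if (length(args) == 1L) args[[1L]] else nary("*"),
    divide = nary("/"),
    power = list(type = "binop", op = "^", lhs = args[[1L]], rhs = args[[2L]]),
    exp = list(type = "call", fn = "exp", args = args),
    ln = list(type = "call", fn = "ln", args = args),
    log = {
      lb <- kids[xml2::xml_name(kids) == "logbase"]
      if (length(lb)) {
        base_ast <- mathml_to_ast(xml2::xml_children(lb[[1L]])[[1L]])
        if (base_ast$type == "num" && base_ast$value == 10)
          list(type = "call", fn = "log10", args = args[-1L])
        else rxn_abort("unsupported MathML: log with non-10 base", "rxnsim_sbml_error")
      } else list(type = "call", fn = "log10", args = args)
    },
    root = {
      dg <- kids[xml2::xml_name(kids) == "degree"]
      if (length(dg))
        rxn_abort("unsupported MathML: root with explicit degree", "rxnsim_sbml_error")
      list(type = "call", fn = "sqrt", args = args)
    },
    abs = list(type = "call", fn = "abs", args = args),
    min = list(type = "call", fn = "min", args = args),
    max = list(type = "call", fn = "max", args = args),
    lt = list(type = "binop", op = "<", lhs = args[[1L]], rhs = args[[2L]]),
    leq = list(type = "binop", op = "<=", lhs = args[[1L]], rhs = args[[2L]]),
    gt = list(type = "binop", op = ">", lhs = args[[1L]], rhs = args[[2L]]),
    geq = list(type = "binop", op = ">=", lhs = args[[1L]], rhs = args[[2L]]),
    eq = list(type = "binop", op = "==", lhs = args[[1L]], rhs = args[[2L]]),
    and = nary("and"),
    or = nary("or"),
    not = list(type = "unop", op = "not", arg = args[[1L]]),
    csymbol = {
      url <- xml2::xml_attr(op, "definitionURL")
      if (!is.na(url) && grepl("delay", url))
        rxn_abort("unsupported SBML feature: csymbol delay", "rxnsim_sbml_unsupported")
      rxn_abort(sprintf("unsupported MathML operator csymbol %s", url),
                "rxnsim_sbml_unsupported")
    },
    rxn_abort(sprintf("unsupported MathML operator <%s>", opname),
              "rxnsim_sbml_error"))
}

ast_to_mathml <- function(ast) {
  apply_op <- function(op, args)
    paste0("<apply><", op, "/>", paste(args, collapse = ""), "</apply>")
  conv <- function(node) {
    switch(node$type,
      num = paste0("<cn> ", num12(node$value), " </cn>"),
      sym = if (node$name == "t")
              paste0('<csymbol encoding="text" definitionURL="', TIME_CSYMBOL,
                     '"> t </csymbol>')
            else paste0("<ci> ", node$name, " </ci>"),
      unop = apply_op(if (node$op == "neg") "minus" else "not", conv(node$arg)),
      binop = {
        op <- switch(node$op, "+" = "plus", "-" = "minus", "*" = "times",
                     "/" = "divide", "^" = "power", "<" = "lt", "<=" = "leq",
                     ">" = "gt", ">=" = "geq", "==" = "eq",
                     "and" = "and", "or" = "or")
        apply_op(op, c(conv(node$lhs), conv(node$rhs)))
      },
      call = {
        a <- vapply(node$args, conv, character(1))
        switch(node$fn,
          ln = apply_op("ln", a),
          log10 = paste0("<apply><log/><logbase><cn> 10 </cn></logbase>", a, "</apply>"),
          sqrt = apply_op("root", a),
          pow = apply_op("power", a),
          piecewise = paste0("<piecewise><piece>", a[[1L]], a[[2L]],
                             "</piece><otherwise>", a[[3L]], "</otherwise></piecewise>"),
          apply_op(node$fn, a))
      })
  }
  paste0('<math xmlns="', MATHML_NS, '">', conv(ast), "</math>")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

# ---------------------------------------------------------------- export --

#' Export a scheme to SBML Level 3 Version 1 Core
#'
#' The scheme is flattened first: SBML cannot represent layers, so shortcut
#' references become ordinary `speciesReference` entries carrying the
#' shortcut's stoichiometric coefficient. Display names are preserved in
#' the `name` attribute; sanitized ids in `id`. Pool species are exported
#' as boundary species; kinetic laws as MathML with their local
#' parameters; rules and events map to their SBML counterparts.
#'
#' @param scheme a validated `reaction_scheme`.
#' @param path optional file path; when given the document is written
#'   there.
#' @return an `xml2` document (invisibly when `path` is given).
#' @export
export_sbml <- function(scheme, path = NULL) {
  flat <- flatten_scheme(scheme)
  model_id <- sanitize_id(scheme$name)

  # parameters assigned by events must not be constant
  event_targets <- unique(unlist(lapply(flat$events, function(ev)
    names(ev$assignments))))
  if (is.null(event_targets)) event_targets <- character()
  local_event_targets <- grep("\\.", event_targets, value = TRUE)
  if (length(local_event_targets))
    rxn_abort(sprintf(
      "SBML cannot address reaction-local parameters in events: %s",
      paste(local_event_targets, collapse = ", ")), "rxnsim_sbml_error")

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" level="3" version="1">', SBML_NS),
    sprintf('  <model id="%s" name="%s">', model_id, xml_escape(scheme$name)),
    '    <listOfCompartments>',
    '      <compartment id="default" size="1" constant="true"/>',
    '    </listOfCompartments>')

  sp_lines <- vapply(flat$species, function(s) {
    pool <- s$type == "pool"
    sprintf(paste0('      <species id="%s" name="%s" compartment="default" ',
                   'initialConcentration="%s" hasOnlySubstanceUnits="false" ',
                   'boundaryCondition="%s" constant="%s"/>'),
            s$id, xml_escape(s$display_name), num12(s$initial),
            if (pool) "true" else "false",
            if (pool && !(s$id %in% event_targets)) "true" else "false")
  }, character(1))
  lines <- c(lines, "    <listOfSpecies>", sp_lines, "    </listOfSpecies>")

  if (length(flat$parameters)) {
    par_lines <- vapply(names(flat$parameters), function(nm)
      sprintf('      <parameter id="%s" value="%s" constant="%s"/>',
              nm, num12(flat$parameters[[nm]]),
              if (nm %in% event_targets) "false" else "true"), character(1))
    lines <- c(lines, "    <listOfParameters>", par_lines, "    </listOfParameters>")
  }

  if (length(flat$rules)) {
    rule_lines <- unlist(lapply(flat$rules, function(ru) c(
      sprintf('      <assignmentRule variable="%s">', ru$target_id),
      paste0("        ", ast_to_mathml(expr_parse(ru$expression)$ast)),
      '      </assignmentRule>')))
    lines <- c(lines, "    <listOfRules>", rule_lines, "    </listOfRules>")
  }

  if (length(flat$reactions)) {
    rxn_lines <- unlist(lapply(flat$reactions, function(r) {
      refs <- function(role, tag) {
        if (!length(r[[role]])) return(character())
        inner <- vapply(r[[role]], function(p) {
          rp <- resolve_participant(flat, p)
          if (tag == "modifierSpeciesReference")
            sprintf('        <modifierSpeciesReference species="%s"/>', rp$species)
          else
            sprintf('        <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                    rp$species, num12(rp$coef))
        }, character(1))
        wrap <- c(substrates = "listOfReactants", products = "listOfProducts",
                  modifiers = "listOfModifiers")[[role]]
        c(sprintf("      <%s>", wrap), inner, sprintf("      </%s>", wrap))
      }
      rate_ast <- expr_parse(law_expression(flat, r))$ast
      locals <- if (length(r$law$parameters))
        c("        <listOfLocalParameters>",
          vapply(names(r$law$parameters), function(nm)
            sprintf('          <localParameter id="%s" value="%s"/>',
                    nm, num12(r$law$parameters[[nm]])), character(1)),
          "        </listOfLocalParameters>") else character()
      c(sprintf('      <reaction id="%s" reversible="false" fast="false">', r$id),
        refs("substrates", "speciesReference"),
        refs("products", "speciesReference"),
        refs("modifiers", "modifierSpeciesReference"),
        "      <kineticLaw>",
        paste0("        ", ast_to_mathml(rate_ast)),
        locals,
        "      </kineticLaw>",
        "      </reaction>")
    }))
    lines <- c(lines, "    <listOfReactions>", rxn_lines, "    </listOfReactions>")
  }

  if (length(flat$events)) {
    ev_lines <- unlist(lapply(flat$events, function(ev) {
      asg <- unlist(lapply(seq_along(ev$assignments), function(i) c(
        sprintf('          <eventAssignment variable="%s">', names(ev$assignments)[[i]]),
        paste0("            ", ast_to_mathml(expr_parse(ev$assignments[[i]])$ast)),
        "          </eventAssignment>")))
      c(sprintf('      <event id="%s" useValuesFromTriggerTime="true">', ev$id),
        '        <trigger initialValue="true" persistent="true">',
        paste0("          ", ast_to_mathml(expr_parse(ev$trigger)$ast)),
        "        </trigger>",
        "        <listOfEventAssignments>", asg, "        </listOfEventAssignments>",
        "      </event>")
    }))
    lines <- c(lines, "    <listOfEvents>", ev_lines, "    </listOfEvents>")
  }

  lines <- c(lines, "  </model>", "</sbml>")
  doc <- xml2::read_xml(paste(lines, collapse = "\n"))
  issues <- check_sbml(doc)
  if (length(issues))
    rxn_abort(paste0("exported SBML failed consistency check:\n",
                     paste("  -", issues, collapse = "\n")), "rxnsim_sbml_error")
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Structural consistency check of an SBML document
#'
#' Verifies the structural constraints the exporter relies on: level/
#' version, unique ids, resolvable species/compartment/parameter
#' references, numeric attributes and well-formed MathML. Returns
#' diagnostics (empty when consistent).
#'
#' @param doc an `xml2` document or file path.
#' @return character vector of diagnostics.
#' @export
check_sbml <- function(doc) {
  if (is.character(doc)) doc <- xml2::read_xml(doc)
  doc <- xml2::xml_root(doc)
  d <- character()
  say <- function(...) d[[length(d) + 1L]] <<- sprintf(...)
  ns_ok <- SBML_NS %in% unlist(xml2::xml_ns(doc))
  x <- xml2::read_xml(as.character(doc))
  xml2::xml_ns_strip(x)
  if (xml2::xml_name(x) != "sbml") { say("root element is not <sbml>"); return(d) }
  model <- xml2::xml_find_first(x, "./model")
  if (inherits(model, "xml_missing")) { say("missing <model>"); return(d) }

  ids <- c(xml2::xml_attr(xml2::xml_find_all(model, ".//species"), "id"),
           xml2::xml_attr(xml2::xml_find_all(model, ".//compartment"), "id"),
           xml2::xml_attr(xml2::xml_find_all(model, "./listOfParameters/parameter"), "id"),
           xml2::xml_attr(xml2::xml_find_all(model, ".//reaction"), "id"))
  if (anyNA(ids)) say("element without id")
  dup <- unique(ids[duplicated(ids)])
  for (i in dup) say("duplicate id '%s'", i)

  comp_ids <- xml2::xml_attr(xml2::xml_find_all(model, ".//compartment"), "id")
  sp_nodes <- xml2::xml_find_all(model, ".//species")
  for (s in sp_nodes) {
    if (!(xml2::xml_attr(s, "compartment") %in% comp_ids))
      say("species '%s': unknown compartment", xml2::xml_attr(s, "id"))
    conc <- xml2::xml_attr(s, "initialConcentration")
    amt <- xml2::xml_attr(s, "initialAmount")
    if (!is.na(conc) && is.na(suppressWarnings(as.numeric(conc))))
      say("species '%s': non-numeric initialConcentration", xml2::xml_attr(s, "id"))
    if (is.na(conc) && is.na(amt))
      say("species '%s': no initial concentration or amount", xml2::xml_attr(s, "id"))
  }
  sp_ids <- xml2::xml_attr(sp_nodes, "id")
  for (ref in xml2::xml_find_all(model, ".//speciesReference | .//modifierSpeciesReference")) {
    if (!(xml2::xml_attr(ref, "species") %in% sp_ids))
      say("speciesReference to unknown species '%s'", xml2::xml_attr(ref, "species"))
  }
  for (m in xml2::xml_find_all(model, ".//math")) {
    ok <- tryCatch({ mathml_to_ast(m); TRUE },
                   error = function(e) { say("bad MathML: %s", conditionMessage(e)); FALSE })
  }
  if (!ns_ok) say("unexpected SBML namespace")
  d
}

# ---------------------------------------------------------------- import --

#' Import an SBML Level 3 Core model
#'
#' Produces a single-layer scheme named after the model id. Boundary or
#' constant species become pools; every kinetic law is imported as a
#' custom rate expression (compartment sizes appear exactly as written in
#' the source math; compartments are carried along as inert global
#' parameters); assignment rules and events map to their scheme
#' counterparts. Reaction-local parameters are renamed
#' `reactionid__param` and promoted to global parameters to avoid
#' collisions. Unsupported constructs (fast reactions, csymbol delay,
#' dynamic stoichiometry, multiple piecewise, rate/algebraic rules, event
#' delay/priority, function definitions) raise an error naming the
#' feature.
#'
#' @param source file path or `xml2` document.
#' @return a list of class `sbml_import` with elements `scheme` and
#'   `report` (construct counts mapped and notes about renamings /
#'   ignored annotation-level content).
#' @export
import_sbml <- function(source) {
  x <- if (inherits(source, "xml_document")) source else xml2::read_xml(source)
  x <- xml2::read_xml(as.character(x))
  xml2::xml_ns_strip(x)
  model <- xml2::xml_find_first(x, "./model")
  if (inherits(model, "xml_missing"))
    rxn_abort("not an SBML document: missing <model>", "rxnsim_sbml_error")

  unsupported <- character()
  note <- function(f) unsupported <<- c(unsupported, f)

  if (length(xml2::xml_find_all(model, "./listOfFunctionDefinitions/functionDefinition")))
    note("functionDefinition")
  if (length(xml2::xml_find_all(model, "./listOfInitialAssignments/initialAssignment")))
    note("initialAssignment")
  if (length(xml2::xml_find_all(model, "./listOfConstraints/constraint")))
    note("constraint")
  for (r in xml2::xml_find_all(model, ".//reaction")) {
    if (identical(xml2::xml_attr(r, "fast"), "true")) note("fast reaction")
  }
  if (length(xml2::xml_find_all(model, ".//speciesReference/stoichiometryMath")))
    note("dynamic change in stoichiometry (stoichiometryMath)")
  for (ref in xml2::xml_find_all(model, ".//speciesReference")) {
    if (identical(xml2::xml_attr(ref, "constant"), "false") ||
        !is.na(xml2::xml_attr(ref, "id")))
      note("dynamic change in stoichiometry")
  }
  if (length(xml2::xml_find_all(model, ".//rateRule"))) note("rateRule")
  if (length(xml2::xml_find_all(model, ".//algebraicRule"))) note("algebraicRule")
  for (ev in xml2::xml_find_all(model, ".//event")) {
    if (length(xml2::xml_find_all(ev, "./delay"))) note("event delay")
    if (length(xml2::xml_find_all(ev, "./priority"))) note("event priority")
  }
  # delay csymbols / multiple piecewise are caught during math conversion,
  # but scan first so the error lists them up front
  for (m in xml2::xml_find_all(model, ".//math")) {
    for (cs in xml2::xml_find_all(m, ".//csymbol")) {
      url <- xml2::xml_attr(cs, "definitionURL")
      if (!is.na(url) && grepl("delay", url)) note("csymbol delay")
    }
    for (pw in xml2::xml_find_all(m, ".//piecewise")) {
      if (length(xml2::xml_find_all(pw, "./piece")) > 1L) note("multiple piecewise")
    }
  }
  unsupported <- unique(unsupported)
  if (length(unsupported))
    rxn_abort(sprintf("unsupported SBML feature(s): %s",
                      paste(unsupported, collapse = ", ")),
              "rxnsim_sbml_unsupported", features = unsupported)

  model_id <- xml2::xml_attr(model, "id")
  if (is.na(model_id)) model_id <- "imported_model"
  layer <- model_id

  report <- list(mapped = list(), notes = character())

  comp_nodes <- xml2::xml_find_all(model, "./listOfCompartments/compartment")
  comp_params <- stats::setNames(
    vapply(comp_nodes, function(cn) {
      sz <- suppressWarnings(as.numeric(xml2::xml_attr(cn, "size")))
      if (is.na(sz)) 1 else sz
    }, numeric(1)),
    xml2::xml_attr(comp_nodes, "id"))
  if (length(comp_params))
    report$notes <- c(report$notes,
                      sprintf("compartment '%s' imported as inert global parameter",
                              names(comp_params)))

  sp_nodes <- xml2::xml_find_all(model, "./listOfSpecies/species")
  species <- lapply(sp_nodes, function(s) {
    conc <- suppressWarnings(as.numeric(xml2::xml_attr(s, "initialConcentration")))
    if (is.na(conc))
      conc <- suppressWarnings(as.numeric(xml2::xml_attr(s, "initialAmount")))
    if (is.na(conc)) conc <- 0
    pool <- identical(xml2::xml_attr(s, "boundaryCondition"), "true") ||
            identical(xml2::xml_attr(s, "constant"), "true")
    nm <- xml2::xml_attr(s, "name")
    id <- xml2::xml_attr(s, "id")
    species_symbol(id, if (is.na(nm)) id else nm, initial = conc,
                   type = if (pool) "pool" else "variable", layer = layer)
  })
  report$mapped$species <- length(species)

  glob_nodes <- xml2::xml_find_all(model, "./listOfParameters/parameter")
  globals <- stats::setNames(
    vapply(glob_nodes, function(p) {
      v <- suppressWarnings(as.numeric(xml2::xml_attr(p, "value")))
      if (is.na(v)) 0 else v
    }, numeric(1)),
    xml2::xml_attr(glob_nodes, "id"))
  parameters <- c(comp_params, globals)
  report$mapped$parameters <- length(globals)

  rename_symbols <- function(ast, map) {
    walk <- function(node) {
      switch(node$type,
        num = node,
        sym = { if (node$name %in% names(map)) node$name <- map[[node$name]]; node },
        unop = { node$arg <- walk(node$arg); node },
        binop = { node$lhs <- walk(node$lhs); node$rhs <- walk(node$rhs); node },
        call = { node$args <- lapply(node$args, walk); node })
    }
    walk(ast)
  }

  reactions <- list()
  for (rn in xml2::xml_find_all(model, "./listOfReactions/reaction")) {
    rid <- xml2::xml_attr(rn, "id")
    get_refs <- function(xpath) {
      lapply(xml2::xml_find_all(rn, xpath), function(ref) {
        st <- suppressWarnings(as.numeric(xml2::xml_attr(ref, "stoichiometry")))
        sp_ref(xml2::xml_attr(ref, "species"), if (is.na(st)) 1 else st)
      })
    }
    mods <- lapply(xml2::xml_find_all(rn, "./listOfModifiers/modifierSpeciesReference"),
                   function(ref) sp_ref(xml2::xml_attr(ref, "species")))
    kl <- xml2::xml_find_first(rn, "./kineticLaw")
    if (inherits(kl, "xml_missing"))
      rxn_abort(sprintf("reaction '%s' has no kineticLaw", rid), "rxnsim_sbml_error")
    loc_nodes <- xml2::xml_find_all(kl, "./listOfLocalParameters/localParameter | ./listOfParameters/parameter")
    loc_map <- character()
    for (lp in loc_nodes) {
      lid <- xml2::xml_attr(lp, "id")
      new_id <- paste0(rid, "__", lid)
      loc_map[[lid]] <- new_id
      parameters[[new_id]] <- suppressWarnings(as.numeric(xml2::xml_attr(lp, "value")))
      report$notes <- c(report$notes,
                        sprintf("local parameter '%s' of reaction '%s' imported as '%s'",
                                lid, rid, new_id))
    }
    math <- xml2::xml_find_first(kl, "./math")
    if (inherits(math, "xml_missing"))
      rxn_abort(sprintf("kineticLaw of reaction '%s' has no math", rid),
                "rxnsim_sbml_error")
    ast <- rename_symbols(mathml_to_ast(math), loc_map)
    reactions[[length(reactions) + 1L]] <- reaction_step(
      rid,
      substrates = get_refs("./listOfReactants/speciesReference"),
      products = get_refs("./listOfProducts/speciesReference"),
      modifiers = mods,
      law = rate_law(expr_render(ast)), layer = layer)
  }
  report$mapped$reactions <- length(reactions)

  rules <- list()
  for (rn in xml2::xml_find_all(model, "./listOfRules/assignmentRule")) {
    ast <- mathml_to_ast(xml2::xml_find_first(rn, "./math"))
    rules[[length(rules) + 1L]] <- assignment_rule(
      paste0("rule_", xml2::xml_attr(rn, "variable")),
      xml2::xml_attr(rn, "variable"), expr_render(ast), layer = layer)
  }
  report$mapped$rules <- length(rules)

  events <- list()
  for (en in xml2::xml_find_all(model, "./listOfEvents/event")) {
    eid <- xml2::xml_attr(en, "id")
    if (is.na(eid)) eid <- paste0("event_", length(events) + 1L)
    trig <- mathml_to_ast(xml2::xml_find_first(en, "./trigger/math"))
    asg <- xml2::xml_find_all(en, "./listOfEventAssignments/eventAssignment")
    assignments <- stats::setNames(
      vapply(asg, function(a)
        expr_render(mathml_to_ast(xml2::xml_find_first(a, "./math"))), character(1)),
      xml2::xml_attr(asg, "variable"))
    events[[length(events) + 1L]] <- event_spec(eid, expr_render(trig),
                                                assignments, layer = layer)
  }
  report$mapped$events <- length(events)

  scheme <- reaction_scheme(species = species, reactions = reactions,
                            rules = rules, events = events,
                            parameters = parameters, layers = layer,
                            name = model_id)
  stop_if_invalid(scheme)
  structure(list(scheme = scheme, report = report), class = "sbml_import")
}

#' @export
print.sbml_import <- function(x, ...) {
  cat("<sbml_import>\n  mapped:\n")
  for (nm in names(x$report$mapped))
    cat(sprintf("    %-12s %d\n", nm, x$report$mapped[[nm]]))
  for (n in x$report$notes) cat("  note:", n, "\n")
  print(x$scheme)
  invisible(x)
}

# ------------------------------------------------------------- partition --

#' Re-layer a flat scheme
#'
#' Splits a (typically imported) scheme into layers according to a
#' user-supplied assignment of element ids to layer names, creating
#' shortcut symbols for every cross-layer participation. The partitioned
#' scheme simulates identically to the original: layers organise, they
#' never change the mathematics.
#'
#' @param scheme a validated `reaction_scheme`.
#' @param assign named character vector mapping element ids (species,
#'   reactions, rules, events) to layer names; unassigned elements keep
#'   their current layer.
#' @param layers optional layer ordering (defaults to order of first
#'   appearance).
#' @return a multi-layered `reaction_scheme`.
#' @export
partition_scheme <- function(scheme, assign, layers = NULL) {
  stop_if_invalid(scheme)
  known <- c(names(scheme$species), names(scheme$reactions),
             names(scheme$rules), names(scheme$events))
  bad <- setdiff(names(assign), known)
  if (length(bad))
    rxn_abort(sprintf("partition config references unknown id(s): %s",
                      paste(bad, collapse = ", ")), "rxnsim_model_error")
  layer_of <- function(id, fallback) {
    if (id %in% names(assign)) assign[[id]] else fallback
  }
  species <- lapply(scheme$species, function(s) {
    s$layer <- layer_of(s$id, s$layer); s
  })
  sp_layer <- vapply(species, `[[`, character(1), "layer")
  shortcuts <- list()
  ensure_shortcut <- function(sp_id, coef, in_layer) {
    sc_id <- sanitize_id(paste0("sc_", sp_id, "_", in_layer),
                         vapply(shortcuts, `[[`, character(1), "id"))
    existing <- Filter(function(sc) sc$target_id == sp_id && sc$layer == in_layer &&
                         sc$coef == coef, shortcuts)
    if (length(existing)) return(existing[[1L]]$id)
    shortcuts[[length(shortcuts) + 1L]] <<-
      shortcut_symbol(sc_id, sp_id, coef = coef, layer = in_layer)
    sc_id
  }
  reactions <- lapply(scheme$reactions, function(r) {
    r$layer <- layer_of(r$id, r$layer)
    for (role in c("substrates", "products", "modifiers")) {
      r[[role]] <- lapply(r[[role]], function(p) {
        rp <- resolve_participant(scheme, p)
        if (sp_layer[[rp$species]] == r$layer)
          return(sp_ref(rp$species, if (is.na(rp$coef)) 1 else rp$coef))
        sc_ref(ensure_shortcut(rp$species, if (is.na(rp$coef)) 1 else rp$coef,
                               r$layer))
      })
    }
    r
  })
  rules <- lapply(scheme$rules, function(ru) {
    ru$layer <- layer_of(ru$id, ru$layer)
    fs <- intersect(expr_parse(ru$expression)$free_symbols, names(scheme$species))
    for (sid in unique(c(ru$target_id, fs)))
      if (sp_layer[[sid]] != ru$layer) ensure_shortcut(sid, 1, ru$layer)
    ru
  })
  events <- lapply(scheme$events, function(ev) {
    ev$layer <- layer_of(ev$id, ev$layer); ev
  })
  all_layers <- layers %||% unique(c(vapply(species, `[[`, character(1), "layer"),
                                     vapply(reactions, `[[`, character(1), "layer"),
                                     vapply(rules, `[[`, character(1), "layer"),
                                     vapply(events, `[[`, character(1), "layer")))
  out <- reaction_scheme(species = unname(species), shortcuts = shortcuts,
                         reactions = unname(reactions), rules = unname(rules),
                         events = unname(events),
                         parameters = scheme$parameters,
                         layers = all_layers, name = scheme$name)
  stop_if_invalid(out)
  out
}

#' Convert between the native JSON format and SBML
#'
#' Direction is inferred from the file extensions (`.json` vs
#' `.xml`/`.sbml`).
#'
#' @param input,output file paths.
#' @return the scheme that was written, invisibly.
#' @export
convert_model <- function(input, output) {
  ext <- function(p) tolower(tools::file_ext(p))
  scheme <- switch(ext(input),
    json = read_scheme(input),
    xml = , sbml = import_sbml(input)$scheme,
    rxn_abort(sprintf("unrecognised input extension '%s'", ext(input)),
              "rxnsim_io_error"))
  switch(ext(output),
    json = write_scheme(scheme, output),
    xml = , sbml = export_sbml(scheme, output),
    rxn_abort(sprintf("unrecognised output extension '%s'", ext(output)),
              "rxnsim_io_error"))
  invisible(scheme)
}
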