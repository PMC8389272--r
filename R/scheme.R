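# Domain model: multi-layered reaction schemes.
#
# A scheme holds species (state variables or constant pools), shortcut
# symbols (aliases to a species defined possibly in another layer, carrying
# their own per-edge stoichiometric coefficient), reactions, assignment
# rules, events and global parameters, all tagged with a layer name.

#' Create a species symbol
#'
#' A species is either a state `"variable"` (integrated by the ODE solver)
#' or a constant `"pool"` (boundary condition, concentration held fixed).
#'
#' @param id identifier, unique scheme-wide (letters/digits/underscore,
#'   not starting with a digit). Derive one from a free-form label with
#'   [sanitize_id()].
#' @param display_name free-form label (may contain `-`, `+`, ...);
#'   defaults to `id`.
#' @param initial non-negative initial concentration (arbitrary units).
#' @param type `"variable"` or `"pool"`.
#' @param layer layer name.
#' @return a `rxn_species` list.
#' @export
species_symbol <- function(id, display_name = id, initial = 0,
                           type = c("variable", "pool"), layer = "main") {
  type <- match.arg(type)
  structure(list(id = id, display_name = display_name,
                 initial = as.numeric(initial), type = type, layer = layer),
            class = "rxn_species")
}

#' Create a shortcut symbol
#'
#' A shortcut is an alias for a species declared elsewhere (possibly in a
#' different layer). Its name, concentration and reactant type are read
#' through from the target; only the stoichiometric coefficient is local,
#' so the same reactant can enter different reactions with different
#' coefficients while remaining one state variable.
#'
#' @param id identifier of the shortcut itself.
#' @param target_id identifier of the target species.
#' @param coef positive stoichiometric coefficient used on every reaction
#'   edge wired to this shortcut.
#' @param layer layer name.
#' @return a `rxn_shortcut` list.
#' @export
shortcut_symbol <- function(id, target_id, coef = 1, layer = "main") {
  structure(list(id = id, target_id = target_id, coef = as.numeric(coef),
                 layer = layer),
            class = "rxn_shortcut")
}

#' Participant references
#'
#' Reactions connect to species either directly (`sp_ref`, with a per-edge
#' stoichiometric coefficient) or through a shortcut (`sc_ref`, which
#' carries the shortcut's own coefficient).
#'
#' @param id species id (`sp_ref`) or shortcut id (`sc_ref`).
#' @param coef positive stoichiometric coefficient for the edge.
#' @return a participant reference list.
#' @export
sp_ref <- function(id, coef = 1) {
  list(species = id, shortcut = NULL, coef = as.numeric(coef))
}

#' @rdname sp_ref
#' @export
sc_ref <- function(id) {
  list(species = NULL, shortcut = id, coef = NA_real_)
}

#' Kinetic laws
#'
#' `mass_action(k)` gives rate `k * prod(substrate^edge_coefficient)` (each
#' substrate edge's stoichiometric coefficient is also its kinetic order).
#' `michaelis_menten(Vmax, Km)` gives the steady-state approximation
#' `Vmax*S/(Km+S)` for a single-substrate step. `rate_law(expression,
#' parameters)` accepts any expression in the mini-language (see
#' [expr_parse()]) over species ids, parameter names and `t`.
#'
#' @param k,Vmax,Km positive kinetic parameters.
#' @param param,Vmax_name,Km_name names under which the parameters appear
#'   in the rendered equations (and can be addressed for estimation).
#' @param expression rate expression text (custom law).
#' @param parameters named numeric vector of local parameters.
#' @return a `rxn_law` list.
#' @export
mass_action <- function(k = 1, param = "k") {
  structure(list(kind = "mass_action",
                 parameters = stats::setNames(as.numeric(k), param),
                 expression = NULL),
            class = "rxn_law")
}

#' @rdname mass_action
#' @export
michaelis_menten <- function(Vmax = 1, Km = 1, Vmax_name = "Vmax", Km_name = "Km") {
  structure(list(kind = "michaelis_menten",
                 parameters = stats::setNames(c(as.numeric(Vmax), as.numeric(Km)),
                                              c(Vmax_name, Km_name)),
                 expression = NULL),
            class = "rxn_law")
}

#' @rdname mass_action
#' @export
rate_law <- function(expression, parameters = numeric()) {
  structure(list(kind = "custom", parameters = parameters,
                 expression = expression),
            class = "rxn_law")
}

#' Create a reaction step
#'
#' @param id identifier.
#' @param substrates,products,modifiers lists of participant references
#'   ([sp_ref()] / [sc_ref()]); a bare character vector is shorthand for
#'   direct references with coefficient 1. One of substrates/products may
#'   be empty (source or sink reaction). Modifiers affect the rate but not
#'   the mass balance.
#' @param law a kinetic law ([mass_action()], [michaelis_menten()],
#'   [rate_law()]).
#' @param layer layer name.
#' @return a `rxn_reaction` list.
#' @export
reaction_step <- function(id, substrates = list(), products = list(),
                          law = mass_action(), modifiers = list(),
                          layer = "main") {
  structure(list(id = id, layer = layer,
                 substrates = as_participants(substrates),
                 products = as_participants(products),
                 modifiers = as_participants(modifiers),
                 law = law),
            class = "rxn_reaction")
}

as_participants <- function(x) {
  if (is.character(x)) return(lapply(x, sp_ref))
  if (is.numeric(x) && !is.null(names(x)))
    return(mapply(sp_ref, names(x), x, SIMPLIFY = FALSE, USE.NAMES = FALSE))
  stopifnot(is.list(x))
  lapply(x, function(p) {
    if (is.character(p) && length(p) == 1L) sp_ref(p) else p
  })
}

#' Create an assignment rule
#'
#' The target species' concentration is continuously computed from the
#' expression (e.g. a "total concentration" read-out); it is excluded from
#' the ODE state.
#'
#' @param id identifier.
#' @param target_id species receiving the computed value.
#' @param expression algebraic expression over species, parameters and `t`.
#' @param layer layer name.
#' @export
assignment_rule <- function(id, target_id, expression, layer = "main") {
  structure(list(id = id, layer = layer, target_id = target_id,
                 expression = expression),
            class = "rxn_rule")
}

#' Create an event
#'
#' When the boolean `trigger` expression switches from false to true during
#' integration, each assignment `target := value-expression` is applied
#' (targets may be species or parameters) and integration restarts. A
#' trigger that is already true at `t0` does not fire at `t0`.
#'
#' @param id identifier.
#' @param trigger boolean expression text over species/parameters/`t`.
#' @param assignments named character vector: names are target identifiers
#'   (species id, global parameter, or `reaction.param` for a local kinetic
#'   parameter), values are expressions.
#' @param layer layer name.
#' @export
event_spec <- function(id, trigger, assignments, layer = "main") {
  structure(list(id = id, layer = layer, trigger = trigger,
                 assignments = assignments),
            class = "rxn_event")
}

#' Assemble a reaction scheme
#'
#' @param layers ordered character vector of layer names (defaults to those
#'   mentioned by the elements).
#' @param species,shortcuts,reactions,rules,events lists of the respective
#'   elements.
#' @param parameters named numeric vector of global parameters.
#' @param name model name (used for SBML export).
#' @return an object of class `reaction_scheme`.
#' @examples
#' s <- reaction_scheme(
#'   species = list(species_symbol("A", initial = 1), species_symbol("B")),
#'   reactions = list(reaction_step("r1", "A", "B", mass_action(0.5, "k1"))))
#' validate_scheme(s)
#' @export
reaction_scheme <- function(species = list(), reactions = list(),
                            shortcuts = list(), rules = list(),
                            events = list(), parameters = numeric(),
                            layers = NULL, name = "model") {
  mentioned <- unique(c(
    vapply(species, function(x) x$layer, character(1)),
    vapply(shortcuts, function(x) x$layer, character(1)),
    vapply(reactions, function(x) x$layer, character(1)),
    vapply(rules, function(x) x$layer, character(1)),
    vapply(events, function(x) x$layer, character(1))))
  if (is.null(layers)) layers <- if (length(mentioned)) mentioned else "main"
  named_by_id <- function(xs) stats::setNames(xs, vapply(xs, `[[`, character(1), "id"))
  structure(list(
    name = name,
    layers = layers,
    species = named_by_id(species),
    shortcuts = named_by_id(shortcuts),
    reactions = named_by_id(reactions),
    rules = named_by_id(rules),
    events = named_by_id(events),
    parameters = parameters
  ), class = "reaction_scheme")
}

#' @export
print.reaction_scheme <- function(x, ...) {
  cat(sprintf("<reaction_scheme> %s\n", x$name))
  cat(sprintf("  layers:    %s\n", paste(x$layers, collapse = ", ")))
  np <- sum(vapply(x$species, function(s) s$type == "pool", logical(1)))
  cat(sprintf("  species:   %d (%d pool)\n", length(x$species), np))
  cat(sprintf("  shortcuts: %d\n", length(x$shortcuts)))
  cat(sprintf("  reactions: %d\n", length(x$reactions)))
  if (length(x$rules)) cat(sprintf("  rules:     %d\n", length(x$rules)))
  if (length(x$events)) cat(sprintf("  events:    %d\n", length(x$events)))
  if (length(x$parameters))
    cat(sprintf("  parameters: %s\n",
                paste(names(x$parameters), x$parameters, sep = "=", collapse = ", ")))
  invisible(x)
}

# Resolve a participant reference to (species_id, coef); shortcut edges use
# the shortcut's own coefficient.
resolve_participant <- function(scheme, p) {
  if (!is.null(p$shortcut)) {
    sc <- scheme$shortcuts[[p$shortcut]]
    if (is.null(sc)) return(NULL)
    list(species = sc$target_id, coef = sc$coef, via = p$shortcut)
  } else {
    list(species = p$species, coef = p$coef, via = NULL)
  }
}

# Read-through view of a shortcut: name/concentration/type come from the
# target, only the coefficient is the shortcut's own.
shortcut_view <- function(scheme, shortcut_id) {
  sc <- scheme$shortcuts[[shortcut_id]]
  tg <- scheme$species[[sc$target_id]]
  list(id = sc$id, display_name = tg$display_name, initial = tg$initial,
       type = tg$type, coef = sc$coef, target_id = tg$id, layer = sc$layer)
}

rule_targets <- function(scheme) {
  vapply(scheme$rules, function(r) r$target_id, character(1), USE.NAMES = FALSE)
}

# All parameter names addressable in expressions of a given reaction:
# species ids + global parameters + the reaction's local parameters + t.
reaction_symbol_universe <- function(scheme, rxn) {
  c(names(scheme$species), names(scheme$parameters),
    names(rxn$law$parameters), "t")
}

#' Validate a reaction scheme
#'
#' Checks every structural invariant (unique ids, resolvable shortcut
#' targets and participants, positive coefficients, parseable expressions
#' referencing only declared symbols, acyclic rules, ...) and returns
#' diagnostics instead of throwing.
#'
#' @param scheme a `reaction_scheme`.
#' @return character vector of diagnostics; empty when the scheme is valid.
#' @export
validate_scheme <- function(scheme) {
  d <- character()
  say <- function(...) d[[length(d) + 1L]] <<- sprintf(...)

  if (length(scheme$layers) < 1L) say("scheme has no layers")
  all_ids <- c(vapply(scheme$species, `[[`, character(1), "id"),
               vapply(scheme$shortcuts, `[[`, character(1), "id"))
  dup <- unique(all_ids[duplicated(all_ids)])
  for (id in dup) say("duplicate id '%s'", id)

  for (s in scheme$species) {
    if (!is_valid_id(s$id)) say("species '%s': invalid id", s$id)
    if (!(s$layer %in% scheme$layers))
      say("species '%s': unknown layer '%s'", s$id, s$layer)
    if (is.na(s$initial) || s$initial < 0)
      say("species '%s': negative initial concentration", s$id)
    if (!(s$type %in% c("variable", "pool")))
      say("species '%s': invalid reactant type '%s'", s$id, s$type)
  }

  for (sc in scheme$shortcuts) {
    if (!(sc$layer %in% scheme$layers))
      say("shortcut '%s': unknown layer '%s'", sc$id, sc$layer)
    if (is.null(scheme$species[[sc$target_id]]))
      say("shortcut '%s': unresolved shortcut target '%s'", sc$id, sc$target_id)
    if (is.na(sc$coef) || sc$coef <= 0)
      say("shortcut '%s': stoichiometric coefficient must be > 0", sc$id)
  }

  rts <- rule_targets(scheme)
  for (r in scheme$reactions) {
    if (!(r$layer %in% scheme$layers))
      say("reaction '%s': unknown layer '%s'", r$id, r$layer)
    if (length(r$substrates) + length(r$products) == 0L)
      say("reaction '%s': substrates and products both empty", r$id)
    for (role in c("substrates", "products", "modifiers")) {
      for (p in r[[role]]) {
        if (!is.null(p$shortcut)) {
          if (is.null(scheme$shortcuts[[p$shortcut]]))
            say("reaction '%s': unresolved shortcut reference '%s'", r$id, p$shortcut)
        } else {
          if (is.null(scheme$species[[p$species]]))
            say("reaction '%s': unresolved species reference '%s'", r$id, p$species)
          if (role != "modifiers" && (is.na(p$coef) || p$coef <= 0))
            say("reaction '%s': coefficient of '%s' must be > 0", r$id, p$species)
        }
      }
    }
    lk <- r$law$kind
    if (!(lk %in% c("mass_action", "michaelis_menten", "custom"))) {
      say("reaction '%s': unknown kinetic law kind '%s'", r$id, lk)
    } else if (lk == "custom") {
      if (is.null(r$law$expression)) {
        say("reaction '%s': custom law without expression", r$id)
      } else {
        fs <- tryCatch(expr_parse(r$law$expression)$free_symbols,
                       rxnsim_parse_error = function(e) {
                         say("reaction '%s': %s", r$id, conditionMessage(e)); NULL
                       })
        if (!is.null(fs)) {
          unknown <- setdiff(fs, reaction_symbol_universe(scheme, r))
          for (u in unknown)
            say("reaction '%s': expression references unknown symbol '%s'", r$id, u)
        }
      }
    } else if (lk == "michaelis_menten" && length(r$substrates) != 1L) {
      say("reaction '%s': michaelis_menten law requires exactly one substrate", r$id)
    }
    if (any(r$law$parameters <= 0, na.rm = TRUE) && lk != "custom")
      say("reaction '%s': kinetic parameters must be positive", r$id)
  }

  # rule-determined species are not ODE states: they must not carry net
  # stoichiometry in any reaction
  sym_universe <- c(names(scheme$species), names(scheme$parameters), "t")
  for (ru in scheme$rules) {
    if (!(ru$layer %in% scheme$layers))
      say("rule '%s': unknown layer '%s'", ru$id, ru$layer)
    if (is.null(scheme$species[[ru$target_id]])) {
      say("rule '%s': unknown target species '%s'", ru$id, ru$target_id)
    }
    fs <- tryCatch(expr_parse(ru$expression)$free_symbols,
                   rxnsim_parse_error = function(e) {
                     say("rule '%s': %s", ru$id, conditionMessage(e)); NULL
                   })
    if (!is.null(fs))
      for (u in setdiff(fs, sym_universe))
        say("rule '%s': expression references unknown symbol '%s'", ru$id, u)
  }
  if (length(scheme$rules)) {
    tgt_dup <- rts[duplicated(rts)]
    for (id in unique(tgt_dup)) say("species '%s' is the target of multiple rules", id)
    # acyclicity of rule dependencies (rule A depends on rule B if A's
    # expression references B's target)
    ord <- tryCatch(rule_order(scheme), rxnsim_model_error = function(e) {
      say("%s", conditionMessage(e)); NULL
    })
    for (r in scheme$reactions) {
      for (role in c("substrates", "products")) {
        for (p in r[[role]]) {
          rp <- resolve_participant(scheme, p)
          if (!is.null(rp) && rp$species %in% rts)
            say("rule target '%s' also carries stoichiometry in reaction '%s'",
                rp$species, r$id)
        }
      }
    }
  }

  for (ev in scheme$events) {
    if (!(ev$layer %in% scheme$layers))
      say("event '%s': unknown layer '%s'", ev$id, ev$layer)
    tr <- tryCatch(expr_parse(ev$trigger), rxnsim_parse_error = function(e) {
      say("event '%s': trigger: %s", ev$id, conditionMessage(e)); NULL
    })
    if (!is.null(tr)) {
      for (u in setdiff(tr$free_symbols, sym_universe))
        say("event '%s': trigger references unknown symbol '%s'", ev$id, u)
      a <- tr$ast
      is_bool <- (a$type == "binop" &&
                    a$op %in% c("<", "<=", ">", ">=", "==", "and", "or")) ||
                 (a$type == "unop" && a$op == "not")
      if (!is_bool) say("event '%s': trigger is not a boolean expression", ev$id)
    }
    local_params <- unlist(lapply(scheme$reactions, function(r)
      paste(r$id, names(r$law$parameters), sep = ".")))
    for (i in seq_along(ev$assignments)) {
      tgt <- names(ev$assignments)[[i]]
      ok <- tgt %in% names(scheme$species) || tgt %in% names(scheme$parameters) ||
        tgt %in% local_params
      if (!ok) say("event '%s': assignment target '%s' is neither a species nor a parameter",
                   ev$id, tgt)
      if (tgt %in% rts)
        say("event '%s': assignment target '%s' is rule-determined", ev$id, tgt)
      tryCatch({
        fs <- expr_parse(ev$assignments[[i]])$free_symbols
        for (u in setdiff(fs, sym_universe))
          say("event '%s': assignment references unknown symbol '%s'", ev$id, u)
      }, rxnsim_parse_error = function(e)
        say("event '%s': assignment: %s", ev$id, conditionMessage(e)))
    }
  }
  d
}

# topological order of rules; aborts with rxnsim_model_error on a cycle
rule_order <- function(scheme) {
  rules <- scheme$rules
  if (!length(rules)) return(character())
  tgt <- rule_targets(scheme)
  deps <- lapply(rules, function(r) {
    fs <- tryCatch(expr_parse(r$expression)$free_symbols, error = function(e) character())
    names(rules)[match(intersect(fs, tgt), tgt)]
  })
  ordered <- character()
  remaining <- names(rules)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(id)
      !any(setdiff(deps[[id]], ordered) %in% remaining), logical(1))]
    if (!length(ready))
      rxn_abort(sprintf("circular dependency among rules: %s",
                        paste(remaining, collapse = ", ")), "rxnsim_model_error")
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  ordered
}

stop_if_invalid <- function(scheme) {
  d <- validate_scheme(scheme)
  if (length(d))
    rxn_abort(paste0("invalid scheme:\n", paste("  -", d, collapse = "\n")),
              "rxnsim_model_error", diagnostics = d)
  invisible(scheme)
}

#' Flatten a multi-layered scheme into a single layer
#'
#' All layers are merged and every shortcut reference is replaced by a
#' direct reference to its target species carrying the shortcut's
#' stoichiometric coefficient. The species set (and hence the derived ODE
#' system) is unchanged: layers are an organisational device only.
#'
#' @param scheme a validated `reaction_scheme`.
#' @param layer_name name of the single remaining layer.
#' @return a single-layer `reaction_scheme` with no shortcuts.
#' @export
flatten_scheme <- function(scheme, layer_name = "main") {
  stop_if_invalid(scheme)
  relayer <- function(x) { x$layer <- layer_name; x }
  species <- lapply(scheme$species, relayer)
  reactions <- lapply(scheme$reactions, function(r) {
    for (role in c("substrates", "products", "modifiers")) {
      r[[role]] <- lapply(r[[role]], function(p) {
        if (is.null(p$shortcut)) return(p)
        rp <- resolve_participant(scheme, p)
        sp_ref(rp$species, if (is.na(rp$coef)) 1 else rp$coef)
      })
    }
    relayer(r)
  })
  reaction_scheme(
    species = unname(species),
    reactions = unname(reactions),
    shortcuts = list(),
    rules = lapply(unname(scheme$rules), relayer),
    events = lapply(unname(scheme$events), relayer),
    parameters = scheme$parameters,
    layers = layer_name,
    name = scheme$name)
}

# species ids referenced by the elements of one layer (reactions in any
# role, rule targets and free symbols, event targets and expressions)
layer_species_usage <- function(scheme, layer) {
  ids <- character()
  spn <- names(scheme$species)
  for (r in scheme$reactions) {
    if (r$layer != layer) next
    for (role in c("substrates", "products", "modifiers"))
      for (p in r[[role]]) {
        rp <- resolve_participant(scheme, p)
        if (!is.null(rp)) ids <- c(ids, rp$species)
      }
  }
  for (ru in scheme$rules) {
    if (ru$layer != layer) next
    fs <- tryCatch(expr_parse(ru$expression)$free_symbols, error = function(e) character())
    ids <- c(ids, ru$target_id, intersect(fs, spn))
  }
  for (ev in scheme$events) {
    if (ev$layer != layer) next
    fs <- tryCatch(expr_parse(ev$trigger)$free_symbols, error = function(e) character())
    ids <- c(ids, intersect(fs, spn), intersect(names(ev$assignments), spn))
    for (e in ev$assignments) {
      fs2 <- tryCatch(expr_parse(e)$free_symbols, error = function(e) character())
      ids <- c(ids, intersect(fs2, spn))
    }
  }
  unique(ids)
}

#' Species connecting each pair of layers
#'
#' A species connects two layers when it participates (directly or through
#' a shortcut) in elements of both. This is how, e.g., glycolysis and a
#' downstream fermentation pathway are coupled through shared cofactors.
#'
#' @param scheme a validated `reaction_scheme`.
#' @param use_display_names report display names (default) or ids.
#' @return a named list: one entry per unordered layer pair (name
#'   `"A | B"`, layers in scheme order), each a sorted character vector of
#'   shared species (possibly empty). A single-layer scheme gives an empty
#'   list.
#' @export
connectors <- function(scheme, use_display_names = TRUE) {
  stop_if_invalid(scheme)
  L <- scheme$layers
  if (length(L) < 2L) return(stats::setNames(list(), character()))
  usage <- lapply(L, function(l) layer_species_usage(scheme, l))
  names(usage) <- L
  out <- list()
  for (i in seq_len(length(L) - 1L)) {
    for (j in seq(i + 1L, length(L))) {
      shared <- intersect(usage[[i]], usage[[j]])
      if (use_display_names && length(shared))
        shared <- vapply(shared, function(id) scheme$species[[id]]$display_name,
                         character(1), USE.NAMES = FALSE)
      out[[paste(L[[i]], L[[j]], sep = " | ")]] <- sort(shared)
    }
  }
  out
}
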