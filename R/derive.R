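# Mass balance derivation: from a (possibly multi-layered) scheme to an
# ODE right-hand side, a stoichiometry matrix and renderable equations.
#
# Shortcut references contribute terms against their TARGET species' state
# index, using the SHORTCUT's stoichiometric coefficient; only target
# species ever get a state index. Under mass action the substrate edge
# coefficient is also the kinetic order (hence ATP^2 for a coefficient-2
# edge).

# Namespaced name of a reaction-local kinetic parameter
local_param_name <- function(reaction_id, param) paste(reaction_id, param, sep = ".")

# Per-reaction resolved edges: list(species=chr, coef=num) for each role
reaction_edges <- function(scheme, rxn, role) {
  lapply(rxn[[role]], function(p) resolve_participant(scheme, p))
}

# Auto-generate the rate expression text for non-custom laws
law_expression <- function(scheme, rxn) {
  law <- rxn$law
  if (law$kind == "custom") return(law$expression)
  if (law$kind == "mass_action") {
    kname <- names(law$parameters)[[1L]]
    subs <- reaction_edges(scheme, rxn, "substrates")
    terms <- vapply(subs, function(e) {
      if (e$coef == 1) e$species else paste0(e$species, "^", num12(e$coef))
    }, character(1))
    return(paste(c(kname, terms), collapse = "*"))
  }
  # michaelis_menten: exactly one substrate (validated)
  s <- reaction_edges(scheme, rxn, "substrates")[[1L]]$species
  pn <- names(law$parameters)
  sprintf("%s*%s/(%s+%s)", pn[[1L]], s, pn[[2L]], s)
}

#' Derive the mass balance ODE system of a scheme
#'
#' Assembles, for every state variable, d\[species\]/dt as the signed sum of
#' stoichiometric coefficient times reaction rate over all reactions the
#' species participates in (directly or via shortcuts). Pool species and
#' rule-determined species are excluded from the state. Deriving a
#' multi-layered scheme and deriving its flattened form give the same
#' system: layers are invisible to the mathematics.
#'
#' @param scheme a validated `reaction_scheme`.
#' @return an object of class `derived_system` with elements
#'   `state_index` (named integer: species id to position), `stoichiometry`
#'   (full species-by-reaction signed matrix), `rhs` (function
#'   `(t, state, parameters)` returning the derivative vector; `parameters`
#'   is the full named vector `c(globals, reaction.local..., pool
#'   concentrations)`, defaulting to `$parameters`), `rates` (function
#'   returning the per-reaction rate vector), `rate_expressions` (text per
#'   reaction), `equations_text` (named character, one mass balance per
#'   variable) and `parameters` (default parameter vector).
#' @examples
#' s <- reaction_scheme(
#'   species = list(species_symbol("A", initial = 1), species_symbol("B")),
#'   reactions = list(reaction_step("r1", "A", "B", mass_action(0.5, "k1"))))
#' d <- derive(s)
#' cat(render_equations(d))
#' @export
derive <- function(scheme) {
  stop_if_invalid(scheme)
  sp_ids <- names(scheme$species)
  rxn_ids <- names(scheme$reactions)
  rts <- rule_targets(scheme)
  types <- vapply(scheme$species, `[[`, character(1), "type")

  # state ordering: declaration order of species, grouped by layer in
  # layer order (deterministic for rendering and regression tests)
  sp_layers <- vapply(scheme$species, `[[`, character(1), "layer")
  ord <- order(match(sp_layers, scheme$layers), seq_along(sp_ids))
  sp_ordered <- sp_ids[ord]
  is_state <- types[sp_ordered] == "variable" & !(sp_ordered %in% rts)
  state_ids <- sp_ordered[is_state]
  state_index <- stats::setNames(seq_along(state_ids), state_ids)
  pool_ids <- sp_ordered[types[sp_ordered] == "pool"]

  # stoichiometry matrix over ALL species (rows) x reactions (columns)
  S <- matrix(0, nrow = length(sp_ids), ncol = length(rxn_ids),
              dimnames = list(sp_ordered, rxn_ids))
  for (r in scheme$reactions) {
    for (e in reaction_edges(scheme, r, "substrates"))
      S[e$species, r$id] <- S[e$species, r$id] - e$coef
    for (e in reaction_edges(scheme, r, "products"))
      S[e$species, r$id] <- S[e$species, r$id] + e$coef
  }

  # default parameter vector: globals, namespaced locals, pool concentrations
  local_defaults <- unlist(unname(lapply(scheme$reactions, function(r) {
    if (!length(r$law$parameters)) return(NULL)
    stats::setNames(r$law$parameters,
                    local_param_name(r$id, names(r$law$parameters)))
  })))
  pool_defaults <- if (length(pool_ids))
    stats::setNames(vapply(pool_ids, function(id) scheme$species[[id]]$initial,
                           numeric(1)), pool_ids) else NULL
  param_defaults <- c(scheme$parameters, local_defaults, pool_defaults)
  if (is.null(param_defaults)) param_defaults <- numeric()

  # compile rate evaluators; local parameter symbols are rewritten to their
  # namespaced form so all rates share one evaluation environment
  rate_exprs <- character(length(rxn_ids))
  names(rate_exprs) <- rxn_ids
  fun_env <- expr_fun_env()
  rate_info <- vector("list", length(rxn_ids))
  for (j in seq_along(rxn_ids)) {
    r <- scheme$reactions[[rxn_ids[[j]]]]
    rate_exprs[[j]] <- law_expression(scheme, r)
    if (r$law$kind == "mass_action") {
      subs <- reaction_edges(scheme, r, "substrates")
      rate_info[[j]] <- list(
        kind = "mass_action",
        k = local_param_name(r$id, names(r$law$parameters)[[1L]]),
        sub_ids = vapply(subs, `[[`, character(1), "species"),
        sub_coefs = vapply(subs, `[[`, numeric(1), "coef"))
    } else {
      rename <- if (length(r$law$parameters))
        stats::setNames(local_param_name(r$id, names(r$law$parameters)),
                        names(r$law$parameters)) else character()
      lang <- ast_to_lang(expr_parse(rate_exprs[[j]])$ast, rename)
      rate_info[[j]] <- list(kind = "compiled", lang = lang)
    }
  }

  r_order <- rule_order(scheme)
  rule_info <- lapply(scheme$rules[r_order], function(ru)
    list(target = ru$target_id, lang = ast_to_lang(expr_parse(ru$expression)$ast)))

  initial_state <- vapply(state_ids, function(id) scheme$species[[id]]$initial,
                          numeric(1))

  n_rxn <- length(rxn_ids)

  # bindings: species concentrations (state + pools + rules), global and
  # namespaced local parameters, t
  make_bindings_env <- function(t, x, p) {
    env <- new.env(parent = fun_env)
    for (nm in names(p)) assign(nm, p[[nm]], envir = env)
    for (nm in state_ids) assign(nm, x[[nm]], envir = env)
    assign("t", t, envir = env)
    for (ri in rule_info) assign(ri$target, eval(ri$lang, env), envir = env)
    env
  }

  # fast path for pure mass-action schemes without rules: index-based
  # arithmetic on plain vectors, no environment construction per call
  all_mass_action <- !length(rule_info) &&
    all(vapply(rate_info, function(ri) ri$kind == "mass_action", logical(1)))
  pn <- names(param_defaults)
  conc_names <- c(state_ids, pool_ids)
  pool_pos <- match(pool_ids, pn)
  if (all_mass_action && n_rxn > 0L) {
    k_pos <- vapply(rate_info, function(ri) match(ri$k, pn), integer(1))
    sub_pos <- lapply(rate_info, function(ri) match(ri$sub_ids, conc_names))
    sub_coefs <- lapply(rate_info, `[[`, "sub_coefs")
  }

  rates_fn <- function(t, x, parameters = param_defaults) {
    if (all_mass_action) {
      if (!identical(names(parameters), pn)) parameters <- parameters[pn]
      conc <- c(x, parameters[pool_pos])
      v <- numeric(n_rxn)
      for (j in seq_len(n_rxn))
        v[[j]] <- parameters[[k_pos[[j]]]] * prod(conc[sub_pos[[j]]] ^ sub_coefs[[j]])
      names(v) <- rxn_ids
      return(v)
    }
    names(x) <- state_ids
    env <- make_bindings_env(t, x, parameters)
    v <- numeric(n_rxn)
    for (j in seq_len(n_rxn)) {
      ri <- rate_info[[j]]
      if (ri$kind == "mass_action") {
        conc <- vapply(ri$sub_ids, function(id) get(id, envir = env), numeric(1))
        v[[j]] <- get(ri$k, envir = env) * prod(conc ^ ri$sub_coefs)
      } else {
        v[[j]] <- eval(ri$lang, env)
      }
    }
    names(v) <- rxn_ids
    v
  }

  S_state <- S[state_ids, , drop = FALSE]
  rhs <- function(t, x, parameters = param_defaults) {
    v <- rates_fn(t, x, parameters)
    drop(S_state %*% v)
  }

  # rule evaluation at a reported point (values for rule-target columns)
  rule_values_fn <- function(t, x, parameters = param_defaults) {
    names(x) <- state_ids
    env <- make_bindings_env(t, x, parameters)
    vapply(rule_info, function(ri) get(ri$target, envir = env), numeric(1))
  }

  equations_text <- render_balance_terms(scheme, S, state_ids, rate_exprs)

  structure(list(
    scheme = scheme,
    state_index = state_index,
    state_ids = state_ids,
    pool_ids = pool_ids,
    rule_target_ids = vapply(rule_info, `[[`, character(1), "target"),
    species_order = sp_ordered,
    stoichiometry = S,
    rates = rates_fn,
    rhs = rhs,
    rule_values = rule_values_fn,
    rate_expressions = rate_exprs,
    equations_text = equations_text,
    parameters = param_defaults,
    initial_state = initial_state
  ), class = "derived_system")
}

# one "d[name]/dt = ..." line per state variable; terms in reaction
# (column) order, each "+c*rate" / "-c*rate" with the coefficient omitted
# when it is 1 and the rate parenthesised when it is a sum
render_balance_terms <- function(scheme, S, state_ids, rate_exprs) {
  needs_parens <- vapply(rate_exprs, function(e) {
    a <- expr_parse(e)$ast
    a$type == "binop" && a$op %in% c("+", "-")
  }, logical(1))
  out <- stats::setNames(character(length(state_ids)), state_ids)
  for (id in state_ids) {
    terms <- character()
    for (j in seq_len(ncol(S))) {
      c_ <- S[id, j]
      if (c_ == 0) next
      rate <- rate_exprs[[j]]
      if (needs_parens[[j]]) rate <- paste0("(", rate, ")")
      mag <- abs(c_)
      body <- if (mag == 1) rate else paste0(num12(mag), "*", rate)
      terms[[length(terms) + 1L]] <- paste0(if (c_ > 0) "+" else "-", body)
    }
    rhs_text <- if (length(terms)) paste(terms, collapse = " ") else "0"
    out[[id]] <- sprintf("d[%s]/dt = %s", scheme$species[[id]]$display_name, rhs_text)
  }
  out
}

#' Render the derived mass balance equations as text
#'
#' One line per state variable, in state order, with `^` denoting
#' exponentiation, e.g. `d[A]/dt = -k1*A`.
#'
#' @param system a `derived_system` (or a `reaction_scheme`, which is
#'   derived first).
#' @return a single string (lines joined with newlines); empty for a
#'   scheme with no state variables.
#' @export
render_equations <- function(system) {
  if (inherits(system, "reaction_scheme")) system <- derive(system)
  paste(system$equations_text, collapse = "\n")
}

#' @export
print.derived_system <- function(x, ...) {
  cat(sprintf("<derived_system> %d state variable(s), %d reaction(s)",
              length(x$state_ids), ncol(x$stoichiometry)))
  if (length(x$pool_ids)) cat(sprintf(", %d pool(s)", length(x$pool_ids)))
  if (length(x$rule_target_ids)) cat(sprintf(", %d rule output(s)", length(x$rule_target_ids)))
  cat("\n")
  if (length(x$equations_text)) cat(render_equations(x), "\n", sep = "")
  invisible(x)
}
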