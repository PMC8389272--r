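# Native model format: a single JSON document with top-level keys
# name, layers, species, shortcuts, reactions, rules, events, parameters.
# Unlike SBML export, it preserves layer assignments and shortcut symbols,
# so multi-layered schemes round-trip losslessly. An informal schema ships
# in inst/extdata/scheme-schema.json.

participant_to_list <- function(p) {
  if (!is.null(p$shortcut)) list(shortcut = p$shortcut)
  else list(species = p$species, coef = p$coef)
}

participant_from_list <- function(x) {
  if (!is.null(x$shortcut)) sc_ref(x$shortcut)
  else sp_ref(x$species, x$coef %||% 1)
}

#' Write / read a scheme in the native JSON format
#'
#' @param scheme a `reaction_scheme`.
#' @param path file path (`.json`).
#' @return `read_scheme` returns a `reaction_scheme`;
#'   `scheme_to_json`/`scheme_from_json` convert to/from JSON text.
#' @export
write_scheme <- function(scheme, path) {
  writeLines(scheme_to_json(scheme), path)
  invisible(scheme)
}

#' @rdname write_scheme
#' @export
scheme_to_json <- function(scheme) {
  doc <- list(
    name = scheme$name,
    layers = as.list(scheme$layers),
    species = lapply(unname(scheme$species), function(s)
      list(id = s$id, display_name = s$display_name, initial = s$initial,
           type = s$type, layer = s$layer)),
    shortcuts = lapply(unname(scheme$shortcuts), function(sc)
      list(id = sc$id, target = sc$target_id, coef = sc$coef, layer = sc$layer)),
    reactions = lapply(unname(scheme$reactions), function(r)
      list(id = r$id, layer = r$layer,
           substrates = lapply(r$substrates, participant_to_list),
           products = lapply(r$products, participant_to_list),
           modifiers = lapply(r$modifiers, participant_to_list),
           law = list(kind = r$law$kind,
                      parameters = as.list(r$law$parameters),
                      expression = r$law$expression))),
    rules = lapply(unname(scheme$rules), function(ru)
      list(id = ru$id, layer = ru$layer, target = ru$target_id,
           expression = ru$expression)),
    events = lapply(unname(scheme$events), function(ev)
      list(id = ev$id, layer = ev$layer, trigger = ev$trigger,
           assignments = as.list(ev$assignments))),
    parameters = as.list(scheme$parameters))
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                   null = "null")
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  scheme_from_json(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

#' @rdname write_scheme
#' @param json JSON text.
#' @export
scheme_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  num_vec <- function(x) {
    if (!length(x)) return(numeric())
    stats::setNames(vapply(x, as.numeric, numeric(1)), names(x))
  }
  chr_vec <- function(x) {
    if (!length(x)) return(character())
    stats::setNames(vapply(x, as.character, character(1)), names(x))
  }
  reaction_scheme(
    name = doc$name %||% "model",
    layers = vapply(doc$layers, as.character, character(1)),
    species = lapply(doc$species, function(s)
      species_symbol(s$id, s$display_name %||% s$id, s$initial %||% 0,
                     s$type %||% "variable", s$layer %||% "main")),
    shortcuts = lapply(doc$shortcuts, function(sc)
      shortcut_symbol(sc$id, sc$target, sc$coef %||% 1, sc$layer %||% "main")),
    reactions = lapply(doc$reactions, function(r) {
      law <- structure(list(kind = r$law$kind,
                            parameters = num_vec(r$law$parameters),
                            expression = r$law$expression),
                       class = "rxn_law")
      reaction_step(r$id,
                    substrates = lapply(r$substrates, participant_from_list),
                    products = lapply(r$products, participant_from_list),
                    modifiers = lapply(r$modifiers, participant_from_list),
                    law = law, layer = r$layer %||% "main")
    }),
    rules = lapply(doc$rules, function(ru)
      assignment_rule(ru$id, ru$target, ru$expression, ru$layer %||% "main")),
    events = lapply(doc$events, function(ev)
      event_spec(ev$id, ev$trigger, chr_vec(ev$assignments), ev$layer %||% "main")),
    parameters = num_vec(doc$parameters))
}
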