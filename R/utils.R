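# Internal helpers: classed conditions and identifier sanitation.

rxn_abort <- function(msg, class = "rxnsim_error", ...) {
  stop(structure(
    class = c(class, "rxnsim_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Sanitize a display name into an identifier
#'
#' Display names such as `"NAD+"` or `"p-cyclin_cdc2-p"` are legal labels,
#' but expressions and SBML ids only allow `[A-Za-z_][A-Za-z0-9_]*`. Every
#' non-alphanumeric character is replaced by an underscore and a leading
#' digit gets an `x` prefix.
#'
#' @param x character vector of display names.
#' @param existing identifiers already taken; clashes are resolved by
#'   appending `_2`, `_3`, ...
#' @return character vector of identifiers, unique against `existing` and
#'   among themselves.
#' @examples
#' sanitize_id(c("NAD+", "NADH", "1,3-diphosphoglycerate"))
#' @export
sanitize_id <- function(x, existing = character()) {
  out <- gsub("[^A-Za-z0-9_]", "_", x)
  out <- ifelse(grepl("^[0-9]", out), paste0("x", out), out)
  out <- ifelse(out == "", "id", out)
  taken <- existing
  for (i in seq_along(out)) {
    cand <- out[[i]]
    if (cand %in% taken) {
      n <- 2L
      while (paste0(cand, "_", n) %in% taken) n <- n + 1L
      cand <- paste0(cand, "_", n)
    }
    out[[i]] <- cand
    taken <- c(taken, cand)
  }
  out
}

is_valid_id <- function(x) {
  is.character(x) && length(x) == 1L && grepl("^[A-Za-z_][A-Za-z0-9_]*$", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# format a numeric with full-enough precision for text round trips
num12 <- function(x) sprintf("%.12g", x)
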