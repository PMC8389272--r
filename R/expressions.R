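# The rate-expression mini-language used by kinetic laws, assignment rules
# and event triggers.
#
# Grammar (lowest to highest precedence):
#   or-expr   := and-expr  ("or"  and-expr)*
#   and-expr  := not-expr  ("and" not-expr)*
#   not-expr  := "not" not-expr | cmp-expr
#   cmp-expr  := add-expr  (("<"|"<="|">"|">="|"==") add-expr)?
#   add-expr  := mul-expr  (("+"|"-") mul-expr)*
#   mul-expr  := unary     (("*"|"/") unary)*
#   unary     := "-" unary | power
#   power     := atom ("^" unary)?          # right-associative
#   atom      := number | identifier | identifier "(" args ")" | "(" or-expr ")"
#
# Functions: exp, ln, log10, sqrt, abs, pow, min, max, piecewise (single
# condition only). The identifier `t` is reserved for time.

EXPR_FUNCTIONS <- c("exp", "ln", "log10", "sqrt", "abs", "pow", "min", "max",
                    "piecewise")

expr_tokenize <- function(source) {
  if (!is.character(source) || length(source) != 1L)
    rxn_abort("expression source must be a single string", "rxnsim_parse_error")
  pats <- c(
    num   = "^([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?",
    id    = "^[A-Za-z_][A-Za-z0-9_]*",
    op    = "^(<=|>=|==|[-+*/^()<>,])",
    space = "^[ \t\r\n]+"
  )
  toks <- list()
  pos <- 1L
  s <- source
  while (nchar(s) > 0L) {
    matched <- FALSE
    for (kind in names(pats)) {
      m <- regmatches(s, regexpr(pats[[kind]], s))
      if (length(m) == 1L && nchar(m) > 0L) {
        if (kind != "space") {
          k <- kind
          if (kind == "id" && m %in% c("and", "or", "not")) k <- "bool"
          toks[[length(toks) + 1L]] <- list(kind = k, text = m, pos = pos)
        }
        pos <- pos + nchar(m)
        s <- substring(s, nchar(m) + 1L)
        matched <- TRUE
        break
      }
    }
    if (!matched)
      rxn_abort(sprintf("syntax error at position %d: unexpected character '%s' in \"%s\"",
                        pos, substring(s, 1L, 1L), source),
                "rxnsim_parse_error")
  }
  toks
}

# recursive-descent parser over a token stream held in an environment
expr_parse_tokens <- function(toks, source) {
  st <- new.env(parent = emptyenv())
  st$i <- 1L

  peek <- function() if (st$i <= length(toks)) toks[[st$i]] else NULL
  advance <- function() { tk <- toks[[st$i]]; st$i <- st$i + 1L; tk }
  expect <- function(text) {
    tk <- peek()
    if (is.null(tk) || tk$text != text)
      rxn_abort(sprintf("syntax error at position %d: expected '%s' in \"%s\"",
                        if (is.null(tk)) nchar(source) + 1L else tk$pos, text, source),
                "rxnsim_parse_error")
    advance()
  }
  at_op <- function(ops) {
    tk <- peek()
    !is.null(tk) && tk$kind %in% c("op", "bool") && tk$text %in% ops
  }

  p_or <- function() {
    node <- p_and()
    while (at_op("or")) { advance(); node <- list(type = "binop", op = "or", lhs = node, rhs = p_and()) }
    node
  }
  p_and <- function() {
    node <- p_not()
    while (at_op("and")) { advance(); node <- list(type = "binop", op = "and", lhs = node, rhs = p_not()) }
    node
  }
  p_not <- function() {
    if (at_op("not")) { advance(); return(list(type = "unop", op = "not", arg = p_not())) }
    p_cmp()
  }
  p_cmp <- function() {
    node <- p_add()
    if (at_op(c("<", "<=", ">", ">=", "=="))) {
      op <- advance()$text
      node <- list(type = "binop", op = op, lhs = node, rhs = p_add())
    }
    node
  }
  p_add <- function() {
    node <- p_mul()
    while (at_op(c("+", "-"))) {
      op <- advance()$text
      node <- list(type = "binop", op = op, lhs = node, rhs = p_mul())
    }
    node
  }
  p_mul <- function() {
    node <- p_unary()
    while (at_op(c("*", "/"))) {
      op <- advance()$text
      node <- list(type = "binop", op = op, lhs = node, rhs = p_unary())
    }
    node
  }
  p_unary <- function() {
    if (at_op("-")) { advance(); return(list(type = "unop", op = "neg", arg = p_unary())) }
    p_power()
  }
  p_power <- function() {
    node <- p_atom()
    if (at_op("^")) {
      advance()
      node <- list(type = "binop", op = "^", lhs = node, rhs = p_unary())
    }
    node
  }
  p_atom <- function() {
    tk <- peek()
    if (is.null(tk))
      rxn_abort(sprintf("syntax error: unexpected end of expression in \"%s\"", source),
                "rxnsim_parse_error")
    if (tk$kind == "num") { advance(); return(list(type = "num", value = as.numeric(tk$text))) }
    if (tk$kind == "id") {
      advance()
      nxt <- peek()
      if (!is.null(nxt) && nxt$kind == "op" && nxt$text == "(") {
        if (!(tk$text %in% EXPR_FUNCTIONS))
          rxn_abort(sprintf("unknown function '%s' at position %d in \"%s\"",
                            tk$text, tk$pos, source), "rxnsim_parse_error")
        advance()
        args <- list()
        if (!at_op(")")) {
          args[[1L]] <- p_or()
          while (at_op(",")) { advance(); args[[length(args) + 1L]] <- p_or() }
        }
        expect(")")
        check_arity(tk$text, length(args), tk$pos, source)
        return(list(type = "call", fn = tk$text, args = args))
      }
      return(list(type = "sym", name = tk$text))
    }
    if (tk$kind == "op" && tk$text == "(") {
      advance()
      node <- p_or()
      expect(")")
      return(node)
    }
    rxn_abort(sprintf("syntax error at position %d: unexpected '%s' in \"%s\"",
                      tk$pos, tk$text, source), "rxnsim_parse_error")
  }

  ast <- p_or()
  tk <- peek()
  if (!is.null(tk))
    rxn_abort(sprintf("syntax error at position %d: unexpected '%s' after expression in \"%s\"",
                      tk$pos, tk$text, source), "rxnsim_parse_error")
  ast
}

check_arity <- function(fn, n, pos, source) {
  ok <- switch(fn,
    exp = , ln = , log10 = , sqrt = , abs = n == 1L,
    pow = n == 2L,
    min = , max = n >= 2L,
    piecewise = n == 3L,
    FALSE)
  if (!ok) {
    msg <- if (fn == "piecewise" && n > 3L)
      sprintf("multiple piecewise is not supported (got %d arguments) in \"%s\"", n, source)
    else
      sprintf("function '%s' called with %d argument(s) at position %d in \"%s\"",
              fn, n, pos, source)
    rxn_abort(msg, "rxnsim_parse_error")
  }
}

#' Parse a rate/trigger expression
#'
#' Parses the arithmetic/boolean expression language used by custom kinetic
#' laws, assignment rules and event triggers. The grammar supports numeric
#' literals, identifiers, `+ - * / ^` (with `^` right-associative and
#' binding tightest), unary minus, the functions `exp`, `ln`, `log10`,
#' `sqrt`, `abs`, `pow`, `min`, `max` and single-condition
#' `piecewise(a, cond, b)`, the comparisons `< <= > >= ==`, the boolean
#' operators `and`, `or`, `not`, and parentheses. The identifier `t` is
#' reserved for simulation time.
#'
#' @param source a single string.
#' @return an object of class `rxn_expression` with elements `source`,
#'   `ast` and `free_symbols`.
#' @examples
#' e <- expr_parse("k*ATP^2")
#' e$free_symbols
#' expr_eval(e, c(k = 0.1, ATP = 3))
#' @export
expr_parse <- function(source) {
  ast <- expr_parse_tokens(expr_tokenize(source), source)
  structure(
    list(source = source, ast = ast, free_symbols = expr_free_symbols(ast)),
    class = "rxn_expression")
}

#' Free symbols of an expression AST
#'
#' Identifiers appearing in the expression that are not function names or
#' literals. The reserved time symbol `t` is included when present (so
#' callers can see time dependence); it is bound via the `time` argument of
#' [expr_eval()], not via `bindings`.
#'
#' @param ast a parsed AST (or an `rxn_expression`).
#' @return character vector of identifiers.
#' @export
expr_free_symbols <- function(ast) {
  if (inherits(ast, "rxn_expression")) ast <- ast$ast
  walk <- function(node) {
    switch(node$type,
      num = character(),
      sym = node$name,
      unop = walk(node$arg),
      binop = c(walk(node$lhs), walk(node$rhs)),
      call = unlist(lapply(node$args, walk)))
  }
  unique(walk(ast))
}

#' Evaluate a parsed expression
#'
#' @param expr an `rxn_expression` or raw AST.
#' @param bindings named numeric vector binding every free symbol (except
#'   `t`, which is bound by `time`).
#' @param time value for the reserved symbol `t` (default 0).
#' @return a number, or a logical for comparison/boolean expressions.
#' @export
expr_eval <- function(expr, bindings = numeric(), time = 0) {
  ast <- if (inherits(expr, "rxn_expression")) expr$ast else expr
  src <- if (inherits(expr, "rxn_expression")) expr$source else "<ast>"
  ev <- function(node) {
    switch(node$type,
      num = node$value,
      sym = {
        if (node$name == "t") return(time)
        if (!(node$name %in% names(bindings)))
          rxn_abort(sprintf("unbound symbol '%s' in \"%s\"", node$name, src),
                    "rxnsim_eval_error")
        unname(bindings[[node$name]])
      },
      unop = {
        v <- ev(node$arg)
        if (node$op == "neg") -v else !v
      },
      binop = {
        a <- ev(node$lhs); b <- ev(node$rhs)
        switch(node$op,
          "+" = a + b, "-" = a - b, "*" = a * b, "/" = a / b, "^" = a ^ b,
          "<" = a < b, "<=" = a <= b, ">" = a > b, ">=" = a >= b, "==" = a == b,
          "and" = a && b, "or" = a || b)
      },
      call = {
        if (node$fn == "piecewise") {
          cond <- ev(node$args[[2L]])
          return(if (isTRUE(cond)) ev(node$args[[1L]]) else ev(node$args[[3L]]))
        }
        args <- vapply(node$args, ev, numeric(1))
        switch(node$fn,
          exp = exp(args),
          ln = {
            if (args <= 0)
              rxn_abort(sprintf("domain error: ln of non-positive value %g in \"%s\"",
                                args, src), "rxnsim_eval_error")
            log(args)
          },
          log10 = {
            if (args <= 0)
              rxn_abort(sprintf("domain error: log10 of non-positive value %g in \"%s\"",
                                args, src), "rxnsim_eval_error")
            log10(args)
          },
          sqrt = {
            if (args < 0)
              rxn_abort(sprintf("domain error: sqrt of negative value %g in \"%s\"",
                                args, src), "rxnsim_eval_error")
            sqrt(args)
          },
          abs = abs(args),
          pow = args[[1L]] ^ args[[2L]],
          min = min(args),
          max = max(args))
      })
  }
  ev(ast)
}

#' Render an AST back to expression text
#'
#' Inverse of [expr_parse()] up to structural equality:
#' `expr_parse(expr_render(ast))$ast` equals `ast`.
#'
#' @param ast a parsed AST or `rxn_expression`.
#' @return a single string.
#' @export
expr_render <- function(ast) {
  if (inherits(ast, "rxn_expression")) ast <- ast$ast
  # precedence levels mirror the grammar
  prec <- function(node) {
    switch(node$type,
      num = 100, sym = 100, call = 100,
      unop = if (node$op == "neg") 45 else 15,
      binop = switch(node$op,
        "or" = 5, "and" = 10,
        "<" = 20, "<=" = 20, ">" = 20, ">=" = 20, "==" = 20,
        "+" = 30, "-" = 30, "*" = 40, "/" = 40, "^" = 50))
  }
  rend <- function(node) {
    switch(node$type,
      num = num12(node$value),
      sym = node$name,
      call = paste0(node$fn, "(", paste(vapply(node$args, rend, character(1)),
                                        collapse = ", "), ")"),
      unop = {
        inner <- rend(node$arg)
        p <- prec(node$arg)
        op <- if (node$op == "neg") "-" else "not "
        if (p < prec(node)) paste0(op, "(", inner, ")") else paste0(op, inner)
      },
      binop = {
        lp <- prec(node$lhs); rp <- prec(node$rhs); p <- prec(node)
        l <- rend(node$lhs); r <- rend(node$rhs)
        # left-assoc operators need parens on right at equal precedence;
        # ^ is right-assoc so it is the mirror case
        lneed <- if (node$op == "^") lp <= p else lp < p
        rneed <- if (node$op == "^") rp < p else rp <= p
        if (lneed) l <- paste0("(", l, ")")
        if (rneed) r <- paste0("(", r, ")")
        sep <- if (node$op %in% c("and", "or")) paste0(" ", node$op, " ") else node$op
        paste0(l, sep, r)
      })
  }
  rend(ast)
}

# Compile an AST to an R language object for fast repeated evaluation inside
# the ODE right-hand side. `rename` maps symbol names (e.g. reaction-local
# parameter names to their namespaced form). Evaluation environment must
# chain to expr_fun_env() for ln/piecewise.
ast_to_lang <- function(ast, rename = character()) {
  conv <- function(node) {
    switch(node$type,
      num = node$value,
      sym = {
        nm <- node$name
        if (nm %in% names(rename)) nm <- rename[[nm]]
        as.name(nm)
      },
      unop = if (node$op == "neg") call("-", conv(node$arg)) else call("!", conv(node$arg)),
      binop = {
        op <- switch(node$op, "and" = "&&", "or" = "||", node$op)
        call(op, conv(node$lhs), conv(node$rhs))
      },
      call = {
        fn <- switch(node$fn, ln = "log", node$fn)
        as.call(c(list(as.name(fn)), lapply(node$args, conv)))
      })
  }
  conv(ast)
}

expr_fun_env <- function() {
  e <- new.env(parent = baseenv())
  e$piecewise <- function(a, cond, b) if (isTRUE(cond)) a else b
  e
}

# Convert a boolean trigger AST into a signed-margin R expression: the
# margin is >= 0 exactly when the trigger is true, so a false->true
# transition is an upward zero crossing the integrator can root-find.
# Equality triggers get -abs(a-b), which only touches zero at the crossing.
trigger_margin_lang <- function(ast, rename = character()) {
  conv <- function(node) {
    if (node$type == "binop") {
      a <- ast_to_lang(node$lhs, rename); b <- ast_to_lang(node$rhs, rename)
      switch(node$op,
        ">" = , ">=" = return(call("-", a, b)),
        "<" = , "<=" = return(call("-", b, a)),
        "==" = return(call("-", call("abs", call("-", a, b)))),
        "and" = return(call("min", conv(node$lhs), conv(node$rhs))),
        "or" = return(call("max", conv(node$lhs), conv(node$rhs))))
    }
    if (node$type == "unop" && node$op == "not")
      return(call("-", conv(node$arg)))
    rxn_abort("event trigger must be a boolean expression (comparison or and/or/not)",
              "rxnsim_model_error")
  }
  conv(ast)
}
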