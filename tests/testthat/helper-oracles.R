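# Independent reference implementations used as oracles. These are kept
# deliberately naive and separate from the package internals: the package
# parses/compiles/vectorises, the oracles enumerate and delegate to base R.

# ---- random expression generator -----------------------------------------
# Builds a random arithmetic AST (as a plain nested list mirroring the
# package's node shapes), together with an equivalent base-R expression
# string. Both renderings are produced by THIS helper, so the package's
# parser+evaluator and base R's parser+evaluator form two independent
# routes from the same abstract expression.
random_expr <- function(depth, vars) {
  if (depth <= 0 || runif(1) < 0.3) {
    if (runif(1) < 0.5) {
      v <- sample(vars, 1)
      return(list(ast = list(type = "sym", name = v), r = v))
    }
    val <- round(runif(1, 0.1, 5), 3)
    return(list(ast = list(type = "num", value = val),
                r = sprintf("%.12g", val)))
  }
  pick <- sample(c("add", "sub", "mul", "div", "pow", "neg", "fun"), 1,
                 prob = c(0.2, 0.2, 0.2, 0.15, 0.1, 0.05, 0.1))
  if (pick == "neg") {
    a <- random_expr(depth - 1, vars)
    return(list(ast = list(type = "unop", op = "neg", arg = a$ast),
                r = sprintf("-(%s)", a$r)))
  }
  if (pick == "fun") {
    fn <- sample(c("exp", "abs", "sqrt", "min", "max"), 1)
    a <- random_expr(depth - 1, vars)
    if (fn %in% c("min", "max")) {
      b <- random_expr(depth - 1, vars)
      return(list(ast = list(type = "call", fn = fn, args = list(a$ast, b$ast)),
                  r = sprintf("%s(%s, %s)", fn, a$r, b$r)))
    }
    if (fn == "sqrt") # keep the argument non-negative
      return(list(ast = list(type = "call", fn = "sqrt",
                             args = list(list(type = "call", fn = "abs",
                                              args = list(a$ast)))),
                  r = sprintf("sqrt(abs(%s))", a$r)))
    if (fn == "exp") # bounded argument so values stay finite
      return(list(ast = list(type = "call", fn = "exp",
                             args = list(list(type = "call", fn = "min",
                                              args = list(a$ast,
                                                          list(type = "num", value = 5))))),
                  r = sprintf("exp(min(%s, 5))", a$r)))
    return(list(ast = list(type = "call", fn = fn, args = list(a$ast)),
                r = sprintf("%s(%s)", fn, a$r)))
  }
  a <- random_expr(depth - 1, vars)
  b <- random_expr(depth - 1, vars)
  op <- switch(pick, add = "+", sub = "-", mul = "*", div = "/", pow = "^")
  if (op == "^") # bounded positive base, small exponent
    return(list(ast = list(type = "binop", op = "^",
                           lhs = list(type = "call", fn = "abs", args = list(a$ast)),
                           rhs = list(type = "num", value = 1.5)),
                r = sprintf("abs(%s)^1.5", a$r)))
  list(ast = list(type = "binop", op = op, lhs = a$ast, rhs = b$ast),
       r = sprintf("(%s)%s(%s)", a$r, op, b$r))
}

# ---- brute-force mass balance oracle -------------------------------------
# Derivative of every species by direct edge enumeration: loop reactions,
# resolve each substrate/product reference (shortcut -> target id + the
# shortcut's coefficient), compute mass-action rates by explicit product,
# and accumulate +/- coef * rate.
oracle_deriv <- function(scheme, conc, t = 0) {
  out <- stats::setNames(rep(0, length(scheme$species)), names(scheme$species))
  resolve <- function(p) {
    if (!is.null(p$shortcut)) {
      sc <- scheme$shortcuts[[p$shortcut]]
      list(species = sc$target_id, coef = sc$coef)
    } else list(species = p$species, coef = p$coef)
  }
  for (r in scheme$reactions) {
    stopifnot(r$law$kind == "mass_action")
    k <- unname(r$law$parameters[[1]])
    rate <- k
    for (p in r$substrates) {
      e <- resolve(p)
      rate <- rate * conc[[e$species]]^e$coef
    }
    for (p in r$substrates) {
      e <- resolve(p)
      out[[e$species]] <- out[[e$species]] - e$coef * rate
    }
    for (p in r$products) {
      e <- resolve(p)
      out[[e$species]] <- out[[e$species]] + e$coef * rate
    }
  }
  for (s in scheme$species) if (s$type == "pool") out[[s$id]] <- 0
  out
}

# ---- brute-force connectors oracle ---------------------------------------
# For every unordered layer pair, intersect the species referenced by each
# layer's reactions (any role, shortcuts resolved).
oracle_connectors <- function(scheme) {
  resolve <- function(p) {
    if (!is.null(p$shortcut)) scheme$shortcuts[[p$shortcut]]$target_id
    else p$species
  }
  used <- lapply(scheme$layers, function(L) {
    ids <- character()
    for (r in scheme$reactions) {
      if (r$layer != L) next
      for (role in c("substrates", "products", "modifiers"))
        for (p in r[[role]]) ids <- c(ids, resolve(p))
    }
    unique(ids)
  })
  names(used) <- scheme$layers
  out <- list()
  L <- scheme$layers
  if (length(L) < 2) return(out)
  for (i in seq_len(length(L) - 1)) for (j in seq(i + 1, length(L))) {
    shared <- intersect(used[[i]], used[[j]])
    disp <- sort(vapply(shared, function(id) scheme$species[[id]]$display_name,
                        character(1), USE.NAMES = FALSE))
    out[[paste(L[[i]], L[[j]], sep = " | ")]] <- disp
  }
  out
}

# ---- linear-system matrix-exponential oracle -----------------------------
# For schemes whose reactions all have exactly one substrate with
# coefficient 1 (first-order mass action), dx/dt = A x + b with constant b
# from pool-fed reactions. Solve exactly via the augmented matrix
# exponential, using Matrix::expm as the independent linear-algebra route.
oracle_linear_solution <- function(scheme, times) {
  d <- rxnsim::derive(scheme)
  vars <- d$state_ids
  pools <- d$pool_ids
  n <- length(vars)
  A <- matrix(0, n, n, dimnames = list(vars, vars))
  b <- stats::setNames(rep(0, n), vars)
  for (r in scheme$reactions) {
    k <- unname(r$law$parameters[[1]])
    resolve <- function(p) {
      if (!is.null(p$shortcut)) {
        sc <- scheme$shortcuts[[p$shortcut]]
        list(species = sc$target_id, coef = sc$coef)
      } else list(species = p$species, coef = p$coef)
    }
    sub <- resolve(r$substrates[[1]])
    stopifnot(length(r$substrates) == 1, sub$coef == 1)
    edges <- c(lapply(r$substrates, function(p) {
      e <- resolve(p); e$sign <- -1; e
    }), lapply(r$products, function(p) {
      e <- resolve(p); e$sign <- +1; e
    }))
    if (sub$species %in% vars) {
      for (e in edges) if (e$species %in% vars)
        A[e$species, sub$species] <- A[e$species, sub$species] + e$sign * e$coef * k
    } else {
      x0 <- scheme$species[[sub$species]]$initial
      for (e in edges) if (e$species %in% vars)
        b[[e$species]] <- b[[e$species]] + e$sign * e$coef * k * x0
    }
  }
  x0 <- vapply(vars, function(id) scheme$species[[id]]$initial, numeric(1))
  # augmented system: d/dt [x; 1] = [[A, b], [0, 0]] [x; 1]
  Aug <- rbind(cbind(A, b), 0)
  sol <- matrix(NA_real_, length(times), n, dimnames = list(NULL, vars))
  for (i in seq_along(times)) {
    E <- as.matrix(Matrix::expm(Matrix::Matrix(Aug * times[[i]])))
    sol[i, ] <- E[seq_len(n), , drop = FALSE] %*% c(x0, 1)
  }
  sol
}

# random first-order scheme suitable for the linear oracle
random_linear_scheme <- function(seed) {
  rxnsim::make_random_scheme(n_species = 5, n_reactions = 6, seed = seed,
                             max_coef = 1, max_substrates = 1,
                             pool_fraction = 0.3)
}

expect_scheme_valid <- function(scheme) {
  expect_length(validate_scheme(scheme), 0)
}
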