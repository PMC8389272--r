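# Kinetic parameter estimation from observed time courses.
#
# Objective: weighted sum of squared errors between simulated and observed
# concentrations at the observation times. Optimizers: modified Powell
# conjugate directions (deterministic local search with bound clipping and
# direction-set replacement), a real-coded genetic algorithm (BLX-alpha
# crossover, Gaussian mutation, binary tournament selection, elitism), and
# their hybrid (GA global phase polished by Powell).

#' Define a parameter-estimation problem
#'
#' @param scheme a validated `reaction_scheme`.
#' @param free named list or data frame of free parameters with finite
#'   bounds: either `list(k1 = c(0.001, 10), ...)` or a data frame with
#'   columns `name`, `lower`, `upper`. Names address global parameters or
#'   reaction-local kinetic parameters as `"reaction.param"` (e.g.
#'   `"r1.k1"`).
#' @param observed a `timecourse` (or data frame with a `time` column)
#'   holding observations for a subset of species, on any time grid.
#'   Columns are matched by species display name.
#' @param settings [sim_settings()] used for the fitting simulations; its
#'   output grid is replaced by the observation times.
#' @param weights optional named positive per-species weights (display
#'   names); defaults to 1 for every observed species.
#' @return an `estimation_problem`.
#' @export
estimation_problem <- function(scheme, free, observed,
                               settings = sim_settings(tf = 1),
                               weights = NULL) {
  sys <- derive(scheme)
  if (is.data.frame(free))
    free <- stats::setNames(lapply(seq_len(nrow(free)), function(i)
      c(free$lower[[i]], free$upper[[i]])), free$name)
  lower <- vapply(free, `[[`, numeric(1), 1L)
  upper <- vapply(free, `[[`, numeric(1), 2L)
  names(lower) <- names(upper) <- names(free)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper))
    rxn_abort("free-parameter bounds must be finite with lower < upper",
              "rxnsim_model_error")
  bad <- setdiff(names(free), names(sys$parameters))
  if (length(bad))
    rxn_abort(sprintf("unknown free parameter(s): %s", paste(bad, collapse = ", ")),
              "rxnsim_model_error")

  if (is.data.frame(observed)) {
    if (!("time" %in% names(observed)))
      rxn_abort("observed data needs a 'time' column", "rxnsim_io_error")
    observed <- timecourse(observed$time,
                           as.matrix(observed[, setdiff(names(observed), "time"),
                                              drop = FALSE]))
  }
  disp_names <- vapply(scheme$species, `[[`, character(1), "display_name")
  missing_sp <- setdiff(colnames(observed$values), disp_names)
  if (length(missing_sp))
    rxn_abort(sprintf("observed column(s) not in scheme: %s",
                      paste(missing_sp, collapse = ", ")), "rxnsim_io_error")
  if (is.null(weights))
    weights <- stats::setNames(rep(1, ncol(observed$values)),
                               colnames(observed$values))
  tf <- max(observed$times)
  t0 <- min(settings$t0, min(observed$times))
  settings <- sim_settings(tf = tf, t0 = t0, max_step = settings$max_step,
                           rel_tol = settings$rel_tol, abs_tol = settings$abs_tol,
                           grid = sort(unique(c(t0, observed$times))))
  structure(list(scheme = scheme, system = sys, lower = lower, upper = upper,
                 observed = observed, settings = settings, weights = weights),
            class = "estimation_problem")
}

#' Weighted sum-of-squared-errors objective
#'
#' Simulates the scheme at the candidate parameter values and returns
#' `sum_s w_s * sum_t (simulated - observed)^2`. A failed simulation
#' yields `Inf` (penalty), so optimizers can treat any parameter vector
#' inside the bounds as evaluable.
#'
#' @param problem an [estimation_problem()].
#' @param parameters named numeric vector of free-parameter values.
#' @return non-negative number (or `Inf`).
#' @export
objective <- function(problem, parameters) {
  if (!is.null(names(parameters)) &&
      all(names(problem$lower) %in% names(parameters))) {
    parameters <- parameters[names(problem$lower)]
  } else {
    names(parameters) <- names(problem$lower)
  }
  tc <- tryCatch(
    suppressWarnings(simulate_scheme(problem$system, problem$settings,
                                     parameters = parameters)),
    error = function(e) NULL)
  if (is.null(tc)) return(Inf)
  obs <- problem$observed
  idx <- match(obs$times, tc$times)
  if (anyNA(idx)) return(Inf)
  total <- 0
  for (sp in colnames(obs$values)) {
    resid <- tc$values[idx, sp] - obs$values[, sp]
    total <- total + problem$weights[[sp]] * sum(resid^2)
  }
  if (!is.finite(total)) return(Inf)
  total
}

new_estimation_result <- function(best, value, evals, method, seed, trace,
                                  problem) {
  structure(list(best_parameters = best, objective_value = value,
                 evaluations = evals, method = method, seed = seed,
                 trace = trace, problem = problem),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf("<estimation_result> method=%s  SSE=%.6g  evaluations=%d\n",
              x$method, x$objective_value, x$evaluations))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  cat("  parameters:\n")
  for (nm in names(x$best_parameters))
    cat(sprintf("    %-12s %.8g\n", nm, x$best_parameters[[nm]]))
  invisible(x)
}

#' @export
coef.estimation_result <- function(object, ...) object$best_parameters

#' @export
summary.estimation_result <- function(object, ...) {
  cat(sprintf("Parameter estimation by %s\n", object$method))
  print(object)
  if (length(object$trace) > 1L)
    cat(sprintf("  trace: %.6g -> %.6g over %d iterations\n",
                object$trace[[1L]], object$trace[[length(object$trace)]],
                length(object$trace)))
  invisible(object)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# feasible step interval for a line search x + a*d inside [lo, hi]
line_bounds <- function(x, d, lo, hi) {
  a_lo <- -Inf; a_hi <- Inf
  for (i in seq_along(x)) {
    if (d[[i]] == 0) next
    r <- sort(c((lo[[i]] - x[[i]]) / d[[i]], (hi[[i]] - x[[i]]) / d[[i]]))
    a_lo <- max(a_lo, r[[1L]]); a_hi <- min(a_hi, r[[2L]])
  }
  c(a_lo, a_hi)
}

#' Fit by the modified Powell conjugate-direction method
#'
#' Derivative-free local minimisation: repeated one-dimensional (Brent)
#' line minimisations along a direction set that starts as the coordinate
#' axes and is updated with the iteration's net displacement when the
#' standard replacement test accepts it, restarting from the identity when
#' the set degenerates. Steps are confined to the parameter bounds.
#' Deterministic given the start point.
#'
#' @param problem an [estimation_problem()].
#' @param start named numeric start values within bounds (default:
#'   midpoint of the bounds).
#' @param maxit maximum outer iterations.
#' @param tol relative convergence tolerance on the objective.
#' @param fn objective override (used by tests with synthetic landscapes);
#'   default evaluates [objective()].
#' @return an `estimation_result`.
#' @export
fit_powell <- function(problem, start = NULL, maxit = 100, tol = 1e-10,
                       fn = NULL) {
  lo <- problem$lower; hi <- problem$upper
  n <- length(lo)
  if (is.null(start)) start <- (lo + hi) / 2
  start <- clip(start[names(lo)], lo, hi)
  evals <- 0L
  f <- function(x) { evals <<- evals + 1L; if (is.null(fn)) objective(problem, x) else fn(x) }

  x <- start
  fx <- f(x)
  U <- diag(n)
  trace <- fx
  replaced <- 0L
  for (iter in seq_len(maxit)) {
    x0 <- x; f0 <- fx
    delta <- 0; delta_i <- 1L
    for (i in seq_len(n)) {
      d <- U[, i]
      ab <- line_bounds(x, d, lo, hi)
      if (!all(is.finite(ab)) || ab[[2L]] - ab[[1L]] < 1e-14) next
      op <- stats::optimize(function(a) f(x + a * d), interval = ab, tol = 1e-10)
      if (op$objective < fx) {
        if (fx - op$objective > delta) { delta <- fx - op$objective; delta_i <- i }
        x <- clip(x + op$minimum * d, lo, hi)
        fx <- op$objective
      }
    }
    trace <- c(trace, fx)
    if (2 * (f0 - fx) <= tol * (abs(f0) + abs(fx)) + 1e-300) break

    # Powell's replacement test on the net displacement direction
    d_new <- x - x0
    if (sqrt(sum(d_new^2)) > 1e-14) {
      xe <- clip(x0 + 2 * d_new, lo, hi)
      fe <- f(xe)
      if (fe < f0) {
        tcrit <- 2 * (f0 - 2 * fx + fe) * (f0 - fx - delta)^2 - delta * (f0 - fe)^2
        if (tcrit < 0) {
          dn <- d_new / sqrt(sum(d_new^2))
          ab <- line_bounds(x, dn, lo, hi)
          if (all(is.finite(ab)) && ab[[2L]] - ab[[1L]] > 1e-14) {
            op <- stats::optimize(function(a) f(x + a * dn), interval = ab, tol = 1e-10)
            if (op$objective < fx) {
              x <- clip(x + op$minimum * dn, lo, hi)
              fx <- op$objective
            }
          }
          U[, delta_i] <- U[, n]
          U[, n] <- dn
          replaced <- replaced + 1L
          if (replaced >= n) { U <- diag(n); replaced <- 0L }  # re-span
        }
      }
    }
  }
  new_estimation_result(stats::setNames(x, names(lo)), fx, evals, "powell",
                        NULL, trace, problem)
}

#' Fit by a real-coded genetic algorithm
#'
#' Uniform random initialisation within the bounds, BLX-alpha crossover
#' (alpha = 0.5), per-gene Gaussian mutation (rate `mut_rate`, standard
#' deviation `mut_sd_frac` of the parameter range), binary tournament
#' selection and single-individual elitism. Fully reproducible from the
#' seed.
#'
#' @param problem an [estimation_problem()].
#' @param pop_size population size (>= 4).
#' @param generations number of generations.
#' @param seed integer seed.
#' @param alpha BLX crossover expansion factor.
#' @param mut_rate per-gene mutation probability.
#' @param mut_sd_frac mutation standard deviation as a fraction of the
#'   parameter range.
#' @param fn objective override (see [fit_powell()]).
#' @return an `estimation_result` whose `trace` is the per-generation best
#'   objective.
#' @export
fit_rcga <- function(problem, pop_size = 40, generations = 100, seed = 1,
                     alpha = 0.5, mut_rate = 0.1, mut_sd_frac = 0.05,
                     fn = NULL) {
  if (pop_size < 4) rxn_abort("pop_size must be >= 4", "rxnsim_model_error")
  lo <- problem$lower; hi <- problem$upper
  n <- length(lo)
  evals <- 0L
  f <- function(x) { evals <<- evals + 1L; if (is.null(fn)) objective(problem, x) else fn(x) }

  res <- local_rng(seed, {
    pop <- matrix(stats::runif(pop_size * n, rep(lo, each = pop_size),
                               rep(hi, each = pop_size)),
                  nrow = pop_size, ncol = n)
    fit <- apply(pop, 1L, f)
    trace <- numeric(generations)
    for (g in seq_len(generations)) {
      newpop <- matrix(0, pop_size, n)
      best_i <- which.min(fit)
      newpop[1L, ] <- pop[best_i, ]  # elitism
      tournament <- function() {
        cand <- sample(pop_size, 2L)
        cand[[which.min(fit[cand])]]
      }
      for (m in 2:pop_size) {
        p1 <- pop[tournament(), ]; p2 <- pop[tournament(), ]
        cmin <- pmin(p1, p2); cmax <- pmax(p1, p2)
        d <- cmax - cmin
        child <- stats::runif(n, cmin - alpha * d, cmax + alpha * d)
        mut <- stats::runif(n) < mut_rate
        if (any(mut))
          child[mut] <- child[mut] +
            stats::rnorm(sum(mut), 0, mut_sd_frac * (hi[mut] - lo[mut]))
        newpop[m, ] <- clip(child, lo, hi)
      }
      pop <- newpop
      fit <- c(fit[best_i], apply(pop[-1L, , drop = FALSE], 1L, f))
      trace[[g]] <- min(fit)
    }
    best_i <- which.min(fit)
    list(x = stats::setNames(pop[best_i, ], names(lo)), fx = fit[[best_i]],
         trace = trace)
  })
  new_estimation_result(res$x, res$fx, evals, "rcga", as.integer(seed),
                        res$trace, problem)
}

#' Fit by the hybrid method (RCGA then Powell)
#'
#' Runs the real-coded genetic algorithm as a global phase, then polishes
#' its best individual with the modified Powell method. The final
#' objective is never worse than the GA phase's.
#'
#' @inheritParams fit_rcga
#' @param ... further arguments passed to [fit_rcga()].
#' @return an `estimation_result` with method `"hybrid"`.
#' @export
fit_hybrid <- function(problem, pop_size = 40, generations = 100, seed = 1,
                       fn = NULL, ...) {
  ga <- fit_rcga(problem, pop_size = pop_size, generations = generations,
                 seed = seed, fn = fn, ...)
  pw <- fit_powell(problem, start = ga$best_parameters, fn = fn)
  if (pw$objective_value <= ga$objective_value) {
    best <- pw$best_parameters; val <- pw$objective_value
  } else {
    best <- ga$best_parameters; val <- ga$objective_value
  }
  new_estimation_result(best, val, ga$evaluations + pw$evaluations, "hybrid",
                        as.integer(seed), c(ga$trace, pw$trace), problem)
}
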