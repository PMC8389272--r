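# Time-course simulation: stiff BDF (Gear-family) integration via deSolve,
# with constant pools, assignment rules applied at every reported point,
# and events localised by root-finding on a signed trigger margin and
# applied by restarting the integrator.

#' Simulation settings
#'
#' @param tf final time (arbitrary time unit).
#' @param t0 initial time.
#' @param max_step maximum integrator step size (default 0.1).
#' @param rel_tol,abs_tol relative/absolute integration tolerances.
#' @param grid explicit output times (overrides `n_out`), or `NULL`.
#' @param n_out number of equally spaced output points when `grid` is
#'   `NULL` (default 201).
#' @return a `sim_settings` list.
#' @export
sim_settings <- function(tf = 10, t0 = 0, max_step = 0.1,
                         rel_tol = 1e-6, abs_tol = 1e-9,
                         grid = NULL, n_out = 201L) {
  if (!(tf > t0)) rxn_abort("tf must be greater than t0", "rxnsim_model_error")
  if (!(max_step > 0)) rxn_abort("max_step must be positive", "rxnsim_model_error")
  structure(list(t0 = t0, tf = tf, max_step = max_step,
                 rel_tol = rel_tol, abs_tol = abs_tol,
                 grid = grid, n_out = as.integer(n_out)),
            class = "sim_settings")
}

settings_times <- function(settings) {
  tt <- settings$grid %||% seq(settings$t0, settings$tf, length.out = settings$n_out)
  tt <- sort(unique(as.numeric(tt)))
  if (any(diff(tt) <= 0)) rxn_abort("output times must be strictly increasing",
                                    "rxnsim_model_error")
  tt
}

#' Simulate a reaction scheme
#'
#' Integrates the automatically derived mass balance ODEs with a
#' variable-order stiff BDF integrator (the Gear family), honouring
#' `max_step`. Pool species stay at their (possibly event-reassigned)
#' concentration, assignment rules are evaluated at every reported point,
#' and events fire when their trigger switches from false to true: the
#' crossing is localised by root-finding, the assignments are applied in
#' declaration order, and integration restarts from the event time.
#' Triggers already true at `t0` do not fire at `t0`. Negative
#' concentrations are reported with a warning, never clamped.
#'
#' @param scheme a validated `reaction_scheme` (or a `derived_system`).
#' @param settings a [sim_settings()] object.
#' @param parameters optional named vector overriding entries of the
#'   derived system's default parameter vector (globals, `reaction.param`
#'   locals, pool concentrations).
#' @return a `timecourse`: list with `times`, `values` (matrix, one column
#'   per species incl. pools and rule outputs, named by display name),
#'   `event_log` (data frame time/event) and `species` (display name to id
#'   map).
#' @examples
#' sch <- make_linear_chain(n = 2)
#' tc <- simulate_scheme(sch, sim_settings(tf = 20))
#' tail(as.data.frame(tc), 2)
#' @export
simulate_scheme <- function(scheme, settings = sim_settings(), parameters = NULL) {
  sys <- if (inherits(scheme, "derived_system")) scheme else derive(scheme)
  scheme <- sys$scheme
  params <- sys$parameters
  if (!is.null(parameters)) {
    bad <- setdiff(names(parameters), names(params))
    if (length(bad))
      rxn_abort(sprintf("unknown parameter(s): %s", paste(bad, collapse = ", ")),
                "rxnsim_model_error")
    params[names(parameters)] <- parameters
  }

  out_times <- settings_times(settings)
  state_ids <- sys$state_ids
  y <- sys$initial_state

  # event machinery: boolean evaluators + signed-margin root functions
  events <- scheme$events
  n_ev <- length(events)
  fun_env <- expr_fun_env()
  ev_info <- lapply(events, function(ev) {
    ast <- expr_parse(ev$trigger)$ast
    list(id = ev$id,
         bool_lang = ast_to_lang(ast),
         margin_lang = trigger_margin_lang(ast),
         assigns = lapply(seq_along(ev$assignments), function(i)
           list(target = names(ev$assignments)[[i]],
                lang = ast_to_lang(expr_parse(ev$assignments[[i]])$ast))))
  })

  bindings_env <- function(t, y, p) {
    env <- list2env(as.list(p), parent = fun_env)
    if (length(y)) for (i in seq_along(state_ids)) assign(state_ids[[i]], y[[i]], envir = env)
    assign("t", t, envir = env)
    if (length(sys$rule_target_ids)) {
      rv <- sys$rule_values(t, y, p)
      for (i in seq_along(rv)) assign(sys$rule_target_ids[[i]], rv[[i]], envir = env)
    }
    env
  }
  trigger_states <- function(t, y, p) {
    if (!n_ev) return(logical())
    env <- bindings_env(t, y, p)
    vapply(ev_info, function(ei) isTRUE(eval(ei$bool_lang, env)), logical(1))
  }

  deriv_fn <- function(t, y, p) list(sys$rhs(t, y, p))
  root_fn <- function(t, y, p) {
    env <- bindings_env(t, y, p)
    vapply(ev_info, function(ei) eval(ei$margin_lang, env), numeric(1))
  }

  # one output row: variables, pools, rule outputs (declaration order)
  row_cols <- unname(c(state_ids, sys$pool_ids, sys$rule_target_ids))
  make_row <- function(t, y, p) {
    rv <- if (length(sys$rule_target_ids)) sys$rule_values(t, y, p) else numeric()
    c(y, unname(p[sys$pool_ids]), unname(rv))
  }

  t_cur <- settings$t0
  prev_trig <- trigger_states(t_cur, y, params)
  rows <- list(make_row(t_cur, y, params))
  row_times <- t_cur
  event_log <- list()
  stall_count <- 0L
  last_stop <- NA_real_

  no_state <- length(state_ids) == 0L

  while (t_cur < settings$tf) {
    seg_times <- c(t_cur, out_times[out_times > t_cur])
    if (seg_times[[length(seg_times)]] < settings$tf)
      seg_times <- c(seg_times, settings$tf)

    if (no_state) {
      # nothing to integrate; events can still fire on time-only triggers:
      # scan the trigger on a max_step-spaced grid merged with the output grid
      hit <- NA_real_
      dense <- sort(unique(c(seg_times, seq(t_cur, settings$tf,
                                            by = settings$max_step), settings$tf)))
      dense <- dense[dense > t_cur]
      for (tt in dense) {
        if (n_ev && any(trigger_states(tt, y, params) & !prev_trig)) {
          hit <- tt
        }
        if (tt %in% out_times || !is.na(hit) || tt == settings$tf) {
          rows[[length(rows) + 1L]] <- make_row(tt, y, params)
          row_times <- c(row_times, tt)
        }
        t_cur <- tt
        if (!is.na(hit)) break
      }
      if (is.na(hit)) {
        t_cur <- settings$tf
        break
      }
      troot <- hit
    } else {
      sol <- try(deSolve::ode(
        y = stats::setNames(y, state_ids), times = seg_times, func = deriv_fn,
        parms = params, method = "bdf",
        hmax = settings$max_step, rtol = settings$rel_tol, atol = settings$abs_tol,
        rootfunc = if (n_ev) root_fn else NULL,
        maxsteps = 50000), silent = TRUE)
      if (inherits(sol, "try-error"))
        rxn_abort(sprintf("integrator failure starting at t=%g: %s",
                          t_cur, attr(sol, "condition")$message),
                  "rxnsim_numerical_error", last_good_time = t_cur)
      istate <- attr(sol, "istate")[[1L]]
      if (is.null(istate)) istate <- 2L
      if (istate < 0L)
        rxn_abort(sprintf(
          "integrator failure (istate=%d) near t=%g; last good time %g",
          istate, sol[nrow(sol), 1L], sol[nrow(sol), 1L]),
          "rxnsim_numerical_error", last_good_time = sol[nrow(sol), 1L])
      troot <- attr(sol, "troot")
      sol_t <- sol[, 1L]
      end_t <- sol_t[[length(sol_t)]]
      keep <- which(sol_t > t_cur & (sol_t %in% out_times | sol_t == end_t))
      for (i in keep) {
        yy <- as.numeric(sol[i, 1L + seq_along(state_ids)])
        rows[[length(rows) + 1L]] <- make_row(sol_t[[i]], yy, params)
        row_times <- c(row_times, sol_t[[i]])
      }
      y <- as.numeric(sol[nrow(sol), 1L + seq_along(state_ids)])
      if (is.null(troot) || !length(troot)) {
        t_cur <- end_t
        next
      }
      troot <- troot[[length(troot)]]
      t_cur <- end_t  # end_t == troot when a root stopped the integration
    }

    # a root was localised: fire events whose trigger flipped false -> true
    if (!is.na(last_stop) && abs(t_cur - last_stop) < 1e-12) {
      stall_count <- stall_count + 1L
      if (stall_count > 100L)
        rxn_abort(sprintf("event trigger stalls integration at t=%g", t_cur),
                  "rxnsim_numerical_error", last_good_time = t_cur)
    } else stall_count <- 0L
    last_stop <- t_cur

    trig <- trigger_states(t_cur, y, params)
    fired <- which(trig & !prev_trig)
    for (i in fired) {
      env <- bindings_env(t_cur, y, params)
      for (a in ev_info[[i]]$assigns) {
        val <- eval(a$lang, env)
        if (a$target %in% state_ids) {
          y[[match(a$target, state_ids)]] <- val
        } else if (a$target %in% names(params)) {
          params[[a$target]] <- val
        } else {
          rxn_abort(sprintf("event '%s': cannot assign to '%s'",
                            ev_info[[i]]$id, a$target), "rxnsim_model_error")
        }
      }
      event_log[[length(event_log) + 1L]] <-
        data.frame(time = t_cur, event = ev_info[[i]]$id,
                   stringsAsFactors = FALSE)
    }
    prev_trig <- trigger_states(t_cur, y, params)
    # refresh the row at the event time with post-assignment values
    if (length(fired) && length(row_times) &&
        row_times[[length(row_times)]] == t_cur) {
      rows[[length(rows)]] <- make_row(t_cur, y, params)
    }
  }

  times <- row_times
  values <- do.call(rbind, rows)
  # strictly increasing times: drop duplicate time points (keep the last,
  # i.e. post-event, row)
  keep <- !duplicated(times, fromLast = TRUE)
  times <- times[keep]
  values <- values[keep, , drop = FALSE]
  disp <- vapply(row_cols, function(id) scheme$species[[id]]$display_name,
                 character(1), USE.NAMES = FALSE)
  colnames(values) <- disp
  rownames(values) <- NULL

  if (length(values) && length(state_ids) &&
      min(values[, seq_along(state_ids)]) < -100 * settings$abs_tol)
    warning(sprintf("negative concentration reached (min %.6g); values are reported, not clamped",
                    min(values[, seq_along(state_ids)])), call. = FALSE)

  timecourse(times, values,
             event_log = if (length(event_log)) do.call(rbind, event_log)
                         else data.frame(time = numeric(), event = character()),
             species = stats::setNames(row_cols, disp))
}

#' Construct a time course
#'
#' @param times strictly increasing numeric vector.
#' @param values numeric matrix, one column per species (column names are
#'   display names).
#' @param event_log data frame with columns `time` and `event`.
#' @param species named character vector mapping display name to id
#'   (optional).
#' @return an object of class `timecourse`.
#' @export
timecourse <- function(times, values,
                       event_log = data.frame(time = numeric(), event = character()),
                       species = NULL) {
  values <- as.matrix(values)
  if (length(times) != nrow(values))
    rxn_abort("times and values have different lengths", "rxnsim_model_error")
  if (length(times) > 1L && any(diff(times) <= 0))
    rxn_abort("times must be strictly increasing", "rxnsim_model_error")
  structure(list(times = as.numeric(times), values = values,
                 event_log = event_log, species = species),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("<timecourse> %d points, t in [%g, %g], %d species\n",
              length(x$times), if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA, ncol(x$values)))
  if (nrow(x$event_log))
    cat(sprintf("  events fired: %s\n",
                paste(sprintf("%s@t=%g", x$event_log$event, x$event_log$time),
                      collapse = ", ")))
  utils::str(utils::head(as.data.frame(x), 3), give.attr = FALSE)
  invisible(x)
}

#' @export
as.data.frame.timecourse <- function(x, ...) {
  df <- data.frame(time = x$times, check.names = FALSE)
  cbind(df, as.data.frame(x$values, check.names = FALSE))
}

#' Plot a time course
#'
#' @param x a `timecourse`.
#' @param species optional character vector of display names to plot.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.timecourse <- function(x, species = NULL, ...) {
  v <- x$values
  if (!is.null(species)) v <- v[, species, drop = FALSE]
  graphics::matplot(x$times, v, type = "l", lty = 1,
                    xlab = "time", ylab = "concentration", ...)
  graphics::legend("topright", legend = colnames(v), lty = 1,
                   col = seq_len(ncol(v)), cex = 0.8, bty = "n")
  invisible(x)
}

#' Write / read a time course as CSV
#'
#' Plain CSV with header `time,<species display names...>`; numbers are
#' written with 12 significant digits, so a write/read round trip is
#' lossless at that precision.
#'
#' @param tc a `timecourse`.
#' @param destination,source file path.
#' @return `read_timecourse` returns a `timecourse` (without event log).
#' @export
write_timecourse <- function(tc, destination) {
  df <- as.data.frame(tc)
  header <- paste(vapply(colnames(df), function(nm) {
    if (grepl('[",]', nm)) paste0('"', gsub('"', '""', nm), '"') else nm
  }, character(1)), collapse = ",")
  body <- apply(df, 1L, function(row) paste(num12(as.numeric(row)), collapse = ","))
  writeLines(c(header, body), destination)
  invisible(tc)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(source) {
  lines <- readLines(source)
  if (!length(lines)) rxn_abort("empty time-course file", "rxnsim_io_error")
  nf <- utils::count.fields(textConnection(lines), sep = ",", quote = '"')
  bad <- which(nf != nf[[1L]])
  if (length(bad))
    rxn_abort(sprintf("malformed CSV at line %d: expected %d fields, found %d",
                      bad[[1L]], nf[[1L]], nf[[bad[[1L]]]]), "rxnsim_io_error")
  df <- utils::read.csv(textConnection(lines), check.names = FALSE)
  if (names(df)[[1L]] != "time")
    rxn_abort("malformed CSV at line 1: first column must be 'time'", "rxnsim_io_error")
  if (!nrow(df))
    return(timecourse(numeric(), matrix(numeric(), nrow = 0,
                                        ncol = ncol(df) - 1L,
                                        dimnames = list(NULL, names(df)[-1L]))))
  timecourse(df[[1L]], as.matrix(df[, -1L, drop = FALSE]))
}
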