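# Stiff simulation: closed forms, linear-system oracle, conservation,
# rules, events, CSV round trips.

test_that("pool-fed two-species chain matches its closed form", {
  tc <- simulate_scheme(make_linear_chain(n = 3), sim_settings(tf = 20))
  expected <- 100 * (1 - exp(-0.1 * tc$times))
  expect_equal(unname(tc$values[, "X2"]), expected, tolerance = 1e-3)
  # spot value highlighted by the closed form: X2(20) ~ 86.466
  i20 <- which(tc$times == 20)
  expect_equal(unname(tc$values[i20, "X2"]), 86.466, tolerance = 1e-3)
  # the pool column stays constant
  expect_true(all(tc$values[, "X1"] == 100))
})

test_that("a scheme with species but no reactions stays at its initial values", {
  s <- reaction_scheme(species = list(species_symbol("A", initial = 3),
                                      species_symbol("B", initial = 1)))
  tc <- simulate_scheme(s, sim_settings(tf = 5))
  expect_true(all(tc$values[, "A"] == 3))
  expect_true(all(tc$values[, "B"] == 1))
})

test_that("random first-order schemes match the matrix-exponential oracle", {
  for (seed in 1:6) {
    s <- random_linear_scheme(seed)
    st <- sim_settings(tf = 20, rel_tol = 1e-9, abs_tol = 1e-12, n_out = 41)
    tc <- simulate_scheme(s, st)
    d <- derive(s)
    disp <- vapply(d$state_ids, function(id) s$species[[id]]$display_name,
                   character(1))
    ref <- oracle_linear_solution(s, tc$times)
    scale <- max(abs(ref), 1)
    expect_lt(max(abs(tc$values[, disp, drop = FALSE] - ref)) / scale, 1e-6,
              label = sprintf("linear scheme seed %d", seed))
  }
})

test_that("closed mass-action systems conserve left null vectors", {
  s <- make_butanol()  # no sources, sinks or pools
  d <- derive(s)
  S <- d$stoichiometry[d$state_ids, , drop = FALSE]
  ns <- MASS::Null(S)  # basis of { v : t(S) v = 0 }
  expect_gt(ncol(ns), 0)  # a closed system has conserved totals
  tc <- simulate_scheme(s, sim_settings(tf = 1000, n_out = 101))
  disp <- vapply(d$state_ids, function(id) s$species[[id]]$display_name,
                 character(1))
  traj <- tc$values[, disp, drop = FALSE]
  for (k in seq_len(ncol(ns))) {
    q <- drop(traj %*% ns[, k])
    expect_lt(max(abs(q - q[[1]])) / max(abs(q[[1]]), 1), 1e-6,
              label = sprintf("conserved quantity %d", k))
  }
  # the biologically meaningful invariant: NAD+ + NADH total
  tot <- tc$values[, "NAD+"] + tc$values[, "NADH"]
  expect_lt(max(abs(tot - tot[[1]])), 1e-6)
})

test_that("assignment rule outputs equal the sum of their inputs at every point", {
  tc <- simulate_scheme(make_rule_event_toy(), sim_settings(tf = 12))
  total <- tc$values[, "A1"] + tc$values[, "A2"] + tc$values[, "A3"] +
    tc$values[, "A4"]
  expect_equal(unname(tc$values[, "total_A"]), unname(total), tolerance = 1e-12)
})

test_that("events are root-localised and match the piecewise closed form", {
  # A -> (sink) with k := 0 at t = 10: A(t) = A0 * exp(-k*min(t, 10))
  s <- reaction_scheme(
    species = list(species_symbol("A", initial = 5)),
    reactions = list(reaction_step("r1", "A", character(), rate_law("k*A"))),
    events = list(event_spec("halt", "t>=10", c(k = "0"))),
    parameters = c(k = 0.2))
  tc <- simulate_scheme(s, sim_settings(tf = 20, rel_tol = 1e-9, abs_tol = 1e-12))
  expected <- 5 * exp(-0.2 * pmin(tc$times, 10))
  expect_equal(unname(tc$values[, "A"]), expected, tolerance = 1e-6)
  expect_equal(nrow(tc$event_log), 1)
  expect_equal(tc$event_log$time, 10, tolerance = 1e-6)

  # state-dependent trigger: reset A when it decays below 1
  s2 <- reaction_scheme(
    species = list(species_symbol("A", initial = 2)),
    reactions = list(reaction_step("r1", "A", character(), mass_action(1, "k"))),
    events = list(event_spec("refill", "A<=1", c(A = "2"))))
  tc2 <- simulate_scheme(s2, sim_settings(tf = 3, rel_tol = 1e-9, abs_tol = 1e-12))
  # first crossing at t = ln 2; the sawtooth then repeats
  expect_gte(nrow(tc2$event_log), 3)
  expect_equal(tc2$event_log$time[1:3], log(2) * 1:3, tolerance = 1e-5)
  # a trigger already true at t0 does not fire at t0
  s3 <- reaction_scheme(
    species = list(species_symbol("A", initial = 5)),
    reactions = list(reaction_step("r1", "A", character(), mass_action(0.1, "k"))),
    events = list(event_spec("never", "A>=1", c(A = "100"))))
  tc3 <- simulate_scheme(s3, sim_settings(tf = 1))
  expect_equal(nrow(tc3$event_log), 0)
  expect_lt(max(tc3$values[, "A"]), 5 + 1e-9)
})

test_that("estimation remains possible with events: parameters change mid-run", {
  # the event resets k1 at t = 5, so the post-event slope is zero
  tc <- simulate_scheme(make_rule_event_toy(), sim_settings(tf = 10))
  after <- tc$values[tc$times >= 5 + 1e-9, "A1"]
  expect_lt(diff(range(after)), 1e-6)
  expect_equal(unname(after[[1]]), 8 * exp(-0.3 * 5), tolerance = 1e-5)
})

test_that("tightening tolerances tenfold moves results by less than the coarser tolerance", {
  s <- make_atp_toy()
  t1 <- simulate_scheme(s, sim_settings(tf = 50, rel_tol = 1e-6, abs_tol = 1e-9))
  t2 <- simulate_scheme(s, sim_settings(tf = 50, rel_tol = 1e-7, abs_tol = 1e-10))
  scale <- max(abs(t2$values))
  expect_lt(max(abs(t1$values - t2$values)) / scale, 1e-6)
})

test_that("negative concentrations warn but are not clamped", {
  # constant outflow from a depleting species goes negative
  s <- reaction_scheme(
    species = list(species_symbol("A", initial = 1),
                   species_symbol("F", initial = 1, type = "pool")),
    reactions = list(reaction_step("r1", list(sp_ref("A")), character(),
                                   rate_law("k0*F", parameters = c(k0 = 1)))))
  expect_warning(tc <- simulate_scheme(s, sim_settings(tf = 2)),
                 "negative concentration")
  expect_lt(min(tc$values[, "A"]), -0.5)
})

test_that("time courses round-trip through CSV at 12 significant digits", {
  tc <- simulate_scheme(make_atp_toy(), sim_settings(tf = 5, n_out = 21))
  path <- withr::local_tempfile(fileext = ".csv")
  write_timecourse(tc, path)
  header <- readLines(path, n = 1)
  expect_equal(header, paste(c("time", colnames(tc$values)), collapse = ","))
  back <- read_timecourse(path)
  expect_equal(back$times, tc$times, tolerance = 1e-12)
  expect_equal(back$values, tc$values, tolerance = 1e-12)

  # empty course -> header-only file
  empty <- timecourse(numeric(),
                      matrix(numeric(), 0, 2, dimnames = list(NULL, c("A", "B"))))
  write_timecourse(empty, path)
  expect_length(readLines(path), 1)
  back2 <- read_timecourse(path)
  expect_length(back2$times, 0)

  # malformed CSV errors with the line number
  writeLines(c("time,A", "0,1", "1,2,3"), path)
  expect_error(read_timecourse(path), "line 3", class = "rxnsim_io_error")
})

test_that("timecourse containers enforce monotone time", {
  expect_error(timecourse(c(0, 0, 1), matrix(0, 3, 1)), "strictly increasing",
               class = "rxnsim_model_error")
})
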