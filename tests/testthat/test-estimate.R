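# Parameter estimation: SSE objective, Powell, RCGA, hybrid.

# noiseless observations from the 3-species chain at the true parameters
chain_problem <- function(obs_times = seq(2, 30, by = 2),
                          bounds = c(0.01, 1), noise_sd = 0, seed = 1) {
  sch <- make_linear_chain(n = 3)
  tc <- simulate_scheme(sch, sim_settings(tf = max(obs_times), grid = obs_times))
  vals <- tc$values[, c("X2", "X3")]
  if (noise_sd > 0) {
    set.seed(seed)
    vals <- vals + matrix(rnorm(length(vals), 0, noise_sd * pmax(abs(vals), 1)),
                          nrow(vals))
  }
  estimation_problem(
    sch,
    list("r1.k1" = bounds, "r2.k2" = bounds, "r3.k3" = bounds),
    timecourse(tc$times, vals))
}

truth <- c("r1.k1" = 0.1, "r2.k2" = 0.1, "r3.k3" = 0.1)

test_that("the SSE objective is zero at the generating parameters and hand-checkable", {
  prob <- chain_problem()
  expect_lt(objective(prob, truth), 1e-10)
  expect_gt(objective(prob, truth * 2), 0)

  # two observation points, one species, worked by hand:
  # chain n=2: X2(t) = 100*(1 - exp(-0.1 t)); observe zeros at t = 5, 10
  sch2 <- make_linear_chain(n = 2)
  obs <- timecourse(c(5, 10), cbind(X2 = c(0, 0)))
  p2 <- estimation_problem(sch2, list("r1.k1" = c(0.01, 1), "r2.k2" = c(0.01, 1)), obs)
  manual <- sum((100 * (1 - exp(-0.1 * c(5, 10))))^2)
  expect_equal(objective(p2, c(0.1, 0.1)), manual, tolerance = 1e-4)

  # observed species absent from the scheme are reported by name
  expect_error(
    estimation_problem(sch2, list("r1.k1" = c(0.01, 1)),
                       timecourse(c(1, 2), cbind(Xmissing = c(0, 0)))),
    "Xmissing", class = "rxnsim_io_error")
})

test_that("Powell converges on a quadratic surrogate and is deterministic", {
  fake <- structure(list(lower = c(a = -5, b = -5), upper = c(a = 5, b = 5)),
                    class = "estimation_problem")
  fn <- function(x) (x[[1]] - 1.3)^2 + 4 * (x[[2]] + 0.7)^2 + 2
  fit <- fit_powell(fake, start = c(a = 4, b = 4), fn = fn)
  expect_equal(unname(fit$best_parameters), c(1.3, -0.7), tolerance = 1e-8)
  expect_equal(fit$objective_value, 2, tolerance = 1e-10)
  fit2 <- fit_powell(fake, start = c(a = 4, b = 4), fn = fn)
  expect_identical(fit$best_parameters, fit2$best_parameters)
})

test_that("Powell recovers chain rate constants from noiseless data", {
  prob <- chain_problem()
  fit <- fit_powell(prob, start = c("r1.k1" = 0.05, "r2.k2" = 0.05, "r3.k3" = 0.05))
  expect_equal(unname(fit$best_parameters), unname(truth), tolerance = 1e-3)
  # starting at the truth stays at the truth
  fit0 <- fit_powell(prob, start = truth)
  expect_lt(fit0$objective_value, 1e-10)
  expect_equal(unname(fit0$best_parameters), unname(truth), tolerance = 1e-6)
})

test_that("the RCGA is reproducible from its seed and improves on its initialisation", {
  fake <- structure(list(lower = c(a = -2, b = -2), upper = c(a = 2, b = 2)),
                    class = "estimation_problem")
  fn <- function(x) sum((x - 0.5)^2)
  g1 <- fit_rcga(fake, pop_size = 20, generations = 25, seed = 7, fn = fn)
  g2 <- fit_rcga(fake, pop_size = 20, generations = 25, seed = 7, fn = fn)
  expect_identical(g1$best_parameters, g2$best_parameters)
  expect_identical(g1$trace, g2$trace)
  g3 <- fit_rcga(fake, pop_size = 20, generations = 25, seed = 8, fn = fn)
  expect_false(identical(g1$best_parameters, g3$best_parameters))

  # improvement over the random initialisation, median across seeds
  gains <- vapply(1:5, function(sd) {
    g <- fit_rcga(fake, pop_size = 16, generations = 20, seed = sd, fn = fn)
    g$trace[[1]] - g$objective_value
  }, numeric(1))
  expect_gt(stats::median(gains), 0)
  # and the trace never worsens (elitism)
  g <- fit_rcga(fake, pop_size = 16, generations = 20, seed = 11, fn = fn)
  expect_true(all(diff(g$trace) <= 1e-12))
})

test_that("RCGA with tight bounds recovers the chain parameters", {
  prob <- chain_problem(obs_times = seq(5, 30, by = 5), bounds = c(0.09, 0.11))
  g <- fit_rcga(prob, pop_size = 16, generations = 15, seed = 3)
  expect_equal(unname(g$best_parameters), unname(truth), tolerance = 5e-2)
  expect_true(all(abs(g$best_parameters - 0.1) < 5e-3))
})

test_that("the hybrid is never worse than its GA phase and escapes local basins", {
  # two-basin landscape: local minimum 0.05 at (0.2, 0.2), global 0 at
  # (0.8, 0.8); axis-parallel line searches from the local basin never see
  # the global one
  fake <- structure(list(lower = c(x = 0, y = 0), upper = c(x = 1, y = 1)),
                    class = "estimation_problem")
  fn <- function(p) min((p[[1]] - 0.2)^2 + (p[[2]] - 0.2)^2 + 0.05,
                        2 * ((p[[1]] - 0.8)^2 + (p[[2]] - 0.8)^2))
  stuck <- fit_powell(fake, start = c(x = 0.2, y = 0.2), fn = fn)
  expect_equal(stuck$objective_value, 0.05, tolerance = 1e-6)

  hits <- 0
  for (sd in 1:10) {
    ga <- fit_rcga(fake, pop_size = 30, generations = 30, seed = sd, fn = fn)
    hy <- fit_hybrid(fake, pop_size = 30, generations = 30, seed = sd, fn = fn)
    expect_lte(hy$objective_value, ga$objective_value,
               label = sprintf("seed %d", sd))
    if (hy$objective_value < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("hybrid estimation recovers chain parameters to sub-percent error", {
  prob <- chain_problem(obs_times = seq(2, 30, by = 2))
  fit <- fit_hybrid(prob, pop_size = 16, generations = 12, seed = 5)
  expect_true(all(abs(fit$best_parameters - truth) / truth < 0.01))
  expect_equal(fit$method, "hybrid")
})

test_that("estimation handles schemes with rules and events", {
  toy <- make_rule_event_toy()
  obs_t <- seq(1, 10, by = 1)
  tc <- simulate_scheme(toy, sim_settings(tf = 10, grid = obs_t))
  obs <- timecourse(tc$times, tc$values[, c("A1", "A2"), drop = FALSE])
  prob <- estimation_problem(toy, list(k1 = c(0.05, 1), k2 = c(0.05, 1)), obs)
  fit <- fit_powell(prob, start = c(k1 = 0.5, k2 = 0.5))
  expect_equal(unname(fit$best_parameters), c(0.3, 0.2), tolerance = 1e-3)
})

test_that("recovery error shrinks with denser observation of noisy data", {
  # two-species chain observed through X2 with 5% (of the 100-unit feed
  # scale) Gaussian noise; denser grids carry more information, so the
  # median recovery error over seeds must fall
  mkprob <- function(obs_times, seed) {
    sch <- make_linear_chain(n = 2)
    tc <- simulate_scheme(sch, sim_settings(tf = max(obs_times), grid = obs_times))
    vals <- tc$values[, "X2", drop = FALSE]
    set.seed(seed)
    vals <- vals + matrix(rnorm(length(vals), 0, 0.05 * 100), nrow(vals))
    estimation_problem(sch, list("r1.k1" = c(0.01, 1), "r2.k2" = c(0.01, 1)),
                       timecourse(tc$times, vals))
  }
  densities <- list(seq(10, 30, by = 10), seq(3, 30, by = 3), seq(1, 30, by = 1))
  med_err <- vapply(densities, function(grid) {
    errs <- vapply(1:10, function(sd) {
      fit <- fit_powell(mkprob(grid, 100 + sd),
                        start = c("r1.k1" = 0.15, "r2.k2" = 0.15), maxit = 20)
      max(abs(fit$best_parameters - c(0.1, 0.1)))
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0), info = paste(med_err, collapse = ", "))
})
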