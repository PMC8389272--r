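# Mass balance derivation: stoichiometry, shortcut aliasing, rendering,
# equivalence with brute-force edge enumeration.

test_that("shortcut coefficients enter the target's balance (ATP/ADP toy)", {
  d <- derive(make_atp_toy())
  # first step: direct symbols, coefficient 1
  expect_equal(d$stoichiometry["ATP", "r1"], -1)
  expect_equal(d$stoichiometry["ADP", "r1"], 1)
  # third step: shortcut symbols, coefficient 2
  expect_equal(d$stoichiometry["ATP", "r3"], -2)
  expect_equal(d$stoichiometry["ADP", "r3"], 2)
  # the coefficient is also the kinetic order of the mass-action rate
  expect_match(d$rate_expressions[["r3"]], "ATP\\^2")
  expect_match(d$rate_expressions[["r1"]], "\\*ATP$")
  # and the rendered ATP balance carries the -2* term
  expect_match(d$equations_text[["ATP"]], "-2\\*k3\\*S3\\*ATP\\^2")
})

test_that("simple schemes render textbook equations", {
  s <- reaction_scheme(
    species = list(species_symbol("A", initial = 1), species_symbol("B")),
    reactions = list(reaction_step("r1", "A", "B", mass_action(0.5, "k1"))))
  d <- derive(s)
  expect_equal(unname(d$equations_text[["A"]]), "d[A]/dt = -k1*A")
  expect_equal(unname(d$equations_text[["B"]]), "d[B]/dt = +k1*A")

  # scheme with no reactions renders the zero balance; with no variables,
  # nothing at all
  s0 <- reaction_scheme(species = list(species_symbol("A", initial = 1)))
  expect_equal(unname(derive(s0)$equations_text[["A"]]), "d[A]/dt = 0")
  s00 <- reaction_scheme(species = list(species_symbol("P", initial = 1, type = "pool")))
  expect_equal(render_equations(derive(s00)), "")
})

test_that("rhs equals the brute-force edge-enumeration oracle on random schemes", {
  set.seed(33)
  for (i in 1:50) {
    s <- make_random_scheme(n_species = sample(3:7, 1),
                            n_reactions = sample(2:9, 1),
                            seed = 1000 + i,
                            two_layers = i %% 2 == 0)
    d <- derive(s)
    conc <- stats::setNames(round(runif(length(s$species), 0.1, 3), 3),
                            names(s$species))
    for (id in d$pool_ids) conc[[id]] <- s$species[[id]]$initial
    got <- d$rhs(0, conc[d$state_ids])
    ref <- oracle_deriv(s, conc)[d$state_ids]
    expect_equal(unname(got), unname(ref), tolerance = 1e-12,
                 label = sprintf("scheme %d", i))
  }
})

test_that("derive(scheme) and derive(flatten(scheme)) give the same system", {
  for (s in list(make_atp_toy(), make_butanol(), make_three_layer_toy())) {
    d1 <- derive(s)
    d2 <- derive(flatten_scheme(s))
    expect_identical(d1$state_ids, d2$state_ids)
    expect_equal(d1$stoichiometry, d2$stoichiometry)
    expect_identical(unname(d1$rate_expressions), unname(d2$rate_expressions))
    x <- seq(0.1, 1, length.out = length(d1$state_ids))
    expect_equal(d1$rhs(0, x), d2$rhs(0, x), tolerance = 1e-15)
  }
})

test_that("butanol redox stoichiometry balances 4/4 across layers", {
  s <- make_butanol()
  d <- derive(s)
  layer_of <- vapply(s$reactions, `[[`, character(1), "layer")
  ec <- names(layer_of)[layer_of == "E. coli"]
  ca <- names(layer_of)[layer_of == "C. acetobutylicum"]
  S <- d$stoichiometry
  # NADH: produced 4 in E. coli, consumed 4 in C. acetobutylicum
  expect_equal(sum(pmax(S["NADH", ec], 0)), 4)
  expect_equal(sum(pmax(-S["NADH", ca], 0)), 4)
  # NAD+: mirrored
  expect_equal(sum(pmax(-S["NAD_", ec], 0)), 4)
  expect_equal(sum(pmax(S["NAD_", ca], 0)), 4)
  # the 2-vs-1 per-edge coefficients at the two narrated steps
  expect_equal(S["NADH", "e2"], 2)
  expect_equal(S["NADH", "c1"], -1)
})

test_that("pool species and rule targets are excluded from the state", {
  chain <- make_linear_chain(n = 4)
  d <- derive(chain)
  expect_false("X1" %in% d$state_ids)
  expect_identical(d$pool_ids, "X1")

  toy <- make_rule_event_toy()
  dt <- derive(toy)
  expect_false("total_A" %in% dt$state_ids)
  expect_identical(unname(dt$rule_target_ids), "total_A")
})

test_that("michaelis-menten laws derive the standard saturation rate", {
  s <- reaction_scheme(
    species = list(species_symbol("S", initial = 2), species_symbol("P"),
                   species_symbol("E", initial = 0.1)),
    reactions = list(reaction_step("v1", "S", "P",
                                   michaelis_menten(Vmax = 1, Km = 1),
                                   modifiers = list(sp_ref("E")))))
  d <- derive(s)
  expect_equal(unname(d$rate_expressions[["v1"]]), "Vmax*S/(Km+S)")
  expect_equal(unname(d$rates(0, c(S = 1, P = 0, E = 0.1))[["v1"]]), 0.5)
})
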