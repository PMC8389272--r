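# Scheme model: validation diagnostics, flattening, connectors,
# shortcut read-through.

test_that("validation reports unresolved shortcuts and duplicate ids", {
  s <- reaction_scheme(
    species = list(species_symbol("A", initial = 1)),
    shortcuts = list(shortcut_symbol("sc1", "MISSING")),
    reactions = list(reaction_step("r1", "A", list(sc_ref("sc1")))))
  expect_match(paste(validate_scheme(s), collapse = "; "),
               "unresolved shortcut target")

  s2 <- reaction_scheme(
    species = list(species_symbol("A"), species_symbol("A")),
    reactions = list(reaction_step("r1", "A", character())))
  expect_match(paste(validate_scheme(s2), collapse = "; "), "duplicate id")

  expect_length(validate_scheme(make_butanol()), 0)
})

test_that("validation catches bad expressions, rules and events", {
  s <- reaction_scheme(
    species = list(species_symbol("A", initial = 1), species_symbol("B")),
    reactions = list(reaction_step("r1", "A", "B", rate_law("k_undeclared*A"))))
  expect_match(paste(validate_scheme(s), collapse = "; "), "unknown symbol")

  # circular rules
  s3 <- reaction_scheme(
    species = list(species_symbol("A"), species_symbol("B"), species_symbol("C", initial = 1)),
    reactions = list(reaction_step("r1", "C", character(), mass_action(1))),
    rules = list(assignment_rule("ru1", "A", "B+1"),
                 assignment_rule("ru2", "B", "A+1")))
  expect_match(paste(validate_scheme(s3), collapse = "; "), "circular")

  # rule target with stoichiometry
  s4 <- reaction_scheme(
    species = list(species_symbol("A", initial = 1), species_symbol("B")),
    reactions = list(reaction_step("r1", "A", "B", mass_action(1))),
    rules = list(assignment_rule("ru1", "B", "2*A")))
  expect_match(paste(validate_scheme(s4), collapse = "; "),
               "rule target 'B' also carries stoichiometry")
})

test_that("flatten resolves shortcuts to their targets with the shortcut's coefficient", {
  toy <- make_atp_toy()
  flat <- flatten_scheme(toy)
  expect_length(flat$layers, 1)
  expect_length(flat$shortcuts, 0)
  expect_identical(names(flat$species), names(toy$species))
  r3 <- flat$reactions[["r3"]]
  atp_edge <- Filter(function(p) p$species == "ATP", r3$substrates)[[1]]
  expect_equal(atp_edge$coef, 2)

  # single-layer scheme without shortcuts flattens to itself
  chain <- make_linear_chain(n = 3)
  flat2 <- flatten_scheme(chain, layer_name = "chain")
  expect_equal(scheme_to_json(flat2), scheme_to_json(chain))
})

test_that("flatten is idempotent and preserves the edge multiset", {
  edge_multiset <- function(s) {
    rows <- list()
    for (r in s$reactions) for (role in c("substrates", "products")) {
      for (p in r[[role]]) {
        e <- if (!is.null(p$shortcut)) {
          sc <- s$shortcuts[[p$shortcut]]
          list(species = sc$target_id, coef = sc$coef)
        } else p
        rows[[length(rows) + 1L]] <-
          sprintf("%s|%s|%s|%.12g", r$id, e$species, role, e$coef)
      }
    }
    sort(unlist(rows))
  }
  for (s in list(make_butanol(), make_three_layer_toy(), make_atp_toy(),
                 make_random_scheme(6, 8, seed = 7, two_layers = TRUE))) {
    f1 <- flatten_scheme(s)
    f2 <- flatten_scheme(f1)
    expect_equal(scheme_to_json(f2), scheme_to_json(f1))
    expect_identical(edge_multiset(f1), edge_multiset(s))
  }
})

test_that("flattened butanol keeps NADH on >= 5 reactions with per-edge coefficients", {
  flat <- flatten_scheme(make_butanol())
  hits <- list()
  for (r in flat$reactions) for (role in c("substrates", "products"))
    for (p in r[[role]])
      if (p$species == "NADH") hits[[length(hits) + 1L]] <- p$coef
  expect_gte(length(hits), 5)
  expect_setequal(unique(unlist(hits)), c(2, 1))
})

test_that("connectors match the paper's layer couplings and the brute-force oracle", {
  cons <- connectors(make_three_layer_toy())
  expect_equal(cons[["layer1 | layer2"]], "B")
  expect_equal(cons[["layer1 | layer3"]], "S")
  expect_equal(cons[["layer2 | layer3"]], c("K", "M", "N"))

  consb <- connectors(make_butanol())
  expect_equal(consb[["E. coli | C. acetobutylicum"]],
               sort(c("acetoacetyl-CoA", "NAD+", "NADH")))

  # single layer: no pairs
  expect_length(connectors(make_linear_chain(n = 4)), 0)

  # random layered schemes agree with the enumeration oracle
  for (seed in 1:5) {
    s <- make_random_scheme(7, 9, seed = seed, two_layers = TRUE)
    expect_equal(connectors(s), oracle_connectors(s), label = paste("seed", seed))
  }
})

test_that("shortcut properties read through to the target species", {
  toy <- make_atp_toy()
  v <- rxnsim:::shortcut_view(toy, "sc_ATP_r3")
  expect_equal(v$display_name, "ATP")
  expect_equal(v$initial, 2)
  expect_equal(v$coef, 2)
  # editing the target is immediately visible through the shortcut
  toy$species[["ATP"]]$initial <- 9
  toy$species[["ATP"]]$display_name <- "ATP*"
  v2 <- rxnsim:::shortcut_view(toy, "sc_ATP_r3")
  expect_equal(v2$initial, 9)
  expect_equal(v2$display_name, "ATP*")
  expect_equal(v2$coef, 2)  # the coefficient stays the shortcut's own
})
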