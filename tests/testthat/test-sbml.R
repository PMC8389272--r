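# SBML Level 3 interchange: import mapping, unsupported-feature detection,
# export consistency, semantic round trips, partitioning.

test_that("a minimal SBML model imports to the expected scheme", {
  imp <- import_sbml(xml2::read_xml(minimal_sbml()))
  s <- imp$scheme
  expect_length(s$species, 2)
  expect_length(s$reactions, 1)
  expect_equal(s$reactions[["r1"]]$law$expression, "k1*A")
  expect_equal(s$layers, "mini")
  expect_equal(unname(s$parameters[["k1"]]), 0.4)
  expect_equal(imp$report$mapped$reactions, 1)
  # simulates like A -> B first-order decay
  tc <- simulate_scheme(s, sim_settings(tf = 5))
  expect_equal(unname(tc$values[nrow(tc$values), "A"]), 2 * exp(-0.4 * 5),
               tolerance = 1e-5)
})

test_that("unsupported SBML constructs abort with the feature name", {
  delay_math <- paste0('<apply><csymbol encoding="text" definitionURL=',
                       '"http://www.sbml.org/sbml/symbols/delay">delay</csymbol>',
                       '<ci>A</ci><cn>1</cn></apply>')
  expect_error(import_sbml(xml2::read_xml(minimal_sbml(delay_math))),
               "csymbol delay", class = "rxnsim_sbml_unsupported")

  expect_error(import_sbml(xml2::read_xml(minimal_sbml(reaction_attrs = 'fast="true"'))),
               "fast reaction", class = "rxnsim_sbml_unsupported")

  pw <- paste0('<piecewise><piece><cn>1</cn><apply><gt/><ci>A</ci><cn>1</cn></apply></piece>',
               '<piece><cn>2</cn><apply><gt/><ci>A</ci><cn>2</cn></apply></piece>',
               '<otherwise><cn>0</cn></otherwise></piecewise>')
  expect_error(import_sbml(xml2::read_xml(minimal_sbml(pw))),
               "multiple piecewise", class = "rxnsim_sbml_unsupported")

  rate_rule <- '<listOfRules><rateRule variable="A"><math xmlns="http://www.w3.org/1998/Math/MathML"><cn>1</cn></math></rateRule></listOfRules>'
  expect_error(import_sbml(xml2::read_xml(minimal_sbml(extra_model = rate_rule))),
               "rateRule", class = "rxnsim_sbml_unsupported")
})

test_that("boundary species import as pools and local parameters are namespaced", {
  doc <- minimal_sbml()
  doc <- sub('boundaryCondition="false" constant="false"/>\n      <species id="B"',
             'boundaryCondition="true" constant="true"/>\n      <species id="B"',
             doc)
  doc <- sub('<kineticLaw>',
             '<kineticLaw>\n<listOfLocalParameters><localParameter id="kloc" value="2"/></listOfLocalParameters>',
             doc)
  doc <- sub('<ci>k1</ci>', '<ci>kloc</ci>', doc)
  imp <- import_sbml(xml2::read_xml(doc))
  expect_equal(imp$scheme$species[["A"]]$type, "pool")
  expect_equal(unname(imp$scheme$parameters[["r1__kloc"]]), 2)
  expect_equal(imp$scheme$reactions[["r1"]]$law$expression, "r1__kloc*A")
})

test_that("export flattens shortcuts into stoichiometric speciesReferences", {
  doc <- export_sbml(make_atp_toy())
  x <- xml2::read_xml(as.character(doc))
  xml2::xml_ns_strip(x)
  ref <- xml2::xml_find_first(
    x, "//reaction[@id='r3']/listOfReactants/speciesReference[@species='ATP']")
  expect_equal(as.numeric(xml2::xml_attr(ref, "stoichiometry")), 2)
  ref1 <- xml2::xml_find_first(
    x, "//reaction[@id='r1']/listOfReactants/speciesReference[@species='ATP']")
  expect_equal(as.numeric(xml2::xml_attr(ref1, "stoichiometry")), 1)
  # display names survive in @name
  sp <- xml2::xml_find_first(x, "//species[@id='ATP']")
  expect_equal(xml2::xml_attr(sp, "name"), "ATP")
})

test_that("every export passes the structural consistency check", {
  for (s in list(make_atp_toy(), make_butanol(), make_three_layer_toy(),
                 make_rule_event_toy(), make_linear_chain(n = 4))) {
    expect_length(check_sbml(export_sbml(s)), 0)
  }
  # an empty single-species scheme still exports valid SBML
  s1 <- reaction_scheme(species = list(species_symbol("A", initial = 1)))
  doc <- export_sbml(s1)
  expect_length(check_sbml(doc), 0)
  imp <- import_sbml(doc)
  expect_length(imp$scheme$species, 1)
  expect_length(imp$scheme$reactions, 0)
})

test_that("export -> import preserves simulated trajectories for all fixtures", {
  fixtures <- list(atp = make_atp_toy(), butanol = make_butanol(),
                   three_layer = make_three_layer_toy(),
                   rule_event = make_rule_event_toy(),
                   chain = make_linear_chain(n = 4),
                   random = make_random_scheme(5, 6, seed = 9, two_layers = TRUE))
  for (nm in names(fixtures)) {
    s <- fixtures[[nm]]
    st <- sim_settings(tf = 8, n_out = 41)
    before <- simulate_scheme(s, st)
    back <- import_sbml(export_sbml(s))$scheme
    after <- simulate_scheme(back, st)
    expect_equal(after$values[, colnames(before$values)], before$values,
                 tolerance = 1e-6, label = nm)
    # counts survive the round trip
    expect_length(back$species, length(s$species))
    expect_length(back$reactions, length(s$reactions))
    expect_length(back$rules, length(s$rules))
    expect_length(back$events, length(s$events))
  }
})

test_that("partitioning re-layers a flat model without changing its mathematics", {
  flat <- import_sbml(export_sbml(make_rule_event_toy()))$scheme
  expect_length(flat$layers, 1)
  # rules to a "Total" layer, everything else stays
  asg <- c(rule_total_A = "Total")
  names(asg) <- names(flat$rules)[1]
  part <- partition_scheme(flat, asg)
  expect_length(part$layers, 2)
  cons <- connectors(part)
  expect_true(all(c("A1", "A2", "A3", "A4") %in%
                    cons[[grep("Total", names(cons))]]))
  st <- sim_settings(tf = 10, n_out = 31)
  t1 <- simulate_scheme(flat, st)
  t2 <- simulate_scheme(part, st)
  expect_equal(t2$values[, colnames(t1$values)], t1$values, tolerance = 1e-9)

  # identity assignment changes nothing
  ident <- partition_scheme(flat, stats::setNames(character(0), character(0)))
  expect_equal(scheme_to_json(ident), scheme_to_json(flat))

  # unknown ids are rejected
  expect_error(partition_scheme(flat, c(nonexistent = "L")),
               "unknown id", class = "rxnsim_model_error")
})

test_that("partition then flatten returns to the original flat scheme", {
  flat <- flatten_scheme(make_atp_toy())
  asg <- stats::setNames(rep(c("one", "two"), length.out = length(flat$species)),
                         names(flat$species))
  part <- partition_scheme(flat, asg)
  expect_gt(length(part$shortcuts), 0)
  back <- flatten_scheme(part)
  d1 <- derive(flat); d2 <- derive(back)
  expect_equal(d2$stoichiometry[rownames(d1$stoichiometry), ],
               d1$stoichiometry)
  x <- seq(0.2, 1.2, length.out = length(d1$state_ids))
  expect_equal(d2$rhs(0, x), d1$rhs(0, x), tolerance = 1e-14)
})
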