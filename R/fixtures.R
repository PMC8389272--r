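# Programmatic model generators: the linear reaction chain benchmark, the
# ATP/ADP per-edge stoichiometry toy, the two-organism butanol pathway,
# a three-layer toy, a rule+event toy, and seeded random schemes. Every
# fixture validates cleanly and round-trips through the native JSON format.

#' Linear chain of first-order reactions
#'
#' `X1 -> X2 -> ... -> Xn` (optionally with a terminal outflow `Xn ->`),
#' all mass action. `X1` is a constant pool, so the chain is constantly
#' fed; downstream species start at 0. With the defaults (`k = 0.1`,
#' `x1_constant = 100`) the two-species chain with outflow has the closed
#' form `X2(t) = 100*(1 - exp(-0.1*t))`.
#'
#' @param n number of species (>= 2).
#' @param k rate constant(s): scalar or vector of length `n` (with
#'   outflow) / `n - 1` (without).
#' @param x1_constant pool concentration of `X1`.
#' @param terminal_outflow add the sink reaction `Xn ->` (default TRUE, so
#'   there are `n` rate constants `k1..kn` for `n` species).
#' @return a `reaction_scheme`.
#' @export
make_linear_chain <- function(n = 10, k = 0.1, x1_constant = 100,
                              terminal_outflow = TRUE) {
  if (n < 2) rxn_abort("chain needs n >= 2 species", "rxnsim_model_error")
  n_rxn <- if (terminal_outflow) n else n - 1L
  k <- rep_len(k, n_rxn)
  species <- c(
    list(species_symbol("X1", initial = x1_constant, type = "pool", layer = "chain")),
    lapply(2:n, function(i)
      species_symbol(paste0("X", i), initial = 0, layer = "chain")))
  reactions <- lapply(seq_len(n_rxn), function(j) {
    prods <- if (j < n) paste0("X", j + 1L) else character()
    reaction_step(paste0("r", j), substrates = paste0("X", j), products = prods,
                  law = mass_action(k[[j]], paste0("k", j)), layer = "chain")
  })
  reaction_scheme(species = species, reactions = reactions,
                  layers = "chain", name = sprintf("linear_chain_n%d", n))
}

#' ATP/ADP per-edge stoichiometry toy
#'
#' A three-step pathway `S1 -> S2 -> S3 -> S4` in which ATP is consumed and
#' ADP produced with coefficient 1 at the first step (direct reactant
#' symbols) and with coefficient 2 at the third step (shortcut symbols
#' carrying their own coefficient). Under mass action the third step's
#' rate is therefore `k3*S3*ATP^2`: the same ATP state variable enters two
#' reactions with different stoichiometric coefficients and kinetic orders.
#'
#' @return a `reaction_scheme`.
#' @export
make_atp_toy <- function() {
  L <- "pathway"
  species <- list(
    species_symbol("S1", initial = 10, layer = L),
    species_symbol("S2", layer = L),
    species_symbol("S3", layer = L),
    species_symbol("S4", layer = L),
    species_symbol("ATP", initial = 2, layer = L),
    species_symbol("ADP", initial = 0.5, layer = L))
  shortcuts <- list(
    shortcut_symbol("sc_ATP_r3", "ATP", coef = 2, layer = L),
    shortcut_symbol("sc_ADP_r3", "ADP", coef = 2, layer = L))
  reactions <- list(
    reaction_step("r1",
                  substrates = list(sp_ref("S1"), sp_ref("ATP", 1)),
                  products = list(sp_ref("S2"), sp_ref("ADP", 1)),
                  law = mass_action(0.1, "k1"), layer = L),
    reaction_step("r2", substrates = "S2", products = "S3",
                  law = mass_action(0.1, "k2"), layer = L),
    reaction_step("r3",
                  substrates = list(sp_ref("S3"), sc_ref("sc_ATP_r3")),
                  products = list(sp_ref("S4"), sc_ref("sc_ADP_r3")),
                  law = mass_action(0.1, "k3"), layer = L))
  reaction_scheme(species = species, shortcuts = shortcuts,
                  reactions = reactions, layers = L, name = "atp_adp_toy")
}

#' Two-organism butanol production pathway
#'
#' Synthetic butanol production couples two metabolisms: glycolysis-side
#' reactions of *Escherichia coli* feeding acetoacetyl-CoA, and the
#' butanol-forming reductive chain of *Clostridium acetobutylicum*. The
#' two layers are connected through the shared reactants acetoacetyl-CoA,
#' NAD+ and NADH (shortcut symbols in the *C. acetobutylicum* layer).
#' The redox balance is conserved across layers: 4 NADH produced in the
#' *E. coli* layer (2 at the glyceraldehyde-3-phosphate oxidation step, 2
#' at pyruvate decarboxylation), 4 NADH consumed in the *C.
#' acetobutylicum* layer (1 each at the acetoacetyl-CoA, crotonyl-CoA,
#' butyryl-CoA and butyraldehyde reduction steps), and the mirror image
#' for NAD+. Kinetics are placeholder unit-rate mass action; the fixture's
#' asserted content is its topology and stoichiometry.
#'
#' @return a two-layer `reaction_scheme`.
#' @export
make_butanol <- function() {
  EC <- "E. coli"; CA <- "C. acetobutylicum"
  sp <- function(name, initial = 0, layer = EC)
    species_symbol(sanitize_id(name), name, initial = initial, layer = layer)
  species <- list(
    sp("glucose", 10),
    sp("glyceraldehyde-3-phosphate"),
    sp("1,3-diphosphoglycerate"),
    sp("pyruvate"),
    sp("acetyl-CoA"),
    sp("acetoacetyl-CoA"),
    sp("NAD+", 1),
    sp("NADH", 0.1),
    sp("3-hydroxybutyryl-CoA", 0, CA),
    sp("crotonyl-CoA", 0, CA),
    sp("butyryl-CoA", 0, CA),
    sp("butyraldehyde", 0, CA),
    sp("butanol", 0, CA))
  # shortcuts: within-layer reuse of NAD+/NADH at the pyruvate step, and the
  # cross-layer connectors used by the C. acetobutylicum reduction steps
  shortcuts <- c(
    list(shortcut_symbol("sc_NAD_e4", "NAD_", coef = 2, layer = EC),
         shortcut_symbol("sc_NADH_e4", "NADH", coef = 2, layer = EC),
         shortcut_symbol("sc_aacoa_c1", "acetoacetyl_CoA", coef = 1, layer = CA)),
    unlist(lapply(1:4, function(i) list(
      shortcut_symbol(paste0("sc_NADH_c", i), "NADH", coef = 1, layer = CA),
      shortcut_symbol(paste0("sc_NAD_c", i), "NAD_", coef = 1, layer = CA))),
      recursive = FALSE))
  ma <- function(id) mass_action(1, paste0("k_", id))
  reactions <- list(
    reaction_step("e1", substrates = "glucose",
                  products = c(glyceraldehyde_3_phosphate = 2),
                  law = ma("e1"), layer = EC),
    # 2 glyceraldehyde-3-phosphate + 2 NAD+ -> 2 1,3-diphosphoglycerate + 2 NADH
    reaction_step("e2",
                  substrates = c(glyceraldehyde_3_phosphate = 2, NAD_ = 2),
                  products = c(x1_3_diphosphoglycerate = 2, NADH = 2),
                  law = ma("e2"), layer = EC),
    reaction_step("e3", substrates = c(x1_3_diphosphoglycerate = 2),
                  products = c(pyruvate = 2), law = ma("e3"), layer = EC),
    reaction_step("e4",
                  substrates = list(sp_ref("pyruvate", 2), sc_ref("sc_NAD_e4")),
                  products = list(sp_ref("acetyl_CoA", 2), sc_ref("sc_NADH_e4")),
                  law = ma("e4"), layer = EC),
    reaction_step("e5", substrates = c(acetyl_CoA = 2),
                  products = "acetoacetyl_CoA", law = ma("e5"), layer = EC),
    # acetoacetyl-CoA + NADH -> 3-hydroxybutyryl-CoA + NAD+
    reaction_step("c1",
                  substrates = list(sc_ref("sc_aacoa_c1"), sc_ref("sc_NADH_c1")),
                  products = list(sp_ref("x3_hydroxybutyryl_CoA"), sc_ref("sc_NAD_c1")),
                  law = ma("c1"), layer = CA),
    reaction_step("c2", substrates = "x3_hydroxybutyryl_CoA",
                  products = "crotonyl_CoA", law = ma("c2"), layer = CA),
    reaction_step("c3",
                  substrates = list(sp_ref("crotonyl_CoA"), sc_ref("sc_NADH_c2")),
                  products = list(sp_ref("butyryl_CoA"), sc_ref("sc_NAD_c2")),
                  law = ma("c3"), layer = CA),
    reaction_step("c4",
                  substrates = list(sp_ref("butyryl_CoA"), sc_ref("sc_NADH_c3")),
                  products = list(sp_ref("butyraldehyde"), sc_ref("sc_NAD_c3")),
                  law = ma("c4"), layer = CA),
    reaction_step("c5",
                  substrates = list(sp_ref("butyraldehyde"), sc_ref("sc_NADH_c4")),
                  products = list(sp_ref("butanol"), sc_ref("sc_NAD_c4")),
                  law = ma("c5"), layer = CA))
  reaction_scheme(species = species, shortcuts = shortcuts,
                  reactions = reactions, layers = c(EC, CA),
                  name = "butanol_two_organism")
}

#' Three-layer toy pathway
#'
#' A small metabolic pathway split into three non-hierarchical layers so
#' that layer 1 and layer 2 share reactant B, layer 1 and layer 3 share
#' reactant S, and layer 2 and layer 3 share reactants K, M and N — the
#' canonical connector pattern of a textbook-style layered pathway.
#'
#' @return a three-layer `reaction_scheme`.
#' @export
make_three_layer_toy <- function() {
  L1 <- "layer1"; L2 <- "layer2"; L3 <- "layer3"
  species <- list(
    species_symbol("A", initial = 10, layer = L1),
    species_symbol("B", layer = L1),
    species_symbol("S", layer = L1),
    species_symbol("C", layer = L2),
    species_symbol("D", layer = L2),
    species_symbol("K", initial = 1, layer = L2),
    species_symbol("M", layer = L2),
    species_symbol("N", layer = L2),
    species_symbol("P", initial = 1, layer = L3),
    species_symbol("Q", layer = L3))
  shortcuts <- list(
    shortcut_symbol("sc_B_l2", "B", layer = L2),
    shortcut_symbol("sc_S_l3", "S", layer = L3),
    shortcut_symbol("sc_K_l3", "K", layer = L3),
    shortcut_symbol("sc_M_l3", "M", layer = L3),
    shortcut_symbol("sc_N_l3", "N", layer = L3))
  k1 <- function(id) mass_action(1, paste0("k_", id))
  reactions <- list(
    reaction_step("l1r1", "A", "B", k1("l1r1"), layer = L1),
    reaction_step("l1r2", "S", "A", k1("l1r2"), layer = L1),
    reaction_step("l2r1", list(sc_ref("sc_B_l2")), "C", k1("l2r1"), layer = L2),
    reaction_step("l2r2", c("C", "K"), c("D", "M"), k1("l2r2"), layer = L2),
    reaction_step("l2r3", "D", "N", k1("l2r3"), layer = L2),
    reaction_step("l3r1", list(sc_ref("sc_N_l3")), "P", k1("l3r1"), layer = L3),
    reaction_step("l3r2", list(sp_ref("P"), sc_ref("sc_M_l3")),
                  list(sp_ref("Q"), sc_ref("sc_K_l3")), k1("l3r2"), layer = L3),
    reaction_step("l3r3", "Q", list(sc_ref("sc_S_l3")), k1("l3r3"), layer = L3))
  reaction_scheme(species = species, shortcuts = shortcuts,
                  reactions = reactions, layers = c(L1, L2, L3),
                  name = "three_layer_toy")
}

#' Rule-and-event toy
#'
#' Four independently decaying species `A1..A4`, an assignment rule
#' computing their running total (the "total concentration" read-out
#' pattern of cell-cycle models), and one event that resets the first
#' decay constant to zero at `t = 5`. The trajectory has the piecewise
#' closed form `A1(t) = A1(0)*exp(-k1*min(t, 5))`, `Ai(t) =
#' Ai(0)*exp(-ki*t)` for the others, and the rule output equals
#' `A1+A2+A3+A4` at every reported time.
#'
#' @return a `reaction_scheme` with one rule and one event.
#' @export
make_rule_event_toy <- function() {
  L <- "toy"
  species <- c(
    lapply(1:4, function(i)
      species_symbol(paste0("A", i), initial = c(8, 4, 2, 1)[[i]], layer = L)),
    list(species_symbol("total_A", layer = L)))
  reactions <- lapply(1:4, function(i)
    reaction_step(paste0("d", i), substrates = paste0("A", i), products = character(),
                  law = rate_law(sprintf("k%d*A%d", i, i)), layer = L))
  rules <- list(assignment_rule("total_rule", "total_A", "A1+A2+A3+A4", layer = L))
  events <- list(event_spec("stop_d1", "t>=5", c(k1 = "0"), layer = L))
  reaction_scheme(species = species, reactions = reactions,
                  rules = rules, events = events,
                  parameters = c(k1 = 0.3, k2 = 0.2, k3 = 0.15, k4 = 0.1),
                  layers = L, name = "rule_event_toy")
}

#' Random mass-action scheme
#'
#' Seeded generator of structurally valid random schemes for oracle-based
#' testing: mass-action reactions with integer stoichiometric coefficients,
#' optional constant pools, and an optional two-layer split in which the
#' second layer reaches first-layer species through shortcuts.
#'
#' @param n_species,n_reactions scheme size.
#' @param seed integer seed; the same seed reproduces the same scheme.
#' @param max_coef maximum stoichiometric coefficient (sampled 1..max_coef).
#' @param max_substrates maximum substrates per reaction (1..max_substrates
#'   sampled; substrate count drives the kinetic order).
#' @param pool_fraction fraction of species marked as constant pools.
#' @param two_layers split species into two layers and wire cross-layer
#'   participations through shortcut symbols.
#' @param k_range range for log-uniform rate constants.
#' @return a `reaction_scheme`.
#' @export
make_random_scheme <- function(n_species = 6, n_reactions = 8, seed = 1,
                               max_coef = 3, max_substrates = 2,
                               pool_fraction = 0.2, two_layers = FALSE,
                               k_range = c(0.05, 1)) {
  stopifnot(n_species >= 2, n_reactions >= 1)
  rs <- local_rng(seed, {
    sp_names <- paste0("S", seq_len(n_species))
    layers <- if (two_layers) c("upper", "lower") else "main"
    sp_layer <- if (two_layers)
      sample(layers, n_species, replace = TRUE) else rep("main", n_species)
    if (two_layers) { sp_layer[1] <- "upper"; sp_layer[2] <- "lower" }
    n_pool <- min(n_species - 1L, stats::rbinom(1, n_species, pool_fraction))
    pool_idx <- if (n_pool > 0) sample(n_species, n_pool) else integer()
    species <- lapply(seq_len(n_species), function(i)
      species_symbol(sp_names[[i]],
                     initial = round(stats::runif(1, 0.5, 5), 3),
                     type = if (i %in% pool_idx) "pool" else "variable",
                     layer = sp_layer[[i]]))
    shortcuts <- list()
    reactions <- vector("list", n_reactions)
    for (j in seq_len(n_reactions)) {
      r_layer <- if (two_layers) sample(layers, 1) else "main"
      ns <- sample(max_substrates, 1)
      np <- sample(max_substrates, 1)
      subs_i <- sample(n_species, ns)
      prod_pool <- setdiff(seq_len(n_species), subs_i)
      prods_i <- sample(prod_pool, min(np, length(prod_pool)))
      mk_ref <- function(i) {
        coef <- sample(max_coef, 1)
        if (two_layers && sp_layer[[i]] != r_layer) {
          sc_id <- paste0("sc_", sp_names[[i]], "_r", j, "_", length(shortcuts))
          shortcuts[[length(shortcuts) + 1L]] <<-
            shortcut_symbol(sc_id, sp_names[[i]], coef = coef, layer = r_layer)
          sc_ref(sc_id)
        } else sp_ref(sp_names[[i]], coef)
      }
      reactions[[j]] <- reaction_step(
        paste0("r", j),
        substrates = lapply(subs_i, mk_ref),
        products = lapply(prods_i, mk_ref),
        law = mass_action(exp(stats::runif(1, log(k_range[[1]]), log(k_range[[2]]))),
                          paste0("k", j)),
        layer = r_layer)
    }
    reaction_scheme(species = species, shortcuts = shortcuts,
                    reactions = reactions, layers = layers,
                    name = sprintf("random_scheme_seed%d", seed))
  })
  rs
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
local_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
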