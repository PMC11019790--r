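test_that("JSON model IO round-trips and validates", {
  m <- chain_model()
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  writeModel(m, f1)
  m2 <- readModel(f1)
  expect_s4_class(m2, "StoichiometricModel")
  expect_equal(stoichMatrix(m2), stoichMatrix(m))
  expect_equal(reactionBounds(m2), reactionBounds(m))
  expect_length(biomassReaction(m2), 1)
  expect_equal(exchangeReactions(m2), "EX_glc")
  # canonical writer: write(read(write(m))) is byte-identical
  writeModel(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("bounds absent from a JSON file default by reversibility", {
  f <- tempfile(fileext = ".json")
  writeLines('{
    "species_id": "min",
    "metabolites": [{"id": "a_e", "compartment": "extracellular"},
                    {"id": "b", "compartment": "intracellular"}],
    "reactions": [
      {"id": "EX_a", "stoich": {"a_e": -1}, "is_exchange": true},
      {"id": "CONV", "stoich": {"a_e": -1, "b": 1}, "reversible": false},
      {"id": "BIOMASS", "stoich": {"b": -1}, "is_biomass": true,
       "reversible": false}
    ]
  }', f)
  m <- readModel(f)
  b <- reactionBounds(m)
  expect_equal(b$lb, c(-1000, 0, 0))
  expect_equal(b$ub, c(1000, 1000, 1000))
})

test_that("undeclared metabolites and broken invariants are rejected", {
  expect_error(
    stoichiometricModel(
      "bad",
      metabolites = data.frame(id = "a_e", compartment = "extracellular"),
      reactions = data.frame(id = "R1", lb = 0, ub = 1, isExchange = FALSE,
                             isBiomass = TRUE),
      stoichiometry = list(R1 = c(ghost = -1))),
    "undeclared metabolite")
  # exchange must touch exactly one extracellular metabolite with coef -1
  expect_error(
    stoichiometricModel(
      "bad2",
      metabolites = data.frame(id = c("a_e", "b"),
                               compartment = c("extracellular",
                                               "intracellular")),
      reactions = data.frame(id = c("EX_a", "BIOMASS"),
                             lb = c(-10, 0), ub = c(10, 10),
                             isExchange = c(TRUE, FALSE),
                             isBiomass = c(FALSE, TRUE)),
      stoichiometry = list(EX_a = c(a_e = -2), BIOMASS = c(b = -1))),
    "coefficient -1")
  # lb > ub
  expect_error(
    stoichiometricModel(
      "bad3",
      metabolites = data.frame(id = "b", compartment = "intracellular"),
      reactions = data.frame(id = "BIOMASS", lb = 5, ub = 1,
                             isExchange = FALSE, isBiomass = TRUE),
      stoichiometry = list(BIOMASS = c(b = -1))),
    "bound")
  expect_error(readModel(tempfile()), "not found")
})

test_that("SBML (core + fbc) reading matches the JSON equivalent", {
  sbml <- system.file("extdata", "chain_model.xml", package = "syncomfba")
  m <- readModel(sbml, format = "sbml")
  expect_equal(speciesId(m), "chain")
  expect_equal(sort(metaboliteIds(m)), c("c", "glc_e"))
  expect_equal(exchangeReactions(m), "EX_glc")
  expect_equal(biomassReaction(m), "BIOMASS")
  b <- reactionBounds(m)
  expect_equal(b$lb[b$id == "EX_glc"], -10)
  expect_equal(growthRate(fba(m)), 1, tolerance = 1e-9)
})

test_that("FBA solves the forced single pathway and starvation", {
  m <- chain_model(yield = 0.1, uptake_lb = -10)
  s <- fba(m)
  expect_equal(solverStatus(s), "optimal")
  expect_equal(growthRate(s), 1.0, tolerance = 1e-9)  # 10 mmol/gDW/h * 0.1
  expect_equal(unname(fluxes(s)["EX_glc"]), -10, tolerance = 1e-9)
  s0 <- fba(m, exchangeBounds = list(EX_glc = c(0, 1000)))
  expect_equal(growthRate(s0), 0, tolerance = 1e-12)
  expect_error(fba(m, exchangeBounds = list(BIOMASS = c(0, 1))),
               "exchange reactions")
})

test_that("FBA equals the vertex-enumeration oracle on random networks", {
  for (seed in 1:40) {
    m <- random_small_model(seed)
    got <- growthRate(fba(m))
    want <- fba_oracle(m)
    expect_equal(got, want, tolerance = 1e-6,
                 label = paste("fba growth, seed", seed),
                 expected.label = "vertex-enumeration optimum")
  }
})

test_that("optimal solutions are mass-balanced and bounded", {
  for (seed in 1:20) {
    m <- random_small_model(seed)
    s <- pfba(m)
    v <- fluxes(s)
    expect_lt(max(abs(stoichMatrix(m) %*% v)), 1e-6)
    b <- reactionBounds(m)
    expect_true(all(v >= b$lb - 1e-7 & v <= b$ub + 1e-7))
  }
})

test_that("relaxing an uptake bound never decreases FBA growth", {
  for (seed in 1:15) {
    m <- random_small_model(seed)
    ex <- exchangeReactions(m)[1]
    b <- reactionBounds(m)
    lb0 <- b$lb[b$id == ex]
    g_tight <- growthRate(fba(m, exchangeBounds =
                                setNames(list(c(lb0 / 2, 1000)), ex)))
    g_loose <- growthRate(fba(m, exchangeBounds =
                                setNames(list(c(lb0 * 2, 1000)), ex)))
    expect_gte(g_loose, g_tight - 1e-9)
  }
})

test_that("pFBA keeps the FBA growth rate and shrinks the L1 norm", {
  for (seed in 1:50) {
    m <- random_small_model(seed + 100)
    sf <- fba(m)
    sp <- pfba(m)
    expect_equal(growthRate(sp), growthRate(sf), tolerance = 1e-8)
    expect_lte(sum(abs(fluxes(sp))), sum(abs(fluxes(sf))) + 1e-7)
  }
})

test_that("pFBA routes flux through the shorter of two equal-yield paths", {
  m <- parallel_model()
  s <- pfba(m)
  v <- fluxes(s)
  expect_equal(growthRate(s), 1, tolerance = 1e-9)
  expect_equal(unname(v["SHORT"]), 10, tolerance = 1e-7)
  expect_equal(unname(v["LONG1"]), 0, tolerance = 1e-7)
  expect_equal(unname(v["LONG2"]), 0, tolerance = 1e-7)
})

test_that("pFBA equals FBA on a single-pathway model", {
  m <- chain_model()
  expect_equal(fluxes(pfba(m)), fluxes(fba(m)), tolerance = 1e-6)
})
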