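# Single-species helpers built on the public constructors
one_species_setup <- function(yield = 0.1, rate = 1, pool = 0.02,
                              X0 = 1e-5) {
  model <- chain_model(yield = yield)
  cfg <- list(solo = speciesConfig(model, limitingUptakeRate = rate,
                                   defaultVmax = 10, initialBiomass = X0))
  fresh <- mediumState(c(glc_e = pool), limitingIds = "glc_e",
                       volumeML = 10)
  list(cfg = cfg, fresh = fresh)
}

test_that("a depleting batch converts the substrate pool at the yield", {
  y <- 0.1
  su <- one_species_setup(yield = y, rate = 1, pool = 0.02, X0 = 1e-4)
  tr <- transferSpec(cycleHours = 48, nPassages = 1, timestep = 0.1)
  state <- communityState(c(solo = 1e-4), su$fresh)
  traj <- runPassage(state, su$cfg, tr)
  X_end <- unname(biomass(finalState(traj)))
  expect_lt(unname(pools(finalState(traj))["glc_e"]), 1e-8)
  expect_equal(X_end, 1e-4 + y * 0.02, tolerance = 0.01)
})

test_that("substrate books balance: consumed plus remaining equals initial", {
  su <- one_species_setup(rate = 2)
  tr <- transferSpec(cycleHours = 24, nPassages = 1, timestep = 0.1)
  traj <- runPassage(communityState(c(solo = 1e-5), su$fresh), su$cfg, tr)
  rec <- exchangeRecord(traj)
  consumed <- sum(-rec$flux_mmol_per_gDW_h * rec$biomass_gDW_h)
  remaining <- unname(pools(finalState(traj))["glc_e"])
  expect_equal(consumed + remaining, 0.02, tolerance = 1e-6 * 0.02)
})

test_that("zero biomass leaves pools untouched; starvation halts growth", {
  su <- one_species_setup()
  tr <- transferSpec(cycleHours = 1, nPassages = 1, timestep = 0.1)
  traj <- runPassage(communityState(c(solo = 0), su$fresh), su$cfg, tr)
  expect_equal(unname(pools(finalState(traj))["glc_e"]), 0.02)
  expect_true(all(biomass(finalState(traj)) == 0))
  # no carbon at all: growth is zero, biomass constant
  empty <- mediumState(c(glc_e = 0), limitingIds = "glc_e", volumeML = 10)
  traj2 <- runPassage(communityState(c(solo = 1e-5), empty), su$cfg, tr)
  expect_equal(unname(biomass(finalState(traj2))), 1e-5)
  expect_true(all(traj2@growth == 0))
})

test_that("dfbaStep returns per-species flux solutions", {
  su <- one_species_setup(yield = 0.1, rate = 1)
  st <- communityState(c(solo = 1e-5), su$fresh)
  out <- dfbaStep(st, su$cfg, 0.1)
  expect_s4_class(out$state, "CommunityState")
  expect_equal(out$state@time, 0.1)
  sol <- out$solutions$solo
  expect_equal(growthRate(sol), 0.1, tolerance = 1e-9)  # 1 mmol/gDW/h * 0.1
  expect_equal(unname(fluxes(sol)["EX_glc"]), -1, tolerance = 1e-9)
  expect_equal(unname(biomass(out$state)), 1e-5 * exp(0.1 * 0.1),
               tolerance = 1e-12)
})

test_that("dilution scales biomass exactly and preserves composition", {
  toy <- makeToyCommunity(toyCommunitySpec(seed = 2))
  tr <- transferSpec()
  st <- communityState(setNames(c(1e-3, 2e-4, 5e-5), names(speciesConfigs(toy))),
                       freshMedium(toy))
  st2 <- dilute(st, tr, freshMedium(toy))
  expect_equal(unname(biomass(st2)), unname(biomass(st)) * 0.1)
  expect_equal(biomass(st2) / sum(biomass(st2)),
               biomass(st) / sum(biomass(st)), tolerance = 1e-12)
  expect_equal(st2@passageIndex, st@passageIndex + 1L)
  # factor 1 is the identity
  tr1 <- transferSpec(dilutionFactor = 1)
  expect_equal(biomass(dilute(st, tr1, freshMedium(toy))), biomass(st))
})

test_that("pools never go negative and unproduced pools never increase", {
  toy <- makeToyCommunity(toyCommunitySpec(seed = 4))
  run <- runSerialTransfer(speciesConfigs(toy), small_transfer(2),
                           freshMedium(toy))
  for (traj in run) {
    expect_true(all(traj@pools >= 0))
    # no toy species produces glucose or the private amino acids
    for (m in c("glc", "ala", "pro", "met")) {
      expect_true(all(diff(traj@pools[, m]) <= 1e-12))
    }
    expect_true(all(traj@biomass >= 0))
    expect_true(all(diff(traj@times) > 0))
  }
})

test_that("identical configurations give bit-identical trajectories", {
  toy <- makeToyCommunity(toyCommunitySpec(seed = 5))
  r1 <- runSerialTransfer(speciesConfigs(toy), small_transfer(2),
                          freshMedium(toy))
  r2 <- runSerialTransfer(speciesConfigs(toy), small_transfer(2),
                          freshMedium(toy))
  expect_identical(lapply(r1, function(t) t@biomass),
                   lapply(r2, function(t) t@biomass))
  expect_identical(lapply(r1, function(t) t@exchangeFlux),
                   lapply(r2, function(t) t@exchangeFlux))
})

test_that("halving the timestep moves final biomass by less than 1%", {
  toy <- makeToyCommunity(toyCommunitySpec(seed = 1))
  cfg <- speciesConfigs(toy)
  fresh <- freshMedium(toy)
  tr1 <- transferSpec(cycleHours = 48, nPassages = 1, timestep = 0.1)
  tr2 <- transferSpec(cycleHours = 48, nPassages = 1, timestep = 0.05)
  b1 <- biomass(finalState(runSerialTransfer(cfg, tr1, fresh)[[1]]))
  b2 <- biomass(finalState(runSerialTransfer(cfg, tr2, fresh)[[1]]))
  expect_true(all(abs(b1 / b2 - 1) < 0.01))
})

test_that("composition converges regardless of which species is rare", {
  toy <- makeToyCommunity(toyCommunitySpec(seed = 1))
  cfg <- speciesConfigs(toy)
  fresh <- freshMedium(toy)
  tr <- small_transfer(5)
  sp <- names(cfg)
  ref_run <- runSerialTransfer(cfg, tr, fresh)
  ref <- communityComposition(ref_run)
  for (rare in sp) {
    x0 <- setNames(rep(3.9e-7, 3), sp)
    x0[rare] <- 3.9e-10
    run <- runSerialTransfer(cfg, tr, fresh, initialBiomass = x0)
    got <- communityComposition(run)
    expect_true(all(abs(got - ref) / ref < 0.05),
                label = paste("composition after diluting", rare))
  }
})

test_that("trajectory tables are tidy and cover the grid", {
  su <- one_species_setup()
  tr <- transferSpec(cycleHours = 2, nPassages = 1, timestep = 0.5)
  traj <- runPassage(communityState(c(solo = 1e-5), su$fresh), su$cfg, tr)
  bt <- biomassTable(traj)
  expect_named(bt, c("time_h", "passage", "species", "biomass_gDW"))
  expect_equal(nrow(bt), 5)          # 4 steps + initial point, one species
  pt <- poolTable(traj)
  expect_equal(sort(unique(pt$time_h)), seq(0, 2, 0.5))
})
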