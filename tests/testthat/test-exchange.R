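# Minimal hand-built trajectory for integration arithmetic
flat_secretion_traj <- function(flux = 1, X = 1e-3, hours = 10, dt = 1) {
  nstep <- hours / dt
  sp <- "a"
  met <- "m1"
  biomass <- matrix(X, nstep + 1, 1, dimnames = list(NULL, sp))
  poolm <- matrix(cumsum(c(0, rep(flux * X * dt, nstep))), nstep + 1, 1,
                  dimnames = list(NULL, met))
  ex <- array(flux, dim = c(nstep, 1, 1),
              dimnames = list(NULL, sp, met))
  bh <- matrix(X * dt, nstep, 1, dimnames = list(NULL, sp))
  fs <- communityState(setNames(X, sp),
                       mediumState(setNames(poolm[nstep + 1], met),
                                   volumeML = 10),
                       time = hours)
  new("Trajectory", times = seq(0, hours, dt), passage = 0L,
      biomass = biomass, pools = poolm,
      growth = matrix(0, nstep, 1, dimnames = list(NULL, sp)),
      exchangeFlux = ex, biomassHours = bh, finalState = fs)
}

test_that("constant secretion integrates as a rectangle", {
  traj <- flat_secretion_traj(flux = 1, X = 1e-3, hours = 10)
  tab <- integrateExchanges(traj)@table
  expect_equal(nrow(tab), 1)
  expect_equal(tab$secretion, 0.01, tolerance = 1e-12)  # 1 * 1e-3 * 10
  expect_equal(tab$uptake, 0)
})

test_that("integration is additive over adjacent windows", {
  traj <- flat_secretion_traj(flux = 0.7, X = 2e-3, hours = 10)
  whole <- integrateExchanges(traj, c(0, 10))@table$secretion
  part1 <- integrateExchanges(traj, c(0, 4))@table$secretion
  part2 <- integrateExchanges(traj, c(4, 10))@table$secretion
  expect_equal(part1 + part2, whole, tolerance = 1e-12)
  expect_error(integrateExchanges(traj, c(5, 5)), "increasing")
  expect_error(integrateExchanges(traj, c(0, 11)), "span")
})

test_that("all-zero fluxes give an empty table", {
  traj <- flat_secretion_traj(flux = 0)
  expect_equal(nrow(integrateExchanges(traj)@table), 0)
})

test_that("the planted toy topology is recovered exactly, medium-absent", {
  toy <- makeToyCommunity(toyCommunitySpec(seed = 3))
  run <- runSerialTransfer(speciesConfigs(toy), small_transfer(2),
                           freshMedium(toy))
  net <- inferNetwork(integrateExchanges(run), freshMedium(toy))
  e <- edges(net)
  planted <- plantedEdges(toy)
  consumed <- planted[!is.na(planted$consumer), ]
  got <- sort(paste(e$producer, e$metabolite, e$consumer))
  want <- sort(paste(consumed$producer, consumed$metabolite,
                     consumed$consumer))
  expect_identical(got, want)
  expect_true(all(e$mediumAbsent))
  # the dangling planted secretion shows up with no consumer
  dang <- plantedEdges(toy)[is.na(planted$consumer), ]
  expect_true(all(paste(dang$producer, dang$metabolite) %in%
                    paste(danglingSecretions(net)$species,
                          danglingSecretions(net)$metabolite)))
})

test_that("edge weights are bounded by secretion and uptake totals", {
  toy <- makeToyCommunity(toyCommunitySpec(seed = 8))
  run <- runSerialTransfer(speciesConfigs(toy), small_transfer(2),
                           freshMedium(toy))
  tab <- integrateExchanges(run)
  net <- inferNetwork(tab, freshMedium(toy))
  t <- tab@table
  for (i in seq_len(nrow(edges(net)))) {
    e <- edges(net)[i, ]
    sec <- t$secretion[t$species == e$producer & t$metabolite == e$metabolite]
    upt <- t$uptake[t$species == e$consumer & t$metabolite == e$metabolite]
    expect_lte(e$mmol, sec + 1e-12)
    expect_lte(e$mmol, upt + 1e-12)
    expect_gt(e$mmol, 0)
  }
})

test_that("medium-supplied metabolites are flagged, not dropped", {
  # plant an exchange over a metabolite that IS in the fresh medium: the
  # edge must exist with mediumAbsent = FALSE
  spec <- toyCommunitySpec(seed = 1)
  spec$plantedEdges <- data.frame(
    producer = "YR343", metabolite = "ala", consumer = "GM17", sigma = 0.2)
  toy <- makeToyCommunity(spec)
  run <- runSerialTransfer(speciesConfigs(toy), small_transfer(1),
                           freshMedium(toy))
  net <- inferNetwork(integrateExchanges(run), freshMedium(toy))
  e <- edges(net)
  hit <- e[e$metabolite == "ala" & e$producer == "YR343", ]
  expect_equal(nrow(hit), 1)
  expect_false(hit$mediumAbsent)
})

test_that("removing a consumer deletes exactly its incident edges", {
  toy <- makeToyCommunity(toyCommunitySpec(seed = 3))
  cfg <- speciesConfigs(toy)
  run_full <- runSerialTransfer(cfg, small_transfer(2), freshMedium(toy))
  net_full <- edges(inferNetwork(integrateExchanges(run_full),
                                 freshMedium(toy)))
  # drop AP49 from the community
  cfg2 <- cfg[c("GM17", "YR343")]
  run2 <- runSerialTransfer(cfg2, small_transfer(2), freshMedium(toy))
  net2 <- edges(inferNetwork(integrateExchanges(run2), freshMedium(toy)))
  expect_false(any(net2$consumer == "AP49" | net2$producer == "AP49"))
  kept <- net_full[net_full$consumer != "AP49" & net_full$producer != "AP49", ]
  expect_setequal(paste(net2$producer, net2$metabolite, net2$consumer),
                  paste(kept$producer, kept$metabolite, kept$consumer))
})

test_that("monoculture baseline marks non-emergent secretions", {
  toy <- makeToyCommunity(toyCommunitySpec(seed = 3))
  cfg <- speciesConfigs(toy)
  fresh <- freshMedium(toy)
  run <- runSerialTransfer(cfg, small_transfer(2), fresh)
  mono <- lapply(names(cfg), function(s) {
    integrateExchanges(runSerialTransfer(cfg[s], small_transfer(2), fresh))
  })
  names(mono) <- names(cfg)
  net <- inferNetwork(integrateExchanges(run), fresh, monoculture = mono)
  e <- edges(net)
  expect_true("secretedInMonoculture" %in% names(e))
  # growth-coupled toy secretions also occur in monoculture
  expect_true(all(e$secretedInMonoculture))
})
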