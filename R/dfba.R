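## Well-mixed batch dynamic FBA with serial growth-dilution cycles.
##
## Numerical scheme, per step of length dt:
##   * per-species uptake bounds: the limiting-carbon rate (or the default
##     Vmax for other nutrients), further capped by pool availability so a
##     finite pool cannot be overdrawn;
##   * parsimonious FBA gives the growth rate mu and the exchange fluxes;
##   * biomass advances exponentially, X <- X * exp(mu * dt);
##   * pools advance by the exact integral of flux over the exponentially
##     growing biomass: dpool = v * X * g(mu) * dt with
##     g(mu) = (exp(mu dt) - 1) / (mu dt), which reduces to the explicit
##     Euler form as mu*dt -> 0 and keeps the substrate/biomass books exact.
##
## Pool availability is shared between competing consumers in proportion to
## their instantaneous demand X_i * rate_i, so that the combined draw can
## never push a pool negative; with a single consumer this reduces to the
## plain cap min(rate, pool / (X dt)).

.POOL_TOL <- 1e-9
.CAP_SAFETY <- 1.0001

.gfun <- function(mu, dt) {
  z <- mu * dt
  ifelse(abs(z) < 1e-8, 1 + z / 2, (exp(z) - 1) / z)
}

#' Per-species simulation settings
#'
#' @param model a [StoichiometricModel-class].
#' @param limitingUptakeRate bound (mmol/gDW/h) applied simultaneously to
#'   all limiting-carbon exchange reactions of this species.
#' @param defaultVmax bound for uptake of all other nutrients (default 10).
#' @param initialBiomass inoculum dry mass, gDW (default 3.9e-7 g, a
#'   ~1e7 CFU/mL inoculum in a 10 mL culture).
#' @return a [SpeciesConfig-class].
#' @export
speciesConfig <- function(model, limitingUptakeRate = 10, defaultVmax = 10,
                          initialBiomass = 3.9e-7) {
  obj <- new("SpeciesConfig", model = model,
             limitingUptakeRate = limitingUptakeRate,
             defaultVmax = defaultVmax, initialBiomass = initialBiomass)
  validObject(obj)
  obj
}

#' Serial growth-dilution schedule
#'
#' @param cycleHours growth-cycle length, h (default 48).
#' @param nPassages number of growth-dilution cycles (default 6, P0..P5).
#' @param dilutionFactor carried-over fraction at transfer (default 0.1,
#'   i.e. 10 percent vol/vol).
#' @param timestep integration step, h (default 0.1); must divide
#'   `cycleHours`.
#' @return a [TransferSpec-class].
#' @export
transferSpec <- function(cycleHours = 48, nPassages = 6,
                         dilutionFactor = 0.1, timestep = 0.1) {
  obj <- new("TransferSpec", cycleHours = cycleHours,
             nPassages = as.integer(nPassages),
             dilutionFactor = dilutionFactor, timestep = timestep)
  validObject(obj)
  obj
}

#' Construct a community state
#'
#' @param biomass named numeric, per-species dry mass (gDW).
#' @param medium a [MediumState-class].
#' @param time clock, h.
#' @param passageIndex zero-based passage counter.
#' @return a [CommunityState-class].
#' @export
communityState <- function(biomass, medium, time = 0, passageIndex = 0L) {
  obj <- new("CommunityState", biomass = biomass, medium = medium,
             time = time, passageIndex = as.integer(passageIndex))
  validObject(obj)
  obj
}

## ---------------------------------------------------------------------------
## Internal fast-path machinery
## ---------------------------------------------------------------------------

## Assemble the plain-list simulation context shared by all steps.
.prepare_sim <- function(configs, medium) {
  if (is.null(names(configs)) || any(!nzchar(names(configs)))) {
    names(configs) <- vapply(configs, function(cf) cf@model@speciesId,
                             character(1))
  }
  sp <- names(configs)
  cms <- lapply(configs, function(cf) .compile_model(cf@model))
  unlimited <- medium@unlimitedIds
  # pool universe: fresh-medium pools plus every extracellular metabolite a
  # model can exchange that is not declared unlimited (secreted byproducts
  # start at zero)
  ex_universe <- unique(unlist(lapply(cms, function(cm) cm$exMet)))
  pool_ids <- union(names(medium@pools), setdiff(ex_universe, unlimited))
  ex_record_ids <- unique(c(intersect(ex_universe, pool_ids)))

  per_species <- lapply(sp, function(s) {
    cm <- cms[[s]]
    cf <- configs[[s]]
    met <- cm$exMet
    pooled <- met %in% pool_ids
    limiting <- met %in% medium@limitingIds
    rate <- ifelse(limiting, cf@limitingUptakeRate, cf@defaultVmax)
    uptake_capable <- cm$lb[cm$exIdx] < 0
    list(cm = cm, exIdx = cm$exIdx, exMet = met, pooled = pooled,
         poolPos = match(met, pool_ids), rate = rate,
         uptakeCapable = uptake_capable,
         recPos = match(met, ex_record_ids),
         defaultVmax = cf@defaultVmax)
  })
  names(per_species) <- sp

  # demand-rate matrix (species x pools): rate of species i for pool m when
  # i can take m up, else 0 -- used for proportional sharing of scarce pools
  R <- matrix(0, length(sp), length(pool_ids),
              dimnames = list(sp, pool_ids))
  for (s in sp) {
    ps <- per_species[[s]]
    k <- ps$pooled & ps$uptakeCapable
    R[s, ps$poolPos[k]] <- ps$rate[k]
  }
  list(species = sp, cfg = per_species, R = R, poolIds = pool_ids,
       recIds = ex_record_ids, unlimited = unlimited,
       limitingIds = medium@limitingIds, volumeML = medium@volumeML)
}

## Extend a medium to the simulation's pool universe (missing pools at 0).
.extend_medium <- function(medium, sim) {
  p <- setNames(numeric(length(sim$poolIds)), sim$poolIds)
  p[names(medium@pools)] <- medium@pools
  mediumState(p, unlimitedIds = medium@unlimitedIds,
              limitingIds = medium@limitingIds, volumeML = medium@volumeML)
}

## One dFBA step on plain vectors. Returns updated state pieces plus the
## per-species records. gEst: per-species growth-factor estimates carried
## between steps (fixed-point handling of the exponential quadrature).
.sim_step <- function(sim, X, P, dt, gEst, want_full = FALSE) {
  nsp <- length(sim$species)
  mu <- numeric(nsp)
  infeasible <- logical(nsp)
  exflux <- matrix(0, nsp, length(sim$recIds))
  full <- if (want_full) vector("list", nsp) else NULL
  gUsed <- gEst

  denom <- as.vector(X %*% sim$R)            # per-pool instantaneous demand

  for (i in seq_len(nsp)) {
    if (X[i] <= 0) next
    ps <- sim$cfg[[i]]
    cm <- ps$cm
    g <- max(1, gEst[i])
    for (iter in 1:6) {
      lb <- cm$lb
      ub <- cm$ub
      for (k in seq_along(ps$exIdx)) {
        j <- ps$exIdx[k]
        if (!ps$uptakeCapable[k]) next
        if (ps$pooled[k]) {
          m <- ps$poolPos[k]
          if (denom[m] > 0) {
            # demand-proportional share: P * w_i / (X_i dt g safety) with
            # w_i = X_i rate_i / denom; the X_i cancels
            avail <- P[m] * ps$rate[k] / (denom[m] * dt * g * .CAP_SAFETY)
          } else {
            avail <- 0
          }
          lb[j] <- max(lb[j], -min(ps$rate[k], avail))
        } else {
          lb[j] <- max(lb[j], -ps$defaultVmax)
        }
      }
      res <- .fba_core(cm, lb, ub)
      if (res$status != "optimal") {
        infeasible[i] <- TRUE
        mu[i] <- 0
        v <- NULL
        break
      }
      mu_i <- res$objval
      gnew <- .gfun(mu_i, dt)
      if (gnew <= g * 1.00005) {
        v <- .pfba_core(cm, lb, ub, mu_i)
        if (is.null(v)) v <- res$x
        mu[i] <- mu_i
        gUsed[i] <- gnew
        break
      }
      g <- gnew
    }
    if (!infeasible[i] && !is.null(v)) {
      exflux[i, ps$recPos] <- v[ps$exIdx]
      if (want_full) full[[i]] <- setNames(v, cm$rxnIds)
    }
  }

  # advance biomass and pools
  bh <- X * .gfun(mu, dt) * dt               # integrated gDW h per species
  bh[X <= 0] <- 0
  Xnew <- X * exp(mu * dt)
  dP <- setNames(numeric(length(sim$poolIds)), sim$poolIds)
  pooled_rec <- match(sim$recIds, sim$poolIds)
  for (i in seq_len(nsp)) {
    if (bh[i] > 0) {
      contrib <- exflux[i, ] * bh[i]
      dP[pooled_rec] <- dP[pooled_rec] + contrib
    }
  }
  Pnew <- P + dP
  neg <- Pnew < 0
  if (any(Pnew < -.POOL_TOL)) {
    worst <- min(Pnew)
    stop("simulation-integrity error: pool(s) ",
         paste(sim$poolIds[Pnew < -.POOL_TOL], collapse = ", "),
         " fell to ", format(worst, digits = 4), " mmol (below -1e-9)")
  }
  Pnew[neg] <- 0

  list(X = Xnew, P = Pnew, mu = mu, gEst = gUsed, exflux = exflux,
       biomassHours = bh, infeasible = infeasible, full = full)
}

## ---------------------------------------------------------------------------
## Exported operations
## ---------------------------------------------------------------------------

#' Advance a community state by one dFBA step
#'
#' For each species the limiting-carbon uptake bound is the smaller of its
#' configured rate and the pool-availability cap (shared proportionally to
#' demand when several species draw on the same pool); other nutrients are
#' bounded by the default Vmax. Parsimonious FBA then yields the growth
#' rate and exchange fluxes, biomass grows exponentially, and pools are
#' updated with the exactly integrated fluxes. An infeasible species LP is
#' treated as starvation (zero growth for the step, with a warning).
#'
#' @param state a [CommunityState-class].
#' @param configs named list of [SpeciesConfig-class] covering every species
#'   in the state.
#' @param dt step length, h.
#' @return list with elements `state` (the advanced [CommunityState-class])
#'   and `solutions` (named list of per-species [FluxSolution-class]).
#' @export
dfbaStep <- function(state, configs, dt) {
  stopifnot(is(state, "CommunityState"), dt > 0)
  if (!all(names(state@biomass) %in% names(configs))) {
    stop("configs must cover every species in the state")
  }
  configs <- configs[names(state@biomass)]
  sim <- .prepare_sim(configs, state@medium)
  med <- .extend_medium(state@medium, sim)
  res <- .sim_step(sim, unname(state@biomass), unname(med@pools), dt,
                   gEst = rep(1, length(configs)), want_full = TRUE)
  if (any(res$infeasible)) {
    warning("species LP infeasible (treated as zero growth): ",
            paste(sim$species[res$infeasible], collapse = ", "))
  }
  sols <- lapply(seq_along(sim$species), function(i) {
    if (is.null(res$full[[i]])) {
      new("FluxSolution",
          fluxes = setNames(rep(0, sim$cfg[[i]]$cm$n), sim$cfg[[i]]$cm$rxnIds),
          growthRate = 0,
          status = if (res$infeasible[i]) "infeasible" else "optimal")
    } else {
      new("FluxSolution", fluxes = res$full[[i]], growthRate = res$mu[i],
          status = "optimal")
    }
  })
  names(sols) <- sim$species
  newMedium <- mediumState(setNames(res$P, sim$poolIds),
                           unlimitedIds = med@unlimitedIds,
                           limitingIds = med@limitingIds,
                           volumeML = med@volumeML)
  newState <- communityState(setNames(res$X, sim$species), newMedium,
                             time = state@time + dt,
                             passageIndex = state@passageIndex)
  list(state = newState, solutions = sols)
}

#' Simulate one growth cycle
#'
#' Iterates [dfbaStep()] over `cycleHours / timestep` steps and records the
#' full trajectory: biomass and pools on the time grid and per-step
#' exchange fluxes with the integrated biomass-time needed to convert them
#' into amounts.
#'
#' @param state starting [CommunityState-class].
#' @param configs named list of [SpeciesConfig-class].
#' @param transfer a [TransferSpec-class].
#' @return a [Trajectory-class].
#' @export
runPassage <- function(state, configs, transfer) {
  stopifnot(is(state, "CommunityState"), is(transfer, "TransferSpec"))
  configs <- configs[names(state@biomass)]
  sim <- .prepare_sim(configs, state@medium)
  med <- .extend_medium(state@medium, sim)
  .run_passage_core(sim, med, unname(state@biomass), state@time,
                    state@passageIndex, transfer)
}

.run_passage_core <- function(sim, med, X, t0, passage, transfer) {
  dt <- transfer@timestep
  nstep <- round(transfer@cycleHours / dt)
  nsp <- length(sim$species)
  npool <- length(sim$poolIds)
  nrec <- length(sim$recIds)

  Bmat <- matrix(0, nstep + 1, nsp, dimnames = list(NULL, sim$species))
  Pmat <- matrix(0, nstep + 1, npool, dimnames = list(NULL, sim$poolIds))
  Gmat <- matrix(0, nstep, nsp, dimnames = list(NULL, sim$species))
  Emat <- array(0, dim = c(nstep, nsp, nrec),
                dimnames = list(NULL, sim$species, sim$recIds))
  BHmat <- matrix(0, nstep, nsp, dimnames = list(NULL, sim$species))

  P <- unname(med@pools)
  Bmat[1, ] <- X
  Pmat[1, ] <- P
  gEst <- rep(1, nsp)
  warned <- logical(nsp)
  for (k in seq_len(nstep)) {
    res <- .sim_step(sim, X, P, dt, gEst)
    if (any(res$infeasible & !warned)) {
      warning("species LP infeasible during passage ", passage,
              " (treated as zero growth): ",
              paste(sim$species[res$infeasible & !warned], collapse = ", "))
      warned <- warned | res$infeasible
    }
    X <- res$X
    P <- res$P
    gEst <- res$gEst
    Bmat[k + 1, ] <- X
    Pmat[k + 1, ] <- P
    Gmat[k, ] <- res$mu
    Emat[k, , ] <- res$exflux
    BHmat[k, ] <- res$biomassHours
  }
  times <- t0 + dt * (0:nstep)
  finalMedium <- mediumState(setNames(P, sim$poolIds),
                             unlimitedIds = sim$unlimited,
                             limitingIds = sim$limitingIds,
                             volumeML = sim$volumeML)
  final <- communityState(setNames(X, sim$species), finalMedium,
                          time = times[nstep + 1], passageIndex = passage)
  new("Trajectory", times = times, passage = as.integer(passage),
      biomass = Bmat, pools = Pmat, growth = Gmat, exchangeFlux = Emat,
      biomassHours = BHmat, finalState = final)
}

#' Serial-transfer dilution
#'
#' Scales every species' biomass by the dilution factor, mixes the spent
#' medium with fresh medium at the same fraction, and increments the
#' passage index. Relative abundances are invariant under dilution.
#'
#' @param state [CommunityState-class] at the end of a growth cycle.
#' @param transfer a [TransferSpec-class].
#' @param fresh fresh-medium [MediumState-class].
#' @return the diluted [CommunityState-class].
#' @export
dilute <- function(state, transfer, fresh) {
  stopifnot(is(state, "CommunityState"), is(transfer, "TransferSpec"))
  f <- transfer@dilutionFactor
  # align the fresh medium with the state's (possibly extended) universe
  if (!setequal(names(fresh@pools), names(state@medium@pools))) {
    missing <- setdiff(names(state@medium@pools), names(fresh@pools))
    extra <- setdiff(names(fresh@pools), names(state@medium@pools))
    if (length(extra)) {
      stop("mismatched metabolite universes: fresh medium has pools absent ",
           "from the culture: ", paste(extra, collapse = ", "))
    }
    p <- setNames(numeric(length(state@medium@pools)),
                  names(state@medium@pools))
    p[names(fresh@pools)] <- fresh@pools
    fresh <- mediumState(p, unlimitedIds = fresh@unlimitedIds,
                         limitingIds = fresh@limitingIds,
                         volumeML = fresh@volumeML)
  }
  communityState(f * state@biomass, refreshMix(state@medium, fresh, f),
                 time = state@time, passageIndex = state@passageIndex + 1L)
}

#' Simulate serial growth-dilution cycles
#'
#' Alternates [runPassage()] and [dilute()] for `nPassages` cycles: growth
#' cycles P0..P(n-1) with a 10 percent (by default) transfer into fresh
#' medium between consecutive cycles. The final state is the end of the
#' last growth cycle, before any further dilution.
#'
#' @param configs named list of [SpeciesConfig-class]; each species starts
#'   at its configured `initialBiomass` unless overridden.
#' @param transfer a [TransferSpec-class].
#' @param fresh fresh-medium [MediumState-class] (also the starting medium).
#' @param initialBiomass optional named numeric overriding the per-species
#'   inoculum (gDW); use e.g. 3.9e-10 for a 1,000-fold diluted species.
#' @return list of [Trajectory-class], one per passage.
#' @examples
#' toy <- makeToyCommunity()
#' tr <- runSerialTransfer(speciesConfigs(toy),
#'                         transferSpec(cycleHours = 12, nPassages = 2),
#'                         freshMedium(toy))
#' communityComposition(tr)
#' @export
runSerialTransfer <- function(configs, transfer, fresh,
                              initialBiomass = NULL) {
  if (is.null(names(configs)) || any(!nzchar(names(configs)))) {
    names(configs) <- vapply(configs, function(cf) cf@model@speciesId,
                             character(1))
  }
  X0 <- vapply(configs, function(cf) cf@initialBiomass, numeric(1))
  if (!is.null(initialBiomass)) {
    if (is.null(names(initialBiomass))) {
      stop("initialBiomass override must be named")
    }
    X0[names(initialBiomass)] <- initialBiomass
  }
  sim <- .prepare_sim(configs, fresh)
  med <- .extend_medium(fresh, sim)
  state <- communityState(X0, med, time = 0, passageIndex = 0L)
  out <- vector("list", transfer@nPassages)
  for (p in seq_len(transfer@nPassages)) {
    traj <- .run_passage_core(sim, state@medium, unname(state@biomass),
                              state@time, state@passageIndex, transfer)
    out[[p]] <- traj
    state <- traj@finalState
    if (p < transfer@nPassages) state <- dilute(state, transfer, med)
  }
  out
}

#' Final community composition
#'
#' Relative biomass fractions at the end of the last supplied passage.
#'
#' @param x a [Trajectory-class] or a list of them (as returned by
#'   [runSerialTransfer()]).
#' @return named numeric fractions summing to 1.
#' @export
communityComposition <- function(x) {
  if (is.list(x)) x <- x[[length(x)]]
  stopifnot(is(x, "Trajectory"))
  b <- biomass(finalState(x))
  b / sum(b)
}
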