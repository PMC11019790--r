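## Generator of toy three-species communities with planted structure, and
## of noisy replicate count series emulating CFU / qPCR assays.

#' Specification of a toy three-species community
#'
#' The generated community emulates, at toy scale, a rhizosphere consortium
#' growing on a complex medium: every species competes for a shared sugar
#' pool, each species additionally owns a private amino-acid niche, and a
#' planted cross-feeding topology routes growth-coupled byproducts between
#' species. Secretion is stoichiometrically coupled to the biomass reaction
#' (a fixed mmol per gDW grown), so planted secretions survive parsimonious
#' flux minimisation.
#'
#' @param speciesIds three species names; the first is the dominant,
#'   reference species.
#' @param sharedPool mmol of the shared sugar ("glc") in the fresh medium.
#' @param privatePools named-by-position numeric: mmol of each species'
#'   private amino acid ("ala", "pro", "met" for the three species).
#' @param yields per-species biomass yield on carbon substrates, gDW/mmol.
#' @param crossYield biomass yield on consumed cross-fed metabolites.
#' @param plantedEdges data.frame with columns `producer`, `metabolite`,
#'   `consumer` (NA for a dangling secretion) and `sigma` (secretion
#'   coupling, mmol per gDW of producer growth). Defaults to the
#'   four-edge topology producer 1 -> {putrescine -> 2, putrescine -> 3,
#'   xanthine -> 2} and 2 -> {glycerol -> 1}, plus a dangling
#'   hypoxanthine secretion by species 3.
#' @param plantedRates named numeric, the limiting-carbon uptake rates
#'   (mmol/gDW/h) the species configs carry.
#' @param initialBiomass inoculum per species, gDW.
#' @param jitterSD lognormal coefficient of variation applied to pools and
#'   yields when randomising communities across seeds (0 = no jitter).
#' @param seed integer; the generator is a pure function of (spec, seed).
#' @return a list spec understood by [makeToyCommunity()].
#' @export
toyCommunitySpec <- function(speciesIds = c("GM17", "YR343", "AP49"),
                             sharedPool = 0.020,
                             privatePools = c(0.030, 0.0042, 0.00042),
                             yields = c(0.05, 0.05, 0.05),
                             crossYield = 0.05,
                             plantedEdges = NULL,
                             plantedRates = c(10, 5, 3),
                             initialBiomass = 3.9e-7,
                             jitterSD = 0.08,
                             seed = 1L) {
  stopifnot(length(speciesIds) == 3L, length(privatePools) == 3L,
            length(yields) == 3L, length(plantedRates) == 3L)
  if (any(yields <= 0) || crossYield < 0) stop("yields must be positive")
  if (any(plantedRates <= 0)) stop("planted rates must be positive")
  if (is.null(plantedEdges)) {
    plantedEdges <- data.frame(
      producer = c(speciesIds[1], speciesIds[1], speciesIds[1],
                   speciesIds[2], speciesIds[3]),
      metabolite = c("ptrc", "ptrc", "xan", "glyc", "hyxn"),
      consumer = c(speciesIds[2], speciesIds[3], speciesIds[2],
                   speciesIds[1], NA),
      sigma = c(0.3, 0.3, 0.2, 0.3, 0.2)
    )
  }
  bad <- setdiff(c(plantedEdges$producer,
                   plantedEdges$consumer[!is.na(plantedEdges$consumer)]),
                 speciesIds)
  if (length(bad)) {
    stop("planted edges reference undeclared species: ",
         paste(bad, collapse = ", "))
  }
  list(speciesIds = speciesIds, sharedPool = sharedPool,
       privatePools = privatePools, yields = yields,
       crossYield = crossYield, plantedEdges = plantedEdges,
       plantedRates = setNames(plantedRates, speciesIds),
       initialBiomass = initialBiomass, jitterSD = jitterSD,
       seed = as.integer(seed))
}

## run fn with a private, seeded RNG stream; restores the caller's stream
.with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Generate a toy three-species community
#'
#' Builds three [StoichiometricModel-class]s realising the spec's yields
#' and planted cross-feeding, the fresh [MediumState-class] (shared sugar
#' pool plus one private amino-acid pool per species; cross-fed metabolites
#' are absent from the medium), and per-species [SpeciesConfig-class]s
#' carrying the planted limiting-carbon uptake rates. Deterministic given
#' the spec and its seed.
#'
#' Model structure per species: an exchange reaction per touched
#' extracellular metabolite (secretion-positive), a catabolic reaction per
#' consumed substrate feeding an intracellular carbon currency with the
#' species' yield, and one biomass reaction that consumes the currency and
#' co-produces the planted secretions.
#'
#' @param spec a [toyCommunitySpec()] list.
#' @return a [ToyCommunity-class].
#' @examples
#' toy <- makeToyCommunity(toyCommunitySpec(seed = 7))
#' plantedEdges(toy)
#' @export
makeToyCommunity <- function(spec = toyCommunitySpec()) {
  sp <- spec$speciesIds
  .with_seed(spec$seed, function() {
    jit <- function(n) {
      if (spec$jitterSD > 0) {
        exp(stats::rnorm(n, 0, spec$jitterSD))
      } else {
        rep(1, n)
      }
    }
    shared <- spec$sharedPool * jit(1)
    priv <- spec$privatePools * jit(3)
    yields <- setNames(spec$yields * jit(3), sp)

    private_ids <- c("ala", "pro", "met")
    edges <- spec$plantedEdges
    models <- list()
    for (i in 1:3) {
      s <- sp[i]
      consumed <- c("glc", private_ids[i],
                    edges$metabolite[!is.na(edges$consumer) &
                                     edges$consumer == s])
      secreted <- unique(edges$metabolite[edges$producer == s])
      secreted_sigma <- vapply(secreted, function(m) {
        sum(unique(edges$sigma[edges$producer == s & edges$metabolite == m]))
      }, numeric(1))
      consumed <- setdiff(unique(consumed), secreted)
      if (length(consumed) == 0) {
        stop("species '", s, "' has no carbon route")
      }
      ex_mets <- unique(c(consumed, secreted))
      mets <- data.frame(id = c(ex_mets, "c"),
                         compartment = c(rep("extracellular",
                                             length(ex_mets)),
                                         "intracellular"))
      rx <- list()
      st <- list()
      for (m in consumed) {
        rx[[length(rx) + 1]] <- data.frame(
          id = paste0("EX_", m), lb = -1000, ub = 1000,
          isExchange = TRUE, isBiomass = FALSE)
        st[[paste0("EX_", m)]] <- setNames(-1, m)
        yld <- if (m %in% c("glc", private_ids)) yields[[s]] else
          spec$crossYield
        rx[[length(rx) + 1]] <- data.frame(
          id = paste0("CAT_", m), lb = 0, ub = 1000,
          isExchange = FALSE, isBiomass = FALSE)
        st[[paste0("CAT_", m)]] <- setNames(c(-1, yld), c(m, "c"))
      }
      for (m in secreted) {
        rx[[length(rx) + 1]] <- data.frame(
          id = paste0("EX_", m), lb = 0, ub = 1000,
          isExchange = TRUE, isBiomass = FALSE)
        st[[paste0("EX_", m)]] <- setNames(-1, m)
      }
      rx[[length(rx) + 1]] <- data.frame(
        id = "BIOMASS", lb = 0, ub = 1000,
        isExchange = FALSE, isBiomass = TRUE)
      st[["BIOMASS"]] <- setNames(c(-1, unname(secreted_sigma)),
                                  c("c", secreted))
      models[[s]] <- stoichiometricModel(s, mets, do.call(rbind, rx), st)
    }

    pools <- setNames(c(shared, priv), c("glc", private_ids))
    medium <- mediumState(pools,
                          unlimitedIds = c("nh4", "pi", "h2o", "o2", "h"),
                          limitingIds = names(pools), volumeML = 10)
    configs <- lapply(sp, function(s) {
      speciesConfig(models[[s]],
                    limitingUptakeRate = spec$plantedRates[[s]],
                    defaultVmax = 10,
                    initialBiomass = spec$initialBiomass)
    })
    names(configs) <- sp
    new("ToyCommunity", configs = configs, medium = medium,
        plantedEdges = edges[, c("producer", "metabolite", "consumer")],
        plantedRates = spec$plantedRates, seed = spec$seed)
  })
}

#' Count-noise specification for synthetic abundance series
#'
#' @param samplingOffsets sampling times within each growth cycle, h
#'   (default 0, 24 and 48, the experimental grid).
#' @param replicates number of parallel replicates (default 3).
#' @param cv coefficient of variation of the multiplicative lognormal
#'   measurement noise (mean 1).
#' @param detectionFloor minimum reportable count per mL.
#' @param seed RNG seed.
#' @return a list spec understood by [makeCountSeries()].
#' @export
countNoiseSpec <- function(samplingOffsets = c(0, 24, 48), replicates = 3,
                           cv = 0.1, detectionFloor = 10, seed = 1L) {
  stopifnot(cv >= 0, replicates >= 1)
  list(samplingOffsets = samplingOffsets, replicates = as.integer(replicates),
       cv = cv, detectionFloor = detectionFloor, seed = as.integer(seed))
}

#' Emulate CFU / qPCR count series from simulated dynamics
#'
#' Converts biomass trajectories (or a generalized Lotka-Volterra
#' simulation) into replicate counts per mL with multiplicative lognormal
#' noise of mean 1, floored at the detection limit.
#'
#' @param x a [Trajectory-class], a list of them, or a
#'   [GLVParams-class] (then `x0` and the sampling grid drive a gLV
#'   simulation whose state is already in counts/mL).
#' @param noise a [countNoiseSpec()] list.
#' @param cellsPerGDW conversion from dry mass to counts (default 5e11
#'   counts/gDW, mapping a 3.9e-7 gDW inoculum in 10 mL to roughly
#'   2e7 counts/mL).
#' @param method assay tag, `"CFU"` or `"qPCR"`.
#' @param x0 initial abundances (counts/mL), only for `GLVParams` input.
#' @return data.frame with columns `species`, `time_h`, `replicate`,
#'   `count`, `method` (counts per mL).
#' @export
makeCountSeries <- function(x, noise = countNoiseSpec(),
                            cellsPerGDW = 5e11,
                            method = c("CFU", "qPCR"), x0 = NULL) {
  method <- match.arg(method)
  if (is(x, "GLVParams")) {
    if (is.null(x0)) stop("x0 is required for GLVParams input")
    times <- sort(unique(noise$samplingOffsets))
    traj <- simulateGLV(x, x0, times)
    dens <- as.matrix(traj[, x@speciesIds, drop = FALSE])
    tt <- traj$time
    passage <- rep(0L, length(tt))
    sp <- x@speciesIds
  } else {
    if (is(x, "Trajectory")) x <- list(x)
    sp <- colnames(x[[1]]@biomass)
    tt <- numeric(0)
    passage <- integer(0)
    dens <- NULL
    for (traj in x) {
      rel <- noise$samplingOffsets
      span <- range(traj@times)
      want <- span[1] + rel[rel <= diff(span) + 1e-9]
      idx <- vapply(want, function(w) which.min(abs(traj@times - w)),
                    integer(1))
      # avoid duplicating a cycle-end point that equals the next cycle start
      keep <- if (length(tt)) traj@times[idx] > max(tt) + 1e-9 else
        rep(TRUE, length(idx))
      idx <- idx[keep]
      tt <- c(tt, traj@times[idx])
      passage <- c(passage, rep(traj@passage, length(idx)))
      block <- traj@biomass[idx, , drop = FALSE] * cellsPerGDW /
        (traj@finalState@medium@volumeML)
      dens <- rbind(dens, block)
    }
  }
  .with_seed(noise$seed, function() {
    sdlog <- sqrt(log(1 + noise$cv^2))
    nrep <- noise$replicates
    ncell <- length(dens)
    eps <- if (noise$cv > 0) {
      stats::rlnorm(ncell * nrep, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      rep(1, ncell * nrep)
    }
    counts <- pmax(rep(as.vector(dens), times = nrep) * eps,
                   noise$detectionFloor)
    data.frame(
      species = rep(rep(sp, each = length(tt)), times = nrep),
      time_h = rep(rep(tt, times = length(sp)), times = nrep),
      passage = rep(rep(passage, times = length(sp)), times = nrep),
      replicate = rep(seq_len(nrep), each = ncell),
      count = counts,
      method = method
    )
  })
}
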