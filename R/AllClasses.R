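#' @import methods
#' @importFrom stats coef lm predict sd setNames t.test
#' @importFrom utils head tail write.csv
NULL

## ---------------------------------------------------------------------------
## Core stoichiometric model classes
## ---------------------------------------------------------------------------

#' StoichiometricModel: one species' reaction network
#'
#' Container for a (toy- or genome-scale) constraint-based metabolic model:
#' a set of metabolites, a set of bounded reactions given as a stoichiometric
#' matrix, and a single biomass reaction whose flux is the specific growth
#' rate (1/h). Exchange reactions connect the model to the shared
#' extracellular environment and follow the secretion-positive convention:
#' an exchange reaction touches exactly one extracellular metabolite with
#' coefficient -1, so positive flux secretes the metabolite into the medium
#' and negative flux takes it up.
#'
#' @slot speciesId single character, the species the model describes.
#' @slot metabolites data.frame with columns `id`, `name`, `compartment`
#'   (one of `"extracellular"`, `"intracellular"`) and `formula`.
#' @slot reactions data.frame with columns `id`, `lb`, `ub` (mmol/gDW/h;
#'   1/h for the biomass reaction), `isExchange`, `isBiomass`.
#' @slot stoichiometry numeric matrix, metabolites x reactions, with
#'   dimnames matching the metabolite and reaction ids.
#'
#' @seealso [readModel()], [fba()], [pfba()]
#' @export
setClass("StoichiometricModel",
  representation(
    speciesId = "character",
    metabolites = "data.frame",
    reactions = "data.frame",
    stoichiometry = "matrix"
  )
)

setValidity("StoichiometricModel", function(object) {
  met <- object@metabolites
  rxn <- object@reactions
  S <- object@stoichiometry
  msgs <- character(0)
  need_m <- c("id", "name", "compartment", "formula")
  need_r <- c("id", "lb", "ub", "isExchange", "isBiomass")
  if (!all(need_m %in% names(met))) {
    return(paste("metabolites must have columns:", paste(need_m, collapse = ", ")))
  }
  if (!all(need_r %in% names(rxn))) {
    return(paste("reactions must have columns:", paste(need_r, collapse = ", ")))
  }
  if (length(object@speciesId) != 1L || is.na(object@speciesId) ||
      !nzchar(object@speciesId)) {
    msgs <- c(msgs, "speciesId must be a non-empty string")
  }
  if (anyDuplicated(met$id)) msgs <- c(msgs, "duplicated metabolite ids")
  if (anyDuplicated(rxn$id)) msgs <- c(msgs, "duplicated reaction ids")
  if (!all(met$compartment %in% c("extracellular", "intracellular"))) {
    msgs <- c(msgs, "compartment must be 'extracellular' or 'intracellular'")
  }
  if (!identical(rownames(S), as.character(met$id)) ||
      !identical(colnames(S), as.character(rxn$id))) {
    msgs <- c(msgs, "stoichiometry dimnames must match metabolite and reaction ids")
  }
  if (any(rxn$lb > rxn$ub)) {
    bad <- rxn$id[rxn$lb > rxn$ub]
    msgs <- c(msgs, paste0("lower bound exceeds upper bound for: ",
                           paste(bad, collapse = ", ")))
  }
  if (sum(rxn$isBiomass) != 1L) {
    msgs <- c(msgs, "exactly one reaction must be flagged as biomass")
  }
  extra <- met$id[met$compartment == "extracellular"]
  for (j in which(rxn$isExchange)) {
    nz <- which(S[, j] != 0)
    ok <- length(nz) == 1L && rownames(S)[nz] %in% extra && S[nz, j] == -1
    if (!ok) {
      msgs <- c(msgs, paste0("exchange reaction '", rxn$id[j],
        "' must touch exactly one extracellular metabolite with coefficient -1"))
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' FluxSolution: result of an FBA or pFBA optimisation
#'
#' @slot fluxes named numeric vector of reaction fluxes (mmol/gDW/h, biomass
#'   in 1/h).
#' @slot growthRate optimal biomass flux (1/h); 0 when infeasible.
#' @slot status `"optimal"` or `"infeasible"`.
#' @export
setClass("FluxSolution",
  representation(fluxes = "numeric", growthRate = "numeric",
                 status = "character")
)

setValidity("FluxSolution", function(object) {
  if (!object@status %in% c("optimal", "infeasible")) {
    return("status must be 'optimal' or 'infeasible'")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Medium
## ---------------------------------------------------------------------------

#' MediumState: the shared extracellular environment
#'
#' Finite molar pools for the limiting nutrients (and any secreted
#' byproducts), a set of metabolites treated as unlimited (inorganic ions,
#' gases, growth factors), and the culture volume. Metabolites in the
#' unlimited set never appear in the pools.
#'
#' @slot pools named numeric vector, mmol per pooled metabolite.
#' @slot unlimitedIds character, ids never depleted by the simulation.
#' @slot limitingIds character, subset of pooled metabolites that count as
#'   limiting carbon sources (the ones the calibrated uptake rate applies to).
#' @slot volumeML culture volume in mL.
#' @export
setClass("MediumState",
  representation(pools = "numeric", unlimitedIds = "character",
                 limitingIds = "character", volumeML = "numeric")
)

setValidity("MediumState", function(object) {
  msgs <- character(0)
  if (is.null(names(object@pools)) && length(object@pools) > 0) {
    msgs <- c(msgs, "pools must be named")
  }
  if (any(object@pools < 0)) msgs <- c(msgs, "pools must be non-negative")
  if (length(object@volumeML) != 1L || object@volumeML <= 0) {
    msgs <- c(msgs, "volumeML must be a single positive number")
  }
  if (any(object@unlimitedIds %in% names(object@pools))) {
    msgs <- c(msgs, "unlimited metabolites must not appear in pools")
  }
  if (!all(object@limitingIds %in% names(object@pools))) {
    msgs <- c(msgs, "limitingIds must be a subset of pooled metabolites")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

## ---------------------------------------------------------------------------
## Community dFBA
## ---------------------------------------------------------------------------

#' SpeciesConfig: per-species simulation settings
#'
#' @slot model a [StoichiometricModel-class].
#' @slot limitingUptakeRate uptake bound (mmol/gDW/h) applied simultaneously
#'   to every limiting-carbon exchange reaction of the species.
#' @slot defaultVmax uptake bound for all other (non-limiting) nutrients.
#' @slot initialBiomass inoculum dry mass in gDW.
#' @export
setClass("SpeciesConfig",
  representation(model = "StoichiometricModel", limitingUptakeRate = "numeric",
                 defaultVmax = "numeric", initialBiomass = "numeric")
)

setValidity("SpeciesConfig", function(object) {
  msgs <- character(0)
  if (object@limitingUptakeRate <= 0) msgs <- c(msgs, "limitingUptakeRate must be > 0")
  if (object@defaultVmax <= 0) msgs <- c(msgs, "defaultVmax must be > 0")
  if (object@initialBiomass <= 0) msgs <- c(msgs, "initialBiomass must be > 0")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' TransferSpec: serial growth-dilution schedule
#'
#' @slot cycleHours length of one growth cycle in hours.
#' @slot nPassages number of growth-dilution cycles.
#' @slot dilutionFactor fraction of the culture carried into fresh medium.
#' @slot timestep dFBA integration step in hours; must divide `cycleHours`.
#' @export
setClass("TransferSpec",
  representation(cycleHours = "numeric", nPassages = "integer",
                 dilutionFactor = "numeric", timestep = "numeric")
)

setValidity("TransferSpec", function(object) {
  msgs <- character(0)
  if (object@dilutionFactor <= 0 || object@dilutionFactor > 1) {
    msgs <- c(msgs, "dilutionFactor must be in (0, 1]")
  }
  if (object@nPassages < 1L) msgs <- c(msgs, "nPassages must be >= 1")
  if (object@timestep <= 0) msgs <- c(msgs, "timestep must be > 0")
  nstep <- object@cycleHours / object@timestep
  if (abs(nstep - round(nstep)) > 1e-8) {
    msgs <- c(msgs, "timestep must divide cycleHours")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' CommunityState: the object advanced by dynamic FBA
#'
#' @slot biomass named numeric, per-species dry mass in gDW.
#' @slot medium a [MediumState-class].
#' @slot time simulation clock in hours.
#' @slot passageIndex zero-based passage counter (P0, P1, ...).
#' @export
setClass("CommunityState",
  representation(biomass = "numeric", medium = "MediumState",
                 time = "numeric", passageIndex = "integer")
)

setValidity("CommunityState", function(object) {
  msgs <- character(0)
  if (is.null(names(object@biomass))) msgs <- c(msgs, "biomass must be named")
  if (any(object@biomass < 0)) msgs <- c(msgs, "biomass must be non-negative")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Trajectory: one passage of simulated community dynamics
#'
#' Dense record of a single growth cycle: biomass and pool values on the
#' time grid, plus the per-step exchange fluxes needed to reconstruct
#' metabolite movements. Fluxes are secretion-positive in mmol/gDW/h;
#' `biomassHours` holds each species' integrated dry-mass-time over each
#' step (gDW h), so that flux * biomassHours is the exact amount moved.
#'
#' @slot times time grid, h (length nsteps + 1).
#' @slot passage zero-based passage index of this cycle.
#' @slot biomass matrix (nsteps + 1) x nspecies, gDW.
#' @slot pools matrix (nsteps + 1) x npools, mmol.
#' @slot growth matrix nsteps x nspecies, per-step growth rate (1/h).
#' @slot exchangeFlux array nsteps x nspecies x npools, mmol/gDW/h.
#' @slot biomassHours matrix nsteps x nspecies, gDW h per step.
#' @slot finalState the [CommunityState-class] at the end of the cycle.
#' @export
setClass("Trajectory",
  representation(times = "numeric", passage = "integer", biomass = "matrix",
                 pools = "matrix", growth = "matrix", exchangeFlux = "array",
                 biomassHours = "matrix", finalState = "CommunityState")
)

## ---------------------------------------------------------------------------
## Calibration
## ---------------------------------------------------------------------------

#' ReferenceComposition: target final biomass fractions
#'
#' @slot fractions named numeric summing to 1.
#' @slot sourceRatio the raw ratio the fractions were derived from.
#' @export
setClass("ReferenceComposition",
  representation(fractions = "numeric", sourceRatio = "numeric")
)

setValidity("ReferenceComposition", function(object) {
  msgs <- character(0)
  if (any(object@fractions <= 0)) msgs <- c(msgs, "fractions must be > 0")
  if (abs(sum(object@fractions) - 1) > 1e-9) {
    msgs <- c(msgs, "fractions must sum to 1 within 1e-9")
  }
  if (is.null(names(object@fractions))) msgs <- c(msgs, "fractions must be named")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' CalibrationSchedule: the coarse-to-fine decrement grid
#'
#' @slot startRate initial limiting-carbon uptake rate, mmol/gDW/h.
#' @slot coarseStep decrement used from `startRate` down to `coarseFloor`.
#' @slot midStep decrement used below `coarseFloor`.
#' @slot fineSteps decreasing decrements used for per-species backtracking.
#' @slot coarseFloor rate at which the sweep switches from coarse to mid step.
#' @slot acceptanceBand two-sided band on achieved/reference fraction ratios.
#' @slot adjustableSpecies species whose rates are adjusted; empty means
#'   "all except the species with the largest reference fraction".
#' @slot maxEvaluations cap on the number of community simulations.
#' @export
setClass("CalibrationSchedule",
  representation(startRate = "numeric", coarseStep = "numeric",
                 midStep = "numeric", fineSteps = "numeric",
                 coarseFloor = "numeric", acceptanceBand = "numeric",
                 adjustableSpecies = "character", maxEvaluations = "integer")
)

setValidity("CalibrationSchedule", function(object) {
  msgs <- character(0)
  steps <- c(object@coarseStep, object@midStep, object@fineSteps)
  if (any(diff(steps) >= 0)) msgs <- c(msgs, "steps must be strictly decreasing")
  if (any(steps <= 0)) msgs <- c(msgs, "steps must be positive")
  band <- object@acceptanceBand
  if (length(band) != 2L || band[1] > 1 || band[2] < 1) {
    msgs <- c(msgs, "acceptanceBand must contain 1")
  }
  if (object@maxEvaluations < 1L) msgs <- c(msgs, "maxEvaluations must be >= 1")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' CalibrationResult: outcome of the uptake-rate search
#'
#' @slot rates named numeric, final limiting-carbon uptake rates.
#' @slot achievedFractions final biomass fractions at those rates.
#' @slot bandRatios achieved/reference per species.
#' @slot nSimulations number of community simulations performed.
#' @slot converged TRUE iff every band ratio lies in the acceptance band.
#' @slot log data.frame, one row per evaluation (rates, fractions, ratios).
#' @export
setClass("CalibrationResult",
  representation(rates = "numeric", achievedFractions = "numeric",
                 bandRatios = "numeric", nSimulations = "integer",
                 converged = "logical", log = "data.frame")
)

## ---------------------------------------------------------------------------
## Exchange network
## ---------------------------------------------------------------------------

#' ExchangeTable: integrated secretion and uptake per species and metabolite
#'
#' @slot table data.frame with columns `species`, `metabolite`,
#'   `secretion` and `uptake` (mmol over the analysis window).
#' @slot window the integration window, h.
#' @export
setClass("ExchangeTable",
  representation(table = "data.frame", window = "numeric")
)

#' ExchangeNetwork: candidate interspecies exchanges
#'
#' Directed edges producer -> metabolite -> consumer with the conservative
#' weight min(producer secretion, consumer uptake). Edges whose metabolite
#' is absent from the fresh medium (and not unlimited) carry
#' `mediumAbsent = TRUE` and are the candidate cross-feedings; edges over
#' medium-supplied metabolites are retained but flagged FALSE.
#'
#' @slot edges data.frame with columns `producer`, `metabolite`, `consumer`,
#'   `mmol`, `mediumAbsent` (and optionally `secretedInMonoculture`).
#' @slot dangling data.frame of secretions with no consumer.
#' @export
setClass("ExchangeNetwork",
  representation(edges = "data.frame", dangling = "data.frame")
)

## ---------------------------------------------------------------------------
## Generalized Lotka-Volterra
## ---------------------------------------------------------------------------

#' GLVParams: generalized Lotka-Volterra parameters
#'
#' Model dx_i/dt = x_i (r_i + sum_j a_ij x_j). The sign of the off-diagonal
#' coefficient a_ij classifies the effect of species j on species i.
#'
#' @slot speciesIds character.
#' @slot r intrinsic growth rates, 1/h.
#' @slot A square interaction matrix, 1/(h * abundance unit).
#' @slot unit abundance unit tag (e.g. "CFU/mL", "genome-equivalents/mL").
#' @export
setClass("GLVParams",
  representation(speciesIds = "character", r = "numeric", A = "matrix",
                 unit = "character")
)

setValidity("GLVParams", function(object) {
  n <- length(object@speciesIds)
  msgs <- character(0)
  if (length(object@r) != n) msgs <- c(msgs, "length(r) must match speciesIds")
  if (!all(dim(object@A) == c(n, n))) msgs <- c(msgs, "A must be n x n")
  if (any(!is.finite(object@r)) || any(!is.finite(object@A))) {
    msgs <- c(msgs, "parameters must be finite")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' InteractionSummary: interaction-sign classification
#'
#' @slot signs character matrix ("+", "-", "0") for ordered pairs, NA on the
#'   diagonal.
#' @slot fractionNegative negative couplings / non-zero off-diagonal
#'   couplings, pooled over all supplied fits; NA when no coupling clears
#'   the threshold.
#' @slot nNegative,nNonzero pooled counts.
#' @slot allBelowThreshold TRUE when no off-diagonal coupling is non-zero.
#' @export
setClass("InteractionSummary",
  representation(signs = "matrix", fractionNegative = "numeric",
                 nNegative = "integer", nNonzero = "integer",
                 allBelowThreshold = "logical")
)

## ---------------------------------------------------------------------------
## Synthetic community container
## ---------------------------------------------------------------------------

#' ToyCommunity: a generated three-species community with planted structure
#'
#' @slot configs named list of [SpeciesConfig-class], carrying the planted
#'   limiting-carbon uptake rates.
#' @slot medium fresh-medium [MediumState-class].
#' @slot plantedEdges data.frame of the planted cross-feeding topology
#'   (`producer`, `metabolite`, `consumer`).
#' @slot plantedRates named numeric, the uptake rates the generator planted.
#' @slot seed integer seed the community was generated from.
#' @export
setClass("ToyCommunity",
  representation(configs = "list", medium = "MediumState",
                 plantedEdges = "data.frame", plantedRates = "numeric",
                 seed = "integer")
)
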