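## Accessor and show methods.

#' @rdname StoichiometricModel-class
#' @export
setMethod("speciesId", "StoichiometricModel", function(object) object@speciesId)

#' @rdname StoichiometricModel-class
#' @export
setMethod("metaboliteIds", "StoichiometricModel",
          function(object) as.character(object@metabolites$id))

#' @rdname StoichiometricModel-class
#' @export
setMethod("reactionIds", "StoichiometricModel",
          function(object) as.character(object@reactions$id))

#' @rdname StoichiometricModel-class
#' @export
setMethod("stoichMatrix", "StoichiometricModel", function(object) object@stoichiometry)

#' @rdname StoichiometricModel-class
#' @export
setMethod("reactionBounds", "StoichiometricModel", function(object) {
  data.frame(id = object@reactions$id, lb = object@reactions$lb,
             ub = object@reactions$ub)
})

#' @rdname StoichiometricModel-class
#' @export
setMethod("exchangeReactions", "StoichiometricModel", function(object) {
  as.character(object@reactions$id[object@reactions$isExchange])
})

#' @rdname StoichiometricModel-class
#' @export
setMethod("biomassReaction", "StoichiometricModel", function(object) {
  as.character(object@reactions$id[object@reactions$isBiomass])
})

setMethod("show", "StoichiometricModel", function(object) {
  cat("StoichiometricModel for species '", object@speciesId, "'\n", sep = "")
  cat("  ", nrow(object@metabolites), " metabolites, ",
      nrow(object@reactions), " reactions (",
      sum(object@reactions$isExchange), " exchange)\n", sep = "")
  cat("  biomass reaction:", biomassReaction(object), "\n")
})

#' @rdname FluxSolution-class
#' @export
setMethod("fluxes", "FluxSolution", function(object) object@fluxes)

#' @rdname FluxSolution-class
#' @export
setMethod("growthRate", "FluxSolution", function(object) object@growthRate)

#' @rdname FluxSolution-class
#' @export
setMethod("solverStatus", "FluxSolution", function(object) object@status)

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution (", object@status, "): growth rate ",
      format(object@growthRate, digits = 6), " 1/h, ",
      length(object@fluxes), " fluxes\n", sep = "")
})

#' @rdname MediumState-class
#' @export
setMethod("pools", "MediumState", function(object) object@pools)

#' @rdname MediumState-class
#' @export
setMethod("unlimitedIds", "MediumState", function(object) object@unlimitedIds)

#' @rdname MediumState-class
#' @export
setMethod("limitingIds", "MediumState", function(object) object@limitingIds)

setMethod("show", "MediumState", function(object) {
  cat("MediumState: ", length(object@pools), " finite pools (",
      format(sum(object@pools), digits = 5), " mmol total), ",
      length(object@unlimitedIds), " unlimited ids, ",
      object@volumeML, " mL\n", sep = "")
})

#' @rdname CommunityState-class
#' @export
setMethod("biomass", "CommunityState", function(object) object@biomass)

#' @rdname CommunityState-class
#' @export
setMethod("pools", "CommunityState", function(object) object@medium@pools)

setMethod("show", "CommunityState", function(object) {
  cat("CommunityState at t = ", object@time, " h (passage ",
      object@passageIndex, ")\n", sep = "")
  b <- object@biomass
  cat("  biomass (gDW):",
      paste(names(b), format(b, digits = 4), sep = " = ", collapse = ", "),
      "\n")
})

#' @rdname Trajectory-class
#' @export
setMethod("biomassTable", "Trajectory", function(object) {
  sp <- colnames(object@biomass)
  data.frame(
    time_h = rep(object@times, times = length(sp)),
    passage = object@passage,
    species = rep(sp, each = length(object@times)),
    biomass_gDW = as.vector(object@biomass)
  )
})

#' @rdname Trajectory-class
#' @export
setMethod("poolTable", "Trajectory", function(object) {
  met <- colnames(object@pools)
  data.frame(
    time_h = rep(object@times, times = length(met)),
    passage = object@passage,
    metabolite = rep(met, each = length(object@times)),
    mmol = as.vector(object@pools)
  )
})

#' @rdname Trajectory-class
#' @export
setMethod("exchangeRecord", "Trajectory", function(object) {
  dm <- dim(object@exchangeFlux)
  sp <- dimnames(object@exchangeFlux)[[2]]
  met <- dimnames(object@exchangeFlux)[[3]]
  tmid <- object@times[-length(object@times)]
  keep <- which(object@exchangeFlux != 0, arr.ind = TRUE)
  if (nrow(keep) == 0) {
    return(data.frame(time_h = numeric(0), passage = integer(0),
                      species = character(0), metabolite = character(0),
                      flux_mmol_per_gDW_h = numeric(0),
                      biomass_gDW_h = numeric(0)))
  }
  data.frame(
    time_h = tmid[keep[, 1]],
    passage = object@passage,
    species = sp[keep[, 2]],
    metabolite = met[keep[, 3]],
    flux_mmol_per_gDW_h = object@exchangeFlux[keep],
    biomass_gDW_h = object@biomassHours[keep[, c(1, 2), drop = FALSE]]
  )
})

#' @rdname Trajectory-class
#' @export
setMethod("finalState", "Trajectory", function(object) object@finalState)

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory: passage ", object@passage, ", t in [",
      min(object@times), ", ", max(object@times), "] h, ",
      ncol(object@biomass), " species, ", ncol(object@pools),
      " pooled metabolites\n", sep = "")
})

#' @rdname CalibrationResult-class
#' @export
setMethod("uptakeRates", "CalibrationResult", function(object) object@rates)

#' @rdname CalibrationResult-class
#' @export
setMethod("achievedFractions", "CalibrationResult",
          function(object) object@achievedFractions)

#' @rdname CalibrationResult-class
#' @export
setMethod("bandRatios", "CalibrationResult", function(object) object@bandRatios)

#' @rdname CalibrationResult-class
#' @export
setMethod("converged", "CalibrationResult", function(object) object@converged)

#' @rdname CalibrationResult-class
#' @export
setMethod("evaluationLog", "CalibrationResult", function(object) object@log)

setMethod("show", "CalibrationResult", function(object) {
  cat("CalibrationResult: ", if (object@converged) "converged" else
      "NOT converged", " after ", object@nSimulations, " simulations\n",
      sep = "")
  cat("  rates (mmol/gDW/h):",
      paste(names(object@rates), format(object@rates, digits = 4),
            sep = " = ", collapse = ", "), "\n")
  cat("  achieved/reference:",
      paste(names(object@bandRatios), format(object@bandRatios, digits = 4),
            sep = " = ", collapse = ", "), "\n")
})

#' @rdname ExchangeTable-class
#' @param object an object.
#' @export
setMethod("show", "ExchangeTable", function(object) {
  cat("ExchangeTable over [", object@window[1], ", ", object@window[2],
      "] h: ", nrow(object@table), " species/metabolite rows\n", sep = "")
})

#' @rdname ExchangeNetwork-class
#' @export
setMethod("edges", "ExchangeNetwork", function(object) object@edges)

#' @rdname ExchangeNetwork-class
#' @export
setMethod("danglingSecretions", "ExchangeNetwork", function(object) object@dangling)

setMethod("show", "ExchangeNetwork", function(object) {
  cat("ExchangeNetwork: ", nrow(object@edges), " edges (",
      sum(object@edges$mediumAbsent), " medium-absent), ",
      nrow(object@dangling), " dangling secretions\n", sep = "")
})

#' @rdname GLVParams-class
#' @export
setMethod("speciesId", "GLVParams", function(object) object@speciesIds)

#' @rdname GLVParams-class
#' @export
setMethod("interactionMatrix", "GLVParams", function(object) object@A)

#' @rdname GLVParams-class
#' @export
setMethod("intrinsicRates", "GLVParams", function(object) object@r)

setMethod("show", "GLVParams", function(object) {
  cat("GLVParams for", length(object@speciesIds), "species (unit:",
      object@unit, ")\n")
  cat("  r:", format(object@r, digits = 4), "\n")
  cat("  sign(A):\n")
  print(matrix(ifelse(object@A > 0, "+", ifelse(object@A < 0, "-", "0")),
               nrow = nrow(object@A),
               dimnames = list(object@speciesIds, object@speciesIds)))
})

#' @rdname InteractionSummary-class
#' @export
setMethod("fractionNegative", "InteractionSummary",
          function(object) object@fractionNegative)

#' @rdname InteractionSummary-class
#' @export
setMethod("interactionSignMatrix", "InteractionSummary",
          function(object) object@signs)

setMethod("show", "InteractionSummary", function(object) {
  if (object@allBelowThreshold) {
    cat("InteractionSummary: no coupling above threshold\n")
  } else {
    cat("InteractionSummary: ", object@nNegative, "/", object@nNonzero,
        " negative off-diagonal couplings (fraction ",
        format(object@fractionNegative, digits = 4), ")\n", sep = "")
  }
})

#' @rdname ToyCommunity-class
#' @export
setMethod("speciesConfigs", "ToyCommunity", function(object) object@configs)

#' @rdname ToyCommunity-class
#' @export
setMethod("freshMedium", "ToyCommunity", function(object) object@medium)

#' @rdname ToyCommunity-class
#' @export
setMethod("plantedEdges", "ToyCommunity", function(object) object@plantedEdges)

#' @rdname ToyCommunity-class
#' @export
setMethod("plantedRates", "ToyCommunity", function(object) object@plantedRates)

setMethod("show", "ToyCommunity", function(object) {
  cat("ToyCommunity: ", length(object@configs), " species (",
      paste(names(object@configs), collapse = ", "), "), ",
      nrow(object@plantedEdges), " planted exchange edges, seed ",
      object@seed, "\n", sep = "")
})
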