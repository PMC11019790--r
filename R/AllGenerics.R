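## Generics and accessors. Slot access from user code should go through
## these, following Bioconductor convention.

#' @rdname StoichiometricModel-class
#' @param object,x an object.
#' @export
setGeneric("speciesId", function(object) standardGeneric("speciesId"))

#' @rdname StoichiometricModel-class
#' @export
setGeneric("metaboliteIds", function(object) standardGeneric("metaboliteIds"))

#' @rdname StoichiometricModel-class
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))

#' @rdname StoichiometricModel-class
#' @export
setGeneric("stoichMatrix", function(object) standardGeneric("stoichMatrix"))

#' @rdname StoichiometricModel-class
#' @export
setGeneric("reactionBounds", function(object) standardGeneric("reactionBounds"))

#' @rdname StoichiometricModel-class
#' @export
setGeneric("exchangeReactions", function(object) standardGeneric("exchangeReactions"))

#' @rdname StoichiometricModel-class
#' @export
setGeneric("biomassReaction", function(object) standardGeneric("biomassReaction"))

#' @rdname FluxSolution-class
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))

#' @rdname FluxSolution-class
#' @export
setGeneric("growthRate", function(object) standardGeneric("growthRate"))

#' @rdname FluxSolution-class
#' @export
setGeneric("solverStatus", function(object) standardGeneric("solverStatus"))

#' @rdname MediumState-class
#' @export
setGeneric("pools", function(object) standardGeneric("pools"))

#' @rdname MediumState-class
#' @export
setGeneric("unlimitedIds", function(object) standardGeneric("unlimitedIds"))

#' @rdname MediumState-class
#' @export
setGeneric("limitingIds", function(object) standardGeneric("limitingIds"))

#' @rdname CommunityState-class
#' @export
setGeneric("biomass", function(object) standardGeneric("biomass"))

#' @rdname Trajectory-class
#' @export
setGeneric("biomassTable", function(object) standardGeneric("biomassTable"))

#' @rdname Trajectory-class
#' @export
setGeneric("poolTable", function(object) standardGeneric("poolTable"))

#' @rdname Trajectory-class
#' @export
setGeneric("exchangeRecord", function(object) standardGeneric("exchangeRecord"))

#' @rdname Trajectory-class
#' @export
setGeneric("finalState", function(object) standardGeneric("finalState"))

#' @rdname CalibrationResult-class
#' @export
setGeneric("uptakeRates", function(object) standardGeneric("uptakeRates"))

#' @rdname CalibrationResult-class
#' @export
setGeneric("achievedFractions", function(object) standardGeneric("achievedFractions"))

#' @rdname CalibrationResult-class
#' @export
setGeneric("bandRatios", function(object) standardGeneric("bandRatios"))

#' @rdname CalibrationResult-class
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))

#' @rdname CalibrationResult-class
#' @export
setGeneric("evaluationLog", function(object) standardGeneric("evaluationLog"))

#' @rdname ExchangeNetwork-class
#' @export
setGeneric("edges", function(object) standardGeneric("edges"))

#' @rdname ExchangeNetwork-class
#' @export
setGeneric("danglingSecretions", function(object) standardGeneric("danglingSecretions"))

#' @rdname GLVParams-class
#' @export
setGeneric("interactionMatrix", function(object) standardGeneric("interactionMatrix"))

#' @rdname GLVParams-class
#' @export
setGeneric("intrinsicRates", function(object) standardGeneric("intrinsicRates"))

#' @rdname InteractionSummary-class
#' @export
setGeneric("fractionNegative", function(object) standardGeneric("fractionNegative"))

#' @rdname InteractionSummary-class
#' @export
setGeneric("interactionSignMatrix", function(object) standardGeneric("interactionSignMatrix"))

#' @rdname ToyCommunity-class
#' @export
setGeneric("speciesConfigs", function(object) standardGeneric("speciesConfigs"))

#' @rdname ToyCommunity-class
#' @export
setGeneric("freshMedium", function(object) standardGeneric("freshMedium"))

#' @rdname ToyCommunity-class
#' @export
setGeneric("plantedEdges", function(object) standardGeneric("plantedEdges"))

#' @rdname ToyCommunity-class
#' @export
setGeneric("plantedRates", function(object) standardGeneric("plantedRates"))
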