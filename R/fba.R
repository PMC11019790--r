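## Flux balance analysis and parsimonious FBA.
##
## Both run on the package's dense two-phase simplex (src/simplex.cpp);
## problems at this scale (tens of reactions) solve in microseconds and the
## solver's Bland pivoting makes every tie-break deterministic in the
## model's reaction order.

#' @useDynLib syncomfba, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.LP_TOL <- 1e-9

## Internal plain-list form of a model, for the dFBA hot loop.
.compile_model <- function(model) {
  rxn <- model@reactions
  S <- model@stoichiometry
  ex <- which(rxn$isExchange)
  ex_met <- vapply(ex, function(j) rownames(S)[which(S[, j] != 0)], character(1))
  n <- nrow(rxn)
  obj <- numeric(n)
  obj[which(rxn$isBiomass)] <- 1
  list(S = S, lb = rxn$lb, ub = rxn$ub, n = n,
       rxnIds = as.character(rxn$id), biomassIdx = which(rxn$isBiomass),
       exIdx = ex, exMet = ex_met, speciesId = model@speciesId,
       obj = obj, zeros = numeric(nrow(S)), Asplit = cbind(S, -S),
       ones2n = rep(1, 2 * n))
}

## Core LP call on a compiled model with explicit bounds.
.fba_core <- function(cm, lb, ub) {
  res <- .solve_lp_cpp(cm$obj, cm$S, cm$zeros, lb, ub, TRUE)
  if (res$status == "unbounded") {
    stop("FBA objective is unbounded: cap the exchange bounds ",
         "(every uptake and secretion needs a finite limit)")
  }
  res
}

.pfba_core <- function(cm, lb, ub, mu) {
  # fix biomass to the FBA optimum (relative tolerance), minimise sum |v|
  lb2 <- lb
  ub2 <- ub
  lb2[cm$biomassIdx] <- mu - abs(mu) * .LP_TOL
  ub2[cm$biomassIdx] <- mu
  n <- cm$n
  # split v = p - q, p in [max(0,lb), max(0,ub)], q in [max(0,-ub), max(0,-lb)]
  plo <- pmax(0, lb2); phi <- pmax(0, ub2)
  qlo <- pmax(0, -ub2); qhi <- pmax(0, -lb2)
  res <- .solve_lp_cpp(cm$ones2n, cm$Asplit, cm$zeros,
                       c(plo, qlo), c(phi, qhi), FALSE)
  if (res$status != "optimal") return(NULL)
  res$x[seq_len(n)] - res$x[n + seq_len(n)]
}

.apply_exchange_bounds <- function(cm, exchange_bounds) {
  lb <- cm$lb
  ub <- cm$ub
  if (length(exchange_bounds)) {
    ids <- names(exchange_bounds)
    bad <- setdiff(ids, cm$rxnIds[cm$exIdx])
    if (length(bad)) {
      stop("exchange_bounds keys must be exchange reactions; offending: ",
           paste(bad, collapse = ", "))
    }
    for (id in ids) {
      j <- match(id, cm$rxnIds)
      lb[j] <- exchange_bounds[[id]][1]
      ub[j] <- exchange_bounds[[id]][2]
    }
  }
  list(lb = lb, ub = ub)
}

#' Flux balance analysis
#'
#' Maximises the biomass flux subject to steady-state mass balance
#' `S v = 0` and the model's flux bounds, optionally overridden for
#' exchange reactions. The optimal biomass flux is the specific growth
#' rate in 1/h.
#'
#' @param model a [StoichiometricModel-class].
#' @param exchangeBounds optional named list/vector mapping exchange
#'   reaction ids to `c(lb, ub)` overrides (mmol/gDW/h,
#'   secretion-positive).
#' @return a [FluxSolution-class]; `status` is `"infeasible"` (with zero
#'   growth) when no feasible flux vector exists.
#' @seealso [pfba()]
#' @export
fba <- function(model, exchangeBounds = list()) {
  cm <- .compile_model(model)
  b <- .apply_exchange_bounds(cm, exchangeBounds)
  res <- .fba_core(cm, b$lb, b$ub)
  if (res$status != "optimal") {
    return(new("FluxSolution", fluxes = setNames(rep(NA_real_, cm$n), cm$rxnIds),
               growthRate = 0, status = "infeasible"))
  }
  v <- setNames(res$x, cm$rxnIds)
  new("FluxSolution", fluxes = v, growthRate = res$objval, status = "optimal")
}

#' Parsimonious flux balance analysis
#'
#' First solves [fba()], then fixes the biomass flux at its optimum (within
#' relative tolerance 1e-9) and minimises the total absolute flux
#' `sum |v|` through the standard split into non-negative forward and
#' reverse components. The reported growth rate equals the FBA optimum;
#' the flux vector is the parsimonious one.
#'
#' @inheritParams fba
#' @return a [FluxSolution-class].
#' @export
pfba <- function(model, exchangeBounds = list()) {
  cm <- .compile_model(model)
  b <- .apply_exchange_bounds(cm, exchangeBounds)
  res <- .fba_core(cm, b$lb, b$ub)
  if (res$status != "optimal") {
    return(new("FluxSolution", fluxes = setNames(rep(NA_real_, cm$n), cm$rxnIds),
               growthRate = 0, status = "infeasible"))
  }
  mu <- res$objval
  v <- .pfba_core(cm, b$lb, b$ub, mu)
  if (is.null(v)) v <- res$x   # numerically degenerate; keep the FBA vertex
  new("FluxSolution", fluxes = setNames(v, cm$rxnIds), growthRate = mu,
      status = "optimal")
}
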