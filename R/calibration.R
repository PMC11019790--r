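## Coarse-to-fine calibration of limiting-carbon uptake rates against a
## reference community composition.

#' Reference community composition
#'
#' @param ratio numeric ratio (e.g. `c(1.0, 0.126, 0.013)`) or a string
#'   `"1.0:0.126:0.013"`; normalised to fractions.
#' @param speciesIds names for the entries.
#' @return a [ReferenceComposition-class].
#' @examples
#' referenceComposition("1.0:0.126:0.013", c("GM17", "YR343", "AP49"))
#' @export
referenceComposition <- function(ratio, speciesIds) {
  if (is.character(ratio)) {
    ratio <- as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]])
  }
  if (length(ratio) != length(speciesIds)) {
    stop("ratio and speciesIds must have the same length")
  }
  fr <- ratio / sum(ratio)
  names(fr) <- speciesIds
  obj <- new("ReferenceComposition", fractions = fr,
             sourceRatio = setNames(ratio, speciesIds))
  validObject(obj)
  obj
}

#' The coarse-to-fine decrement schedule
#'
#' Defaults follow the published procedure: rates start at 10 mmol/gDW/h,
#' are decreased jointly by 1 down to 1 mmol/gDW/h and then by 0.1; when a
#' species' achieved fraction falls below 95 percent of its reference, its
#' rate is returned to the last value and descended again with decrements
#' of 0.01 and then 0.001, until every species' achieved/reference ratio
#' lies in the 95-105 percent band.
#'
#' @param startRate starting rate, mmol/gDW/h.
#' @param coarseStep,midStep,fineSteps,coarseFloor decrement grid.
#' @param acceptanceBand two-sided band on achieved/reference.
#' @param adjustableSpecies species whose rates are adjusted; `character(0)`
#'   (the default) means all except the species with the largest reference
#'   fraction.
#' @param maxEvaluations cap on community simulations (default 500).
#' @return a [CalibrationSchedule-class].
#' @export
calibrationSchedule <- function(startRate = 10, coarseStep = 1,
                                midStep = 0.1, fineSteps = c(0.01, 0.001),
                                coarseFloor = 1,
                                acceptanceBand = c(0.95, 1.05),
                                adjustableSpecies = character(0),
                                maxEvaluations = 500L) {
  obj <- new("CalibrationSchedule", startRate = startRate,
             coarseStep = coarseStep, midStep = midStep,
             fineSteps = fineSteps, coarseFloor = coarseFloor,
             acceptanceBand = acceptanceBand,
             adjustableSpecies = adjustableSpecies,
             maxEvaluations = as.integer(maxEvaluations))
  validObject(obj)
  obj
}

#' Evaluate final community fractions at given uptake rates
#'
#' Runs the full serial-transfer simulation with the supplied
#' limiting-carbon uptake rates and returns the end-of-last-passage
#' biomass fractions. Deterministic: identical rates give identical
#' fractions.
#'
#' @param rates named numeric, limiting-carbon uptake rate per species.
#' @param configs named list of [SpeciesConfig-class].
#' @param transfer a [TransferSpec-class].
#' @param fresh fresh-medium [MediumState-class].
#' @return named numeric fractions summing to 1.
#' @export
evaluateRates <- function(rates, configs, transfer, fresh) {
  if (any(rates <= 0)) stop("rates must be positive")
  cfgs <- configs
  for (s in names(rates)) {
    if (!s %in% names(cfgs)) stop("unknown species in rates: ", s)
    cfgs[[s]]@limitingUptakeRate <- rates[[s]]
  }
  communityComposition(runSerialTransfer(cfgs, transfer, fresh))
}

## round to the calibration grid (decrements are >= 0.001)
.grid_round <- function(x) round(x, 6)

#' Calibrate limiting-carbon uptake rates to a reference composition
#'
#' Phase 1 sweeps the rates of all adjustable species down together from
#' the start rate (coarse decrement above the coarse floor, then the mid
#' decrement), evaluating the full serial-transfer simulation after every
#' move, and stops when any adjustable species undershoots the band
#' (achieved/reference < 0.95). Phase 2 then refines per species, rarest
#' first: the species' rate is returned to the last value before its
#' undershoot and descended again with the next finer decrement, down to
#' the finest. Calibration converges when every species' ratio lies in
#' the acceptance band; otherwise the best rates found are returned with
#' `converged = FALSE`.
#'
#' @param configs named list of [SpeciesConfig-class].
#' @param transfer a [TransferSpec-class].
#' @param fresh fresh-medium [MediumState-class].
#' @param reference a [ReferenceComposition-class].
#' @param schedule a [CalibrationSchedule-class].
#' @return a [CalibrationResult-class].
#' @export
calibrateUptakeRates <- function(configs, transfer, fresh, reference,
                                 schedule = calibrationSchedule()) {
  if (is.null(names(configs)) || any(!nzchar(names(configs)))) {
    names(configs) <- vapply(configs, function(cf) cf@model@speciesId,
                             character(1))
  }
  sp <- names(configs)
  ref <- reference@fractions
  if (!all(names(ref) %in% sp)) {
    stop("reference species absent from configs: ",
         paste(setdiff(names(ref), sp), collapse = ", "))
  }
  ref <- ref[sp]
  band <- schedule@acceptanceBand
  adj <- schedule@adjustableSpecies
  if (length(adj) == 0) adj <- sp[-which.max(ref)]
  if (!all(adj %in% sp)) stop("adjustableSpecies must name configured species")
  # phase-2 order: rarest first
  adj <- adj[order(ref[adj])]

  rates <- setNames(rep(schedule@startRate, length(sp)), sp)
  n_sim <- 0L
  log_rows <- list()
  cache <- new.env(parent = emptyenv())

  eval_rates <- function(r) {
    key <- paste(format(r, digits = 12), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    if (n_sim >= schedule@maxEvaluations) return(NULL)
    fr <- evaluateRates(r, configs, transfer, fresh)[sp]
    n_sim <<- n_sim + 1L
    ratios <- fr / ref
    rec <- list(fractions = fr, ratios = ratios)
    cache[[key]] <- rec
    log_rows[[length(log_rows) + 1]] <<- data.frame(
      evaluation = n_sim,
      t(setNames(r, paste0("rate_", sp))),
      t(setNames(fr, paste0("fraction_", sp))),
      t(setNames(ratios, paste0("ratio_", sp)))
    )
    rec
  }
  in_band <- function(ratios) {
    all(ratios >= band[1] & ratios <= band[2])
  }

  steps <- c(schedule@coarseStep, schedule@midStep, schedule@fineSteps)
  step_at <- function(rate) {
    # joint-sweep step: coarse above the floor, mid below
    if (rate > schedule@coarseFloor + 1e-12) schedule@coarseStep else
      schedule@midStep
  }

  best <- NULL
  remember_best <- function(r, rec) {
    miss <- sum(pmax(0, band[1] - rec$ratios) + pmax(0, rec$ratios - band[2]))
    if (is.null(best) || miss < best$miss) {
      best <<- list(rates = r, rec = rec, miss = miss)
    }
  }

  ## Phase 1: joint descent
  rec <- eval_rates(rates)
  undershoot_step <- setNames(rep(NA_real_, length(adj)), adj)
  phase1_last_ok <- rates
  if (!is.null(rec)) {
    remember_best(rates, rec)
    while (!in_band(rec$ratios) && !any(rec$ratios[adj] < band[1])) {
      stp <- step_at(rates[[adj[1]]])
      nxt <- .grid_round(rates[adj] - stp)
      if (any(nxt <= 0)) break
      phase1_last_ok <- rates
      rates[adj] <- nxt
      rec2 <- eval_rates(rates)
      if (is.null(rec2)) break
      rec <- rec2
      remember_best(rates, rec)
    }
    under <- adj[rec$ratios[adj] < band[1]]
    if (length(under)) {
      stp <- step_at(.grid_round(rates[[adj[1]]] + step_at(rates[[adj[1]]])))
      undershoot_step[under] <- stp
    }
  }

  ## Phase 2: per-species refinement, rarest first, repeated until stable
  if (!is.null(rec) && !in_band(rec$ratios)) {
    for (sweep in 1:3) {
      changed <- FALSE
      for (s in adj) {
        if (is.null(rec)) break
        if (rec$ratios[s] >= band[1] && rec$ratios[s] <= band[2]) next
        # restore to the last value before the undershoot (if any)
        stp_idx <- if (!is.na(undershoot_step[s])) {
          match(undershoot_step[s], steps) + 1L
        } else {
          match(step_at(rates[[s]]), steps)
        }
        if (rec$ratios[s] < band[1]) {
          back_step <- if (!is.na(undershoot_step[s])) undershoot_step[s] else
            step_at(rates[[s]])
          rates[s] <- .grid_round(rates[[s]] + back_step)
          rec <- eval_rates(rates)
          if (is.null(rec)) break
          remember_best(rates, rec)
        }
        while (!is.null(rec) && stp_idx <= length(steps)) {
          stp <- steps[stp_idx]
          descended <- FALSE
          while (!is.null(rec) && rec$ratios[s] > band[2] &&
                 rates[[s]] - stp > 0) {
            rates[s] <- .grid_round(rates[[s]] - stp)
            rec <- eval_rates(rates)
            if (is.null(rec)) break
            remember_best(rates, rec)
            changed <- TRUE
            descended <- TRUE
          }
          if (is.null(rec)) break
          if (rec$ratios[s] >= band[1]) break       # in band (or above floor)
          # undershot at this step size: back up and refine
          rates[s] <- .grid_round(rates[[s]] + stp)
          rec <- eval_rates(rates)
          if (is.null(rec)) break
          remember_best(rates, rec)
          changed <- changed || descended
          stp_idx <- stp_idx + 1L
        }
        undershoot_step[s] <- NA_real_
      }
      if (is.null(rec) || in_band(rec$ratios) || !changed) break
    }
  }

  if (is.null(rec)) rec <- best$rec
  if (!is.null(best) && !in_band(rec$ratios) && best$miss == 0) {
    rates <- best$rates
    rec <- best$rec
  }
  logdf <- do.call(rbind, log_rows)
  new("CalibrationResult", rates = rates,
      achievedFractions = rec$fractions, bandRatios = rec$ratios,
      nSimulations = n_sim, converged = in_band(rec$ratios),
      log = logdf)
}
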