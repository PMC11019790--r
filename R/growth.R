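## Growth-curve statistics and community-level comparisons.

.check_series <- function(series) {
  need <- c("species", "time_h", "replicate", "count")
  if (!all(need %in% names(series))) {
    stop("series must have columns: ", paste(need, collapse = ", "))
  }
  if (any(series$time_h < 0)) stop("times must be non-negative")
  invisible(series)
}

#' Maximum specific growth rate from a growth curve
#'
#' mu_max is the least-squares slope of ln(X/X0) against time over the
#' exponential window. The window is chosen deterministically: all
#' contiguous windows of at least `minPoints` replicate-mean points with a
#' positive slope are scanned and the one with maximal r-squared wins
#' (ties: the longest window, then the earliest). Per-replicate slopes
#' over the selected window are also returned.
#'
#' @param series long data.frame (`species`, `time_h`, `replicate`,
#'   `count`).
#' @param species which species to estimate; default the first present.
#' @param minPoints minimum window width in points (default 3).
#' @return list with `muMax` (1/h), `window` (h), `rSquared`,
#'   `perReplicate`, `noGrowth` (TRUE when no positive-slope window
#'   exists, in which case `muMax` is 0).
#' @examples
#' d <- expand.grid(time_h = c(0, 2, 4, 6), replicate = 1)
#' d$species <- "a"; d$count <- 1e4 * exp(0.6 * d$time_h)
#' muMax(d)$muMax   # 0.6
#' @export
muMax <- function(series, species = NULL, minPoints = 3) {
  .check_series(series)
  if (is.null(species)) species <- series$species[1]
  d <- series[series$species == species, , drop = FALSE]
  if (nrow(d) == 0) stop("species not found in series: ", species)
  if (any(d$count <= 0)) stop("counts must be positive")
  m <- stats::aggregate(count ~ time_h, data = d, FUN = mean)
  m <- m[order(m$time_h), ]
  if (nrow(m) < minPoints) stop("need at least ", minPoints, " time points")
  y <- log(m$count / m$count[1])
  tt <- m$time_h
  npt <- length(tt)
  best <- NULL
  for (a in 1:(npt - minPoints + 1)) {
    for (b in (a + minPoints - 1):npt) {
      ti <- tt[a:b]
      yi <- y[a:b]
      fit <- stats::lm.fit(cbind(1, ti), yi)
      slope <- fit$coefficients[2]
      if (!is.finite(slope) || slope <= 0) next
      ssr <- sum(fit$residuals^2)
      sst <- sum((yi - mean(yi))^2)
      r2 <- if (sst > 0) 1 - ssr / sst else 1
      len <- b - a + 1
      if (is.null(best) ||
          r2 > best$r2 + 1e-12 ||
          (abs(r2 - best$r2) <= 1e-12 && len > best$len) ||
          (abs(r2 - best$r2) <= 1e-12 && len == best$len && a < best$a)) {
        best <- list(a = a, b = b, slope = slope, r2 = r2, len = len)
      }
    }
  }
  if (is.null(best)) {
    return(list(muMax = 0, window = c(tt[1], tt[npt]), rSquared = NA_real_,
                perReplicate = setNames(numeric(0), character(0)),
                noGrowth = TRUE))
  }
  win <- c(tt[best$a], tt[best$b])
  per_rep <- vapply(split(d, d$replicate), function(dr) {
    dr <- dr[dr$time_h >= win[1] & dr$time_h <= win[2], ]
    if (nrow(dr) < 2) return(NA_real_)
    yr <- log(dr$count / dr$count[which.min(dr$time_h)])
    unname(stats::lm.fit(cbind(1, dr$time_h), yr)$coefficients[2])
  }, numeric(1))
  list(muMax = unname(best$slope), window = win, rSquared = unname(best$r2),
       perReplicate = per_rep, noGrowth = FALSE)
}

#' Fold increase in population size over a growth cycle
#'
#' N(t1)/N(t0) using replicate-mean counts (default the 0-48 h cycle).
#'
#' @inheritParams muMax
#' @param t0,t1 endpoint times, h.
#' @return the ratio (single numeric).
#' @export
foldIncrease <- function(series, species = NULL, t0 = 0, t1 = 48) {
  .check_series(series)
  if (is.null(species)) species <- series$species[1]
  d <- series[series$species == species, , drop = FALSE]
  pick <- function(tq) {
    v <- d$count[abs(d$time_h - tq) < 1e-9]
    if (length(v) == 0) stop("no counts at t = ", tq, " h")
    mean(v)
  }
  pick(t1) / pick(t0)
}

#' Relative abundance of each species at a time point
#'
#' Fractions are computed per replicate (each species' count over the
#' replicate total) and then averaged, with the standard error over
#' replicates.
#'
#' @param series long data.frame (`species`, `time_h`, `replicate`,
#'   `count`).
#' @param time time point, h.
#' @return data.frame with `species`, `fraction`, `se`; fractions sum to 1.
#' @export
relativeAbundance <- function(series, time) {
  .check_series(series)
  d <- series[abs(series$time_h - time) < 1e-9, , drop = FALSE]
  if (nrow(d) == 0) stop("no counts at t = ", time, " h")
  sp <- sort(unique(series$species))
  per_rep <- lapply(split(d, d$replicate), function(dr) {
    if (!setequal(dr$species, sp)) {
      stop("all community species must be present at the time point")
    }
    v <- dr$count[match(sp, dr$species)]
    v / sum(v)
  })
  M <- do.call(rbind, per_rep)
  data.frame(species = sp,
             fraction = colMeans(M),
             se = apply(M, 2, function(col) {
               if (length(col) > 1) sd(col) / sqrt(length(col)) else NA_real_
             }),
             row.names = NULL)
}

#' Null-model community productivity comparison
#'
#' The expected community yield under no interaction is the weighted sum
#' of the monoculture yields, with weights given by the initial inoculum
#' fractions (or equal weights). Observed below expected indicates net
#' negative interactions. A two-sided Welch t-test compares observed and
#' expected across replicates (replicates are paired by index to form the
#' expected distribution).
#'
#' @param monocultureYields matrix or data.frame, species x replicate
#'   yields in a common unit (rows named by species).
#' @param initialFractions named weights; default equal.
#' @param communityYield numeric vector of community yields (replicates).
#' @return list with `expected`, `observed`, `ratio`, `pValue`,
#'   `netNegative` (TRUE when ratio < 1).
#' @export
nullModelProductivity <- function(monocultureYields, communityYield,
                                  initialFractions = NULL) {
  M <- as.matrix(monocultureYields)
  sp <- rownames(M)
  if (is.null(sp)) stop("monocultureYields must have species row names")
  if (is.null(initialFractions)) {
    w <- setNames(rep(1 / nrow(M), nrow(M)), sp)
  } else {
    if (!all(sp %in% names(initialFractions))) {
      stop("initialFractions must cover all species")
    }
    w <- initialFractions[sp] / sum(initialFractions[sp])
  }
  expected_reps <- as.vector(crossprod(M, w))
  expected <- mean(expected_reps)
  observed <- mean(communityYield)
  pval <- if (length(communityYield) > 1 && length(expected_reps) > 1 &&
              (sd(communityYield) > 0 || sd(expected_reps) > 0)) {
    t.test(communityYield, expected_reps)$p.value
  } else {
    NA_real_
  }
  list(expected = expected, observed = observed, ratio = observed / expected,
       pValue = pval, netNegative = observed / expected < 1)
}
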