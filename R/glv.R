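## Generalized Lotka-Volterra: simulation, fitting by gradient matching,
## and interaction-sign classification.

#' Construct gLV parameters
#'
#' @param r named (or unnamed) intrinsic growth rates, 1/h.
#' @param A square interaction matrix a_ij (effect of species j on the
#'   per-capita growth of species i), 1/(h * abundance unit).
#' @param speciesIds species names; taken from `names(r)` when missing.
#' @param unit abundance unit tag.
#' @return a [GLVParams-class].
#' @export
glvParams <- function(r, A, speciesIds = names(r), unit = "CFU/mL") {
  if (is.null(speciesIds)) speciesIds <- paste0("sp", seq_along(r))
  A <- as.matrix(A)
  dimnames(A) <- list(speciesIds, speciesIds)
  obj <- new("GLVParams", speciesIds = speciesIds,
             r = setNames(as.numeric(r), speciesIds), A = A, unit = unit)
  validObject(obj)
  obj
}

#' Simulate generalized Lotka-Volterra dynamics
#'
#' Integrates dx_i/dt = x_i (r_i + sum_j a_ij x_j) with an adaptive
#' solver. Integration is carried out in log abundance, so trajectories
#' stay strictly positive by construction.
#'
#' @param params a [GLVParams-class].
#' @param x0 strictly positive initial abundances.
#' @param times increasing vector of output times, h.
#' @param blowupLimit abort with an error when any abundance exceeds this
#'   multiple of the largest initial abundance (diverging system with no
#'   self-limitation).
#' @return data.frame with column `time` and one abundance column per
#'   species.
#' @examples
#' p <- glvParams(r = c(a = 0.5), A = matrix(-0.5 / 1e8, 1, 1))
#' tail(simulateGLV(p, c(a = 1e6), seq(0, 48, 1)), 3)  # logistic to K = 1e8
#' @export
simulateGLV <- function(params, x0, times, blowupLimit = 1e12) {
  stopifnot(is(params, "GLVParams"))
  if (any(x0 <= 0)) stop("x0 must be strictly positive")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  n <- length(params@speciesIds)
  if (length(x0) != n) stop("x0 length must match the species count")
  r <- unname(params@r)
  A <- unname(params@A)
  cap <- blowupLimit * max(x0)
  rhs <- function(t, u, parms) {
    x <- exp(u)
    list(r + as.vector(A %*% x))
  }
  sol <- deSolve::ode(y = log(unname(x0)), times = times, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  u <- sol[, -1, drop = FALSE]
  if (anyNA(u) || any(!is.finite(u)) || any(exp(u) > cap)) {
    stop("gLV integration blew up in finite time: the system has ",
         "unbounded growth (check for missing self-limitation a_ii < 0)")
  }
  out <- data.frame(time = sol[, 1])
  x <- exp(u)
  colnames(x) <- params@speciesIds
  cbind(out, as.data.frame(x))
}

## replicate-mean long series -> per-segment wide matrices
.series_segments <- function(series) {
  need <- c("species", "time_h", "count")
  if (!all(need %in% names(series))) {
    stop("series must have columns: ", paste(need, collapse = ", "))
  }
  if (any(series$count <= 0)) stop("abundances must be > 0")
  seg_col <- if ("passage" %in% names(series)) series$passage else 0L
  agg <- stats::aggregate(count ~ species + time_h + seg,
                          data = cbind(series, seg = seg_col), FUN = mean)
  sp <- sort(unique(agg$species))
  lapply(split(agg, agg$seg), function(d) {
    tt <- sort(unique(d$time_h))
    X <- matrix(NA_real_, length(tt), length(sp),
                dimnames = list(NULL, sp))
    for (s in sp) {
      ds <- d[d$species == s, ]
      X[match(ds$time_h, tt), s] <- ds$count
    }
    list(times = tt, X = X)
  })
}

#' Fit gLV parameters by ridge-regularised gradient matching
#'
#' Replicates are averaged at each time point. Within each passage segment
#' (dilution discontinuities are excluded by segmenting, not modelling),
#' the per-capita growth rate d ln x_i / dt is estimated by central finite
#' differences at interior grid points and regressed on `[1, x_1 .. x_n]`
#' by ridge-regularised least squares with a normalised (centred/scaled)
#' design; the intercept (r_i) is not penalised. Rescaling abundance units
#' by a constant rescales the interaction coefficients inversely and
#' leaves their signs unchanged.
#'
#' @param series long data.frame with columns `species`, `time_h`,
#'   `replicate`, `count` and optionally `passage`.
#' @param ridgePenalty ridge penalty on the standardised design
#'   (default 1e-3).
#' @param unit abundance unit tag carried into the result.
#' @return a [GLVParams-class].
#' @export
fitGLV <- function(series, ridgePenalty = 1e-3, unit = "CFU/mL") {
  segs <- .series_segments(series)
  sp <- colnames(segs[[1]]$X)
  n <- length(sp)
  rows_y <- vector("list", n)
  rows_X <- list()
  for (seg in segs) {
    tt <- seg$times
    if (length(tt) < 3) next
    X <- seg$X
    if (anyNA(X)) stop("inconsistent replicate/time structure in series")
    L <- log(X)
    interior <- 2:(length(tt) - 1)
    D <- (L[interior + 1, , drop = FALSE] - L[interior - 1, , drop = FALSE]) /
      (tt[interior + 1] - tt[interior - 1])
    rows_X[[length(rows_X) + 1]] <- X[interior, , drop = FALSE]
    for (i in seq_len(n)) {
      rows_y[[i]] <- c(rows_y[[i]], D[, i])
    }
  }
  if (length(rows_X) == 0) {
    stop("need at least 3 time points per passage segment")
  }
  Xall <- do.call(rbind, rows_X)
  nobs <- nrow(Xall)
  if (nobs < n + 1 && ridgePenalty <= 0) {
    stop("fewer observations (", nobs, ") than parameters (", n + 1,
         ") and no ridge penalty: supply ridgePenalty > 0")
  }
  mu <- colMeans(Xall)
  sdv <- apply(Xall, 2, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  Z <- sweep(sweep(Xall, 2, mu), 2, sdv, "/")
  ZtZ <- crossprod(Z)
  A <- matrix(0, n, n, dimnames = list(sp, sp))
  r <- setNames(numeric(n), sp)
  for (i in seq_len(n)) {
    y <- rows_y[[i]]
    ybar <- mean(y)
    yc <- y - ybar
    beta_s <- solve(ZtZ + ridgePenalty * diag(n), crossprod(Z, yc))
    beta <- beta_s / sdv
    A[i, ] <- beta
    r[i] <- ybar - sum(beta * mu)
  }
  glvParams(r, A, speciesIds = sp, unit = unit)
}

#' Classify interaction signs from fitted gLV parameters
#'
#' Off-diagonal coefficients with |a_ij| below the threshold are reported
#' as 0; the remaining ones as "+" or "-". The negative fraction is the
#' number of negative couplings over the number of non-zero off-diagonal
#' couplings, pooled across all supplied fits (e.g. one fit per inoculum
#' ratio).
#'
#' @param params a [GLVParams-class] or a list of them.
#' @param threshold absolute-coupling threshold; default
#'   `1e-6 * max(|A|)` per fit.
#' @return an [InteractionSummary-class]; when several fits are supplied,
#'   `signs` is the sign matrix of the first fit and the pooled counts
#'   cover all fits.
#' @export
interactionSigns <- function(params, threshold = NULL) {
  plist <- if (is(params, "GLVParams")) list(params) else params
  stopifnot(all(vapply(plist, is, logical(1), "GLVParams")))
  n_neg <- 0L
  n_nonzero <- 0L
  sign_mats <- lapply(plist, function(p) {
    A <- p@A
    thr <- if (is.null(threshold)) 1e-6 * max(abs(A)) else threshold
    s <- matrix(NA_character_, nrow(A), ncol(A), dimnames = dimnames(A))
    for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
      if (i == j) next
      s[i, j] <- if (abs(A[i, j]) < thr) "0" else if (A[i, j] < 0) "-" else "+"
    }
    n_neg <<- n_neg + sum(s == "-", na.rm = TRUE)
    n_nonzero <<- n_nonzero + sum(s %in% c("-", "+"), na.rm = TRUE)
    s
  })
  new("InteractionSummary", signs = sign_mats[[1]],
      fractionNegative = if (n_nonzero > 0) n_neg / n_nonzero else NA_real_,
      nNegative = as.integer(n_neg), nNonzero = as.integer(n_nonzero),
      allBelowThreshold = n_nonzero == 0L)
}
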