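# Shared fixtures: hand-built toy models and a brute-force LP oracle.

# single linear pathway: glucose uptake -> conversion (yield gDW/mmol) ->
# biomass; growth = yield * uptake rate
chain_model <- function(yield = 0.1, uptake_lb = -10) {
  stoichiometricModel(
    "chain",
    metabolites = data.frame(id = c("glc_e", "c"),
                             compartment = c("extracellular",
                                             "intracellular")),
    reactions = data.frame(id = c("EX_glc", "CAT_glc", "BIOMASS"),
                           lb = c(uptake_lb, 0, 0), ub = c(1000, 1000, 1000),
                           isExchange = c(TRUE, FALSE, FALSE),
                           isBiomass = c(FALSE, FALSE, TRUE)),
    stoichiometry = list(EX_glc = c(glc_e = -1),
                         CAT_glc = c(glc_e = -1, c = yield),
                         BIOMASS = c(c = -1))
  )
}

# two parallel routes of equal yield; the second is one reaction longer,
# so parsimonious FBA must route everything through the first
parallel_model <- function(uptake_lb = -10) {
  stoichiometricModel(
    "parallel",
    metabolites = data.frame(
      id = c("glc_e", "c", "m2"),
      compartment = c("extracellular", "intracellular", "intracellular")),
    reactions = data.frame(
      id = c("EX_glc", "SHORT", "LONG1", "LONG2", "BIOMASS"),
      lb = c(uptake_lb, 0, 0, 0, 0), ub = c(1000, 1000, 1000, 1000, 1000),
      isExchange = c(TRUE, FALSE, FALSE, FALSE, FALSE),
      isBiomass = c(FALSE, FALSE, FALSE, FALSE, TRUE)),
    stoichiometry = list(EX_glc = c(glc_e = -1),
                         SHORT = c(glc_e = -1, c = 0.1),
                         LONG1 = c(glc_e = -1, m2 = 1),
                         LONG2 = c(m2 = -1, c = 0.1),
                         BIOMASS = c(c = -1))
  )
}

# random small constraint-based model: <= 6 reactions, exchanges plus random
# internal conversions feeding a biomass reaction
random_small_model <- function(seed) {
  set.seed(seed)
  n_ex <- sample(1:2, 1)
  n_int <- sample(1:2, 1)
  n_conv <- sample(1:(6 - n_ex - 1), 1)
  ex_mets <- paste0("e", seq_len(n_ex))
  int_mets <- paste0("c", seq_len(n_int))
  mets <- data.frame(id = c(ex_mets, int_mets),
                     compartment = c(rep("extracellular", n_ex),
                                     rep("intracellular", n_int)))
  rxn <- list()
  st <- list()
  for (i in seq_len(n_ex)) {
    id <- paste0("EX_", ex_mets[i])
    rxn[[id]] <- data.frame(id = id, lb = -round(runif(1, 1, 10), 1),
                            ub = 1000, isExchange = TRUE, isBiomass = FALSE)
    st[[id]] <- setNames(-1, ex_mets[i])
  }
  for (k in seq_len(n_conv)) {
    id <- paste0("R", k)
    sub <- sample(c(ex_mets, int_mets), 1)
    prod <- sample(int_mets, 1)
    if (prod == sub) prod <- int_mets[1]
    coefs <- setNames(c(-1, round(runif(1, 0.05, 1), 2)), c(sub, prod))
    if (sub == prod) next
    rxn[[id]] <- data.frame(id = id, lb = 0, ub = 1000,
                            isExchange = FALSE, isBiomass = FALSE)
    st[[id]] <- coefs
  }
  bm_sub <- sample(int_mets, 1)
  rxn[["BIOMASS"]] <- data.frame(id = "BIOMASS", lb = 0, ub = 1000,
                                 isExchange = FALSE, isBiomass = TRUE)
  st[["BIOMASS"]] <- setNames(-1, bm_sub)
  stoichiometricModel(paste0("rand", seed), mets, do.call(rbind, rxn), st)
}

# brute-force LP oracle: enumerate basic solutions of
# max obj'v s.t. S v = 0, lb <= v <= ub (n - rank free vars at bounds)
lp_vertex_oracle <- function(obj, S, lb, ub) {
  n <- length(obj)
  qrS <- qr(S)
  m <- qrS$rank
  bestv <- -Inf
  k <- n - m
  if (k < 0) return(NULL)
  combs <- if (k == 0) list(integer(0)) else
    utils::combn(n, k, simplify = FALSE)
  for (fix in combs) {
    free <- setdiff(seq_len(n), fix)
    grid <- if (length(fix)) expand.grid(rep(list(1:2), length(fix))) else
      data.frame(row.names = 1)
    for (g in seq_len(max(1, nrow(grid)))) {
      v <- numeric(n)
      if (length(fix)) {
        v[fix] <- ifelse(unlist(grid[g, ]) == 1, lb[fix], ub[fix])
      }
      rhs <- -if (length(fix)) S[, fix, drop = FALSE] %*% v[fix] else
        numeric(nrow(S))
      sol <- tryCatch(qr.solve(S[, free, drop = FALSE], rhs),
                      error = function(e) NULL)
      if (is.null(sol) && length(free)) next
      if (length(free)) v[free] <- sol
      if (max(abs(S %*% v)) > 1e-6) next
      if (all(v >= lb - 1e-7) && all(v <= ub + 1e-7)) {
        bestv <- max(bestv, sum(obj * v))
      }
    }
  }
  bestv
}

fba_oracle <- function(model) {
  S <- stoichMatrix(model)
  b <- reactionBounds(model)
  obj <- as.numeric(model@reactions$isBiomass)
  lp_vertex_oracle(obj, S, b$lb, b$ub)
}

# a fast, scaled-down serial-transfer schedule for property tests
small_transfer <- function(nPassages = 3) {
  transferSpec(cycleHours = 24, nPassages = nPassages,
               dilutionFactor = 0.1, timestep = 0.2)
}
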