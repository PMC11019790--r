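## Integration of per-step exchange fluxes and inference of candidate
## interspecies metabolite exchanges.

.EDGE_EPS <- 1e-9   # mmol; below solver-leakage noise

#' Integrate secretion and uptake over an analysis window
#'
#' For every (species, metabolite) pair, sums positive fluxes (secretion)
#' and negative fluxes (uptake) over the steps falling inside the window,
#' each weighted by the species' integrated biomass-time in that step, so
#' the result is the amount moved in mmol. A species may show both
#' secretion and uptake of the same metabolite (transient reuptake).
#'
#' @param x a [Trajectory-class] or list of them (e.g. all six passages).
#' @param window `c(t0, t1)` in hours; defaults to the full span.
#' @return an [ExchangeTable-class].
#' @export
integrateExchanges <- function(x, window = NULL) {
  if (is(x, "Trajectory")) x <- list(x)
  span <- range(unlist(lapply(x, function(tr) range(tr@times))))
  if (is.null(window)) window <- span
  if (length(window) != 2 || window[1] >= window[2]) {
    stop("window must be an increasing pair c(t0, t1)")
  }
  if (window[1] < span[1] - 1e-9 || window[2] > span[2] + 1e-9) {
    stop("window must lie within the trajectory span [",
         span[1], ", ", span[2], "]")
  }
  sec <- NULL
  upt <- NULL
  for (tr in x) {
    nstep <- dim(tr@exchangeFlux)[1]
    tmid <- tr@times[seq_len(nstep)]       # step start times
    tend <- tr@times[seq_len(nstep) + 1]
    inw <- tmid >= window[1] - 1e-9 & tend <= window[2] + 1e-9
    if (!any(inw)) next
    fl <- tr@exchangeFlux[inw, , , drop = FALSE]
    bh <- tr@biomassHours[inw, , drop = FALSE]
    pos <- pmax(fl, 0)
    negv <- pmax(-fl, 0)
    # weight each step/species slice by biomass-hours
    for (m in seq_len(dim(fl)[3])) {
      pos[, , m] <- pos[, , m] * bh
      negv[, , m] <- negv[, , m] * bh
    }
    s <- apply(pos, c(2, 3), sum)
    u <- apply(negv, c(2, 3), sum)
    if (is.null(sec)) {
      sec <- s
      upt <- u
    } else {
      sec <- sec + s
      upt <- upt + u
    }
  }
  if (is.null(sec)) {
    tab <- data.frame(species = character(0), metabolite = character(0),
                      secretion = numeric(0), uptake = numeric(0))
  } else {
    tab <- data.frame(
      species = rep(rownames(sec), times = ncol(sec)),
      metabolite = rep(colnames(sec), each = nrow(sec)),
      secretion = as.vector(sec),
      uptake = as.vector(upt)
    )
    tab <- tab[tab$secretion > 0 | tab$uptake > 0, , drop = FALSE]
    rownames(tab) <- NULL
  }
  new("ExchangeTable", table = tab, window = window)
}

#' Infer the candidate interspecies exchange network
#'
#' An edge (producer, metabolite, consumer) exists when the producer's
#' integrated secretion and the consumer's integrated uptake of the
#' metabolite both exceed the noise floor (1e-9 mmol); its weight is the
#' conservative bound min(secretion, uptake). Edges whose metabolite is
#' absent from the fresh medium and not in the unlimited set are flagged
#' `mediumAbsent = TRUE` - these are the candidate cross-feedings; edges
#' over medium-supplied metabolites are kept with the flag FALSE, since
#' sharing a supplied nutrient is not an absolute interspecies exchange.
#' Secretions consumed by no other species are reported as dangling.
#'
#' @param table an [ExchangeTable-class].
#' @param fresh the fresh-medium [MediumState-class].
#' @param monoculture optional named list mapping species to an
#'   [ExchangeTable-class] from a monoculture run under identical
#'   settings; adds a `secretedInMonoculture` column marking whether each
#'   edge's producer also secretes the metabolite alone (i.e. the
#'   secretion is not an emergent community flux).
#' @return an [ExchangeNetwork-class].
#' @export
inferNetwork <- function(table, fresh, monoculture = NULL) {
  stopifnot(is(table, "ExchangeTable"))
  tab <- table@table
  producers <- tab[tab$secretion > .EDGE_EPS, , drop = FALSE]
  consumers <- tab[tab$uptake > .EDGE_EPS, , drop = FALSE]
  medium_has <- function(m) {
    (m %in% names(fresh@pools) && fresh@pools[[m]] > 0) ||
      m %in% fresh@unlimitedIds
  }
  rows <- list()
  for (i in seq_len(nrow(producers))) {
    m <- producers$metabolite[i]
    p <- producers$species[i]
    cons <- consumers[consumers$metabolite == m & consumers$species != p, ,
                      drop = FALSE]
    for (j in seq_len(nrow(cons))) {
      rows[[length(rows) + 1]] <- data.frame(
        producer = p, metabolite = m, consumer = cons$species[j],
        mmol = min(producers$secretion[i], cons$uptake[j]),
        mediumAbsent = !medium_has(m)
      )
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(producer = character(0), metabolite = character(0),
               consumer = character(0), mmol = numeric(0),
               mediumAbsent = logical(0))
  if (!is.null(monoculture)) {
    edges$secretedInMonoculture <- vapply(seq_len(nrow(edges)), function(i) {
      mt <- monoculture[[edges$producer[i]]]
      if (is.null(mt)) return(NA)
      tb <- mt@table
      any(tb$species == edges$producer[i] &
            tb$metabolite == edges$metabolite[i] &
            tb$secretion > .EDGE_EPS)
    }, logical(1))
  }
  consumed_mets <- unique(edges$metabolite)
  dang <- producers[!mapply(function(m, p) {
    any(edges$metabolite == m & edges$producer == p)
  }, producers$metabolite, producers$species), , drop = FALSE]
  dangling <- data.frame(species = dang$species,
                         metabolite = dang$metabolite,
                         mmol = dang$secretion)
  rownames(dangling) <- NULL
  new("ExchangeNetwork", edges = edges, dangling = dangling)
}

#' Write an exchange network as an edge list (and optional GraphML)
#'
#' @param network an [ExchangeNetwork-class].
#' @param path output path for the tab-delimited edge list.
#' @param graphml optional path; when given, a GraphML rendering of the
#'   bipartite species/metabolite graph is written for visualisation.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(network, path, graphml = NULL) {
  utils::write.table(network@edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml)) {
    e <- network@edges
    nodes <- unique(c(e$producer, e$consumer, e$metabolite))
    kind <- ifelse(nodes %in% c(e$producer, e$consumer), "species",
                   "metabolite")
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '<key id="kind" for="node" attr.name="kind" attr.type="string"/>',
      '<key id="mmol" for="edge" attr.name="mmol" attr.type="double"/>',
      '<graph edgedefault="directed">',
      vapply(seq_along(nodes), function(i) {
        sprintf('<node id="%s"><data key="kind">%s</data></node>',
                nodes[i], kind[i])
      }, character(1)),
      unlist(lapply(seq_len(nrow(e)), function(i) {
        c(sprintf('<edge source="%s" target="%s"><data key="mmol">%g</data></edge>',
                  e$producer[i], e$metabolite[i], e$mmol[i]),
          sprintf('<edge source="%s" target="%s"><data key="mmol">%g</data></edge>',
                  e$metabolite[i], e$consumer[i], e$mmol[i]))
      })),
      '</graph>', '</graphml>')
    writeLines(lines, graphml)
  }
  invisible(path)
}
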