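## Medium construction: limiting carbon pools from a complex-medium recipe.

#' Monoisotopic-free molecular weights (g/mol) of the 20 proteinogenic
#' amino acids, used to convert mass shares into molar pools.
#' @return named numeric vector, g/mol.
#' @export
aminoAcidWeights <- function() {
  c(ala = 89.09,  arg = 174.20, asn = 132.12, asp = 133.10, cys = 121.16,
    gln = 146.15, glu = 147.13, gly = 75.07,  his = 155.15, ile = 131.17,
    leu = 131.17, lys = 146.19, met = 149.21, phe = 165.19, pro = 115.13,
    ser = 105.09, thr = 119.12, trp = 204.23, tyr = 181.19, val = 117.15)
}

#' Default R2A-style component masses (g/L)
#'
#' A standard R2A recipe: 0.5 g/L each of proteose peptone, casamino acids,
#' yeast extract, glucose (dextrose), soluble starch and sodium pyruvate,
#' plus 0.3 g/L K2HPO4 and 0.05 g/L MgSO4. Only glucose and the peptide
#' components (peptone, casamino acids, yeast extract) feed the limiting
#' carbon pools; starch, pyruvate and the salts are treated as unlimited
#' unless explicitly declared limiting.
#' @return named numeric vector, g/L.
#' @export
r2aComponentMasses <- function() {
  c(peptone = 0.5, casamino_acids = 0.5, yeast_extract = 0.5, glucose = 0.5,
    starch = 0.5, pyruvate = 0.5, k2hpo4 = 0.3, mgso4 = 0.05)
}

#' Construct a MediumState directly from pools
#'
#' @param pools named numeric vector of finite pools, mmol.
#' @param unlimitedIds metabolite ids treated as unlimited.
#' @param limitingIds subset of pooled metabolites counted as limiting
#'   carbon sources; defaults to all pooled metabolites.
#' @param volumeML culture volume, mL.
#' @return a [MediumState-class].
#' @export
mediumState <- function(pools, unlimitedIds = character(0),
                        limitingIds = names(pools), volumeML = 10) {
  obj <- new("MediumState", pools = pools,
             unlimitedIds = as.character(unlimitedIds),
             limitingIds = as.character(limitingIds), volumeML = volumeML)
  validObject(obj)
  obj
}

#' Build the extracellular medium from a complex-medium recipe
#'
#' Glucose is converted to a molar pool from its mass concentration. The
#' total mass of the peptide components (peptone, casamino acids, yeast
#' extract) is split equally over the listed amino acids by weight, and
#' each share is converted to mmol by the amino acid's molecular weight.
#' Glucose and the amino acids form the limiting carbon pools; everything
#' in `unlimitedIds` is carried through as unlimited.
#'
#' @param componentMasses named numeric, g/L; recognised peptide components
#'   are `peptone`, `casamino_acids` and `yeast_extract`, and `glucose` is
#'   the sugar pool. Other components are ignored unless listed in
#'   `unlimitedIds`.
#' @param aminoAcids named numeric of molecular weights g/mol (ids become
#'   pool ids); defaults to the 20 proteinogenic amino acids. May also be a
#'   character vector of ids drawn from [aminoAcidWeights()].
#' @param unlimitedIds ids available without limit (inorganic ions, gases,
#'   growth factors).
#' @param volumeML culture volume, mL (default 10, a test-tube culture).
#' @param glucoseMW molecular weight of glucose, g/mol.
#' @return a [MediumState-class] with pools in mmol.
#' @examples
#' m <- buildMedium(c(glucose = 0.5), volumeML = 10)
#' pools(m)["glc"]  # 0.5 g/L / 180.16 g/mol * 0.01 L * 1000 = 0.02775 mmol
#' @export
buildMedium <- function(componentMasses = r2aComponentMasses(),
                        aminoAcids = aminoAcidWeights(),
                        unlimitedIds = c("nh4", "pi", "h2o", "o2", "h",
                                         "starch", "pyruvate", "k2hpo4",
                                         "mgso4"),
                        volumeML = 10, glucoseMW = 180.16) {
  if (any(componentMasses < 0)) stop("component masses must be >= 0")
  if (volumeML <= 0) stop("volume must be > 0")
  if (is.character(aminoAcids)) {
    known <- aminoAcidWeights()
    bad <- setdiff(aminoAcids, names(known))
    if (length(bad)) {
      stop("unknown amino acid id(s) with no molecular weight: ",
           paste(bad, collapse = ", "))
    }
    aminoAcids <- known[aminoAcids]
  }
  if (length(aminoAcids) && (is.null(names(aminoAcids)) ||
                             any(!nzchar(names(aminoAcids))))) {
    stop("aminoAcids must be a named vector of molecular weights")
  }
  if (any(aminoAcids <= 0)) stop("amino acid molecular weights must be > 0")
  peptide_components <- c("peptone", "casamino_acids", "yeast_extract")
  peptide_mass <- sum(componentMasses[intersect(names(componentMasses),
                                                peptide_components)])
  if (peptide_mass > 0 && length(aminoAcids) == 0) {
    stop("peptide components present but the amino-acid list is empty")
  }
  liters <- volumeML / 1000
  pools <- numeric(0)
  glc_mass <- if ("glucose" %in% names(componentMasses)) {
    componentMasses[["glucose"]]
  } else {
    0
  }
  pools["glc"] <- glc_mass / glucoseMW * liters * 1000
  if (length(aminoAcids)) {
    share <- peptide_mass / length(aminoAcids)      # g/L per amino acid
    aa_pools <- share / aminoAcids * liters * 1000  # mmol
    pools <- c(pools, aa_pools)
  }
  mediumState(pools, unlimitedIds = unlimitedIds,
              limitingIds = names(pools), volumeML = volumeML)
}

#' Mix a carried-over culture medium with fresh medium
#'
#' Models the serial transfer of `transferFraction` of the spent culture
#' into `1 - transferFraction` of fresh medium at constant volume:
#' `pools' = f * current + (1 - f) * fresh`.
#'
#' @param current,fresh [MediumState-class] objects over the same
#'   metabolite universe, volume and unlimited set.
#' @param transferFraction fraction of the old culture carried over,
#'   in (0, 1].
#' @return the mixed [MediumState-class].
#' @export
refreshMix <- function(current, fresh, transferFraction) {
  stopifnot(is(current, "MediumState"), is(fresh, "MediumState"))
  if (transferFraction <= 0 || transferFraction > 1) {
    stop("transferFraction must be in (0, 1]")
  }
  if (!setequal(names(current@pools), names(fresh@pools)) ||
      !setequal(current@unlimitedIds, fresh@unlimitedIds)) {
    stop("mismatched metabolite universes between current and fresh medium")
  }
  if (abs(current@volumeML - fresh@volumeML) > 1e-9) {
    stop("current and fresh medium must share the same volume")
  }
  f <- transferFraction
  fr <- fresh@pools[names(current@pools)]
  mediumState(f * current@pools + (1 - f) * fr,
              unlimitedIds = current@unlimitedIds,
              limitingIds = current@limitingIds,
              volumeML = current@volumeML)
}

#' Dump a medium state as a delimited table
#'
#' @param medium a [MediumState-class].
#' @return data.frame with columns `metabolite`, `mmol`, `limiting`.
#' @export
mediumTable <- function(medium) {
  data.frame(metabolite = names(medium@pools),
             mmol = unname(medium@pools),
             limiting = names(medium@pools) %in% medium@limitingIds)
}
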