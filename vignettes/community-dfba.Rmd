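---
title: "Methods: serial-transfer community dFBA, calibration, and interaction inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serial-transfer community dFBA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syncomfba)
```

# Scope and model

`syncomfba` simulates the assembly of a small bacterial community under a
serial growth-dilution regime and infers interaction structure from the
simulated (or measured) dynamics. The package treats each species as a
stoichiometric metabolic model, the culture as a well-mixed batch with
finite nutrient pools, and the passaging regime as a deterministic
dilution operator. All stochastic elements live in the synthetic-data
generator, never in the simulator.

## Flux balance analysis

Growth of one species at one instant is the linear program

$$\max v_{\mathrm{biomass}} \quad \text{s.t.} \quad S v = 0,\; lb \le v \le ub,$$

where $S$ is the metabolites-by-reactions stoichiometric matrix and the
biomass flux has units 1/h. Exchange reactions carry one extracellular
metabolite with coefficient $-1$, so positive flux secretes and negative
flux takes up (the COMETS/SBML convention); all downstream bookkeeping
relies on this sign convention. Parsimonious FBA (pFBA) re-solves with
the biomass flux fixed at its optimum (relative tolerance $10^{-9}$) and
minimises $\sum_j |v_j|$ via the standard split into non-negative
forward/reverse components. pFBA is used inside every dFBA step so the
reported exchange fluxes are unique: degenerate alternate optima of the
growth LP would otherwise make the inferred exchange network an artifact
of solver internals.

Both LPs run on a dense two-phase simplex implemented in C++ in the
package. The choice is deliberate: the models this package targets are
toy- to mid-scale (tens of reactions), where a dense tableau solves in
microseconds, carries no external solver dependency, and — with
most-negative-cost pricing switching to Bland's rule after a burn-in —
terminates deterministically with ties broken in the model's reaction
order. Feasibility and optimality tolerances are $10^{-9}$; the test
suite checks the solver against brute-force vertex enumeration of the
feasible polytope on networks of up to six reactions, and checks mass
balance $\max |S v| \le 10^{-6}$ on every reported optimum.

## Batch dynamic FBA

The community state is per-species dry mass $X_i$ (gDW) plus a vector of
extracellular pools (mmol) in a fixed culture volume (default 10 mL).
One step of length $\Delta t$ (default 0.1 h):

1. **Uptake bounds.** For a pooled metabolite $m$, species $i$ may draw
   at most $\min(r_{im},\, a_{im})$ mmol/gDW/h, where $r_{im}$ is the
   species' limiting-carbon uptake rate for limiting nutrients (glucose
   and amino acids) or its default Vmax (10 mmol/gDW/h) otherwise, and
   $a_{im}$ is the availability cap. Availability is shared between
   competing consumers in proportion to instantaneous demand
   $X_i r_{im}$:
   $a_{im} = P_m\, r_{im} / (\sum_j X_j r_{jm}\,\Delta t\, g_i \cdot 1.0001)$.
   With a single consumer this reduces to the plain cap
   $P_m/(X_i \Delta t \cdot 1.0001)$; with several it guarantees the
   joint draw cannot push a pool negative, which a purely per-species
   cap cannot. Metabolites in the unlimited set are bounded only by the
   default Vmax. A Michaelis–Menten (Monod) uptake form is deliberately
   not the default: no half-saturation constants are part of the study
   conditions, and the hard cap reproduces batch depletion exactly and
   testably.

2. **Growth.** Each species' pFBA is solved; an infeasible LP is treated
   as starvation (zero growth for the step, with a warning), not death —
   the regime has no maintenance drain or death rate.

3. **Update.** Biomass advances exponentially,
   $X_i \leftarrow X_i e^{\mu_i \Delta t}$, and each pool by the exact
   integral of a constant per-gDW flux over exponentially growing
   biomass:
   $\Delta P_m = \sum_i v_{im} X_i\, g(\mu_i)\, \Delta t$, with
   $g(\mu) = (e^{\mu \Delta t} - 1)/(\mu \Delta t) \to 1$ as
   $\mu\Delta t \to 0$. This quadrature makes the substrate/biomass
   books close exactly (the test suite audits consumed + remaining =
   initial to $10^{-6}$ relative), where a plain Euler pool update would
   leak $O(\mu \Delta t / 2)$ per step. Because $\mu$ is only known
   after the LP solve, the availability caps use a growth-factor
   estimate carried between steps and the step is re-solved in the rare
   case the realised factor exceeds it — so the no-overdraw guarantee
   survives the quadrature. Pools are clamped to zero only for residual
   negativity below $10^{-9}$ mmol; anything larger aborts as a
   simulation-integrity error rather than being papered over.

4. **Serial transfer.** After each 48 h cycle, biomass scales by the
   dilution factor (0.1) and the medium becomes
   $0.1 \times \mathrm{spent} + 0.9 \times \mathrm{fresh}$, i.e. volume
   is held fixed across the 1 mL into 9 mL transfer. Passages are
   indexed P0..P5, so the default six passages mirror the experimental
   regime; the reported final composition is read at the end of the last
   growth cycle, before any further dilution (composition is invariant
   under dilution in any case).

Timestep convergence is a tested property (halving $\Delta t$ moves the
final per-species biomass of the default toy community by less than
1 %), not an assumption.

## Medium construction

The complex-medium rule: glucose contributes
$\mathrm{mass}/\mathrm{MW} \times \mathrm{volume}$ mmol; the total mass
of the peptide components (peptone, casamino acids, yeast extract) is
split **equally by weight** over the amino-acid list and converted per
amino acid by its molecular weight. The amino-acid list defaults to the
20 proteinogenic amino acids with standard molecular weights, since the
source recipe names "amino acids" without enumerating them; the list and
all component masses are overridable, and every quantitative test
parameterises them explicitly. Starch, pyruvate and salts are treated as
unlimited unless declared limiting, because only glucose and amino acids
are designated limiting carbon sources in this regime.

## Uptake-rate calibration

The calibration searches the limiting-carbon uptake rates of the
adjustable species (default: all but the species with the largest
reference fraction) over the decrement grid starting at 10 mmol/gDW/h:
joint descent by 1 down to 1, then by 0.1, evaluating the full
six-passage simulation after every move; when a species' achieved
fraction falls below 95 % of its reference, its rate returns to the last
value and descends again with 0.01 and then 0.001 decrements. The search
terminates when every species' achieved/reference ratio lies in
[0.95, 1.05].

Decisions taken where the procedure is underdetermined:

* **Evaluation cadence.** The simulation is evaluated after every
  decrement (not only at phase boundaries); this is the only reading
  under which "returned to the last value" is well defined for every
  step size.
* **Per-species refinement order** is ascending reference fraction
  (rarest first): the rarest species' fraction is the most sensitive to
  everyone's rates, so fixing it first minimises re-work, and repeated
  sweeps handle residual cross-talk. Species may therefore end at
  different rates; the joint sweep is only phase 1.
* **Undershoot vs overshoot.** Only undershoot (ratio < 0.95) triggers
  backtracking; overshoot simply continues the descent, mirroring the
  one-sided wording of the stopping rule.
* **Ascent extension.** If the very first evaluation already undershoots
  for an adjustable species — possible on randomised toy communities
  whose reference lies above the fraction reachable at the start rate —
  the refinement is allowed to step that species' rate *upward* on the
  same grid. A descent-only search would simply fail there; the
  extension preserves grid membership and the stopping rule.
* **Budget.** At most 500 simulations (grid-size bound); evaluations are
  memoised on the rate vector, and `converged` is by definition
  equivalent to all band ratios lying in the band.

The reference composition for the bundled reproduction recipe is the
stabilised qPCR ratio 1.0 : 0.126 : 0.013 (fractions 0.8780, 0.1106,
0.0114). Note an accepted consequence of the band: two species
individually within ±5 % of their reference fractions can have a
pairwise ratio up to ~10 % off; the calibration targets fractions, not
ratios.

## Exchange-network inference

Per-step exchange fluxes are integrated over an analysis window (default
all passages) into secretion and uptake totals per (species, metabolite),
using each step's integrated biomass-time so amounts are exact. An edge
(producer, metabolite, consumer) requires both totals to exceed an
$\varepsilon = 10^{-9}$ mmol noise floor — below LP-tolerance leakage —
and is weighted by min(secretion, uptake): in a well-mixed pool,
molecule-level attribution is ill-posed, so the conservative bound is
reported rather than a flux-tracking estimate. Metabolites absent from
the fresh medium (and not unlimited) mark the candidate interspecies
exchanges; medium-supplied metabolites yield edges flagged
`mediumAbsent = FALSE`, since shared consumption of a supplied nutrient
is not an absolute exchange. A monoculture baseline can be attached to
flag secretions that are not emergent community fluxes. Secretions with
no consumer are reported as dangling rather than dropped.

## Generalized Lotka–Volterra fitting

`simulateGLV()` integrates $\dot x_i = x_i (r_i + \sum_j a_{ij} x_j)$
with an adaptive solver in log abundance (trajectories stay positive by
construction; genuinely divergent systems abort with a finite-time
diagnostic instead of returning overflow). `fitGLV()` uses gradient
matching: replicate-averaged series, central finite differences of
$\ln x_i$ at interior grid points, and ridge-regularised least squares
of those derivatives on $[1, x_1, \dots, x_n]$ with a centred/scaled
design (intercept unpenalised, default penalty $10^{-3}$). Dilution
events are handled by segmenting the series at passages — the gLV model
has no dilution term, so the 10× drops are excluded from differencing
rather than modelled. Unit changes rescale $a_{ij}$ inversely and leave
signs unchanged (a tested invariance). A practical identifiability note
encoded in the tests: a single trajectory explores a one-dimensional
path through state space and cannot pin down a full interaction matrix;
accurate recovery needs several inoculum ratios, which is exactly what
the multi-ratio experimental design provides.

`interactionSigns()` zeroes couplings below $10^{-6} \times \max|A|$ and
pools the negative fraction over all supplied fits; when nothing clears
the threshold the summary is flagged degenerate instead of reporting a
fraction.

## The synthetic community generator

`makeToyCommunity()` builds the three-species testbed the pipeline is
validated on. Design:

* **Niche structure.** All species consume a shared glucose pool; each
  species additionally owns one private amino-acid pool (alanine,
  proline, methionine for the three species). The private pools act as
  finite species-specific niches: once a pool is fully consumed within a
  cycle, the biomass it supports is independent of the inoculum, which
  gives the community a genuine compositional attractor — the mechanism
  behind the inoculum-ratio convergence experiments. The shared pool is
  what the calibrated uptake rates compete over, giving the calibration
  a smooth, monotone handle on the final fractions.
* **Pools and yields.** Defaults (10 mL): glucose 0.020 mmol, private
  pools 0.030 / 0.0042 / 0.00042 mmol, yields 0.05 gDW/mmol. These were
  chosen once so that (i) the dominant species ends near 88 % of roughly
  2.8 mg total dry mass, matching the reference composition's scale of
  asymmetry, (ii) at the start rate of 10 mmol/gDW/h the two minority
  fractions sit *above* their reference values so the descent grid can
  reach the band, and (iii) growth completes well within a 48 h cycle.
* **Planted cross-feeding** is realised as growth-coupled byproduct
  secretion: the biomass reaction co-produces the secreted metabolite at
  a fixed stoichiometry (mmol/gDW), so the secretion survives pFBA's
  flux minimisation; optional secretion routes would be zeroed by the
  $L_1$ objective and make planted-topology tests meaningless. The
  default topology is four consumed edges (putrescine from the dominant
  species to both partners, xanthine to one, glycerol returned) plus one
  dangling hypoxanthine secretion.
* **Randomisation.** A seed drives mild lognormal jitter (CV 0.08) of
  pools and yields; generators are pure functions of (spec, seed) and
  restore the caller's RNG stream.
* **Count series.** `makeCountSeries()` converts biomass to counts/mL
  with 5×10¹¹ counts/gDW (mapping the 3.9×10⁻⁷ gDW inoculum in 10 mL to
  ~2×10⁷ counts/mL, a convenience mapping, not a biological claim),
  applies mean-one multiplicative lognormal noise per replicate
  (default 3 replicates, CV 0.1), floors at a detection limit, and tags
  the assay (CFU or qPCR; the two are the same semantic type here — no
  live/dead correction is attempted).

What the toy community does **not** emulate: genome-scale reaction
content, realistic byproduct chemistry, lag phases, death, pH or any
spatial structure. Passing the end-to-end tests therefore demonstrates
that the pipeline's logic is correct on systems whose ground truth is
known, not that any particular real community behaves this way.

## Growth statistics

µ_max is the least-squares slope of $\ln(X/X_0)$ versus time over a
deterministically selected window: all contiguous windows of ≥ 3
replicate-mean points with positive slope are scanned and the maximal
$r^2$ wins, ties going to the longer and then the earlier window. The
scan rule is the package's own (no window policy is standard), chosen
for reproducibility over judgment; it is greedy for high local $r^2$, so
with dense noisy sampling a minimum window of 4–5 points is the more
robust setting. The null-model productivity comparison weights
monoculture yields by initial inoculum fractions by default (equal
weights optional), pairs replicates by index, and reports the
observed/expected ratio with a two-sided Welch test.

## Problem sizes and runtime

The package's own test runs use the full study conditions — 48 h cycles,
six passages, dilution 0.1, timestep 0.1 h (2,880 steps, ~18,000 LP
solves per community simulation) — for the acceptance-style end-to-end
checks, and a reduced schedule (24 h cycles, three passages, timestep
0.2 h) for property sweeps that repeat calibration or simulation across
many seeds. The reduced schedule preserves every mechanism (depletion,
transfer, competition) at roughly 1/20 the cost; all stated tolerances
are evaluated at the conditions under which each test runs.

## Known limitations

* Uptake kinetics are hard caps, not saturating; sub-timestep depletion
  is handled by the availability cap rather than event detection.
* The calibration assumes the final fractions respond monotonically to
  the adjustable rates; a non-monotone landscape terminates at the
  evaluation budget with `converged = FALSE` and the best rates found.
* Exchange-network edge weights are conservative bounds, not attributed
  molecule flows.
* gLV fitting from a single trajectory is ill-conditioned by nature;
  supply several inoculum conditions.
* The simplex solver is dense and intended for toy- to mid-scale models;
  genome-scale models would need a sparse external LP backend behind the
  same `fba()`/`pfba()` interface.
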