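---
title: "Modelling the survival/death switching response of beta-adrenergic signalling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the survival/death switching response of beta-adrenergic signalling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Cardiomyocytes respond to catecholamines through two beta-adrenergic
receptor (beta-AR) subtypes. Chronic stimulation is linked to cardiomyocyte
death and heart failure, yet low agonist concentrations can protect cells.
`barswitch` models the hypothesis that this dual behaviour is a genuine
*switching response* of a single signalling network: the anti-apoptotic
protein Bcl-2 rises above its basal level at nanomolar isoproterenol (ISO)
and falls to roughly half its basal level in the micromolar range, so the
same ligand promotes survival or death depending only on its concentration.

The mechanistic core is an incoherent feed-forward loop. A fast positive
arm (beta2-AR/Gi -> Shc/SOS/Grb2 -> Ras -> Raf -> MEK -> ERK1/2 -> RSK/MSK
-> CREB) saturates at low agonist and drives Bcl-2 transcription. A
delayed negative arm (cAMP -> PKA -> CREB -> ICER) engages only at high
agonist; the induced repressor ICER shuts the Bcl-2 promoter down. A
central feedback module couples the two: ICER also represses the
phosphodiesterase PDE3, and the loss of cAMP degradation ignites a
positive feedback (more cAMP -> more PKA -> more CREB -> more ICER ->
even less PDE3) that makes the death arm switch-like in dose.

## The full network model

The shipped model (`bar_full_model()`, declarative description in
`bar_model_file()`) has 32 dynamic state variables and exactly 105 kinetic
parameters organised in four modules: cAMP/PKA signalling, the central
CREB/ICER/PDE3 feedback, ERK1/2 signalling, and Ca2+ regulation. The
count pair (32, 105) is enforced at build time so any editing error in the
model file surfaces as a validation failure.

The equation set is a *synthetic reconstruction*: rate laws, parameter
values and pool totals were chosen by us so that the model reproduces the
qualitative and quantitative behaviour reported for this network
(monotone PKA/p-CREB/p-ERK/ICER dose responses at 24 h, a decreasing PDE3
dose response, a switching Bcl-2 profile with a nanomolar interior peak
and a ~50% terminal level, an eight-link essential core, beta-blocker
shifts of the survival range, arm-specific effects of graded
feed-forward inhibition, and a rise-then-fall Bcl-2 trajectory under a
clamped cAMP analogue). It is *not* a transcription of any published
parameter table, and individual rate constants should not be quoted as
measured quantities.

Conventions: intracellular concentrations in uM, time in hours,
agonist/antagonist doses in molar. Conserved protein pools (receptors, G
proteins, kinase cascades, Ca2+ handling proteins) are modelled with one
dynamic "active" state whose inactive complement is the pool total minus
the active form, so conservation holds exactly along any trajectory.
Fold-change readouts are reported relative to the basal (unstimulated)
steady state, obtained by pre-equilibrating the model for at least 200 h
at dose zero and polishing with Newton iteration.

Two implementations of the right-hand side exist: a compiled C version
(used by default for the shipped model) and an interpreted evaluator of
the declarative reaction list, used for toy models, steady-state
polishing, and as the reference in cross-checking tests. The integrator
is `deSolve::lsoda` with rtol 1e-6 and atol 1e-9; halving the tolerances
moves the Bcl-2 dose response by less than 0.1%.

```{r}
library(barswitch)
model <- bar_full_model()
curve <- dose_response(model)          # Bcl-2 at 24 h, 1e-12..1e-3 M
classify_switching(curve)
```

## The switching classifier

A dose-response curve "switches" when its fold change over basal reaches
`theta_up` (default 1.2) at a strictly interior grid dose and its value at
the maximal dose has fallen to `theta_down` (default 0.8) or below.
The reported phenotype fixes no quantitative meaning for "increase" and
"decrease below basal", so both thresholds are explicit arguments
everywhere, and screen results are reported as functions of them. The *survival range* is the widest
contiguous dose interval with fold change at or above `theta_up`, with
edges interpolated linearly in log10(dose) — dose-response structure is
approximately log-linear between grid points, so interpolation on the
log axis is the natural choice.

## Coarse-graining and the circuit screen

`coarse_grain()` clusters the 32 species into six functional units (PKA,
ERK, ICER, PDE, Bcl-2, Ca) and derives the directed, signed inter-unit
links from the reaction list: a link exists when a reaction changing a
species of one unit carries a rate factor in a species of another, with
the sign given by the factor's monotonicity. On the shipped model this
yields exactly 15 links; parallel same-signed couplings merge. Each link
gates one or more kinetic parameters (for inhibitory links a dimensionless
potency factor exists solely so that zeroing it removes the inhibition
rather than the target reaction), and `knockout_links()` sets the gated
parameters of disconnected links to zero.

`screen_full()` enumerates all on/off combinations of a chosen link
subset, recomputes basal state and Bcl-2 dose response per rewiring, and
classifies switching. `essential_links()` extracts, under the default
necessity criterion, the links that are on in *every* switching-capable
rewiring. On this model the essential set is
`ISO->PKA, PKA->ERK, PKA->Bcl2, Bcl2->ICER, ICER-|Bcl2, ICER-|PDE,
PDE-|PKA, ERK->Bcl2` — eight links forming the incoherent feed-forward
loop plus the PDE-mediated ignition feedback — while the seven remaining
links (Raf inhibition by PKA, acute PDE3 activation, and the Ca2+-module
couplings) can be removed in any combination without losing the
switching phenotype. Screening all 2^15 rewirings takes hours on one
CPU; the shipped tests and the acceptance script therefore screen reduced
registries (the eight core links plus two modulators, 2^10 rewirings, or
smaller), which exercises the same machinery and recovers the same
eight-link core. The screen supports checkpoint files and deterministic
partitioning by mask index for distributed execution.

## The simplified five-node model

`build_simplified()` implements the non-dimensional five-node model (PKA,
PDE, ERK, ICER, Bcl-2) over the eight core links:

tau_x dx/dt = beta_x * prod(activations) * prod(inhibitions) + b0_x - x

with Hill activation u^n/(K^n + u^n) per incoming activation and Hill
inhibition Ki^n/(Ki^n + y^n) per repression, combined multiplicatively
(AND gating; additive gating was considered and rejected as the default
because the multiplicative form is the natural composition of saturating
regulatory factors). Off-links drop their factor; a node whose activators
are all off falls back to basal production b0 = 0.1 * beta. The basal
production term exists so that "below basal" remains meaningful when
simulating from zero initial conditions; 0.1 is a configuration default
(`b0_frac`). PDE carries constitutive production (it has no activating
link), matching the constitutive PDE3 synthesis of the full model.

`robustness_screen()` evaluates all 256 rewirings of the eight links
against log-uniformly sampled parameter sets (tau in [10, 1000], n in
[1, 10], K and Ki in [0.01, 1], beta in [0.1, 10]), integrating each cell
from zero initial conditions to steady state (adaptive Cash-Karp RK45 in
C, convergence when every node balances its production to 1e-6 relative)
over a stimulus grid spanning 1e-3..1e1, and counts parameter sets whose
Bcl-2 dose response switches. Per-cell switching is rare (the
all-links-on circuit switches for roughly 0.5% of random parameter sets),
so rankings need a thousand or more parameter sets before the top of the
table stabilises; the package defaults and the acceptance script use
1000, and the full-scale reference condition is 10,000. The `has_iffl`
column annotates circuits containing the complete ERK/ICER incoherent
feed-forward loop (stimulus into both arms, ERK->Bcl2 positive,
PKA->ICER-|Bcl2 negative).

At 10,000 parameter sets the two most robust structures are decisively
the minimal ERK/ICER feed-forward circuits (switching rate ~1.8%,
several standard errors above everything else). Below rank two the table
is nearly degenerate: feed-forward variants that add the PDE arm
(~1.26%) sit within sampling noise of a *PKA-mediated* incoherent
feed-forward family (S->PKA->Bcl2 with PKA->ICER-|Bcl2, no ERK arm;
~1.22%). Under steady-state readout and multiplicative gating, a single
pathway can serve as both arms of an incoherent loop almost as robustly
as two separate pathways, so statements about "the top four" structures
are resolution-limited at any affordable sample size — a known
limitation of this realisation that the acceptance test reports rather
than hides.

## Fitting and sensitivity analysis

`fit_parameters()` minimises the sum of squared differences between
simulated and observed time courses with an elitist genetic algorithm on
log-scaled parameters (tournament selection, uniform crossover, Gaussian
log-space mutation; population 40 and 30 generations by default — a
desk-scale setting, deliberately far from cluster-scale fits). Each
observable is normalised to its own maximum before differencing because
immunoblot-style data carry fold-change information only; the consequence
is that purely amplitude-setting parameters of unobserved species are not
identifiable, and recovery benchmarks must observe the species whose
kinetics they probe.

The sensitivity metric is the trapezoidal integral of Bcl-2 over 24-48 h
under 1 uM ISO (`bcl2_metric()`). `lsa()` reports elasticities (percent
metric change per 1% parameter change, forward difference by default).
`gsa_report()` draws Sobol points (own base-2 Gray-code implementation,
direction numbers after Joe & Kuo, cross-checked in development against
an independent implementation), mapped log-uniformly onto
[p/fold, p*fold] around each nominal value — "a 10-fold range around
nominal" is read as ten-fold in each direction, the log-symmetric
interpretation — and computes partial rank correlation coefficients by
the rank-regression residual construction. The tests verify PRCC against
an independent precision-matrix formulation to 1e-10.

## Interventions

Receptor blockers are purely competitive and subtype-exclusive: occupancy
of the targeted subtype becomes (L/K_L)/(1 + L/K_L + I/K_I), so the
agonist EC50 of the isolated binding step shifts by exactly the Schild
factor 1 + I/K_I. Default dissociation constants (1e-7 M for the beta1
blocker, 1e-9 M for the beta2 blocker) are configuration values in the
published affinity range of metoprolol and ICI 118,551. On the default
model the beta1 blocker widens the survival range by shifting its upper
edge to higher ISO, and the beta2 blocker narrows it from both sides
(weaker ERK arm, disinhibited adenylyl cyclase). An optional
Gi-uncoupling mechanism for the beta2 blocker was considered and left
out: the competitive mechanism already reproduces the reported
directionality, and the extra mechanism has no constraining observation.

Graded arm inhibition (`scale_link()`) multiplies gated parameters by a
factor in [0, 1]; factor 0 equals a knockout. ICER-arm relief raises
Bcl-2 only at micromolar ISO (at nanomolar doses ICER is not induced, so
there is nothing to relieve); ERK-arm inhibition lowers Bcl-2 across the
nanomolar range. Readout times follow the corresponding protocols: 12 h
for arm-inhibition comparisons, 24 h for blocker curves.

`pka_inhibitor_scan()` scales PKA activation by 1/(1 + I/K_I) and reads
Bcl-2 at 12 h under 1 uM ISO. Read along decreasing inhibition
(increasing cAMP/PKA flux) the profile rises and then falls, and under
saturating inhibition the Bcl-2 dose response loses its switching shape
entirely (the beta2->Gi coupling that feeds the ERK arm is itself
PKA-licensed, so full PKA inhibition silences both arms). A small
residual ISO response (of order tens of percent of basal) survives
saturating inhibition through the receptor-driven cAMP pool; the tests
therefore assert the disappearance of switching and the rise-fall flux
profile rather than exact basal pinning.

`camp_clamp()` holds the cAMP state at a fixed level, bypassing receptor
input and PDE degradation, emulating a degradation-resistant cAMP
analogue; level 0 means no analogue (the unperturbed control). A high
clamp produces an early Bcl-2 rise (CREB activation outruns ICER
accumulation) followed by a fall below basal as ICER accumulates — the
duration of the cAMP signal, not only its strength, selects the outcome.

## Synthetic data

`generate_timecourses()` draws multiplicative log-normal noise (meanlog
0, so the *median* replicate equals the clean trajectory; sdlog =
sqrt(log(1 + CV^2))) around simulated time courses at the default doses
10 pM / 10 nM / 10 uM and sampling times 0-48 h (dense early, sparse
late), then summarises replicates as mean and s.e.m. Log-normal noise
was chosen because densitometry-style readouts are positive and
fold-change scaled. The default CV of 0.2 is a stand-in magnitude, not a
measured value. Manifests record the generating parameters, seed and
checksums so datasets can be regenerated byte-identically.
`generate_curves()` builds labelled dose-response shapes (including
switching curves constructed to satisfy the classifier definition) for
validating the classifier against ground truth.

What synthetic data do not capture: real blots have correlated
within-gel errors, saturation at high signal, and background
subtraction artefacts; passing recovery tests on synthetic data
demonstrates the estimator machinery, not robustness to those real-data
pathologies.

## Parameter-jitter robustness, honestly stated

`ensemble_dose_response()` repeats the dose response under multiplicative
uniform jitter (factors in [1 - v, 1 + v], independent per parameter and
replicate). Hill exponents are excluded from jitter by default
(`jitter_hill = FALSE`): cooperativity coefficients are structural, and
multiplicative jitter on an exponent of 10 swings tail activations by
orders of magnitude, which no kinetic measurement uncertainty motivates.
Under the reference condition (n = 30 replicates, up to 30% jitter on
all 98 rate/affinity constants) the *majority* of replicates — typically
two thirds — retain the switching classification; the failures split
between replicates whose ignition feedback never fires (terminal fold
stays above 0.8) and replicates that ignite already at basal. A
bistable ignition window cannot be made immune to +/-30% joint variation
of every constant, and we report the majority statistic rather than
claiming universal per-replicate robustness. The deterministic curve,
the essential-link structure, and all intervention directions are stable
across these ensembles.

## Numerical choices and limitations

* Stiff-capable adaptive integration everywhere; compiled right-hand
  sides for the two hot paths (full network, simplified-model screen).
* Steady states by long-time integration plus damped Newton polishing;
  states with no remaining dynamics (knocked-out receptors) are pinned
  to keep the Newton system solvable. Non-convergence is an error that
  reports the residual.
* Non-negativity: rate laws evaluate states clipped at zero; trajectories
  below -1e-6 uM abort with an error, and smaller negative excursions are
  clipped in the output.
* Problem sizes in tests and the acceptance script are scaled down from
  the full-scale reference conditions (2^10 instead of 2^15 rewirings
  for the necessity screen; 1000 instead of 10,000 parameter sets for
  the robustness table); both scales are stated where they are used, and
  the machinery is identical.
* The Ca2+ module is deliberately shallow (no excitation-contraction
  electrophysiology): it exists to carry the modulatory couplings of the
  coarse-grained graph, and its species are reported, not calibrated.
* SBML export writes genuine Level 3 documents (species, parameters,
  reactions with MathML kinetic laws) plus a structured annotation of
  the declarative description; import reconstructs the model from that
  annotation and cross-checks it against the SBML lists, i.e. the
  importer reads the subset of SBML this package writes.
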