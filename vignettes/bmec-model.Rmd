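---
title: "A mechanistic multi-pathway model of brain microvascular endothelial cell signaling under oxygen-glucose deprivation and reoxygenation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BMEC signaling model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmecsim)
```

## The biological problem

Brain microvascular endothelial cells (BMECs) form the blood-brain
barrier. After an ischemic stroke with reperfusion — modeled in vitro as
oxygen-glucose deprivation followed by reoxygenation (OGD/R) — BMECs
integrate inflammatory ligands, growth factors, oxygen and glucose
availability, and internally generated free radicals into a cell-fate
decision: barrier maintenance and survival versus inflammation, tight
junction loss and apoptosis. `bmecsim` implements a mechanistic
ordinary-differential-equation model of this decision and the analysis
stack around it: quiescent steady-state construction, OGD/R protocol
simulation, biomarker scoring, global sensitivity analysis, virtual-cell
cohort screening, and parameter calibration against time-course data.

## Model structure

The network couples five pathway modules around a shared oxidative-stress
core:

* **Inflammation.** TNFa and LPS activate TNFR and TLR4; the activated
  receptors drive TRAF6 and RIPK1 ubiquitination, converging on
  TAK1 and IKK phosphorylation, dissociation of the IkB-NFkB complex,
  nuclear NFkB, and synthesis of IL-6, IL-1b, CCL2, A20 and IkB mRNA.
  A20 closes a negative feedback by promoting TRAF6/RIPK1
  deubiquitination; TAK1 also feeds the p38/JNK/ERK MAPKs.
* **Survival.** VEGF phosphorylates VEGFR at two sites with distinct
  signaling: pY1175 drives PLCg/MEK/ERK, calcium release and eNOS; pY951
  drives PI3K/AKT. Ang1-Tie2 feeds AKT and ERK; FGF-FGFR feeds PI3K/AKT
  (supporting tight junctions) and PLCg/PKC/MEK/ERK; Wnt stabilizes
  beta-catenin.
* **Hypoxia sensing.** O2 controls PHD activity; active PHD hydroxylates
  HIF1a and HIF2a and keeps them low. Under hypoxia the HIFs accumulate,
  enter the nucleus, and induce Lon, BDNF, SEMA3G and Ang2, and activate
  p53. p53 induces MDM2 (negative feedback), TIGAR (raising NADPH, which
  lowers ROS) and BAX, which activates Caspase3.
* **Metabolism.** A conserved adenine pool cycles between ATP and AMP;
  regeneration has an aerobic branch (glucose and O2 dependent) and a
  lower-yield anaerobic branch (glucose only). AMP activates AMPK (and
  then ULK); low O2 induces PFKFB3. Tight-junction protein synthesis
  requires ATP, so junctions also erode during deprivation.
* **Oxidative stress.** Low O2 reverses SDH flux and succinate
  accumulates; restored O2 rapidly oxidizes succinate, and the oxidation
  flux produces the reperfusion ROS burst (reverse electron transport).
  ROS induces iNOS and NO; NO and ROS combine into peroxynitrite; ROS
  oxidizes BH4 to BH2, which feeds back on ROS production; ROS activates
  the Keap1/NRF2 axis, which clears ROS; ROS and peroxynitrite degrade
  ZO-1 and Claudin5, ROS activates IKK, and ROS promotes ER calcium
  release.

Kinetics are mass action and Hill-type. Each reaction carries one rate
constant; Hill regulators multiply the rate by
x^n/(K^n + x^n) (activation) or K^n/(K^n + x^n) (inhibition). Units:
proteins in copies per cell, metabolites/radicals in relative units with
quiescent value 1, O2 as a fraction, glucose in mmol/L, time in hours.
The published description of this system counts 108 species and 145
reactions including supplementary detail; this implementation has
`r nrow(buildDefaultNetwork()@species)` species and carries those counts
as descriptive metadata only.

## Quiescent state by construction

A usable control state must keep every species within 0.9x-1.1x of its
initial value over about 7 days of simulated culture. Rather than
searching for such a state, the builder solves for it: for each species
one designated rate constant (typically its decay or the activating arm
of a phosphorylation cycle) is computed so that total influx equals
total efflux at the declared literature-style baseline under the control
environment (21% O2, 5.05 mmol/L glucose). The balancing sweep iterates
until the largest relative net flux is below 1e-10, so the baseline is a
steady state to solver precision and the quiescence criterion holds with
a wide margin. `findQuiescentState()` still verifies the band by
simulation and, for perturbed parameterizations, offers a damped
fixed-point refinement that reports non-convergence honestly.

## Protocols and the OGD/R handoff

O2 and glucose are clamped environment inputs, set per protocol phase
(an open modeling choice; consuming them dynamically would add little at
cell scale but complicate the steady state). OGD sets O2 = 0.001 and
glucose = 0.05 mmol/L — close to zero, but not zero, because hard zeros
sit on singular points of Michaelis terms. Phases are integrated
sequentially with the terminal state of one phase (plus any ligand
bolus) seeding the next, which is exactly the state handoff used in the
experimental OGD-to-reoxygenation transition. Ligand doses convert from
ng/ml to molecules per cell via Avogadro's number and the culture
density. Integration uses `deSolve::lsoda` (stiff-capable) with rtol
1e-6, atol 1e-9; output grids refine to 0.01 h near phase boundaries.
Post-integration negative values are clamped to zero and counted; more
than 0.1% clamped samples raises a warning.

Interventions (target modulation, cohort treatments) are *acute*: the
pre-equilibration segment runs with the untreated parameters and the
modulated parameters apply from stimulus onset, mirroring pharmacological
treatment applied at OGD. Chronic re-equilibration would instead fold the
intervention into each cell's own baseline and, after per-baseline
normalization, cancel most of a near-linear intervention's effect.

## Scores and the phenotype grid

Module outputs are products of baseline-normalized markers
(inflammation: IL-6 x IL-1b x CCL2; growth: Ang2 x SEMA3G x BDNF; tight
junction: ZO-1 x Claudin5). The cell-function (CF) score divides the
proliferation score (Ang2 x SEMA3G x BDNF x ZO-1 x Claudin5) by the
damage score (IL-6 x IL-1b x CCL2 x ROS x ONOO x Caspase3); all scores
equal 1 at control. The phenotype grid simulates OGD durations of 1, 3,
4, 6, 24 h crossed with reoxygenation periods of 1, 6, 12, 18, 24 h and
records log2 fold changes of the 12 markers. Markers are sampled at the
end of each reoxygenation period (the sampling convention is not fixed
by the figure labeling; end-of-period matches it most directly), and
values are clipped at 1e-6 of baseline before the log2 transform.

## Sensitivity analysis, cohorts, calibration

Latin hypercube sampling draws stratified multipliers in [0.5, 2]
(`lhs::randomLHS` under a fixed seed); each sample scales the rate
constants, runs OGD 6 h / R 24 h, and records the module outputs and CF
score at the protocol endpoint (endpoint is the default summary; AUC is
available — the choice is not fixed by the source material). PRCC is
computed by rank-transforming inputs and outputs and correlating the
residuals after partialling out all other parameters (implemented via
the inverse correlation matrix; an independent brute-force rank
regression serves as the test oracle). P-values use the
t-approximation with df = n - 2 - (k - 1); raw and Benjamini-Hochberg
adjusted values are both reported. Failed samples are excluded with a
logged count.

Virtual cells draw i.i.d. normal multipliers (mean 1, sd 0.25,
resampled into [0.5, 2]; the distribution family and range are stated
in the source, the sd and truncation method are declared here) for a
registry of influential parameters. Interventions compose a uniform
[0.5, 0.8] efficacy multiplier onto a named parameter group (succinate
synthesis, p53 synthesis, HIF1a synthesis/nuclear loading, IkB
synthesis). Each cell is normalized to its own control baseline so
heterogeneity does not masquerade as dysfunction.

Calibration minimizes a weighted sum of squared residuals between
normalized simulations and time-course datasets, one simulation per
distinct protocol. The optimizer is a generalized pattern search in
log-parameter space (so the multiplicative 0.5x-2x bounds become a
symmetric box): poll +/- coordinate directions, accept the best
improvement, expand on success, contract on failure, stop when the mesh
collapses. The two-stage procedure (module-by-module, then global
refinement) is exposed as `stagedCalibration()`.

## The synthetic-data generator

`generateCalibrationSuite()` emulates the statistical structure of the
calibration corpus: sparse normalized time courses (normalized to series
maximum) under TNFa 100 ng/ml, LPS 300 ng/ml, VEGF 50 ng/ml, FGF
1 ug/ml, 1% O2 hypoxia and OGD 6 h / R 24 h, totalling over 300 points
across all five modules, with multiplicative lognormal noise (default
sigma 0.05, a conventional CV for densitometry/ELISA data — the true
replicate CV of such experiments is not published). It does not emulate
systematic biases of real data: blot saturation, loading-control error,
inter-lab protocol differences, or model misspecification. Passing the
recovery tests therefore shows the estimation machinery is sound, not
that the model is identified by real data.

Qualitative expectations are encoded as machine-checkable shape fixtures
(tolerances versioned in `inst/extdata/shape_fixtures.yaml`): succinate
rises through OGD and sheds at least half its rise within 2 h of
reoxygenation; ROS peaks after reoxygenation onset; pAMPK shows two
peaks with the second 4-8 h post-reoxygenation; p53 rises and returns to
within 0.8-1.2x baseline; HIF1a is at least 1.2x baseline at the end of
OGD and declines during reoxygenation; cytokines are monotone in OGD
duration; growth factors return to baseline; Caspase3 declines after
short OGD but stays within 10% of its reoxygenation maximum after 24 h
OGD; ZO-1/Claudin5 decline, and FGF co-treatment attenuates the decline.

## Numerical choices and degenerate inputs

* Balancing tolerance 1e-10 relative net flux; bounded rate constants
  0.5x-2x of baseline.
* Hill coefficients above 1 are used only where a switch is mechanistically
  needed (redox IKK activation, BH4 oxidation, caspase self-amplification,
  calcium-gated AMPK); each is justified in
  `inst/notes/parameter-notes.md`.
* Zero-duration OGD or reoxygenation phases are omitted, so an OGD-0
  protocol is exactly a control run.
* Constant sensitivity outputs yield PRCC 0 with p 1 (logged); collinear
  design columns are a named error.
* Pattern search never returns a point worse than its start; a flat
  objective terminates by mesh collapse at the start point.
* Problem sizes used in the shipped tests: 200-300 LHS samples
  (the full analysis uses 5000), 100-cell cohorts, and a 300-evaluation
  pattern-search budget against a ~430-point synthetic suite; these sizes
  make the full suite a desk-scale run while leaving every statistical
  conclusion qualitative rather than borderline.

## Known limitations

* The supplementary equation listing of the source system is not public;
  this network is a faithful reconstruction against the documented wiring
  and qualitative dynamics, not a transcription, and rate constants are
  design choices, not measurements.
* Single-cell, well-mixed ODEs: no spatial gradients, no multi-cell
  neurovascular-unit crosstalk, no stochastic kinetics.
* CF scores are relative multiplicative indices; mapping them onto
  categorical cell phenotypes is out of scope.
* Interventions are parameter multipliers; no pharmacokinetics of any
  actual inhibitor is modeled.

## A short session

```{r example, eval = FALSE}
net <- buildDefaultNetwork()
params <- defaultParameters(net)
state <- initialState(net)

# 7-day control culture: quiescence check
q <- findQuiescentState(net, params, state)
range(q$report$minFold); range(q$report$maxFold)

# OGD 6 h / reoxygenation 24 h
traj <- runProtocol(net, params, state, makeOGDRProtocol(6, 24))
score <- cellFunctionScore(traj)
endpointCF(score)

# succinate inhibition on the standard cell
mod <- simulateTargetModulation(net, params, "succinate", 0.6)
endpointCF(mod$treated) / endpointCF(mod$control)
```
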