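---
title: "Modeling cytokine-driven GMP fate decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cytokine-driven GMP fate decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmpfate)
```

## The model

Granulocyte–monocyte progenitor (GMP) cells commit to the monocyte or the
granulocyte lineage depending on which colony stimulating factors (CSFs)
they see: M-CSF drives monopoiesis, G-CSF granulopoiesis, and GM-CSF drives
monopoiesis at low doses but granulopoiesis at high doses, with a hybrid
monocytic myeloid-derived suppressor cell (M-MDSC) phenotype in between.
`gmpfate` implements a standard-component dynamical model of the
transcription-factor/receptor network behind these decisions.

Eight proteins are tracked, each as a dimensionless activity
$X_i \in [0,1]$: the master regulators PU.1 and C/EBP (lumping
C/EBP$\alpha$/$\beta$), the cross-antagonistic pair Gfi-1 and Egr-2, the
C/EBP antagonist IRF8, and the three receptors M-CSFR, G-CSFR and GM-CSFR.
Every protein obeys

$$\frac{dX_i}{dt} = \rho_i\left(\frac{1}{1+e^{-\sigma_i W_i}} - X_i\right),
\qquad W_i = \omega_i^o + \sum_j \omega_{i,j}\,X_j,$$

a sigmoidal production term balanced by first-order decay. The weights
$\omega_{i,j}$ carry the network wiring: positive for activation, negative
for inhibition. Transcription factors share one time scale $\rho_{TF}$;
receptors are ten-fold slower ($\rho_R = \rho_{TF}/10$), reflecting
trafficking, assembly and signal transduction delays. One time unit
corresponds to roughly two hours, so commitments completing within 20–60
units span one to five days.

Two algebraic layers close the system:

* **C/EBP sequestration.** IRF8 binds C/EBP into a transcriptionally
  inactive heterodimer. With binding at mass-action equilibrium
  ($K_{eq} = [\mathrm{complex}]/([\mathrm{C/EBP}]_F\,[\mathrm{IRF8}]_F$)),
  free C/EBP is the positive root of a quadratic in the two totals
  (`partition_cebp_irf8()`). Wherever C/EBP acts as a regulator, the *free*
  form enters $W_i$; the total is the state variable.
* **Receptor occupancy.** Cytokine doses are held constant and in excess,
  so the signaling species is the bound complex
  $[R{:}L] = L\,R_T/(L + K_d)$ (`receptor_occupancy()`). Receptor *totals*
  are dynamic; occupancies drive the downstream weights.

The regulator sets mirror the lineage biology: C/EBP auto-activates and is
driven by G-CSF and GM-CSF signaling; PU.1 auto-activates, is activated by
free C/EBP and M-CSF signaling and repressed by Gfi-1; Gfi-1 is driven by
free C/EBP and G-CSF signaling and repressed by Egr-2; Egr-2 by PU.1,
repressed by Gfi-1; IRF8 by PU.1, repressed by G-CSF/GM-CSF signaling; and
the receptors are transcriptional targets of the lineage factors
(M-CSFR: PU.1, C/EBP, Egr-2, repressed by Gfi-1; G-CSFR: PU.1, C/EBP,
Gfi-1; GM-CSFR: PU.1, C/EBP).

## Parameter provenance

The packaged parameter file (`inst/extdata/gmp_model_params.yaml`) is a
**synthetic, re-calibrated set**, constructed in two stages:

1. *Anchoring.* The three unstimulated attractors — the naive GMP state at
   $(\mathrm{PU.1}, [\mathrm{C/EBP}]_T) = (0.15, 0.15)$, a monocyte state
   (PU.1 high, C/EBP low, IRF8/Egr-2/M-CSFR/GM-CSFR high) and a granulocyte
   progenitor state (C/EBP/Gfi-1/G-CSFR high) — were prescribed and the
   node weights solved from the resulting linear systems, so all three are
   exact fixed points of the unstimulated system.
2. *Dose-coupling calibration.* The six cytokine-input weights, the three
   $K_d$, $K_{eq}$ and the sigmoid steepness were tuned by numerical
   continuation and fate scans until the model displays the documented
   bifurcation structure: loss of the naive state at moderate M-CSF
   (fold near dose 0.5), at low G-CSF (near 0.21) and at moderate GM-CSF
   (near 0.3), a monocyte-to-hybrid saddle-node near GM-CSF 0.86, the
   low-dose-monopoiesis / high-dose-granulopoiesis switch of GM-CSF with
   the hybrid window between, and irreversible M-CSF commitment.

Because the wiring fixes every edge's sign but not its magnitude, many
equally defensible parameterizations exist; the checksum embedded in the
file pins this one, and `load_parameters()` refuses silently drifted
copies. The calibration's remaining quantitative gaps are listed under
*Limitations*.

A deliberate asymmetry matters dynamically: C/EBP's auto-activation weight
exceeds PU.1's, so granulocytic commitment completes faster than monocytic
commitment, while PU.1's dominance at low GM-CSF arises from the IRF8
route — as long as IRF8 is not suppressed by strong GM-CSF signaling, it
sequesters the rising C/EBP and starves Gfi-1, buying PU.1 time to
self-amplify. At high dose, IRF8 suppression frees C/EBP, Gfi-1 fires
first, and the cell goes granulocytic.

## Phase-plane reduction

Six of the eight variables are slaved to (PU.1, free C/EBP, Gfi-1): Egr-2,
IRF8 and the three receptors are explicit logistic functions of those
three once the dependency order receptor → occupancy → IRF8 is respected
(`pss_closure()`), and the C/EBP total is reconstructed from the
equilibrium partition. Gfi-1 itself has no explicit solution and is closed
numerically: `gfi1_pseudo_steady()` subdivides $[0,1]$ into 100
subintervals, refines every sign change of $d[\mathrm{Gfi1}]/dt$ into ten
sub-subintervals, and recurses to a bracketing width of $10^{-9}$.
Newton's method would converge faster; the subdivision scheme is kept
because it finds *all* roots — the Gfi-1 closure is genuinely multivalued
in parts of the plane, and each root generates its own nullcline layer.

`nullcline()` sweeps one axis (free C/EBP for the PU.1 nullcline, PU.1 for
the C/EBP nullcline; rate tolerances $10^{-7}$ and $10^{-8}$), converts to
total-C/EBP coordinates, and strings points into branches by
nearest-neighbor continuity with a 0.05 jump threshold. Intersections of
the two curves in the 2-D projection are only candidate fixed points:
under G-CSF the projection produces apparent crossings whose
eight-dimensional residual does not vanish, and the census
(`find_steady_states()`) therefore always polishes candidates in the full
system before counting them.

## Steady states, stability, continuation

`find_steady_states()` seeds candidates from a graded lattice over
(PU.1, free C/EBP) — denser near free C/EBP $= 0$ because strong IRF8
sequestration parks the monocyte attractor at free-C/EBP values of order
$10^{-3}$ — then polishes with an eight-dimensional Newton iteration
(derivative-free simplex minimization of the reduced two-variable residual
serves as a fallback), deduplicates at $10^{-4}$, and labels stability
from the eigenvalues of a central-difference Jacobian (step $10^{-6}$) of
the *full* system. Phenotypes follow the quadrant convention on
(PU.1, C/EBP$_T$) at threshold 0.5: GMP low/low, GP low/high, MO high/low,
M-MDSC high/high.

`continue_branch()` performs natural-parameter continuation with step
0.005 and adaptive halving. Near folds the parameter step collapses; the
code then swaps roles, stepping whichever master regulator (PU.1 *or*
total C/EBP) moved fastest and solving for the parameter. The
generalization beyond PU.1 is necessary here: the monocyte-to-hybrid fold
moves almost entirely in the C/EBP direction while PU.1 stays near 0.95.
Fold points are recorded where the parameter direction reverses;
`attractor_loss_dose()` provides the independent grid-scan counterpart
(default step 0.01, continuity guard 0.15), and the two agree to within a
step everywhere we assert folds. On the GM-CSF axis the naive state's
*stability* is lost near dose 0.3 while the branch itself folds much
later; both numbers are reported by the acceptance script because they
answer different questions (where cells must leave, versus where the
branch turns).

## Population simulations

The stochastic component reproduces the stated sampling rule exactly: each
cell starts from the naive steady state with every component multiplied by
an independent $\mathcal{N}(1, 0.2)$ factor, clamped to $[0,1]$ (the clamp
matters only for components near 1; the naive state's components are all
$\le 0.165$, so clamping is rare). Cells are integrated with a
stiff-capable solver (lsoda; relative tolerance $10^{-8}$, absolute
$10^{-10}$ for reported trajectories, relaxed to $10^{-6}/10^{-8}$ inside
population loops) with root-triggered early stopping once
$\max_i |dX_i/dt| < 10^{-8}$, or to $t = 300$ units. Endpoints are
classified by nearest stable attractor in eight-dimensional Euclidean
distance (warning and label `other` beyond distance 0.2). The classifier
is the package's own reconstruction — the composition tables it produces
are integer counts and sum to one exactly.

Heat maps follow the cube-root RGB rule: red, green and blue encode the
granulocyte, M-MDSC and monocyte fractions over the largest category
(naive cells included), so all-naive pixels are black. Each pixel derives
its own RNG substream from the master seed, making the map independent of
evaluation order.

What the generator does *not* emulate: cell-to-cell signaling,
proliferation and death (so compositions are fate fractions, not expanded
population sizes), autocrine cytokine production, and receptor
internalization. Passing composition tests therefore validate the
decision layer of the model, not population expansion dynamics.

## Numerical choices

* Solver tolerances $10^{-8}/10^{-10}$; convergence criterion
  $\max|dX/dt| < 10^{-8}$; horizon 300 units (commitments plateau well
  before 150).
* Fixed-point residual tolerance $10^{-9}$ after Newton polish; stability
  analysis refuses states with residual above $10^{-8}$.
* The solver may overshoot $[0,1]$ by its tolerance; states are clamped
  before derived-quantity evaluation because the partition quadratic
  requires non-negative totals.
* Problem sizes in the shipped tests and acceptance script (populations of
  60–1000 cells, 25×25 census lattices, 41–61-point nullcline grids) were
  chosen so the full suite completes in minutes on one core while keeping
  binomial noise well inside the asserted margins; all are arguments, and
  larger runs only sharpen the same statistics.
* Simulations start at stimulus onset from the supplied state; the
  optional `pre_period` argument reproduces a cytokine-free baseline
  segment for figure parity. Starting from the naive fixed point makes the
  pre-period cosmetic.

## Limitations

* The parameter set is a re-calibration, not a transcription of an
  experimentally fitted set; individual weight magnitudes should not be
  interpreted biologically. Quantities asserted by the tests are
  structural (fixed-point counts, fold windows, orderings, composition
  patterns), not printed-precision dose values.
* The model's GMP branch under GM-CSF destabilizes once and for all near
  dose 0.3; no brief re-stabilization window at intermediate doses exists
  in this parameterization.
* GM-CSF signal-timing magnitudes are compressed relative to the
  qualitative template (half-maximal near 15 units at dose 0.6; peak near
  22 units at dose 1.2): the signatures — early-strong, then declining
  signal in granulopoiesis; late, switch-like rise in monopoiesis; higher
  final GM-CSFR in monocytes — are reproduced, their absolute times only
  approximately.
* The deterministic hybrid (M-MDSC) fate window sits near GM-CSF 0.8;
  above it the mean cell goes granulocytic and the hybrid fate persists
  only through initial-condition spread.

## A worked tour

```{r tour, eval = FALSE}
params <- default_parameters()
naive <- naive_steady_state(params)
round(naive[c("PU1", "CEBP")], 3)

# fate census without stimulation: trilobed landscape
find_steady_states(cytokine_dose(), params)

# M-CSF commitment and its irreversibility
hysteresis_scan("MCSF", 1, params)[c("phenotype_up", "phenotype_back")]

# GM-CSF dose response of a 500-cell population
composition_table("GMCSF", c(0, 0.4, 0.8, 1.2), params, n = 500, seed = 1)
```
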