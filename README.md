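# gmpfate

Dynamical modeling of cytokine-driven granulocyte–monocyte progenitor
(GMP) fate decisions in R.

GMP cells are bipotent myeloid precursors: M-CSF pushes them toward
monocytes, G-CSF toward granulocytes, and GM-CSF toward monocytes at low
doses, granulocytes at high doses, and a hybrid monocytic
myeloid-derived-suppressor-cell (M-MDSC) phenotype in between. `gmpfate`
implements an eight-protein regulatory-network model of this decision —
PU.1, C/EBP, Gfi-1, Egr-2, IRF8 and the three CSF receptors — and the
dynamical-systems machinery to interrogate it: nullclines in the
(PU.1, C/EBP) pseudo-phase plane, fixed-point censuses with eigenvalue
stability analysis, one-parameter bifurcation continuation with
saddle-node handling, hysteresis scans, and stochastic population
simulations with composition tables and RGB fate heat maps.

## The model

Each protein activity $X_i \in [0,1]$ obeys a standard-component equation

$$\frac{dX_i}{dt} = \rho_i\left(\frac{1}{1+e^{-\sigma_i W_i}} - X_i\right),
\qquad W_i = \omega_i^o + \sum_j \omega_{i,j} X_j,$$

where the regulators entering $W_i$ are the *free* (IRF8-unbound) C/EBP
fraction — obtained from the mass-action equilibrium
$K_{eq} = [\mathrm{C/EBP{:}IRF8}]/([\mathrm{C/EBP}]_F [\mathrm{IRF8}]_F)$ —
and receptor:cytokine occupancies $[R{:}L] = L R_T/(L + K_d)$. Receptors
evolve ten-fold slower than transcription factors
($\rho_R = \rho_{TF}/10$); one time unit is roughly 2 h. The packaged
parameter set is a documented re-calibration anchored at the three
unstimulated attractors (naive GMP, monocyte, granulocyte progenitor);
see the vignette (`vignettes/gmp-fate-decisions.Rmd`) for its
construction and limitations.

## Worked example

```r
library(gmpfate)
params <- default_parameters()
naive  <- naive_steady_state(params)
round(naive[c("PU1", "CEBP")], 3)
#>  PU1 CEBP
#> 0.15 0.15

find_steady_states(cytokine_dose(), params)
#> Steady states at dose MCSF = 0, GCSF = 0, GMCSF = 0
#>      PU1   CEBP   GFI1    EGR   IRF8 MCSFR  GCSFR GMCSFR  max_re stability phenotype
#> 1 0.1000 0.9950 0.9000 0.0300 0.1392 0.150 0.9000 0.5000 -0.1000    stable        GP
#> 2 0.1500 0.1500 0.1000 0.1000 0.1650 0.100 0.1000 0.1000 -0.1000    stable       GMP
#> 3 0.4115 0.1333 0.0616 0.3073 0.3606 0.291 0.1438 0.2982  0.2649    saddle       GMP
#> 4 0.4489 0.9347 0.5474 0.2238 0.3959 0.359 0.7477 0.7171  0.4563    saddle        GP
#> 5 0.9000 0.1316 0.0200 0.8500 0.8000 0.900 0.3000 0.8500 -0.1000    stable        MO
```

Without stimulation the system is tristable: the naive GMP state at
(PU.1, C/EBP$_T$) = (0.15, 0.15) coexists with committed monocyte and
granulocyte-progenitor states, separated by two saddles — an
unstimulated cell sits in the naive state indefinitely. Stimulation
removes the naive state and commits the cell:

```r
br <- continue_branch(naive, "MCSF", 0, c(0, 1), params = params)
attr(br, "folds")
#> [1] 0.4848462
hysteresis_scan("MCSF", 1, params)[c("phenotype_up", "phenotype_back")]
#> $phenotype_up
#> [1] "MO"
#> $phenotype_back
#> [1] "MO"
```

The naive state is destroyed in a saddle-node bifurcation at M-CSF
$\approx 0.48$, and commitment is irreversible — withdrawing the cytokine
leaves the cell in the monocyte state. The GM-CSF axis carries the full
dose-dependent program; a 1000-cell stochastic population (each cell's
initial state perturbed by multiplicative $\mathcal{N}(1, 0.2)$ noise)
gives:

```r
composition_table("GMCSF", c(0, 0.4, 1.0), params, n = 1000, seed = 1)
#>   MCSF GCSF GMCSF   GMP    GP    MO MMDSC other    n seed n_nonconverged
#> 1    0    0   0.0 0.999 0.000 0.001 0.000     0 1000    1              0
#> 2    0    0   0.4 0.000 0.124 0.876 0.000     0 1000    1              0
#> 3    0    0   1.0 0.000 0.573 0.000 0.427     0 1000    1              5
```

Undifferentiated cells at zero dose, near-uniform monopoiesis at dose
0.4, and a granulocyte/M-MDSC split with *no* monocytes at dose 1.0 —
the monocyte-versus-M-MDSC dichotomy created by the monocyte branch's
fold at GM-CSF $\approx 0.86$.

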