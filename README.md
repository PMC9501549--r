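# camnet

Deterministic modelling of calmodulin competition in the CaMKII–PP1
synaptic-plasticity signalling network.

## What it is for

In hippocampal dendritic spines, calcium pulses are decoded by calmodulin
(CaM). Fully loaded CaM (CaM₄) activates both potentiation machinery
(CaMKII, whose T286 autophosphorylation traps CaM by slowing its
dissociation 1000-fold) and depression machinery (calcineurin → inhibitor-1
→ PP1). Because the CaM pool (17.7 µM) is smaller than the summed pools of
its binding partners (~29 µM), the targets compete for CaM₄, and the
outcome of that competition depends on the frequency structure of the
calcium signal. `camnet` is for systems biologists who want to simulate and
interrogate that competition:

- a nine-state Ca²⁺–CaM binding module (independent N/C lobes, tense→relaxed
  cooperativity) coupled to the full mass-action reaction network (CaM₄
  binding to AC1/AC8/PDE1/PP2B/CaMKII, T286 autophosphorylation, cAMP
  production/hydrolysis, the PKA→PDE4 and PKA→I-1→PP1 loops), with a
  compiled stiff right-hand side;
- calcium pulse-train stimuli Ca(t) = Ca_basal + A·Σᵢ exp(−(t−tᵢ)/τ) with
  the four standard induction protocols (LFS 1 Hz, 10 Hz, theta burst,
  100 Hz);
- in silico knockouts (T286A, PP1 KO, PDE1 KO) and redistribution metrics;
- a steady-state PKA dose–response and its Hill-equation reduction
  PKAc = PKA_max / (1 + (IC50/cAMP)^n);
- a global sensitivity pipeline: ±90% Latin hypercube sampling,
  one-at-a-time monotonicity screening with range truncation, partial rank
  correlation coefficients (PRCC) with p-values, and Kolmogorov–Smirnov
  regionalised sensitivity.

## Worked example

Simulate a 100 Hz train (100 pulses of 1 µM) and look at the competition:

```r
library(camnet)
p <- default_parameters()
r <- integrate_network(p, make_protocol("HZ100"))
redistribution_metrics(r)
#>   target  peak peak_time end_of_train decline_fraction
#> 1    AC1  1.89     0.355         1.72         0.087933
#> 2    AC8  0.30     0.555         0.29         0.031676
#> 3   PDE1  3.60     0.265         3.23         0.103291
#> 4   PP2B  1.97     1.000         1.97         0.000000
#> 5 CaMKII 10.14     0.996        10.14         0.000131
```

The low-affinity, fast-binding targets (AC1, AC8, PDE1) grab CaM₄ early —
bound PDE1 peaks at 3.60 µM only 0.27 s into the train — and then *decline*
as CaM is redistributed onto CaMKII, which ends the train holding 10.1 µM
of CaM with essentially no loss, and onto calcineurin. Nearly the whole CaM
pool is converted: total CaM₄ (free + bound) peaks at 17.39 µM of the
17.7 µM pool, and phospho-T286 CaMKII reaches 3.25 µM by the end of the
train. Re-run with `apply_variant(p, "T286A")` and the declines essentially
vanish — the redistribution is phosphorylation-dependent: CaM trapping by
phospho-CaMKII is what starves the other targets.

The PKA reduction:

```r
dr <- pka_dose_response(p)            # steady states over 0-10 uM cAMP
fit_hill(dr$cAMP, dr$PKAc)
#> <pka_fit> PKA_max = 0.2398 uM, IC50 = 0.2018 uM, n = 1.522, R2 = 0.9931
```

(The release-step rate constants are printed with inconsistent units in the
source kinetic table; see the methods vignette for how the orientation is
selected and why network simulations use the calibrated Hill constants
instead.)

A sensitivity analysis over ±90% parameter ranges:

```r
cfg <- gsa_config(p, n_samples = 400, protocol = "HZ100", seed = 1)
tab <- run_gsa(p, cfg)
head(tab[order(-abs(tab$prcc)), ])
```

ranks the CaM-lobe kinetics, the CaMKII trapping parameters (kc5f, kc5b1)
and the total CaMKII concentration — the top-ranked concentration
parameter — as the dominant controls of total CaM₄ under 100 Hz drive.

## Layout

- `R/` — parameters (published kinetic table + packaged constants file),
  stimulus generator, nine-state CaM module, network RHS and integrator,
  PKA models, experiment grids, GSA machinery, config/IO.
- `src/` — compiled network right-hand side (deSolve convention), tested
  against the pure-R reference implementation.
- `vignettes/camnet-methods.Rmd` — model assumptions, numerical choices,
  open design decisions and known limitations.
- `tests/testthat/` — unit and property tests plus end-to-end acceptance
  checks of the published results.
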