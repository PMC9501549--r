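---
title: "Modelling calmodulin competition in the CaMKII-PP1 synaptic plasticity network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling calmodulin competition in the CaMKII-PP1 synaptic plasticity network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camnet)
```

## The scientific problem

In hippocampal dendritic spines, calcium entering through NMDA receptors is
read out by calmodulin (CaM). Fully calcium-loaded CaM (CaM₄) activates both
the kinase side of synaptic plasticity — CaMKII, whose T286
autophosphorylation is the canonical trigger of long-term potentiation — and
the phosphatase side — calcineurin (PP2B), which, through inhibitor-1 and
PP1, drives depression. The total CaM pool (17.7 µM here) is smaller than the
summed concentration of its binding partners (about 29 µM), so the targets
must *compete* for CaM₄. `camnet` implements a deterministic mass-action
model of that competition: a nine-state calcium–CaM binding scheme feeding a
CaMKII–PP1 reaction network with a cAMP/PKA feedback loop, plus the
machinery used to analyse it — calcium pulse-train stimuli, knockout
experiments, a Hill reduction of PKA activation, and a global sensitivity
pipeline (Latin hypercube sampling, monotonicity screening, partial rank
correlation, Kolmogorov–Smirnov regionalisation).

## The nine-state calcium–CaM module

Each CaM lobe (N and C) carries two calcium sites that fill sequentially:
the first ion binds while the lobe is in its tense (T) conformation and
relaxes the neighbouring EF-hand, so the second ion binds with the relaxed
(R) rates. The two lobes load independently, giving a 3 × 3 grid of nine
species from apo-CaM to CaM₄; only CaM₄ binds targets. The grid with eight
rate constants is exactly the tensor product of two three-state chains, and
the package exploits that: `equilibrate_cam()` is the analytic product of
the two lobe equilibria and is cross-checked in the tests against long-time
integration of `cam_fluxes()`.

The lobe rate constants are not part of the published kinetic table of the
downstream network; they enter through the packaged constants file
(`inst/extdata/model_constants.yaml`), populated with the canonical
flash-photolysis estimates for the T/R scheme (fast, low-affinity N-lobe:
kon 770, koff 1.6e5 µM⁻¹s⁻¹/s⁻¹ for the first ion; slow, high-affinity
C-lobe: kon 84, koff 2600). Loading fails loudly, naming the missing symbol,
if the file is incomplete — these constants are a sourcing decision, and a
silent default would hide it.

## The reaction network

`network_rhs()` (and its compiled twin in `src/camnet_rhs.c`) assembles:

* reversible CaM₄ binding to AC1, AC8, PDE1, calcineurin A and CaMKII
  (both phospho-forms bind with the same on-rate, 21 µM⁻¹s⁻¹; the off-rate
  drops 1000-fold on T286 phosphorylation, from 1.1 to 0.0011 s⁻¹ — the
  "CaM trapping" at the heart of the competition);
* T286 autophosphorylation requiring two adjacent CaM-bound subunits of the
  dodecameric holoenzyme, closed at mean field as
  flux = kcat14 · [CaMCaMKII] · ([CaMCaMKII]+[CaMCaMKIIᴾ]) / CaMKII_T;
* dephosphorylation of phospho-CaMKII by active PP1 and by PP2A
  (Michaelis–Menten, shared saturation over bound plus free phospho-forms);
* cAMP production by CaM-bound AC1/AC8 and by CaM-independent cyclases,
  hydrolysis by PDE1 (CaM-stimulated) and PDE4B/D (PKA-stimulated);
* PKA activation by cAMP (full four-state model or reduced Hill form),
  phosphorylation of PDE4B/D (negative feedback on cAMP) and of
  inhibitor-1; phospho-I-1 binds and inhibits PP1 (mass action, Kd 1 nM,
  fast relative to the train — an explicit-rate implementation of a rapid
  equilibrium, which keeps the PP1 pool conservation exact);
* calcineurin-A CaM binding gated by calcium loading of the B subunit
  (fast pre-equilibrium with half-saturation `K1`), with a
  calcium-dependent blend of the high-calcium (0.0012 s⁻¹) and low-calcium
  (2 s⁻¹) off-rates through the two printed Hill terms.

Free pools (inhibited AC1, free CaMKII, free PP1, ...) are computed
algebraically from the total-pool constants inside the right-hand side, so
pool conservation is exact by construction; only the free-CaM pool is
integrated dynamically, and the conservation suite verifies it drifts by
less than 10⁻⁶ relative across every protocol × knockout combination.

Where the published table pairs two catalytic rates without describing the
second (kcat5/kcat6, kcat7/kcat8, kcat9/kcat10), the pair is interpreted as
basal versus stimulated hydrolysis of the corresponding phosphodiesterase,
sharing one Michaelis constant; the PDE4 Michaelis constants (Km7, Km9),
absent from the table, are set to 2 µM in the constants file, a typical
PDE4 value.

## Stimulus model

Calcium transients are phenomenological: each pulse adds an amplitude A
instantaneously and decays exponentially with constant τ on top of a basal
level, so pulses summate when the inter-pulse interval is short relative to
τ. Four named protocols are built in: LFS (1 Hz, 0.4 µM per pulse, 30
pulses), 10 Hz (1 µM, 10 pulses), theta burst (10 epochs of 4 pulses at
100 Hz separated by 0.2 s, 1 µM) and 100 Hz (1 µM, 100 pulses). τ and the
basal level are never printed in the source material; the defaults
(τ = 0.05 s, basal 0.1 µM) are chosen so that at 1 Hz each pulse decays
essentially completely between pulses while at 100 Hz the train summates to
a ~5.5 µM plateau, and both are ordinary config fields, not constants baked
into the logic.

What the generator deliberately does not emulate: NMDA receptor gating,
calcium pumps, buffers and diffusion (the model is deterministic and
non-spatial), and trial-to-trial stochasticity of transmission. Passing
tests therefore show that the *reaction network* behaves as published under
idealised calcium drive, not that the calcium model is realistic.

## Numerical choices

The network is stiff (the fastest lobe off-rate is 1.6 × 10⁵ s⁻¹), so
integration uses `deSolve::lsoda` with the production right-hand side in C.
Because each pulse is a jump discontinuity in the drive, the integrator is
restarted at every pulse time and never steps across a jump; between pulses
the right-hand side is smooth. Default tolerances are rtol 10⁻⁸ and atol
10⁻¹² µM (sensitivity runs relax to 10⁻⁶/10⁻¹⁰, far below the effects being
ranked). The pure-R reference right-hand side is integrated against the C
version in the tests and agrees to better than 10⁻⁶ µM along whole
trajectories.

Initial conditions are resting: every complex, phospho-form and cAMP at
zero, free CaM distributed at its analytic equilibrium for basal calcium.
Runs span the train plus one second, matching the published observation
window; "end of train" is the last pulse time plus one inter-pulse
interval, and peak searches break ties toward the earliest time.

## The PKA reduction and the k19 orientation

The four-state PKA model binds two cAMP pairs (k17, k18) and then releases
two catalytic subunits. The printed units of the release pair are
internally inconsistent (a second-order constant labelled as release, a
first-order constant labelled as rebinding), so both orientations are
implemented behind a flag and an oracle (`select_k19_orientation`) picks
the one whose saturating steady state has the right magnitude: first-order
release at 0.0016 s⁻¹ with third-order rebinding at 0.25 µM⁻²s⁻¹, which is
also the dimensionally consistent reading. With that orientation the
steady-state dose–response over 0–10 µM cAMP saturates at 0.240 µM PKAc
with a half-activation near 0.2 µM and an effective Hill slope of about
1.5 (R² ≈ 0.993 for the Hill fit) — the release equilibrium is cubic in
released subunits, which compresses the slope. These values are computed,
not assumed, by `pka_dose_response()` + `fit_hill()`, and the algebraic
steady state is cross-checked against direct integration.

For network simulations the reduced mode uses the *calibrated* Hill
constants carried in the parameter set (PKA_max 0.2170 µM, IC50 0.3760 µM,
n 2.569), i.e. the published reduction, so that downstream results match
the published simulation conditions regardless of the k19 ambiguity. The
reduced model is the default for CaM₄-output work; cAMP and I1PP1 analyses
use the full model.

## Knockout experiments

`apply_variant()` implements three in silico mutants: T286A (kcat14 = 0, no
autophosphorylation), PP1 knockout (PP1_T = 0) and PDE1 knockout
(PDE1_T = 0). The headline contrasts reproduced by the test suite: under
100 Hz wild-type drive the low-affinity targets AC1/AC8/PDE1 peak mid-train
and decline as CaM is redistributed onto trapping phospho-CaMKII, whose
level grows monotonically; under LFS, PP1 knockout raises phospho-CaMKII at
every time point; and at 100 Hz, deleting PDE1 (a competitor for CaM)
shifts end-of-train phospho-CaMKII more than deleting PP1 (the direct
phosphatase). One caveat is documented rather than hidden: under T286A at
100 Hz the AC1/AC8 declines essentially vanish (< 5%), but bound PDE1 still
relaxes by ~7% from its early kinetic overshoot, because unphosphorylated
CaMKII (Kd ≈ 52 nM from the printed rates) and PP2B continue to take CaM
slowly late in the train. That residual decline is a property of the printed
rate constants under this realization of the unprinted lobe kinetics.

## Global sensitivity analysis

`run_gsa()` chains the published procedure: every parameter is swept
one-at-a-time over ±90% of baseline (21 grid points by default) and
truncated to its largest monotone subrange (longer side of a unimodal
response, ties to the lower side); parameters with no response are removed;
a Latin hypercube sample is drawn over the retained ranges; the model is
evaluated once per sample; and PRCC is computed by rank-transforming all
columns and taking partial correlations from the precision matrix, with
p-values from the t statistic and the published significance threshold
(p < 10⁻⁴). The KS regionalised screen (`ks_regionalized`) takes an
explicit acceptance predicate — the source material never defines
"acceptable behaviour", so the predicate is config, with output-within-50%-
of-baseline as a documented artifact default — and flags parameters whose
accepted/rejected marginals differ at p < 0.01.

Two choices deserve emphasis because the source material leaves them open.
First, the scalar output summary is the time average of the observable over
the train (end-of-train and peak are available); published PRCC magnitudes
are therefore matched only loosely. Second, the flatness threshold for
"no correlation" exclusion is deliberately tiny (10⁻⁶ relative): exclusion
is reserved for parameters with no pathway to the output, while weak but
clean monotone effects stay in the analysis — rank statistics are exactly
the tool meant to rank those.

Scaled problem sizes: the packaged analyses use 300–500 LHS samples and an
11-point screen grid (the published tables used 5000 samples), which keeps
a full protocol analysis to a few minutes on one CPU while leaving PRCC
standard errors near 0.05. At those sizes the qualitative structure of the
published tables is reproduced — CaM lobe rates and the CaMKII trapping
parameters dominate total CaM₄ at 100 Hz, with CaMKII_T the top
concentration parameter, and PDE1_T the top protein concentration under
LFS — while individual PRCC magnitudes can differ from the published
values where they hinge on the unprinted lobe-rate constants (CaMKII_T
reaches ≈ 0.58 here versus 0.83 published) or on loop fluxes that are
vanishingly small under this parameterisation (the LFS phospho-CaMKII loop
carries ~10⁻⁵ µM, leaving kcat14/kcat15 with real but tiny effects).

## Known limitations

* T305/T306 inhibitory phosphorylation, GluN2B binding, AMPAR trafficking
  and spatial/stochastic effects are out of scope, as in the source model.
* Calcium cannot dissociate from target-bound CaM₄; complexes decay only
  through their off-rate.
* The k19 ambiguity means the full PKA sub-model is quantitatively
  trustworthy only up to the documented orientation choice; the calibrated
  Hill reduction sidesteps this for network work.
* The nine-state lobe rates, Km7/Km9, K1 and the I-1/PP1 binding rates are
  sourced, not published with the network; all live in one versioned
  constants file so a better-sourced set can be swapped in without touching
  code.
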