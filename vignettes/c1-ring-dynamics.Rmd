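---
title: "Modelling C1-ring dynamics: unmixing, binding kinetics, and structural metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling C1-ring dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaicdyn)
```

`kaicdyn` analyses tryptophan-fluorescence readouts of the KaiC C1 ring:
how the ring's conformation varies with the phosphorylation state of the
C2 ring, and how its slow, ATP-hydrolysis-coupled transition gates
assembly with KaiB. This vignette records the models, the assumptions
behind them, the numerical choices, and what the accompanying tests do
and do not establish.

## The phosphoform cycle

A KaiC protomer occupies one of four phosphoforms of S431/T432, cycling
in the fixed order S/pT → pS/pT → pS/T → S/T (→ S/pT). We model the
population fractions $A_i(t)$ as a linear first-order system
$\dot A = M A$, where $M$ collects the step rates $k_1,\dots,k_4$
(h⁻¹). Columns of $M$ sum to zero, so total abundance is conserved and
every simulated row of $A$ sums to 1 (enforced to $10^{-9}$).

The solution is computed by matrix exponential,
$A(t) = e^{tM} A(0)$, rather than eigendecomposition: equal step rates —
a perfectly reasonable parameter choice — make $M$ defective, and the
exponential is exact there too. The tests cross-check it against an
independent stiff ODE integration (agreement $10^{-6}$) and against
fine-step Euler integration ($10^{-4}$ at step $10^{-4}$ h).

The closing step $k_4$ (S/T → S/pT) is kept in the parameter set but
defaults to 0: re-phosphorylation requires KaiA, which the
auto-dephosphorylation assay lacks. With $k_4 = 0$, S/T is absorbing and
its occupancy is non-decreasing — both asserted as properties.

`default_dephospho_scenario()` supplies package constants
$k = (0.55, 0.45, 0.30, 0)$ h⁻¹ and initial fractions
$(0.35, 0.45, 0.15, 0.05)$, chosen once so that relaxation into S/T is
substantially complete within ~20 h, the time scale such assays show.
Published dephosphorylation curves are graphical, so these constants are
deliberately *not* fits to them and should not be treated as measured
rates.

## Linear unmixing of fluorescence time courses

The apparent, band-integrated (320–370 nm), NATA- and
concentration-normalised intensity is modelled as

$$FI_\mathrm{app}(t) = \sum_i FI_i\, A_i(t),$$

with the *measured* abundances as the design matrix. Because $A_i(t)$
are data, not a smooth model, the reconstruction inherits their scatter
("jagged" fits are expected, not a defect). Choices made here:

* **Strict grid equality.** The fluorescence course and the abundances
  must share the time grid exactly; interpolation is an explicit
  pre-processing step the caller performs, never something the fitter
  does silently, because the abundances are measurements.
* **Non-negativity by default.** Intensities are physical, so the
  default fit constrains $FI_i \ge 0$ (active-set NNLS); the
  unconstrained solution is retained for diagnostics. By construction
  the unconstrained residual sum of squares is never larger — asserted
  as a property.
* **Identifiability screen.** A state whose abundance never exceeds 0.01
  (roughly the resolution of gel densitometry) is reported by name as
  unidentifiable instead of silently receiving an arbitrary coefficient;
  rank deficiency of the design is likewise an error.
* **Replicates.** The default fits each replicate separately and reports
  mean ± SE with SE = SD/√n, the convention for n = 3 independent
  experiments. A pooled fit (all replicates stacked) is available. Note
  a small-sample fact the tests pin down: with n = 3 the replicate-based
  SE has 2 degrees of freedom, so a ±2·SE band covers the truth only
  ~82% of the time (the t-distribution value), whereas the pooled fit's
  SE (~56 residual df) covers ~95%. Calibration claims about "2 SE"
  should therefore be read against the pooled fit.

Per-probe contributions difference two fits:
$\Delta FI_i = FI_i(\mathrm{WT}) - FI_i(\mathrm{mutant})$ for a masked
probe (e.g. W92F), and the reverse for an inserted one (e.g. S157W),
with quadrature-propagated errors.

## KaiB–KaiC assembly kinetics

Slow complex formation is modelled on a 1:1, monomer-concentration basis
with three mass-action schemes:

* **Conformational selection (CS):** $C_\mathrm{pre} \rightleftharpoons
  C_\mathrm{post}$ ($k_{cf}, k_{cr}$), then $C_\mathrm{post} + B
  \rightleftharpoons C{\cdot}B$ ($k_{on}, k_{off}$). The forward
  conformational step is identified with the slow C1 ATPase turnover;
  activities quoted per day convert via `atpase_to_rate()` (/24).
* **Induced fit (IF):** binding first, conversion second; the observable
  is the converted complex, since quenching reports the ring
  rearrangement.
* **CS with a KaiB fold switch (`CS_dual`):** KaiB itself
  interconverts between a ground state and a binding-competent fold
  ($k_{bf}, k_{br}$), and only the latter binds. At mixing, KaiB is
  placed at its own fold equilibrium (it is pre-incubated separately),
  while KaiC starts entirely unbound in the pre state.

Observable mapping: $FI_\mathrm{app}(t) = FI_\mathrm{free} +
(FI_\mathrm{bound} - FI_\mathrm{free})\,\mathrm{complex}(t)/C_\mathrm{total}$,
with $FI_\mathrm{bound} \le FI_\mathrm{free}$ (binding quenches the
probe). Integration uses `lsoda` at relative tolerance $10^{-8}$ and
absolute tolerance $10^{-10}$ µM on a default 0–18 h grid at 5-min
spacing; KaiC mass conservation is verified to $10^{-6}$ µM at every
point, and non-finite trajectories are errors carrying the full
parameter echo.

Defaults: $k_{on} = 100$ µM⁻¹h⁻¹ with small $k_{off} = 0.5$ h⁻¹ —
assembled complexes survive gel filtration, so dissociation is slow.
The AMP-PNP condition is modelled as $k_{cf} = 0$ (no hydrolysis-driven
transition, hence no binding-competent state); there is no separate
nucleotide state variable.

### Half-life, amplitude, and the factor ln 2

Two observables summarise each relaxation: the **midpoint-crossing
half-life** (first time $FI_\mathrm{app}$ crosses the midpoint of its
first and last values, linearly interpolated; curves whose total change
is below $10^{-3}$ a.u. raise an explicit "no transition" error — the
AMP-PNP phenotype), and the **first-minus-last amplitude**. An
exponential fit $a e^{-kt} + c$ is provided as a separate operation and
is never silently substituted for the midpoint convention.

One consequence deserves emphasis because it is easy to conflate: for a
(near-)exponential relaxation with rate constant $k_\mathrm{obs}$, the
inverse midpoint half-life is $1/t_{1/2} = k_\mathrm{obs}/\ln 2 \approx
1.44\,k_\mathrm{obs}$, *not* $k_\mathrm{obs}$. At saturating KaiB the CS
scheme's rate constant approaches $k_{cf}$; the fitted exponential rate
of the simulated relaxation indeed matches the closed form
$k_\mathrm{obs} = k_{cf} + k_{cr}/(1 + L/K_d)$ within 5% (an asserted
oracle equivalence), but the inverse *half-life* at the same point sits
a factor $1/\ln 2$ higher (0.74 h⁻¹ for $k_{cf} = 0.5$ h⁻¹). Statements
that identify an observed $1/t_{1/2}$ of ~0.5 h⁻¹ with an ATPase
turnover of 0.5 h⁻¹ are therefore order-of-magnitude correspondences,
exact only if $t_{1/2}$ is read as the reciprocal rate. The package
keeps both conventions explicit and the acceptance machinery reports the
midpoint-based value honestly.

### Mechanism classification

`kobs_profile()` titrates KaiB at fixed KaiC and collects $1/t_{1/2}$
and amplitude per concentration. `classify_mechanism()` fits both
hyperbolic forms — decreasing (CS) and increasing (IF) — and returns the
better-fitting one provided its fitted change across the observed range
exceeds 5% of the mean rate; otherwise "ambiguous" (flat profiles, e.g.
$k_{cr} = 0$, degenerate to a constant under both forms).

The classifier is a **pseudo-first-order diagnostic**: its validity
requires KaiB in excess of KaiC. At sub-stoichiometric KaiB the
half-life reflects titration (how long until the limited KaiB is
consumed) rather than mechanism, and the IF signature in particular can
invert. The classification study in the tests therefore draws its 200
random parameter sets under excess-ligand conditions (0.2 µM KaiC
against 0.9–10.5 µM KaiB), with "detectable" defined as: all
concentrations produce a transition, and the rate spans ≥10% relative
change across the grid. Under those conditions the classifier agrees
with the generator on ≥95% of sets (measured: 100%). The amplitude
readout is complementary and *does* exploit stoichiometry: under tight
binding ($K_d \to 0$) the plateau is reached at equimolar KaiB, asserted
to within one titration step.

`fit_cs_profile()` estimates $(k_{cf}, k_{cr}, K_d)$ by
Levenberg–Marquardt with non-negative bounds, starting from the
profile's saturation value, span, and median concentration; flat
profiles are flagged `kd_identifiable = FALSE` rather than fitted. With
5% multiplicative noise on the five-concentration grid, the median
$k_{cf}$ error over 100 seeds is ~6% (asserted < 15%); occasional
collapses at high noise are expected and are why the median, not the
maximum, is the calibrated quantity.

## Structural metrics

* **Superposition.** `kabsch_rmsd()` pairs atoms by (chain mapping,
  author residue number + insertion code, atom name) over common
  residues — backbone N, CA, C, O by default, first-chain pairing unless
  a mapping is given — and solves the optimal rotation by SVD with the
  determinant correction that excludes reflections. Tests verify
  rigid-motion invariance to $10^{-9}$ Å and agreement with an
  exhaustive, iteratively refined Euler-angle grid search to $10^{-4}$ Å
  and with an established superposition routine.
* **SASA.** `residue_sasa()` implements Shrake–Rupley point quadrature:
  deterministic golden-spiral points (960/atom by default) on each
  atom's probe-expanded sphere (probe 1.4 Å), occluded by neighbours
  found through a cell list. Radii are a Bondi-type table (C 1.70,
  N 1.55, O 1.52, S 1.80, P 1.80, H 1.20 Å); unknown elements are
  errors unless an override radius is supplied. Residue SASA sums all
  atoms of the residue. Waters are always excluded; other heteroatoms
  (notably bound ATP) are excluded by default with an opt-in flag —
  published values often leave the nucleotide treatment unstated, so
  both modes are worth reporting. Accuracy anchors: isolated-sphere
  closed form ($<10^{-6}$ relative), two-sphere spherical-cap overlap
  (<1%), 960- vs 4000-point convergence (<2%).
* **Burial and distances.** `assembly_burial()` computes one residue's
  SASA in its isolated chain and in the full assembly with identical
  settings; the difference is non-negative by construction (occluders
  only remove accessibility). `min_distance()` is an exact minimum over
  the target selection, tested against brute force.

The crystallographic benchmark values (backbone RMSD of the engineered
C1 ring vs wild type, W229 burial across the protomer interface, W92
interior SASA, probe-site-to-KaiB distance) require the deposited
multi-megabyte entries 4TL7/5YZ8/5JWO, which are not redistributed;
the corresponding test runs when those files are placed under
`structures/` at the repository root.

## The synthetic-data generator

`generate_dephospho_dataset()` emulates one dephosphorylation
experiment: exact cycle simulation; per-replicate **densitometry noise**
applied multiplicatively to the abundances, clipped at zero, and
renormalised to the simplex (multiplicative-then-renormalise mimics
per-band gel quantification and cannot produce negative fractions —
additive noise could); and FI built from the *clean* abundances (the
shared underlying truth) plus additive Gaussian noise. Default sigmas
are 1% of signal, stated as assumptions — the instrument noise of the
real measurements is not quantified anywhere we can cite. Replicate
seeds derive deterministically from the master seed; identical seeds
reproduce datasets byte-for-byte in serialised form.

What the generator does *not* emulate: instrument response,
photobleaching, inner-filter effects, correlated densitometry errors
across bands, or spectral shape beyond a smooth unimodal band
(`generate_spectrum()` exists to exercise band integration —
trapezoidal on the 1-nm grid — and NATA normalisation, nothing more).
Passing tests on synthetic data therefore establish the *estimators*
(recovery, calibration, classification) under the stated noise model,
not the behaviour of any particular instrument.

## Problem sizes and runtime posture

The test suite uses 20-point hourly time courses with 3 replicates for
unmixing; 200 seeded experiments for the coverage studies; 100 seeds
for profile-fit recovery; 200 random parameter sets (5 ODE solves each)
for classification; and 4-point toy structures plus ≤100-atom fixtures
for the structural oracles. These sizes were chosen so each study's
Monte-Carlo error is comfortably below the margin it asserts while the
whole suite stays desk-scale; all randomness is seeded, so every number
is reproducible.

## Known limitations

* Binding is 1:1 on a monomer basis; hexamer cooperativity, multiple
  KaiB sites per ring, and KaiA feedback are out of scope.
* The phosphoform cycle is first-order and unidirectional per step;
  KaiA-stimulated phosphorylation is represented only by the dormant
  $k_4$ parameter.
* The mechanism classifier presumes excess ligand (above) and monotone
  relaxations; multiphasic curves are summarised by their best single
  exponential only on request.
* Quenching is treated as proportional to bound fraction with two fixed
  levels; the photophysics of *why* W157 quenches is not modelled.
* Default rate constants are plausible package constants, not fitted
  values; analyses of real data should fit their own.
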