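---
title: "Methods: SAXS analysis of monomer-dimer equilibria with oligosaxs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SAXS analysis of monomer-dimer equilibria with oligosaxs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligosaxs)
```

## Scope and model

Small-angle X-ray scattering of a dilute protein solution measures the
orientationally averaged intensity $I(q)$, $q = 4\pi\sin\theta/\lambda$
(here always in $\mathrm{\AA}^{-1}$). For a protein that populates a
monomer–dimer equilibrium, the curve is an intensity-weighted mixture of
the two species, and the package's purpose is to extract, from such
curves, the quantities that adjudicate the oligomeric state:

* **Guinier analysis.** At low $q$, $\ln I = \ln I(0) - q^2 R_g^2/3$,
  valid for globular particles up to $q R_g \approx 1.3$. `guinier_fit()`
  scans contiguous windows of at least 5 points (after an optional
  `skip_low_q` exclusion for trace aggregation) and accepts a window only
  when its own fit satisfies $q_{max} R_g \le 1.3$ and
  $q_{min} R_g \le 0.65$. Among admissible windows the earliest start is
  preferred, then the best weighted $r^2$, then the longest run. The
  earliest-start rule matters: on curved, low-noise data a purely
  length-based rule can lock onto a high-$q$ stretch whose locally small
  apparent $R_g$ makes the $q R_g$ bound vacuously true. The $r^2$
  preference shrinks the window when curvature (breakdown of the Guinier
  approximation) dominates the residuals and grows it when noise
  dominates, which is what keeps the systematic $R_g$ bias on smooth
  analytic curves below 0.5% while still using wide windows on noisy data.
* **Porod invariant and volume.** $Q = \int_0^\infty q^2 I\,dq$ and
  $V_p = 2\pi^2 I(0)/Q$. The integrand is integrated by trapezoids on the
  measured grid with the exact $q^2 I \to 0$ limit prepended at $q = 0$;
  beyond $q_{max}$ the Porod law $I \propto q^{-4}$ is assumed, whose
  tail contributes exactly $I(q_{max})\,q_{max}^3$. Without the tail term
  $Q$ is underestimated and $V_p$ inflated on truncated ranges. The mass
  conversion is $M = 0.588\,\mathrm{Da\,\AA^{-3}} \times V_p$.
* **Dimer content.** Under the assumption that only monomers and dimers
  scatter, the apparent mass is $M = (1 + w)\,M_{mono}$, so
  `oligomer_fraction()` reports $w = M_{app}/M_{mono} - 1$ clipped to
  $[0, 1]$. The same statistic applies to the $I(0)$ route (apparent mass
  proportional to forward scattering per concentration) and the
  $V_p$ route; both are ratio-based and calibration-free. Absolute mass
  from $I(0)$ requires an instrument constant and is exposed as
  `mass_from_forward_scattering(I0, c, k_cal)` with a user-supplied
  `k_cal`.
* **Pair-distance distribution.** `fit_pr()` inverts
  $I(q) = 4\pi \int_0^{D_{max}} P(r)\,\mathrm{sinc}(qr)\,dr$ on a uniform
  $r$ grid with pinned endpoints ($P(0) = P(D_{max}) = 0$), a
  second-difference smoothness penalty, and (by default) a
  non-negativity constraint solved by Lawson–Hanson non-negative least
  squares. The real-space invariants follow from the solution:
  $R_g^2 = \int r^2 P\,dr / (2\int P\,dr)$, $I(0) = 4\pi\int P\,dr$.
* **Debye prediction and ranking.** `debye_curve()` evaluates
  $I(q) = \sum_{ij} w_i w_j\,\mathrm{sinc}(q r_{ij})$ exactly for models
  up to 500 sites and through a 0.5 Å pair-distance histogram above
  that. The default coordinate representation is one site per residue
  with uniform weight: a deliberate simplification of atomic form
  factors plus hydration shell, adequate for shape ranking (which is the
  supported use), not for absolute $\chi$ comparison with atomistic
  predictors. Excluded volume is an optional q-independent contrast
  reduction of the per-site weights; at `solvent_contrast = 1` the mean
  contrast is zero.
* **Mixture decomposition and ensembles.** `fit_mixture()` solves the
  sigma-weighted non-negative least-squares problem for component
  amplitudes (optionally plus a free-sign constant) and renormalizes to
  fractions. `select_ensemble()` runs a seeded genetic algorithm
  (population 50, tournament selection, single-point crossover on sorted
  member lists, member-swap mutation at rate 0.1, elitism) over
  fixed-size sub-ensembles of a conformer pool, in 3 independent rounds,
  minimizing the mixture-fit $\chi$. `generate_pool()` supplies the
  random-coil pool: rigid core plus self-avoiding walks with 3.8 Å
  virtual C$\alpha$ steps and a 3.0 Å hard-sphere clash distance.
* **Bead-shape reconstruction.** `reconstruct()` anneals single-bead
  occupancy flips on a simple cubic lattice (bead radius
  $0.62\times$ spacing, i.e. overlapping spheres — simpler neighbor
  logic than hexagonal packings and indistinguishable at SAXS
  resolution), minimizing $E = \chi^2 + \alpha\,L$ where $L$ is the
  fraction of occupied beads with fewer than 6 of 26 neighbors occupied
  and $\alpha = 10\chi^2_0$ is normalized at the start so the fit and
  compactness terms begin comparable. Connectivity is enforced by
  rejecting disconnecting removals. P2 symmetry is enforced
  constructively: flips are applied jointly to a site and its
  $180^\circ$ image about $z$, so the constraint holds at every accepted
  step. For polydisperse samples, a fixed monomer fraction mixes an
  area-normalized monomer form factor into the fitted curve
  (intensity-fraction convention with area-normalized components — the
  convention is stated here precisely because mixture-aware shape
  reconstruction tools leave it ambiguous), so the beads model only the
  dimer.
* **Model comparison.** `nsd()` implements the normalized spatial
  discrepancy with principal-axes superposition over the four proper
  axis-sign combinations; `average_filter()` aligns repeated
  reconstructions to the lowest-mean-NSD reference, thresholds the
  per-node occupancy map (default 0.5) and keeps the largest connected
  component.

## Synthetic phantoms and what they do (not) show

`synthetic.R` generates the validation world: analytic sphere and
Gaussian-chain curves (closed forms with known $R_g$, $D_{max}$,
volume), uniform-ball point samples, a compact-core-plus-flexible-tail
monomer stand-in (285-residue core, 31-residue tail — the architecture
of a ~38 kDa enzyme with a disordered C-terminal extension), an exact P2
dimer builder, and concentration series in which the dimer weight
fraction follows $w(c) = c/(c + K)$. The isotherm is a deliberately
simple stand-in for a low-micromolar self-association; only its
monotonicity and endpoints are relied upon. Per-unit-mass intensities
are mixed as $(1-w)\,I_{mono} + (w/2)\,I_{dimer}$ so the apparent mass
interpolates from $M$ to $2M$. Counting-like noise uses
$\sigma(q) = s\,I(0)\sqrt{I(q)/I(0) + 0.01}$ — Poisson scaling with a
floor at 1% of the forward-scattering scale.

Phantoms share the contrast, smoothness and noise *structure* of real
measurements but not their systematic errors: no beam smearing, no
buffer-subtraction artifacts beyond an additive constant, no
interparticle structure factor beyond the linear term removed by the
infinite-dilution extrapolation, and uniform per-residue contrast.
Passing the phantom suite therefore demonstrates the correctness of the
estimators, not the absence of instrument-specific biases in real data.

## Numerical choices

* $\mathrm{sinc}(x)$ is evaluated by its quadratic series below
  $10^{-4}$ everywhere.
* When a profile carries no error column, `fit_pr()` assumes 1% relative
  errors with a floor at $10^{-3} I_{max}$. A counting-shaped floor at 1%
  of $I(0)$ was rejected: it drowns the high-$q$ features that carry the
  $D_{max}$ information, letting visibly truncated distributions fit
  "within errors". `fit_to_profile()` keeps the conventional unit-error
  default and flags it (`sigma_assumed`).
* The smoothness weight $\alpha$ is normalized by the weighted design
  scale so that the $P(r)$ solution is exactly equivariant under joint
  rescaling of $I$ and $\sigma$; its automatic value comes from an
  L-curve corner search (maximum Menger curvature over a
  $10^{-4}$–$10^4$ log grid).
* The $D_{max}$ scan score is
  $0.5\,e^{-\max(\chi - 1,\,0)} + 0.05\,e^{-\chi} + 0.3\,f_+ + 0.2\,d$,
  with $f_+$ the positivity fraction and $d = e^{-5\max(z - 0.05,\,0)}$
  penalizing a trailing run of near-zero $P$ values occupying a fraction
  $z$ of the grid (the signature of an overestimated $D_{max}$). The fit
  term is one-sided — $\chi \le 1$ earns essentially full credit — with
  a small monotone tie-break: a symmetric $|\chi - 1|$ term would
  perversely prefer a truncated $D_{max}$ whose misfit happens to land
  near $\chi = 1$ over the true $D_{max}$ fitting to $\chi \approx 0$ on
  clean data. The scan uses a fixed $\alpha = 1$ so scores are
  comparable across $D_{max}$.
* Annealing defaults: initial temperature calibrated so about half of
  the uphill trial moves would be accepted, geometric cooling
  $\times 0.93$ per 1000 attempted flips, stop after 60 temperature
  steps without best-energy improvement, 250 steps maximum. Slower
  canonical schedules (cooling 0.98 from an 80%-acceptance start) keep
  the lattice molten for most of a desk-scale run and return
  $\chi \sim 10$; the faster defaults reach $\chi \le 1.5$ on 150–200
  bead round-trips in about a minute on one CPU, and the slower settings
  remain available through the `schedule` argument.
* The non-negative solver is an in-package Lawson–Hanson implementation
  with a $50n$ iteration budget; tightly capped library implementations
  abort on the ill-conditioned regularized IFT systems.
* Degenerate inputs: all-zero profiles invert to $P \equiv 0$ with
  $I(0) = 0$; models with a single site have $R_g = 0$ and a flat Debye
  curve; NSD is refused for single-point sets (the internal
  nearest-neighbor scale is undefined); `average_filter()` falls back to
  identity alignment when any model has fewer than 4 beads.

## Problem sizes

The validation suite runs phantom studies sized for a single CPU:
150–200 bead reconstructions on a 45 Å search radius with 60-point
curves, 2000-site Debye cross-checks, 50-replicate noisy mixture
studies, and 20–25 member conformer pools for the genetic algorithm.
These sizes were chosen so each study completes in seconds to a couple
of minutes while leaving the estimators' error well below the asserted
tolerances; all of them scale up by changing the corresponding
arguments.

## External validation on deposited data

The quantities printed for the original beamline measurements — the
experimental $R_g$ (23.0/31.6 Å), $D_{max}$ (80.5/105.4 Å), the Porod
volumes, the absolute $\chi$ of atomistic-model fits, and the NSD
statistics of the published envelopes — depend on the deposited
measurement series and on atomistic hydration-shell form factors, and
are not reproduced by the phantom suite. They can be recomputed by
downloading the deposited raw data (Zenodo record 3375375), reading the
concentration series with `read_profile()`, reducing it with
`scale_and_extrapolate()` and `merge_ranges()`, and running
`run_oligomer_analysis()`; ranking of coordinate models against those
curves uses `rank_models()` on the deposited PDB files. Absolute
$\chi$ values will differ systematically from atomistic predictors
(residue-level contrast, no hydration shell); rankings are comparable.

## Known limitations

Residue-level Debye prediction cannot reproduce atomistic $\chi$
magnitudes; the Porod tail assumes ideal $q^{-4}$ decay (no constant
subtraction before integration); the annealing energy has no
chain-compatibility term, so bead models are envelopes, not folds; the
genetic algorithm optimizes a fixed ensemble size rather than selecting
it; and the binding isotherm of the phantom series is phenomenological.
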