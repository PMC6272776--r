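---
title: "Methods: lipophilicity fields, pocket polarity, binding and permeability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lipophilicity fields, pocket polarity, binding and permeability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostguest)
```

This vignette documents the models behind `hostguest`, the choices made
where the methodology is genuinely open, and what the synthetic-data
generators do and do not emulate.

## The molecular lipophilicity potential

The MLP treats a molecule as a set of fragments, each carrying a
lipophilic constant $f_i$ (positive = hydrophobic, negative = polar),
and projects them into space:

$$\mathrm{MLP}(k) \;=\; \sum_{i=1}^{N} f_i \, \mathrm{fct}(d_{ik}),$$

where $d_{ik}$ is the distance between fragment $i$ and space point $k$.
The package operates on heavy atoms, with hydrogen contributions folded
into the heavy-atom constants — the level of description at which
element-wise fragmental tables (Broto; Ghose–Crippen lineage) are
published and at which depictions of large hosts usually omit
hydrogens. Explicit-hydrogen tables work unchanged through
`read_fragment_table()`; any atom-typing scheme can be carried in the
`fragment_type` column.

**Distance weighting.** The literature leaves $\mathrm{fct}$ open; two
common forms are implemented. The default is the exponential
$e^{-d/2}$ (length scale 2 Å, a soft range typical of MLP
implementations) with a 10 Å cutoff, beyond which atom contributions
are well below $10^{-2}$ of their contact value; the hyperbolic
$1/(1+d)$ is available for sensitivity analysis. With a cutoff at least
as large as the largest atom–point distance, the field equals the
cutoff-free double sum to machine precision — this is tested against an
independent brute-force loop rather than assumed.

**Linearity and invariance.** MLP is linear in the constants and
invariant under a rigid motion applied jointly to molecule and points;
both are exercised as property tests across seeded random molecules.

## Surface sampling

Molecular surfaces are sampled Shrake–Rupley style: each atom's van der
Waals sphere (Bondi radii, packaged) is inflated by a probe radius
(default 1.4 Å, water) and covered with a deterministic golden-spiral
point set (default 100 points per atom); a point survives if it lies at
or beyond every other atom's inflated sphere.

Two numerical choices deserve note:

* **Frame covariance.** Sphere sample directions are expressed in a
  canonical molecule-fixed frame (principal axes of the coordinate
  spread, signs fixed by third moments). This makes the sampled surface
  co-rotate with the molecule — a property lab-frame sampling lacks —
  so downstream quantities are rigid-motion stable. For degenerate
  geometries (single atoms, highly symmetric molecules) no canonical
  orientation exists and the sampler falls back to the lab frame: still
  deterministic, but the point set then does not co-rotate.
* **Boundary ties.** A point lying exactly on another atom's inflated
  sphere is kept only for the lowest-index atom. Coincident duplicate
  atoms therefore contribute exactly one sphere's point set instead of
  doubled points.

## Pocket fitting points and the lipophilicity index

Cavity polarity is scored on *fitting points*: a cubic grid (default
pitch 1 Å) intersected with a pocket sphere (default radius 5 Å),
excluding points inside any atom's van der Waals sphere, ordered by
x, then y, then z. A grid is preferred over surface points because a
cavity's interior volume — not the host's outer surface — is what a
bound guest experiences; the published descriptions of pocket MLP do
not fix the construction, so this choice is the package's own and the
exact index value of a given pocket depends on it.

$$LI = \frac{|\Sigma \mathrm{MLP}^+|}{|\Sigma \mathrm{MLP}^+| + |\Sigma \mathrm{MLP}^-|}\times 100\,\%$$

is scale-invariant, bounded in $[0,100]$, and classified polar strictly
below 10 % (the boundary itself is non-polar, since polar sites are
defined by $LI < 10\%$). An all-negative field gives $LI = 0$, which is
well defined; only an all-zero field is rejected. The default pocket
center follows the docking-box convention of the cyclodextrin workflow
this package supports (x = 56.49, y = 12.97, z = 9.29 Å); any center
can be supplied.

## logP back-calculation and its calibration

$$\log P_{\mathrm{MLP}} = \Sigma\mathrm{MLP}^+ \cdot w^+ + \Sigma\mathrm{MLP}^- \cdot w^- + C$$

over a molecular surface field. The weights are meaningful only after
calibration on molecules with experimental logP; `calibrate_logp()`
fits them by ordinary least squares on $(\Sigma^+, \Sigma^-, 1)$ with a
rank check — no regularisation, because calibration sets here are small
and noiseless synthetic recovery must be exact. The package ships no
claimed universal weights: uncalibrated use warns and yields only an
ordering. This is deliberate; published pocket-index values such as a
2.79 % cavity LI or host/guest logP values of −18.03 and +2.85 depend
on an unpublished fragment table, distance function and calibration,
so the package asserts (and tests) sign and ordering consistency —
all-polar cavity constants give $LI < 10$ and a surface logP below the
intercept, all-hydrophobic the reverse — rather than those exact
numbers.

## Binding-pose post-processing

Poses carry a docking energy $\Delta G_{\mathrm{bind}}$ (kcal·mol⁻¹)
and guest coordinates in the shared receptor frame. RMSD between poses
is computed **without superposition**: aligning poses first would
discard exactly the translational diversity a 2 Å clustering threshold
is meant to resolve inside a cavity. Clustering is greedy and
energy-ordered (lowest-energy unassigned pose seeds, collects all poses
within threshold, repeats) — the standard docking-report convention.
Ties in energy are broken by input order, making the partition
deterministic.

Top-pose summaries take the $k=3$ lowest energies by default (directly,
matching the usual "top poses" reading; representative-per-cluster
ranking is a flag). The free-energy/constant conversion is

$$K = e^{\Delta G/(RT)}, \qquad R = 1.9872\times10^{-3}\ \mathrm{kcal\,mol^{-1}K^{-1}},\ T = 298.15\ \mathrm{K},$$

a **dissociation-scale** convention, under which $\Delta G \approx
-1.7$ kcal·mol⁻¹ maps to tens of millimolar — the scale on which weak,
rapidly-liberating host–guest complexes are reported. $K$ statistics
are computed per pose and then averaged (mean and sample sd, in mM);
propagating the energy sd through the exponential instead gives a
smaller spread, so the two conventions are not interchangeable and the
per-pose one is reported. Affinity is high iff
$\Delta G \le -6.0$ kcal·mol⁻¹ (boundary inclusive).

## Transwell apparent permeability

The estimator implements

$$P_{app} = \frac{dQ/dt \cdot V_b}{A\, C_0}$$

with $A = 0.336\ \mathrm{cm^2}$, $V_b = 0.9$ mL and
$C_0$ the initial apical concentration. Sampling draws 100 µL from the
basolateral chamber at 5, 15, 30, 60 and 120 min with fresh-medium
replacement, so each draw removes mass later samples cannot see. The
package assumes the measured concentration refers to the chamber at
draw time and restores the removed mass:

$$Q_i = V_b C_i + V_s \sum_{j<i} C_j,$$

verified in tests against an explicit step-by-step re-simulation of the
chamber; an uncorrected mode exists for comparison. Cumulative
*concentration* ($Q_i/V_b$) is fitted with a quadratic in time
(seconds internally), and the initial slope is the fit's derivative at
$t=0$ by default — the quadratic absorbs the late flattening of
non-sink courses while its linear coefficient captures the initial
flux. A first-$k$-points linear-fit mode (default $k=3$) is provided
because "initial slope" is also commonly read that way, and a
`max_time_min` filter excludes late flux-reversal points without
aborting the analysis. Classification: low $\le 10^{-6}$ cm·s⁻¹ <
high $\le 2\times10^{-6}$ < high-bioavailable.

The apical volume has no canonical published value for this geometry;
the default 0.3 mL is typical for a 0.336 cm² insert and only enters
the two-compartment generator (never the estimator itself).

`dose_equivalent()` converts free-drug to complex concentrations via
the drug mass fraction, e.g. 40 µg·mL⁻¹ at 8.6 w% → 465.1 µg·mL⁻¹.

## What the generators emulate — and what they do not

`synthetic_spec()` pins every generator input under one seed; its
defaults are the assay conditions the workflow targets: sampling
times 5/15/30/60/120 min, $C_0 = 10^5$ µg·mL⁻¹ (100 mg·mL⁻¹ complex),
true $P_{app} = 12.32\times10^{-6}$ cm·s⁻¹, 5 % multiplicative noise,
and docking energies $\mathcal N(-1.727, 0.042^2)$ over 100 runs.

* `make_cage_host()` builds a torus-like amphiphile stand-in: two
  concentric rings of pseudo-atoms whose interior/exterior constants
  are tunable, with an atom-free central cavity. It captures the
  topology that matters for cavity scoring (a ring of atoms projecting
  their field inward) but none of a real cyclodextrin's chemistry.
* `simulate_transwell()` generates the measured aliquot concentrations
  under either strict sink conditions (linear transported amount) or a
  closed two-compartment exchange
  $Q(t) = Q_{eq}(1-e^{-kt})$,
  $k = P_{app}A(1/V_a + 1/V_b)$, which reproduces the early-onset
  steady state of real non-sink courses. Noise is multiplicative
  (concentration-proportional, LC-MS/MS-like); an optional flag censors
  values below a 2.5 µg·mL⁻¹ quantification limit to zero. Volatility
  losses and serum protein binding — both plausible in real anesthetic
  transport data, and a likely source of the high inter-replicate
  deviation seen in practice — are not modelled, so passing recovery
  tests demonstrate estimator correctness under the stated noise model,
  not robustness to those effects.
* `make_pose_ensemble()` draws energies from the normal target and
  jitters a fixed guest template; it emulates the summary statistics of
  a docking run, not its energy landscape.

Noiseless sink courses close the loop with the estimator to $10^{-9}$
relative across $P_{app} \in \{1, 5, 12\}\times10^{-6}$ cm·s⁻¹, and at
5 % noise the median relative error over 200 seeded replicates stays
below 10 % — both are standing tests.

## Problem sizes and determinism

Test and acceptance workloads are sized for interactive turnaround:
50 random molecules of up to 50 atoms for the brute-force oracle,
200 noisy permeability replicates, 10-record calibration sets,
60–100 surface points per atom, 81-point cavity grids. All randomness
flows through explicit seeds; generator functions restore the caller's
RNG state, and identical configs produce byte-identical reports and
CSV bundles.

## Known limitations

* Atom typing is element-level out of the box; finer fragmental schemes
  must be supplied by the user.
* `logP_MLP` is relative unless calibrated; no universal weights are
  shipped.
* Surface sampling is not rotation-covariant for degenerate/symmetric
  geometries (documented fallback).
* Pose clustering is greedy; it does not optimise a global partition
  criterion.
* The permeability estimator assumes a well-stirred basolateral chamber
  and draw-time concentrations; partial mixing is not modelled.
* No docking, conformer generation, charge assignment or cavity
  detection is performed — inputs come from external tools or the
  generators.
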