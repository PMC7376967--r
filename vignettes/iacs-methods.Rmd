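---
title: "Modelling epidural AC stimulation fields and reconstructing neurogenesis statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling epidural AC stimulation fields and reconstructing neurogenesis statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iacsim)
```

## Scope and scientific question

`iacsim` answers two questions that arise when weak alternating current is
delivered to the mouse brain through screw electrodes resting on the dura:

1. **Dosimetry.** With a bilateral epidural montage (AP −2 mm, ML ±4 mm
   from bregma, 1.5 mm contacts) driving 100 µA at 40 Hz, what electric
   field |E| and current density |J| reach the two neurogenic niches — the
   subventricular zone (SVZ) lining the lateral ventricles and the
   hippocampal dentate gyrus — and does the peak tissue current density stay
   below the ~20 A/m² range reported to cause electrode-induced lesions?
2. **Inference.** Given per-animal immunopositive-cell counts (Ki67,
   Nestin, DCX) in three groups (wild-type, 5xFAD, 5xFAD with stimulation;
   n = 5 each), do the published one-way ANOVA F statistics, Tukey HSD
   p-values and fold changes follow from the published group summaries
   (mean ± SEM)?

## The volume-conductor model

At 40 Hz, tissue conduction is overwhelmingly ohmic: the ratio of
displacement to conduction current, `2*pi*f*eps0*eps_r/sigma`, is well
below 1 for CSF and on the order of 0.1 for gray matter even with the
largest low-frequency permittivities in the dispersion literature
(`check_quasistatic()` reports the per-tissue ratios and flags anything
above 0.1). The package therefore solves the real-valued quasi-static
problem

  ∇·(σ∇φ) = 0,   E = −∇φ,   J = σE,

with zero-flux outer boundaries and current injection at the electrode
contacts. Permittivity is carried in the tissue table solely for the
validity report.

### The parametric phantom

A segmented MRI/Nissl atlas is deliberately not a dependency. The field
pattern at the two targets is controlled by a handful of conductivity
contrasts — a resistive dura over a highly conductive sub-dural CSF film,
conductive CSF-filled ventricles embedded in parenchyma, and the
depth of the targets below the contacts — so `build_phantom()` rasterizes a
parametric head that reproduces exactly those relations on the reference
grid (189 × 236 × 152 voxels at 100 µm; any isotropic resolution can be
requested and the bounding box is preserved):

* an ellipsoidal brain (semi-axes 7 × 5 × 3.5 mm) with a 0.8 mm cortical
  gray shell over white matter;
* paired lateral ventricles (CSF) about 2.4 mm below the dorsal surface,
  ±1.2 mm off the midline, wrapped by a 1-voxel parenchymal **SVZ shell**
  (every parenchymal voxel 6-adjacent to ventricular CSF);
* paired dorsal hippocampal bodies centred ±2.6 mm off the midline about
  1.8 mm below the surface, i.e. directly deep to the contacts — the
  standard stereotaxic position of the dorsal dentate gyrus;
* a CSF film and a 300 µm dura layer grown outward over the brain surface.

These dimensions were fixed once, from mouse stereotaxic anatomy, before
any field was computed, and are all configurable in `phantom_spec()`.

The 43 µm CSF film is far thinner than a voxel. Representing it as a full
voxel of CSF would multiply its tangential sheet conductance several-fold,
and the lateral shunting of current under the dura is precisely the effect
that matters. The film is therefore rasterized one voxel thick with the
conductance-preserving effective conductivity σ·t/Δ
(`effective_shell_conductivity()`); the same rule applies to the dura
whenever the requested voxel is coarser than 300 µm. An anisotropic
thin-layer tensor would be more faithful to the normal direction but is a
non-goal; the error is second-order for the dominant tangential transport.

Default conductivities are the values in routine use for low-frequency
head models — CSF 1.79, gray matter 0.276, white matter 0.126, dura
0.367 S/m — shipped in `inst/extdata/tissue_properties.csv` and
overridable; loading enforces CSF > gray > white, the ordering the layered
physics relies on.

### Electrodes and discretization

Contacts are rasterized on the dura surface: a grid column belongs to a
disc when its centre lies strictly within `diameter/2` of the contact
centre (half-open rule, which makes rasterized contact sizes reproducible),
and the contact voxel is the topmost dura voxel of the column. Placement
fails, by design, if any contact voxel would touch parenchyma — the screws
touch the dura only.

The operator is a 7-point finite-volume stencil with harmonic-mean face
conductances, which is exact for layered piecewise-constant media (the
test suite checks the two-layer slab against the series-resistance closed
form at 1e−8). Current is injected in equal shares over each contact's
voxels — a uniform-flux model, not a complete-electrode (equipotential)
model. The choice keeps the problem linear and symmetric; its price is
that fields inside and immediately around a contact are
discretization-dominated. Two consequences are built in:

* `safety_check()` evaluates the lesion bound over parenchymal labels only
  (gray, white, hippocampus, SVZ shell) and additionally excludes the
  contact voxels plus a 1-voxel shell;
* the pointwise maximum parenchymal |J| under a contact is the
  least-converged quantity in the model: the continuum disc-electrode
  solution has an edge singularity, so the peak sharpens as the grid is
  refined (about 18 A/m² at 200 µm against about 22 A/m² at 100 µm for the
  default montage), whereas region-mean quantities move by only a few
  percent (hippocampal mean |E| changes < 6% between those grids). Safety
  statements are therefore quoted at the 200 µm analysis resolution at
  which they are computed.

One sink-contact voxel is pinned to 0 V (gauge); the solve is a
Jacobi-preconditioned conjugate gradient on the reduced symmetric
positive-definite system to a relative residual of 1e−8 by default
(1e−10 to 1e−12 in oracle tests). On one CPU the default phantom solves in
a few seconds at 200 µm and well under a minute at 100 µm. A multigrid
preconditioner would reduce iteration counts but adds nothing at these
problem sizes.

### Field summaries, montage ranking, safety

`roi_statistics()` reports unweighted voxel means and maxima of |E| and
|J| per label. `compare_montages()` ranks montages by the **maximin**
coverage score min(mean |E| over targets): a montage must reach *both*
neurogenic targets, and the maximin rule is the weakest-link reading of
that requirement. Ties break by summed target mean |E|, then input order.
With the default geometry the wide ±4 mm pair beats ±1 and ±2 mm variants:
closely spaced electrodes short-circuit through the dura/CSF shells and
penetrate less deeply — reproducing the qualitative finding that motivated
the montage. `lesion_threshold_current()` exploits linearity to report the
injected current at which the parenchymal maximum would reach the bound.

## Reconstructing the count statistics

For k groups summarized by (mᵢ, semᵢ, nᵢ):

* SD per group: sᵢ = semᵢ·√nᵢ;
* between-group sum of squares about the n-weighted grand mean,
  MSB = Σnᵢ(mᵢ−m̄)²/(k−1);
* pooled within-group mean square MSW = Σ(nᵢ−1)sᵢ²/(N−k);
* F = MSB/MSW on (k−1, N−k) df, p from the F distribution.

`anova_from_counts()` implements the classical raw-data path and the two
agree to 1e−10 on exact summaries (a property test), so the only error in
reconstructing published F values is the rounding of printed means and
SEMs — empirically ≲ 5% relative on F, the tolerance used throughout.
Five of the six published F(2,12) values are recovered within that
tolerance. The sixth (DCX in the SVZ, published F = 78.2) is **not**
consistent with its own published summaries (873 ± 71, 172 ± 51, 454 ± 39;
n = 5), which give F ≈ 40.7 by either computational path;
`reproduce_published_table()` flags this cell rather than forcing agreement.
Both values imply p < 1e−5, so no inferential conclusion changes.

Tukey HSD uses q = |mᵢ−mⱼ|/√(MSW/n) with the studentized-range
distribution evaluated internally: the classical double integral over the
range probability of k standard normals and the scaled-chi density of the
SD estimate, on fixed Gauss–Legendre grids (128 nodes in z over ±8.5, 160
nodes in s up to the 1−1e−13 chi quantile). Agreement with `stats::ptukey`
— used only as an oracle in the tests, never in the computation — is
better than 1e−8 over k ∈ {2,3,4}, df ∈ {6,12,20}, and the k = 2 case
collapses to the two-sided t-test as it must. Equal group sizes are
required; Tukey–Kramer is out of scope. p-values carry no multiple-testing
correction across the six ANOVAs, matching the published analysis.

Fold changes are simple mean ratios reported both raw and rounded to one
decimal; the four published ratios (3.6, 1.7, 2.6, 1.9) are reproduced
exactly after rounding.

### Aggregation convention

Counts are sampled in 6 sections × 3 views of 200 × 200 µm² per animal.
Whether a published per-animal value is the sum or the mean of its views
is not stated; the package defaults to the **sum**, which matches the
magnitude of the published group means (hundreds to thousands of cells —
a single 0.04 mm² view plausibly holds tens, not thousands), and exposes
`convention = "mean"` for the alternative.

## Synthetic data

`generate_animal_counts()` draws from Normal(µ, σ²) truncated at zero and
rounded — exactly the between-animal model the ANOVA assumes. Truncation
bias is negligible at the modelled scales (all published means exceed
their SD by ≳ 2.7×). `generate_view_counts()` adds the minimal hierarchy
that makes view aggregation testable: a latent per-animal total θ with
Poisson view counts at rate θ/18. The published data constrain only the
between-animal variance, so the animal/view variance split is a modelling
choice (Poisson at the view level, no extra overdispersion by default);
passing tests show the pipeline's arithmetic and power, not that real
sections are Poisson. A power property holds by a wide margin: with the
published Ki67/SVZ effect sizes, 2000 seeded replicates at n = 5 per group
reject H0 at α = 0.05 in > 99% of replicates.

`toy_phantom()` supplies the three solver oracles (uniform cube, layered
slab, point source in a grounded box). In the point-source box the sink is
spread over the whole outer boundary: a near-uniform shell sink adds an
almost constant potential inside, so radial potential drops follow the
free-space monopole I/(4πσr) — with a compact counter-electrode the
Neumann-wall images would contaminate the comparison at the 25% level.

## Problem sizes and determinism

Everything is deterministic for a fixed configuration and seed; the seeded
generators use R's default RNG. The test suite runs the head model at
400 µm (seconds per solve; odd ML grid so that mirror symmetry is exact
voxel-for-voxel) and the acceptance checks at 200 µm, with one 100 µm
reference solve in the refinement test. These resolutions were chosen as
the coarsest grids at which the reported region statistics are
grid-converged to a few percent.

## Known limitations

* The phantom is topological, not anatomical: 8 tissue classes, smooth
  ellipsoids, no skull/scalp (electrodes sit on the dura), no vasculature,
  no white-matter anisotropy, no glymphatics. Absolute field values at the
  targets are therefore indicative; the package's quantitative claims are
  the band-level ones tested (hippocampal mean |E| in 10–50 V/m, SVZ mean
  |J| in 1–10 A/m² at 100 µA) plus the exactly reproducible statistics.
* The uniform-flux electrode model mis-states fields within a voxel or two
  of the contacts (see above).
* Statistics reconstructed from printed summaries inherit their rounding;
  p-values near a decision boundary (the published 0.048) are reproduced
  to ±0.02, not exactly.
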