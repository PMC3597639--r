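---
title: "Methods: simulating and quantifying connexin gap-junction plaques"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying connexin gap-junction plaques}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cxplaque)
```

## The problem

Retinal astrocytes couple through gap junctions built from four connexin
isoforms (Cx26, Cx30, Cx43, Cx45). Six-marker immunofluorescence of retinal
wholemounts — the four connexins plus GFAP (astrocyte cytoskeleton) and GS
isolectin B4 (blood vessels) — lets one count gap-junction plaques, measure
their sizes, classify each plaque by which connexins it contains (15
nonempty subsets of four isoforms), and split all of it between astrocytes
lying in the parenchyma and astrocytes ensheathing vessels. Comparing young
and aged animals then asks which connexin classes change with age.

Because six fluorophores overlap spectrally, acquisition uses a lambda
stack — 32 images spanning 411–754 nm — and each voxel's spectrum is
decomposed into per-dye contributions against reference emission
fingerprints ("linear unmixing"). `cxplaque` implements that full chain,
plus a synthetic-scene generator with planted ground truth, so that every
stage is testable without access to any real images.

## Forward model (synthetic scenes)

`build_scene()` plants, per field of view:

* **Vessels**: cylindrical tube segments (default: two 4 µm-radius vessels
  crossing the field, an artery/vein pair typical of nerve-fibre-layer
  fields). The vessel mask drives the GS-lectin channel and defines the
  vascular compartment.
* **Astrocytes**: stellate cells (disk somata plus radiating processes)
  rendered into the GFAP channel.
* **Plaques**: per combination class and compartment, a Poisson-distributed
  count with configurable mean. Each plaque is a small in-plane ellipsoid
  (log-normal voxel count, default 2–30 voxels, `meanlog = log 5`,
  `sdlog = 0.5`) since the structures being modeled are small irregular
  puncta far thinner than the 8.2 µm optical section. Each member connexin
  contributes an independent log-normal intensity (default mean 120 a.u.,
  CV 0.25). Planted plaques never touch (26-neighbourhood separation):
  two unresolvable adjacent puncta are operationally a single plaque, so
  touching plants would make ground-truth counts ill-defined.

Vascular plaques are planted entirely within 2 µm of the vessel surface;
parenchymal plaques at least 3 µm further out, so planted compartment
labels are unambiguous under the recovery rule.

`render_lambda_stack()` mixes the per-channel abundance maps through
skewed-Gaussian emission fingerprints (AMCA 448, Alexa488 519, Alexa532
553, Cy3 569, Alexa594 617, Cy5 670 nm peaks; Gaussian core σ = 18 nm with
a slower red tail), adds a flat background (default 4 a.u./bin) and flat
autofluorescence (2 a.u./bin), then applies Poisson shot noise and Gaussian
read noise (σ = 2). With all noise terms zero the stack is the exact linear
mixture, which is what makes the render→unmix round trip an exact oracle.

Geometry defaults follow the modeled acquisition: 512×512 pixel frames, a
thin z-range of 8.2 µm sections, 32 bins spanning 411–754 nm with both
endpoints on the grid (so the per-bin width is ~11 nm rather than a rounded
10). The xy pixel pitch is *not* fixed by the acquisition description; we
assume 0.28 µm (a typical 63×/1.4 oil configuration) and expose it as
configuration. Tests and the bundled cohort use 128×128×3 fields — the
statistical structure (counts per field, not pixels per field) is what the
quantification consumes, and smaller fields keep full-cohort simulations
cheap without changing per-field plaque statistics.

## Spectral unmixing

`linear_unmix()` solves, per voxel, `min ||s − Bx||₂` with `x ≥ 0`
(nonnegativity is the default because abundances are physical dye
quantities; the unconstrained solution is retained as an option for
comparison). The solver treats every voxel independently — no spatial
regularization — mirroring online instrument unmixing and keeping the
oracle simple.

For K ≤ 10 fluorophores the exact NNLS solution is found by vectorized KKT
screening over all 2^K support sets: the objective is strictly convex, so
the unique support whose equality-constrained solution is feasible and
dually feasible is the global optimum. This turns per-voxel NNLS into ~64
batched matrix products over all voxels at once. Larger K falls back to
per-voxel Lawson–Hanson. The suite verifies exact agreement with an
independent dense solver (`pracma::lsqnonneg`).

Two practical points:

* **Background column.** A flat fingerprint appended to the design matrix
  (`background = TRUE`, the pipeline default) absorbs the uniform
  background + autofluorescence. Without it, the flat offset is projected
  onto the broad dyes and inflates their abundance maps.
* **Rank checks.** Reference sets are rejected when rank-deficient and the
  error names the most collinear fluorophore pair; the condition number is
  recorded on every `reference_spectra` object.

`extract_reference_spectra()` rebuilds fingerprints from user ROIs (mean
spectrum, optional median-background subtraction, unit-sum normalization),
the in-silico analogue of building an emission-fingerprint database from
regions of interest.

## Segmentation and classification

`segment_channel()` thresholds one abundance channel and labels 3D
connected components. Defaults and their reasons:

* **Connectivity 26** — surface-oriented commercial tools merge diagonal
  contacts; 6 and 18 are available since the source workflow does not
  state a rule.
* **Threshold** — the original workflow used unpublished *manual*
  per-channel thresholds. We default to `"otsu_sparse"`: Otsu iterated on
  the supra-threshold tail until the foreground fraction drops below 1%.
  Plain Otsu is available but fails a known failure mode: with puncta
  occupying ≪1% of the field, the histogram is effectively unimodal and
  Otsu lands inside the background noise; iterating climbs out of the
  background mode. A numeric manual threshold overrides both.
* **min_size 2 voxels** — suppresses single-voxel shot-noise detections.

Object ids are ordered by each object's lexicographically smallest
(z, y, x) voxel, making labeling deterministic. Sizes are reported in
voxels, µm³ (count × voxel volume) and 2D pixel footprint (z-projection
area), matching how plaque sizes are tabulated in the modeled study.

`merge_channels()` performs object-based colocalization: per-channel
objects are graph nodes, edges join objects from different channels that
share ≥ 1 voxel (default; a centroid-distance rule is the alternative,
since the original criterion is internal to the instrument software), and
each connected component becomes one plaque whose class is the union of
its members' channels. The package records co-occurrence only: no
inference about heteromeric vs heterotypic channel architecture is
attempted, since colocalization cannot distinguish them.

`assign_compartment()` calls a plaque vascular iff ≥ 50% of its voxels lie
within 2 µm of the vessel mask — an operationalization of the
"processes ensheathing vessels" criterion; in the pipeline the vessel mask
itself is segmented from the unmixed GS-lectin channel, keeping the chain
end to end.

## Quantification

Counts are averaged over all 24 fields of a retina (8 fields × 3 retinal
regions), divided by the relevant reference area (field area for
parenchymal plaques; measured vessel surface area for vascular ones), and
scaled to whole-retina totals by the total retinal area (default 52 mm²)
or total vessel surface area (default 15 mm²) — both inputs, as in the
modeled workflow, which derived them from separate montage images. SEM
uses n = retinas. `number_times_size()` gives the count × mean-size product
index per connexin.

Surface area from a mask uses the coarea formula — the integral of the
gradient magnitude of the Gaussian-smoothed indicator — which converges to
the interface area and sits within 5% of the closed form for a cylinder at
isotropic voxels (verified in the suite). From tube specifications the
analytic lateral area Σ2πrL is used directly.

**Percent change** between 3- and 22-month totals is reported both raw and
truncated toward zero to a signed integer. Truncation is the convention
that reproduces the printed reference table this package re-derives: all
25 internally consistent integer rows match exactly under truncation
(422.96→422, 176.60→176, −52.67→−52, 72.99→72, 171.93→171 — several of
which rounding would get wrong). Three caveats are documented rather than
modeled: one row prints 636 where its own totals give +635.69 (rounding,
not truncation), one row prints a percent inconsistent with its own
printed totals (71 vs +43.38), and the two sub-10% rows are printed with
one decimal. The bundled copy of the printed totals
(`table2_totals()`) ships in `inst/extdata/`.

## Statistics

`anova_bonferroni()` is a classical one-way ANOVA plus all pairwise
comparisons using the pooled ANOVA mean-square error, each p multiplied by
the number of pairs (capped at 1) — i.e. classical Bonferroni post-hoc,
the natural reading of "ANOVA with Bonferroni correction". Retinas (n = 4
per age), not fields, are the replicate unit, following the modeled
design. The suite cross-checks F/p against `stats::aov` and the pairwise
adjusted p against `pairwise.t.test(pool.sd = TRUE)`.

## The bundled cohort and what passing tests show

`run_config()` defaults describe a 2-age (3 vs 22 months) × 4-retina × 24
field cohort with a planted aging effect: 6-fold homotypic Cx30 increase,
flat Cx43, halved Cx26, doubled Cx45 and Cx26/Cx45 — round effect sizes
echoing the qualitative pattern of the modeled system. Baseline per-field
class means follow the young-adult ranking (homotypic classes dominant,
Cx26 most abundant; multi-connexin classes roughly an order of magnitude
rarer). On this cohort the pipeline recovers the planted +500% Cx30 change
within ±15% relative in both compartments, leaves Cx43 within ±20%, and
flags Cx30 (not Cx43) at Bonferroni-adjusted p < 0.05; detection
efficiency is ~95% and, critically, balanced across ages, which is why
ratio quantities (percent change) are recovered more tightly than absolute
counts.

What the synthetic scenes do **not** emulate: optical blur (no PSF
convolution), bleaching, depth-dependent attenuation, real plaque
morphology (ellipsoids vs irregular puncta), fingerprint estimation error
(the renderer and the unmixer share the same spectra unless you extract
them from ROIs), and montage-level area measurement. Passing tests
therefore demonstrate correctness of the computational chain under a known
forward model — not that the specific biological numbers of any real
retina would be reproduced.

## Numerical choices

* NNLS feasibility/dual tolerances scale with each voxel's gradient norm
  (`1e-9` relative); degenerate voxels fall back to Lawson–Hanson.
* Otsu uses 256 histogram levels on the intensity-normalized channel.
* The coarea surface estimator smooths with σ = 1.2 × the smallest voxel
  pitch; gradients are clamped at volume borders, so structures cut by the
  field edge contribute no spurious end-cap area.
* Poisson noise is applied as `Pois(signal/gain)·gain`, then Gaussian read
  noise, then clamping at zero (the clamp slightly biases the deepest
  shadows; negligible at the default background of 4 a.u.).
* All randomness flows from one integer seed: scenes, renders and field
  iterations derive bounded sub-seeds; RNG state is saved and restored
  around every seeded computation.

## Known limitations

* Very crowded fields undercount: plaques merged by the 26-connected
  segmentation cannot be split (no watershed), so fold changes much above
  the bundled 6-fold, or baseline densities much above the defaults, will
  bias recovery downward.
* The compartment rule is distance-based only; a plaque sitting on an
  astrocyte process that happens to pass near a vessel is called vascular.
* Absolute per-retina totals depend linearly on the configured whole-organ
  areas; only ratio quantities are area-independent.
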