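---
title: "Quantifying histone-modification dynamics in live embryo movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying histone-modification dynamics in live embryo movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fabquant)
```

## The measurement problem

Fab-based live endogenous modification labeling (FabLEM) injects
fluorescent antigen-binding fragments against a histone or RNA polymerase II
modification into an embryo. Because Fabs bind their target transiently and
diffuse freely through nuclear pores, the *nucleus-to-cytoplasm (N/C)
intensity ratio* of a Fab channel tracks the global level of its target
modification in each nucleus, and bright intranuclear *foci* report local
enrichment at strongly transcribed loci (in early zebrafish embryos, the
two alleles of the miR-430 cluster). fabquant turns multichannel 3D+time
recordings of cleavage-stage embryos into these quantities:

1. nuclei are segmented and tracked through interphase on a broad nuclear
   marker channel (e.g. H3K9ac-Fab);
2. each nucleus gets a *cytoplasmic ring mask* at a fixed physical distance
   from its surface — between 3.3 µm and 8.3 µm — and the
   background-corrected ratio of nuclear to ring mean intensity is the N/C
   ratio;
3. foci are detected inside nuclei, measured through a 1 µm-diameter
   circular ROI on the z-plane of maximal cross-section, and normalised to
   the whole nucleus (foci/nucleus ratio); the per-channel peak times of
   those ratio time courses order events such as acetylation versus
   elongating-polymerase accumulation;
4. FRAP recovery series are normalised to their pre-bleach mean and fitted
   with double-exponential association kinetics
   $I(t) = P_1(1-e^{-k_1 t}) + P_2(1-e^{-k_2 t}) + C$, summarised by the
   amplitude-weighted half-time
   $t_{1/2} = \frac{P_1}{P_1+P_2}\frac{\ln 2}{k_1} +
   \frac{P_2}{P_1+P_2}\frac{\ln 2}{k_2}$.

No public raw recordings exist for this kind of experiment, so the package
carries a first-class synthetic-embryo generator with complete ground
truth; every stage of the pipeline is validated against it.

## Geometry and conventions

Volumes are arrays ordered `(y, x, z)` and movies `(y, x, z, frame)`;
voxel spacing is a named vector `c(z=, y=, x=)` in µm and all physical
parameters are given in µm and seconds. Frames are 1-based and the time of
frame *f* is `t0 + (f-1) * frame_interval`. Distances between voxels are
anisotropic Euclidean distances between voxel centres, computed by an
exact separable squared-distance transform (compiled code); "distance from
a nucleus" always means distance to the nearest voxel of its mask.
Detector units are never rescaled on input.

The ring mask implements the published dilation range as a distance band:
a voxel belongs to the ring of nucleus *i* iff its distance to nucleus *i*
lies in (3.3 µm, 8.3 µm], it is inside no nuclear mask, and it is farther
than 3.3 µm from every nucleus (`exclude_all_nuclei`, default on). For
isotropic voxels this is the same set that repeated unit dilations
produce; for 4 µm z-steps it is better defined. Rings of neighbouring
nuclei may overlap and each nucleus is measured independently. The N/C
ratio subtracts a per-frame, per-channel background from both
compartments — the only convention that leaves the ratio invariant under
affine detector transforms — with the background taken as the median
intensity of all voxels beyond 8.3 µm of every nucleus (the far field).

## Segmentation and tracking choices

Thresholding is per-frame Otsu on a Gaussian-smoothed marker (σ = 1 µm,
converted per axis by the voxel spacing), which tolerates the rising Fab
signal across stages. Early-embryo fields are often tri-modal — mounting
medium, cytoplasm, nuclei — and a single Otsu split then separates embryo
from medium; when the selected class is itself strongly bimodal
(between-class variance ratio of a second split > 0.7) the threshold is
re-computed within it. The label masks are finally tightened to the raw
marker at the same threshold, because smoothing otherwise inflates every
nucleus by a partial-volume shell of cytoplasm that dilutes nuclear means.

Touching nuclei are split by a distance-transform-seeded watershed: seeds
are 3D local maxima of the anisotropic depth map, suppressed when closer
than `seed_min_distance_um` to a deeper seed, shallower than half that
distance, or less than half as deep as their component's deepest seed (the
last two rules remove bridge/neck maxima); each connected component is
then partitioned among its seeds by proximity. `seed_min_distance_um`
should exceed the z-step (discrete depth plateaus otherwise split one
nucleus across planes) and stay below the closest true nucleus spacing;
the default is 5 µm, and 4.5 µm is used for the dense doubling movie
analysed below. Frames whose components are all smaller than
`min_volume_um3` or all larger than `max_volume_um3` are reported empty —
that is what a blank frame or a fully dispersed mitotic frame looks like —
while mixed frames keep their out-of-bounds objects flagged (`too_small`,
`too_large`, `border`), never deleted. `flag_mitotic` additionally flags
objects by low solidity (a moment-based convexity proxy) or low marker
contrast against a 2 µm perinuclear shell; all cutoffs are strict
inequalities.

Tracking links detections frame to frame by maximum-weight bipartite
matching on centroid displacement with a hard gate
(`max_displacement_um`); among matchings of maximal cardinality the total
displacement is minimal, which survives the coherent, path-crossing motion
of cleavage-stage nuclei where nearest-neighbour linking swaps identities.
Tracks bridge at most `max_gap` (default 1) missed frames and end silently
at mitosis; lineage is not inferred. Manual review is replaced by an
ordered corrections CSV (`reassign`, `terminate`, `merge`, `delete`)
applied in file order; order dependence is documented rather than resolved
by constraint solving. Developmental stages are annotated from the
interphase count series: a division wave is called when the
running-median-smoothed count first exceeds 1.5× the median of the current
cycle's positive counts, and the embryo-wide stage label doubles at each
wave.

## Foci and peak ordering

The original measurements placed 1 µm ROIs by hand; fabquant replaces the
placement with a deterministic detector — difference-of-Gaussians band-pass
at `detection_sigma_um` (and 1.6×) restricted to the nuclear interior,
local maxima above `prominence` nuclear standard deviations, ranked and
kept up to `max_foci = 2` (the two alleles of a single locus) — while
keeping the measurement protocol itself: the z-plane maximising the
focus's half-max cross-sectional area is selected per time point, ROI
pixels are those whose centres fall within 0.5 µm of the focus centre
(closed boundary), and all ROI intensities are summed. Because the
published protocol does not say whether the whole-nucleus reference was
summed or averaged, both ratios are always reported; the default is
mean/mean, which is invariant to nucleus size. With a `reference_channel`
set, ROIs detected on that channel are measured identically in every
channel (bit-identical pixel sets). Peak times are the argmax of a
3-frame moving average, ties to the earliest point, and a monotone series
peaks at its last point by convention.

## FRAP fitting

Curves are background-subtracted and normalised so the pre-bleach mean is
exactly 1. With `bleach_index` pre-bleach frames, t = 0 is the first
post-bleach sample (the association form reaches `C` at t = 0) and the
fitted window starts `fit_start_offset` (default 4) frames after the
bleach. The fit is bounded Levenberg–Marquardt
(`p ∈ [0, 1.5]`, `k ∈ [10⁻⁶, 10³] s⁻¹`) with multi-start initialisation
over rate pairs spanning three decades; the best residual wins, components
are reordered so `k1 ≥ k2`, and a `k1/k2 < 3` fit warns that the
components are barely distinct. A single-versus-double exponential F-ratio
is reported but never switches the model. The published half-time formula
contains sign/operator slips (its `ln(1/2)` terms are negative and a
product appears as a difference); the amplitude-weighted `ln2/k` form —
positive, symmetric and exact in the single-component and equal-rate
limits — is what `half_time()` computes, and the literal printed
expression stays available behind `literal = TRUE` for audit only.

## What the generator emulates — and what it does not

`simulate_embryo_movie()` renders a blastoderm cap (a lateral ellipse of
cytoplasm over pure background — the cap does not grow as cells divide) in
which hard-edged spherical nuclei undergo synchronous cycles: interphase,
a mitotic phase in which nuclear signal disperses into the cytoplasm and
no interphase ground truth exists, then replacement of each nucleus by two
displaced, smaller daughters. Channels carry an N/C trajectory (nuclei
render at `bg + nc·(cyto − bg)`), optional pairs of antipodal Gaussian
foci whose amplitude follows a triangular ramp with a configurable peak
time (the simplest peaked shape with an unambiguous ground-truth peak),
and Poisson plus Gaussian detector noise quantised to integer counts.
Defaults describe a confocal-like recording: 0.8 µm lateral pixels, 4 µm
z-steps, 60 s frames, 15 min cycles with 3 min mitoses, 5 µm nuclei,
cytoplasm 200 over background 50 counts. The cap is sized so the far
field stays background-dominated; otherwise the median background
estimator — which the measurement model fixes — would be biased by
cytoplasm.

Deliberately not emulated: optics (no PSF, hard nuclear edges), embryo
curvature and drift, light-sheet striping, asynchronous divisions,
photobleaching, chromosome rendering during mitosis. Passing tests
therefore demonstrate that the measurement chain is correct and unbiased
under the stated statistical structure, not that segmentation is robust to
every optical artefact of real recordings.

## Validation conditions and numerical choices

The test suite validates each stage against ground truth or independent
brute-force oracles (all-pairs distances for ring geometry, pixel
enumeration for the ROI disc, direct evaluation for the FRAP model). The
end-to-end conditions use a 256×256×8, 60-frame movie with 64-cell to
512-cell-like doubling (8 → 64 nuclei in view, radii 5 → 3.07 µm with a
0.85 per-cycle shrink so nuclei stay above the 4 µm axial sampling
limit): per-frame median N/C ratios stay within 5% of truth on both a
constant (4.0) and a ramping (1 → 3) channel, stage labels match ground
truth in ≥ 95% of frames, and tracking shows < 2% identity switches. A
20-seed study with focus peaks staggered by three frame intervals
recovers the sign of the peak-time difference in ≥ 95% of nuclei.
Problem sizes were chosen so the whole suite runs in minutes; the same
quantities are recomputed by `scripts/acceptance.R`.

Numerical conventions worth knowing: Otsu on 256 histogram bins (scale
invariant up to threshold-tie voxels); ROI and ring bands use closed upper
boundaries with a 10⁻⁹ relative epsilon against floating-point exclusion
of exact-boundary pixels; detection ties break lexicographically in
(z, y, x); the simulator consumes a single seed and is bit-reproducible,
and the pipeline writes a run manifest (config hash, seed, package
version) so re-runs can be audited.

## Known limitations

Solidity is a moment-based proxy, not a convex-hull ratio; it is a QC
heuristic, not a morphometric. The far-field background estimator requires
signal-free background in the field of view — fields fully covered by
embryo need a different background strategy. Watershed seeding assumes
nuclei are at least as far apart as `seed_min_distance_um` and deeper than
half of it; nuclei smaller than the z-step are not reliably separable.
Identity switches are minimised, not provably zero, when nuclei approach
within the displacement gate; the corrections mechanism exists precisely
for that residue. The FRAP model is the published two-population
association form; reaction–diffusion kinetics and bleach-spot geometry are
out of scope.
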