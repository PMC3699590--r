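---
title: "Building and using a probabilistic brain atlas: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and using a probabilistic brain atlas: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`atlaskit` implements a complete small-animal MRI atlas pipeline: from a
cohort of labeled T1-like volumes it builds an average-shape,
average-intensity population template and per-region probability maps, and
then parcellates new volumes automatically by registering the template to
them and assigning each voxel to the most probable region. This vignette
records the methods, the numerical choices, and the reasoning behind design
decisions that were genuinely open — the kind of detail a maintainer or a
reviewer of the method would want and that does not fit in function
reference pages.

## Coordinate conventions

All spatial computation happens in 0-based voxel coordinates of a fixed
grid. Voxel spacing (mm) and a world origin are carried as metadata and
written to NIfTI headers, but no operation reslices through an orientation
matrix: orientation handling varies wildly between acquisition pipelines,
and keeping every transform in voxel space makes each operation testable
without reference headers.

Non-rigid transforms are dense displacement fields under the *pull-back*
convention: warping a moving image by a field `d` defined on the fixed grid
samples the moving image at `x + d(x)`. Affine transforms follow the same
resampling convention (`M x + t` gives the sampling position). Pull-back
fields compose exactly: refining an accumulated field `a` by an increment
`e` estimated on the fixed grid gives `e(x) + a(x + e(x))`, which is what
`compose_fields()` computes. An affine followed by an elastic refinement
collapses to the single field `M (x + d(x)) + t − x`
(`compose_affine_field()`), so data are resampled once, not twice — with
structures only one or two voxels thick, every avoided interpolation pass
is measurable in the final Dice.

## Registration

Two registration engines are provided, matching the two jobs the pipeline
needs.

**Affine, by mutual information.** `register_affine_mi()` estimates a
12-parameter transform (translation, rotation, log-scale, shear) maximizing
the joint-histogram mutual information, which is invariant to monotone
intensity remappings and therefore usable across modalities (T1 against a
diffusion baseline, for instance). The optimizer is a deterministic
coordinate-descent with step halving on a coarse-to-fine pyramid; MI under
histogram binning is piecewise constant, so derivative-free search is the
appropriate tool. Two details matter in practice. The histogram bin ranges
are fixed per pyramid level from the *unwarped* images; recomputing them
from each candidate's warped output makes objective values incomparable
between candidates, and the search then drifts into small scale/shear
errors that amount to about a voxel at the brain edge. And the
rotation/scale/shear steps shrink with pyramid level, since those
parameters act over the whole field of view and only need refining once the
translation is roughly right.

**Elastic, by block matching.** `register_elastic()` places cubic blocks
(default 5³ voxels every 3 voxels) over the fixed image and exhaustively
searches integer offsets within a radius (default 3) for the maximum
Pearson correlation against the current warped moving image, on a
multiresolution pyramid (default 3 levels, 2 iterations per level). Blocks
whose intensity variance falls below a fraction (default 1e-6) of the
squared intensity range are skipped: uniform regions carry no matching
information. Offsets are deliberately integer — subvoxel accuracy comes
from the Gaussian scatter of per-block offsets into a dense field
(default sigma 2 voxels) and from composition across pyramid levels, which
keeps the search exhaustive, deterministic and cheap.

The scatter uses *ridge-regularized* normalized convolution: smoothed
offsets divided by smoothed block weights plus a ridge of 5% of the peak
weight. Plain normalized convolution extends boundary estimates unchanged
into signal-free space; at coarse pyramid levels (where the smoothing
kernel spans much of the grid and offsets are upsampled four-fold) this
filled the empty background with multi-voxel junk vectors. The ridge makes
the field decay smoothly to zero away from any informative block, which is
also the correct statement of ignorance: where there is no signal, the
best displacement estimate is none.

Ties in the block search go to the smaller squared offset, then to search
order; ties in every label-voting or argmax step go to the smaller region
id, with background (id 0) allowed to win ties it takes part in. These
rules are arbitrary but fixed, which is what reproducibility needs.

On the synthetic cohort (48³ voxels, deformations of 2-voxel amplitude,
5% noise) the elastic engine recovers a known smooth field with a mean
foreground endpoint error of ≈ 0.35 voxels, and the affine engine recovers
a 3-voxel translation to within 0.3 voxels; those two numbers set the scale
for everything downstream.

## Template construction

The template is built in three stages.

1. **Reference selection.** Every candidate subject is elastically
   registered to every other; the candidate whose fields have the smallest
   average mean displacement — the "most normal" subject, needing the least
   transformation to reach everyone else — initializes the template. Ties
   go to the lowest index.
2. **Average shape.** The current template is registered toward every
   subject (subject as the fixed grid, template as moving), the fields are
   averaged voxelwise, and the template is warped by the mean field. With
   the fields oriented this way, the pull-back application of the averaged
   field moves the template toward the population's shape barycenter; on a
   two-subject population deformed by `+f` and `−f` this provably
   contracts toward the undeformed shape, whereas fields estimated in the
   opposite direction make the same literal update diverge — an easy sign
   error to make, caught by the contraction test. Iteration stops when the
   mean displacement of the mean field drops below `tol` (default 0.1
   voxel), or when it stops decreasing: registration noise puts a floor
   under the metric (background voxels carry no displacement information),
   and once the update is no longer contracting, applying it only degrades
   the template. The accumulated warp is composed and applied to the
   *original* reference each iteration, so the template is the product of
   exactly one resampling however many iterations run.
3. **Average intensity.** Every subject is registered onto the converged
   shape and resampled there; at each voxel the template intensity is the
   mean after excluding values more than 2 sample standard deviations from
   the voxel mean (one pass, two-sided by default with an upper-sided
   variant behind `trim_side`). This protects the template against
   occasional misregistration without the expense of robust M-estimation.
   Note that with n = 10 a single gross outlier sits near z ≈ 2.85 and is
   excluded; two-sided trimming can never empty a voxel for n ≥ 2.

The fields stored in the final model map template-grid voxels to sampling
positions in each subject. That is exactly the resampling needed to carry
each subject's labels onto the template (nearest-neighbour pull-back), so
probability-map construction requires no numerical field inversion — a
deliberate choice, since field inversion is itself an error source.

## Probabilistic atlas and parcellation

The probability of region `r` at template voxel `x` is the fraction of
subjects whose propagated label there is `r`. Probabilities are therefore
multiples of `1/N` and, with background counted (out-of-field votes are
background votes), sum to exactly 1 at every voxel. Segmentation of a new
volume registers the template to it — MI affine first (the default), its
result seeding the elastic stage — then resamples every probability map
with *trilinear* interpolation and takes the per-voxel argmax. Resampling
the soft maps rather than a hard label map preserves partial-volume
information at region borders, which is where parcellations are won and
lost; the winning probability is returned alongside the labels as a
per-voxel confidence.

## Evaluation

Per-region overlap uses the Dice coefficient, with the conventions Dice = 1
when a region is empty in both maps and 0 when empty in exactly one. The
global matching index is label-aggregated Dice — the sum of intersections
over the sum of region sizes across all non-background regions — which
weights regions by size; a per-region-mean variant is available
(`method = "mean"`) for sensitivity analysis because summary indices of
this kind are sometimes reported as plain means of per-region values. The
confusion matrix is row-normalized to percent over reference regions, with
background as an explicit row and column and empty reference rows flagged
rather than silently zeroed. `merge_bilateral()` folds left/right pairs of
the same structure into single regions (the default 60-entry rabbit-like
table merges to 35), since bilateral structures are usually reported
jointly.

## The synthetic cohort: what it does and does not emulate

`synth_population()` stands in for the imaging study: a deterministic base
phantom, per-subject smooth random deformations (Gaussian-smoothed white
noise rescaled so the maximum displacement equals the amplitude), fresh
per-region and global intensity noise, and retained ground-truth fields
and labels so every stage can be scored against truth.

The base phantom is an ellipsoidal brain (filling ~80% of the grid) built
from nested layers: an outer cortical shell divided into azimuthal sectors,
a sub-cortical band shared by the white-matter and "other" structure
groups, and deep-gray nuclei as ellipsoidal blobs in the core. Default
parameters come from reference statistics of an adult rabbit brain
parcellation: per-region volume fractions, relative T1 intensities (brain
mean = 1), FA and relative MD, for twelve regions chosen so their
volume-weighted mean relative T1 is ≈ 1 (keeping recovered relative
intensities directly comparable to the reference values). Layer radii are
solved so each layer's volume matches its regions' summed fractions, and
sector angles are proportional to fractions — in normalized ellipsoid
coordinates both relations are exact, so realized voxel counts land within
discretization error of their targets.

One geometry decision deserves its own paragraph. The white-matter group
totals only ~3.8% of brain volume; as its own full shell that is ~0.3
voxels thick at the default 48³ grid — a structure that cannot be
represented on the grid at all (it discretizes to scattered voxels) and
that no radiological protocol would delineate at that resolution. The
phantom therefore places white-matter and "other" regions as sectors of one
shared band, making every region at least a voxel or two thick. This is a
statement about resolvability, the same constraint that leads real atlas
protocols to exclude structures finer than the acquisition can support; it
changes no cohort parameter (population size 10, 48³ grid, 12 regions,
2-voxel deformations, 5% noise, reference volume fractions and
intensities).

The diffusion generator gives each region a cylindrically symmetric tensor:
the unique eigenvalues with λ2 = λ3 matching an FA target below 1 and a
trace of three times the MD target are available in closed form
(λ1 = MD(1+2δ), λ2 = MD(1−δ), δ = FA/√(3−2FA²)). Relative MD values are
scaled by 2×10⁻⁴ mm²/s — a representative diffusivity for fixed post-mortem
tissue at room temperature — so that with b = 3000 s/mm² the weighted
signals sit in a realistic attenuation range.

What the generator does **not** emulate: bias fields, Rician noise
statistics, partial-volume smoothing at acquisition, susceptibility or
eddy-current distortion, or any real neuroanatomy — regions are geometric
sectors and blobs, placed conveniently, with none of the shape complexity
of cortex or hippocampus. Passing the end-to-end tests therefore
demonstrates that the pipeline's machinery is correct and self-consistent
under known ground truth; it does not certify accuracy on real
acquisitions, where registration difficulty is dominated by exactly the
effects the generator leaves out.

## Problem sizes and runtimes

The shipped analyses and tests run at population size 10 on 48³ grids with
12 regions (unit tests use 24³ with an 8-region subset where registration
accuracy is not itself under test). At this scale a single elastic
registration takes roughly a second on one core, the full template plus
atlas build from nine subjects about a minute, and the complete end-to-end
validation a few minutes. These sizes were chosen so that the whole
analysis reruns comfortably on a laptop while every structural feature of
the full-scale problem (thin structures, multi-region competition,
background handling) is still present.

## Known limitations

- The elastic model is smoothed block matching: no diffeomorphic guarantee,
  no inverse consistency. Large or non-smooth deformations (beyond the
  pyramid's capture range of roughly `search_radius × 2^levels` voxels)
  will not be recovered.
- The atlas argmax competes regions against background only through the
  propagated label fractions; there is no intensity-driven posterior
  refinement (EM-style), which is listed as future work rather than hidden
  behind a flag.
- The tensor fit is ordinary least squares on log-signals: unweighted,
  unconstrained, with negative eigenvalues allowed and flagged rather than
  clamped. At very low SNR a weighted or positivity-constrained fit would
  behave better.
- NIfTI headers are single precision, so voxel spacings like 0.27 mm round
  trip only to float32 accuracy; all internal computation is double.
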