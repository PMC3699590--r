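# atlaskit

Atlas construction and atlas-based parcellation for small-animal brain MRI,
in R.

Regional analysis of animal-model MRI (volumetry, diffusion metrics,
connectivity seeds) needs every brain mapped to a common set of labeled
regions. Doing that by hand is the bottleneck; doing it automatically needs
a digital atlas: a population-average template plus a spatial model of where
each region lies. `atlaskit` implements that whole workflow for researchers
building such atlases from cohorts of labeled volumes:

- **Delineation bootstrap** — propagate existing parcellations to a new
  subject by elastic registration and fuse them by per-voxel majority vote,
  giving each new subject a starting parcellation instead of a blank slate.
- **Average template** — pick the reference needing the least deformation to
  reach everyone else, iterate registration + mean-deformation updates to an
  average *shape*, then average the registered *intensities* with 2-SD
  outlier trimming.
- **Probabilistic atlas** — carry every subject's labels onto the template;
  the probability of region *r* at voxel *x* is the fraction of subjects
  labeled *r* there:

  p_r(x) = |{ i : L̃_i(x) = r }| / N

- **Automatic parcellation** — register the template to a new volume
  (mutual-information affine seeding multiresolution block-matching elastic
  registration), resample the probability maps, and label each voxel by
  maximum probability.
- **Evaluation** — per-region Dice DC_r = 2|A_r∩B_r| / (|A_r|+|B_r|), a
  label-aggregated global matching index, and a row-normalized confusion
  matrix; left/right structures mergeable for bilateral reporting.
- **Diffusion support** — log-linear least-squares tensor fit, eigenanalysis,
  FA/MD, FA-weighted direction color maps, and gradient-table reorientation
  (rotation component of the affine by polar decomposition) for multimodal
  delineation.
- **Synthetic cohort generator** — a labeled ellipsoidal phantom
  parameterized by reference rabbit-brain region statistics (volume
  fractions, relative T1, FA, MD), deformed per subject by smooth random
  fields with retained ground truth, so the entire pipeline is testable
  end-to-end without any data download.

The compute-heavy kernels (block matching, warping, smoothing, joint
histograms) are in C++ via Rcpp; everything else is plain R over RNifti,
jsonlite and yaml.

## Worked example

Generate the default phantom, check that its regional statistics recover
the generating parameters, and fit diffusion tensors on its synthetic DWI:

```r
library(atlaskit)

p  <- synth_params(seed = 1)       # 10 subjects, 48^3 voxels, 12 regions
ph <- make_phantom(p)
ph$volume
#> <volume> 48 x 48 x 48 voxels, spacing 1 x 1 x 1 mm, range [0, 147.2]
ph$labels
#> <label_map> 48 x 48 x 48 voxels, 12 regions, 11432 labeled voxels

st <- region_statistics(ph$volume, ph$labels, normalize = TRUE)
head(st[, c("name", "n_voxels", "volume_pct", "rel_intensity")], 6)
#>               name n_voxels volume_pct rel_intensity
#> 1   Frontal cortex     1488      13.02         0.932
#> 2  Parietal cortex     1052       9.20         0.862
#> 3  Temporal cortex     1118       9.78         0.825
#> 4 Occipital cortex      630       5.51         0.801
#> 5 Internal capsule      278       2.43         1.284
#> 6   Corona radiata      298       2.61         1.175
```

`rel_intensity` is the region mean divided by the whole-brain mean, so the
internal-capsule-like region reads 1.284 against its generating value of
1.28: bright white matter sits ~28% above the brain average, as specified.

```r
dwi <- synth_dwi(ph$labels, p, noise_sd = 0)
ti  <- fit_tensor(dwi, ph$labels$labels > 0)
fav <- fa(eigen_decompose(ti)$lambda)
median(fav[ph$labels$labels == 5])   # internal-capsule-like region
#> [1] 0.35                           # FA target for that region: 0.35
```

The full study — simulate a cohort, bootstrap delineations, build the
template and probabilistic atlas from nine subjects, parcellate the held-out
tenth and score it — is laid out as numbered drivers under `analysis/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_dti.R
Rscript analysis/03_bootstrap_delineation.R
Rscript analysis/04_build_atlas.R
Rscript analysis/05_segment_evaluate.R
```

Each script prints what it found and writes its tables and images under
`results/`. On the default cohort, step 5 reports a global matching index of
0.87 and a mean per-region Dice of 0.83 against the held-out subject's
ground truth, with segmenting the template itself reproducing the atlas's
own labeling exactly (Dice 1.0) — i.e., automatic parcellation recovers the
regions to within the registration error, not the atlas representation.

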