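# Small-scale fixtures shared by the unit tests. Everything is generated in
# code; the reduced grid and region subset keep individual registrations fast
# while exercising every group of the phantom geometry.

small_specs <- function() {
  rs <- default_region_specs()
  rs[rs$name %in% c("Frontal cortex", "Parietal cortex", "Internal capsule",
                    "Corona radiata", "Mesencephalon", "Vermis",
                    "Thalamus", "Hippocampus"), ]
}

small_params <- function(seed = 1L, ...) {
  synth_params(grid_shape = c(24L, 24L, 24L), region_specs = small_specs(),
               deform_amplitude = 1.5, deform_smoothness = 4,
               n_subjects = 3L, noise_sd_frac = 0.02, seed = seed, ...)
}

# Registration config scaled to the small grids (coarser pyramid, fewer
# histogram bins so the coarse-level joint histograms stay populated).
small_cfg <- function(...) reg_config(pyramid_levels = 2L, mi_bins = 16L, ...)

ramp_volume <- function(dims = c(8L, 8L, 8L)) {
  volume(array(seq_len(prod(dims)), dims))
}

# A tiny two-region parcellation on an n^3 grid: a box and a ball.
toy_labels <- function(n = 12L) {
  rt <- region_table(data.frame(
    region_id = c(1L, 2L),
    name = c("box", "ball"),
    group = c("cortical", "deep_gray"),
    hemisphere = c("midline", "midline")))
  lab <- array(0L, c(n, n, n))
  lab[2:5, 2:5, 2:5] <- 1L
  ctr <- n * 0.7
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n))
    if ((i - ctr)^2 + (j - ctr)^2 + (k - ctr)^2 <= 9) lab[i, j, k] <- 2L
  label_map(lab, rt)
}

random_label_map <- function(n, ids, regions, seed) {
  set.seed(seed)
  label_map(array(sample(c(0L, ids), n^3, replace = TRUE), c(n, n, n)),
            regions)
}

toy_region_table <- function(k) {
  region_table(data.frame(
    region_id = seq_len(k),
    name = paste0("region ", seq_len(k)),
    group = "other",
    hemisphere = "midline"))
}
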