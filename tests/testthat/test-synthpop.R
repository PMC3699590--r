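test_that("phantom generation is deterministic and honors volume targets", {
  p <- synth_params(seed = 3)
  ph1 <- make_phantom(p)
  ph2 <- make_phantom(p)
  expect_identical(ph1$volume$data, ph2$volume$data)
  expect_identical(ph1$labels$labels, ph2$labels$labels)

  brain_n <- attr(ph1, "brain_voxels")
  rs <- p$region_specs
  for (i in seq_len(nrow(rs))) {
    realized <- sum(ph1$labels$labels == rs$region_id[i]) / brain_n
    expect_lt(abs(realized / rs$vol_frac[i] - 1), 0.2)
  }

  # zero noise: each region is constant at its relative T1 times the scale
  rs0 <- rs; rs0$t1_sd <- 0
  p0 <- synth_params(region_specs = rs0, seed = 3)
  ph0 <- make_phantom(p0)
  for (i in seq_len(nrow(rs0))) {
    vals <- unique(ph0$volume$data[ph0$labels$labels == rs0$region_id[i]])
    expect_equal(vals, p0$intensity_scale * rs0$t1[i])
  }
  expect_equal(unique(ph0$volume$data[ph0$labels$labels == 0L]), 0)
})

test_that("random deformations hit their amplitude exactly and reproduce by seed", {
  expect_equal(max(abs(random_deformation(c(8L, 8L, 8L), 0, 3, 1)$d)), 0)
  f1 <- random_deformation(c(12L, 12L, 12L), 2, 4, 7)
  norms <- sqrt(apply(f1$d^2, 1:3, sum))
  expect_equal(max(norms), 2, tolerance = 1e-9)
  f2 <- random_deformation(c(12L, 12L, 12L), 2, 4, 7)
  expect_identical(f1$d, f2$d)
  f3 <- random_deformation(c(12L, 12L, 12L), 2, 4, 8)
  expect_false(identical(f1$d, f3$d))
})

test_that("synthetic subjects are warped copies of the base with retained ground truth", {
  p <- small_params(seed = 13)
  pop <- synth_population(p)
  expect_length(pop$subjects, p$n_subjects)

  s <- pop$subjects[[2]]
  # label maps equal the NN-warp of the base labels by the stored field
  expect_identical(s$labels$labels,
                   warp_volume(pop$base$labels, s$field)$labels)
  # distinct subjects received distinct deformations
  expect_false(identical(pop$subjects[[1]]$field$d, pop$subjects[[2]]$field$d))
  # full determinism of the generator
  pop2 <- synth_population(p)
  expect_identical(pop$subjects[[3]]$volume$data,
                   pop2$subjects[[3]]$volume$data)
  # smooth small-amplitude fields do not fold: forward differences of each
  # diagonal term of the Jacobian stay above -1
  d <- s$field$d
  n <- dim(d)[1:3]
  gx <- d[2:n[1], , , 1] - d[1:(n[1] - 1), , , 1]
  gy <- d[, 2:n[2], , 2] - d[, 1:(n[2] - 1), , 2]
  gz <- d[, , 2:n[3], 3] - d[, , 1:(n[3] - 1), 3]
  expect_gt(min(1 + gx), 0)
  expect_gt(min(1 + gy), 0)
  expect_gt(min(1 + gz), 0)
})

test_that("population output directory contains the documented artifact set", {
  dir <- withr::local_tempdir()
  p <- small_params(seed = 2)
  pop <- synth_population(p)
  write_population(pop, dir, p)
  expect_true(file.exists(file.path(dir, "base_t1.nii.gz")))
  expect_true(file.exists(file.path(dir, "regions.tsv")))
  expect_true(file.exists(file.path(dir, "params.json")))
  for (i in seq_len(p$n_subjects)) {
    expect_true(file.exists(file.path(dir, sprintf("subject_%02d_t1.nii.gz", i))))
    expect_true(file.exists(file.path(dir, sprintf("subject_%02d_labels.nii.gz", i))))
    expect_true(file.exists(file.path(dir, sprintf("subject_%02d_field.nii.gz", i))))
  }
  back <- read_volume(file.path(dir, "subject_01_t1.nii.gz"))
  expect_equal(back$data, pop$subjects[[1]]$volume$data)
})

test_that("infeasible region specs fail loudly", {
  rs <- default_region_specs()
  rs$vol_frac <- rs$vol_frac * 12
  expect_error(synth_params(region_specs = rs), "sum")
  expect_error(synth_dwi(toy_labels(6L), small_params(),
                         bvecs = gradient_directions(3L)), ">= 6")
  expect_error(atlaskit:::cylindrical_eigenvalues(1, 1), "FA target")
})
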