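test_that("reference selection minimizes mean pairwise displacement", {
  p <- small_params()
  base <- make_phantom(p, noise = FALSE)$volume
  cfg <- small_cfg()

  same <- list(base, base, base)
  expect_equal(as.integer(select_reference(same, cfg)), 1L)

  f <- random_deformation(p$grid_shape, 1.5, 5, 31)
  plus <- warp_volume(base, f)
  minus <- warp_volume(base, displacement_field(-f$d))
  vols <- list(plus, base, minus)
  ref2 <- select_reference(vols, cfg)
  expect_equal(as.integer(ref2), 2L)

  # displacement matrix equals an independently scripted loop
  D <- attr(ref2, "displacement_matrix")
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    d <- register_elastic(vols[[j]], vols[[i]], cfg)
    expect_equal(D[i, j], mean_displacement(d))
  }
})

test_that("mean shape iteration is exact for identical inputs and contracts toward the base", {
  p <- small_params()
  base <- make_phantom(p, noise = FALSE)$volume
  cfg <- small_cfg()

  same <- list(base, base, base)
  ms <- build_mean_shape(same, 1L, cfg)
  expect_true(ms$converged)
  expect_length(ms$history, 1L)
  expect_lt(ms$history[1], 0.1)
  expect_identical(ms$shape_template$data, base$data)

  # contraction toward the population barycenter, at full phantom scale so
  # the registration is well conditioned (thin shells need the resolution)
  pf <- synth_params(seed = 1)
  phf <- make_phantom(pf, noise = FALSE)
  basef <- phf$volume
  fgm <- phf$labels$labels != 0L
  cfgf <- reg_config()
  ff <- random_deformation(pf$grid_shape, 2, 6, 41)
  plus <- warp_volume(basef, ff)
  minus <- warp_volume(basef, displacement_field(-ff$d))
  ms2 <- build_mean_shape(list(plus, minus), 1L, cfgf, tol = 0.1,
                          max_iter = 6L)
  # the template must end up strictly closer to the (unseen) base than
  # either input subject: registration mean displacement over the brain
  dist_to_base <- function(v)
    mean_displacement(register_elastic(basef, v, cfgf), mask = fgm)
  d_tmpl <- dist_to_base(ms2$shape_template)
  expect_lt(d_tmpl, dist_to_base(plus))
  expect_lt(d_tmpl, dist_to_base(minus))
})

test_that("2-SD intensity trimming follows the single-pass rule", {
  trim <- atlaskit:::trimmed_mean_rows
  # outlier at z = 2.83 sample SDs: excluded, survivors' mean remains
  x1 <- matrix(c(rep(1, 9), 100), ncol = 1)
  expect_equal(sd(x1), 31.3066, tolerance = 1e-4)
  expect_equal(trim(x1)[1], 1)
  # {0 x 9, 10}: 2 * SD = 6.32, |10 - 1| = 9 > 6.32: excluded
  x2 <- matrix(c(rep(0, 9), 10), ncol = 1)
  expect_equal(2 * sd(x2), 6.3246, tolerance = 1e-4)
  expect_equal(trim(x2)[1], 0)
  # no variance: everything survives
  x3 <- matrix(rep(4, 10), ncol = 1)
  expect_equal(trim(x3)[1], 4)
  # mild spread: nothing excluded, plain mean
  x4 <- matrix(c(9, 10, 11, 10, 10), ncol = 1)
  expect_equal(trim(x4)[1], 10)
  # upper-sided variant keeps low outliers
  x5 <- matrix(c(rep(10, 9), 0), ncol = 1)
  expect_equal(trim(x5, side = "upper")[1], 9)
})

test_that("full template build is deterministic and exact for identical subjects", {
  p <- small_params()
  base <- make_phantom(p, noise = FALSE)$volume
  cfg <- small_cfg()
  same <- list(base, base, base)
  tm <- build_template(same, cfg)
  expect_identical(tm$volume$data, base$data)
  expect_equal(length(tm$subject_fields), 3L)
  tm2 <- build_template(same, cfg)
  expect_identical(tm$volume$data, tm2$volume$data)
})

test_that("template model round-trips through its on-disk form", {
  dir <- withr::local_tempdir()
  p <- small_params()
  base <- make_phantom(p, noise = FALSE)$volume
  tm <- build_template(list(base, base), small_cfg())
  write_template_model(tm, dir)
  back <- read_template_model(dir)
  expect_equal(back$volume$data, tm$volume$data)
  expect_equal(length(back$subject_fields), 2L)
  expect_equal(back$subject_fields[[1]]$d, tm$subject_fields[[1]]$d)
  expect_equal(back$ref_index, tm$ref_index)
})
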