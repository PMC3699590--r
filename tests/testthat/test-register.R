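test_that("mutual information is symmetric, non-negative, and self-MI equals entropy", {
  set.seed(5)
  a <- volume(array(rnorm(16^3), c(16, 16, 16)))
  b <- volume(array(rnorm(16^3), c(16, 16, 16)))
  expect_equal(mutual_information(a, a), atlaskit:::shannon_entropy(a$data))
  expect_gte(mutual_information(a, b), 0)
  expect_equal(mutual_information(a, b), mutual_information(b, a),
               tolerance = 1e-12)
  # independent large samples: MI sampling bias stays small
  set.seed(6)
  x <- volume(array(rnorm(32^3), c(32, 32, 32)))
  y <- volume(array(rnorm(32^3), c(32, 32, 32)))
  expect_lt(mutual_information(x, y), 0.05)
  expect_error(mutual_information(a, volume(array(0:7, c(2, 2, 2)))),
               "mismatch")
})

test_that("warping identities: zero field, integer shift, closed-form trilinear shift", {
  v <- ramp_volume(c(10L, 10L, 10L))
  z <- zero_field(c(10L, 10L, 10L))
  expect_equal(warp_volume(v, z)$data, v$data)
  expect_equal(warp_volume(v, z, interp = "nearest")$data, v$data)

  lab <- toy_labels(12L)
  shift <- affine_transform(diag(3), c(2, 0, 0))
  wl <- warp_volume(lab, shift)
  # interior labels rigidly shifted, counts preserved away from the border
  expect_equal(wl$labels[1:10, , ], lab$labels[3:12, , ])
  expect_true(all(unique(as.vector(wl$labels)) %in%
                  c(0L, lab$regions$region_id)))

  # linear ramp along x shifted by 1.5 voxels, trilinear: exact in interior
  dims <- c(12L, 6L, 6L)
  ramp <- volume(array(rep(seq_len(12), times = 36), dims))
  f <- displacement_field(array(rep(c(1.5, 0, 0), each = prod(dims)),
                                c(dims, 3L)))
  w <- warp_volume(ramp, f)
  expect_equal(w$data[1:10, , ], ramp$data[1:10, , ] + 1.5, tolerance = 1e-12)
  expect_error(warp_volume(ramp, f, interp = "cubic"))
})

test_that("mean displacement and field averaging match naive voxel loops", {
  expect_equal(mean_displacement(zero_field(c(4L, 4L, 4L))), 0)
  const <- displacement_field(array(rep(c(3, 4, 0), each = 64), c(4, 4, 4, 3)))
  expect_equal(mean_displacement(const), 5)

  set.seed(11)
  f1 <- displacement_field(array(rnorm(4^3 * 3), c(4, 4, 4, 3)))
  f2 <- displacement_field(array(rnorm(4^3 * 3), c(4, 4, 4, 3)))
  f3 <- displacement_field(array(rnorm(4^3 * 3), c(4, 4, 4, 3)))
  expect_equal(mean_displacement(f1), oracle_mean_displacement(f1))
  mask <- array(c(TRUE, FALSE), c(4, 4, 4))
  expect_equal(mean_displacement(f1, mask),
               mean(sqrt(apply(f1$d^2, 1:3, sum))[mask]))
  expect_error(mean_displacement(f1, array(FALSE, c(4, 4, 4))), "empty")

  expect_equal(average_fields(list(f1))$d, f1$d)
  neg <- displacement_field(-f1$d)
  expect_equal(max(abs(average_fields(list(f1, neg))$d)), 0)
  expect_equal(average_fields(list(f1, f2, f3))$d,
               oracle_average_fields(list(f1, f2, f3)))
  expect_error(average_fields(list()), "empty")
})

test_that("field composition equals sequential warping", {
  set.seed(3)
  dims <- c(12L, 12L, 12L)
  v <- volume(gauss_smooth(array(rnorm(prod(dims)), dims), 2) * 10)
  sm <- function(seed, amp) random_deformation(dims, amp, 3, seed)
  a <- sm(1, 1); b <- sm(2, 1)
  comp <- compose_fields(a, b)
  two_step <- warp_volume(warp_volume(v, a), b)
  one_step <- warp_volume(v, comp)
  # interpolation differs, so compare away from the border with tolerance
  core <- 4:9
  expect_lt(max(abs(one_step$data[core, core, core] -
                    two_step$data[core, core, core])), 0.2)
})

test_that("affine MI registration recovers identity and known translations", {
  p <- small_params()
  base <- make_phantom(p, noise = FALSE)$volume
  a0 <- register_affine_mi(base, base, small_cfg())
  expect_lt(max(abs(a0$matrix - diag(3))), 1e-2)
  expect_lt(max(abs(a0$translation)), 1e-2)

  tr <- affine_transform(diag(3), c(-2, 1, 0))
  mov <- warp_volume(base, tr)
  a <- suppressWarnings(register_affine_mi(base, mov, small_cfg()))
  expect_lt(max(abs(a$translation - c(2, -1, 0))), 0.5)

  # monotone intensity remap (multimodal surrogate)
  mov2 <- mov
  mov2$data <- sqrt(mov2$data + 5) * 13
  a2 <- suppressWarnings(register_affine_mi(base, mov2, small_cfg()))
  expect_lt(max(abs(a2$translation - c(2, -1, 0))), 0.5)
})

test_that("elastic registration recovers a known smooth deformation", {
  p <- small_params()
  base <- make_phantom(p, noise = FALSE)$volume
  cfg <- small_cfg()

  d0 <- register_elastic(base, base, cfg)
  expect_lt(mean_displacement(d0), 0.1)

  f <- random_deformation(p$grid_shape, 1.5, 5, 21)
  mov <- warp_volume(base, f)
  d <- register_elastic(volume(mov$data), base, cfg)
  fg <- make_phantom(p, noise = FALSE)$labels$labels > 0L
  epe <- sqrt(apply((d$d - f$d)^2, 1:3, sum))
  expect_lt(mean(epe[fg]), 0.5)

  # residual similarity improves over no registration
  w <- warp_volume(base, d)
  expect_gt(cor(as.vector(mov$data), as.vector(w$data)),
            cor(as.vector(mov$data), as.vector(base$data)))

  flat <- volume(array(1, c(12, 12, 12)))
  expect_warning(zf <- register_elastic(flat, flat, small_cfg()),
                 "variance")
  expect_equal(max(abs(zf$d)), 0)
})
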