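make_dwi_from_tensor <- function(D, bvecs, bval = 1000, s0 = 100,
                                 dims = c(3L, 3L, 3L)) {
  weighted <- lapply(seq_len(ncol(bvecs)), function(j) {
    g <- bvecs[, j]
    volume(array(s0 * exp(-bval * as.numeric(t(g) %*% D %*% g)), dims))
  })
  dwi_set(volume(array(s0, dims)), weighted, rep(bval, ncol(bvecs)), bvecs)
}

test_that("bvec reorientation extracts only the rotation component", {
  g <- gradient_directions(8L)
  id <- affine_transform()
  expect_equal(reorient_bvecs(g, id), g)

  rz90 <- affine_transform(matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3,
                                  byrow = TRUE))
  expect_equal(as.vector(reorient_bvecs(matrix(c(1, 0, 0)), rz90)),
               c(0, 1, 0), tolerance = 1e-12)

  scaling <- affine_transform(diag(c(1.2, 0.9, 1.0)))
  expect_equal(reorient_bvecs(g, scaling), g, tolerance = 1e-12)

  # rotation * anisotropic scaling: polar factor is the rotation
  A <- affine_transform(rz90$matrix %*% diag(c(1.3, 0.8, 1.1)))
  expect_equal(reorient_bvecs(g, A), rz90$matrix %*% g, tolerance = 1e-12)

  # angles between directions are preserved
  out <- reorient_bvecs(g, A)
  expect_equal(crossprod(out), crossprod(g), tolerance = 1e-12)
})

test_that("tensor fit recovers a known tensor from noiseless signals", {
  D <- diag(c(1.7, 0.3, 0.3)) * 1e-3
  g <- gradient_directions(12L)
  dwi <- make_dwi_from_tensor(D, g)
  mask <- array(TRUE, c(3, 3, 3))
  ti <- fit_tensor(dwi, mask)
  expect_equal(unname(ti$tensors[1, 1, 1, ]),
               c(1.7e-3, 0.3e-3, 0.3e-3, 0, 0, 0), tolerance = 1e-8)
  expect_false(any(ti$unfit))
  # noiseless round trip through the forward model
  for (j in 1:3) {
    gj <- g[, j]
    q <- sum(gj^2 * diag(D))
    expect_equal(dwi$weighted[[j]]$data[2, 2, 2], 100 * exp(-1000 * q),
                 tolerance = 1e-8)
  }
})

test_that("tensor fit handles flat signals, masks and dropped measurements", {
  g <- gradient_directions(8L)
  dims <- c(2L, 2L, 2L)
  flat <- dwi_set(volume(array(100, dims)),
                  lapply(seq_len(8), function(j) volume(array(100, dims))),
                  rep(1000, 8), g)
  mask <- array(TRUE, dims); mask[1, 1, 1] <- FALSE
  ti <- fit_tensor(flat, mask)
  expect_equal(max(abs(ti$tensors)), 0)
  expect_true(ti$unfit[1, 1, 1])       # outside the mask: not fitted
  expect_false(ti$unfit[2, 2, 2])

  # a voxel with too few positive measurements is flagged unfit
  bad <- flat
  for (j in 1:4) bad$weighted[[j]]$data[2, 1, 1] <- 0
  ti2 <- fit_tensor(bad, array(TRUE, dims))
  expect_true(ti2$unfit[2, 1, 1])
  expect_equal(unname(ti2$tensors[2, 1, 1, ]), rep(0, 6))

  tp <- file.path(withr::local_tempdir(), "tensor.nii.gz")
  write_tensor_image(ti2, tp)
  expect_equal(dim(as.array(RNifti::readNifti(tp))), c(2, 2, 2, 6))
})

test_that("eigen-decomposition matches the characteristic polynomial roots", {
  dims <- c(1L, 1L, 1L)
  mk <- function(comp) {
    structure(list(tensors = array(comp, c(dims, 6L)),
                   mask = array(TRUE, dims),
                   unfit = array(FALSE, dims)), class = "tensor_image")
  }
  ed <- eigen_decompose(mk(c(3, 2, 1, 0, 0, 0)))
  expect_equal(unname(ed$lambda[1, 1, 1, ]), c(3, 2, 1))
  expect_equal(unname(ed$e1[1, 1, 1, ]), c(1, 0, 0))
  expect_false(ed$degenerate[1, 1, 1])

  iso <- eigen_decompose(mk(c(1, 1, 1, 0, 0, 0)))
  expect_equal(unname(iso$lambda[1, 1, 1, ]), c(1, 1, 1))
  expect_true(iso$degenerate[1, 1, 1])

  set.seed(9)
  for (rep in 1:5) {
    comp <- rnorm(6)
    D <- matrix(c(comp[1], comp[4], comp[5],
                  comp[4], comp[2], comp[6],
                  comp[5], comp[6], comp[3]), 3, 3)
    lam <- sort(unname(eigen_decompose(mk(comp))$lambda[1, 1, 1, ]),
                decreasing = TRUE)
    # independent root search of det(D - x I)
    chr <- polyroot(c(det(D),
                      -(D[1, 1] * D[2, 2] - D[1, 2]^2 +
                        D[1, 1] * D[3, 3] - D[1, 3]^2 +
                        D[2, 2] * D[3, 3] - D[2, 3]^2),
                      sum(diag(D)), -1))
    expect_equal(lam, sort(Re(chr), decreasing = TRUE), tolerance = 1e-8)
  }
})

test_that("FA and MD match their closed forms and invariances", {
  expect_equal(fa(c(1, 1, 1)), 0)
  expect_equal(md(c(1, 1, 1)), 1)
  expect_equal(fa(c(1, 0, 0)), 1)
  expect_equal(md(c(1, 0, 0)), 1 / 3)
  expect_equal(fa(c(2, 1, 1)), 1 / sqrt(6), tolerance = 1e-12)
  expect_equal(md(c(2, 1, 1)), 4 / 3)
  expect_equal(fa(c(0, 0, 0)), 0)
  # invariant under permutation and positive scaling
  set.seed(2)
  for (rep in 1:10) {
    lam <- rexp(3)
    expect_equal(fa(lam), fa(sample(lam)), tolerance = 1e-12)
    expect_equal(fa(lam), fa(lam * runif(1, 0.1, 10)), tolerance = 1e-12)
  }
  # array form agrees with the scalar form
  arr <- array(c(2, 1, 1), c(1, 1, 1, 3))
  expect_equal(as.vector(fa(arr)), 1 / sqrt(6), tolerance = 1e-12)
  expect_equal(as.vector(md(arr)), 4 / 3)
})

test_that("FA color map weights direction by anisotropy", {
  e1 <- array(c(1, 0, 0), c(1, 1, 1, 3))
  expect_equal(as.vector(fa_color(array(1, c(1, 1, 1)), e1)), c(1, 0, 0))
  expect_equal(as.vector(fa_color(array(0, c(1, 1, 1)), e1)), c(0, 0, 0))
  diag_e1 <- array(rep(1, 3) / sqrt(3), c(1, 1, 1, 3))
  expect_equal(as.vector(fa_color(array(0.5, c(1, 1, 1)), diag_e1)),
               rep(0.5 / sqrt(3), 3), tolerance = 1e-12)
})

test_that("synthetic DWI round-trips through the tensor fit", {
  p <- small_params()
  ph <- make_phantom(p, noise = FALSE)
  dwi <- synth_dwi(ph$labels, p, noise_sd = 0)
  mask <- ph$labels$labels > 0L
  ti <- fit_tensor(dwi, mask)
  ed <- eigen_decompose(ti)
  fav <- fa(ed$lambda)
  mdv <- md(ed$lambda)
  rs <- p$region_specs
  true_t <- attr(dwi, "true_tensors")
  for (i in seq_len(nrow(rs))) {
    sel <- ph$labels$labels == rs$region_id[i]
    if (!any(sel)) next
    # per-region tensors reproduced to numerical precision
    fitted <- apply(matrix(ti$tensors[array(sel, c(dim(sel), 6L))],
                           ncol = 6), 2, stats::median)
    expect_lt(max(abs(fitted - true_t[i, ])), 1e-6 * max(true_t))
    expect_lt(abs(stats::median(fav[sel]) - rs$fa[i]), 0.02)
    expect_lt(abs(stats::median(mdv[sel]) / (rs$md[i] * 2e-4) - 1), 0.01)
  }
  # an isotropic region: FA target 0
  rs0 <- rs[1, ]; rs0$fa <- 0
  p0 <- synth_params(grid_shape = p$grid_shape, region_specs = rs0,
                     n_subjects = 1L)
  lab0 <- label_map(array(rep(c(0L, 1L), length.out = prod(p$grid_shape)),
                          p$grid_shape),
                    toy_region_table(1L))
  dwi0 <- synth_dwi(lab0, p0, noise_sd = 0)
  ti0 <- fit_tensor(dwi0, lab0$labels > 0)
  fa0 <- fa(eigen_decompose(ti0)$lambda)
  expect_lt(max(fa0[lab0$labels > 0]), 0.01)
})
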