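#' Registration configuration
#'
#' Parameters shared by the affine and elastic registration routines. The
#' defaults are conventional desk-scale settings for the multiresolution
#' block-matching family; all are exposed because the appropriate block and
#' search sizes depend on image resolution and expected deformation.
#'
#' @param pyramid_levels Number of resolution levels (coarse to fine), >= 1.
#' @param block_size Cubic block edge in voxels (odd recommended).
#' @param block_spacing Block placement stride in voxels.
#' @param search_radius Exhaustive integer search radius per level, voxels.
#' @param smoothing_sigma Gaussian sigma (voxels) used to scatter per-block
#'   offsets into a dense field.
#' @param min_block_variance_frac Blocks whose intensity variance is below
#'   this fraction of the squared intensity range are skipped.
#' @param iterations_per_level Block-matching iterations at each level.
#' @param mi_bins Histogram bins per axis for mutual information.
#' @param affine_sweeps Coordinate-descent sweeps per level for the affine
#'   optimizer.
#' @param seed Integer seed recorded for provenance (the registration
#'   routines themselves are deterministic).
#' @return A list of class `reg_config`.
#' @export
reg_config <- function(pyramid_levels = 3L, block_size = 5L, block_spacing = 3L,
                       search_radius = 3L, smoothing_sigma = 2,
                       min_block_variance_frac = 1e-6,
                       iterations_per_level = 2L, mi_bins = 32L,
                       affine_sweeps = 6L, seed = 1L) {
  cfg <- list(pyramid_levels = as.integer(pyramid_levels),
              block_size = as.integer(block_size),
              block_spacing = as.integer(block_spacing),
              search_radius = as.integer(search_radius),
              smoothing_sigma = smoothing_sigma,
              min_block_variance_frac = min_block_variance_frac,
              iterations_per_level = as.integer(iterations_per_level),
              mi_bins = as.integer(mi_bins),
              affine_sweeps = as.integer(affine_sweeps),
              seed = as.integer(seed))
  if (cfg$pyramid_levels < 1L) stop("pyramid_levels must be >= 1")
  if (any(unlist(cfg[c("block_size", "block_spacing", "search_radius",
                       "iterations_per_level", "mi_bins")]) <= 0))
    stop("registration config values must be positive")
  if (cfg$smoothing_sigma <= 0) stop("smoothing_sigma must be positive")
  class(cfg) <- "reg_config"
  cfg
}

#' Mutual information between two equally shaped volumes
#'
#' Computed from a joint histogram with `bins` x `bins` uniform bins spanning
#' each image's own range. Reported in bits. Symmetric and non-negative.
#'
#' @param a,b [volume()]s or 3-D arrays of equal shape.
#' @param bins Bins per axis, >= 2.
#' @return Scalar MI in bits.
#' @export
mutual_information <- function(a, b, bins = 32L) {
  av <- if (is_volume(a)) a$data else a
  bv <- if (is_volume(b)) b$data else b
  stopifnot_same_grid(av, bv)
  if (bins < 2L) stop("bins must be >= 2")
  H <- .cpp_joint_hist(as.vector(av), as.vector(bv), as.integer(bins),
                       min(av), max(av), min(bv), max(bv))
  p <- H / sum(H)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
  max(mi, 0)
}

shannon_entropy <- function(x, bins = 32L) {
  h <- .cpp_joint_hist(as.vector(x), as.vector(x), as.integer(bins),
                       min(x), max(x), min(x), max(x))
  p <- rowSums(h) / sum(h)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Gaussian pyramid: list of arrays, coarsest first. Each level halves
# the grid (ceiling) after sigma-1 smoothing.
build_pyramid <- function(arr, levels) {
  pyr <- vector("list", levels)
  pyr[[levels]] <- arr
  for (l in rev(seq_len(levels - 1))) {
    prev <- pyr[[l + 1]]
    sm <- gauss_smooth(prev, 1)
    idx <- lapply(dim(prev), function(n) seq(1, n, by = 2))
    pyr[[l]] <- sm[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  pyr
}

affine_from_params <- function(p, center) {
  # p: tx ty tz, rx ry rz (radians), log-scales sx sy sz, shears hxy hxz hyz
  cx <- cos(p[4]); sx <- sin(p[4])
  cy <- cos(p[5]); sy <- sin(p[5])
  cz <- cos(p[6]); sz <- sin(p[6])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  S <- diag(exp(p[7:9]))
  H <- matrix(c(1, p[10], p[11], 0, 1, p[12], 0, 0, 1), 3, 3, byrow = TRUE)
  M <- Rz %*% Ry %*% Rx %*% S %*% H
  t <- as.vector(center - M %*% center) + p[1:3]
  list(matrix = M, translation = t)
}

#' Affine registration by mutual-information maximization
#'
#' Estimates a 12-parameter affine transform (translation, rotation,
#' log-scale, shear) aligning `moving` into the space of `fixed` by
#' maximizing the joint-histogram mutual information, using deterministic
#' coordinate-wise derivative-free search on a coarse-to-fine pyramid.
#' MI is invariant to monotone intensity remapping, so the two volumes may
#' come from different modalities.
#'
#' @param fixed,moving [volume()]s (finite everywhere).
#' @param cfg A [reg_config()].
#' @return An `affine_transform` whose application to `moving` (see
#'   [warp_volume()]) resamples it onto the fixed grid; carries attributes
#'   `mi` (final value) and `converged`.
#' @export
register_affine_mi <- function(fixed, moving, cfg = reg_config()) {
  stopifnot(is_volume(fixed), is_volume(moving))
  fpyr <- build_pyramid(fixed$data, cfg$pyramid_levels)
  mpyr <- build_pyramid(moving$data, cfg$pyramid_levels)
  p <- rep(0, 12)
  # search steps per parameter group at the finest level
  base_step <- c(rep(1, 3), rep(0.05, 3), rep(0.05, 3), rep(0.03, 3))
  converged <- TRUE
  for (l in seq_len(cfg$pyramid_levels)) {
    farr <- fpyr[[l]]
    marr <- mpyr[[l]]
    scale <- (dim(fixed$data)[1] - 1) / max(dim(farr)[1] - 1, 1)
    center <- (dim(farr) - 1) / 2
    # fixed histogram ranges keep the objective comparable across transforms
    fmin <- min(farr); fmax <- max(farr)
    mmin <- min(0, min(marr)); mmax <- max(marr)
    objective <- function(q) {
      a <- affine_from_params(q, center)
      w <- .cpp_warp_affine(as.vector(marr), as.integer(dim(marr)),
                            as.integer(dim(farr)), as.vector(t(a$matrix)),
                            a$translation, 0L, 0)
      H <- .cpp_joint_hist(as.vector(farr), w, cfg$mi_bins,
                           fmin, fmax, mmin, mmax)
      pj <- H / sum(H)
      px <- rowSums(pj); py <- colSums(pj)
      nz <- pj > 0
      sum(pj[nz] * log2(pj[nz] / outer(px, py)[nz]))
    }
    # translations are expressed in this level's voxels
    p[1:3] <- p[1:3] / scale
    cur <- objective(p)
    # rotation/scale/shear act over the whole extent: refine them with the
    # resolution instead of re-searching coarse steps at fine levels
    step <- base_step
    step[4:12] <- step[4:12] / 2^(l - 1)
    improved_any <- FALSE
    for (sweep in seq_len(cfg$affine_sweeps)) {
      improved_any <- FALSE
      for (j in seq_len(12)) {
        repeat {
          up <- p; up[j] <- up[j] + step[j]
          dn <- p; dn[j] <- dn[j] - step[j]
          fu <- objective(up); fd <- objective(dn)
          if (fu > cur && fu >= fd) { p <- up; cur <- fu; improved_any <- TRUE }
          else if (fd > cur) { p <- dn; cur <- fd; improved_any <- TRUE }
          else break
        }
      }
      step <- step / 2
      if (!improved_any && sweep > 1) break
    }
    # still finding improvements in the final sweep of the finest level means
    # the search was cut short by the sweep budget
    if (l == cfg$pyramid_levels && improved_any) {
      converged <- FALSE
      warning("affine optimizer stopped before convergence; ",
              "returning best transform found")
    }
    p[1:3] <- p[1:3] * scale
  }
  center <- (dim(fixed$data) - 1) / 2
  a <- affine_from_params(p, center)
  out <- affine_transform(a$matrix, a$translation)
  attr(out, "mi") <- objective_final(fixed$data, moving$data, out, cfg$mi_bins)
  attr(out, "converged") <- converged
  out
}

objective_final <- function(farr, marr, tf, bins) {
  w <- .cpp_warp_affine(as.vector(marr), as.integer(dim(marr)),
                        as.integer(dim(farr)), as.vector(t(tf$matrix)),
                        tf$translation, 0L, 0)
  mutual_information(farr, array(w, dim(farr)), bins)
}

#' Elastic registration by multiresolution block matching
#'
#' At each level of a coarse-to-fine pyramid, cubic blocks placed on a regular
#' lattice over the fixed image search integer offsets (within
#' `search_radius`) maximizing the Pearson correlation with the current
#' warped moving image. Blocks below the variance gate are skipped. Offsets
#' are scattered to a dense field by normalized Gaussian convolution
#' (`smoothing_sigma`) and composed with the running field; the field is
#' upsampled between levels.
#'
#' @param fixed,moving [volume()]s of equal shape (apply any affine
#'   pre-alignment first, or pass it as `init`).
#' @param cfg A [reg_config()].
#' @param init Optional initial `displacement_field` on the fixed grid
#'   (e.g. the field induced by an affine pre-registration); the block
#'   matching refines it while always sampling the original moving image.
#' @return A `displacement_field` on the fixed grid: warping `moving` by it
#'   approximates `fixed`. Attribute `all_blocks_flat` is set (with a
#'   warning) when no block anywhere passed the variance gate.
#' @export
register_elastic <- function(fixed, moving, cfg = reg_config(), init = NULL) {
  stopifnot(is_volume(fixed), is_volume(moving))
  stopifnot_same_grid(fixed, moving)
  fpyr <- build_pyramid(fixed$data, cfg$pyramid_levels)
  mpyr <- build_pyramid(moving$data, cfg$pyramid_levels)
  rng2 <- (max(fixed$data) - min(fixed$data))^2
  min_var <- cfg$min_block_variance_frac * rng2
  d <- if (is.null(init)) zero_field(dim(fpyr[[1]]), fixed$spacing)
       else resample_field(init, dim(fpyr[[1]]))
  any_valid <- FALSE
  for (l in seq_len(cfg$pyramid_levels)) {
    farr <- fpyr[[l]]
    if (!identical(dim(d$d)[1:3], dim(farr)))
      d <- resample_field(d, dim(farr))
    for (it in seq_len(cfg$iterations_per_level)) {
      warped <- array(.cpp_warp_field(as.vector(mpyr[[l]]),
                                      as.integer(dim(farr)),
                                      as.vector(d$d[, , , 1]),
                                      as.vector(d$d[, , , 2]),
                                      as.vector(d$d[, , , 3]), 0L, 0),
                      dim(farr))
      bm <- .cpp_block_match(as.vector(farr), as.vector(warped),
                             as.integer(dim(farr)), cfg$block_size,
                             cfg$block_spacing, cfg$search_radius, min_var)
      ok <- bm[, 7] == 1
      if (!any(ok)) next
      any_valid <- TRUE
      inc <- scatter_offsets(bm[ok, , drop = FALSE], dim(farr),
                             cfg$smoothing_sigma, fixed$spacing)
      d <- compose_fields(d, inc)
    }
  }
  if (!identical(dim(d$d)[1:3], dim(fixed$data)))
    d <- resample_field(d, dim(fixed$data))
  if (!any_valid) {
    warning("all blocks below the variance threshold; returning zero field")
    d <- zero_field(dim(fixed$data), fixed$spacing)
    attr(d, "all_blocks_flat") <- TRUE
  }
  d
}

# Regularized normalized Gaussian scatter of sparse block offsets to a dense
# field. The ridge term (a fraction of the peak smoothed weight) makes the
# interpolated field decay to zero away from any valid block instead of
# extending boundary estimates indefinitely into signal-free regions.
scatter_offsets <- function(bm, dim3, sigma, spacing, ridge_frac = 0.05) {
  w <- array(0, dim3)
  vx <- array(0, dim3); vy <- array(0, dim3); vz <- array(0, dim3)
  ix <- cbind(round(bm[, 1]) + 1, round(bm[, 2]) + 1, round(bm[, 3]) + 1)
  w[ix] <- 1
  vx[ix] <- bm[, 4]; vy[ix] <- bm[, 5]; vz[ix] <- bm[, 6]
  sw <- gauss_smooth(w, sigma)
  lam <- ridge_frac * max(sw)
  out <- array(0, c(dim3, 3L))
  comp <- list(vx, vy, vz)
  for (k in 1:3) {
    sv <- gauss_smooth(comp[[k]], sigma)
    out[, , , k] <- sv / (sw + lam)
  }
  displacement_field(out, spacing)
}
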