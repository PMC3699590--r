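#' Diffusion-weighted image set
#'
#' Bundles a non-diffusion-weighted reference (`b0`), the diffusion-weighted
#' volumes, and the acquisition tables: one b-value (s/mm^2) and one unit
#' gradient direction per weighted volume.
#'
#' @param b0 A [volume()], non-negative.
#' @param weighted List of [volume()]s, same grid as `b0`.
#' @param bvals Numeric vector, one b-value per weighted volume.
#' @param bvecs 3 x n matrix of unit-norm gradient directions (tolerance 1e-6).
#' @return An object of class `dwi_set`.
#' @export
dwi_set <- function(b0, weighted, bvals, bvecs) {
  stopifnot(is_volume(b0))
  if (any(b0$data < 0)) stop("b0 must be non-negative")
  n <- length(weighted)
  if (length(bvals) != n || ncol(bvecs) != n)
    stop("weighted volumes, bvals and bvecs must have matching length")
  for (w in weighted) stopifnot_same_grid(b0, w)
  norms <- sqrt(colSums(bvecs^2))
  if (any(abs(norms - 1) > 1e-6))
    stop("every bvec must have unit norm (tolerance 1e-6)")
  structure(list(b0 = b0, weighted = weighted, bvals = as.numeric(bvals),
                 bvecs = bvecs), class = "dwi_set")
}

#' Rotate gradient directions after an affine alignment
#'
#' When diffusion volumes are resampled by an affine transform the gradient
#' table must follow the orientation change. The rotation component is
#' extracted by polar decomposition `A = R S` (via SVD) and applied to every
#' direction; pure scalings and shears leave the directions untouched.
#' Outputs are renormalized to unit length.
#'
#' @param bvecs 3 x n matrix of unit directions.
#' @param affine An `affine_transform` (invertible).
#' @return 3 x n matrix of rotated unit directions.
#' @export
reorient_bvecs <- function(bvecs, affine) {
  stopifnot(inherits(affine, "affine_transform"))
  A <- affine$matrix
  if (abs(det(A)) <= 1e-12) stop("singular affine")
  sv <- svd(A)
  R <- sv$u %*% t(sv$v)
  out <- R %*% bvecs
  out <- out / rep(sqrt(colSums(out^2)), each = 3)
  dimnames(out) <- dimnames(bvecs)
  out
}

#' Per-voxel diffusion tensor fit (log-linear least squares)
#'
#' Fits the monoexponential model `ln(S_j / S0) = -b_j g_j' D g_j` by
#' ordinary least squares at every voxel inside the mask. Non-positive
#' measurements at a voxel are dropped from its fit; the voxel is flagged
#' unfit (zero tensor) when fewer than 6 usable measurements remain or
#' `S0 <= 0`. Negative eigenvalues are permitted (no positivity constraint).
#'
#' @param dwi A [dwi_set()] with >= 6 non-collinear directions.
#' @param mask Logical 3-D array of voxels to fit.
#' @return A `tensor_image`: list with `tensors` (n_voxel-grid x 6 array in
#'   component order Dxx, Dyy, Dzz, Dxy, Dxz, Dyz, mm^2/s), `mask`, and
#'   `unfit` (logical array of masked voxels that could not be fitted).
#' @export
fit_tensor <- function(dwi, mask) {
  stopifnot(inherits(dwi, "dwi_set"))
  dims <- dim(dwi$b0$data)
  stopifnot(identical(dim(mask), dims))
  g <- dwi$bvecs
  X <- -dwi$bvals * t(rbind(g[1, ]^2, g[2, ]^2, g[3, ]^2,
                            2 * g[1, ] * g[2, ], 2 * g[1, ] * g[3, ],
                            2 * g[2, ] * g[3, ]))
  if (qr(X)$rank < 6L)
    stop("need >= 6 non-collinear gradient directions")
  nmeas <- nrow(X)
  nvox <- prod(dims)
  S <- matrix(0, nmeas, nvox)
  for (j in seq_len(nmeas)) S[j, ] <- as.vector(dwi$weighted[[j]]$data)
  s0 <- as.vector(dwi$b0$data)
  tens <- matrix(0, nvox, 6)
  unfit <- array(!mask, dims)   # outside the mask nothing is fitted
  idx <- which(as.vector(mask))
  good0 <- s0[idx] > 0
  unfit[idx[!good0]] <- TRUE
  idx <- idx[good0]
  if (length(idx)) {
    Sm <- S[, idx, drop = FALSE]
    pos <- Sm > 0
    allpos <- colSums(pos) == nmeas
    # common design: batch solve for voxels with all-positive signals
    if (any(allpos)) {
      Y <- log(sweep(Sm[, allpos, drop = FALSE], 2, s0[idx[allpos]], "/"))
      tens[idx[allpos], ] <- t(qr.coef(qr(X), Y))
    }
    # per-voxel fits where measurements were dropped
    for (k in which(!allpos)) {
      use <- pos[, k]
      if (sum(use) < 6L || qr(X[use, , drop = FALSE])$rank < 6L) {
        unfit[idx[k]] <- TRUE
        next
      }
      y <- log(Sm[use, k] / s0[idx[k]])
      tens[idx[k], ] <- qr.coef(qr(X[use, , drop = FALSE]), y)
    }
  }
  tens[as.vector(!mask), ] <- 0
  structure(list(tensors = array(tens, c(dims, 6L)), mask = mask,
                 unfit = unfit, spacing = dwi$b0$spacing),
            class = "tensor_image")
}

#' Eigen-decomposition of a tensor image
#'
#' Per-voxel symmetric 3x3 eigenanalysis with descending eigenvalues. The
#' principal eigenvector's sign is fixed by making its first non-zero
#' component non-negative. Voxels where `lambda1 - lambda2 < 1e-12 * |lambda|`
#' are flagged degenerate: the principal direction is not meaningful there.
#'
#' @param t A `tensor_image` from [fit_tensor()].
#' @return List with `lambda` (grid x 3 array, descending), `e1`
#'   (grid x 3 array of unit principal directions) and `degenerate`
#'   (logical array).
#' @export
eigen_decompose <- function(t) {
  stopifnot(inherits(t, "tensor_image"))
  dims <- dim(t$tensors)[1:3]
  nvox <- prod(dims)
  tm <- matrix(t$tensors, nvox, 6)
  lambda <- matrix(0, nvox, 3)
  e1 <- matrix(0, nvox, 3)
  degenerate <- rep(FALSE, nvox)
  idx <- which(as.vector(t$mask) & !as.vector(t$unfit))
  for (i in idx) {
    D <- matrix(c(tm[i, 1], tm[i, 4], tm[i, 5],
                  tm[i, 4], tm[i, 2], tm[i, 6],
                  tm[i, 5], tm[i, 6], tm[i, 3]), 3, 3)
    ev <- eigen(D, symmetric = TRUE)
    lambda[i, ] <- ev$values
    v <- ev$vectors[, 1]
    nzc <- which(abs(v) > 0)[1]
    if (!is.na(nzc) && v[nzc] < 0) v <- -v
    e1[i, ] <- v
    nl <- sqrt(sum(ev$values^2))
    if (ev$values[1] - ev$values[2] < 1e-12 * max(nl, .Machine$double.eps))
      degenerate[i] <- TRUE
  }
  list(lambda = array(lambda, c(dims, 3L)),
       e1 = array(e1, c(dims, 3L)),
       degenerate = array(degenerate, dims))
}

#' Write a tensor image as a 6-component 4-D NIfTI
#'
#' Component order Dxx, Dyy, Dzz, Dxy, Dxz, Dyz along the fourth axis.
#'
#' @param t A `tensor_image` from [fit_tensor()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_tensor_image <- function(t, path) {
  stopifnot(inherits(t, "tensor_image"))
  img <- nifti_with_meta(t$tensors, t$spacing, c(0, 0, 0), "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Fractional anisotropy and mean diffusivity from eigenvalues
#'
#' `fa` is `sqrt(3/2) * |lambda - mean(lambda)| / |lambda|` (0 when the
#' eigenvalue vector is all zero), clamped to `[0, 1]` against rounding.
#' `md` is the eigenvalue mean. Both accept a length-3 vector or a
#' grid x 3 array and return a scalar or grid-shaped array accordingly.
#'
#' @param lambda Numeric length-3 vector or `(nx, ny, nz, 3)` array.
#' @return Scalar or 3-D array.
#' @export
fa <- function(lambda) {
  if (is.null(dim(lambda)) || length(dim(lambda)) == 1L) {
    stopifnot(length(lambda) == 3L)
    nrm <- sqrt(sum(lambda^2))
    if (nrm == 0) return(0)
    m <- mean(lambda)
    return(min(1, sqrt(1.5) * sqrt(sum((lambda - m)^2)) / nrm))
  }
  dims <- dim(lambda)[1:3]
  lm <- matrix(lambda, prod(dims), 3)
  nrm <- sqrt(rowSums(lm^2))
  m <- rowMeans(lm)
  dev <- sqrt(rowSums((lm - m)^2))
  out <- ifelse(nrm > 0, pmin(1, sqrt(1.5) * dev / nrm), 0)
  array(out, dims)
}

#' @rdname fa
#' @export
md <- function(lambda) {
  if (is.null(dim(lambda)) || length(dim(lambda)) == 1L) {
    stopifnot(length(lambda) == 3L)
    return(mean(lambda))
  }
  dims <- dim(lambda)[1:3]
  array(rowMeans(matrix(lambda, prod(dims), 3)), dims)
}

#' FA-weighted direction color map
#'
#' Standard directional coloring: `RGB = FA * (|e1x|, |e1y|, |e1z|)`, clipped
#' to `[0, 1]`, so brightness encodes anisotropy and hue the principal
#' diffusion direction.
#'
#' @param fa_vol 3-D FA array (or [volume()]).
#' @param e1_vol `(nx, ny, nz, 3)` array of principal directions.
#' @return `(nx, ny, nz, 3)` RGB array in `[0, 1]`.
#' @export
fa_color <- function(fa_vol, e1_vol) {
  fav <- if (is_volume(fa_vol)) fa_vol$data else fa_vol
  stopifnot(identical(dim(fav), dim(e1_vol)[1:3]))
  out <- abs(e1_vol) * as.vector(fav)
  pmin(pmax(out, 0), 1)
}
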