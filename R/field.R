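#' Dense displacement field
#'
#' A per-voxel 3-vector field in voxel units defined on a fixed grid, under
#' the pull-back convention: warping a moving image by the field samples it
#' at `x + d(x)` for each fixed-grid voxel `x`.
#'
#' @param d 4-D numeric array `(nx, ny, nz, 3)`, all finite.
#' @param spacing Voxel spacing metadata (mm), as for [volume()].
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(d, spacing = c(1, 1, 1)) {
  d <- as.array(d)
  if (length(dim(d)) != 4L || dim(d)[4] != 3L)
    stop("displacement field must be a (nx, ny, nz, 3) array")
  d <- array(as.double(d), dim(d))
  if (!all(is.finite(d))) stop("displacement field contains non-finite values")
  structure(list(d = d, spacing = as.numeric(spacing)),
            class = "displacement_field")
}

#' Zero displacement field on a grid
#' @param dim Integer length-3 grid shape.
#' @param spacing Voxel spacing metadata.
#' @return A `displacement_field` of zeros.
#' @export
zero_field <- function(dim, spacing = c(1, 1, 1)) {
  displacement_field(array(0, c(dim, 3L)), spacing)
}

#' @export
print.displacement_field <- function(x, ...) {
  n <- sqrt(x$d[, , , 1]^2 + x$d[, , , 2]^2 + x$d[, , , 3]^2)
  cat("<displacement_field> ", paste(dim(x$d)[1:3], collapse = " x "),
      " voxels, |d| mean ", signif(mean(n), 4), ", max ", signif(max(n), 4),
      " voxels\n", sep = "")
  invisible(x)
}

#' Affine transform in voxel coordinates
#'
#' Resampling convention: applying the transform to a moving image samples it
#' at `M x + t` for each fixed-grid voxel `x` (0-based voxel units).
#'
#' @param matrix Invertible 3 x 3 matrix.
#' @param translation Numeric length-3.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  matrix <- base::matrix(as.numeric(matrix), 3, 3)
  if (abs(det(matrix)) <= 1e-12) stop("affine matrix is singular")
  structure(list(matrix = matrix, translation = as.numeric(translation)),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform> translation (",
      paste(signif(x$translation, 4), collapse = ", "), ")\n", sep = "")
  print(signif(x$matrix, 4))
  invisible(x)
}

#' Warp a volume by a displacement field or affine transform
#'
#' Pull-back resampling on the transform's fixed grid: the output at voxel
#' `x` samples the input at `x + d(x)` (field) or `M x + t` (affine).
#' Out-of-bounds samples take `fill`.
#'
#' @param v A [volume()], [label_map()] (forces nearest-neighbour) or bare
#'   3-D array.
#' @param t A `displacement_field` or `affine_transform`.
#' @param interp `"trilinear"` or `"nearest"`.
#' @param fill Fill value for out-of-bounds samples (default 0).
#' @param outdim Output grid shape for affine transforms (defaults to the
#'   input shape); fields always define their own grid.
#' @return Same class as the input, on the output grid.
#' @export
warp_volume <- function(v, t, interp = c("trilinear", "nearest"), fill = 0,
                        outdim = NULL) {
  interp <- match.arg(interp)
  if (inherits(v, "label_map")) {
    arr <- warp_array(array(as.double(v$labels), dim(v$labels)), t,
                      "nearest", fill, outdim)
    return(label_map(array(as.integer(round(arr)), dim(arr)), v$regions,
                     v$spacing, v$origin))
  }
  if (is_volume(v)) {
    arr <- warp_array(v$data, t, interp, fill, outdim)
    return(volume(arr, v$spacing, v$origin))
  }
  warp_array(v, t, interp, fill, outdim)
}

warp_array <- function(arr, t, interp, fill, outdim = NULL) {
  code <- if (interp == "trilinear") 0L else 1L
  if (inherits(t, "displacement_field")) {
    fd <- dim(t$d)[1:3]
    if (!identical(dim(arr), as.integer(fd)) && !identical(dim(arr), fd))
      stop("field grid ", paste(fd, collapse = "x"),
           " does not match volume grid ", paste(dim(arr), collapse = "x"))
    out <- .cpp_warp_field(as.vector(arr), as.integer(fd),
                           as.vector(t$d[, , , 1]), as.vector(t$d[, , , 2]),
                           as.vector(t$d[, , , 3]), code, fill)
    return(array(out, fd))
  }
  if (inherits(t, "affine_transform")) {
    if (is.null(outdim)) outdim <- dim(arr)
    out <- .cpp_warp_affine(as.vector(arr), as.integer(dim(arr)),
                            as.integer(outdim), as.vector(t(t$matrix)),
                            t$translation, code, fill)
    return(array(out, outdim))
  }
  stop("unknown transform type; use a displacement_field or affine_transform")
}

#' Mean displacement magnitude of a field
#'
#' Mean over (optionally masked) voxels of the Euclidean norm of the
#' displacement vectors, in voxel units.
#'
#' @param d A `displacement_field`.
#' @param mask Optional logical 3-D array selecting voxels.
#' @return Scalar mean norm.
#' @export
mean_displacement <- function(d, mask = NULL) {
  stopifnot(inherits(d, "displacement_field"))
  n <- sqrt(d$d[, , , 1]^2 + d$d[, , , 2]^2 + d$d[, , , 3]^2)
  if (is.null(mask)) return(mean(n))
  if (!any(mask)) stop("empty mask")
  mean(n[mask])
}

#' Voxelwise average of displacement fields
#'
#' @param fields Non-empty list of `displacement_field`s on the same grid.
#' @return A `displacement_field`: the arithmetic mean of the vectors.
#' @export
average_fields <- function(fields) {
  if (length(fields) == 0L) stop("empty field list")
  stopifnot(all(vapply(fields, inherits, TRUE, "displacement_field")))
  d0 <- dim(fields[[1]]$d)
  acc <- array(0, d0)
  for (f in fields) {
    if (!identical(dim(f$d), d0)) stop("field shape mismatch")
    acc <- acc + f$d
  }
  displacement_field(acc / length(fields), fields[[1]]$spacing)
}

#' Compose two displacement fields
#'
#' Exact pull-back composition: warping by the result equals warping by
#' `acc` first in sampling order, refined by the increment `inc`, i.e.
#' `result(x) = inc(x) + acc(x + inc(x))` so that
#' `warp(v, result) == warp(warp(v, acc), inc)` up to interpolation.
#'
#' @param acc Accumulated field.
#' @param inc New increment estimated on the fixed grid.
#' @return The composed `displacement_field`.
#' @export
compose_fields <- function(acc, inc) {
  stopifnot(inherits(acc, "displacement_field"),
            inherits(inc, "displacement_field"))
  fd <- dim(acc$d)[1:3]
  if (!identical(dim(inc$d), dim(acc$d))) stop("field shape mismatch")
  out <- array(0, dim(acc$d))
  for (k in 1:3) {
    # sample acc component at x + inc(x); outside the grid extend with 0
    out[, , , k] <- inc$d[, , , k] +
      array(.cpp_warp_field(as.vector(acc$d[, , , k]), as.integer(fd),
                            as.vector(inc$d[, , , 1]),
                            as.vector(inc$d[, , , 2]),
                            as.vector(inc$d[, , , 3]), 0L, 0), fd)
  }
  displacement_field(out, acc$spacing)
}

#' Compose an affine transform after a displacement field
#'
#' Returns the single displacement field equivalent to warping by `d` after
#' an affine pre-warp of the moving image, i.e. sampling the original moving
#' image at `M (x + d(x)) + t`. Using the composed field resamples the data
#' once instead of twice.
#'
#' @param affine An `affine_transform`.
#' @param d A `displacement_field` estimated against the affinely warped
#'   moving image.
#' @return A `displacement_field` `D` with `D(x) = M (x + d(x)) + t - x`.
#' @export
compose_affine_field <- function(affine, d) {
  stopifnot(inherits(affine, "affine_transform"),
            inherits(d, "displacement_field"))
  dims <- dim(d$d)[1:3]
  x1 <- array(seq_len(dims[1]) - 1, dims)
  x2 <- array(rep(seq_len(dims[2]) - 1, each = dims[1]), dims)
  x3 <- array(rep(seq_len(dims[3]) - 1, each = dims[1] * dims[2]), dims)
  s1 <- x1 + d$d[, , , 1]; s2 <- x2 + d$d[, , , 2]; s3 <- x3 + d$d[, , , 3]
  M <- affine$matrix; t <- affine$translation
  out <- array(0, c(dims, 3L))
  out[, , , 1] <- M[1, 1] * s1 + M[1, 2] * s2 + M[1, 3] * s3 + t[1] - x1
  out[, , , 2] <- M[2, 1] * s1 + M[2, 2] * s2 + M[2, 3] * s3 + t[2] - x2
  out[, , , 3] <- M[3, 1] * s1 + M[3, 2] * s2 + M[3, 3] * s3 + t[3] - x3
  displacement_field(out, d$spacing)
}

#' Gaussian-smooth a 3-D array (separable, truncated at 3 sigma)
#'
#' Border kernels are renormalized so constants are preserved.
#'
#' @param arr 3-D numeric array.
#' @param sigma Standard deviation in voxels; `sigma <= 0` is the identity.
#' @return Smoothed array of the same shape.
#' @export
gauss_smooth <- function(arr, sigma) {
  array(.cpp_gauss_smooth(as.vector(arr), as.integer(dim(arr)), sigma),
        dim(arr))
}

# Resample a field defined on `from_dim` to `to_dim` (component-wise
# trilinear), rescaling the vectors by the per-axis grid ratio.
resample_field <- function(f, to_dim) {
  from_dim <- dim(f$d)[1:3]
  scale <- (from_dim - 1) / pmax(to_dim - 1, 1)
  M <- diag(scale)
  out <- array(0, c(to_dim, 3L))
  for (k in 1:3) {
    comp <- .cpp_warp_affine(as.vector(f$d[, , , k]), as.integer(from_dim),
                             as.integer(to_dim), as.vector(t(M)),
                             c(0, 0, 0), 0L, 0)
    out[, , , k] <- array(comp, to_dim) / scale[k]
  }
  displacement_field(out, f$spacing)
}
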