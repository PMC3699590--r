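#' Read a 3-D volume from a NIfTI-1 file
#'
#' Spacing is taken from the pixdim header fields and the origin from the
#' sform/qform offset. Orientation matrices beyond the offset are passed
#' through unused: the package operates in voxel coordinates.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1, drop = TRUE]
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D image, got ", length(dim(arr)), " dimensions: ", path)
  hdr <- RNifti::niftiHeader(img)
  storage.mode(arr) <- "double"
  volume(arr, spacing = RNifti::pixdim(img)[1:3],
         origin = c(hdr$srow_x[4], hdr$srow_y[4], hdr$srow_z[4]))
}

nifti_with_meta <- function(arr, spacing, origin, datatype) {
  hdr <- list(
    srow_x = c(spacing[1], 0, 0, origin[1]),
    srow_y = c(0, spacing[2], 0, origin[2]),
    srow_z = c(0, 0, spacing[3], origin[3]),
    sform_code = 2L,
    pixdim = c(-1, spacing, rep(0, 4)))
  RNifti::asNifti(arr, hdr, datatype = datatype)
}

#' Write a volume to a NIfTI-1 file
#'
#' @param v A [volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(is_volume(v))
  img <- nifti_with_meta(v$data, v$spacing, v$origin, "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a label map as NIfTI + region-table TSV
#'
#' Labels are stored as 32-bit integers so the round trip is exact. The region
#' table travels separately as a tab-separated file with header
#' `region_id name group hemisphere`.
#'
#' @param path NIfTI path for the labels.
#' @param regions_path TSV path for the region table.
#' @return A [label_map()] (`read_label_map`) or `path` invisibly.
#' @export
read_label_map <- function(path, regions_path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3-D label image: ", path)
  hdr <- RNifti::niftiHeader(img)
  label_map(arr, regions = read_region_table(regions_path),
            spacing = RNifti::pixdim(img)[1:3],
            origin = c(hdr$srow_x[4], hdr$srow_y[4], hdr$srow_z[4]))
}

#' @rdname read_label_map
#' @param lm A [label_map()].
#' @export
write_label_map <- function(lm, path, regions_path) {
  stopifnot(inherits(lm, "label_map"))
  img <- nifti_with_meta(lm$labels, lm$spacing, lm$origin, "int32")
  RNifti::writeNifti(img, path)
  write_region_table(lm$regions, regions_path)
  invisible(path)
}

#' @rdname read_label_map
#' @export
read_region_table <- function(regions_path) {
  if (!file.exists(regions_path)) stop("file not found: ", regions_path)
  region_table(utils::read.delim(regions_path, sep = "\t",
                                 stringsAsFactors = FALSE))
}

#' @rdname read_label_map
#' @param rt A [region_table()].
#' @export
write_region_table <- function(rt, regions_path) {
  utils::write.table(as.data.frame(rt), regions_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(regions_path)
}

#' Read / write a displacement field as a 4-D NIfTI
#'
#' The field is stored with the three vector components (voxel units,
#' pull-back convention) along the fourth axis.
#'
#' @param path NIfTI path.
#' @return A `displacement_field` (`read_field`) or `path` invisibly.
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L || dim(arr)[4] != 3L)
    stop("expected a 4-D field with 3 components: ", path)
  storage.mode(arr) <- "double"
  displacement_field(arr, spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_field
#' @param f A `displacement_field`.
#' @export
write_field <- function(f, path) {
  stopifnot(inherits(f, "displacement_field"))
  img <- nifti_with_meta(f$d, f$spacing, c(0, 0, 0), "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write an affine transform as JSON
#'
#' Stored as `{matrix: 9 numbers row-major, translation: 3 numbers,
#' space: "voxel"}`.
#'
#' @param path JSON path.
#' @return An `affine_transform` (`read_affine`) or `path` invisibly.
#' @export
read_affine <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine_transform(matrix(x$matrix, 3, 3, byrow = TRUE), x$translation)
}

#' @rdname read_affine
#' @param a An `affine_transform`.
#' @export
write_affine <- function(a, path) {
  stopifnot(inherits(a, "affine_transform"))
  jsonlite::write_json(
    list(matrix = as.vector(t(a$matrix)), translation = a$translation,
         space = "voxel"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write FSL-style gradient tables
#'
#' `bvals` is one whitespace-separated row of b-values; `bvecs` has three
#' rows (x, y, z components), one column per diffusion volume.
#'
#' @param path Text file path.
#' @return `read_bvals`: numeric vector. `read_bvecs`: 3 x n matrix.
#' @export
read_bvals <- function(path) {
  scan(path, what = double(), quiet = TRUE)
}

#' @rdname read_bvals
#' @export
read_bvecs <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (nrow(m) != 3L) stop("bvecs file must have 3 rows")
  dimnames(m) <- NULL
  m
}

#' @rdname read_bvals
#' @param bvals Numeric vector of b-values.
#' @export
write_bvals <- function(bvals, path) {
  writeLines(paste(format(bvals, trim = TRUE, digits = 17), collapse = " "),
             path)
  invisible(path)
}

#' @rdname read_bvals
#' @param bvecs 3 x n matrix of unit gradient directions.
#' @export
write_bvecs <- function(bvecs, path) {
  stopifnot(nrow(bvecs) == 3L)
  writeLines(apply(bvecs, 1, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")), path)
  invisible(path)
}
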