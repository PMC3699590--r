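#' Create a 3-D scalar volume
#'
#' The basic image container of the package: a 3-D numeric grid plus voxel
#' spacing in millimetres and a world origin. All spatial operations in the
#' package work in 0-based voxel coordinates of the grid; spacing and origin
#' are carried as metadata only.
#'
#' @param data 3-D numeric array, all values finite.
#' @param spacing Numeric length-3, per-axis voxel size in mm, strictly positive.
#' @param origin Numeric length-3, position of voxel (0,0,0) in mm.
#' @return An object of class `volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L || any(dim(data) < 1L))
    stop("volume data must be a 3-D array with each axis >= 1")
  data <- array(as.double(data), dim(data))   # drop foreign attributes
  if (!all(is.finite(data)))
    stop("volume contains non-finite voxel values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive numbers")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat("<volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, range [", signif(min(x$data), 4), ", ", signif(max(x$data), 4),
      "]\n", sep = "")
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "volume")

stopifnot_same_grid <- function(a, b) {
  da <- if (is_volume(a)) dim(a$data) else if (inherits(a, "label_map")) dim(a$labels) else dim(a)
  db <- if (is_volume(b)) dim(b$data) else if (inherits(b, "label_map")) dim(b$labels) else dim(b)
  if (!identical(da, db))
    stop("grid shape mismatch: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
  invisible(TRUE)
}

#' Create a region lookup table
#'
#' Validates a table describing the anatomical regions of a parcellation.
#' Region id 0 is reserved for background and must never be listed.
#'
#' @param df Data frame with columns `region_id` (unique positive integers),
#'   `name`, `group` (one of cortical, white_matter, deep_gray, other) and
#'   `hemisphere` (one of left, right, midline).
#' @return The validated data frame with class `region_table` prepended.
#' @export
region_table <- function(df) {
  need <- c("region_id", "name", "group", "hemisphere")
  if (!all(need %in% names(df)))
    stop("region table needs columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[, need]
  df$region_id <- as.integer(df$region_id)
  if (anyNA(df$region_id) || any(df$region_id <= 0L))
    stop("region_id must be positive integers (0 is reserved for background)")
  if (anyDuplicated(df$region_id))
    stop("region_id values must be unique")
  if (!all(df$group %in% c("cortical", "white_matter", "deep_gray", "other")))
    stop("group must be one of cortical, white_matter, deep_gray, other")
  if (!all(df$hemisphere %in% c("left", "right", "midline")))
    stop("hemisphere must be one of left, right, midline")
  df <- df[order(df$region_id), ]
  rownames(df) <- NULL
  class(df) <- c("region_table", "data.frame")
  df
}

#' Create a label map
#'
#' An integer parcellation over the same grid contract as [volume()]:
#' non-negative integer labels where 0 means background and every non-zero
#' label must appear in the accompanying region table.
#'
#' @param labels 3-D array of non-negative integers.
#' @param regions A [region_table()] (or data frame coercible to one).
#' @param spacing,origin As for [volume()].
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, regions, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3-D array")
  if (any(!is.finite(labels)) || any(labels < 0) || any(labels != round(labels)))
    stop("labels must be finite non-negative integers")
  labels <- array(as.integer(round(labels)), dim(labels))
  if (!inherits(regions, "region_table")) regions <- region_table(regions)
  present <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(present, regions$region_id)
  if (length(missing))
    stop("labels not listed in region table: ", paste(missing, collapse = ", "))
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("invalid spacing")
  structure(list(labels = labels, regions = regions,
                 spacing = spacing, origin = origin),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map> ", paste(dim(x$labels), collapse = " x "), " voxels, ",
      nrow(x$regions), " regions, ",
      sum(x$labels != 0L), " labeled voxels\n", sep = "")
  invisible(x)
}

#' @export
dim.label_map <- function(x) dim(x$labels)
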