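#' Dice coefficient for one region
#'
#' `2 |A_r intersect B_r| / (|A_r| + |B_r|)`, with the conventions: 1 when the
#' region is empty in both maps, 0 when it is empty in exactly one.
#'
#' @param a,b [label_map()]s of equal shape.
#' @param r Region id (0 allowed for background).
#' @return Scalar in `[0, 1]`; symmetric in `a` and `b`.
#' @export
dice <- function(a, b, r) {
  stopifnot(inherits(a, "label_map"), inherits(b, "label_map"))
  stopifnot_same_grid(a, b)
  ar <- a$labels == r
  br <- b$labels == r
  na <- sum(ar); nb <- sum(br)
  if (na + nb == 0L) return(1)
  2 * sum(ar & br) / (na + nb)
}

#' Global matching index between two parcellations
#'
#' Label-aggregated Dice over all non-background regions:
#' `2 * sum_r |A_r intersect B_r| / sum_r (|A_r| + |B_r|)`. The alternative
#' summary `method = "mean"` averages the per-region Dice over regions
#' non-empty in at least one map.
#'
#' @param a,b [label_map()]s of equal shape with a shared region table.
#' @param method `"aggregated"` (default) or `"mean"`.
#' @return Scalar in `[0, 1]`; symmetric.
#' @export
global_index <- function(a, b, method = c("aggregated", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(a, "label_map"), inherits(b, "label_map"))
  stopifnot_same_grid(a, b)
  ids <- a$regions$region_id
  if (method == "mean") {
    keep <- vapply(ids, function(r)
      sum(a$labels == r) + sum(b$labels == r) > 0L, TRUE)
    if (!any(keep)) return(0)
    return(mean(vapply(ids[keep], function(r) dice(a, b, r), 0)))
  }
  inter <- 0; tot <- 0
  for (r in ids) {
    ar <- a$labels == r; br <- b$labels == r
    inter <- inter + sum(ar & br)
    tot <- tot + sum(ar) + sum(br)
  }
  if (tot == 0L) return(1)
  2 * inter / tot
}

#' Confusion matrix between a reference and a test parcellation
#'
#' `C[r, s]` is the percentage of voxels labeled `r` in the reference that
#' the test map labels `s`. Rows and columns include background (id 0).
#' Rows of non-empty reference regions sum to 100; empty reference regions
#' give an all-zero row, flagged in the `undefined_rows` attribute.
#'
#' @param reference,test [label_map()]s of equal shape.
#' @return Square matrix in percent with dimnames the ids, attribute
#'   `undefined_rows`.
#' @export
confusion_matrix <- function(reference, test) {
  stopifnot(inherits(reference, "label_map"), inherits(test, "label_map"))
  stopifnot_same_grid(reference, test)
  ids <- sort(unique(c(0L, reference$regions$region_id,
                       test$regions$region_id)))
  ri <- factor(match(as.vector(reference$labels), ids), levels = seq_along(ids))
  ti <- factor(match(as.vector(test$labels), ids), levels = seq_along(ids))
  C <- as.matrix(table(ri, ti))
  rowtot <- rowSums(C)
  out <- matrix(0, length(ids), length(ids),
                dimnames = list(as.character(ids), as.character(ids)))
  nonempty <- rowtot > 0
  out[nonempty, ] <- 100 * C[nonempty, , drop = FALSE] / rowtot[nonempty]
  attr(out, "undefined_rows") <- ids[!nonempty]
  out
}

#' Merge left/right region pairs into bilateral regions
#'
#' Pairs are matched by identical name after stripping a trailing or leading
#' left/right marker; midline regions pass through unchanged. Each merged
#' pair keeps the smaller of the two ids. Unpaired left/right entries are
#' kept as-is with a warning. Voxel counts are conserved.
#'
#' @param labels A [label_map()] whose region table has hemisphere entries.
#' @return A [label_map()] with the merged region table (hemisphere set to
#'   `"midline"` for merged entries).
#' @export
merge_bilateral <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  rt <- labels$regions
  base_name <- sub("^(left|right)\\s+", "",
                   sub("\\s*\\((left|right)\\)$", "", tolower(rt$name)))
  remap <- rt$region_id
  names(remap) <- as.character(rt$region_id)
  keep <- rep(TRUE, nrow(rt))
  merged_name <- rt$name
  for (nm in unique(base_name)) {
    rows <- which(base_name == nm)
    lat <- rt$hemisphere[rows]
    if (length(rows) == 2L && setequal(lat, c("left", "right"))) {
      ids <- sort(rt$region_id[rows])
      remap[as.character(ids[2])] <- ids[1]
      drop_row <- rows[rt$region_id[rows] == ids[2]]
      keep[drop_row] <- FALSE
      keep_row <- rows[rt$region_id[rows] == ids[1]]
      merged_name[keep_row] <- sub("^(left|right)\\s+", "",
                                   sub("\\s*\\((left|right)\\)$", "",
                                       rt$name[keep_row]),
                                   ignore.case = TRUE)
      rt$hemisphere[keep_row] <- "midline"
    } else if (any(lat %in% c("left", "right")) && length(rows) != 2L) {
      warning("unpaired hemisphere entry kept as-is: ", nm)
    }
  }
  rt$name <- merged_name
  new_rt <- region_table(rt[keep, ])
  lab <- labels$labels
  nz <- lab != 0L
  lab[nz] <- as.integer(remap[as.character(lab[nz])])
  label_map(lab, new_rt, labels$spacing, labels$origin)
}

#' Per-region volume and intensity statistics
#'
#' For every region: voxel count, volume as a percentage of all labeled
#' voxels, and mean intensity of an aligned scalar volume. With
#' `normalize = TRUE` the mean intensity is divided by the mean over all
#' labeled voxels, so values above 1 mean brighter than the brain average —
#' the same operation applies to FA or MD maps.
#'
#' @param v A [volume()] aligned with `labels`.
#' @param labels A [label_map()].
#' @param normalize Report intensities relative to the whole-brain mean.
#' @return Data frame with columns `region_id`, `name`, `n_voxels`,
#'   `volume_pct`, `mean_intensity` (and `rel_intensity` if normalized).
#' @export
region_statistics <- function(v, labels, normalize = FALSE) {
  stopifnot(is_volume(v), inherits(labels, "label_map"))
  stopifnot_same_grid(v, labels)
  lab <- as.vector(labels$labels)
  val <- as.vector(v$data)
  labeled <- lab != 0L
  if (!any(labeled)) stop("no labeled voxels")
  total <- sum(labeled)
  brain_mean <- mean(val[labeled])
  ids <- labels$regions$region_id
  n_vox <- vapply(ids, function(r) sum(lab == r), 0L)
  mean_int <- vapply(ids, function(r)
    if (any(lab == r)) mean(val[lab == r]) else NA_real_, 0)
  out <- data.frame(region_id = ids,
                    name = labels$regions$name,
                    n_voxels = n_vox,
                    volume_pct = 100 * n_vox / total,
                    mean_intensity = mean_int)
  if (normalize) out$rel_intensity <- mean_int / brain_mean
  out
}

#' Full evaluation report between two parcellations
#'
#' Bundles per-region Dice, the global matching index, the confusion matrix
#' and voxel counts into one object; writable as JSON + TSV.
#'
#' @param reference,test [label_map()]s of equal shape, shared region table.
#' @return An `eval_report` list.
#' @export
evaluate_parcellation <- function(reference, test) {
  ids <- reference$regions$region_id
  per_region <- vapply(ids, function(r) dice(reference, test, r), 0)
  names(per_region) <- as.character(ids)
  structure(list(per_region_dice = per_region,
                 global_index = global_index(reference, test),
                 confusion = confusion_matrix(reference, test),
                 voxel_counts = vapply(ids, function(r)
                   sum(reference$labels == r), 0L),
                 regions = reference$regions),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> global matching index ", signif(x$global_index, 4),
      "; per-region Dice mean ", signif(mean(x$per_region_dice), 4),
      " (range ", signif(min(x$per_region_dice), 4), "-",
      signif(max(x$per_region_dice), 4), ")\n", sep = "")
  invisible(x)
}

#' Render a confusion matrix as a heat-map PNG
#'
#' Rows are reference regions, columns assigned regions; brightness encodes
#' the percentage of reference voxels, so a perfect parcellation is a
#' bright diagonal.
#'
#' @param C Matrix from [confusion_matrix()].
#' @param path Output PNG path.
#' @param width,height Device size in pixels.
#' @return `path`, invisibly.
#' @export
confusion_heatmap <- function(C, path, width = 600, height = 600) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  n <- nrow(C)
  graphics::image(seq_len(ncol(C)), seq_len(n), t(C[n:1, , drop = FALSE]),
                  col = grDevices::gray.colors(64, start = 0, end = 1),
                  zlim = c(0, 100), axes = FALSE,
                  xlab = "assigned region", ylab = "reference region")
  graphics::axis(1, seq_len(ncol(C)), colnames(C), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(n), rev(rownames(C)), las = 2, cex.axis = 0.7)
  graphics::box()
  invisible(path)
}

#' Write an evaluation report as JSON plus a confusion-matrix TSV
#'
#' @param report An `eval_report`.
#' @param json_path Output JSON path.
#' @param confusion_path Optional TSV path for the confusion matrix.
#' @return `json_path`, invisibly.
#' @export
write_eval_report <- function(report, json_path, confusion_path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(
    list(global_index = report$global_index,
         per_region_dice = as.list(report$per_region_dice),
         voxel_counts = as.list(stats::setNames(report$voxel_counts,
                                names(report$per_region_dice)))),
    json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(confusion_path))
    utils::write.table(report$confusion, confusion_path, sep = "\t",
                       quote = FALSE, col.names = NA)
  invisible(json_path)
}
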