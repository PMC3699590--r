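#' Propagate a label map through a spatial transform
#'
#' Nearest-neighbour warp of an integer parcellation: the transform must be
#' defined on the target subject's grid (pull-back convention). The output
#' label set is always a subset of the input labels plus background;
#' out-of-field voxels become background.
#'
#' @param labels A [label_map()].
#' @param t A `displacement_field` or `affine_transform` on the target grid.
#' @return The propagated [label_map()].
#' @export
propagate_labels <- function(labels, t) {
  stopifnot(inherits(labels, "label_map"))
  warp_volume(labels, t)
}

#' Majority-vote label fusion
#'
#' Per-voxel mode over a list of equally shaped label maps sharing one region
#' table. Background (0) participates as a vote; ties are broken toward the
#' smallest region id (background wins any tie it is part of).
#'
#' @param maps Non-empty list of [label_map()]s.
#' @return The fused [label_map()].
#' @export
majority_vote <- function(maps) {
  if (length(maps) == 0L) stop("empty list of label maps")
  stopifnot(all(vapply(maps, inherits, TRUE, "label_map")))
  d0 <- dim(maps[[1]]$labels)
  for (m in maps) stopifnot_same_grid(maps[[1]], m)
  ids <- sort(unique(c(0L, unlist(lapply(maps, function(m)
    unique(as.vector(m$labels)))))))
  nvox <- prod(d0)
  counts <- matrix(0L, nvox, length(ids))
  for (m in maps) {
    col <- match(as.vector(m$labels), ids)
    counts[cbind(seq_len(nvox), col)] <- counts[cbind(seq_len(nvox), col)] + 1L
  }
  # columns ordered by ascending id, so "first" max implements the tie rule
  win <- max.col(counts, ties.method = "first")
  label_map(array(ids[win], d0), maps[[1]]$regions,
            maps[[1]]$spacing, maps[[1]]$origin)
}

#' Bootstrap an initial parcellation from previously labeled subjects
#'
#' The delineation-bootstrap step: each prior subject's label map is carried
#' onto the new subject's grid by elastic registration (optionally preceded
#' by affine alignment) and the propagated maps are fused by majority vote.
#' The result is a starting parcellation meant to be reviewed or corrected;
#' `editor` accepts a function `(fused, new_subject) -> label_map` standing in
#' for that correction (tests use the synthetic ground truth as the editor).
#'
#' @param new_subject A [volume()] to be parcellated.
#' @param priors Non-empty list of `list(volume = , labels = )` pairs.
#' @param cfg A [reg_config()].
#' @param affine_first Run MI affine alignment before elastic registration.
#' @param editor Optional correction hook applied to the fused map.
#' @return The fused (possibly edited) [label_map()] on the new subject's
#'   grid, with attribute `propagated` holding the individual propagated maps.
#' @export
bootstrap_initialization <- function(new_subject, priors, cfg = reg_config(),
                                     affine_first = TRUE, editor = NULL) {
  stopifnot(is_volume(new_subject))
  if (length(priors) == 0L) stop("empty priors list")
  propagated <- vector("list", length(priors))
  for (i in seq_along(priors)) {
    pv <- priors[[i]]$volume
    pl <- priors[[i]]$labels
    stopifnot(is_volume(pv), inherits(pl, "label_map"))
    if (affine_first) {
      aff <- register_affine_mi(new_subject, pv, cfg)
      pv <- warp_volume(pv, aff, outdim = dim(new_subject$data))
      pl <- warp_volume(pl, aff, outdim = dim(new_subject$data))
    }
    d <- register_elastic(new_subject, pv, cfg)
    propagated[[i]] <- propagate_labels(pl, d)
  }
  fused <- majority_vote(propagated)
  if (!is.null(editor)) fused <- editor(fused, new_subject)
  attr(fused, "propagated") <- propagated
  fused
}
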