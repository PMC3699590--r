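#' Build probabilistic region maps over a template
#'
#' Each subject's parcellation is carried onto the template grid with the
#' subject field stored in the template model (nearest-neighbour pull-back:
#' the template-grid field samples the subject at `x + d(x)`, which is
#' exactly the propagation the probability maps need — no field inversion).
#' The probability of region `r` at voxel `x` is the fraction of subjects
#' whose propagated label there is `r`; out-of-field voxels count as
#' background votes. Probabilities are therefore multiples of `1/N` and sum
#' to 1 at every voxel once background is included.
#'
#' @param tm A `template_model` from [build_template()].
#' @param labelmaps List of [label_map()]s, one per subject, in the same
#'   order as the stored fields.
#' @return A `prob_atlas`: list with `template` ([volume()]), `prob`
#'   (`(nx, ny, nz, R)` array ordered by region id), `background`
#'   (3-D array), `n_subjects`, `regions`.
#' @export
build_probability_maps <- function(tm, labelmaps) {
  stopifnot(inherits(tm, "template_model"))
  n <- length(labelmaps)
  if (n != length(tm$subject_fields))
    stop("need one label map per stored subject field (",
         length(tm$subject_fields), "), got ", n)
  stopifnot(all(vapply(labelmaps, inherits, TRUE, "label_map")))
  regions <- labelmaps[[1]]$regions
  ids <- regions$region_id
  dims <- dim(tm$volume$data)
  counts <- array(0L, c(dims, length(ids)))
  bg <- array(0L, dims)
  for (i in seq_len(n)) {
    lm <- labelmaps[[i]]
    if (!is.null(tm$subject_affines)) {
      lm <- warp_volume(lm, tm$subject_affines[[i]], outdim = dims)
    }
    warped <- warp_volume(lm, tm$subject_fields[[i]])
    lab <- warped$labels
    bg <- bg + (lab == 0L)
    for (k in seq_along(ids)) {
      counts[, , , k] <- counts[, , , k] + (lab == ids[k])
    }
  }
  structure(list(template = tm$volume,
                 prob = counts / n,
                 background = bg / n,
                 n_subjects = n,
                 regions = regions),
            class = "prob_atlas")
}

#' @export
print.prob_atlas <- function(x, ...) {
  cat("<prob_atlas> ", paste(dim(x$template$data), collapse = " x "),
      " voxels, ", nrow(x$regions), " regions, N = ", x$n_subjects,
      " subjects\n", sep = "")
  invisible(x)
}

#' Most-probable label map of a probabilistic atlas
#'
#' Per-voxel argmax over the region probabilities with background as an
#' explicit competing class; ties break toward the smallest region id
#' (background, id 0, wins ties it takes part in). Voxels where every region
#' probability is zero are background.
#'
#' @param atlas A `prob_atlas`.
#' @return A [label_map()] on the template grid.
#' @export
max_label_map <- function(atlas) {
  stopifnot(inherits(atlas, "prob_atlas"))
  argmax_labels(atlas$prob, atlas$background, atlas$regions,
                atlas$template$spacing, atlas$template$origin)$labels
}

argmax_labels <- function(prob, background, regions, spacing, origin) {
  dims <- dim(prob)[1:3]
  nvox <- prod(dims)
  P <- cbind(as.vector(background), matrix(prob, nvox, dim(prob)[4]))
  win <- max.col(P, ties.method = "first")   # columns ordered 0, ids ascending
  ids <- c(0L, regions$region_id)
  list(labels = label_map(array(ids[win], dims), regions, spacing, origin),
       maxprob = volume(array(P[cbind(seq_len(nvox), win)], dims),
                        spacing, origin))
}

#' Atlas-based automatic parcellation of a new volume
#'
#' Registers the template to the new volume (MI affine, then block-matching
#' elastic), resamples every region probability map (and the background map)
#' onto the new grid with trilinear interpolation — preserving the partial
#' volume information a hard label map would lose — and assigns each voxel
#' the region of maximum probability.
#'
#' @param new_volume A [volume()], same modality as the template.
#' @param atlas A `prob_atlas`.
#' @param cfg A [reg_config()].
#' @param affine_first Run the affine stage before the elastic one.
#' @return List with `labels` ([label_map()]), `maxprob` ([volume()] of the
#'   winning probability) and `transforms` (the affine and field used).
#' @export
segment <- function(new_volume, atlas, cfg = reg_config(),
                    affine_first = TRUE) {
  stopifnot(is_volume(new_volume), inherits(atlas, "prob_atlas"))
  dims <- dim(new_volume$data)
  tmpl <- atlas$template
  aff <- NULL
  init <- NULL
  same_grid0 <- identical(dim(tmpl$data), dims)
  if (affine_first) {
    aff <- tryCatch(register_affine_mi(new_volume, tmpl, cfg),
                    error = function(e) {
                      warning("affine stage failed (", conditionMessage(e),
                              "); continuing with identity")
                      affine_transform()
                    })
    if (same_grid0) {
      # fold the affine into the elastic initialization so the template is
      # only ever resampled once
      init <- compose_affine_field(aff, zero_field(dims,
                                                   new_volume$spacing))
      aff <- NULL
    } else {
      tmpl <- warp_volume(tmpl, aff, outdim = dims)
    }
  }
  d <- tryCatch(register_elastic(new_volume, tmpl, cfg, init = init),
                error = function(e) {
                  warning("elastic stage failed (", conditionMessage(e),
                          "); falling back to affine-only labeling")
                  if (is.null(init)) zero_field(dims, new_volume$spacing)
                  else init
                })
  nreg <- dim(atlas$prob)[4]
  prob_new <- array(0, c(dims, nreg))
  same_grid <- identical(dim(atlas$template$data), dims)
  if (same_grid || is.null(aff)) {
    # one combined resampling: the affine composed with the elastic field
    total <- if (is.null(aff)) d else compose_affine_field(aff, d)
    for (k in seq_len(nreg)) {
      prob_new[, , , k] <- warp_array(atlas$prob[, , , k], total,
                                      "trilinear", 0)
    }
    bg <- warp_array(atlas$background, total, "trilinear", 1)
  } else {
    # differing grids: resample through the affine first
    for (k in seq_len(nreg)) {
      pk <- warp_array(atlas$prob[, , , k], aff, "trilinear", 0, dims)
      prob_new[, , , k] <- warp_array(pk, d, "trilinear", 0)
    }
    bg <- warp_array(atlas$background, aff, "trilinear", 1, dims)
    bg <- warp_array(bg, d, "trilinear", 1)
  }
  res <- argmax_labels(prob_new, bg, atlas$regions,
                       new_volume$spacing, new_volume$origin)
  res$transforms <- list(affine = aff, field = d)
  res
}

#' Persist / load a probabilistic atlas
#'
#' Written as a directory: `template.nii.gz`, the region probability maps as
#' one 4-D NIfTI ordered by region id, the background map, the region table
#' TSV and a JSON manifest.
#'
#' @param atlas A `prob_atlas`.
#' @param dir Directory path.
#' @return `dir` (`write_prob_atlas`) or a `prob_atlas`.
#' @export
write_prob_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "prob_atlas"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(atlas$template, file.path(dir, "template.nii.gz"))
  sp <- atlas$template$spacing
  RNifti::writeNifti(nifti_with_meta(atlas$prob, sp, c(0, 0, 0), "double"),
                     file.path(dir, "prob.nii.gz"))
  RNifti::writeNifti(nifti_with_meta(atlas$background, sp, c(0, 0, 0),
                                     "double"),
                     file.path(dir, "background.nii.gz"))
  write_region_table(atlas$regions, file.path(dir, "regions.tsv"))
  jsonlite::write_json(list(n_subjects = atlas$n_subjects),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_prob_atlas
#' @export
read_prob_atlas <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  prob <- as.array(RNifti::readNifti(file.path(dir, "prob.nii.gz")))
  prob <- array(as.double(prob), dim(prob))
  bg <- as.array(RNifti::readNifti(file.path(dir, "background.nii.gz")))
  structure(list(template = read_volume(file.path(dir, "template.nii.gz")),
                 prob = prob,
                 background = array(as.double(bg), dim(bg)),
                 n_subjects = man$n_subjects,
                 regions = read_region_table(file.path(dir, "regions.tsv"))),
            class = "prob_atlas")
}
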