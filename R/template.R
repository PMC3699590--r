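#' Select the reference subject for template construction
#'
#' The reference is the volume requiring the minimum transformation to match
#' all the others: every candidate is elastically registered to every other
#' volume, each pairwise field is summarized by its mean displacement norm,
#' and the candidate with the smallest average is selected (ties toward the
#' smallest index).
#'
#' @param volumes List of >= 2 [volume()]s on one grid.
#' @param cfg A [reg_config()].
#' @return Integer index of the reference, with attribute
#'   `displacement_matrix` (n x n, entry i,j = mean displacement of the
#'   field registering volume j as fixed against candidate i as moving).
#' @export
select_reference <- function(volumes, cfg = reg_config()) {
  n <- length(volumes)
  if (n < 2L) stop("need at least 2 volumes")
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- register_elastic(volumes[[j]], volumes[[i]], cfg)
      D[i, j] <- mean_displacement(d)
    }
  }
  score <- rowSums(D) / (n - 1)
  ref <- which.min(score)   # which.min returns the first minimum: tie rule
  attr(ref, "displacement_matrix") <- D
  ref
}

#' Iterative average-shape template
#'
#' Starting from the reference volume, the current template is elastically
#' registered toward every subject (subject as fixed grid), the resulting
#' fields are averaged, and the template is warped by the mean field. The
#' loop stops when the mean displacement of the mean field drops below `tol`
#' voxels or `max_iter` is reached. With the fields oriented this way the
#' pull-back application of the averaged field moves the template toward the
#' population shape barycenter, so the update is contractive.
#'
#' @param volumes List of [volume()]s on one grid.
#' @param ref_index Index of the initial template (see [select_reference()]).
#' @param cfg A [reg_config()].
#' @param tol Convergence threshold on the mean displacement (voxels).
#' @param max_iter Iteration cap.
#' @return List with `shape_template` ([volume()]), `history` (per-iteration
#'   mean displacement of the mean field) and `converged`.
#' @export
build_mean_shape <- function(volumes, ref_index, cfg = reg_config(),
                             tol = 0.1, max_iter = 10L) {
  stopifnot(ref_index >= 1L, ref_index <= length(volumes))
  ref <- volumes[[ref_index]]
  tmpl <- ref
  total <- zero_field(dim(ref$data), ref$spacing)
  history <- numeric(0)
  converged <- FALSE
  prev_md <- Inf
  for (it in seq_len(max_iter)) {
    fields <- lapply(volumes, function(v) register_elastic(v, tmpl, cfg))
    mean_field <- average_fields(fields)
    md_it <- mean_displacement(mean_field)
    history <- c(history, md_it)
    if (md_it < tol) { converged <- TRUE; break }
    # registration noise puts a floor under the mean displacement; once the
    # update stops contracting, applying it would only degrade the template
    if (md_it >= prev_md) break
    # accumulate the warp and resample the reference once, so the template
    # does not blur through repeated interpolation
    total <- compose_fields(total, mean_field)
    tmpl <- warp_volume(ref, total)
    prev_md <- md_it
  }
  list(shape_template = tmpl, history = history, converged = converged)
}

# Single-pass two-sided 2-SD trimmed mean across subjects, per voxel.
# x: n_subject x n_voxel matrix. Values with |x - mean| > k * SD are
# excluded; when SD is zero all values survive. side = "upper" excludes
# only values above mean + k * SD.
trimmed_mean_rows <- function(x, k = 2, side = c("two", "upper")) {
  side <- match.arg(side)
  m <- colMeans(x)
  n <- nrow(x)
  s <- sqrt(colSums(sweep(x, 2, m)^2) / (n - 1))
  dev <- sweep(x, 2, m)
  keep <- if (side == "two") abs(dev) <= rep(k * s, each = n)
          else dev <= rep(k * s, each = n)
  keep[, s == 0] <- TRUE
  nk <- colSums(keep)
  if (any(nk == 0)) stop("all values excluded at a voxel")  # impossible for n >= 2
  colSums(x * keep) / nk
}

#' Average-intensity template over the mean shape
#'
#' Every subject volume is elastically registered onto the shape template
#' (template as fixed grid) and resampled there. At each voxel the template
#' intensity is the mean of the per-subject values after excluding outliers
#' more than `trim_sd` standard deviations from the voxel mean (single pass;
#' two-sided by default, `trim_side = "upper"` for the one-sided variant).
#' The per-subject fields are retained: they map template-grid voxels to
#' sampling positions in each subject, which is exactly what label
#' propagation onto the template needs.
#'
#' @param volumes List of [volume()]s.
#' @param shape_template The [volume()] from [build_mean_shape()].
#' @param cfg A [reg_config()].
#' @param trim_sd Exclusion threshold in SD units (default 2).
#' @param trim_side `"two"` (default) or `"upper"`.
#' @param affine_first Affine-align each subject to the template before the
#'   elastic step.
#' @return A `template_model`: list with `volume`, `subject_fields` (list of
#'   `displacement_field`s on the template grid), `subject_affines` (or NULL),
#'   `iterations_run`, `converged`, `history`, `config`.
#' @export
build_mean_intensity <- function(volumes, shape_template, cfg = reg_config(),
                                 trim_sd = 2, trim_side = c("two", "upper"),
                                 affine_first = FALSE) {
  trim_side <- match.arg(trim_side)
  stopifnot(is_volume(shape_template))
  n <- length(volumes)
  fields <- vector("list", n)
  affines <- if (affine_first) vector("list", n) else NULL
  warped <- matrix(0, n, prod(dim(shape_template$data)))
  for (i in seq_len(n)) {
    mov <- volumes[[i]]
    if (affine_first) {
      affines[[i]] <- register_affine_mi(shape_template, mov, cfg)
      mov <- warp_volume(mov, affines[[i]], outdim = dim(shape_template$data))
    }
    fields[[i]] <- register_elastic(shape_template, mov, cfg)
    warped[i, ] <- as.vector(warp_volume(mov, fields[[i]])$data)
  }
  mean_int <- trimmed_mean_rows(warped, k = trim_sd, side = trim_side)
  structure(list(volume = volume(array(mean_int, dim(shape_template$data)),
                                 shape_template$spacing,
                                 shape_template$origin),
                 subject_fields = fields,
                 subject_affines = affines,
                 iterations_run = NA_integer_,
                 converged = NA,
                 history = numeric(0),
                 config = cfg),
            class = "template_model")
}

#' @export
print.template_model <- function(x, ...) {
  cat("<template_model> ", paste(dim(x$volume$data), collapse = " x "),
      " voxels, ", length(x$subject_fields), " subjects, ",
      x$iterations_run, " shape iterations (converged: ", x$converged,
      ")\n", sep = "")
  invisible(x)
}

#' Build the full average-shape, average-intensity template
#'
#' Orchestrates [select_reference()], [build_mean_shape()] and
#' [build_mean_intensity()]. Deterministic given inputs and config. The
#' stored per-subject fields are reused by [build_probability_maps()].
#'
#' @inheritParams build_mean_shape
#' @inheritParams build_mean_intensity
#' @param ref_index Optional: skip reference selection and use this index.
#' @return A `template_model` (see [build_mean_intensity()]), with
#'   `ref_index` recorded.
#' @export
build_template <- function(volumes, cfg = reg_config(), tol = 0.1,
                           max_iter = 10L, trim_sd = 2,
                           trim_side = c("two", "upper"),
                           affine_first = FALSE, ref_index = NULL) {
  if (length(volumes) < 2L) stop("need at least 2 volumes")
  trim_side <- match.arg(trim_side)
  if (is.null(ref_index)) ref_index <- select_reference(volumes, cfg)
  ms <- build_mean_shape(volumes, ref_index, cfg, tol, max_iter)
  tm <- build_mean_intensity(volumes, ms$shape_template, cfg,
                             trim_sd, trim_side, affine_first)
  tm$iterations_run <- length(ms$history)
  tm$converged <- ms$converged
  tm$history <- ms$history
  tm$ref_index <- as.integer(ref_index)
  tm
}

#' Persist / load a template model
#'
#' Written as a directory: `template.nii.gz`, one `field_XX.nii.gz` per
#' subject and a JSON manifest with the iteration history and config.
#'
#' @param tm A `template_model`.
#' @param dir Output directory (created if needed).
#' @return `dir` (`write_template_model`) or a `template_model`.
#' @export
write_template_model <- function(tm, dir) {
  stopifnot(inherits(tm, "template_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(tm$volume, file.path(dir, "template.nii.gz"))
  for (i in seq_along(tm$subject_fields))
    write_field(tm$subject_fields[[i]],
                file.path(dir, sprintf("field_%02d.nii.gz", i)))
  jsonlite::write_json(
    list(n_subjects = length(tm$subject_fields),
         iterations_run = tm$iterations_run,
         converged = tm$converged,
         history = tm$history,
         ref_index = tm$ref_index,
         config = unclass(tm$config)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_template_model
#' @export
read_template_model <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  fields <- lapply(seq_len(man$n_subjects), function(i)
    read_field(file.path(dir, sprintf("field_%02d.nii.gz", i))))
  structure(list(volume = read_volume(file.path(dir, "template.nii.gz")),
                 subject_fields = fields,
                 subject_affines = NULL,
                 iterations_run = man$iterations_run,
                 converged = man$converged,
                 history = man$history,
                 ref_index = man$ref_index,
                 config = do.call(reg_config, man$config)),
            class = "template_model")
}
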