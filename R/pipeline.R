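# Config handling shared by the orchestrators: accept a YAML/JSON path or an
# already-parsed list; validate before any compute so malformed configs fail
# fast with a message naming the offending entry.
load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    cfg <- yaml::read_yaml(config)
    attr(cfg, "path") <- config
    cfg
  } else if (is.list(config)) config
  else stop("config must be a file path or a list")
}

cfg_reg <- function(cfg) {
  args <- cfg$registration
  if (is.null(args)) args <- list()
  if (!is.null(cfg$seed)) args$seed <- cfg$seed
  do.call(reg_config, args)
}

stage_log <- function(log_con, stage, expr) {
  t0 <- Sys.time()
  res <- withCallingHandlers(expr, warning = function(w) {
    msg <- sprintf("[%s] warning: %s", stage, conditionMessage(w))
    message(msg)
    if (!is.null(log_con)) writeLines(msg, log_con)
    invokeRestart("muffleWarning")
  })
  dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  msg <- sprintf("[%s] done in %.1f s", stage, dt)
  message(msg)
  if (!is.null(log_con)) writeLines(msg, log_con)
  res
}

read_subjects <- function(cfg) {
  if (is.null(cfg$subjects) || !length(cfg$subjects))
    stop("config lists no subjects")
  if (is.null(cfg$regions)) stop("config is missing the regions TSV path")
  lapply(seq_along(cfg$subjects), function(i) {
    s <- cfg$subjects[[i]]
    nm <- if (!is.null(s$id)) s$id else paste0("subject ", i)
    if (is.null(s$volume) || !file.exists(s$volume))
      stop("missing volume for ", nm, ": ", s$volume)
    if (is.null(s$labels) || !file.exists(s$labels))
      stop("missing label map for ", nm, ": ", s$labels)
    list(id = nm,
         volume = read_volume(s$volume),
         labels = read_label_map(s$labels, cfg$regions))
  })
}

#' Build a template and probabilistic atlas from a config
#'
#' End-to-end atlas construction: reads the subject volumes and label maps
#' listed in the config, builds the average-shape/average-intensity template
#' and the per-region probability maps, and writes everything (template
#' model, atlas, manifest with config and per-stage timing log) to the
#' output directory. Reruns with the same config are bit-identical.
#'
#' Config keys: `subjects` (list of `{id, volume, labels}`), `regions`
#' (TSV path), `out` (directory), optional `seed`, `registration`
#' (arguments to [reg_config()]), `template` (`tol`, `max_iter`, `trim_sd`,
#' `trim_side`).
#'
#' @param config Path to a YAML config, or an equivalent list.
#' @param out Output directory (overrides `config$out`).
#' @return Invisible list with `template_model`, `atlas`, `out`.
#' @export
run_build <- function(config, out = NULL) {
  cfg <- load_config(config)
  if (is.null(out)) out <- cfg$out
  if (is.null(out)) stop("no output directory (config$out or out=)")
  subjects <- read_subjects(cfg)
  reg <- cfg_reg(cfg)
  tpl_args <- cfg$template
  if (is.null(tpl_args)) tpl_args <- list()
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out, "run.log"), open = "wt")
  on.exit(close(log_con))
  vols <- lapply(subjects, `[[`, "volume")
  labs <- lapply(subjects, `[[`, "labels")
  tm <- stage_log(log_con, "template",
                  do.call(build_template,
                          c(list(volumes = vols, cfg = reg), tpl_args)))
  atlas <- stage_log(log_con, "probatlas", build_probability_maps(tm, labs))
  stage_log(log_con, "write", {
    write_template_model(tm, file.path(out, "template_model"))
    write_prob_atlas(atlas, file.path(out, "atlas"))
    jsonlite::write_json(
      list(n_subjects = length(subjects),
           subject_ids = vapply(subjects, `[[`, "", "id"),
           config = cfg[setdiff(names(cfg), "subjects")],
           config_hash = unname(config_hash(cfg))),
      file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA)
  })
  invisible(list(template_model = tm, atlas = atlas, out = out))
}

config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tf)
  tools::md5sum(tf)
}

#' Segment a new volume with a built atlas
#'
#' Runs the atlas-based parcellation of [segment()] on a new volume and, if
#' reference labels are supplied, evaluates the result (per-region Dice,
#' global matching index, confusion matrix). Outputs are written next to the
#' atlas unless `out` is given.
#'
#' @param config Path/list with at least `atlas` (directory from
#'   [run_build()]; the `atlas` subdirectory is used if present); optional
#'   `seed`, `registration`.
#' @param new_volume Path to the volume to parcellate (or a [volume()]).
#' @param reference Optional path to reference labels (NIfTI; region TSV
#'   taken from the atlas) or a [label_map()].
#' @param out Output directory.
#' @return Invisible list with `labels`, `maxprob`, and `report` (NULL
#'   without a reference).
#' @export
run_segment <- function(config, new_volume, reference = NULL, out = NULL) {
  cfg <- load_config(config)
  atlas_dir <- cfg$atlas
  if (is.null(atlas_dir)) stop("config is missing the atlas directory")
  if (dir.exists(file.path(atlas_dir, "atlas")))
    atlas_dir <- file.path(atlas_dir, "atlas")
  atlas <- read_prob_atlas(atlas_dir)
  v <- if (is_volume(new_volume)) new_volume else read_volume(new_volume)
  reg <- cfg_reg(cfg)
  res <- segment(v, atlas, reg)
  report <- NULL
  if (!is.null(reference)) {
    ref <- if (inherits(reference, "label_map")) reference
           else label_map(as.array(RNifti::readNifti(reference)),
                          atlas$regions, v$spacing, v$origin)
    report <- evaluate_parcellation(ref, res$labels)
  }
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_label_map(res$labels, file.path(out, "segmentation.nii.gz"),
                    file.path(out, "regions.tsv"))
    write_volume(res$maxprob, file.path(out, "maxprob.nii.gz"))
    jsonlite::write_json(list(atlas = atlas_dir,
                              n_subjects = atlas$n_subjects,
                              evaluated = !is.null(report)),
                         file.path(out, "provenance.json"), auto_unbox = TRUE)
    if (!is.null(report))
      write_eval_report(report, file.path(out, "report.json"),
                        file.path(out, "confusion.tsv"))
  }
  invisible(list(labels = res$labels, maxprob = res$maxprob, report = report))
}

#' Bootstrap parcellations across an unlabeled cohort
#'
#' Sequential delineation bootstrap: starting from the labeled subjects, each
#' unlabeled subject in config order receives an initial parcellation fused
#' from all subjects labeled so far ([bootstrap_initialization()]); the
#' (optionally editor-corrected) result joins the prior pool before the next
#' subject is processed. The growing pool order is logged.
#'
#' @param config Path/list with `labeled` (list of `{id, volume, labels}`),
#'   `unlabeled` (list of `{id, volume}`), `regions` TSV path, optional
#'   `seed`, `registration`, `out`.
#' @param editor Optional correction hook passed to
#'   [bootstrap_initialization()].
#' @return Invisible list of [label_map()]s for the unlabeled subjects, in
#'   config order.
#' @export
run_bootstrap <- function(config, editor = NULL) {
  cfg <- load_config(config)
  if (is.null(cfg$labeled) || !length(cfg$labeled))
    stop("need at least one labeled seed subject")
  if (is.null(cfg$unlabeled) || !length(cfg$unlabeled))
    stop("config lists no unlabeled subjects")
  reg <- cfg_reg(cfg)
  out <- cfg$out
  log_con <- NULL
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    log_con <- file(file.path(out, "run.log"), open = "wt")
    on.exit(close(log_con))
  }
  pool <- lapply(cfg$labeled, function(s)
    list(volume = read_volume(s$volume),
         labels = read_label_map(s$labels, cfg$regions)))
  results <- list()
  for (i in seq_along(cfg$unlabeled)) {
    s <- cfg$unlabeled[[i]]
    nm <- if (!is.null(s$id)) s$id else paste0("unlabeled ", i)
    v <- read_volume(s$volume)
    fused <- stage_log(log_con, paste0("bootstrap:", nm, ":pool",
                                       length(pool)),
                       bootstrap_initialization(v, pool, reg,
                                                editor = editor))
    results[[nm]] <- fused
    pool[[length(pool) + 1L]] <- list(volume = v, labels = fused)
    if (!is.null(out))
      write_label_map(fused,
                      file.path(out, sprintf("init_labels_%s.nii.gz", nm)),
                      file.path(out, "regions.tsv"))
  }
  invisible(results)
}
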