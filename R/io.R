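# Cohort and configuration I/O: NIfTI volumes, CSV feature tables, JSON
# manifests, YAML (or JSON) configs.

#' Write a phantom cohort to disk
#'
#' One directory per subject with `t1/t1ce/t2/flair/mask.nii.gz`, a cohort
#' `features.csv` (subject id, labels, 101 features) and a `manifest.json`
#' recording the generating spec, seed and package version.
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort) {
    sd <- file.path(dir, s$subject_id)
    dir.create(sd, showWarnings = FALSE)
    for (m in names(s$volumes)) {
      write_nifti(s$volumes[[m]], file.path(sd, paste0(m, ".nii.gz")))
    }
    write_nifti(s$roi_mask + 0, file.path(sd, "mask.nii.gz"))
  }
  feats <- cohort_features(cohort)
  lab <- subject_labels(cohort)
  dt <- data.table::data.table(
    subject_id = vapply(cohort, function(s) s$subject_id, character(1)),
    idh_label = lab$idh, grade_label = lab$grade)
  dt <- cbind(dt, data.table::as.data.table(feats))
  data.table::fwrite(dt, file.path(dir, "features.csv"))
  spec <- attr(cohort, "spec")
  manifest <- list(
    package_version = as.character(utils::packageVersion("mtglioma")),
    n_subjects = length(cohort),
    subject_ids = vapply(cohort, function(s) s$subject_id, character(1)),
    spec = if (!is.null(spec)) unclass(spec),
    mask_labels = list(background = 0, necrotic_core = 1, enhancing = 2,
                       edema = 3))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return a `phantom_cohort`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  dt <- data.table::fread(file.path(dir, "features.csv"))
  feat_cols <- setdiff(colnames(dt), c("subject_id", "idh_label",
                                       "grade_label"))
  subjects <- lapply(manifest$subject_ids, function(id) {
    sd <- file.path(dir, id)
    vols <- lapply(c(t1 = "t1", t1ce = "t1ce", t2 = "t2", flair = "flair"),
                   function(m) read_nifti(file.path(sd, paste0(m, ".nii.gz"))))
    mask <- read_nifti(file.path(sd, "mask.nii.gz"))
    storage.mode(mask) <- "integer"
    row <- dt[dt$subject_id == id, ]
    feats <- as.numeric(row[, feat_cols, with = FALSE])
    names(feats) <- feat_cols
    structure(list(volumes = vols, roi_mask = mask,
                   idh_label = as.integer(row$idh_label),
                   grade_label = as.integer(row$grade_label),
                   features = feats, subject_id = id),
              class = "phantom_subject")
  })
  spec <- if (!is.null(manifest$spec)) {
    do.call(phantom_spec, manifest$spec)
  }
  structure(subjects, class = "phantom_cohort", spec = spec)
}

#' Export a mismatch or attention map as NIfTI
#'
#' @param x a `mismatch_map`, `gradcam_map` or bare 3D array.
#' @param path output `.nii`/`.nii.gz` path.
#' @export
export_map <- function(x, path) {
  vol <- if (is.list(x)) x$data %||% x$map else x
  write_nifti(vol, path)
}

# ---- configs ----------------------------------------------------------------

#' Read a training config from YAML or JSON
#'
#' Recognized keys mirror [train_config()] and [encoder_config()] (nested
#' under `encoder`) and [loss_config()] (nested under `loss`).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a [train_config()].
#' @export
read_config <- function(path) {
  lst <- if (grepl("\\.(yaml|yml)$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML configs; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  enc <- if (!is.null(lst$encoder)) do.call(encoder_config, lst$encoder)
         else encoder_config()
  loss <- if (!is.null(lst$loss)) do.call(loss_config, lst$loss)
          else loss_config()
  rest <- lst[setdiff(names(lst), c("encoder", "loss"))]
  do.call(train_config, c(list(encoder = enc, loss = loss), rest))
}

#' Write a training config to YAML or JSON
#'
#' @param cfg a [train_config()].
#' @param path output path; format chosen by extension.
#' @export
write_config <- function(cfg, path) {
  lst <- serialize_cfg(cfg)
  lst$encoder <- unclass(cfg$encoder)
  lst$encoder$adapter_hidden <- NULL
  lst$encoder$grid <- NULL
  if (grepl("\\.(yaml|yml)$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML configs; use JSON instead")
    }
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
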