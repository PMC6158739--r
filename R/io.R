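# Readers and writers: NIfTI volumes, subject/biomarker tables, YAML configs.

#' Write a 3-D volume (or mask) as NIfTI-1
#'
#' @param vol numeric or logical 3-D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param datatype NIfTI storage type (default float32 for data).
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path, affine = diag(c(2.5, 2.5, 2.5, 1)),
                         datatype = "float") {
  img <- RNifti::asNifti(vol + 0)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a 3-D NIfTI volume
#'
#' @param path NIfTI file.
#' @param as_mask return a logical array (`> 0`).
#' @return numeric (or logical) array with an `affine` attribute.
#' @export
read_volume <- function(path, as_mask = FALSE) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  out <- array(as.numeric(img), dim = dim(img))
  if (as_mask) out <- out > 0
  attr(out, "affine") <- aff
  out
}

#' Read and validate a subject table
#'
#' Required columns: `subject_id`, `mutation_carrier`, `eyo`, `sex`,
#' `education`; `cdr_positive` is optional (defaults to FALSE). Unknown
#' columns are preserved. Duplicate ids and unparseable EYO values are
#' reported with the offending id/row.
#'
#' @param path CSV file with a header.
#' @return data frame of typed subject records.
#' @export
read_subject_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "mutation_carrier", "eyo", "sex", "education")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stopf("subject table %s lacks required column(s): %s", path,
          paste(miss, collapse = ", "))
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup))
    stopf("duplicate subject id(s): %s", paste(unique(dup), collapse = ", "))
  eyo <- suppressWarnings(as.numeric(df$eyo))
  bad <- which(!is.finite(eyo))
  if (length(bad))
    stopf("unparseable EYO value '%s' in row %d", df$eyo[bad[1]], bad[1])
  df$eyo <- eyo
  df$mutation_carrier <- as.logical(df$mutation_carrier)
  if (anyNA(df$mutation_carrier)) stopf("unparseable mutation_carrier values")
  df$sex <- as.integer(df$sex)
  df$education <- as.numeric(df$education)
  if (any(df$education < 0, na.rm = TRUE)) stopf("negative education years")
  if (!"cdr_positive" %in% names(df)) df$cdr_positive <- FALSE
  df$cdr_positive <- as.logical(df$cdr_positive)
  df
}

#' Write a cohort to disk in standard formats
#'
#' One MD NIfTI per subject, the skeleton mask, atlas labels, per-subject WMH
#' masks, subject and biomarker CSVs, the generating config as YAML and the
#' planted truth as JSON.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "md"), showWarnings = FALSE)
  dir.create(file.path(dir, "wmh"), showWarnings = FALSE)
  aff <- cohort$affine
  write_volume(cohort$mask, file.path(dir, "skeleton_mask.nii.gz"), aff,
               datatype = "uint8")
  write_volume(cohort$atlas$labels, file.path(dir, "atlas_labels.nii.gz"),
               aff, datatype = "int16")
  for (i in seq_len(nrow(cohort$subjects))) {
    id <- cohort$subjects$subject_id[i]
    write_volume(vec_to_vol(cohort$md[i, ], cohort$mask),
                 file.path(dir, "md", paste0(id, "_md.nii.gz")), aff)
    write_volume(vec_to_vol(as.numeric(cohort$wmh[i, ]), cohort$mask),
                 file.path(dir, "wmh", paste0(id, "_wmh.nii.gz")), aff,
                 datatype = "uint8")
  }
  write.csv(cohort$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  write.csv(cohort$biomarkers, file.path(dir, "biomarkers.csv"),
            row.names = FALSE)
  write.csv(cohort$atlas$tracts, file.path(dir, "atlas_tracts.csv"),
            row.names = FALSE)
  cfg <- cohort$config
  cfg_plain <- unclass(cfg)
  cfg_plain$covariate_effects <- as.list(cfg$covariate_effects)
  yaml::write_yaml(cfg_plain, file.path(dir, "cohort_config.yaml"))
  truth <- cohort$truth
  truth$baseline <- NULL   # large arrays stay out of the JSON truth file
  truth$noiseless_tract_md <- NULL
  truth$wmh_probability <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a directory of skeletonized MD volumes into a matrix
#'
#' @param dir directory of per-subject NIfTI files (`<id>_md.nii.gz`).
#' @param mask logical skeleton mask.
#' @return subjects x voxels matrix with subject ids as row names.
#' @export
read_md_matrix <- function(dir, mask) {
  files <- sort(list.files(dir, pattern = "\\.nii(\\.gz)?$",
                           full.names = TRUE))
  if (!length(files)) stopf("no NIfTI volumes in %s", dir)
  ids <- sub("_(md|wmh)\\.nii(\\.gz)?$", "", basename(files))
  md <- t(vapply(files, function(f) {
    vol <- read_volume(f)
    if (!all(dim(vol) == dim(mask))) stopf("%s is not on the mask grid", f)
    vol[mask]
  }, numeric(sum(mask))))
  rownames(md) <- ids
  md
}
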