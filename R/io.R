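#' Read a NIfTI file as an intensity or label image
#'
#' Voxel dimensions are taken from the NIfTI header zooms. A file read as a
#' label image must be integer-valued.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param kind `"intensity"` or `"label"`.
#' @return An [intensity_image] or [label_image].
#' @export
read_image <- function(path, kind = c("intensity", "label")) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  vals <- array(as.vector(img), dim = dim(img))  # drop RNifti attributes
  vs <- RNifti::pixdim(img)[seq_len(3)]
  if (kind == "intensity") return(intensity_image(vals, vs))
  if (any(vals != round(vals)))
    stop("file declared as a label image contains non-integer values: ",
         path, call. = FALSE)
  label_image(vals, vs)
}

#' Write an intensity or label image to NIfTI
#'
#' Label images are written with an integer datatype; voxel dimensions go
#' into the header zooms.
#'
#' @param image an [intensity_image] or [label_image].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (inherits(image, "label_image")) {
    arr <- image$labels
    datatype <- "int16"
  } else if (inherits(image, "intensity_image")) {
    arr <- image$values
    datatype <- "double"
  } else stop("image must be an intensity_image or label_image", call. = FALSE)
  hdr <- list(pixdim = c(1, image$voxel_size, 1, 1, 1, 1))
  nif <- RNifti::asNifti(arr, hdr, datatype = datatype)
  RNifti::writeNifti(nif, path, datatype = datatype)
  invisible(path)
}

#' Read a cohort CSV
#'
#' Validates the schema used across the package: required columns present,
#' volumes positive, any weight columns strictly positive and finite,
#' subject ids unique. Duplicate ids are legal only inside resampled
#' experiment internals, never in input files.
#'
#' @param path CSV path (UTF-8, header row).
#' @param require character vector of required columns.
#' @return data.frame.
#' @export
read_cohort <- function(path,
                        require = c("subject_id", "volume_mm3", "group",
                                    "age", "icv")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(require, names(d))
  if (length(miss))
    stop("cohort file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if ("subject_id" %in% names(d) && anyDuplicated(d$subject_id))
    stop("duplicate subject_id in cohort file", call. = FALSE)
  if ("volume_mm3" %in% names(d) && any(d$volume_mm3 <= 0))
    stop("volumes must be positive", call. = FALSE)
  for (col in intersect(c("precision_weight", "cv_weight"), names(d))) {
    if (any(!is.finite(d[[col]])) || any(d[[col]] <= 0))
      stop("column '", col, "' must be positive and finite", call. = FALSE)
  }
  d
}

#' Write a result record as JSON with provenance
#'
#' Serialises a test or experiment result together with the seed and
#' package version, so every output file is traceable to the run that
#' produced it.
#'
#' @param result a `permutation_result`, `experiment_result`, or plain
#'   list.
#' @param path output JSON path.
#' @param extra named list merged into the record (e.g. the run config).
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, extra = list()) {
  rec <- if (inherits(result, "permutation_result")) {
    list(method = result$method, t_observed = result$t_observed,
         p_value = result$p_value, n_perm = result$n_perm,
         seed = result$seed)
  } else if (inherits(result, "experiment_result")) {
    list(rates = result$rates, seed = result$config$seed,
         alpha = result$config$alpha, n_perm = result$config$n_perm)
  } else as.list(result)
  rec$package_version <- as.character(utils::packageVersion("atlasboot"))
  rec <- c(rec, extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be YAML or JSON: ", path, call. = FALSE)
}
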