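#' Intensity image
#'
#' A 3D voxel grid of real-valued intensities together with the physical
#' voxel dimensions in millimetres. This is the in-memory representation of
#' a target scan or of an atlas's grey-level channel.
#'
#' @param values numeric 3D array of intensities.
#' @param voxel_size numeric length-3 vector of positive voxel dimensions (mm).
#' @return An object of class `intensity_image` with elements `values` and
#'   `voxel_size`.
#' @examples
#' img <- intensity_image(array(rnorm(8), c(2, 2, 2)), c(1, 1, 1))
#' dim(img$values)
#' @export
intensity_image <- function(values, voxel_size = c(1, 1, 1)) {
  values <- as_grid3d(values, "values")
  voxel_size <- check_voxel_size(voxel_size)
  structure(list(values = values, voxel_size = voxel_size),
            class = "intensity_image")
}

#' Label image
#'
#' A 3D voxel grid of non-negative integer label ids (0 is background) with
#' physical voxel dimensions in millimetres.
#'
#' @param labels integer-valued 3D array of label ids, all >= 0.
#' @param voxel_size numeric length-3 vector of positive voxel dimensions (mm).
#' @return An object of class `label_image` with elements `labels` and
#'   `voxel_size`.
#' @examples
#' seg <- label_image(array(0L, c(3, 3, 3)), c(1, 1, 2))
#' @export
label_image <- function(labels, voxel_size = c(1, 1, 1)) {
  labels <- as_grid3d(labels, "labels")
  if (any(labels != round(labels)))
    stop("label image must be integer-valued", call. = FALSE)
  if (any(labels < 0))
    stop("label ids must be >= 0", call. = FALSE)
  storage.mode(labels) <- "integer"
  voxel_size <- check_voxel_size(voxel_size)
  structure(list(labels = labels, voxel_size = voxel_size),
            class = "label_image")
}

#' Atlas: a paired intensity and label image
#'
#' An atlas is an expert-labelled image: a grey-level channel plus the label
#' map on the same grid, assumed already registered to the target space.
#'
#' @param id character identifier.
#' @param intensity an [intensity_image].
#' @param labels a [label_image] on the identical grid with identical
#'   voxel size.
#' @return An object of class `atlas`.
#' @export
atlas <- function(id, intensity, labels) {
  stopifnot(inherits(intensity, "intensity_image"),
            inherits(labels, "label_image"))
  if (!identical(dim(intensity$values), dim(labels$labels)))
    stop("atlas intensity and labels must share the same grid shape",
         call. = FALSE)
  if (!isTRUE(all.equal(intensity$voxel_size, labels$voxel_size)))
    stop("atlas intensity and labels must share the same voxel size",
         call. = FALSE)
  structure(list(id = as.character(id), intensity = intensity,
                 labels = labels),
            class = "atlas")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat("<intensity_image> ", paste(dim(x$values), collapse = " x "),
      " voxels, voxel size ", paste(signif(x$voxel_size, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.label_image <- function(x, ...) {
  ids <- sort(unique(as.integer(x$labels)))
  cat("<label_image> ", paste(dim(x$labels), collapse = " x "),
      " voxels, labels {", paste(utils::head(ids, 8), collapse = ", "),
      if (length(ids) > 8) ", ..." else "", "}\n", sep = "")
  invisible(x)
}

#' @export
print.atlas <- function(x, ...) {
  cat("<atlas> id=", x$id, ", ",
      paste(dim(x$labels$labels), collapse = " x "), " voxels\n", sep = "")
  invisible(x)
}

as_grid3d <- function(x, what) {
  x <- as.array(x)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L)
    stop(what, " must be a 3D array", call. = FALSE)
  if (anyNA(x)) stop(what, " contains NA", call. = FALSE)
  x
}

check_voxel_size <- function(voxel_size) {
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be three positive lengths (mm)", call. = FALSE)
  voxel_size
}

# shared-grid contract for a list of atlases (optionally against a target)
check_atlas_grid <- function(atlases, target = NULL) {
  if (length(atlases) == 0L) stop("need at least one atlas", call. = FALSE)
  if (!all(vapply(atlases, inherits, logical(1), "atlas")))
    stop("all elements must be atlas objects", call. = FALSE)
  ref_dim <- dim(atlases[[1L]]$labels$labels)
  ref_vs <- atlases[[1L]]$labels$voxel_size
  for (a in atlases) {
    if (!identical(dim(a$labels$labels), ref_dim) ||
        !isTRUE(all.equal(a$labels$voxel_size, ref_vs)))
      stop("atlases must share grid shape and voxel size", call. = FALSE)
  }
  if (!is.null(target)) {
    if (!identical(dim(target$values), ref_dim) ||
        !isTRUE(all.equal(target$voxel_size, ref_vs)))
      stop("target grid does not match the atlases", call. = FALSE)
  }
  invisible(list(dim = ref_dim, voxel_size = ref_vs))
}
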