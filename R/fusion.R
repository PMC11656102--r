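#' Fusion engine specification
#'
#' A fusion engine is a deterministic rule that combines the label maps of a
#' set of registered atlases into one consensus segmentation of the target.
#' Two desk-scale engines are provided: `"majority"` (voxel-wise majority
#' vote) and `"local_weighted"` (patch-similarity weighted vote). Both are
#' pure functions of their inputs, so re-fusing the same atlas collection
#' always yields the identical label image — a property the bootstrap layer
#' relies on.
#'
#' @param name `"majority"` or `"local_weighted"`.
#' @param patch_radius patch radius in voxels for the locally weighted
#'   engine (default 1, i.e. a 3x3x3 patch).
#' @param bandwidth positive kernel bandwidth for the locally weighted
#'   engine, on the scale of squared intensity; `NULL` (default) adapts it
#'   to the sample variance of the target intensities.
#' @return An object of class `fusion_engine`.
#' @seealso [fuse()], [majority_vote()], [local_weighted_vote()]
#' @export
fusion_engine <- function(name = c("majority", "local_weighted"),
                          patch_radius = 1L, bandwidth = NULL) {
  name <- match.arg(name)
  patch_radius <- as.integer(patch_radius)
  if (patch_radius < 0L) stop("patch_radius must be >= 0", call. = FALSE)
  if (!is.null(bandwidth) && (!is.finite(bandwidth) || bandwidth <= 0))
    stop("bandwidth must be positive", call. = FALSE)
  structure(list(name = name, patch_radius = patch_radius,
                 bandwidth = bandwidth),
            class = "fusion_engine")
}

#' Fuse a collection of atlases with a fusion engine
#'
#' @param engine a [fusion_engine].
#' @param target the target [intensity_image] (required by the locally
#'   weighted engine; ignored by majority vote).
#' @param atlases list of [atlas] objects on the target grid.
#' @return The fused [label_image].
#' @export
fuse <- function(engine, target, atlases) {
  stopifnot(inherits(engine, "fusion_engine"))
  switch(engine$name,
    majority = majority_vote(atlases),
    local_weighted = local_weighted_vote(target, atlases,
                                         patch_radius = engine$patch_radius,
                                         bandwidth = engine$bandwidth))
}

#' Voxel-wise majority vote label fusion
#'
#' Labels each voxel with the label endorsed by the largest number of
#' atlases. Ties are broken deterministically in favour of the smallest
#' label id.
#'
#' @param atlases non-empty list of [atlas] objects sharing grid shape and
#'   voxel size.
#' @return The fused [label_image].
#' @examples
#' seg <- label_image(array(c(0L, 1L), c(2, 1, 1)))
#' img <- intensity_image(array(0, c(2, 1, 1)))
#' a <- atlas("a1", img, seg)
#' majority_vote(list(a, a, a))$labels
#' @export
majority_vote <- function(atlases) {
  grid <- check_atlas_grid(atlases)
  label_mats <- lapply(atlases, function(a) a$labels$labels)
  ids <- sort(unique(unlist(lapply(label_mats, function(l) unique(as.vector(l))))))
  n_vox <- prod(grid$dim)
  best_count <- integer(n_vox)
  best_label <- rep.int(ids[1L], n_vox)
  for (id in ids) {  # increasing id order makes strict > the smallest-id tie rule
    count <- integer(n_vox)
    for (l in label_mats) count <- count + (as.vector(l) == id)
    win <- count > best_count
    best_label[win] <- id
    best_count[win] <- count[win]
  }
  label_image(array(best_label, grid$dim), grid$voxel_size)
}

#' Locally weighted vote label fusion
#'
#' At each voxel every atlas receives the weight
#' `exp(-SSD / (bandwidth * patch_size))`, where SSD is the sum of squared
#' intensity differences between target and atlas over the cubic patch of
#' the given radius centred at the voxel (patches are clipped at the image
#' border and SSD is normalised by the clipped patch size). The output label
#' maximises the summed weight of the endorsing atlases; ties go to the
#' smallest label id. With identical target and atlas intensities all
#' weights are equal and the result coincides with [majority_vote()].
#'
#' @inheritParams fusion_engine
#' @param target target [intensity_image].
#' @param atlases non-empty list of [atlas] objects on the target grid.
#' @return The fused [label_image].
#' @export
local_weighted_vote <- function(target, atlases, patch_radius = 1L,
                                bandwidth = NULL) {
  stopifnot(inherits(target, "intensity_image"))
  grid <- check_atlas_grid(atlases, target)
  patch_radius <- as.integer(patch_radius)
  if (patch_radius < 0L) stop("patch_radius must be >= 0", call. = FALSE)
  if (is.null(bandwidth)) {
    bandwidth <- stats::var(as.vector(target$values))
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1
  }
  if (bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)

  n_vox <- prod(grid$dim)
  patch_n <- box_sum_3d(array(1, grid$dim), patch_radius)  # clipped patch sizes
  ids <- sort(unique(unlist(lapply(atlases,
                                   function(a) unique(as.vector(a$labels$labels))))))
  weights <- lapply(atlases, function(a) {
    ssd <- box_sum_3d((target$values - a$intensity$values)^2, patch_radius)
    exp(-as.vector(ssd) / (bandwidth * as.vector(patch_n)))
  })
  best_score <- rep.int(-Inf, n_vox)
  best_label <- rep.int(ids[1L], n_vox)
  for (id in ids) {
    score <- numeric(n_vox)
    for (k in seq_along(atlases)) {
      score <- score + weights[[k]] * (as.vector(atlases[[k]]$labels$labels) == id)
    }
    win <- score > best_score  # increasing id order: strict > keeps the smallest id on ties
    best_label[win] <- id
    best_score[win] <- score[win]
  }
  label_image(array(best_label, grid$dim), grid$voxel_size)
}

#' ROI volume of a label image
#'
#' The physical volume of a region of interest: the number of voxels
#' carrying the ROI label times the voxel volume. A label absent from the
#' image yields 0.
#'
#' @param labels a [label_image].
#' @param roi_label non-negative integer label id (default 1).
#' @return Volume in cubic millimetres.
#' @examples
#' seg <- label_image(array(c(1L, 1L, 1L, 0L), c(4, 1, 1)), c(1, 1, 2))
#' roi_volume(seg, 1)  # 3 voxels x 2 mm^3
#' @export
roi_volume <- function(labels, roi_label = 1L) {
  stopifnot(inherits(labels, "label_image"))
  roi_label <- as.integer(roi_label)
  if (roi_label < 0L) stop("roi_label must be >= 0", call. = FALSE)
  sum(labels$labels == roi_label) * prod(labels$voxel_size)
}

# Sum of `arr` over the cubic window of radius r centred at each voxel,
# clipped at the borders. Separable running sums along each axis via
# cumulative sums, so cost is linear in the grid size.
box_sum_3d <- function(arr, r) {
  if (r == 0L) return(arr)
  for (axis in 1:3) arr <- run_sum_axis(arr, r, axis)
  arr
}

run_sum_axis <- function(arr, r, axis) {
  d <- dim(arr)
  n <- d[axis]
  if (n == 1L) return(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(arr, perm)
  dim(m) <- c(n, prod(d[-axis]))
  cs <- apply(m, 2L, cumsum)
  dim(cs) <- dim(m)
  hi <- pmin(seq_len(n) + r, n)
  lo <- seq_len(n) - r
  out <- cs[hi, , drop = FALSE]
  pos <- lo >= 2L
  if (any(pos))
    out[pos, ] <- out[pos, , drop = FALSE] - cs[lo[pos] - 1L, , drop = FALSE]
  dim(out) <- d[perm]
  aperm(out, order(perm))
}
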