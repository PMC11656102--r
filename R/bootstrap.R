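#' Bootstrap configuration
#'
#' Settings for resampling atlas collections. The defaults follow the usual
#' practice of drawing same-size collections with replacement and using 300
#' replicates, the point at which per-subject running variances typically
#' stabilise (see [running_variance_curve()]).
#'
#' @param n_replicates number of bootstrap replicates B (>= 2, default 300).
#' @param collection_size atlases per resampled collection; `NULL` (default)
#'   uses the size of the atlas pool supplied at run time.
#' @param seed integer seed making the whole resampling reproducible.
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_replicates = 300L, collection_size = NULL,
                             seed = 1L) {
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 2L) stop("n_replicates must be >= 2", call. = FALSE)
  if (!is.null(collection_size)) {
    collection_size <- as.integer(collection_size)
    if (collection_size < 1L) stop("collection_size must be >= 1", call. = FALSE)
  }
  structure(list(n_replicates = n_replicates,
                 collection_size = collection_size,
                 seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' Resample an atlas collection with replacement
#'
#' Draws `collection_size` atlases uniformly with replacement from the pool.
#' Duplicates are permitted (and expected); degenerate collections in which
#' one atlas fills every slot are legal and kept, since excluding them would
#' bias the downstream variance. Draws consume the current R random stream,
#' so the caller controls reproducibility via `set.seed()`.
#'
#' @param atlases non-empty list of [atlas] objects.
#' @param collection_size number of draws; default `length(atlases)`.
#' @return List of `collection_size` atlases.
#' @export
resample_collection <- function(atlases, collection_size = length(atlases)) {
  if (length(atlases) == 0L) stop("need at least one atlas", call. = FALSE)
  idx <- sample.int(length(atlases), size = collection_size, replace = TRUE)
  atlases[idx]
}

#' Bootstrap replicate ROI volumes for one target image
#'
#' The core resampling loop: for each of B replicates, draw an atlas
#' collection with replacement, fuse it with the given engine, and record
#' the ROI volume of the fused segmentation. The spread of the replicate
#' volumes estimates the conditional variance of the subject's volume
#' estimate given its target image — the variability attributable to the
#' atlas set, which downstream becomes the subject's precision weight.
#'
#' @param target target [intensity_image].
#' @param atlases non-empty list of [atlas] objects registered to the target.
#' @param engine a [fusion_engine].
#' @param roi_label ROI label id (default 1).
#' @param config a [bootstrap_config].
#' @param subject_id identifier stored with the samples.
#' @return An object of class `volume_samples`: list with `subject_id`,
#'   `volumes` (length B, mm^3, in generation order) and `config`.
#' @export
bootstrap_volumes <- function(target, atlases, engine = fusion_engine(),
                              roi_label = 1L, config = bootstrap_config(),
                              subject_id = "subject") {
  check_atlas_grid(atlases, target)
  size <- if (is.null(config$collection_size)) length(atlases)
          else config$collection_size
  vols <- local_seed(config$seed, {
    vapply(seq_len(config$n_replicates), function(b) {
      coll <- resample_collection(atlases, size)
      roi_volume(fuse(engine, target, coll), roi_label)
    }, numeric(1))
  })
  volume_samples(subject_id, vols, config)
}

#' Construct a volume_samples object
#'
#' Container for the ordered bootstrap-replicate ROI volumes of one subject.
#' Replicate order is the generation order; the running-variance diagnostic
#' depends on it.
#'
#' @param subject_id identifier.
#' @param volumes numeric vector of replicate volumes (mm^3), all >= 0.
#' @param config the [bootstrap_config] that produced them (its
#'   `n_replicates` must equal `length(volumes)`).
#' @return An object of class `volume_samples`.
#' @export
volume_samples <- function(subject_id, volumes, config = NULL) {
  volumes <- as.numeric(volumes)
  if (any(!is.finite(volumes)) || any(volumes < 0))
    stop("replicate volumes must be finite and >= 0", call. = FALSE)
  if (is.null(config)) config <- bootstrap_config(n_replicates = length(volumes))
  if (config$n_replicates != length(volumes))
    stop("length(volumes) must equal config$n_replicates", call. = FALSE)
  structure(list(subject_id = as.character(subject_id), volumes = volumes,
                 config = config),
            class = "volume_samples")
}

#' @export
print.volume_samples <- function(x, ...) {
  cat("<volume_samples> subject ", x$subject_id, ": B=",
      length(x$volumes), ", mean ", signif(mean(x$volumes), 6), " mm^3, var ",
      signif(bootstrap_variance(x), 6), " mm^6\n", sep = "")
  invisible(x)
}

#' Bootstrap variance of the replicate volumes
#'
#' Unbiased sample variance (divisor B - 1) across the bootstrap-replicate
#' ROI volumes; the estimate of the conditional variance of the subject's
#' volume estimate.
#'
#' @param samples a [volume_samples] object (or bare numeric vector of
#'   replicate volumes, length >= 2).
#' @return Variance in mm^6.
#' @export
bootstrap_variance <- function(samples) {
  v <- if (inherits(samples, "volume_samples")) samples$volumes else as.numeric(samples)
  if (length(v) < 2L) stop("need at least 2 replicates", call. = FALSE)
  stats::var(v)
}

#' Precision weight: inverse bootstrap variance
#'
#' Inverts the bootstrap variance into the weight the subject's volume
#' estimate receives in weighted least squares — under uncorrelated
#' heteroskedastic errors, inverse-variance weighting is the
#' minimum-variance (Aitken-optimal) choice. A small floor guards against
#' infinite weights when the replicates are degenerate (all identical),
#' which never happens with real fusion variability but can with synthetic
#' unanimity.
#'
#' @param boot_variance non-negative variance in mm^6.
#' @param variance_floor positive floor (mm^6, default 1e-9).
#' @return Weight `1 / max(boot_variance, variance_floor)` in 1/mm^6.
#' @export
precision_weight <- function(boot_variance, variance_floor = 1e-9) {
  if (any(boot_variance < 0)) stop("variance must be >= 0", call. = FALSE)
  if (variance_floor <= 0) stop("variance_floor must be > 0", call. = FALSE)
  1 / pmax(boot_variance, variance_floor)
}

#' Coefficient of variation and CV weight
#'
#' The CV of the replicate volumes (sample standard deviation over mean) and
#' its reciprocal, a comparison weighting scheme that quantifies relative
#' rather than absolute variability.
#'
#' @param samples a [volume_samples] object or numeric vector with positive
#'   mean.
#' @param cv_floor positive floor on the CV before inversion (default 1e-6).
#' @return List with elements `cv` and `weight`.
#' @export
cv_weight <- function(samples, cv_floor = 1e-6) {
  v <- if (inherits(samples, "volume_samples")) samples$volumes else as.numeric(samples)
  if (length(v) < 2L) stop("need at least 2 replicates", call. = FALSE)
  m <- mean(v)
  if (m <= 0) stop("mean volume must be positive for a CV", call. = FALSE)
  cv <- stats::sd(v) / m
  list(cv = cv, weight = 1 / max(cv, cv_floor))
}

#' Running-variance convergence diagnostic
#'
#' Tracks the sample variance of the first n replicate volumes as n grows,
#' in generation order. Plotting this curve per subject shows when the
#' bootstrap variance has stabilised and hence how many replicates are
#' needed; with the defaults used here, curves typically flatten by B = 300.
#'
#' @param samples a [volume_samples] object.
#' @param grid increasing integer vector of replicate counts, each >= 2 and
#'   <= B.
#' @return data.frame with columns `n` and `variance` (mm^6).
#' @export
running_variance_curve <- function(samples,
                                   grid = unique(round(seq(10, length(samples$volumes),
                                                           length.out = 25)))) {
  stopifnot(inherits(samples, "volume_samples"))
  grid <- as.integer(grid)
  if (any(grid < 2L) || any(grid > length(samples$volumes)))
    stop("grid values must lie in [2, n_replicates]", call. = FALSE)
  data.frame(n = grid,
             variance = vapply(grid,
                               function(n) stats::var(samples$volumes[seq_len(n)]),
                               numeric(1)))
}

#' Weight record for one subject
#'
#' Bundles a subject's bootstrap variance with the two weighting schemes
#' derived from it. Degenerate (floor-capped) values are flagged.
#'
#' @param samples a [volume_samples] object.
#' @param variance_floor floor used by [precision_weight()].
#' @param cv_floor floor used by [cv_weight()].
#' @return One-row data.frame with columns `subject_id`,
#'   `boot_variance_mm6`, `precision_weight`, `cv`, `cv_weight`,
#'   `n_replicates`, `flags`.
#' @export
weight_record <- function(samples, variance_floor = 1e-9, cv_floor = 1e-6) {
  stopifnot(inherits(samples, "volume_samples"))
  bv <- bootstrap_variance(samples)
  flags <- character(0)
  if (bv <= variance_floor) flags <- c(flags, "variance_floored")
  cw <- if (mean(samples$volumes) > 0) cv_weight(samples, cv_floor)
        else list(cv = NA_real_, weight = NA_real_)
  if (!is.na(cw$cv) && cw$cv <= cv_floor) flags <- c(flags, "cv_floored")
  data.frame(subject_id = samples$subject_id,
             boot_variance_mm6 = bv,
             precision_weight = precision_weight(bv, variance_floor),
             cv = cw$cv,
             cv_weight = cw$weight,
             n_replicates = length(samples$volumes),
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Bootstrap weights for a set of target images
#'
#' Runs [bootstrap_volumes()] for each target against the shared atlas pool
#' and assembles the per-subject weight table. Each subject gets its own
#' random stream derived from the global seed and its position, so subjects
#' can be processed in any order with identical results.
#'
#' @param targets named list of [intensity_image] targets (names are
#'   subject ids).
#' @param atlases shared atlas pool.
#' @param engine a [fusion_engine].
#' @param roi_label ROI label id.
#' @param config a [bootstrap_config]; its `seed` is the global seed.
#' @return data.frame of weight records, one row per subject.
#' @export
bootstrap_weights <- function(targets, atlases, engine = fusion_engine(),
                              roi_label = 1L, config = bootstrap_config()) {
  if (is.null(names(targets)))
    names(targets) <- sprintf("subject%03d", seq_along(targets))
  recs <- lapply(seq_along(targets), function(i) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, names(targets)[i])
    s <- bootstrap_volumes(targets[[i]], atlases, engine, roi_label, cfg_i,
                           subject_id = names(targets)[i])
    weight_record(s)
  })
  do.call(rbind, recs)
}

#' Weights from precomputed replicate volumes
#'
#' The statistical route: replicate ROI volumes produced by any external
#' fusion tool, supplied as a long table, are turned into the same weight
#' records as the imaging route. This keeps the inference layer agnostic to
#' the fusion method that generated the volumes.
#'
#' @param replicates data.frame with columns `subject_id`,
#'   `replicate_index`, `volume_mm3`.
#' @param variance_floor,cv_floor floors passed to [weight_record()].
#' @return data.frame of weight records, one row per subject.
#' @export
weights_from_replicates <- function(replicates, variance_floor = 1e-9,
                                    cv_floor = 1e-6) {
  need <- c("subject_id", "replicate_index", "volume_mm3")
  miss <- setdiff(need, names(replicates))
  if (length(miss))
    stop("replicate table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  recs <- lapply(split(replicates, replicates$subject_id), function(d) {
    d <- d[order(d$replicate_index), ]
    weight_record(volume_samples(d$subject_id[1L], d$volume_mm3),
                  variance_floor, cv_floor)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
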