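#' Phantom scene configuration
#'
#' Parameters of a synthetic imaging scene: an ellipsoidal region of
#' interest on a background, plus a set of atlases derived from the true
#' labels by random rigid translation (the stand-in for registration error)
#' and boundary label noise. The translation magnitude `shift_sd` is the
#' dial that controls how much re-fused segmentations disagree, and hence
#' the bootstrap variance of the fused ROI volume.
#'
#' @param grid_shape integer voxel triple (default `c(24, 24, 24)`).
#' @param voxel_size mm triple (default 1 mm isotropic).
#' @param roi_semi_axes ellipsoid semi-axes in mm (default `c(6, 5, 4)`).
#' @param n_atlases number of atlases (default 35).
#' @param shift_sd per-axis standard deviation of the atlas translation, mm
#'   (default 1).
#' @param label_flip_rate probability that a boundary voxel's label is
#'   flipped in an atlas (default 0.05).
#' @param intensity_noise_sd additive Gaussian intensity noise (default 0.05).
#' @param seed integer seed.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(grid_shape = c(24L, 24L, 24L),
                         voxel_size = c(1, 1, 1),
                         roi_semi_axes = c(6, 5, 4),
                         n_atlases = 35L,
                         shift_sd = 1,
                         label_flip_rate = 0.05,
                         intensity_noise_sd = 0.05,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1),
            length(roi_semi_axes) == 3L, all(roi_semi_axes > 0),
            n_atlases >= 1L, shift_sd >= 0,
            label_flip_rate >= 0, label_flip_rate <= 1,
            intensity_noise_sd >= 0)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = check_voxel_size(voxel_size),
                 roi_semi_axes = as.numeric(roi_semi_axes),
                 n_atlases = as.integer(n_atlases),
                 shift_sd = shift_sd,
                 label_flip_rate = label_flip_rate,
                 intensity_noise_sd = intensity_noise_sd,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Generate a phantom scene: target, truth, and perturbed atlases
#'
#' Builds a voxelised ellipsoid (label 1 on background 0) as ground truth,
#' a target intensity image as the smoothed truth plus Gaussian noise, and
#' `n_atlases` atlases, each the truth translated by an independent
#' per-axis Normal(0, `shift_sd`) displacement (rounded to whole voxels —
#' nearest-voxel resampling keeps labels integer), with boundary voxels
#' flipped independently at `label_flip_rate`, and an intensity channel
#' built from the atlas's own labels by the same smoothing-plus-noise
#' recipe. Everything is a pure function of the config, seed included.
#'
#' @param config a [scene_config].
#' @return List with elements `target` ([intensity_image]), `truth`
#'   ([label_image]) and `atlases` (list of [atlas]).
#' @examples
#' sc <- make_phantom_scene(scene_config(grid_shape = c(12, 12, 12),
#'                                       roi_semi_axes = c(3, 3, 3),
#'                                       n_atlases = 5))
#' roi_volume(sc$truth)
#' @export
make_phantom_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  shape <- config$grid_shape
  vs <- config$voxel_size
  if (any(2 * config$roi_semi_axes >= shape * vs))
    stop("ROI does not fit inside the grid", call. = FALSE)
  truth_arr <- ellipsoid_mask(shape, vs, config$roi_semi_axes)
  truth <- label_image(truth_arr, vs)
  local_seed(config$seed, {
    target <- intensity_image(
      smooth3(truth_arr) + stats::rnorm(prod(shape), 0, config$intensity_noise_sd),
      vs)
    atlases <- lapply(seq_len(config$n_atlases), function(k) {
      shift_vox <- round(stats::rnorm(3, 0, config$shift_sd) / vs)
      lab <- shift_array(truth_arr, shift_vox)
      if (config$label_flip_rate > 0) {
        bnd <- which(boundary_mask(lab))
        flip <- bnd[stats::runif(length(bnd)) < config$label_flip_rate]
        lab[flip] <- 1L - lab[flip]
      }
      intens <- intensity_image(
        smooth3(lab) + stats::rnorm(prod(shape), 0, config$intensity_noise_sd),
        vs)
      atlas(sprintf("atlas%02d", k), intens, label_image(lab, vs))
    })
    list(target = target, truth = truth, atlases = atlases)
  })
}

# binary ellipsoid centred in the grid, in physical coordinates
ellipsoid_mask <- function(shape, voxel_size, semi_axes) {
  ctr <- (shape + 1) / 2
  x <- (seq_len(shape[1]) - ctr[1]) * voxel_size[1] / semi_axes[1]
  y <- (seq_len(shape[2]) - ctr[2]) * voxel_size[2] / semi_axes[2]
  z <- (seq_len(shape[3]) - ctr[3]) * voxel_size[3] / semi_axes[3]
  d2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
  array(as.integer(d2 <= 1), shape)
}

# integer-shift with background (0) fill; nearest-voxel resampling of a
# rigid translation
shift_array <- function(arr, shift) {
  d <- dim(arr)
  out <- array(0L, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    s <- as.integer(shift[ax])
    if (abs(s) >= d[ax]) return(out)
    if (s >= 0) { dst[[ax]] <- (1 + s):d[ax]; src[[ax]] <- 1:(d[ax] - s) }
    else        { dst[[ax]] <- 1:(d[ax] + s); src[[ax]] <- (1 - s):d[ax] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# voxels with a 6-neighbour of a different label
boundary_mask <- function(lab) {
  d <- dim(lab)
  bnd <- array(FALSE, d)
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      shift <- integer(3); shift[ax] <- s
      nb <- shift_array(lab + 1L, shift)  # +1 so background fill differs from 0-labels
      inside <- nb != 0L
      bnd <- bnd | (inside & (nb - 1L != lab))
    }
  }
  bnd
}

# 3x3x3 box-mean smoothing (border-clipped)
smooth3 <- function(arr) {
  box_sum_3d(arr + 0, 1L) / box_sum_3d(array(1, dim(arr)), 1L)
}

#' Cohort configuration
#'
#' Parameters of the synthetic cohort generator, which draws subject tables
#' from the heteroskedastic linear model the inference layer assumes:
#' `volume_i = b0 + b_age (age_i - age_center) + b_icv icv_i + delta 1[group=1]
#' + eps_i`, with `eps_i ~ Normal(0, sigma_i^2)` independent across
#' subjects and subject-specific `sigma_i = base_sd * LogNormal(0,
#' lognormal_sd)`. An optional outlier model marks a fraction of each group
#' and gives those subjects an additive volume shift plus a variance
#' inflation, emulating the high outlying, low-precision volume estimates
#' that disease-group images tend to produce when segmented with
#' healthy-control atlases.
#'
#' Default calibration: mean volume near 7.4 cm^3 (7400 mm^3, the centre of
#' typical atlas hippocampal volumes), ages uniform on 55-95 years, ICV
#' around 1.4e6 mm^3, base volume noise 100 mm^3 with log-normal sd 0.5.
#'
#' @param n_per_group subjects per group (default 80).
#' @param beta length-3 coefficient vector: intercept (mm^3), age slope
#'   (mm^3 per year, applied to age - `age_center`), ICV slope
#'   (dimensionless).
#' @param age_center centring constant for the age effect (years).
#' @param group_effect additive volume shift for group 1 (mm^3; negative
#'   for atrophy).
#' @param base_sd baseline error sd (mm^3).
#' @param lognormal_sd sd of the log-normal per-subject sd multiplier
#'   (0 gives a homoskedastic cohort).
#' @param outlier_rate per-group probability of the outlier flag, length 2
#'   `c(group0, group1)`.
#' @param outlier_shift additive volume shift for flagged subjects (mm^3,
#'   positive for high outliers).
#' @param outlier_var_factor multiplicative variance inflation for flagged
#'   subjects (applied to sigma_i^2).
#' @param age_range years, length 2.
#' @param icv_mean,icv_sd intracranial volume distribution (mm^3).
#' @param noisy_weights if `TRUE`, additionally emulate bootstrap
#'   estimation error in the weights: the estimated variance is a scaled
#'   chi-square draw of the true sigma_i^2 at `boot_df` degrees of freedom.
#' @param boot_df degrees of freedom of the noisy variance estimate
#'   (default 299, i.e. B - 1 at B = 300).
#' @param seed integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 80L,
                          beta = c(7400, 10, 0.001),
                          age_center = 75,
                          group_effect = 0,
                          base_sd = 100,
                          lognormal_sd = 0.5,
                          outlier_rate = c(0, 0),
                          outlier_shift = 0,
                          outlier_var_factor = 1,
                          age_range = c(55, 95),
                          icv_mean = 1.4e6,
                          icv_sd = 1.2e5,
                          noisy_weights = FALSE,
                          boot_df = 299L,
                          seed = 1L) {
  if (length(outlier_rate) == 1L) outlier_rate <- rep(outlier_rate, 2L)
  stopifnot(n_per_group >= 3L, length(beta) == 3L, base_sd >= 0,
            lognormal_sd >= 0, all(outlier_rate >= 0), all(outlier_rate <= 1),
            outlier_var_factor > 0, icv_sd >= 0, boot_df >= 1L,
            age_range[2] > age_range[1])
  structure(list(n_per_group = as.integer(n_per_group), beta = as.numeric(beta),
                 age_center = age_center, group_effect = group_effect,
                 base_sd = base_sd, lognormal_sd = lognormal_sd,
                 outlier_rate = as.numeric(outlier_rate),
                 outlier_shift = outlier_shift,
                 outlier_var_factor = outlier_var_factor,
                 age_range = as.numeric(age_range),
                 icv_mean = icv_mean, icv_sd = icv_sd,
                 noisy_weights = noisy_weights, boot_df = as.integer(boot_df),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic cohort table
#'
#' Draws one cohort from the model described in [cohort_config()]. The
#' returned table carries, besides the observable columns, the hidden truth
#' columns `true_sigma2` and `outlier` that tests use for parameter
#' recovery; the oracle `precision_weight` column is `1/true_sigma2` (or
#' its noisy chi-square analogue when `noisy_weights` is on), and
#' `cv`/`cv_weight` are derived as sigma_i over expected volume and its
#' reciprocal.
#'
#' @param config a [cohort_config].
#' @return data.frame with columns `subject_id`, `group`, `age`, `icv`,
#'   `volume_mm3`, `precision_weight`, `cv`, `cv_weight`, `true_sigma2`,
#'   `outlier`.
#' @examples
#' head(make_cohort(cohort_config(n_per_group = 5)))
#' @export
make_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- 2L * config$n_per_group
  group <- rep(0:1, each = config$n_per_group)
  local_seed(config$seed, {
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    icv <- stats::rnorm(n, config$icv_mean, config$icv_sd)
    sigma <- config$base_sd * stats::rlnorm(n, 0, config$lognormal_sd)
    outlier <- stats::runif(n) < config$outlier_rate[group + 1L]
    sigma2 <- sigma^2 * ifelse(outlier, config$outlier_var_factor, 1)
    mu <- config$beta[1] + config$beta[2] * (age - config$age_center) +
      config$beta[3] * icv + config$group_effect * group +
      config$outlier_shift * outlier
    volume <- mu + stats::rnorm(n, 0, sqrt(sigma2))
    est_sigma2 <- if (config$noisy_weights) {
      sigma2 * stats::rchisq(n, df = config$boot_df) / config$boot_df
    } else sigma2
    cv <- sqrt(est_sigma2) / pmax(mu, 1)
    data.frame(subject_id = sprintf("S%04d", seq_len(n)),
               group = group, age = age, icv = icv, volume_mm3 = volume,
               precision_weight = 1 / est_sigma2,
               cv = cv, cv_weight = 1 / pmax(cv, 1e-6),
               true_sigma2 = sigma2, outlier = outlier,
               stringsAsFactors = FALSE)
  })
}
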