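test_that("resample_collection draws uniformly with replacement, reproducibly", {
  a <- lapply(1:4, function(k) toy_atlas(array(k, c(1, 1, 1)), id = paste0("a", k)))

  # single-atlas pool: the collection is that atlas repeated
  one <- resample_collection(a[1], collection_size = 6)
  expect_length(one, 6)
  expect_true(all(vapply(one, function(x) x$id, character(1)) == "a1"))

  set.seed(5); c1 <- resample_collection(a, 10)
  set.seed(5); c2 <- resample_collection(a, 10)
  expect_identical(vapply(c1, `[[`, character(1), "id"),
                   vapply(c2, `[[`, character(1), "id"))

  expect_error(resample_collection(list()), "at least one atlas")

  # per-slot frequencies over many draws consistent with uniform sampling
  set.seed(99)
  ids <- unlist(lapply(1:600, function(i)
    vapply(resample_collection(a, 5), `[[`, character(1), "id")))
  expect_gt(stats::chisq.test(table(ids))$p.value, 0.01)
})

test_that("bootstrap_volumes has the right length and collapses under unanimity", {
  sc <- small_scene(seed = 2, n_atlases = 6)
  vs <- bootstrap_volumes(sc$target, sc$atlases,
                          config = bootstrap_config(n_replicates = 2, seed = 1))
  expect_length(vs$volumes, 2)

  un <- unanimous_atlases(sc$truth$labels, m = 6)
  vs0 <- bootstrap_volumes(sc$target, un,
                           config = bootstrap_config(n_replicates = 20, seed = 1))
  expect_true(all(vs0$volumes == vs0$volumes[1]))
  expect_identical(bootstrap_variance(vs0), 0)
})

test_that("replicate volumes lie in the set attainable by fusing atlas multisets", {
  # 3 atlases -> 10 distinct multisets of size 3; enumerate all fused volumes
  set.seed(21)
  atl <- lapply(1:3, function(k)
    toy_atlas(array(sample(0:1, 27, TRUE), c(3, 3, 3)), id = paste0("a", k)))
  target <- intensity_image(array(0, c(3, 3, 3)))
  combos <- list()
  for (i in 1:3) for (j in i:3) for (k in j:3)
    combos[[length(combos) + 1]] <- c(i, j, k)
  attainable <- unique(vapply(combos, function(cc)
    roi_volume(majority_vote(atl[cc])), numeric(1)))
  vs <- bootstrap_volumes(target, atl, fusion_engine("majority"),
                          config = bootstrap_config(n_replicates = 60, seed = 4))
  expect_true(all(vs$volumes %in% attainable))
})

test_that("bootstrap_variance is the unbiased sample variance", {
  expect_equal(bootstrap_variance(c(5, 5, 5, 5)), 0)
  expect_equal(bootstrap_variance(c(1, 3)), 2)
  expect_error(bootstrap_variance(3), "at least 2")

  # independent two-pass oracle on random inputs
  set.seed(31)
  for (case in 1:20) {
    v <- rlnorm(sample(5:200, 1), 8, 0.3)
    m <- sum(v) / length(v)
    two_pass <- sum((v - m)^2) / (length(v) - 1)
    expect_equal(bootstrap_variance(v), two_pass, tolerance = 1e-10)
  }
})

test_that("precision_weight inverts the variance with a floor", {
  expect_equal(precision_weight(0.25), 4)
  expect_equal(precision_weight(0, variance_floor = 1e-9), 1e9)
  expect_error(precision_weight(-1), ">= 0")
  # scaling identity: volumes scaled by c -> weight divided by c^2
  set.seed(2); v <- rnorm(50, 100, 3)
  expect_equal(precision_weight(bootstrap_variance(3 * v)),
               precision_weight(bootstrap_variance(v)) / 9)
})

test_that("cv_weight computes sd/mean and is scale invariant", {
  cw <- cv_weight(c(1, 3))
  expect_equal(cw$cv, sqrt(2) / 2)
  expect_equal(cw$weight, sqrt(2), tolerance = 1e-12)

  const <- cv_weight(rep(4, 10))
  expect_equal(const$cv, 0)
  expect_equal(const$weight, 1e6)  # 1/cv_floor

  set.seed(3); v <- rlnorm(40, 8, 0.2)
  expect_equal(cv_weight(v)$cv, cv_weight(5 * v)$cv, tolerance = 1e-12)
  expect_error(cv_weight(c(-3, 1)), "positive")
})

test_that("running variance curve is consistent with the full-sample variance", {
  vs <- volume_samples("s1", rep(7, 50))
  curve <- running_variance_curve(vs, grid = c(10, 25, 50))
  expect_true(all(curve$variance == 0))

  sc <- small_scene(seed = 6, n_atlases = 6)
  vs2 <- bootstrap_volumes(sc$target, sc$atlases,
                           config = bootstrap_config(n_replicates = 80, seed = 2))
  curve2 <- running_variance_curve(vs2, grid = c(10, 40, 80))
  expect_identical(curve2$variance[3], bootstrap_variance(vs2))
  expect_error(running_variance_curve(vs2, grid = c(10, 200)), "n_replicates")
})

test_that("weight records flag degenerate variances and floor-capped weights", {
  rec <- weight_record(volume_samples("s1", rep(100, 10)))
  expect_equal(rec$boot_variance_mm6, 0)
  expect_equal(rec$precision_weight, 1e9)
  expect_match(rec$flags, "variance_floored")

  sc <- small_scene(seed = 4, n_atlases = 6)
  vs <- bootstrap_volumes(sc$target, sc$atlases,
                          config = bootstrap_config(n_replicates = 50, seed = 3))
  rec2 <- weight_record(vs)
  expect_equal(rec2$precision_weight, 1 / rec2$boot_variance_mm6)
  expect_equal(rec2$flags, "")
})

test_that("the seed -> samples -> weights map is deterministic and order-free", {
  sc <- small_scene(seed = 10, n_atlases = 5)
  cfg <- bootstrap_config(n_replicates = 30, seed = 17)
  v1 <- bootstrap_volumes(sc$target, sc$atlases, config = cfg)
  v2 <- bootstrap_volumes(sc$target, sc$atlases, config = cfg)
  expect_identical(v1$volumes, v2$volumes)

  sc2 <- small_scene(seed = 11, n_atlases = 5)
  targets <- list(s1 = sc$target, s2 = sc2$target)
  w12 <- bootstrap_weights(targets, sc$atlases, config = cfg)
  w21 <- bootstrap_weights(rev(targets), sc$atlases, config = cfg)
  expect_equal(w12[order(w12$subject_id), ], w21[order(w21$subject_id), ],
               ignore_attr = TRUE)
})

test_that("the statistical route reproduces weights from a replicate table", {
  sc <- small_scene(seed = 12, n_atlases = 5)
  vs <- bootstrap_volumes(sc$target, sc$atlases,
                          config = bootstrap_config(n_replicates = 40, seed = 2),
                          subject_id = "s1")
  tab <- data.frame(subject_id = "s1",
                    replicate_index = seq_along(vs$volumes),
                    volume_mm3 = vs$volumes)
  # shuffled rows must not matter: replicate_index restores generation order
  tab <- tab[sample(nrow(tab)), ]
  expect_equal(weights_from_replicates(tab), weight_record(vs),
               ignore_attr = TRUE)
  expect_error(weights_from_replicates(tab[, 1:2]), "volume_mm3")
})
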