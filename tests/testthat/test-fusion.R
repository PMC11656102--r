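test_that("majority vote is unanimous on identical atlases and follows the mode", {
  lab <- array(c(0L, 1L, 2L, 1L), c(2, 2, 1))
  expect_identical(majority_vote(unanimous_atlases(lab, m = 5))$labels, lab)

  # voxel votes {1,1,2} -> 1; tie {1,2} -> smallest id 1
  a1 <- toy_atlas(array(1L, c(1, 1, 1)))
  a2 <- toy_atlas(array(1L, c(1, 1, 1)))
  a3 <- toy_atlas(array(2L, c(1, 1, 1)))
  expect_equal(as.integer(majority_vote(list(a1, a2, a3))$labels), 1L)
  expect_equal(as.integer(majority_vote(list(a1, a3))$labels), 1L)
  expect_equal(as.integer(majority_vote(list(a3, a1))$labels), 1L)
})

test_that("majority vote matches the exhaustive per-voxel count oracle", {
  set.seed(42)
  for (case in 1:25) {
    atlases <- lapply(1:3, function(k)
      toy_atlas(array(sample(0:2, 4, replace = TRUE), c(2, 2, 1)),
                id = paste0("a", k)))
    expect_identical(majority_vote(atlases)$labels,
                     majority_oracle(atlases)$labels)
  }
})

test_that("majority vote validates its inputs", {
  expect_error(majority_vote(list()), "at least one atlas")
  a <- toy_atlas(array(0L, c(2, 2, 1)))
  b <- toy_atlas(array(0L, c(3, 3, 1)))
  expect_error(majority_vote(list(a, b)), "share grid shape")
  c2 <- toy_atlas(array(0L, c(2, 2, 1)), voxel_size = c(2, 1, 1))
  expect_error(majority_vote(list(a, c2)), "share grid shape and voxel size")
})

test_that("locally weighted vote reduces to majority vote for identical intensities", {
  set.seed(7)
  lab_arrs <- lapply(1:4, function(k) array(sample(0:1, 27, TRUE), c(3, 3, 3)))
  shared_int <- array(rnorm(27), c(3, 3, 3))
  atlases <- lapply(seq_along(lab_arrs), function(k)
    toy_atlas(lab_arrs[[k]], id = paste0("a", k), intensity = shared_int))
  target <- intensity_image(shared_int)
  expect_identical(local_weighted_vote(target, atlases)$labels,
                   majority_vote(atlases)$labels)
})

test_that("locally weighted vote with a single atlas returns its labels", {
  set.seed(8)
  lab <- array(sample(0:2, 27, TRUE), c(3, 3, 3))
  a <- toy_atlas(lab, intensity = array(rnorm(27), c(3, 3, 3)))
  target <- intensity_image(array(rnorm(27), c(3, 3, 3)))
  expect_identical(local_weighted_vote(target, list(a))$labels, a$labels$labels)
})

test_that("locally weighted vote matches direct evaluation of the weight formula", {
  # 3x3x1 scene: two atlases with unequal patch SSD around the centre voxel,
  # where they disagree on the label; the lower-SSD atlas must win there
  tgt <- array(c(1, 1, 1, 1, 5, 1, 1, 1, 1), c(3, 3, 1))
  int1 <- tgt                          # atlas 1 aligned with the target
  int2 <- tgt; int2[2, 2, 1] <- 0      # atlas 2 far off at the centre
  lab1 <- array(0L, c(3, 3, 1)); lab1[2, 2, 1] <- 1L
  lab2 <- array(0L, c(3, 3, 1)); lab2[2, 2, 1] <- 2L
  a1 <- toy_atlas(lab1, intensity = int1)
  a2 <- toy_atlas(lab2, intensity = int2)
  target <- intensity_image(tgt)
  got <- local_weighted_vote(target, list(a1, a2), patch_radius = 1,
                             bandwidth = 1)
  expect_equal(got$labels[2, 2, 1], 1L)
  expect_identical(got$labels,
                   lwv_oracle(target, list(a1, a2), 1, 1)$labels)

  # random scenes against the loop oracle, including border clipping
  set.seed(11)
  for (case in 1:5) {
    atl <- lapply(1:3, function(k)
      toy_atlas(array(sample(0:2, 36, TRUE), c(4, 3, 3)),
                id = paste0("a", k),
                intensity = array(rnorm(36), c(4, 3, 3))))
    tg <- intensity_image(array(rnorm(36), c(4, 3, 3)))
    expect_identical(local_weighted_vote(tg, atl, 1, 0.7)$labels,
                     lwv_oracle(tg, atl, 1, 0.7)$labels)
  }
})

test_that("locally weighted vote rejects bad parameters", {
  a <- toy_atlas(array(0L, c(2, 2, 1)))
  t <- intensity_image(array(0, c(2, 2, 1)))
  expect_error(local_weighted_vote(t, list(a), bandwidth = -1), "bandwidth")
  expect_error(local_weighted_vote(t, list(a), patch_radius = -1),
               "patch_radius")
  expect_error(local_weighted_vote(t, list()), "at least one atlas")
})

test_that("both engines are deterministic and idempotent on unanimity", {
  sc <- small_scene(seed = 3, n_atlases = 5)
  for (eng in list(fusion_engine("majority"), fusion_engine("local_weighted"))) {
    f1 <- fuse(eng, sc$target, sc$atlases)
    f2 <- fuse(eng, sc$target, sc$atlases)
    expect_identical(f1$labels, f2$labels)
    # unanimity: m copies of one atlas return exactly its labels
    un <- unanimous_atlases(sc$atlases[[1]]$labels$labels, m = 4)
    expect_identical(fuse(eng, sc$target, un)$labels,
                     sc$atlases[[1]]$labels$labels)
  }
})

test_that("fused labels are closed over the per-voxel atlas labels", {
  sc <- small_scene(seed = 9, n_atlases = 5)
  for (eng in list(fusion_engine("majority"), fusion_engine("local_weighted"))) {
    fused <- fuse(eng, sc$target, sc$atlases)$labels
    seen <- Reduce(`|`, lapply(sc$atlases,
                               function(a) a$labels$labels == as.vector(fused)))
    expect_true(all(seen))
  }
})

test_that("roi_volume counts voxels times the physical voxel volume", {
  lab <- array(0L, c(4, 1, 1)); lab[1:3] <- 1L
  img <- label_image(lab, c(1, 1, 2))
  expect_equal(roi_volume(img, 1), 6)
  expect_equal(roi_volume(img, 7), 0)           # absent label
  # additive over disjoint labels and linear in voxel volume
  lab2 <- lab; lab2[4] <- 2L
  img2 <- label_image(lab2, c(1, 1, 2))
  expect_equal(roi_volume(img2, 1) + roi_volume(img2, 2),
               sum(lab2 > 0) * 2)
  img3 <- label_image(lab, c(2, 2, 2))
  expect_equal(roi_volume(img3, 1), roi_volume(img, 1) * 4)
})

test_that("voxelised ellipsoid volume approaches the analytic value", {
  sc <- make_phantom_scene(scene_config(grid_shape = c(40, 40, 40),
                                        roi_semi_axes = c(12, 10, 8),
                                        n_atlases = 1, shift_sd = 0,
                                        label_flip_rate = 0,
                                        intensity_noise_sd = 0, seed = 1))
  analytic <- 4 / 3 * pi * 12 * 10 * 8
  expect_lt(abs(roi_volume(sc$truth) - analytic) / analytic, 0.05)
})
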