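# Small in-code fixtures shared across the test files.

# atlas with given label array; intensity defaults to the labels themselves
toy_atlas <- function(labels, id = "a", voxel_size = c(1, 1, 1),
                      intensity = NULL) {
  lab <- label_image(array(as.integer(labels), dim(as.array(labels))),
                     voxel_size)
  if (is.null(intensity)) intensity <- lab$labels + 0
  atlas(id, intensity_image(intensity, voxel_size), lab)
}

# list of m atlases that are exact copies of one label array
unanimous_atlases <- function(labels, m = 3, voxel_size = c(1, 1, 1)) {
  lapply(seq_len(m), function(k)
    toy_atlas(labels, id = paste0("a", k), voxel_size = voxel_size))
}

# independent per-voxel vote-count oracle for majority_vote: explicit
# tabulation at every voxel, smallest label id on ties
majority_oracle <- function(atlases) {
  d <- dim(atlases[[1]]$labels$labels)
  out <- array(0L, d)
  for (v in seq_len(prod(d))) {
    votes <- vapply(atlases, function(a) a$labels$labels[v], integer(1))
    tab <- table(votes)
    winners <- as.integer(names(tab)[tab == max(tab)])
    out[v] <- min(winners)
  }
  label_image(out, atlases[[1]]$labels$voxel_size)
}

# independent locally-weighted-vote oracle: explicit loops over voxels,
# patches and atlases, evaluating the weight formula directly
lwv_oracle <- function(target, atlases, patch_radius, bandwidth) {
  d <- dim(target$values)
  out <- array(0L, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    ii <- max(1, i - patch_radius):min(d[1], i + patch_radius)
    jj <- max(1, j - patch_radius):min(d[2], j + patch_radius)
    kk <- max(1, k - patch_radius):min(d[3], k + patch_radius)
    npatch <- length(ii) * length(jj) * length(kk)
    scores <- list()
    for (a in atlases) {
      ssd <- sum((target$values[ii, jj, kk] - a$intensity$values[ii, jj, kk])^2)
      w <- exp(-ssd / (bandwidth * npatch))
      lab <- as.character(a$labels$labels[i, j, k])
      scores[[lab]] <- (if (is.null(scores[[lab]])) 0 else scores[[lab]]) + w
    }
    s <- unlist(scores)
    ids <- as.integer(names(s))
    out[i, j, k] <- min(ids[s >= max(s) - 1e-12])
  }
  label_image(out, target$voxel_size)
}

# all permutations of 1..n (for exhaustive permutation-test oracles)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- list()
  for (p in sub) for (pos in 0:(n - 1L)) {
    out[[length(out) + 1L]] <- append(p, n, after = pos)
  }
  out
}

# default small phantom scene used by several files
small_scene <- function(seed = 1, shift_sd = 1, n_atlases = 8,
                        label_flip_rate = 0.05, intensity_noise_sd = 0.05) {
  make_phantom_scene(scene_config(grid_shape = c(16, 16, 16),
                                  roi_semi_axes = c(4, 3.5, 3),
                                  n_atlases = n_atlases, shift_sd = shift_sd,
                                  label_flip_rate = label_flip_rate,
                                  intensity_noise_sd = intensity_noise_sd,
                                  seed = seed))
}
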