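#' Test a group effect on ROI volume in a cohort table
#'
#' Convenience wrapper tying the cohort schema to the permutation tests:
#' regresses `volume_mm3` on the group label with the nuisance covariates
#' (age and ICV by default, plus an intercept) under the requested
#' weighting scheme.
#'
#' @param cohort data.frame with columns `volume_mm3`, `group`, the
#'   nuisance covariates, and the weight column required by `scheme`.
#' @param scheme `"precision"` (column `precision_weight`), `"inverse_cv"`
#'   (column `cv_weight`) or `"identity"` (unit weights).
#' @param nuisance character vector of nuisance covariate columns.
#' @param n_perm,seed,strict passed to the permutation test.
#' @param method `"collins_dekker"` (default) or `"freedman_lane"`.
#' @return A `permutation_result`.
#' @export
test_group_effect <- function(cohort,
                              scheme = c("precision", "inverse_cv", "identity"),
                              nuisance = c("age", "icv"),
                              n_perm = 999L, seed = 1L, strict = FALSE,
                              method = c("collins_dekker", "freedman_lane")) {
  scheme <- match.arg(scheme)
  method <- match.arg(method)
  need <- c("volume_mm3", "group", nuisance)
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  w <- scheme_weights(cohort, scheme)
  Z <- cbind(intercept = 1, as.matrix(cohort[nuisance]))
  fun <- if (method == "collins_dekker") collins_dekker_test else freedman_lane_test
  fun(cohort$volume_mm3, cohort$group, Z, w = w, n_perm = n_perm, seed = seed,
      strict = strict)
}

scheme_weights <- function(cohort, scheme) {
  col <- switch(scheme, precision = "precision_weight",
                inverse_cv = "cv_weight", identity = NULL)
  if (is.null(col)) return(rep(1, nrow(cohort)))
  if (!col %in% names(cohort))
    stop("scheme '", scheme, "' requires column '", col, "'", call. = FALSE)
  w <- cohort[[col]]
  if (any(!is.finite(w)) || any(w <= 0))
    stop("column '", col, "' must be positive and finite", call. = FALSE)
  w
}

#' Experiment configuration
#'
#' Settings shared by the type-I-error and power experiments.
#'
#' @param n_grid per-group sample sizes to sweep.
#' @param n_reps replicates per grid point (default 1000).
#' @param alpha nominal rejection threshold (default 0.05); rejection uses
#'   strict `p < alpha`.
#' @param schemes weighting schemes to compare.
#' @param nuisance nuisance covariate columns.
#' @param n_perm permutations per test (default 999).
#' @param seed master seed; every replicate derives its own stream.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_grid = c(5L, 20L, 80L), n_reps = 1000L,
                              alpha = 0.05,
                              schemes = c("precision", "identity"),
                              nuisance = c("age", "icv"),
                              n_perm = 999L, seed = 1L) {
  stopifnot(all(n_grid >= 3L), alpha > 0, alpha <= 1, n_reps >= 1L,
            all(schemes %in% c("precision", "inverse_cv", "identity")))
  structure(list(n_grid = as.integer(n_grid), n_reps = as.integer(n_reps),
                 alpha = alpha, schemes = schemes, nuisance = nuisance,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "experiment_config")
}

#' Type-I-error experiment with artificial group labels
#'
#' For each per-group sample size n: repeatedly draw 2n subjects without
#' replacement from a single (null) pool, assign an artificial 0/1 label at
#' random (n per group), and test the label effect with the permutation
#' test under each weighting scheme. Since the label is pure noise, the
#' fraction of p-values below alpha estimates the type I error rate, which
#' a valid procedure keeps at the nominal level for every scheme.
#'
#' @param controls cohort data.frame (schema as [make_cohort()]); needs at
#'   least `2 * max(n_grid)` rows.
#' @param config an [experiment_config].
#' @return An object of class `experiment_result`: list with `rates`
#'   (data.frame scheme, n, rejection_rate, n_reps, alpha, seed) and
#'   `p_values` (long data.frame of every replicate p-value).
#' @export
type1_experiment <- function(controls, config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  if (nrow(controls) < 2L * max(config$n_grid))
    stop("need at least 2*max(n_grid) control subjects", call. = FALSE)
  for (s in config$schemes) scheme_weights(controls, s)  # fail fast
  run_experiment(config, function(n, rep_seed) {
    local_seed(rep_seed, {
      rows <- sample.int(nrow(controls), 2L * n)
      labels <- sample(rep(0:1, each = n))
    })
    d <- controls[rows, ]
    d$group <- labels
    d
  })
}

#' Power experiment comparing weighting schemes
#'
#' For each per-group sample size n: draw n subjects with replacement from
#' each group's pool, test the group effect under each scheme, and record
#' the rejection fraction. Resampled duplicates are treated as distinct
#' observations. When the two pools share one distribution the experiment
#' degenerates to a null calibration; with a true effect it estimates
#' power.
#'
#' @param group0,group1 cohort data.frames for the two groups.
#' @param config an [experiment_config].
#' @return An `experiment_result`, as in [type1_experiment()].
#' @export
power_experiment <- function(group0, group1, config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"),
            nrow(group0) > 0L, nrow(group1) > 0L)
  for (s in config$schemes) {
    scheme_weights(group0, s)
    scheme_weights(group1, s)
  }
  run_experiment(config, function(n, rep_seed) {
    local_seed(rep_seed, {
      i0 <- sample.int(nrow(group0), n, replace = TRUE)
      i1 <- sample.int(nrow(group1), n, replace = TRUE)
    })
    d0 <- group0[i0, ]; d0$group <- 0L
    d1 <- group1[i1, ]; d1$group <- 1L
    rbind(d0, d1)
  })
}

# shared driver: `draw(n, rep_seed)` returns the replicate's cohort with a
# `group` column; every (n, replicate) pair gets its own derived seed so
# results do not depend on evaluation order
run_experiment <- function(config, draw) {
  pv <- list()
  for (n in config$n_grid) {
    for (r in seq_len(config$n_reps)) {
      rep_seed <- derive_seed(config$seed, n * 1000003 + r)
      d <- draw(n, rep_seed)
      perm_seed <- derive_seed(rep_seed, "perm")  # shared across schemes so
      for (s in config$schemes) {                 # the comparison is paired
        res <- test_group_effect(d, scheme = s, nuisance = config$nuisance,
                                 n_perm = config$n_perm, seed = perm_seed)
        pv[[length(pv) + 1L]] <- data.frame(scheme = s, n = n, rep = r,
                                            p_value = res$p_value,
                                            stringsAsFactors = FALSE)
      }
    }
  }
  pv <- do.call(rbind, pv)
  rates <- do.call(rbind, lapply(split(pv, pv[c("scheme", "n")], drop = TRUE),
    function(d) data.frame(scheme = d$scheme[1L], n = d$n[1L],
                           rejection_rate = mean(d$p_value < config$alpha),
                           n_reps = nrow(d), alpha = config$alpha,
                           seed = config$seed, stringsAsFactors = FALSE)))
  rates <- rates[order(rates$scheme, rates$n), ]
  rownames(rates) <- NULL
  structure(list(rates = rates, p_values = pv, config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  print(x$rates)
  invisible(x)
}
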