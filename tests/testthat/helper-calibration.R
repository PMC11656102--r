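# Null-calibration driver shared by the type-I-error and p-value-uniformity
# checks: generates independent null cohorts (no group effect,
# heteroskedastic errors), randomly assigns artificial group labels, and
# runs the weighted and unweighted permutation tests on each.
null_calibration <- function(n_reps, n_per_group = 80, n_perm = 999,
                             master_seed = 20260101) {
  p_prec <- p_id <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    cohort_seed <- (master_seed + 7919 * r) %% 2147483647
    d <- make_cohort(cohort_config(n_per_group = n_per_group,
                                   group_effect = 0, seed = cohort_seed))
    set.seed(cohort_seed + 1)
    d$group <- sample(d$group)          # artificial labels, n per group
    perm_seed <- (cohort_seed + 2) %% 2147483647
    p_prec[r] <- test_group_effect(d, "precision", n_perm = n_perm,
                                   seed = perm_seed)$p_value
    p_id[r] <- test_group_effect(d, "identity", n_perm = n_perm,
                                 seed = perm_seed)$p_value
  }
  list(precision = p_prec, identity = p_id)
}
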