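#' Weighted residual-permutation test (Collins-Dekker / Smith scheme)
#'
#' Permutation inference for the effect of one predictor of interest in a
#' weighted linear model with nuisance covariates. The predictor of
#' interest is first residualised against the nuisance design by weighted
#' least squares; the (raw) residuals are then permuted to build surrogate
#' predictors carrying no true association with the response, and for each
#' surrogate the full weighted model is refitted and the t-statistic of the
#' surrogate recorded. The two-sided p-value is the proportion, among the
#' permuted t-statistics pooled with the observed one, whose absolute value
#' is at least the observed absolute value — so p is never below
#' `1/(n_perm + 1)`. With unit weights the procedure is the standard
#' unweighted residual-permutation method.
#'
#' Permutation inference is used here because the weights are themselves
#' estimated (from the bootstrap), which puts the usual parametric t
#' reference distribution in doubt; the permutation null does not rely on
#' it.
#'
#' @param y numeric response (e.g. ROI volume, mm^3).
#' @param x_interest numeric predictor of interest (e.g. a 0/1 group label).
#' @param Z_nuisance nuisance design matrix including an explicit intercept
#'   column.
#' @param w positive subject weights (default unit weights).
#' @param n_perm number of permutations (default 999, giving 1000 pooled
#'   statistics).
#' @param seed integer seed; permutations are drawn uniformly with
#'   replacement from the permutation group, reproducibly.
#' @param strict if `TRUE`, ties in |t| are not counted as exceedances
#'   (anti-conservative in the presence of ties); the default counts them.
#' @return An object of class `permutation_result`: list with
#'   `t_observed`, `t_permuted`, `p_value`, `n_perm`, `seed`, `method`.
#' @seealso [freedman_lane_test()] for the response-residual scheme.
#' @export
collins_dekker_test <- function(y, x_interest, Z_nuisance,
                                w = rep(1, length(y)), n_perm = 999L,
                                seed = 1L, strict = FALSE) {
  pr <- perm_setup(y, x_interest, Z_nuisance, w, n_perm)
  # raw residuals of the weighted fit of x on the nuisance design
  e <- wls_fit(pr$Z, pr$x, pr$w)$residuals
  perms <- draw_permutations(pr$n, n_perm, seed)
  E <- matrix(e[perms], nrow = pr$n) * pr$sw
  RX <- E - pr$Q %*% crossprod(pr$Q, E)
  rx2 <- colSums(RX^2)
  if (any(rx2 < pr$n * 1e-24))
    stop("predictor of interest is constant after residualisation",
         call. = FALSE)
  b <- colSums(RX * pr$ry) / rx2
  rss <- pmax(sum(pr$ry^2) - b^2 * rx2, 0)
  t_perm <- b * sqrt(rx2 * pr$df / rss)
  perm_result(pr, t_perm, n_perm, seed, strict, "collins_dekker")
}

#' Weighted Freedman-Lane permutation test
#'
#' Alternative permutation scheme: the response is fitted on the nuisance
#' design alone by weighted least squares; the raw residuals of that
#' reduced fit are permuted and added back to the reduced-model fitted
#' values to form surrogate responses, each of which is refitted on the
#' full design. The p-value pools the observed statistic with the permuted
#' ones exactly as in [collins_dekker_test()]; under the null both schemes
#' are valid and behave similarly.
#'
#' @inheritParams collins_dekker_test
#' @return An object of class `permutation_result`.
#' @export
freedman_lane_test <- function(y, x_interest, Z_nuisance,
                               w = rep(1, length(y)), n_perm = 999L,
                               seed = 1L, strict = FALSE) {
  pr <- perm_setup(y, x_interest, Z_nuisance, w, n_perm)
  r <- wls_fit(pr$Z, pr$y, pr$w)$residuals
  perms <- draw_permutations(pr$n, n_perm, seed)
  # fitted values of the reduced model lie in the span of the weighted
  # nuisance design, so only the permuted residuals survive residualisation
  R <- matrix(r[perms], nrow = pr$n) * pr$sw
  RY <- R - pr$Q %*% crossprod(pr$Q, R)
  rx2 <- sum(pr$rx^2)
  b <- colSums(RY * pr$rx) / rx2
  rss <- pmax(colSums(RY^2) - b^2 * rx2, 0)
  t_perm <- b * sqrt(rx2 * pr$df / rss)
  perm_result(pr, t_perm, n_perm, seed, strict, "freedman_lane")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> ", x$method, ": t_obs = ",
      signif(x$t_observed, 5), ", p = ", signif(x$p_value, 4),
      " (", x$n_perm, " permutations, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# Shared preparation: checks, weighted QR of the nuisance design, and the
# residualised observed predictor/response (Frisch-Waugh-Lovell form, which
# makes each permutation refit a pair of vector operations).
perm_setup <- function(y, x_interest, Z_nuisance, w, n_perm) {
  y <- as.numeric(y)
  x <- as.numeric(x_interest)
  Z <- as.matrix(Z_nuisance)
  w <- as.numeric(w)
  n <- length(y)
  if (length(x) != n || nrow(Z) != n || length(w) != n)
    stop("y, x_interest, Z_nuisance and w must agree in length", call. = FALSE)
  if (any(!is.finite(w)) || any(w <= 0))
    stop("weights must be positive and finite", call. = FALSE)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  if (!any(apply(Z, 2L, function(col) all(col == col[1L]) && col[1L] != 0)))
    stop("Z_nuisance must include an intercept column", call. = FALSE)
  sw <- sqrt(w)
  qz <- qr(Z * sw)
  if (qz$rank < ncol(Z)) stop("nuisance design is rank deficient", call. = FALSE)
  Q <- qr.Q(qz)
  ry <- y * sw - Q %*% crossprod(Q, y * sw)
  rx <- x * sw - Q %*% crossprod(Q, x * sw)
  df <- n - ncol(Z) - 1L
  if (df < 1L) stop("need more observations than predictors", call. = FALSE)
  rx2 <- sum(rx^2)
  if (rx2 < n * 1e-24)
    stop("predictor of interest is collinear with the nuisance design",
         call. = FALSE)
  b_obs <- sum(rx * ry) / rx2
  rss_obs <- max(sum(ry^2) - b_obs^2 * rx2, 0)
  t_obs <- b_obs * sqrt(rx2 * df / rss_obs)
  list(y = y, x = x, Z = Z, w = w, sw = sw, Q = Q, ry = drop(ry),
       rx = drop(rx), df = df, n = n, t_observed = t_obs)
}

# n x n_perm matrix of row indices, each column one uniform permutation
draw_permutations <- function(n, n_perm, seed) {
  local_seed(seed, {
    vapply(seq_len(n_perm), function(j) sample.int(n), integer(n))
  })
}

perm_result <- function(pr, t_perm, n_perm, seed, strict, method) {
  t_obs <- pr$t_observed
  exceed <- if (strict) abs(t_perm) > abs(t_obs) else abs(t_perm) >= abs(t_obs)
  p <- (sum(exceed) + 1) / (n_perm + 1)
  structure(list(t_observed = t_obs, t_permuted = t_perm, p_value = p,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 method = method),
            class = "permutation_result")
}
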