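#' Weighted least squares by the closed form
#'
#' Fits the linear model `y = X beta + eps` minimising the weighted sum of
#' squared residuals `sum(w_i * r_i^2)`. The estimator is the closed form
#' `beta = (X'WX)^{-1} X'W y` with `W = diag(w)`, computed via the QR
#' decomposition of `sqrt(w) X` for numerical stability. Standard errors
#' treat the weights as known inverse error variances up to a common
#' factor: `sigma2 = sum(w r^2) / (n - p)` and `cov = sigma2 (X'WX)^{-1}`.
#' With unit weights the fit is exactly ordinary least squares. Rescaling
#' all weights by a positive constant leaves the coefficients and
#' t-statistics unchanged.
#'
#' @param X numeric design matrix, n x p, full column rank, including an
#'   explicit intercept column if one is wanted.
#' @param y numeric response vector of length n.
#' @param w positive, finite weights of length n (default unit weights).
#' @return An object of class `wls_fit`: list with `beta`, `se`, `t_stats`,
#'   `cov`, `sigma2`, `residuals`, `fitted`, `df`.
#' @examples
#' X <- cbind(1, rnorm(20))
#' y <- X %*% c(2, 1) + rnorm(20)
#' wls_fit(X, y, rep(1, 20))$beta
#' @export
wls_fit <- function(X, y, w = rep(1, length(y))) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  w <- as.numeric(w)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n || length(w) != n)
    stop("X, y and w must agree in length", call. = FALSE)
  if (any(!is.finite(w)) || any(w <= 0))
    stop("weights must be positive and finite", call. = FALSE)
  if (n <= p) stop("need more observations than predictors", call. = FALSE)
  sw <- sqrt(w)
  qr_x <- qr(X * sw)
  if (qr_x$rank < p) stop("design matrix is rank deficient", call. = FALSE)
  beta <- qr.coef(qr_x, y * sw)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  df <- n - p
  sigma2 <- sum(w * res^2) / df
  xtwxi <- chol2inv(qr.R(qr_x))
  covb <- sigma2 * xtwxi
  se <- sqrt(diag(covb))
  nm <- colnames(X)
  if (!is.null(nm)) names(beta) <- names(se) <- nm
  structure(list(beta = beta, se = se, t_stats = beta / se, cov = covb,
                 sigma2 = sigma2, residuals = res, fitted = fitted, df = df),
            class = "wls_fit")
}

#' @export
print.wls_fit <- function(x, ...) {
  cat("<wls_fit> df =", x$df, "\n")
  print(data.frame(beta = x$beta, se = x$se, t = x$t_stats))
  invisible(x)
}
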