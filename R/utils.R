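# Least-squares helpers for fits constrained through the origin.
# Degrees of freedom are n - p with no intercept term; confidence
# intervals are normal-theory (t) intervals from the regression SE.

origin_slope <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  sxx <- sum(x^2)
  if (sxx <= 0) stop("all predictors are zero: no direction to fit", call. = FALSE)
  slope <- sum(x * y) / sxx
  n <- length(x)
  df <- n - 1L
  if (df >= 1L) {
    rss <- sum((y - slope * x)^2)
    se <- sqrt(rss / df / sxx)
    half <- stats::qt(1 - (1 - level) / 2, df) * se
    ci <- c(slope - half, slope + half)
  } else {
    se <- NA_real_
    ci <- c(NA_real_, NA_real_)
  }
  list(estimate = slope, se = se, ci = ci, df = df, n = n)
}

origin_plane <- function(X, y, level = 0.95) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), ncol(X) == 2L)
  qrX <- qr(X)
  if (qrX$rank < 2L) {
    # name the direction that collapsed
    norms <- sqrt(colSums(X^2))
    deg <- if (any(norms == 0)) colnames(X)[norms == 0][1L] else
      paste(colnames(X), collapse = " ~ ")
    stop(sprintf("rank-deficient predictors: degenerate direction '%s'", deg),
         call. = FALSE)
  }
  coef <- qr.coef(qrX, y)
  n <- nrow(X)
  df <- n - 2L
  if (df >= 1L) {
    rss <- sum((y - X %*% coef)^2)
    sigma2 <- rss / df
    covm <- sigma2 * chol2inv(qr.R(qrX))
    se <- sqrt(diag(covm))
    half <- stats::qt(1 - (1 - level) / 2, df) * se
    ci <- cbind(coef - half, coef + half)
  } else {
    covm <- matrix(NA_real_, 2L, 2L)
    se <- rep(NA_real_, 2L)
    ci <- matrix(NA_real_, 2L, 2L)
  }
  rownames(ci) <- names(se) <- names(coef)
  list(estimate = coef, se = se, ci = ci, cov = covm, df = df, n = n)
}

clamp_cos <- function(z) max(-1, min(1, z))

deg <- function(rad) rad * 180 / pi
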