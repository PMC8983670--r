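# Empirical-Bayes variance shrinkage shared by the moderated tests.
#
# Residual variances s2 with df residual degrees of freedom are modelled as
# scaled inverse-chi-square draws around a prior (d0, s0^2); the prior is
# estimated by moment matching on log(s2) and the posterior variance
# var_post = (d0 s0^2 + df s2) / (d0 + df) is used with df + d0 total
# degrees of freedom.

# solve trigamma(y) = x by Newton iteration
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

.squeeze_var <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    df_prior <- Inf
    s0 <- exp(emean)
  } else {
    df_prior <- 2 * .trigamma_inverse(evar)
    s0 <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  }
  var_post <- if (is.infinite(df_prior)) rep(s0, length(s2))
              else (df_prior * s0 + df * s2) / (df_prior + df)
  var_post[!ok] <- s0
  list(df_prior = df_prior, var_prior = s0, var_post = var_post)
}

# Ordinary least squares of many response rows on a common design matrix.
# Y: features x samples; X: samples x p. Returns coefficients (features x p),
# residual sum of squares and residual df.
.ols_rows <- function(Y, X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design matrix is rank deficient")
  coefs <- t(qr.coef(qx, t(Y)))
  fitted <- coefs %*% t(X)
  rss <- rowSums((Y - fitted)^2)
  list(coef = coefs, rss = rss, df = ncol(Y) - qx$rank,
       xtx_inv = chol2inv(qr.R(qx)))
}

# Moderated F-test for dropping the columns `drop` from design X, one test
# per row of Y. moderate = FALSE gives the ordinary F-test.
.drop_ftest <- function(Y, X, drop, moderate = TRUE) {
  full <- .ols_rows(Y, X)
  red <- .ols_rows(Y, X[, -drop, drop = FALSE])
  q <- length(drop)
  s2 <- full$rss / full$df
  if (moderate) {
    sq <- .squeeze_var(s2, full$df)
    fstat <- ((red$rss - full$rss) / q) / sq$var_post
    df2 <- full$df + sq$df_prior
  } else {
    fstat <- ((red$rss - full$rss) / q) / s2
    df2 <- full$df
  }
  p <- if (is.finite(df2)) {
    stats::pf(fstat, q, df2, lower.tail = FALSE)
  } else {
    stats::pchisq(fstat * q, df = q, lower.tail = FALSE)
  }
  list(coef = full$coef, f = fstat, p = p, df1 = q, df2 = df2,
       s2 = s2, rss = full$rss, df_res = full$df)
}
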