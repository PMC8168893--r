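# Linear mixed model with a subject random intercept, plus Satterthwaite
# degrees of freedom for the fixed effects.
#
# Estimation is delegated to lme4 (REML). The Satterthwaite machinery is
# implemented here: for each fixed effect j, with variance components
# v = (sigma^2_subject, sigma^2_resid),
#   df_j = 2 * C_jj(v)^2 / (g_j' A g_j),
# where C(v) = (X' V(v)^-1 X)^-1, g_j = dC_jj/dv (central differences) and
# A = Var(v_hat) is the inverse Hessian of the REML negative log-likelihood,
# also obtained numerically. When every subject contributes one session, or
# the subject variance collapses to zero, the model reduces to ordinary
# least squares with df = n - p (the documented boundary behaviour).

# REML negative log-likelihood in the (s2_subject, s2_resid) parametrisation
reml_nll <- function(v, X, y, subj_idx) {
  n <- length(y)
  V <- diag(rep(v[2L], n))
  for (ix in subj_idx) V[ix, ix] <- V[ix, ix] + v[1L]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(X, Vi_y))
  r <- y - X %*% beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  as.numeric(0.5 * (logdetV +
                      as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) +
                      sum(r * Vi_r)))
}

# C(v) = (X' V^-1 X)^-1
coef_cov <- function(v, X, subj_idx) {
  n <- nrow(X)
  V <- diag(rep(v[2L], n))
  for (ix in subj_idx) V[ix, ix] <- V[ix, ix] + v[1L]
  solve(crossprod(X, solve(V, X)))
}

# 2x2 Hessian by central differences on a 3x3 stencil
hessian2 <- function(f, v, rel = 1e-4) {
  h <- pmax(abs(v) * rel, 1e-10)
  H <- matrix(NA_real_, 2L, 2L)
  for (i in 1:2) {
    ei <- numeric(2L); ei[i] <- h[i]
    H[i, i] <- (f(v + ei) - 2 * f(v) + f(v - ei)) / h[i]^2
  }
  e1 <- c(h[1L], 0); e2 <- c(0, h[2L])
  H[1L, 2L] <- H[2L, 1L] <-
    (f(v + e1 + e2) - f(v + e1 - e2) - f(v - e1 + e2) + f(v - e1 - e2)) /
    (4 * h[1L] * h[2L])
  H
}

#' Fit a random-intercept linear mixed model with Satterthwaite p-values
#'
#' Fits `y ~ X + (1 | subject)` by REML through \pkg{lme4} and computes
#' per-coefficient t-statistics with Satterthwaite degrees of freedom.
#' When every subject contributes a single observation, or the estimated
#' subject variance is (numerically) zero, the fit falls back to ordinary
#' least squares with `df = n - p`; mixed-model p-values then coincide with
#' simple-regression p-values, as they must.
#'
#' @param y numeric response.
#' @param X design matrix including an intercept column.
#' @param subject subject identifier vector (factor/character/integer).
#' @return list with `coefficients` (matrix: estimate, se, t, df, p),
#'   `sigma2_subject`, `sigma2_resid`, `n`, `n_subjects`, `method`
#'   (`"satterthwaite"` or `"ols"`).
#' @export
lmm_ri <- function(y, X, subject) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, length(subject) == n)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_invalid("rank-deficient design; collinear columns: %s",
                 paste(bad, collapse = ", "))
  }
  subject <- factor(subject)
  p <- ncol(X)
  n_subj <- nlevels(subject)
  ols <- function() {
    fit <- stats::lm.fit(X, y)
    s2 <- sum(fit$residuals^2) / (n - p)
    se <- sqrt(diag(chol2inv(qr.R(qrX))) * s2)
    est <- fit$coefficients
    tt <- est / se
    df <- rep(n - p, p)
    pv <- 2 * stats::pt(-abs(tt), df)
    list(coefficients = cbind(estimate = est, se = se, t = tt, df = df,
                              p = pv),
         sigma2_subject = 0, sigma2_resid = s2, n = n, n_subjects = n_subj,
         method = "ols")
  }
  if (max(table(subject)) == 1L) return(ols())

  dat <- as.data.frame(X[, -1L, drop = FALSE])
  xnames <- if (ncol(dat)) paste0("x", seq_len(ncol(dat))) else character(0)
  names(dat) <- xnames
  dat$.y <- y
  dat$.subj <- subject
  form <- stats::as.formula(paste(
    ".y ~", paste(c("1", xnames), collapse = " + "), "+ (1 | .subj)"))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = dat, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2b <- vc$vcov[vc$grp == ".subj"]
  s2e <- stats::sigma(fit)^2
  if (!length(s2b) || s2e < 1e-12 || s2b < 1e-8 * max(s2e, 1e-12))
    return(ols())

  est <- lme4::fixef(fit)
  subj_idx <- split(seq_len(n), subject)
  v <- c(s2b, s2e)
  C <- coef_cov(v, X, subj_idx)
  se <- sqrt(diag(C))
  tt <- est / se
  H <- hessian2(function(vv) reml_nll(vv, X, y, subj_idx), v)
  A <- tryCatch(solve(H), error = function(e) NULL)
  df <- rep(n - p, p)
  if (!is.null(A) && all(is.finite(A)) && all(diag(A) > 0)) {
    h <- pmax(v * 1e-4, 1e-10)
    for (j in seq_len(p)) {
      g <- numeric(2L)
      for (i in 1:2) {
        ei <- numeric(2L); ei[i] <- h[i]
        g[i] <- (coef_cov(v + ei, X, subj_idx)[j, j] -
                   coef_cov(v - ei, X, subj_idx)[j, j]) / (2 * h[i])
      }
      denom <- drop(t(g) %*% A %*% g)
      if (is.finite(denom) && denom > 0)
        df[j] <- min(max(2 * C[j, j]^2 / denom, 1), n - p)
    }
  }
  pv <- 2 * stats::pt(-abs(tt), df)
  cf <- cbind(estimate = est, se = se, t = tt, df = df, p = pv)
  rownames(cf) <- colnames(X)
  list(coefficients = cf, sigma2_subject = s2b, sigma2_resid = s2e,
       n = n, n_subjects = n_subj, method = "satterthwaite")
}
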