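# Lagged cross-correlation between the global BOLD signal and the CSF
# signal, the +1 TR (+3 s) coupling metric, and the session-shuffling
# permutation null.
#
# Lag-sign convention: CC(tau) = Pearson(G(t), F(t - tau)). A negative lag
# therefore shifts the CSF series ahead of time: tau = -6 s pairs G(t) with
# F(t + 6 s). Under this convention the canonical geometry is a positive
# peak at a negative lag and a negative peak at +1 TR.

#' Lagged cross-correlation function
#'
#' Computes `CC(tau) = cor(G(t), F(t - tau))` for every lag `tau = k * TR`,
#' `k = -K..K`, using only the overlapping samples at each lag,
#' re-standardised per lag (so every value is a genuine Pearson correlation
#' with `|r| <= 1`).
#'
#' @param g,f equal-length numeric series (global BOLD and CSF).
#' @param max_lag_seconds maximum |lag| in seconds (default 21 s = 7 TR at
#'   TR 3 s).
#' @param tr_seconds sampling interval, defines the lag grid.
#' @return a `crosscorr_fn` object: `lags_seconds`, `r`, `n_overlap`,
#'   `tr_seconds`.
#' @export
crosscorr <- function(g, f, max_lag_seconds = 21, tr_seconds) {
  stopifnot(is.numeric(g), is.numeric(f), tr_seconds > 0)
  if (length(g) != length(f))
    stop_invalid("series lengths differ (%d vs %d)", length(g), length(f))
  K <- floor(max_lag_seconds / tr_seconds + 1e-9)
  n <- length(g)
  if (n < 2 * K + 3)
    stop_invalid("series length %d too short for max lag %g s at TR %g s",
                 n, max_lag_seconds, tr_seconds)
  if (stats::sd(g) == 0 || stats::sd(f) == 0)
    stop_invalid("correlation undefined for a constant series")
  ks <- seq.int(-K, K)
  r <- numeric(length(ks))
  n_overlap <- integer(length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    if (k >= 0) {
      gi <- (1 + k):n; fi <- 1:(n - k)
    } else {
      gi <- 1:(n + k); fi <- (1 - k):n
    }
    r[i] <- stats::cor(g[gi], f[fi])
    n_overlap[i] <- n - abs(k)
  }
  structure(list(lags_seconds = ks * tr_seconds, r = r,
                 n_overlap = n_overlap, tr_seconds = tr_seconds),
            class = "crosscorr_fn")
}

#' Cross-correlation of the negative BOLD derivative with the CSF signal
#'
#' Applies [negative_derivative()] to the global signal (forward stencil,
#' value at the leading timepoint), truncates the CSF series by its last
#' sample to match, then computes [crosscorr()]. For a CSF signal built as
#' the delayed negative derivative of the global signal, the peak sits at
#' the lag nearest `-delay`.
#'
#' @inheritParams crosscorr
#' @return a `crosscorr_fn` object.
#' @export
crosscorr_derivative <- function(g, f, max_lag_seconds = 21, tr_seconds) {
  if (length(g) != length(f))
    stop_invalid("series lengths differ (%d vs %d)", length(g), length(f))
  dg <- negative_derivative(g, tr_seconds)
  crosscorr(dg, f[-length(f)], max_lag_seconds, tr_seconds)
}

#' @export
print.crosscorr_fn <- function(x, ...) {
  cat(sprintf("<crosscorr_fn> %d lags spanning %g..%g s (TR = %g s)\n",
              length(x$lags_seconds), min(x$lags_seconds),
              max(x$lags_seconds), x$tr_seconds))
  peak <- which.max(abs(x$r))
  cat(sprintf("  extremum r = %.3f at lag %g s\n",
              x$r[peak], x$lags_seconds[peak]))
  invisible(x)
}

#' @export
as.data.frame.crosscorr_fn <- function(x, ...) {
  data.frame(lag_s = x$lags_seconds, r = x$r, n_overlap = x$n_overlap)
}

#' Coupling strength: the cross-correlation at +1 TR
#'
#' The coupling metric is the cross-correlation at the `+3 s` lag (one TR
#' at TR = 3 s), the negative peak of the canonical cross-correlation
#' function; more negative values mean stronger coupling. A generic
#' `lag_seconds` argument supports lag-sweep analyses.
#'
#' @param ccf a `crosscorr_fn` object.
#' @param lag_seconds lag at which to read the correlation (default +1 TR).
#' @return scalar correlation.
#' @export
coupling_strength <- function(ccf, lag_seconds = ccf$tr_seconds) {
  stopifnot(inherits(ccf, "crosscorr_fn"))
  i <- which(abs(ccf$lags_seconds - lag_seconds) < 1e-9)
  if (length(i) != 1L)
    stop_invalid("lag %g s not present in the cross-correlation function",
                 lag_seconds)
  ccf$r[i]
}

#' Average cross-correlation functions across sessions
#'
#' @param ccfs list of `crosscorr_fn` objects sharing one lag grid.
#' @return list with `lags_seconds`, `r_mean`, `sem` (NA for a single
#'   session), `sd`, `n_sessions`, `tr_seconds`.
#' @export
session_mean_ccf <- function(ccfs) {
  stopifnot(length(ccfs) >= 1L, all(vapply(ccfs, inherits, TRUE,
                                           "crosscorr_fn")))
  lags <- ccfs[[1L]]$lags_seconds
  for (cc in ccfs)
    if (!isTRUE(all.equal(cc$lags_seconds, lags)))
      stop_invalid("cross-correlation functions have mismatched lag grids")
  R <- do.call(rbind, lapply(ccfs, `[[`, "r"))
  n <- nrow(R)
  sds <- apply(R, 2L, stats::sd)
  list(lags_seconds = lags,
       r_mean = colMeans(R),
       sem = if (n > 1L) sds / sqrt(n) else rep(NA_real_, length(lags)),
       sd = if (n > 1L) sds else rep(NA_real_, length(lags)),
       n_sessions = n,
       tr_seconds = ccfs[[1L]]$tr_seconds)
}

# Pairwise lagged correlations for all (global_j, csf_i) session pairs,
# after truncating every series to the common shortest length. Returns a
# list of n x n matrices, one per lag: R[[k]][j, i] = cor at lag k between
# session j's global signal and session i's CSF signal.
pairwise_lagged_correlations <- function(sessions, max_lag_seconds,
                                         tr_seconds) {
  L <- min(vapply(sessions, function(s) length(s$global_bold), 1L))
  G <- vapply(sessions, function(s) s$global_bold[seq_len(L)], numeric(L))
  F_ <- vapply(sessions, function(s) s$csf[seq_len(L)], numeric(L))
  K <- floor(max_lag_seconds / tr_seconds + 1e-9)
  if (L < 2 * K + 3)
    stop_invalid("common session length %d too short for max lag %g s",
                 L, max_lag_seconds)
  ks <- seq.int(-K, K)
  out <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    if (k >= 0) {
      gi <- (1 + k):L; fi <- 1:(L - k)
    } else {
      gi <- 1:(L + k); fi <- (1 - k):L
    }
    Gs <- scale(G[gi, , drop = FALSE])
    Fs <- scale(F_[fi, , drop = FALSE])
    out[[i]] <- crossprod(Gs, Fs) / (length(gi) - 1L)
  }
  list(lags_seconds = ks * tr_seconds, R = out)
}

#' Session-shuffling permutation null for the mean cross-correlation
#'
#' Each iteration applies one uniform random permutation to the session
#' labels of the global signals, re-pairs every CSF series with the permuted
#' global series, recomputes the session-mean cross-correlation function,
#' and accumulates it into a per-lag null distribution. Series of unequal
#' length are truncated to the common shortest length up front. Two-sided
#' empirical p-values use the add-one convention, so the smallest attainable
#' p is `1 / (n_permutations + 1)`.
#'
#' @param sessions list of [session_signals()] (>= 2).
#' @param n_permutations number of random permutations (default 10000).
#' @param max_lag_seconds maximum |lag| in seconds.
#' @param seed optional RNG seed for the permutations.
#' @param keep_null if `TRUE`, also return the full matrix of per-lag null
#'   means (`n_permutations` x lags) as `null_means`.
#' @return a `permutation_null` object: per-lag observed mean, null mean,
#'   2.5/97.5 percentiles, two-sided `p`, plus `n_permutations` and `seed`.
#' @export
permutation_null <- function(sessions, n_permutations = 10000,
                             max_lag_seconds = 21, seed = NULL,
                             keep_null = FALSE) {
  if (length(sessions) < 2L)
    stop_invalid("permutation test needs at least 2 sessions")
  stopifnot(is_count(n_permutations))
  tr <- sessions[[1L]]$tr_seconds
  pw <- pairwise_lagged_correlations(sessions, max_lag_seconds, tr)
  n <- length(sessions)
  n_lag <- length(pw$lags_seconds)
  observed <- vapply(pw$R, function(m) mean(diag(m)), 1)
  null_means <- with_seed(seed, {
    perms <- t(replicate(n_permutations, sample.int(n)))
    sapply(seq_len(n_lag), function(i) {
      Rm <- pw$R[[i]]
      vapply(seq_len(n_permutations),
             function(b) mean(Rm[cbind(perms[b, ], seq_len(n))]), 1)
    })
  })
  null_means <- matrix(null_means, nrow = n_permutations)
  p <- vapply(seq_len(n_lag), function(i) {
    (1 + sum(abs(null_means[, i]) >= abs(observed[i]) - 1e-12)) /
      (1 + n_permutations)
  }, 1)
  qs <- apply(null_means, 2L, stats::quantile, probs = c(0.025, 0.975))
  structure(list(lags_seconds = pw$lags_seconds,
                 observed_mean = observed,
                 null_mean = colMeans(null_means),
                 null_lo = qs[1L, ], null_hi = qs[2L, ],
                 p = p,
                 n_permutations = n_permutations,
                 n_sessions = n,
                 seed = seed,
                 null_means = if (keep_null) null_means else NULL),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null> %d sessions, %d permutations\n",
              x$n_sessions, x$n_permutations))
  df <- data.frame(lag_s = x$lags_seconds, observed = round(x$observed_mean, 4),
                   null_lo = round(x$null_lo, 4), null_hi = round(x$null_hi, 4),
                   p = signif(x$p, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Fit the BOLD-CSF coupling model for a set of sessions
#'
#' The central fitting function: computes the per-session lagged
#' cross-correlation functions (optionally of the negative BOLD derivative),
#' their session mean and SEM, the per-session coupling strengths at +1 TR,
#' and (when `n_permutations > 0`) the session-shuffling permutation null
#' with per-lag p-values.
#'
#' @param sessions list of [session_signals()].
#' @param max_lag_seconds maximum |lag| in seconds (default 21).
#' @param n_permutations permutations for the null (0 skips the null).
#' @param derivative if `TRUE`, correlate the negative derivative of the
#'   global signal with the CSF signal instead.
#' @param seed RNG seed for the permutation null.
#' @return an object of class `bold_csf_coupling` with `print`, `summary`,
#'   `plot` and `coef` methods. `coef()` returns the per-session coupling
#'   strengths (cross-correlation at +1 TR; more negative = stronger).
#' @export
bold_csf_coupling <- function(sessions, max_lag_seconds = 21,
                              n_permutations = 0, derivative = FALSE,
                              seed = NULL) {
  stopifnot(length(sessions) >= 1L,
            all(vapply(sessions, inherits, TRUE, "session_signals")))
  tr <- sessions[[1L]]$tr_seconds
  fun <- if (derivative) crosscorr_derivative else crosscorr
  ccfs <- lapply(sessions, function(s)
    fun(s$global_bold, s$csf, max_lag_seconds, tr))
  m <- session_mean_ccf(ccfs)
  null <- NULL
  if (n_permutations > 0 && length(sessions) >= 2L && !derivative)
    null <- permutation_null(sessions, n_permutations, max_lag_seconds, seed)
  structure(list(ccfs = ccfs, mean = m, null = null,
                 strengths = vapply(ccfs, coupling_strength, 1),
                 derivative = derivative,
                 tr_seconds = tr, max_lag_seconds = max_lag_seconds,
                 n_sessions = length(sessions)),
            class = "bold_csf_coupling")
}

#' @export
print.bold_csf_coupling <- function(x, ...) {
  cat(sprintf("BOLD-CSF coupling fit (%s), %d session%s, TR = %g s\n",
              if (x$derivative) "negative-derivative variant" else
                "global signal vs CSF",
              x$n_sessions, if (x$n_sessions == 1) "" else "s",
              x$tr_seconds))
  i <- which(abs(x$mean$lags_seconds - x$tr_seconds) < 1e-9)
  cat(sprintf("  mean coupling at +%g s lag: %.3f", x$tr_seconds,
              x$mean$r_mean[i]))
  if (!is.null(x$null)) cat(sprintf(" (permutation p = %.4g)", x$null$p[i]))
  cat("\n")
  pk <- which.min(x$mean$r_mean); pp <- which.max(x$mean$r_mean)
  cat(sprintf("  mean CCF extrema: %.3f at %g s, %.3f at %g s\n",
              x$mean$r_mean[pk], x$mean$lags_seconds[pk],
              x$mean$r_mean[pp], x$mean$lags_seconds[pp]))
  invisible(x)
}

#' @export
coef.bold_csf_coupling <- function(object, ...) object$strengths

#' @export
summary.bold_csf_coupling <- function(object, ...) {
  df <- data.frame(lag_s = object$mean$lags_seconds,
                   r_mean = object$mean$r_mean,
                   sem = object$mean$sem)
  if (!is.null(object$null)) {
    df$null_mean <- object$null$null_mean
    df$null_lo <- object$null$null_lo
    df$null_hi <- object$null$null_hi
    df$p <- object$null$p
  }
  structure(list(table = df, n_sessions = object$n_sessions,
                 derivative = object$derivative,
                 strengths = object$strengths),
            class = "summary.bold_csf_coupling")
}

#' @export
print.summary.bold_csf_coupling <- function(x, ...) {
  cat(sprintf("Session-mean cross-correlation function (%d sessions)\n",
              x$n_sessions))
  print(x$table, row.names = FALSE, digits = 3)
  cat(sprintf("coupling strength at +1 TR: mean %.3f, SD %.3f\n",
              mean(x$strengths), stats::sd(x$strengths)))
  invisible(x)
}

#' @export
plot.bold_csf_coupling <- function(x, ...) {
  m <- x$mean
  ylim <- range(c(m$r_mean - m$sem, m$r_mean + m$sem,
                  x$null$null_lo, x$null$null_hi), na.rm = TRUE)
  graphics::plot(m$lags_seconds, m$r_mean, type = "n", ylim = ylim,
                 xlab = "lag (s)  [negative = CSF shifted ahead]",
                 ylab = "cross-correlation r", ...)
  if (!is.null(x$null))
    graphics::polygon(c(m$lags_seconds, rev(m$lags_seconds)),
                      c(x$null$null_lo, rev(x$null$null_hi)),
                      col = "grey88", border = NA)
  graphics::abline(h = 0, col = "grey60", lty = 3)
  graphics::abline(v = x$tr_seconds, col = "red3", lty = 2)
  if (any(is.finite(m$sem)))
    graphics::arrows(m$lags_seconds, m$r_mean - m$sem,
                     m$lags_seconds, m$r_mean + m$sem,
                     angle = 90, code = 3, length = 0.02, col = "grey40")
  graphics::lines(m$lags_seconds, m$r_mean, lwd = 2)
  graphics::points(m$lags_seconds, m$r_mean, pch = 16)
  invisible(x)
}
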