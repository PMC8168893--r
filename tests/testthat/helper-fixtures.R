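# Shared fixtures and independent oracles.

# Independent brute-force lagged cross-correlation: explicit shift, trim,
# and first-principles Pearson (no cor()).
brute_ccf <- function(g, f, max_lag_seconds, tr_seconds) {
  K <- floor(max_lag_seconds / tr_seconds + 1e-9)
  n <- length(g)
  vapply(-K:K, function(k) {
    if (k >= 0) {
      x <- g[(1 + k):n]; y <- f[1:(n - k)]
    } else {
      x <- g[1:(n + k)]; y <- f[(1 - k):n]
    }
    dx <- x - sum(x) / length(x)
    dy <- y - sum(y) / length(y)
    sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  }, 1)
}

# Cosine/derivative fixture: G = cos(2 pi t / period); F is the negative
# derivative of G delayed by `delay` (analytic, not finite-difference):
# F(t) = (2 pi / period) sin(2 pi (t - delay) / period).
cosine_fixture <- function(dt = 1, total_s = 400, period = 20, delay = 3) {
  tt <- seq(0, total_s - dt, by = dt)
  list(t = tt,
       g = cos(2 * pi * tt / period),
       f = (2 * pi / period) * sin(2 * pi * (tt - delay) / period))
}

# Small synthetic session list built directly from white noise (for
# permutation machinery tests that need no physiology).
noise_sessions <- function(n_sessions, n_t = 130, tr = 3, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_sessions), function(i)
    session_signals(global_bold = rnorm(n_t), csf = rnorm(n_t),
                    tr_seconds = tr))
}

# Default-world cohort -> extracted signals + coupling strengths.
quick_cohort <- function(seed, n_subjects = 15, sessions_per_subject = 2,
                         ...) {
  cfg <- sim_config(n_subjects = n_subjects,
                    sessions_per_subject = sessions_per_subject,
                    seed = seed, ...)
  coh <- simulate_cohort(cfg)
  sig <- extract_cohort_signals(coh)
  list(cfg = cfg, cohort = coh, signals = sig)
}
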