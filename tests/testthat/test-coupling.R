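test_that("crosscorr matches the brute-force oracle and basic identities", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(60:200, 1)
    g <- rnorm(n); f <- rnorm(n)
    cc <- crosscorr(g, f, 21, 3)
    expect_equal(cc$r, brute_ccf(g, f, 21, 3), tolerance = 1e-12)
    expect_true(all(abs(cc$r) <= 1 + 1e-12))
    # lag 0 equals the plain Pearson correlation
    expect_equal(cc$r[cc$lags_seconds == 0], cor(g, f), tolerance = 1e-12)
    # swapping the series reflects the lag axis
    expect_equal(crosscorr(f, g, 21, 3)$r, rev(cc$r), tolerance = 1e-12)
    expect_equal(cc$n_overlap, n - abs(cc$lags_seconds) / 3)
  }
  g <- rnorm(100)
  expect_equal(coupling_strength(crosscorr(g, g, 21, 3), 0), 1)
  expect_error(crosscorr(g, rep(1, 100), 21, 3), "constant")
  expect_error(crosscorr(g, rnorm(99), 21, 3), "lengths differ")
  expect_error(crosscorr(rnorm(10), rnorm(10), 21, 3), "too short")
})

test_that("cosine fixture reproduces the published peak geometry", {
  # dt = 1 s: closed form CC(tau) = -sin(2 pi (tau + 3) / 20)
  fx <- cosine_fixture(dt = 1, total_s = 400)
  cc <- crosscorr(fx$g, fx$f, 10, 1)
  closed <- -sin(2 * pi * (cc$lags_seconds + 3) / 20)
  expect_equal(cc$r, closed, tolerance = 0.02)
  expect_equal(cc$lags_seconds[which.min(cc$r)], 2)    # negative extremum
  expect_equal(cc$lags_seconds[which.max(cc$r)], -8)   # positive extremum
  # TR = 3 s grid: the +3 s value is the coupling metric
  fx3 <- cosine_fixture(dt = 3, total_s = 402)
  cc3 <- crosscorr(fx3$g, fx3$f, 21, 3)
  expect_equal(coupling_strength(cc3), -sin(2 * pi * 6 / 20),
               tolerance = 0.01)
  expect_lt(coupling_strength(cc3), 0)
  expect_gt(max(cc3$r[cc3$lags_seconds < 0]), 0.9)
  # metric invariant to rescaling of the CSF series
  cc3b <- crosscorr(fx3$g, 10 * fx3$f, 21, 3)
  expect_equal(coupling_strength(cc3b), coupling_strength(cc3),
               tolerance = 1e-12)
  expect_error(coupling_strength(cc3, 100), "not present")
})

test_that("derivative-variant peak localises the injected delay", {
  set.seed(8)
  tr <- 3
  g <- as.numeric(arima.sim(list(ar = 0.9), 400))
  d <- 2L  # samples of delay (6 s)
  f <- c(rep(0, d), -diff(g) / tr)[1:400]  # -g' delayed, forward stencil
  cc <- crosscorr_derivative(g, f, 30, tr)
  expect_equal(cc$lags_seconds[which.max(cc$r)], -d * tr)
  expect_gt(max(cc$r), 0.95)
  # positive derivative flips the peak into a trough
  cc2 <- crosscorr_derivative(g, -f, 30, tr)
  expect_equal(cc2$r, -cc$r, tolerance = 1e-12)
  # white-noise pairs stay inside the null band almost always
  set.seed(9)
  mx <- replicate(40, {
    x <- rnorm(190); y <- rnorm(190)
    max(abs(crosscorr_derivative(x, y, 21, 3)$r))
  })
  expect_gte(mean(mx < 0.3), 0.95)
})

test_that("session_mean_ccf averages and propagates uncertainty", {
  fx <- cosine_fixture(dt = 3, total_s = 402)
  cc <- crosscorr(fx$g, fx$f, 21, 3)
  one <- session_mean_ccf(list(cc))
  expect_equal(one$r_mean, cc$r)
  expect_true(all(is.na(one$sem)))
  # r and -r average to zero
  ccneg <- crosscorr(fx$g, -fx$f, 21, 3)
  two <- session_mean_ccf(list(cc, ccneg))
  expect_equal(two$r_mean, rep(0, length(cc$r)), tolerance = 1e-12)
  # mismatched grids are rejected
  cc7 <- crosscorr(fx$g, fx$f, 9, 3)
  expect_error(session_mean_ccf(list(cc, cc7)), "lag grids")
  # 50 coupled synthetic sessions: canonical shape of the mean CCF
  q <- quick_cohort(seed = 61, n_subjects = 25)
  fit <- bold_csf_coupling(q$signals)
  m <- fit$mean
  neg_pk <- m$lags_seconds[which.min(m$r_mean)]
  pos_pk <- m$lags_seconds[which.max(m$r_mean)]
  expect_equal(neg_pk, 3)      # negative extremum at +1 TR
  expect_lt(pos_pk, 0)         # positive extremum at a negative lag
})

test_that("permutation null: floor, determinism, and enumeration oracle", {
  # observed mean beyond every null draw hits the add-one floor
  q <- quick_cohort(seed = 77, n_subjects = 10)
  pn <- permutation_null(q$signals, n_permutations = 200, seed = 5)
  i3 <- which(pn$lags_seconds == 3)
  expect_gte(min(pn$p), 1 / 201)
  expect_equal(pn$p[i3], 1 / 201)
  expect_true(all(pn$p > 0 & pn$p <= 1))
  pn2 <- permutation_null(q$signals, n_permutations = 200, seed = 5)
  expect_identical(pn$p, pn2$p)

  # 3-session toy: every sampled null mean must equal one of the 6
  # exhaustively enumerated permutation means
  ss <- noise_sessions(3, n_t = 60, seed = 13)
  K <- 2; tr <- 3
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  enum <- sapply(-K:K, function(k) {
    vapply(perms, function(p) {
      mean(vapply(1:3, function(i) {
        g <- ss[[p[i]]]$global_bold; f <- ss[[i]]$csf
        n <- length(g)
        if (k >= 0) cor(g[(1 + k):n], f[1:(n - k)])
        else cor(g[1:(n + k)], f[(1 - k):n])
      }, 1))
    }, 1)
  })
  pn3 <- permutation_null(ss, n_permutations = 50, max_lag_seconds = K * tr,
                          seed = 99, keep_null = TRUE)
  # observed mean is the identity permutation row
  expect_equal(pn3$observed_mean, enum[1, ], tolerance = 1e-12)
  # every sampled null mean lies exactly on the enumerated support
  for (j in seq_len(ncol(enum))) {
    d <- vapply(pn3$null_means[, j],
                function(v) min(abs(v - enum[, j])), 1)
    expect_lt(max(d), 1e-12)
  }
  # with 50 draws of 6 permutations, all 6 values should have been visited
  expect_identical(
    sort(unique(round(pn3$null_means[, 1], 12))),
    sort(unique(round(enum[, 1], 12))))
  expect_error(permutation_null(ss[1], 10), "at least 2 sessions")
})

test_that("mean coupling strengthens monotonically with injected gain", {
  strengths <- numeric(0); gains <- numeric(0)
  for (g in c(0, 0.5, 1, 2)) {
    q <- quick_cohort(seed = 300 + g * 10, n_subjects = 8,
                      coupling_gain_baseline = g, gain_noise_sd = 0,
                      gain_effects = list(age = 0, gender_female = 0,
                                          group = 0, suvr = 0))
    strengths <- c(strengths, coef(bold_csf_coupling(q$signals)))
    gains <- c(gains, rep(g, 16))
  }
  expect_lte(cor(gains, strengths, method = "spearman"), -0.8)
  means <- tapply(strengths, gains, mean)
  expect_true(all(diff(means) < 0))
})
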