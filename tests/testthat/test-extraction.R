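test_that("edge-volume discard keeps the stated interior", {
  expect_length(discard_edge_volumes(rnorm(140), 5), 130)
  expect_length(discard_edge_volumes(rnorm(200), 5), 190)
  x <- rnorm(50)
  expect_identical(discard_edge_volumes(x, 0), x)
  expect_identical(discard_edge_volumes(1:10, 2), 3:8)
  expect_error(discard_edge_volumes(rnorm(10), 5), "too short")
})

test_that("polynomial detrending removes its basis and spares slow sinusoids", {
  t <- seq_len(200)
  quad <- 3 + 0.2 * t - 0.01 * t^2
  expect_lt(max(abs(detrend_poly(quad))), 1e-8 * max(abs(quad)))
  expect_lt(max(abs(detrend_poly(rep(4, 50)))), 1e-10)
  # 0.05 Hz sinusoid over 600 s at 1 s sampling: essentially unchanged
  tt <- seq(0, 599)
  s <- sin(2 * pi * 0.05 * tt)
  expect_gt(cor(detrend_poly(s), s), 0.999)
  expect_error(detrend_poly(rnorm(3), order = 2), "too short")
})

test_that("band-pass is zero-phase with the stated pass/stop behaviour", {
  tr <- 3
  tt <- seq(0, by = tr, length.out = 200)
  probe <- function(f_hz) {
    x <- sin(2 * pi * f_hz * tt)
    y <- bandpass(x, tr)
    # amplitude ratio and phase from the projection onto sin/cos
    a <- 2 * mean(y * sin(2 * pi * f_hz * tt))
    b <- 2 * mean(y * cos(2 * pi * f_hz * tt))
    list(ratio = sqrt(a^2 + b^2), phase = atan2(b, a))
  }
  mid <- probe(0.05)
  expect_gt(mid$ratio, 0.8)
  expect_lt(abs(mid$phase), 0.05)
  expect_lt(probe(0.15)$ratio, 0.2)
  expect_lt(probe(0.002)$ratio, 0.2)
  # constant input -> exactly zero (DC removed)
  expect_lt(max(abs(bandpass(rep(7, 100), tr))), 1e-12)
  expect_lt(abs(mean(bandpass(rnorm(150) + 5, tr))), 1e-12)
  expect_error(bandpass(rnorm(100), tr, high_hz = 0.2), "Nyquist")
  expect_error(bandpass(rnorm(100), tr, low_hz = 0.2, high_hz = 0.1),
               "low_hz")
})

test_that("spatial smoothing applies the requested Gaussian kernel", {
  dims <- c(15, 15, 9)
  arr <- array(0, c(dims, 1))
  arr[8, 8, 5, 1] <- 1
  vol <- volume_series(arr, tr_seconds = 3, voxel_mm = c(3, 3, 3))
  fwhm <- 6
  sm <- spatial_smooth(vol, fwhm)
  # kernel sum preserved for an interior impulse
  expect_equal(sum(sm$data), 1, tolerance = 1e-6)
  # recover sigma from the profile through the impulse
  prof <- sm$data[, 8, 5, 1]
  xs <- seq_along(prof) - 8
  sig_hat <- sqrt(sum(prof * xs^2) / sum(prof))
  sig_true <- (fwhm / 2.3548) / 3
  expect_lt(abs(sig_hat - sig_true) / sig_true, 0.02)
  # fwhm 0 is the identity
  expect_identical(spatial_smooth(vol, 0)$data, arr)
})

test_that("global signal extraction follows the z-then-average convention", {
  set.seed(2)
  nt <- 600
  s <- as.numeric(arima.sim(list(ar = 0.5), nt))
  # perfect synchrony: every masked voxel carries the same series
  arr <- array(0, c(3, 3, 2, nt))
  for (i in 1:3) for (j in 1:2) arr[i, j, 2, ] <- s * (i + j)  # scaled copies
  mask <- array(FALSE, c(3, 3, 2)); mask[1:3, 1:2, 2] <- TRUE
  vol <- volume_series(arr, 3)
  g <- extract_global_signal(vol, region_mask(mask))
  expect_equal(g, (s - mean(s)) / sd(s), tolerance = 1e-10)
  expect_equal(sd(g), 1, tolerance = 1e-10)
  # two independent-noise voxels: SD of the average ~ sqrt(1/2)
  arr2 <- array(rnorm(2 * nt), c(2, 1, 1, nt))
  m2 <- region_mask(array(TRUE, c(2, 1, 1)))
  g2 <- extract_global_signal(volume_series(arr2, 3), m2)
  expect_lt(abs(sd(g2) - sqrt(0.5)), 0.05)
  # errors: empty mask, zero-variance voxel
  expect_error(extract_global_signal(vol,
                                     region_mask(array(FALSE, c(3, 3, 2)))),
               "empty mask")
  arr3 <- arr; arr3[1, 1, 2, ] <- 5
  expect_error(extract_global_signal(volume_series(arr3, 3),
                                     region_mask(mask)),
               "zero temporal variance")
})

test_that("CSF extraction averages then z-scores and polices the bottom slice", {
  set.seed(3)
  nt <- 200
  f <- cumsum(rnorm(nt))
  arr <- array(rnorm(4 * 4 * 3 * nt, sd = 0.01), c(4, 4, 3, nt))
  arr[2, 2, 1, ] <- f
  vol <- volume_series(arr, 3)
  m1 <- array(FALSE, c(4, 4, 3)); m1[2, 2, 1] <- TRUE
  out <- extract_csf_signal(vol, region_mask(m1, "csf-bottom-slice"))
  expect_equal(out, (f - mean(f)) / sd(f), tolerance = 1e-10)
  # mask reaching other slices warns but still computes
  m2 <- m1; m2[2, 3, 2] <- TRUE
  expect_warning(out2 <- extract_csf_signal(vol, region_mask(m2)),
                 "bottom slice")
  expect_length(out2, nt)
  expect_error(extract_csf_signal(vol,
                                  region_mask(array(FALSE, c(4, 4, 3)))),
               "empty mask")
})

test_that("percent change and the negative derivative follow their contracts", {
  expect_equal(percent_change(rep(100, 10)), rep(0, 10))
  expect_equal(percent_change(c(200, 210, 190))[2], 5)
  expect_error(percent_change(c(-1, 1)), "nonzero temporal mean")

  expect_equal(negative_derivative(1 + 0.5 * (1:10), 1), rep(-0.5, 9))
  expect_length(negative_derivative(rnorm(130), 3), 129)
  expect_error(negative_derivative(1, 3), "at least 2")
  # cos(2 pi t / 20) at 1 s sampling: derivative ~ (2 pi / 20) sin(...)
  tt <- 0:399
  d <- negative_derivative(cos(2 * pi * tt / 20), 1)
  expect_lt(max(abs(d - (2 * pi / 20) * sin(2 * pi * tt[-400] / 20))), 0.05)
})

test_that("downstream correlations are invariant to affine rescaling", {
  set.seed(4)
  g <- rnorm(130); f <- rnorm(130)
  cc <- crosscorr(g, f, 21, 3)
  for (ab in list(c(3, 1), c(-2, 5), c(0.1, -4))) {
    cc2 <- crosscorr(ab[1] * g + ab[2], f, 21, 3)
    cc3 <- crosscorr(g, ab[1] * f + ab[2], 21, 3)
    sgn <- sign(ab[1])
    expect_equal(cc2$r, sgn * cc$r, tolerance = 1e-12)
    expect_equal(cc3$r, sgn * cc$r, tolerance = 1e-12)
  }
})

test_that("round trip: assembled volumes reproduce the injected signals", {
  cfg <- sim_config(n_subjects = 2, n_volumes = 80, noise_sd_gm = 0,
                    noise_sd_csf = 0, seed = 5)
  n_t <- 80 * 6
  G0 <- simulate_global_activity(n_t, 0.5, 3, 5, arousal_level = 1,
                                 background_noise_sd = 0.05, seed = 8)
  F_ <- simulate_csf_inflow(G0, 0.5, 3, gain = 1, seed = 9)
  av <- assemble_volume_series(G0, as.numeric(F_), cfg, seed = 10)
  g_ds <- colMeans(matrix(G0, nrow = 6))
  f_ds <- colMeans(matrix(as.numeric(F_), nrow = 6))
  g_hat <- extract_global_signal(av$volumes, av$gm_mask)
  expect_gt(cor(g_hat, (g_ds - mean(g_ds)) / sd(g_ds)), 0.999)
  f_hat <- extract_csf_signal(av$volumes, av$csf_mask)
  expect_gt(cor(f_hat, f_ds), 0.99)
  # masks disjoint by construction; overlap is rejected
  expect_false(any(av$gm_mask$data & av$csf_mask$data))
  bad <- list(gm = av$gm_mask,
              csf = region_mask(av$gm_mask$data, "csf-bottom-slice"))
  expect_error(assemble_volume_series(G0, as.numeric(F_), cfg, masks = bad),
               "overlap")
})

test_that("extract_session_signals output satisfies the series invariants", {
  cfg <- sim_config(n_subjects = 1, n_volumes = 60, seed = 12)
  coh <- simulate_cohort(cfg, signals_only = FALSE)
  s <- extract_session_signals(coh$sessions[[1]]$volumes,
                               coh$sessions[[1]]$gm_mask,
                               coh$sessions[[1]]$csf_mask)
  expect_length(s$global_bold, 50)
  expect_length(s$csf, 50)
  expect_lt(abs(mean(s$global_bold)), 1e-8)
  expect_lte(sd(s$global_bold), 1 + 1e-8)
  expect_identical(s$provenance$order,
                   c("smooth", "bandpass", "detrend", "edge-discard",
                     "extract"))
  # deterministic: same inputs, same output
  s2 <- extract_session_signals(coh$sessions[[1]]$volumes,
                                coh$sessions[[1]]$gm_mask,
                                coh$sessions[[1]]$csf_mask)
  expect_identical(s$global_bold, s2$global_bold)
})

test_that("global-signal SD rises with injected inter-voxel synchrony", {
  set.seed(6)
  nt <- 300
  shared <- as.numeric(arima.sim(list(ar = 0.6), nt))
  sds <- vapply(c(0.25, 1, 4), function(noise) {
    arr <- array(0, c(4, 4, 1, nt))
    for (v in 1:16)
      arr[((v - 1) %% 4) + 1, ((v - 1) %/% 4) + 1, 1, ] <-
        shared + rnorm(nt, sd = noise)
    g <- extract_global_signal(volume_series(arr, 3),
                               region_mask(array(TRUE, c(4, 4, 1))))
    sd(g)
  }, 1)
  expect_true(all(diff(sds) < 0))
  expect_true(all(sds <= 1 + 1e-8))
})
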