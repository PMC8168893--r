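# Synthetic cohort generator.
#
# The generator emulates the stated acquisition world: sessions of 140 or
# 200 volumes at TR = 3 s, a slow (< 0.1 Hz) global signal made of smooth
# arousal-related events, and a CSF inflow signal driven by the delayed
# negative derivative of the global signal with a known per-session gain
# and delay. Covariates are tied to the gain with configured effect sizes
# so that weaker coupling accompanies higher Alzheimer-related risk, which
# lets the downstream pipeline be tested for sign and monotonicity recovery
# without access-restricted imaging data.

#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic cohort
#' generator. All randomness downstream flows from `seed`.
#'
#' @param n_subjects number of subjects (default 60).
#' @param sessions_per_subject sessions per subject (default 2).
#' @param n_volumes volumes per session, conventionally 140 or 200.
#' @param tr_seconds repetition time (default 3), an integer multiple of
#'   `generation_dt`.
#' @param generation_dt generation grid in seconds (default 0.5), finer
#'   than TR so sub-TR delays are representable.
#' @param grid_dims 3D grid for volume mode (default `c(12, 12, 8)`).
#' @param event_rate_per_minute Poisson rate of arousal events (default 3,
#'   one event every ~20 s, as in drowsy-state recordings).
#' @param event_width_seconds Gaussian event-kernel SD (default 5 s; events
#'   then span roughly 10-20 s).
#' @param arousal_level_range per-session arousal scaling drawn uniformly
#'   from this interval (default `c(0.3, 1.7)`, spanning alert to light
#'   sleep).
#' @param background_noise_sd SD of the band-limited (< 0.08 Hz) background
#'   component of the global signal (default 0.1).
#' @param coupling_delay_seconds inflow delay (default 3 s), a multiple of
#'   `generation_dt`.
#' @param coupling_gain_baseline baseline coupling gain `kappa0` (default 1).
#' @param gain_effects named list of covariate effects on the gain deficit:
#'   `age` (per year above 74), `gender_female`, `group` (per ordinal step
#'   HC=0..AD=3), `suvr` (per SUVR unit above 0.88). Larger deficit means
#'   weaker coupling.
#' @param gain_noise_sd SD of the per-session gain noise (default 0.2).
#' @param mmse_decline_per_unit_gain_deficit MMSE points lost over 2 years
#'   per unit of systematic gain deficit (default 2.5).
#' @param noise_sd_gm,noise_sd_csf per-voxel measurement noise SD (default
#'   0.5 each).
#' @param rectify_inflow if `TRUE`, half-wave rectify the inflow drive
#'   (true inflow cannot be negative); default `FALSE` (linear, tractable).
#' @param motion_step_sd_mm SD of the per-frame translation random-walk
#'   steps (default 0.02 mm; rotation steps scaled to the same arc length).
#' @param group_probs sampling probabilities for HC, SMC, MCI, AD.
#' @param n_pseudo_voxels_gm,n_pseudo_voxels_csf pseudo-voxel counts used
#'   by the fast signal-only mode to emulate mask averaging.
#' @param seed integer master seed (default 1).
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 60,
                       sessions_per_subject = 2,
                       n_volumes = 140,
                       tr_seconds = 3.0,
                       generation_dt = 0.5,
                       grid_dims = c(12, 12, 8),
                       event_rate_per_minute = 3,
                       event_width_seconds = 5,
                       arousal_level_range = c(0.3, 1.7),
                       background_noise_sd = 0.1,
                       coupling_delay_seconds = 3.0,
                       coupling_gain_baseline = 1.0,
                       gain_effects = list(age = 0.02, gender_female = 0.15,
                                           group = 0.08, suvr = 1.2),
                       gain_noise_sd = 0.2,
                       mmse_decline_per_unit_gain_deficit = 2.5,
                       noise_sd_gm = 0.5,
                       noise_sd_csf = 0.5,
                       rectify_inflow = FALSE,
                       motion_step_sd_mm = 0.02,
                       group_probs = c(HC = 0.26, SMC = 0.15,
                                       MCI = 0.53, AD = 0.06),
                       n_pseudo_voxels_gm = 24,
                       n_pseudo_voxels_csf = 8,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(is_count(cfg$n_subjects), is_count(cfg$sessions_per_subject),
            is_count(cfg$n_volumes),
            cfg$tr_seconds > 0, cfg$generation_dt > 0,
            length(cfg$grid_dims) == 3L, all(cfg$grid_dims >= 4),
            cfg$event_rate_per_minute > 0, cfg$event_width_seconds > 0,
            length(cfg$arousal_level_range) == 2L,
            cfg$arousal_level_range[1] <= cfg$arousal_level_range[2],
            cfg$arousal_level_range[1] >= 0,
            cfg$coupling_delay_seconds >= 0,
            cfg$coupling_gain_baseline >= 0,
            cfg$gain_noise_sd >= 0, cfg$noise_sd_gm >= 0,
            cfg$noise_sd_csf >= 0, cfg$motion_step_sd_mm >= 0,
            length(cfg$group_probs) == 4L, all(cfg$group_probs >= 0))
  steps <- cfg$tr_seconds / cfg$generation_dt
  if (abs(steps - round(steps)) > 1e-9)
    stop_invalid("tr_seconds must be an integer multiple of generation_dt")
  dsteps <- cfg$coupling_delay_seconds / cfg$generation_dt
  if (abs(dsteps - round(dsteps)) > 1e-9)
    stop_invalid("coupling_delay_seconds must be a multiple of generation_dt")
  needed <- c("age", "gender_female", "group", "suvr")
  missing <- setdiff(needed, names(cfg$gain_effects))
  if (length(missing))
    stop_invalid("gain_effects is missing: %s", paste(missing, collapse = ", "))
  cfg$group_probs <- cfg$group_probs / sum(cfg$group_probs)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d subjects x %d sessions, %d volumes at TR %g s (dt %g s)\n",
              x$n_subjects, x$sessions_per_subject, x$n_volumes,
              x$tr_seconds, x$generation_dt))
  cat(sprintf("  gain %g - deficit (age %g/yr, female %g, group %g/step, suvr %g) , delay %g s, seed %d\n",
              x$coupling_gain_baseline, x$gain_effects$age,
              x$gain_effects$gender_female, x$gain_effects$group,
              x$gain_effects$suvr, x$coupling_delay_seconds, x$seed))
  invisible(x)
}

#' Simulate the slow global activity signal
#'
#' A sum of Gaussian event kernels at Poisson-distributed onsets (the
#' arousal-related events behind large global signal excursions), with
#' amplitudes scaled by `arousal_level`, plus band-limited (< 0.08 Hz)
#' background noise. The dominant power sits below 0.1 Hz.
#'
#' @param n_t number of samples (>= 2).
#' @param dt sampling interval in seconds (> 0).
#' @param event_rate_per_minute Poisson event rate.
#' @param event_width_seconds Gaussian kernel SD in seconds.
#' @param arousal_level scales event amplitudes; 0 disables events.
#' @param background_noise_sd SD of the band-limited background (0 = off).
#' @param seed optional RNG seed.
#' @return numeric series of length `n_t`.
#' @export
simulate_global_activity <- function(n_t, dt, event_rate_per_minute = 1,
                                     event_width_seconds = 5,
                                     arousal_level = 1,
                                     background_noise_sd = 0.1,
                                     seed = NULL) {
  if (!is_count(n_t) || n_t < 2) stop_invalid("n_t must be an integer >= 2")
  if (!is.numeric(dt) || dt <= 0) stop_invalid("dt must be positive")
  with_seed(seed, {
    tt <- (seq_len(n_t) - 1) * dt
    total_s <- n_t * dt
    g <- numeric(n_t)
    if (arousal_level > 0) {
      n_ev <- stats::rpois(1L, event_rate_per_minute * total_s / 60)
      if (n_ev > 0) {
        onsets <- stats::runif(n_ev, 0, total_s)
        amps <- arousal_level * stats::rlnorm(n_ev, 0, 0.25)
        for (e in seq_len(n_ev))
          g <- g + amps[e] *
            exp(-(tt - onsets[e])^2 / (2 * event_width_seconds^2))
      }
    }
    if (background_noise_sd > 0) {
      bg <- bandpass(stats::rnorm(n_t), dt,
                     low_hz = max(1 / total_s, 0.005), high_hz = 0.08)
      s <- stats::sd(bg)
      if (s > 0) g <- g + background_noise_sd * bg / s
    }
    g
  })
}

#' Simulate the CSF inflow signal from a global activity signal
#'
#' `F(t) = gain * r(-G0'(t - delay)) + noise`, where `G0'` is the centred
#' finite-difference derivative of the global activity and `r` is the
#' identity (default) or half-wave rectification (`rectify = TRUE`; physical
#' inflow cannot be negative). Samples whose delayed derivative is undefined
#' (the first `delay/dt + 1` and the last one) are zero-filled and flagged
#' in the `"edge_samples"` attribute.
#'
#' @param G0 global activity series on the `dt` grid.
#' @param dt sampling interval in seconds.
#' @param delay_seconds inflow delay, a multiple of `dt`.
#' @param gain coupling gain (>= 0 in cohort use; any real accepted here).
#' @param rectify half-wave rectify the drive.
#' @param noise_sd additive white-noise SD.
#' @param seed optional RNG seed.
#' @return numeric series aligned to `G0`'s time grid.
#' @export
simulate_csf_inflow <- function(G0, dt, delay_seconds = 3, gain = 1,
                                rectify = FALSE, noise_sd = 0,
                                seed = NULL) {
  stopifnot(is.numeric(G0), dt > 0, delay_seconds >= 0)
  dlag <- delay_seconds / dt
  if (abs(dlag - round(dlag)) > 1e-9)
    stop_invalid("delay_seconds (%g) must be a multiple of dt (%g)",
                 delay_seconds, dt)
  dlag <- as.integer(round(dlag))
  n <- length(G0)
  if (n < dlag + 2) stop_invalid("G0 too short for a %g s delay", delay_seconds)
  # centred derivative, defined for t = 2..n-1
  dG <- c(NA_real_, (G0[3:n] - G0[1:(n - 2)]) / (2 * dt), NA_real_)
  drive <- rep(NA_real_, n)
  idx <- (dlag + 1):n
  drive[idx] <- -dG[idx - dlag]
  edge <- which(is.na(drive))
  drive[edge] <- 0
  if (rectify) drive <- pmax(drive, 0)
  f <- with_seed(seed, gain * drive +
                   if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0)
  attr(f, "edge_samples") <- edge
  f
}

# default gray-matter and bottom-slice CSF masks for a generation grid
default_sim_masks <- function(grid_dims) {
  nx <- grid_dims[1]; ny <- grid_dims[2]; nz <- grid_dims[3]
  gm <- array(FALSE, grid_dims)
  gm[3:(nx - 2), 3:(ny - 2), 3:(nz - 1)] <- TRUE
  csf <- array(FALSE, grid_dims)
  cx <- floor(nx / 2); cy <- floor(ny / 2)
  csf[(cx - 1):(cx + 2), cy:(cy + 1), 1] <- TRUE
  list(gm = region_mask(gm, "gray-matter"),
       csf = region_mask(csf, "csf-bottom-slice"))
}

#' Assemble a 4D volume series from a signal pair
#'
#' The inverse of mask-based extraction: gray-matter voxels carry
#' `loading_v * G0` plus iid noise (positive log-normal loadings drawn once
#' per voxel), bottom-slice CSF voxels carry `F` plus iid noise, all other
#' voxels are zero. Both series are block-averaged from the generation grid
#' `dt` to the TR grid before assembly.
#'
#' @param G0,F signal pair on the `generation_dt` grid (see
#'   [simulate_global_activity()], [simulate_csf_inflow()]).
#' @param config a [sim_config()].
#' @param masks optional list with `gm` and `csf` [region_mask()]s
#'   (defaults are built from `config$grid_dims`); they must not overlap.
#' @param seed optional RNG seed for loadings and noise.
#' @return list with `volumes` (a [volume_series()]), `gm_mask`, `csf_mask`
#'   and `loading_map` (3D array; the synthetic arousal template).
#' @export
assemble_volume_series <- function(G0, F, config, masks = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), length(G0) == length(F))
  if (is.null(masks)) masks <- default_sim_masks(config$grid_dims)
  gm <- masks$gm; csf <- masks$csf
  stopifnot(inherits(gm, "region_mask"), inherits(csf, "region_mask"))
  if (any(gm$data & csf$data))
    stop_invalid("gray-matter and CSF masks overlap")
  csf_slices <- unique(which(csf$data, arr.ind = TRUE)[, 3L])
  if (any(csf_slices != 1L))
    stop_invalid("CSF mask must be confined to the lowest slice")
  steps <- as.integer(round(config$tr_seconds / config$generation_dt))
  g_ds <- block_average(G0, steps)
  f_ds <- block_average(F, steps)
  nt <- length(g_ds)
  dims <- config$grid_dims
  with_seed(seed, {
    arr <- array(0, c(dims, nt))
    flat <- matrix(arr, ncol = nt)
    gm_idx <- which(gm$data); csf_idx <- which(csf$data)
    loadings <- stats::rlnorm(length(gm_idx), 0, 0.2)
    flat[gm_idx, ] <- loadings %o% g_ds +
      matrix(stats::rnorm(length(gm_idx) * nt, 0, config$noise_sd_gm),
             nrow = length(gm_idx))
    flat[csf_idx, ] <- rep(f_ds, each = length(csf_idx)) +
      matrix(stats::rnorm(length(csf_idx) * nt, 0, config$noise_sd_csf),
             nrow = length(csf_idx))
    loading_map <- array(0, dims)
    loading_map[gm_idx] <- loadings
    list(volumes = volume_series(array(flat, c(dims, nt)),
                                 tr_seconds = config$tr_seconds),
         gm_mask = gm, csf_mask = csf, loading_map = loading_map)
  })
}

# covariate draws for one subject; group-dependent means follow the cohort
# characteristics table of the source study population
.group_levels <- c("HC", "SMC", "MCI", "AD")
.suvr_mean <- c(HC = 0.82, SMC = 0.83, MCI = 0.90, AD = 1.08)
.suvr_sd   <- c(HC = 0.13, SMC = 0.10, MCI = 0.14, AD = 0.07)
.mmse_mean <- c(HC = 28.8, SMC = 29.2, MCI = 28.0, AD = 22.0)
.mmse_sd   <- c(HC = 1.3,  SMC = 0.9,  MCI = 2.0,  AD = 2.4)
.apoe_p    <- c(HC = 0.18, SMC = 0.15, MCI = 0.25, AD = 0.6)

#' Simulate a synthetic cohort
#'
#' Draws subjects (age, gender, diagnostic group, APOE e4 count, baseline
#' and follow-up amyloid SUVR and MMSE), assigns each session a coupling
#' gain `kappa = max(0, kappa0 - deficit)` where the deficit is a linear
#' combination of the covariates plus noise, and generates the session
#' signals with that gain. Follow-up MMSE declines in proportion to the
#' subject's systematic gain deficit. In the default fast mode each session
#' is a small set of pseudo-voxel time courses (so the voxelwise
#' z-score-then-average amplitude convention behaves as in volume mode); in
#' volume mode full 4D series are assembled via [assemble_volume_series()].
#'
#' @param config a [sim_config()].
#' @param signals_only `TRUE` (default) for the fast pseudo-voxel mode;
#'   `FALSE` assembles full 4D volumes.
#' @return an object of class `csf_cohort`: `sessions` (per-session raw
#'   materials), `table` (cohort data.frame), `truth` (per-session injected
#'   gain, delay, arousal; effects in `attr(truth, "effects")`), `config`.
#' @export
simulate_cohort <- function(config, signals_only = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    ns <- config$n_subjects
    spp <- config$sessions_per_subject
    eff <- config$gain_effects
    grp <- sample(.group_levels, ns, replace = TRUE, prob = config$group_probs)
    subj <- data.frame(
      subject_id = sprintf("S%03d", seq_len(ns)),
      group = grp,
      age = round(stats::rnorm(ns, 74, 6), 1),
      gender = ifelse(stats::runif(ns) < 0.5, "F", "M"),
      apoe_e4_count = stats::rbinom(ns, 2L, .apoe_p[grp]),
      suvr_base = round(stats::rnorm(ns, .suvr_mean[grp], .suvr_sd[grp]), 3),
      stringsAsFactors = FALSE)
    subj$suvr_fu <- round(subj$suvr_base + stats::rnorm(ns, 0.015, 0.04), 3)
    subj$mmse_base <- pmin(30L, pmax(0L, as.integer(round(
      stats::rnorm(ns, .mmse_mean[grp], .mmse_sd[grp])))))
    gscore <- match(subj$group, .group_levels) - 1L
    deficit_sys <- eff$age * (subj$age - 74) +
      eff$gender_female * (subj$gender == "F") +
      eff$group * gscore +
      eff$suvr * (subj$suvr_base - 0.88)
    subj$mmse_fu <- pmin(30L, pmax(0L, as.integer(round(
      subj$mmse_base -
        config$mmse_decline_per_unit_gain_deficit * deficit_sys +
        stats::rnorm(ns, 0, 1.5)))))

    steps <- as.integer(round(config$tr_seconds / config$generation_dt))
    n_t <- config$n_volumes * steps
    n_sess <- ns * spp
    # all non-signal session randomness drawn up front so that the cohort
    # table and ground truth are identical across generator modes
    kappa_all <- pmax(0, config$coupling_gain_baseline -
                        rep(deficit_sys, each = spp) -
                        stats::rnorm(n_sess, 0, config$gain_noise_sd))
    arousal_all <- stats::runif(n_sess, config$arousal_level_range[1],
                                config$arousal_level_range[2])
    batch_all <- sample(c("ADNI2", "ADNI3", "ADNIGO"), n_sess,
                        replace = TRUE, prob = c(0.85, 0.10, 0.05))
    rows <- vector("list", n_sess)
    sessions <- vector("list", n_sess)
    truth <- vector("list", n_sess)
    k <- 0L
    for (i in seq_len(ns)) {
      for (s in seq_len(spp)) {
        k <- k + 1L
        kappa <- kappa_all[k]
        arousal <- arousal_all[k]
        G0 <- simulate_global_activity(n_t, config$generation_dt,
                                       config$event_rate_per_minute,
                                       config$event_width_seconds,
                                       arousal_level = arousal,
                                       background_noise_sd =
                                         config$background_noise_sd)
        F_ <- simulate_csf_inflow(G0, config$generation_dt,
                                  config$coupling_delay_seconds,
                                  gain = kappa,
                                  rectify = config$rectify_inflow,
                                  noise_sd = 0)
        motion <- apply(matrix(stats::rnorm(config$n_volumes * 6L, 0,
                                            rep(c(config$motion_step_sd_mm,
                                                  config$motion_step_sd_mm / 50),
                                                each = 3L * config$n_volumes)),
                               ncol = 6L), 2L, cumsum)
        sid <- sprintf("%s_V%02d", subj$subject_id[i], s)
        if (signals_only) {
          g_ds <- block_average(G0, steps)
          f_ds <- block_average(as.numeric(F_), steps)
          vg <- config$n_pseudo_voxels_gm
          vc <- config$n_pseudo_voxels_csf
          loadings <- stats::rlnorm(vg, 0, 0.2)
          g_mat <- g_ds %o% loadings +
            matrix(stats::rnorm(length(g_ds) * vg, 0, config$noise_sd_gm),
                   ncol = vg)
          f_mat <- matrix(f_ds, nrow = length(f_ds), ncol = vc) +
            matrix(stats::rnorm(length(f_ds) * vc, 0, config$noise_sd_csf),
                   ncol = vc)
          sessions[[k]] <- list(session_id = sid, g_mat = g_mat,
                                f_mat = f_mat, motion = motion,
                                tr_seconds = config$tr_seconds)
        } else {
          av <- assemble_volume_series(G0, as.numeric(F_), config)
          sessions[[k]] <- list(session_id = sid, volumes = av$volumes,
                                gm_mask = av$gm_mask, csf_mask = av$csf_mask,
                                loading_map = av$loading_map, motion = motion,
                                tr_seconds = config$tr_seconds)
        }
        rows[[k]] <- data.frame(subject_id = subj$subject_id[i],
                                session_id = sid, group = subj$group[i],
                                age = subj$age[i], gender = subj$gender[i],
                                apoe_e4_count = subj$apoe_e4_count[i],
                                suvr_base = subj$suvr_base[i],
                                suvr_fu = subj$suvr_fu[i],
                                mmse_base = subj$mmse_base[i],
                                mmse_fu = subj$mmse_fu[i],
                                batch = batch_all[k],
                                stringsAsFactors = FALSE)
        truth[[k]] <- data.frame(session_id = sid,
                                 subject_id = subj$subject_id[i],
                                 kappa = kappa,
                                 delay_seconds = config$coupling_delay_seconds,
                                 arousal_level = arousal,
                                 gain_deficit_systematic = deficit_sys[i],
                                 stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, truth)
    attr(truth, "effects") <- eff
    structure(list(sessions = sessions,
                   table = do.call(rbind, rows),
                   truth = truth,
                   signals_only = signals_only,
                   config = config),
              class = "csf_cohort")
  })
}

#' @export
print.csf_cohort <- function(x, ...) {
  cat(sprintf("<csf_cohort> %d sessions from %d subjects (%s mode), seed %d\n",
              nrow(x$table), length(unique(x$table$subject_id)),
              if (x$signals_only) "signal-only" else "volume",
              x$config$seed))
  print(table(x$table$group))
  invisible(x)
}

# run the temporal pipeline on pseudo-voxel matrices (the signal-only
# analogue of extract_session_signals: z-then-average for gray matter,
# average-then-z for CSF)
process_session_matrices <- function(g_mat, f_mat, tr_seconds,
                                     low_hz = 0.01, high_hz = 0.1,
                                     detrend_order = 2, n_edge = 5) {
  pipe <- function(m) {
    m <- bandpass_matrix(m, tr_seconds, low_hz, high_hz)
    m <- detrend_poly_matrix(m, detrend_order)
    m[(n_edge + 1):(nrow(m) - n_edge), , drop = FALSE]
  }
  g <- pipe(g_mat); f <- pipe(f_mat)
  session_signals(global_bold = rowMeans(scale(g)),
                  csf = zscore(rowMeans(f)),
                  tr_seconds = tr_seconds,
                  n_discarded_edge_volumes = n_edge,
                  provenance = list(bandpass_hz = c(low_hz, high_hz),
                                    detrend_order = detrend_order,
                                    edge_discard = n_edge,
                                    order = c("bandpass", "detrend",
                                              "edge-discard", "extract")))
}

#' Extract session signals for a whole synthetic cohort
#'
#' Runs the temporal preprocessing and extraction stage on every session of
#' a [simulate_cohort()] result, in either mode.
#'
#' @param cohort a `csf_cohort`.
#' @param ... passed to [extract_session_signals()] /
#'   [process_session_matrices()] (band edges, detrend order, `n_edge`).
#' @return named list of [session_signals()], one per session.
#' @export
extract_cohort_signals <- function(cohort, ...) {
  stopifnot(inherits(cohort, "csf_cohort"))
  out <- lapply(cohort$sessions, function(s) {
    if (cohort$signals_only)
      process_session_matrices(s$g_mat, s$f_mat, s$tr_seconds, ...)
    else
      extract_session_signals(s$volumes, s$gm_mask, s$csf_mask, ...)
  })
  names(out) <- vapply(cohort$sessions, `[[`, "", "session_id")
  out
}
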