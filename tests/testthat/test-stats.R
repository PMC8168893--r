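test_that("longitudinal change and SUVR arithmetic", {
  expect_equal(longitudinal_change(0.90, 0.91), 0.01)
  expect_equal(longitudinal_change(5, 5), 0)
  expect_equal(longitudinal_change(28, 26), -2)    # decline coded negative
  expect_true(is.na(longitudinal_change(NA, 26)))

  expect_equal(compute_suvr(1.0, 1.0), 1.0)
  expect_equal(compute_suvr(0.9, 1.0), 0.9)
  expect_equal(compute_suvr(3 * 0.9, 3 * 1.0), compute_suvr(0.9, 1.0))
  expect_error(compute_suvr(1, 0), "positive")
})

test_that("pooled two-sample t from summaries matches oracles", {
  r <- two_sample_t(10, 1, 10, 11, 1, 10)
  expect_equal(r$t, -2.2360679, tolerance = 1e-6)
  expect_equal(r$df, 18)
  expect_equal(r$p, 2 * pt(-sqrt(5), 18), tolerance = 1e-12)
  expect_equal(round(r$p, 3), 0.038)
  # identical groups
  r0 <- two_sample_t(5, 2, 8, 5, 2, 8)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # summary-statistic route equals the raw-data pooled t test
  set.seed(41)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  raw <- t.test(x, y, var.equal = TRUE)
  smry <- two_sample_t(mean(x), sd(x), 12, mean(y), sd(y), 15)
  expect_equal(smry$t, unname(raw$statistic), tolerance = 1e-10)
  expect_equal(smry$p, raw$p.value, tolerance = 1e-10)
  expect_error(two_sample_t(1, 1, 1, 2, 1, 5), ">= 2")
})

test_that("fisher exact matches full enumeration and stats::fisher.test", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1.0)
  expect_equal(fisher_exact_2x2(2, 3, 3, 2), 1.0)
  set.seed(17)
  for (i in 1:40) {
    n <- sample(4:40, 1)
    cells <- as.vector(rmultinom(1, n, runif(4, 0.05, 1)))
    if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0 ||
        sum(cells[c(1, 3)]) == 0 || sum(cells[c(2, 4)]) == 0) next
    ours <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])
    ref <- fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-10)
  }
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "nonnegative")
  expect_error(fisher_exact_2x2(0, 0, 3, 4), "margin")
})

test_that("adjust_outcome removes nuisance contributions", {
  set.seed(23)
  n_subj <- 100
  tab <- data.frame(subject_id = rep(sprintf("S%03d", 1:n_subj), each = 2),
                    session_id = sprintf("V%03d", 1:(2 * n_subj)),
                    age = rep(rnorm(n_subj, 74, 6), each = 2),
                    gender = rep(sample(c("M", "F"), n_subj, TRUE), each = 2))
  u <- rep(rnorm(n_subj, 0, 0.5), each = 2)
  # outcome driven purely by age
  tab$y <- 2 * tab$age + u + rnorm(200, 0, 0.5)
  adj <- adjust_outcome(tab, "y", "age")
  expect_lt(abs(cor(adj, tab$age, method = "spearman")), 0.1)
  # null covariate effects: adjusted ~ raw
  tab$y2 <- u + rnorm(200)
  adj2 <- adjust_outcome(tab, "y2", c("age", "gender"))
  expect_gt(cor(adj2, tab$y2), 0.99)
  # one session per subject: equals OLS residualisation (+ intercept)
  t1 <- tab[seq(1, 200, 2), ]
  adj3 <- adjust_outcome(t1, "y", "age")
  ols <- residuals(lm(y ~ age, t1)) + coef(lm(y ~ age, t1))[1]
  expect_equal(unname(adj3), unname(ols), tolerance = 1e-6)
  # rank-deficient designs are named
  t1$age2 <- t1$age
  expect_error(lmm_ri(t1$y, cbind(1, a = t1$age, b = t1$age2),
                      t1$subject_id), "collinear")
})

test_that("association returns rho and Satterthwaite p with exact cases", {
  set.seed(29)
  n_subj <- 60
  tab <- data.frame(subject_id = rep(1:n_subj, each = 2),
                    session_id = 1:(2 * n_subj),
                    x = rep(rnorm(n_subj), each = 2))
  tab$y <- tab$x                                  # identity
  r <- association(tab, "y", "x")
  expect_equal(r$spearman_rho, 1)
  expect_lt(r$lmm_p, 1e-10)
  # constant predictor rejected
  tab$c1 <- 1
  expect_error(association(tab, "y", "c1"), "constant")
  # monotone-transform invariance of Spearman
  tab$y2 <- tab$x + rep(rnorm(n_subj, 0, 0.4), each = 2) + rnorm(120, 0, 0.4)
  r1 <- association(tab, "y2", "x")
  tab$x3 <- exp(tab$x)
  r2 <- association(tab, "y2", "x3")
  expect_equal(r1$spearman_rho, r2$spearman_rho, tolerance = 1e-12)
})

test_that("mixed-model p reduces to simple regression when subjects are unique", {
  set.seed(37)
  n <- 80
  tab <- data.frame(subject_id = 1:n, session_id = 1:n,
                    x = rnorm(n))
  tab$y <- 0.3 * tab$x + rnorm(n)
  r <- association(tab, "y", "x")
  ref <- summary(lm(y ~ x, tab))$coefficients["x", 4]
  expect_lt(abs(r$lmm_p - ref), 1e-4)
  expect_identical(r$method, "ols")
})

test_that("satterthwaite df equals the closed form on balanced designs", {
  # balanced two-session design with a between-subject predictor:
  # Satterthwaite df = n_subjects - p exactly
  set.seed(43)
  for (m in c(20, 50)) {
    x <- rep(rnorm(m), each = 2)
    y <- 0.4 * x + rep(rnorm(m, 0, 1), each = 2) + rnorm(2 * m, 0, 0.6)
    fit <- lmm_ri(y, cbind(1, x = x), rep(1:m, each = 2))
    expect_identical(fit$method, "satterthwaite")
    expect_equal(unname(fit$coefficients["x", "df"]), m - 2,
                 tolerance = 0.02)
  }
})

test_that("group trend: direction, symmetry, separation, contrasts", {
  set.seed(47)
  grp <- sample(c("HC", "SMC", "MCI", "AD"), 120, TRUE)
  tab <- data.frame(subject_id = 1:120, session_id = 1:120, group = grp,
                    age = rnorm(120, 74, 6),
                    gender = sample(c("M", "F"), 120, TRUE))
  score <- match(grp, c("HC", "SMC", "MCI", "AD")) - 1
  # noise-free increase across groups: overwhelming significance
  tab$y <- score * 1.0
  r <- group_trend(tab, "y")
  expect_lt(r$lmm_p, 1e-6)
  expect_gt(r$estimate, 0)
  pw <- attr(r, "pairwise")
  expect_true(all(c("group1", "group2", "p") %in% names(pw)))
  expect_equal(nrow(pw), 6)
  # reversing the coding flips the sign, keeps the p-value
  tab$y2 <- tab$y + rnorm(120, 0, 0.5)
  r1 <- group_trend(tab, "y2")
  tab$group <- c("HC" = "AD", "SMC" = "MCI", "MCI" = "SMC",
                 "AD" = "HC")[tab$group]
  r2 <- group_trend(tab, "y2")
  expect_equal(r1$estimate, -r2$estimate, tolerance = 1e-8)
  expect_equal(r1$lmm_p, r2$lmm_p, tolerance = 1e-8)
  expect_error(group_trend(tab[tab$group == "AD", ], "y2"), "2 groups")
})

test_that("subject-level view keeps one earliest session per subject", {
  tab <- data.frame(subject_id = c("B", "A", "A", "C", "B"),
                    session_id = c("B_V02", "A_V02", "A_V01", "C_V01",
                                   "B_V01"),
                    x = 1:5)
  red <- subject_level_view(tab)
  expect_equal(nrow(red), 3)
  expect_setequal(red$session_id, c("A_V01", "B_V01", "C_V01"))
  # single-session subjects retained
  expect_true("C_V01" %in% red$session_id)
})

test_that("lag-wise profile is consistent with the scalar association", {
  q <- quick_cohort(seed = 71, n_subjects = 40)
  tab <- q$cohort$table
  fit <- bold_csf_coupling(q$signals)
  tab$coupling <- coef(fit)
  lag_mat <- do.call(rbind, lapply(fit$ccfs, `[[`, "r"))
  colnames(lag_mat) <- csfcoupling:::lag_col_name(fit$mean$lags_seconds)
  tab <- cbind(tab, lag_mat)
  prof <- lagwise_association_profile(tab, "suvr_base", c("age", "gender"))
  expect_equal(nrow(prof), 15)
  scalar <- association(tab, "coupling", "suvr_base", c("age", "gender"))
  row3 <- prof[prof$lag_s == 3, ]
  expect_equal(row3$spearman_rho, scalar$spearman_rho, tolerance = 1e-12)
  expect_equal(row3$lmm_p, scalar$lmm_p, tolerance = 1e-12)
})

test_that("run_full_analysis covers the battery and is deterministic", {
  q <- quick_cohort(seed = 83, n_subjects = 30)
  tab <- q$cohort$table
  fit <- bold_csf_coupling(q$signals)
  tab$coupling <- coef(fit)
  met <- session_metrics(q$signals,
                         motion = lapply(q$cohort$sessions, `[[`, "motion"))
  tab <- cbind(tab, met)
  b1 <- run_full_analysis(tab)
  b2 <- run_full_analysis(tab)
  expect_identical(b1$results, b2$results)
  expect_s3_class(b1, "coupling_battery")
  expect_gt(nrow(b1$results), 20)
  expect_true(all(c("risk", "marker", "arousal") %in% b1$results$analysis))
  expect_true(all(b1$results$lmm_p > 0 & b1$results$lmm_p <= 1))
  expect_true(all(abs(b1$results$spearman_rho) <= 1))
  # effective n reported per cell
  expect_true(all(b1$results$n_sessions <= nrow(tab)))
  expect_equal(nrow(b1$subject_level), 4)
  # missing required columns are named
  expect_error(run_full_analysis(tab[, setdiff(names(tab), "coupling")]),
               "coupling")
})
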