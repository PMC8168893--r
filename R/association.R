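# Covariate-adjusted association battery.
#
# Convention used throughout: session-level analyses fit a linear mixed
# model with a subject random intercept (lmm_ri); the reported effect-size
# descriptor is the Spearman correlation between the nuisance-adjusted
# outcome and the predictor, while significance always comes from the full
# mixed model with the predictor included. "Adjusted" means the outcome
# minus the nuisance fixed-effect contributions, intercept retained.

.group_score <- function(g) match(g, .group_levels) - 1L

# numeric coding for predictors/markers
covariate_numeric <- function(table, var) {
  v <- table[[var]]
  switch(var,
         gender = as.numeric(v == "F"),
         group = as.numeric(.group_score(v)),
         as.numeric(v))
}

# design matrix (with intercept) for nuisance covariates; group and batch
# enter as factors, gender as a female indicator
build_design <- function(table, vars) {
  n <- nrow(table)
  if (!length(vars)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  cols <- lapply(vars, function(v) {
    x <- table[[v]]
    if (v == "gender") factor(x, levels = c("M", "F"))
    else if (v == "group") factor(x, levels = .group_levels)
    else if (v == "batch") factor(x)
    else as.numeric(x)
  })
  names(cols) <- vars
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  # drop unused factor levels so the design stays full rank
  df[] <- lapply(df, function(x) if (is.factor(x)) droplevels(x) else x)
  stats::model.matrix(~ ., data = df)
}

check_columns <- function(table, cols) {
  miss <- setdiff(cols, names(table))
  if (length(miss))
    stop_invalid("missing required column(s): %s", paste(miss, collapse = ", "))
}

#' Adjust an outcome for nuisance covariates under a subject random intercept
#'
#' Fits `outcome ~ nuisance + (1 | subject)` and returns the outcome minus
#' the fixed-effect contribution of the nuisance covariates (intercept
#' retained). Rows with missing outcome or covariates come back as `NA`.
#'
#' @param table cohort data.frame (see [read_session_table()] for columns).
#' @param outcome outcome column name.
#' @param nuisance_covariates character vector of covariate columns (may be
#'   empty, in which case the outcome is returned unchanged).
#' @param subject_col subject identifier column (default `"subject_id"`).
#' @return numeric vector, same length as `nrow(table)`.
#' @export
adjust_outcome <- function(table, outcome, nuisance_covariates = character(),
                           subject_col = "subject_id") {
  check_columns(table, c(outcome, nuisance_covariates, subject_col))
  y <- as.numeric(table[[outcome]])
  if (!length(nuisance_covariates)) return(y)
  X <- build_design(table, nuisance_covariates)
  ok <- stats::complete.cases(cbind(y, X)) & !is.na(table[[subject_col]])
  if (sum(ok) < ncol(X) + 2)
    stop_invalid("too few complete rows (%d) to adjust for %s", sum(ok),
                 paste(nuisance_covariates, collapse = ", "))
  fit <- lmm_ri(y[ok], X[ok, , drop = FALSE], table[[subject_col]][ok])
  beta <- fit$coefficients[, "estimate"]
  out <- rep(NA_real_, length(y))
  contrib <- X[ok, -1L, drop = FALSE] %*% beta[-1L]
  out[ok] <- y[ok] - drop(contrib)
  out
}

#' Covariate-adjusted association between an outcome and a predictor
#'
#' Computes (i) the Spearman correlation between the nuisance-adjusted
#' outcome and the predictor and (ii) the mixed-model p-value for the
#' predictor from `outcome ~ predictor + nuisance + (1 | subject)` with
#' Satterthwaite degrees of freedom (see [lmm_ri()]).
#'
#' @inheritParams adjust_outcome
#' @param predictor predictor column name (`gender` is coded as a female
#'   indicator, `group` as the ordinal severity score HC=0..AD=3).
#' @param simple_regression if `TRUE`, ignore the subject structure and use
#'   ordinary least squares (the subject-based variant).
#' @return an `association_result`: one-row data.frame with `outcome`,
#'   `predictor`, `covariates`, `spearman_rho`, `estimate`, `lmm_p`, `df`,
#'   `n_sessions`, `n_subjects`, `method`.
#' @export
association <- function(table, outcome, predictor,
                        nuisance_covariates = character(),
                        subject_col = "subject_id",
                        simple_regression = FALSE) {
  check_columns(table, c(outcome, predictor, nuisance_covariates, subject_col))
  y <- as.numeric(table[[outcome]])
  x <- covariate_numeric(table, predictor)
  Xn <- build_design(table, nuisance_covariates)
  ok <- stats::complete.cases(cbind(y, x, Xn)) & !is.na(table[[subject_col]])
  n <- sum(ok)
  if (n < ncol(Xn) + 3)
    stop_invalid("too few complete rows (%d) for %s ~ %s", n, outcome,
                 predictor)
  if (stats::sd(x[ok]) == 0)
    stop_invalid("predictor %s is constant on the analysis rows", predictor)
  sub <- table[ok, , drop = FALSE]
  adj <- adjust_outcome(sub, outcome, nuisance_covariates, subject_col)
  rho <- stats::cor(adj, x[ok], method = "spearman", use = "complete.obs")
  X <- cbind(Xn[ok, , drop = FALSE], predictor = x[ok])
  colnames(X)[ncol(X)] <- predictor
  subj <- if (simple_regression) seq_len(n) else sub[[subject_col]]
  fit <- lmm_ri(y[ok], X, subj)
  cf <- fit$coefficients[predictor, ]
  structure(data.frame(outcome = outcome, predictor = predictor,
                       covariates = paste(nuisance_covariates,
                                          collapse = "+"),
                       spearman_rho = rho,
                       estimate = unname(cf["estimate"]),
                       lmm_p = unname(cf["p"]),
                       df = unname(cf["df"]),
                       n_sessions = n,
                       n_subjects = fit$n_subjects,
                       method = fit$method,
                       stringsAsFactors = FALSE),
            class = c("association_result", "data.frame"))
}

#' Dose-response trend of an outcome across diagnostic groups
#'
#' Treats the ordered conditions HC < SMC < MCI < AD as a linear severity
#' score 0-3 in the mixed model (the monotone dose-response contrast) and
#' additionally reports all pairwise group contrasts.
#'
#' @inheritParams association
#' @return an `association_result` for the linear trend, with a
#'   `data.frame` of pairwise contrasts in `attr(, "pairwise")`.
#' @export
group_trend <- function(table, outcome, nuisance_covariates = character(),
                        subject_col = "subject_id") {
  check_columns(table, c(outcome, "group"))
  present <- intersect(.group_levels, unique(table$group))
  if (length(present) < 2L)
    stop_invalid("group trend needs at least 2 groups, found %d",
                 length(present))
  res <- association(table, outcome, "group", nuisance_covariates,
                     subject_col)
  pairs <- utils::combn(present, 2L, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    sub <- table[table$group %in% pr, , drop = FALSE]
    sub$.contrast <- as.numeric(sub$group == pr[2L])
    out <- tryCatch(
      association(sub, outcome, ".contrast", nuisance_covariates,
                  subject_col),
      error = function(e) NULL)
    if (is.null(out)) return(NULL)
    data.frame(group1 = pr[1L], group2 = pr[2L],
               estimate = out$estimate, p = out$lmm_p,
               n = out$n_sessions, stringsAsFactors = FALSE)
  }))
  attr(res, "pairwise") <- pw
  res
}

#' Lag-wise association profile
#'
#' Re-runs [association()] using the cross-correlation value at every lag
#' (columns `ccf_lag_m6`, `ccf_lag_0`, `ccf_lag_p3`, ...) as the outcome,
#' against one marker, and flags the lags with `p < 0.05`.
#'
#' @inheritParams association
#' @param marker marker column used as the predictor at every lag.
#' @param lag_prefix prefix of the per-lag outcome columns.
#' @return data.frame with `lag_s`, `spearman_rho`, `lmm_p`, `significant`.
#' @export
lagwise_association_profile <- function(table, marker,
                                        nuisance_covariates = character(),
                                        subject_col = "subject_id",
                                        lag_prefix = "ccf_lag_") {
  cols <- grep(paste0("^", lag_prefix), names(table), value = TRUE)
  if (!length(cols))
    stop_invalid("no per-lag columns with prefix '%s' in the table",
                 lag_prefix)
  lag_of <- function(cl) {
    s <- sub(lag_prefix, "", cl, fixed = TRUE)
    sign <- if (startsWith(s, "m")) -1 else 1
    as.numeric(sub("^[mp]", "", s)) * sign
  }
  lags <- vapply(cols, lag_of, 1)
  ord <- order(lags)
  rows <- lapply(cols[ord], function(cl)
    association(table, cl, marker, nuisance_covariates, subject_col))
  data.frame(lag_s = lags[ord],
             spearman_rho = vapply(rows, `[[`, 1, "spearman_rho"),
             lmm_p = vapply(rows, `[[`, 1, "lmm_p"),
             significant = vapply(rows, `[[`, 1, "lmm_p") < 0.05)
}

#' Reduce a session table to one session per subject
#'
#' Keeps the earliest session (by session identifier order) for every
#' subject; downstream analyses on the reduced table use simple regression
#' instead of mixed models.
#'
#' @param table cohort data.frame.
#' @return the reduced table, one row per subject.
#' @export
subject_level_view <- function(table) {
  check_columns(table, c("subject_id", "session_id"))
  ord <- order(table$subject_id, table$session_id)
  tab <- table[ord, , drop = FALSE]
  tab[!duplicated(tab$subject_id), , drop = FALSE]
}

lag_col_name <- function(lag_s) {
  paste0("ccf_lag_", ifelse(lag_s < 0, "m", ifelse(lag_s > 0, "p", "")),
         abs(lag_s))
}

#' Run the full association battery
#'
#' One call reproducing the study's analysis battery on a cohort table with
#' coupling metrics attached: coupling versus age / gender / diagnostic
#' group / APOE e4 count (raw, disease-condition-controlled and
#' amyloid-controlled variants), coupling versus baseline amyloid SUVR,
#' 2-year SUVR change, baseline MMSE and 2-year MMSE change (age+gender
#' adjusted, plus head-motion, batch, global-amplitude and arousal-index
#' controlled variants where those columns are available), the
#' amplitude-marker controls, the lag-wise profile, and the subject-level
#' simple-regression variant. No multiplicity correction is applied
#' (nominal p-values); the number of tests run is reported.
#'
#' @param table cohort data.frame with at least the identifier, covariate,
#'   marker and `coupling` columns; `amplitude`, `arousal_index`, `mean_fd`,
#'   `batch` and `ccf_lag_*` columns are used when present.
#' @param subject_col subject identifier column.
#' @return a `coupling_battery` object: `$results` (tidy data.frame, one row
#'   per battery cell), `$lag_profiles`, `$subject_level`, `$n_tests`.
#' @export
run_full_analysis <- function(table, subject_col = "subject_id") {
  check_columns(table, c("subject_id", "session_id", "group", "age",
                         "gender", "apoe_e4_count", "suvr_base", "suvr_fu",
                         "mmse_base", "mmse_fu", "coupling"))
  if (!"d_suvr" %in% names(table))
    table$d_suvr <- longitudinal_change(table$suvr_base, table$suvr_fu)
  if (!"d_mmse" %in% names(table))
    table$d_mmse <- longitudinal_change(table$mmse_base, table$mmse_fu)
  has <- function(v) v %in% names(table) && any(!is.na(table[[v]]))
  ag <- c("age", "gender")

  cells <- list(
    list("risk", "coupling", "age", character(0)),
    list("risk", "coupling", "gender", character(0)),
    list("risk_group_controlled", "coupling", "age", "group"),
    list("risk_group_controlled", "coupling", "gender", "group"),
    list("risk", "coupling", "apoe_e4_count", ag),
    list("risk_group_controlled", "coupling", "apoe_e4_count",
         c(ag, "group")),
    list("risk_amyloid_controlled", "coupling", "age", "suvr_base"),
    list("risk_amyloid_controlled", "coupling", "gender", "suvr_base"),
    list("risk_amyloid_controlled", "coupling", "apoe_e4_count",
         c(ag, "suvr_base")),
    list("marker", "coupling", "suvr_base", ag),
    list("marker", "coupling", "d_suvr", ag),
    list("marker", "coupling", "mmse_base", ag),
    list("marker", "coupling", "d_mmse", ag))
  for (ctrl in c("mean_fd", "batch", "amplitude", "arousal_index")) {
    if (!has(ctrl)) next
    lbl <- paste0("marker_", ctrl, "_controlled")
    cells <- c(cells, lapply(c("suvr_base", "d_suvr", "mmse_base", "d_mmse"),
                             function(m) list(lbl, "coupling", m,
                                              c(ag, ctrl))))
  }
  if (has("amplitude")) {
    cells <- c(cells,
               list(list("arousal", "coupling", "amplitude", ag),
                    list("arousal", "amplitude", "suvr_base", ag),
                    list("arousal", "amplitude", "d_mmse", ag)))
    if (has("arousal_index"))
      cells <- c(cells,
                 list(list("arousal", "arousal_index", "amplitude",
                           character(0))))
  }

  rows <- list()
  for (cl in cells) {
    res <- tryCatch({
      if (identical(cl[[3]], "group"))
        group_trend(table, cl[[2]], cl[[4]], subject_col)
      else
        association(table, cl[[2]], cl[[3]], cl[[4]], subject_col)
    }, error = function(e) NULL)
    if (is.null(res)) next
    res$analysis <- cl[[1]]
    rows[[length(rows) + 1L]] <- as.data.frame(res)
  }
  # group dose-response trends
  for (spec in list(list("risk", character(0) , ag),
                    list("risk_amyloid_controlled", "suvr_base",
                         c(ag, "suvr_base")))) {
    res <- tryCatch(group_trend(table, "coupling", spec[[3]], subject_col),
                    error = function(e) NULL)
    if (is.null(res)) next
    res$analysis <- paste0(spec[[1]], "_trend")
    rows[[length(rows) + 1L]] <- as.data.frame(res)
  }
  results <- do.call(rbind, rows)
  results <- results[, c("analysis", setdiff(names(results), "analysis"))]

  lag_profiles <- NULL
  if (any(startsWith(names(table), "ccf_lag_"))) {
    lag_profiles <- list(
      suvr_base = lagwise_association_profile(table, "suvr_base", ag,
                                              subject_col),
      d_mmse = lagwise_association_profile(table, "d_mmse", ag, subject_col))
  }

  subj_tab <- subject_level_view(table)
  subject_level <- do.call(rbind, lapply(
    c("suvr_base", "d_suvr", "mmse_base", "d_mmse"),
    function(m) {
      res <- tryCatch(
        association(subj_tab, "coupling", m, ag, subject_col,
                    simple_regression = TRUE),
        error = function(e) NULL)
      if (is.null(res)) NULL else as.data.frame(res)
    }))

  n_tests <- nrow(results) +
    sum(vapply(lag_profiles, nrow, 1L)) +
    if (is.null(subject_level)) 0L else nrow(subject_level)
  structure(list(results = results, lag_profiles = lag_profiles,
                 subject_level = subject_level, n_tests = n_tests),
            class = "coupling_battery")
}

#' @export
print.coupling_battery <- function(x, ...) {
  cat(sprintf("Association battery: %d tests (nominal p-values, no multiplicity correction)\n",
              x$n_tests))
  df <- x$results
  df$spearman_rho <- round(df$spearman_rho, 3)
  df$lmm_p <- signif(df$lmm_p, 3)
  print(df[, c("analysis", "outcome", "predictor", "covariates",
               "spearman_rho", "lmm_p", "n_sessions")], row.names = FALSE)
  invisible(x)
}
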