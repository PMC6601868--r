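#' Accessibility-residual correlation between two TFs' binding changes
#'
#' Quantifies how much of the correlation between two TFs' binding
#' changes at one time point is explained by accessibility: it
#' correlates the residuals of accessibility-based predictors of
#' interspecies ChIP change for each TF (residual = measured change
#' minus out-of-fold accessibility-based prediction) and reports the
#' drop relative to the raw correlation. The statistic resembles, but
#' is not exactly, a partial correlation: the accessibility effect is
#' removed by a fitted non-linear regression rather than a linear
#' projection.
#'
#' @param cohort A `synthetic_cohort`.
#' @param tf1,tf2 TF names with ChIP data at `tp`.
#' @param tp Time point (integer).
#' @param acc_predictions Optional named list of accessibility-based
#'   `delta_prediction`s (names `"acc_all_tp:<condition>"`), e.g. from
#'   [run_condition_matrix()]; computed if omitted. The all-time-point
#'   accessibility variant is used so that conditions at time points
#'   without accessibility data are covered.
#' @param k,seed Passed to [fit_predict_cv()] when predictions must be
#'   computed.
#' @return A list of class `codivergence_result` with `tf1`, `tf2`,
#'   `tp`, `raw_r`, `residual_r` and `drop = raw_r - residual_r`.
#' @export
residual_correlation <- function(cohort, tf1, tf2, tp,
                                 acc_predictions = NULL, k = 5,
                                 seed = 1) {
  stopifnot(is(cohort, "synthetic_cohort"))
  c1 <- sprintf("%s:TP%d", tf1, tp)
  c2 <- sprintf("%s:TP%d", tf2, tp)
  chip_cols <- colnames(cohort$chip$mel$values)
  if (!all(c(c1, c2) %in% chip_cols))
    stop("missing predictions: no ChIP data for ",
         paste(setdiff(c(c1, c2), chip_cols), collapse = ", "))
  dchip <- delta_table(cohort$chip$mel, cohort$chip$vir)$values
  get_pred <- function(cond) {
    key <- paste0("acc_all_tp:", cond)
    if (!is.null(acc_predictions)) {
      if (is.null(acc_predictions[[key]]))
        stop("missing predictions for condition ", cond)
      acc_predictions[[key]]$predicted
    } else {
      feats <- build_delta_features(cohort, cond, "acc_all_tp")
      fit_predict_cv(feats, dchip[, cond], k = k, seed = seed,
                     condition = cond, variant = "acc_all_tp",
                     decile_pct = NA)$predicted
    }
  }
  raw_r <- cor(dchip[, c1], dchip[, c2])
  res1 <- dchip[, c1] - get_pred(c1)
  res2 <- if (c1 == c2) res1 else dchip[, c2] - get_pred(c2)
  residual_r <- cor(res1, res2)
  structure(list(tf1 = tf1, tf2 = tf2, tp = tp, raw_r = raw_r,
                 residual_r = residual_r, drop = raw_r - residual_r),
            class = "codivergence_result")
}

#' @export
print.codivergence_result <- function(x, ...) {
  cat(sprintf(
    "codivergence %s vs %s @ TP%d: raw r = %.3f, residual r = %.3f (drop %.3f)\n",
    x$tf1, x$tf2, x$tp, x$raw_r, x$residual_r, x$drop))
  invisible(x)
}

#' Screen all same-time-point TF pairs for accessibility-explained
#' codivergence
#'
#' Enumerates every unordered pair of distinct TFs sharing a time
#' point, keeps the pairs whose raw binding-change correlation exceeds
#' `min_raw_r`, and flags those whose correlation drops by at least
#' `drop_threshold` after removing the accessibility-based
#' predictions.
#'
#' @param cohort A `synthetic_cohort`.
#' @param min_raw_r Raw-correlation cutoff (default 0.2, strict).
#' @param drop_threshold Drop flag threshold (default 0.04).
#' @param k,seed Passed to the accessibility predictors, which are fit
#'   once per condition and reused across pairs.
#' @return data.frame with one row per retained pair: `tf1`, `tf2`,
#'   `tp`, `raw_r`, `residual_r`, `drop`, `flagged`.
#' @export
codivergence_screen <- function(cohort, min_raw_r = 0.2,
                                drop_threshold = 0.04, k = 5,
                                seed = 1) {
  stopifnot(is(cohort, "synthetic_cohort"))
  conds <- cohort$config$conditions
  pair_rows <- list()
  for (tp in sort(unique(conds$tp))) {
    tfs <- sort(conds$tf[conds$tp == tp])
    if (length(tfs) < 2) next
    cmb <- utils::combn(tfs, 2)
    for (j in seq_len(ncol(cmb)))
      pair_rows[[length(pair_rows) + 1]] <-
        data.frame(tf1 = cmb[1, j], tf2 = cmb[2, j], tp = tp)
  }
  if (!length(pair_rows))
    return(data.frame(tf1 = character(0), tf2 = character(0),
                      tp = integer(0), raw_r = numeric(0),
                      residual_r = numeric(0), drop = numeric(0),
                      flagged = logical(0)))
  pairs <- do.call(rbind, pair_rows)
  need <- unique(sprintf("%s:TP%d", c(pairs$tf1, pairs$tf2),
                         c(pairs$tp, pairs$tp)))
  acc_preds <- run_condition_matrix(cohort, variants = "acc_all_tp",
                                    conditions = need, k = k,
                                    seed = seed)
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    r <- residual_correlation(cohort, pairs$tf1[i], pairs$tf2[i],
                              pairs$tp[i], acc_predictions = acc_preds)
    if (r$raw_r > min_raw_r)
      out[[length(out) + 1]] <-
        data.frame(tf1 = r$tf1, tf2 = r$tf2, tp = r$tp,
                   raw_r = r$raw_r, residual_r = r$residual_r,
                   drop = r$drop, flagged = r$drop >= drop_threshold)
  }
  if (!length(out))
    return(data.frame(tf1 = character(0), tf2 = character(0),
                      tp = integer(0), raw_r = numeric(0),
                      residual_r = numeric(0), drop = numeric(0),
                      flagged = logical(0)))
  do.call(rbind, out)
}
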