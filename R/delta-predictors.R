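#' Feature matrix for predicting interspecies ChIP change
#'
#' Assembles, per enhancer, the predictor variables for one condition
#' under one of four variants:
#' \describe{
#'   \item{`acc_matched`}{species-1 accessibility and its interspecies
#'     change at the condition's own time point (2 features; only
#'     available for conditions at observed accessibility time
#'     points).}
#'   \item{`acc_all_tp`}{species-1 accessibility and its change at all
#'     observed time points (6 features); usable for every condition,
#'     including time points without accessibility data.}
#'   \item{`motif`}{species-1 motif-occupancy score and its
#'     interspecies change for the condition (2 features).}
#'   \item{`combined`}{motif plus `acc_all_tp` (8 features).}
#' }
#'
#' @param cohort A `synthetic_cohort` (or list with `acc` tables).
#' @param condition Condition name, e.g. `"Twi:TP1"`.
#' @param variant One of `"acc_matched"`, `"acc_all_tp"`, `"motif"`,
#'   `"combined"`.
#' @param stap Optional list with normalized `score_table`s `mel` and
#'   `vir` from [stap_score_table()]; required for motif-containing
#'   variants.
#' @return Numeric feature matrix with enhancer ids as row names.
#' @export
build_delta_features <- function(cohort, condition,
                                 variant = c("acc_matched", "acc_all_tp",
                                             "motif", "combined"),
                                 stap = NULL) {
  variant <- match.arg(variant)
  acc_mel <- cohort$acc$mel$values
  d_acc <- acc_mel - cohort$acc$vir$values
  acc_block <- function(cols) {
    m <- cbind(acc_mel[, cols, drop = FALSE],
               d_acc[, cols, drop = FALSE])
    colnames(m) <- c(paste0("mel_", cols), paste0("d_", cols))
    m
  }
  motif_block <- function() {
    if (is.null(stap))
      stop("missing table: motif features for ", condition,
           " need stap score tables")
    if (!condition %in% colnames(stap$mel$values))
      stop("missing table: no stap scores for condition ", condition)
    m <- cbind(stap$mel$values[, condition],
               stap$mel$values[, condition] -
                 stap$vir$values[, condition])
    colnames(m) <- c("mel_STAP", "d_STAP")
    rownames(m) <- rownames(stap$mel$values)
    m
  }
  if (variant == "acc_matched") {
    tp <- sub("^.*:", "", condition)
    col <- paste0("Acc:", tp)
    if (!col %in% colnames(acc_mel))
      stop("missing table: no accessibility data at ", tp,
           " for condition ", condition)
    acc_block(col)
  } else if (variant == "acc_all_tp") {
    acc_block(colnames(acc_mel))
  } else if (variant == "motif") {
    motif_block()
  } else {
    cbind(motif_block(), acc_block(colnames(acc_mel)))
  }
}

#' Cross-validated support-vector regression of ChIP change
#'
#' Fits epsilon-insensitive support-vector regression (radial-basis
#' kernel, cost 1, epsilon 0.1, kernel width 1/#features, features
#' standardized within each training fold) and returns out-of-fold
#' predictions for every enhancer. Fold shuffling is the only source
#' of randomness, so results are deterministic given `seed`.
#'
#' @param features Numeric feature matrix (ids as row names).
#' @param target Numeric target vector (interspecies ChIP change),
#'   same length/order as rows of `features`.
#' @param k Number of folds (default 5); requires at least `2k`
#'   samples.
#' @param seed Integer seed for the fold shuffle.
#' @param condition,variant Optional labels carried into the result.
#' @param decile_pct Percentile for the extreme-change AUROC
#'   evaluation (default 10); set `NA` to skip.
#' @return A list of class `delta_prediction` with `predicted`,
#'   `folds`, `pcc` (pooled out-of-fold correlation),
#'   `pcc_per_fold`, `pcc_mean_folds` (their average) and
#'   `auroc_decile`.
#' @export
fit_predict_cv <- function(features, target, k = 5, seed = 1,
                           condition = NA_character_,
                           variant = NA_character_, decile_pct = 10) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(length(target) == n)
  if (n < 2 * k) stop("need at least 2k samples")
  if (sd(target) == 0) stop("degenerate target: constant")
  set.seed(seed)
  folds <- sample(rep_len(seq_len(k), n))
  preds <- numeric(n)
  pcc_per_fold <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- e1071::svm(features[tr, , drop = FALSE], target[tr],
                      type = "eps-regression", kernel = "radial",
                      cost = 1, epsilon = 0.1,
                      gamma = 1 / ncol(features), scale = TRUE)
    preds[!tr] <- predict(fit, features[!tr, , drop = FALSE])
    pcc_per_fold[f] <- if (sd(preds[!tr]) > 0)
      cor(preds[!tr], target[!tr]) else 0
  }
  names(preds) <- rownames(features)
  res <- list(condition = condition, variant = variant,
              predicted = preds, folds = folds, target = target,
              pcc = if (sd(preds) > 0) cor(preds, target) else 0,
              pcc_per_fold = pcc_per_fold,
              pcc_mean_folds = mean(pcc_per_fold),
              auroc_decile = NA_real_)
  if (!is.na(decile_pct) && n >= 20 * decile_pct / 100 * 2)
    res$auroc_decile <- tryCatch(
      evaluate_decile_auroc(preds, target, decile_pct),
      error = function(e) NA_real_)
  class(res) <- "delta_prediction"
  res
}

#' @export
print.delta_prediction <- function(x, ...) {
  cat(sprintf(
    "delta_prediction [%s, %s]: pooled PCC %.3f, fold-mean PCC %.3f, decile AUROC %s\n",
    x$condition, x$variant, x$pcc, x$pcc_mean_folds,
    ifelse(is.na(x$auroc_decile), "NA",
           sprintf("%.3f", x$auroc_decile))))
  invisible(x)
}

#' Pearson correlation between predicted and measured change
#'
#' @param pred,target Numeric vectors.
#' @return A `correlation_result` (see [pearson_with_pvalue()]).
#' @export
evaluate_pcc <- function(pred, target) pearson_with_pvalue(pred, target)

#' AUROC for extreme increases versus extreme decreases
#'
#' Labels the enhancer pairs with measured change in the top `pct`
#' percentile as positives and those in the bottom `pct` percentile as
#' negatives (`floor(n * pct / 100)` per tail, ties in the measured
#' change broken by stable input order), discards the middle, and
#' returns the AUROC of the predictions on this balanced set.
#'
#' @param pred Predicted changes.
#' @param target Measured changes.
#' @param pct Tail percentile in (0, 50); default 10.
#' @return AUROC in \[0, 1\].
#' @export
evaluate_decile_auroc <- function(pred, target, pct = 10) {
  stopifnot(length(pred) == length(target), pct > 0, pct < 50)
  n <- length(target)
  m <- floor(n * pct / 100)
  if (m < 10) stop("too few samples per class after selection")
  ord <- order(target)           # stable: ties keep input order
  neg <- ord[seq_len(m)]
  pos <- ord[seq.int(n - m + 1, n)]
  sel <- c(pos, neg)
  auroc(pred[sel], rep(c(TRUE, FALSE), c(m, m)))
}

#' Run the condition-by-variant prediction matrix
#'
#' Fits cross-validated predictors of interspecies ChIP change for
#' every requested condition under every requested variant. The
#' `acc_matched` variant is fit only for conditions whose time point
#' has observed accessibility; the other variants cover all
#' conditions.
#'
#' @param cohort A `synthetic_cohort`.
#' @param variants Character vector of feature variants (see
#'   [build_delta_features()]).
#' @param conditions Condition names (default: all in the cohort).
#' @param stap_models Optional named list of fitted `stap_model`s; if
#'   omitted and a motif-containing variant is requested, models are
#'   fit with [fit_condition_staps()].
#' @param k,seed Passed to [fit_predict_cv()].
#' @return Named list of `delta_prediction`s (names
#'   `"<variant>:<condition>"`); summarize with
#'   [prediction_summary()].
#' @export
run_condition_matrix <- function(cohort,
                                 variants = c("motif", "acc_all_tp",
                                              "combined"),
                                 conditions = NULL, stap_models = NULL,
                                 k = 5, seed = 1) {
  stopifnot(is(cohort, "synthetic_cohort"))
  if (is.null(conditions)) conditions <- cohort$config$conditions$name
  miss <- setdiff(conditions, colnames(cohort$chip$mel$values))
  if (length(miss))
    stop("missing table: no ChIP data for condition ",
         paste(miss, collapse = ", "))
  stap <- NULL
  if (any(variants %in% c("motif", "combined"))) {
    if (is.null(stap_models))
      stap_models <- fit_condition_staps(cohort, conditions)
    stap <- stap_score_table(stap_models, cohort$pairs)
  }
  dchip <- delta_table(cohort$chip$mel, cohort$chip$vir)
  acc_tps <- sub("Acc:", "", colnames(cohort$acc$mel$values))
  out <- list()
  for (v in variants) {
    for (cond in conditions) {
      if (v == "acc_matched" && !sub("^.*:", "", cond) %in% acc_tps)
        next
      feats <- build_delta_features(cohort, cond, v, stap = stap)
      out[[paste0(v, ":", cond)]] <-
        fit_predict_cv(feats, dchip$values[, cond], k = k, seed = seed,
                       condition = cond, variant = v)
    }
  }
  out
}

#' Summarize a list of delta predictions
#'
#' @param preds List returned by [run_condition_matrix()].
#' @return data.frame with condition, variant, pooled and fold-mean
#'   PCC, and decile AUROC.
#' @export
prediction_summary <- function(preds) {
  do.call(rbind, lapply(preds, function(p)
    data.frame(condition = p$condition, variant = p$variant,
               pcc = p$pcc, pcc_mean_folds = p$pcc_mean_folds,
               auroc_decile = p$auroc_decile,
               row.names = NULL)))
}
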