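#' Synthetic minority oversampling
#'
#' Balances a binary training set by interpolating synthetic minority
#' samples between minority points and their k nearest minority
#' neighbors (k = 5, reduced when fewer neighbors exist): each
#' synthetic sample lies on the segment between an original minority
#' point and one of its neighbors, at a uniform random position. The
#' class ratio is brought to 1:1; an already balanced set is returned
#' unchanged. Deterministic given `seed`.
#'
#' @param features Numeric matrix (samples x features).
#' @param labels Logical (or 0/1) class membership vector.
#' @param seed Integer seed.
#' @param k Number of minority nearest neighbors (default 5).
#' @return List with augmented `features`, `labels`, and `synthetic`
#'   (logical flag marking generated rows).
#' @export
oversample_minority <- function(features, labels, seed = 1, k = 5) {
  features <- as.matrix(features)
  lab <- as.logical(labels)
  stopifnot(nrow(features) == length(lab), !anyNA(lab))
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == n_neg)
    return(list(features = features, labels = lab,
                synthetic = rep(FALSE, length(lab))))
  minority <- if (n_pos < n_neg) lab else !lab
  n_min <- sum(minority)
  if (n_min < 2) stop("minority class needs at least 2 samples")
  need <- abs(n_neg - n_pos)
  mf <- features[minority, , drop = FALSE]
  d <- as.matrix(stats::dist(mf))
  diag(d) <- Inf
  kk <- min(k, n_min - 1)
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(kk)]))
  set.seed(seed)
  base_idx <- sample(rep_len(seq_len(n_min), need))
  nbr_pick <- sample.int(kk, need, replace = TRUE)
  t_mix <- runif(need)
  synth <- mf[base_idx, , drop = FALSE] +
    t_mix * (mf[nn[cbind(base_idx, nbr_pick)], , drop = FALSE] -
             mf[base_idx, , drop = FALSE])
  rownames(synth) <- sprintf("synthetic%04d", seq_len(need))
  list(features = rbind(features, synth),
       labels = c(lab, rep(n_pos < n_neg, need)),
       synthetic = c(rep(FALSE, length(lab)), rep(TRUE, need)))
}

activity_xgb_params <- function(seed) {
  list(objective = "binary:logistic", eta = 0.2, max_depth = 4,
       subsample = 0.9, colsample_bytree = 0.8, nthread = 1,
       seed = seed)
}

#' Train a one-vs-rest enhancer-activity classifier
#'
#' Gradient-boosted trees (logistic objective; learning rate 0.2, 50
#' rounds, max depth 4, row subsample 0.9, column subsample 0.8)
#' discriminating members of one activity class from members of the
#' other classes, using each enhancer's ChIP profile across all
#' conditions as features. The minority class is oversampled to parity
#' before training (see [oversample_minority()]).
#'
#' @param profiles Numeric matrix of ChIP profiles (enhancers x
#'   conditions).
#' @param labels Character class labels, one per enhancer.
#' @param class_c The class to discriminate (positives = enhancers of
#'   this class).
#' @param seed Integer seed (drives oversampling and tree
#'   subsampling).
#' @param nrounds Boosting rounds; default 50.
#' @return An object of class `activity_model` whose predictions are
#'   confidences in \[0, 1\].
#' @export
train_activity_classifier <- function(profiles, labels, class_c,
                                      seed = 1, nrounds = 50) {
  profiles <- as.matrix(profiles)
  stopifnot(nrow(profiles) == length(labels))
  y <- labels == class_c
  if (all(y) || !any(y))
    stop("single-class input: need members and non-members of ",
         class_c)
  aug <- oversample_minority(profiles, y, seed = seed)
  dtrain <- xgboost::xgb.DMatrix(aug$features,
                                 label = as.numeric(aug$labels),
                                 nthread = 1)
  booster <- xgboost::xgb.train(params = activity_xgb_params(seed),
                                data = dtrain, nrounds = nrounds,
                                verbose = 0)
  structure(list(class_c = class_c, booster = booster,
                 features = colnames(profiles), seed = seed),
            class = "activity_model")
}

#' @export
print.activity_model <- function(x, ...) {
  cat(sprintf("activity_model for class '%s' (%d features)\n",
              x$class_c, length(x$features)))
  invisible(x)
}

#' Per-class activity confidences
#'
#' Scores ChIP profiles with a set of one-vs-rest activity models.
#' Classes are scored independently; confidences do not sum to 1
#' across classes.
#'
#' @param models Named list of `activity_model`s (or a single model).
#' @param profiles Numeric matrix of ChIP profiles with the same
#'   feature columns the models were trained on.
#' @return Matrix of confidences in \[0, 1\] (enhancers x classes).
#' @export
predict_activity <- function(models, profiles) {
  if (is(models, "activity_model")) models <- list(models)
  profiles <- as.matrix(profiles)
  out <- vapply(models, function(m) {
    if (ncol(profiles) != length(m$features))
      stop(sprintf(
        "profile dimension mismatch: %d columns, model expects %d",
        ncol(profiles), length(m$features)))
    predict(m$booster, xgboost::xgb.DMatrix(profiles, nthread = 1))
  }, numeric(nrow(profiles)))
  out <- matrix(out, nrow = nrow(profiles),
                dimnames = list(rownames(profiles),
                                vapply(models, `[[`, "", "class_c")))
  out
}

#' Leave-one-out confusion summary for one activity class
#'
#' Scores every enhancer with a model trained on all other enhancers
#' (minority oversampling is performed inside each training split, so
#' the held-out sample never leaks into the synthetic points), applies
#' the confidence threshold, and tabulates the confusion matrix.
#'
#' @param profiles Numeric ChIP-profile matrix.
#' @param labels Character class labels.
#' @param class_c Class treated as positive.
#' @param threshold Confidence threshold (default 0.5).
#' @param seed Integer seed.
#' @param nrounds Boosting rounds per fit.
#' @return A `confusion_summary`; the out-of-fold confidences are
#'   attached as attribute `"scores"`.
#' @export
loocv_confusion <- function(profiles, labels, class_c,
                            threshold = 0.5, seed = 1, nrounds = 50) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  stopifnot(n >= 3, length(labels) == n)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    m <- train_activity_classifier(profiles[-i, , drop = FALSE],
                                   labels[-i], class_c,
                                   seed = seed + i, nrounds = nrounds)
    scores[i] <- predict_activity(list(m),
                                  profiles[i, , drop = FALSE])[1, 1]
  }
  y <- labels == class_c
  pred <- scores >= threshold
  cs <- confusion_summary(tn = sum(!y & !pred), fn = sum(y & !pred),
                          tp = sum(y & pred), fp = sum(!y & pred))
  attr(cs, "scores") <- scores
  cs
}
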