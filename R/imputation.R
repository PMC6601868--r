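#' Impute an ortholog's ChIP profile from predicted binding change
#'
#' Since the interspecies change is defined as species-1 minus
#' species-2, the ortholog profile is imputed as
#' `species-1 profile - predicted change`, clipped to \[0, 1\] so that
#' it remains a valid input to the activity classifiers.
#'
#' @param mel_profile Numeric vector or matrix of normalized species-1
#'   ChIP scores (values in \[0, 1\]).
#' @param predicted_dchip Predicted interspecies change, same
#'   dimensions.
#' @return Imputed species-2 profile(s), clipped to \[0, 1\].
#' @export
impute_ortholog_chip <- function(mel_profile, predicted_dchip) {
  if (is.null(dim(mel_profile)) != is.null(dim(predicted_dchip)) ||
      length(mel_profile) != length(predicted_dchip) ||
      (!is.null(dim(mel_profile)) &&
       !all(dim(mel_profile) == dim(predicted_dchip))))
    stop("dimension mismatch between profile and predicted change")
  if (min(mel_profile) < 0 || max(mel_profile) > 1)
    stop("species-1 profile must be normalized to [0, 1]")
  pmin(pmax(mel_profile - predicted_dchip, 0), 1)
}

#' Select the assessment set for one activity class
#'
#' Restricts to the enhancers whose species-1 activity confidence is
#' in the top `top_pct` percentile (`floor(n * top_pct / 100)`
#' enhancers, ties broken by stable id order), then within that set
#' returns the ids whose activity change is above the
#' `(100 - extreme_pct)` percentile ("high": predicted activity
#' change) and below the `extreme_pct` percentile ("low": predicted
#' conservation). Percentile thresholds use the standard interpolated
#' sample quantile with strict inequalities, which for continuous
#' scores yields equal-sized sides.
#'
#' @param ac Named numeric vector of species-1 activity confidences.
#' @param da Named numeric vector of activity changes (same ids).
#' @param top_pct Activity percentile defining the candidate set
#'   (default 20).
#' @param extreme_pct Tail percentile within the candidate set
#'   (default 10); in (0, 50\].
#' @return List with `top`, `high`, `low` (character id vectors) and
#'   `n = length(high) + length(low)`.
#' @export
select_assessment_set <- function(ac, da, top_pct = 20,
                                  extreme_pct = 10) {
  stopifnot(length(ac) == length(da), !is.null(names(ac)))
  stopifnot(top_pct > 0, top_pct <= 100,
            extreme_pct > 0, extreme_pct <= 50)
  da <- da[names(ac)]
  n <- length(ac)
  n_top <- floor(n * top_pct / 100)
  top_ids <- names(ac)[order(-ac)][seq_len(n_top)]
  d <- da[top_ids]
  hi_thr <- quantile(d, 1 - extreme_pct / 100, names = FALSE)
  lo_thr <- quantile(d, extreme_pct / 100, names = FALSE)
  high <- top_ids[d > hi_thr]
  low <- top_ids[d < lo_thr]
  if (length(high) < 10 || length(low) < 10)
    stop("fewer than 10 enhancers per side after selection")
  list(top = top_ids, high = high, low = low,
       n = length(high) + length(low))
}

#' Agreement between measured and imputed activity change
#'
#' Given a predicted interspecies ChIP-change matrix, imputes the
#' ortholog profiles, scores them with the activity model, and
#' compares the imputation-based activity change against the
#' measured-profile activity change on the selected assessment set,
#' by Pearson correlation and by AUROC (classifying high- versus
#' low-change enhancers).
#'
#' @param cohort A `synthetic_cohort`.
#' @param models Named list of `activity_model`s containing
#'   `class_c`.
#' @param class_c Activity class under assessment.
#' @param pred_dchip Predicted change matrix (enhancers x conditions,
#'   rows named by id, same conditions as the cohort's ChIP tables).
#' @param sel Optional selection from [select_assessment_set()];
#'   computed from the measured profiles if omitted.
#' @param top_pct,extreme_pct Selection parameters when `sel` is
#'   omitted.
#' @return List with `r`, `auroc`, `n`, `sel`, `da`, `da_hat`.
#' @export
imputed_agreement <- function(cohort, models, class_c, pred_dchip,
                              sel = NULL, top_pct = 20,
                              extreme_pct = 10) {
  stopifnot(is(cohort, "synthetic_cohort"), class_c %in% names(models))
  mel <- cohort$chip$mel$values
  vir <- cohort$chip$vir$values
  stopifnot(all(rownames(mel) %in% rownames(pred_dchip)),
            identical(colnames(mel), colnames(pred_dchip)))
  pred_dchip <- pred_dchip[rownames(mel), , drop = FALSE]
  a_mel <- predict_activity(models[class_c], mel)[, 1]
  a_vir <- predict_activity(models[class_c], vir)[, 1]
  da <- setNames(a_mel - a_vir, rownames(mel))
  if (is.null(sel))
    sel <- select_assessment_set(setNames(a_mel, rownames(mel)), da,
                                 top_pct, extreme_pct)
  imputed <- impute_ortholog_chip(mel, pred_dchip)
  a_hat <- predict_activity(models[class_c], imputed)[, 1]
  da_hat <- setNames(a_mel - a_hat, rownames(mel))
  ids <- c(sel$high, sel$low)
  r <- if (sd(da_hat[ids]) > 0 && sd(da[ids]) > 0)
    cor(da[ids], da_hat[ids]) else NA_real_
  au <- auroc(da_hat[ids],
              rep(c(TRUE, FALSE), c(length(sel$high), length(sel$low))))
  list(r = r, auroc = au, n = sel$n, sel = sel, da = da,
       da_hat = da_hat)
}

#' Permuted-change control for the agreement analysis
#'
#' Null baseline in which the enhancer-to-change assignment is
#' destroyed: whole rows of the measured interspecies ChIP-change
#' matrix are permuted (keeping each enhancer's conditions together,
#' which preserves within-enhancer condition correlation and each
#' column's marginal distribution exactly), the ortholog profiles are
#' imputed from the permuted changes, and the agreement statistics are
#' recomputed. Deterministic given `seed`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param class_c Activity class.
#' @param models Named list of `activity_model`s (trained from the
#'   cohort labels if omitted).
#' @param seed Integer seed driving the permutations.
#' @param n_perms Number of permutations (default 1); the returned
#'   `control_r`/`control_auroc` are means across permutations.
#' @param sel Optional precomputed assessment selection.
#' @param top_pct,extreme_pct Selection parameters.
#' @return List with `control_r`, `control_auroc` and `per_perm`
#'   (data.frame of per-permutation values).
#' @export
permuted_control <- function(cohort, class_c, models = NULL, seed = 1,
                             n_perms = 1, sel = NULL, top_pct = 20,
                             extreme_pct = 10) {
  stopifnot(is(cohort, "synthetic_cohort"))
  if (is.null(models))
    models <- train_activity_models(cohort, seed = seed)
  dchip <- delta_table(cohort$chip$mel, cohort$chip$vir)$values
  n <- nrow(dchip)
  set.seed(seed)
  rows <- replicate(n_perms, sample.int(n), simplify = FALSE)
  per <- lapply(rows, function(p) {
    perm <- dchip[p, , drop = FALSE]
    rownames(perm) <- rownames(dchip)
    ag <- imputed_agreement(cohort, models, class_c, perm, sel = sel,
                            top_pct = top_pct,
                            extreme_pct = extreme_pct)
    data.frame(r = ag$r, auroc = ag$auroc)
  })
  per <- do.call(rbind, per)
  list(control_r = mean(per$r), control_auroc = mean(per$auroc),
       per_perm = per)
}

#' Train activity models for every class of a cohort
#'
#' One-vs-rest classifier per activity class, trained on the species-1
#' ChIP profiles and the cohort labels.
#'
#' @param cohort A `synthetic_cohort`.
#' @param ids Optional subset of enhancer ids to train on (e.g. the
#'   experimentally characterized subset); default all.
#' @param seed Integer seed.
#' @param nrounds Boosting rounds.
#' @return Named list of `activity_model`s.
#' @export
train_activity_models <- function(cohort, ids = NULL, seed = 1,
                                  nrounds = 50) {
  stopifnot(is(cohort, "synthetic_cohort"))
  if (is.null(ids)) ids <- names(cohort$labels)
  profiles <- cohort$chip$mel$values[ids, , drop = FALSE]
  labels <- cohort$labels[ids]
  classes <- names(cohort$config$activity_rule)
  setNames(lapply(classes, function(cl)
    train_activity_classifier(profiles, labels, cl, seed = seed,
                              nrounds = nrounds)), classes)
}

#' Full agreement assessment for one class and one predictor variant
#'
#' Combines the measured-profile activity change, the imputed-profile
#' activity change under a set of cross-validated ChIP-change
#' predictions, and the permuted-change control into one result.
#'
#' @param cohort A `synthetic_cohort`.
#' @param predictions Named list of `delta_prediction`s covering every
#'   cohort condition under one variant (from
#'   [run_condition_matrix()]).
#' @param class_c Activity class.
#' @param models Named list of `activity_model`s (trained from the
#'   cohort labels if omitted).
#' @param seed Seed for the control permutations.
#' @param control_perms Number of control permutations (default 1).
#' @param top_pct,extreme_pct Assessment-set selection parameters.
#' @return A list of class `agreement_result` with fields `class_c`,
#'   `variant`, `r`, `auroc`, `control_r`, `control_auroc`, `n`,
#'   `sel`, `da`, `da_hat`.
#' @export
assess_agreement <- function(cohort, predictions, class_c,
                             models = NULL, seed = 1,
                             control_perms = 1, top_pct = 20,
                             extreme_pct = 10) {
  stopifnot(is(cohort, "synthetic_cohort"), length(predictions) >= 1)
  conds <- colnames(cohort$chip$mel$values)
  variant <- predictions[[1]]$variant
  have <- vapply(predictions, `[[`, "", "condition")
  if (!all(conds %in% have))
    stop("predictions missing for conditions: ",
         paste(setdiff(conds, have), collapse = ", "))
  if (is.null(models))
    models <- train_activity_models(cohort, seed = seed)
  ids <- rownames(cohort$chip$mel$values)
  pred_dchip <- vapply(conds, function(cc)
    predictions[[which(have == cc)[1]]]$predicted[ids],
    numeric(length(ids)))
  pred_dchip <- matrix(pred_dchip, length(ids),
                       dimnames = list(ids, conds))
  ag <- imputed_agreement(cohort, models, class_c, pred_dchip,
                          top_pct = top_pct,
                          extreme_pct = extreme_pct)
  ctrl <- permuted_control(cohort, class_c, models = models,
                           seed = seed, n_perms = control_perms,
                           sel = ag$sel, top_pct = top_pct,
                           extreme_pct = extreme_pct)
  structure(list(class_c = class_c, variant = variant, r = ag$r,
                 auroc = ag$auroc, control_r = ctrl$control_r,
                 control_auroc = ctrl$control_auroc, n = ag$n,
                 sel = ag$sel, da = ag$da, da_hat = ag$da_hat),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "agreement [%s, %s]: r = %.3f (control %.3f), AUROC = %.3f (control %.3f), n = %d\n",
    x$class_c, x$variant, x$r, x$control_r, x$auroc,
    x$control_auroc, x$n))
  invisible(x)
}
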