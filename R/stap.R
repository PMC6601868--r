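#' Thermodynamic occupancy model (PWM + concentration parameter)
#'
#' Couples a PWM with a single non-negative concentration parameter
#' gamma. The predicted net occupancy of a sequence is the sum of
#' fractional site occupancies \eqn{\gamma K / (1 + \gamma K)} over all
#' windows on both strands, where K is the window's relative affinity
#' (see [site_affinity()]). This integrates strong as well as weak
#' sites into one quantitative motif-presence score.
#'
#' @param pwm A `pwm`.
#' @param gamma Non-negative finite concentration parameter.
#' @return An object of class `stap_model`.
#' @export
stap_model <- function(pwm, gamma) {
  stopifnot(is(pwm, "pwm"), is.numeric(gamma), length(gamma) == 1,
            is.finite(gamma), gamma >= 0)
  structure(list(pwm = pwm, gamma = gamma), class = "stap_model")
}

#' @export
print.stap_model <- function(x, ...) {
  cat(sprintf("stap_model: motif '%s' (L=%d), gamma = %.4g\n",
              x$pwm$name, pwm_length(x$pwm), x$gamma))
  invisible(x)
}

occupancy_from_K <- function(K, gamma) {
  gk <- gamma * K
  sum(gk / (1 + gk))
}

#' Predicted net TF occupancy of a sequence
#'
#' Expected number of bound TF molecules: the sum of
#' \eqn{\gamma K_w / (1 + \gamma K_w)} over every length-L window w on
#' both strands. The value is 0 at gamma = 0, monotone non-decreasing
#' in gamma, and bounded by twice the number of windows.
#'
#' @param model A `stap_model`.
#' @param seq_chr Character DNA sequence, at least as long as the
#'   motif.
#' @return Non-negative occupancy.
#' @examples
#' uni <- pwm(matrix(0.25, 2, 4), pseudocount = 0)
#' occupancy(stap_model(uni, 1), "ACGTA")  # 8 windows x 1/2 = 4
#' @export
occupancy <- function(model, seq_chr) {
  stopifnot(is(model, "stap_model"))
  occupancy_from_K(window_affinities(model$pwm, seq_chr), model$gamma)
}

#' Training set for the occupancy model
#'
#' Sequences paired with normalized ChIP scores in \[0, 1\], with a
#' provenance flag distinguishing positives (e.g. top ChIP peaks) from
#' negatives (e.g. random genomic windows).
#'
#' @param sequences Character vector of DNA sequences.
#' @param targets Normalized scores in \[0, 1\], same length.
#' @param provenance Character vector (`"positive"`/`"negative"`) or
#'   single value recycled; default `"positive"`.
#' @return An object of class `stap_training_set`.
#' @export
stap_training_set <- function(sequences, targets,
                              provenance = "positive") {
  sequences <- as.character(sequences)
  stopifnot(length(sequences) == length(targets),
            all(targets >= 0), all(targets <= 1))
  provenance <- rep_len(as.character(provenance), length(sequences))
  structure(list(sequences = sequences, targets = as.numeric(targets),
                 provenance = provenance),
            class = "stap_training_set")
}

#' Random background windows
#'
#' Uniform i.i.d. DNA windows usable as the negative portion of a
#' training set.
#'
#' @param n Number of windows.
#' @param length Window length in bp.
#' @param seed Integer seed.
#' @return Character vector of sequences.
#' @export
random_background_windows <- function(n, length, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = ""), character(1))
}

# scaled occupancies for a fixed K list at a given gamma; min-max
# scaling parameters are returned so they can be applied to held-out
# sequences
scaled_occupancies <- function(K_list, gamma, lo = NULL, hi = NULL) {
  occ <- vapply(K_list, occupancy_from_K, numeric(1), gamma = gamma)
  if (is.null(lo)) lo <- min(occ)
  if (is.null(hi)) hi <- max(occ)
  scaled <- if (hi > lo) (occ - lo) / (hi - lo) else rep(0, length(occ))
  list(scaled = scaled, lo = lo, hi = hi)
}

fit_gamma_K <- function(K_list, targets) {
  sse <- function(log_gamma) {
    s <- scaled_occupancies(K_list, exp(log_gamma))$scaled
    sum((s - targets)^2)
  }
  grid <- log(10) * seq(-6, 6, length.out = 49)
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  lower <- grid[max(1, i - 1)]
  upper <- grid[min(length(grid), i + 1)]
  opt <- optimise(sse, c(lower, upper), tol = 1e-8)
  if (opt$objective <= vals[i]) exp(opt$minimum) else exp(grid[i])
}

#' Fit the concentration parameter against ChIP scores
#'
#' Finds the gamma minimizing the sum of squared differences between
#' min-max-scaled occupancies of the training sequences and their
#' normalized ChIP scores. The search is a log-scale grid over
#' gamma in \[1e-6, 1e6\] refined by golden-section search, and is
#' fully deterministic.
#'
#' @param train A `stap_training_set` with at least 2 distinct target
#'   values.
#' @param pwm A `pwm`.
#' @return A fitted `stap_model`.
#' @export
fit_gamma <- function(train, pwm) {
  stopifnot(is(train, "stap_training_set"), is(pwm, "pwm"))
  if (length(unique(train$targets)) < 2)
    stop("uninformative training set: constant targets")
  K_list <- lapply(train$sequences, window_affinities, x = pwm)
  stap_model(pwm, fit_gamma_K(K_list, train$targets))
}

#' Cross-validated evaluation of the occupancy model
#'
#' Splits the training set into k folds (deterministic contiguous
#' assignment in input order), fits gamma on each training split,
#' scores the held-out split with the training split's min-max scaling,
#' and evaluates the pooled out-of-fold predictions against the targets
#' by Pearson correlation.
#'
#' @param train A `stap_training_set`.
#' @param pwm A `pwm`.
#' @param k Number of folds (>= 2); `k = length(train$targets)` gives
#'   leave-one-out.
#' @return List with `pcc`, `fold_gamma` (per-fold fitted gammas),
#'   `predictions` (pooled out-of-fold scaled occupancies) and `folds`
#'   (fold assignment).
#' @export
crossval_stap <- function(train, pwm, k = 4) {
  stopifnot(is(train, "stap_training_set"), k >= 2)
  n <- length(train$targets)
  if (k > n) stop("more folds than samples")
  folds <- rep_len(seq_len(k), n)
  K_list <- lapply(train$sequences, window_affinities, x = pwm)
  preds <- numeric(n)
  fold_gamma <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(train$targets[tr])) < 2)
      stop("uninformative training fold: constant targets")
    g <- fit_gamma_K(K_list[tr], train$targets[tr])
    fold_gamma[f] <- g
    sc_tr <- scaled_occupancies(K_list[tr], g)
    preds[!tr] <- scaled_occupancies(K_list[!tr], g,
                                     lo = sc_tr$lo, hi = sc_tr$hi)$scaled
  }
  list(pcc = cor(preds, train$targets), fold_gamma = fold_gamma,
       predictions = preds, folds = folds)
}

#' Motif-occupancy score tables for an orthologous cohort
#'
#' Scores every enhancer sequence in both species with the fitted
#' occupancy model of each condition, then applies the same capped
#' min-max normalization used for ChIP scores.
#'
#' @param models Named list of `stap_model`s, one per condition
#'   (conditions of the same TF may share a PWM; affinities are
#'   computed once per distinct motif).
#' @param pairs Orthologous pair data.frame with columns `id`,
#'   `seq_mel`, `seq_vir` (as produced by [generate_cohort()]).
#' @return List with normalized `score_table`s `mel` and `vir`.
#' @export
stap_score_table <- function(models, pairs) {
  stopifnot(is.list(models), !is.null(names(models)))
  need <- c("id", "seq_mel", "seq_vir")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns id, seq_mel, seq_vir")
  if (any(!nzchar(pairs$seq_mel)) || any(!nzchar(pairs$seq_vir)))
    stop("missing sequence for id: ",
         pairs$id[!nzchar(pairs$seq_mel) | !nzchar(pairs$seq_vir)][1])
  # group conditions by motif so window affinities are computed once
  motif_key <- vapply(models, function(m)
    paste0(m$pwm$name, "#", paste(signif(m$pwm$probs, 8), collapse = ",")),
    character(1))
  K_cache <- list()
  score_species <- function(seqs) {
    m <- matrix(0, nrow(pairs), length(models),
                dimnames = list(pairs$id, names(models)))
    for (key in unique(motif_key)) {
      conds <- names(models)[motif_key == key]
      pw <- models[[conds[1]]]$pwm
      Ks <- lapply(seqs, window_affinities, x = pw)
      for (cond in conds)
        m[, cond] <- vapply(Ks, occupancy_from_K, numeric(1),
                            gamma = models[[cond]]$gamma)
    }
    m
  }
  raw_mel <- score_species(pairs$seq_mel)
  raw_vir <- score_species(pairs$seq_vir)
  list(
    mel = normalize_scores(score_table(raw_mel, species = "mel"))$table,
    vir = normalize_scores(score_table(raw_vir, species = "vir"))$table)
}
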