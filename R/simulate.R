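#' Default TF:time-point condition set
#'
#' The 14 shared TF:time-point conditions of the mesoderm core network
#' across two species: Twi at TP1-3, Tin at TP2-3, Mef2 at TP1-5, Bap
#' at TP3 and Bin at TP3-5.
#'
#' @return data.frame with columns `tf`, `tp` and `name`
#'   (`"TF:TPk"`).
#' @export
default_conditions <- function() {
  d <- rbind(
    data.frame(tf = "Twi", tp = 1:3),
    data.frame(tf = "Tin", tp = 2:3),
    data.frame(tf = "Mef2", tp = 1:5),
    data.frame(tf = "Bap", tp = 3),
    data.frame(tf = "Bin", tp = 3:5))
  d$name <- sprintf("%s:TP%d", d$tf, d$tp)
  d
}

consensus_pwm <- function(consensus, name, dominant = 0.85) {
  bases <- strsplit(consensus, "")[[1]]
  other <- (1 - dominant) / 3
  probs <- matrix(other, length(bases), 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
  probs[cbind(seq_along(bases), match(bases, c("A", "C", "G", "T")))] <-
    dominant
  pwm(probs, name = name)
}

#' Default motif set for the five mesoderm TFs
#'
#' Informative consensus-derived PWMs resembling the binding
#' preferences of the five factors: an E-box for Twi, NK-homeodomain
#' sites for Tin and Bap, an A/T-rich MADS-box site for Mef2 and a
#' forkhead site for Bin. Each position gives probability 0.85 to the
#' consensus base.
#'
#' @return Named list of `pwm`s.
#' @export
default_mesoderm_pwms <- function() {
  list(
    Twi = consensus_pwm("CACATGT", "Twi"),
    Tin = consensus_pwm("TCAAGTG", "Tin"),
    Mef2 = consensus_pwm("CTAAAAATAG", "Mef2"),
    Bap = consensus_pwm("TTAAGTGG", "Bap"),
    Bin = consensus_pwm("TGTTTAC", "Bin"))
}

#' Default activity rule
#'
#' Maps each spatio-temporal activity class to the conditions whose
#' mean ChIP score defines it: early Twi/Tin binding for unspecified
#' mesoderm (Meso), Bap/Bin binding for visceral muscle (VM) and late
#' Mef2 binding for somatic muscle (SM).
#'
#' @return Named list of condition-name character vectors.
#' @export
default_activity_rule <- function() {
  list(
    Meso = c("Twi:TP1", "Twi:TP2", "Twi:TP3", "Tin:TP2", "Tin:TP3"),
    VM = c("Bap:TP3", "Bin:TP3", "Bin:TP4", "Bin:TP5"),
    SM = c("Mef2:TP3", "Mef2:TP4", "Mef2:TP5"))
}

#' Configuration for synthetic orthologous-enhancer cohorts
#'
#' Fixes the generative conditions for [generate_cohort()]: cohort
#' size, sequence model (motif planting and interspecies
#' substitution), latent accessibility process, the linear link from
#' occupancy and accessibility to ChIP signal, and the activity rule.
#'
#' @param n_pairs Number of orthologous enhancer pairs.
#' @param seq_length Enhancer length in bp (must be at least the
#'   longest motif).
#' @param per_tf_pwm Named list of `pwm`s, one per TF.
#' @param site_density Expected planted sites per enhancer per TF
#'   (Poisson mean).
#' @param substitution_rate Per-bp probability of base change between
#'   the two species, in \[0, 1\].
#' @param accessibility_autocorr AR(1) coefficient of the latent
#'   accessibility process across adjacent time points, in \[0, 1\].
#' @param acc_divergence_sd Std-dev of the interspecies perturbation of
#'   the accessibility latent.
#' @param chip_weights Named numeric `c(w_occ=, w_acc=)`: coefficients
#'   linking scaled true occupancy and accessibility to the raw ChIP
#'   signal.
#' @param chip_noise_sd Std-dev of additive ChIP measurement noise.
#' @param class_effect Raw-signal increment added (in both species) to
#'   the conditions defining an enhancer's latent activity class; makes
#'   the three classes separable combinatorial binding profiles.
#' @param gamma_true Concentration parameter at which true occupancies
#'   are computed (single value recycled per TF, or named per TF).
#' @param activity_rule Named list mapping each class to its defining
#'   conditions (see [default_activity_rule()]).
#' @param conditions Condition data.frame (see
#'   [default_conditions()]).
#' @param acc_timepoints Time points at which accessibility is
#'   observed (default TP1, TP3, TP5).
#' @param seed Integer seed; identical seed and config give a
#'   byte-identical cohort, and the per-enhancer RNG streams make
#'   cohort prefixes reproducible across different `n_pairs`.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_pairs = 2754, seq_length = 500,
                              per_tf_pwm = default_mesoderm_pwms(),
                              site_density = 1,
                              substitution_rate = 0.1,
                              accessibility_autocorr = 0.7,
                              acc_divergence_sd = 0.7,
                              chip_weights = c(w_occ = 0.5, w_acc = 0.5),
                              chip_noise_sd = 0.1,
                              class_effect = 0.25,
                              gamma_true = 0.5,
                              activity_rule = default_activity_rule(),
                              conditions = default_conditions(),
                              acc_timepoints = c(1, 3, 5),
                              seed = 1) {
  stopifnot(n_pairs >= 0, n_pairs == round(n_pairs))
  if (substitution_rate < 0 || substitution_rate > 1)
    stop("substitution_rate must be in [0, 1]")
  if (accessibility_autocorr < 0 || accessibility_autocorr > 1)
    stop("accessibility_autocorr must be in [0, 1]")
  if (site_density < 0) stop("site_density must be >= 0")
  if (acc_divergence_sd < 0 || chip_noise_sd < 0)
    stop("standard deviations must be >= 0")
  stopifnot(is.list(per_tf_pwm), length(per_tf_pwm) >= 1,
            !is.null(names(per_tf_pwm)))
  lens <- vapply(per_tf_pwm, pwm_length, integer(1))
  if (seq_length < max(lens))
    stop("seq_length shorter than the longest motif: config rejected")
  stopifnot(all(conditions$tf %in% names(per_tf_pwm)))
  stopifnot(all(c("w_occ", "w_acc") %in% names(chip_weights)))
  if (is.null(names(gamma_true)))
    gamma_true <- setNames(rep_len(gamma_true, length(per_tf_pwm)),
                           names(per_tf_pwm))
  stopifnot(all(names(per_tf_pwm) %in% names(gamma_true)),
            all(gamma_true >= 0))
  rule_conds <- unlist(activity_rule)
  if (!all(rule_conds %in% conditions$name))
    stop("activity_rule refers to unknown conditions: ",
         paste(setdiff(rule_conds, conditions$name), collapse = ", "))
  structure(list(n_pairs = as.integer(n_pairs),
                 seq_length = as.integer(seq_length),
                 per_tf_pwm = per_tf_pwm, site_density = site_density,
                 substitution_rate = substitution_rate,
                 accessibility_autocorr = accessibility_autocorr,
                 acc_divergence_sd = acc_divergence_sd,
                 chip_weights = chip_weights,
                 chip_noise_sd = chip_noise_sd,
                 class_effect = class_effect,
                 gamma_true = gamma_true[names(per_tf_pwm)],
                 activity_rule = activity_rule,
                 conditions = conditions,
                 acc_timepoints = as.integer(acc_timepoints),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# site base codes drawn from the PWM's per-position distribution
sample_site_codes <- function(cum_probs) {
  L <- nrow(cum_probs)
  rowSums(runif(L) > cum_probs) + 1L
}

# per-bp substitution to one of the three other bases, uniformly
mutate_codes <- function(codes, rate) {
  hit <- which(runif(length(codes)) < rate)
  if (length(hit))
    codes[hit] <- ((codes[hit] - 1L +
                    sample.int(3, length(hit), replace = TRUE)) %% 4L) + 1L
  codes
}

# capped min-max used for the latent occupancy scale: same rule as
# normalize_scores, so heavy-tailed occupancies do not squash the bulk
cap_minmax <- function(x) {
  if (length(x) == 0) return(numeric(0))
  mu <- mean(x)
  cap <- mu + 3 * sqrt(mean((x - mu)^2))
  x <- pmin(x, cap)
  lo <- min(x); hi <- max(x)
  if (hi > lo) (x - lo) / (hi - lo) else rep(0, length(x))
}

#' Generate a synthetic orthologous-enhancer cohort
#'
#' Simulates `n_pairs` orthologous enhancer pairs with the statistical
#' structure the downstream analyses assume, plus the ground-truth
#' latents needed for recovery tests:
#' \itemize{
#'   \item Species-1 sequences are i.i.d. uniform background with
#'     Poisson-planted motif sites drawn from each TF's PWM; species-2
#'     sequences are species-1 sequences mutated independently per bp
#'     at `substitution_rate`.
#'   \item True occupancies are computed for both species with the
#'     thermodynamic model at `gamma_true` and min-max scaled per TF.
#'   \item Accessibility follows a latent AR(1) Gaussian process over
#'     the five time points (coefficient `accessibility_autocorr`),
#'     perturbed between species by `acc_divergence_sd` and squashed to
#'     \[0, 1\] by the logistic function; it is observed at
#'     `acc_timepoints`.
#'   \item Raw ChIP signal per condition is
#'     `w_occ * occupancy + w_acc * accessibility(tp) + class bump +
#'     noise`, then capped min-max normalized per condition and
#'     species.
#'   \item Each enhancer's activity label is the class whose
#'     `activity_rule` conditions have the largest mean normalized
#'     ChIP score in species 1.
#' }
#' A single global seed drives one RNG stream per enhancer, so a
#' cohort with smaller `n_pairs` is a prefix of a larger one.
#'
#' @param cfg A `simulation_config`.
#' @return A list of class `synthetic_cohort` with elements `pairs`
#'   (data.frame `id`, `seq_mel`, `seq_vir`), `chip` and `acc` (lists
#'   of normalized `score_table`s per species), `labels` (named
#'   character), `intervals` (`GRanges` per species), `pwms`, `truth`
#'   (latent occupancies, true gammas, noise-free delta-ChIP) and
#'   `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(is(cfg, "simulation_config"))
  n <- cfg$n_pairs
  tfs <- names(cfg$per_tf_pwm)
  classes <- names(cfg$activity_rule)
  n_tp <- 5L
  set.seed(cfg$seed)
  enh_seeds <- sample.int(.Machine$integer.max - 1L, max(n, 1))

  ids <- sprintf("enh%05d", seq_len(n))
  seq_mel <- character(n); seq_vir <- character(n)
  latent_class <- character(n)
  acc_mel_lat <- matrix(0, n, n_tp)
  acc_vir_lat <- matrix(0, n, n_tp)
  noise_mel <- matrix(0, n, nrow(cfg$conditions))
  noise_vir <- matrix(0, n, nrow(cfg$conditions))
  rho <- cfg$accessibility_autocorr
  bases <- c("A", "C", "G", "T")
  cum_probs <- lapply(cfg$per_tf_pwm, function(p)
    t(apply(p$probs, 1, cumsum)))

  for (i in seq_len(n)) {
    set.seed(enh_seeds[i])
    latent_class[i] <- sample(classes, 1)
    codes <- sample.int(4, cfg$seq_length, replace = TRUE)
    for (tf in tfs) {
      L <- pwm_length(cfg$per_tf_pwm[[tf]])
      n_sites <- rpois(1, cfg$site_density)
      for (s in seq_len(n_sites)) {
        pos <- sample.int(cfg$seq_length - L + 1L, 1)
        codes[pos:(pos + L - 1L)] <- sample_site_codes(cum_probs[[tf]])
      }
    }
    seq_mel[i] <- paste(bases[codes], collapse = "")
    seq_vir[i] <- paste(
      bases[mutate_codes(codes, cfg$substitution_rate)], collapse = "")
    z <- numeric(n_tp)
    z[1] <- rnorm(1)
    for (t in 2:n_tp)
      z[t] <- rho * z[t - 1] + sqrt(max(0, 1 - rho^2)) * rnorm(1)
    acc_mel_lat[i, ] <- z
    acc_vir_lat[i, ] <- z + rnorm(n_tp, 0, cfg$acc_divergence_sd)
    noise_mel[i, ] <- rnorm(nrow(cfg$conditions), 0, cfg$chip_noise_sd)
    noise_vir[i, ] <- rnorm(nrow(cfg$conditions), 0, cfg$chip_noise_sd)
  }

  # plogis drops dim attributes on zero-row matrices, so restore them
  acc_mel <- array(plogis(acc_mel_lat), dim(acc_mel_lat))
  acc_vir <- array(plogis(acc_vir_lat), dim(acc_vir_lat))

  # true occupancies at gamma_true, capped min-max scaled per TF
  # across both species pooled so interspecies differences stay on a
  # common scale
  occ <- list(mel = matrix(0, n, length(tfs), dimnames = list(ids, tfs)),
              vir = matrix(0, n, length(tfs), dimnames = list(ids, tfs)))
  for (tf in tfs) {
    p <- cfg$per_tf_pwm[[tf]]
    g <- cfg$gamma_true[[tf]]
    raw_mel <- vapply(seq_mel, function(s)
      occupancy_from_K(window_affinities(p, s), g), numeric(1),
      USE.NAMES = FALSE)
    raw_vir <- vapply(seq_vir, function(s)
      occupancy_from_K(window_affinities(p, s), g), numeric(1),
      USE.NAMES = FALSE)
    pooled <- cap_minmax(c(raw_mel, raw_vir))
    occ$mel[, tf] <- pooled[seq_len(n)]
    occ$vir[, tf] <- pooled[n + seq_len(n)]
  }

  conds <- cfg$conditions
  bump <- matrix(0, n, nrow(conds), dimnames = list(ids, conds$name))
  for (cl in classes)
    bump[latent_class == cl, cfg$activity_rule[[cl]]] <-
      cfg$class_effect
  w <- cfg$chip_weights
  signal <- function(occ_sp, acc_sp) {
    s <- matrix(0, n, nrow(conds), dimnames = list(ids, conds$name))
    for (j in seq_len(nrow(conds)))
      s[, j] <- w[["w_occ"]] * occ_sp[, conds$tf[j]] +
        w[["w_acc"]] * acc_sp[, conds$tp[j]]
    s + bump
  }
  sig_mel <- signal(occ$mel, acc_mel)
  sig_vir <- signal(occ$vir, acc_vir)

  norm_tab <- function(m, species) {
    if (nrow(m) == 0)
      return(score_table(m, species = species, normalized = TRUE))
    suppressWarnings(
      normalize_scores(score_table(m, species = species))$table)
  }
  chip <- list(
    mel = norm_tab(sig_mel + noise_mel, "mel"),
    vir = norm_tab(sig_vir + noise_vir, "vir"))

  acc_cols <- sprintf("Acc:TP%d", cfg$acc_timepoints)
  obs_acc <- function(m, species) {
    m <- m[, cfg$acc_timepoints, drop = FALSE]
    dimnames(m) <- list(ids, acc_cols)
    norm_tab(m, species)
  }
  acc <- list(mel = obs_acc(acc_mel, "mel"),
              vir = obs_acc(acc_vir, "vir"))

  labels <- character(n)
  if (n > 0) {
    rule_means <- vapply(cfg$activity_rule, function(cc)
      rowMeans(chip$mel$values[, cc, drop = FALSE]), numeric(n))
    rule_means <- matrix(rule_means, n, length(classes),
                         dimnames = list(ids, classes))
    labels <- classes[max.col(rule_means, ties.method = "first")]
  }
  names(labels) <- ids

  gap <- 100L
  starts0 <- (seq_len(n) - 1L) * (cfg$seq_length + gap)
  intervals <- list(
    mel = enhancer_intervals(rep("chrS", n), starts0,
                             starts0 + cfg$seq_length, ids, "mel"),
    vir = enhancer_intervals(rep("chrS", n), starts0,
                             starts0 + cfg$seq_length, ids, "vir"))

  structure(list(
    pairs = data.frame(id = ids, seq_mel = seq_mel, seq_vir = seq_vir,
                       stringsAsFactors = FALSE),
    chip = chip, acc = acc, labels = labels, intervals = intervals,
    pwms = cfg$per_tf_pwm,
    truth = list(occupancy = occ, gamma = cfg$gamma_true,
                 delta_chip_true = sig_mel - sig_vir,
                 latent_class = setNames(latent_class, ids),
                 acc_latent = list(mel = acc_mel_lat,
                                   vir = acc_vir_lat)),
    config = cfg), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d orthologous pairs, %d conditions, %d TFs\n",
    nrow(x$pairs), ncol(x$chip$mel$values), length(x$pwms)))
  if (nrow(x$pairs)) print(table(x$labels))
  invisible(x)
}

#' Fit occupancy models for every condition of a cohort
#'
#' For each TF:time-point condition, fits the concentration parameter
#' against the species-1 normalized ChIP scores of the cohort's
#' enhancers, sharing window-affinity computations across conditions of
#' the same TF.
#'
#' @param cohort A `synthetic_cohort`.
#' @param conditions Subset of condition names (default all).
#' @return Named list of `stap_model`s.
#' @export
fit_condition_staps <- function(cohort, conditions = NULL) {
  stopifnot(is(cohort, "synthetic_cohort"))
  conds <- cohort$config$conditions
  if (!is.null(conditions)) conds <- conds[conds$name %in% conditions, ]
  models <- list()
  for (tf in unique(conds$tf)) {
    p <- cohort$pwms[[tf]]
    K_list <- lapply(cohort$pairs$seq_mel, window_affinities, x = p)
    for (cond in conds$name[conds$tf == tf]) {
      targets <- cohort$chip$mel$values[, cond]
      if (length(unique(targets)) < 2)
        stop("uninformative training set: constant targets for ", cond)
      models[[cond]] <- stap_model(p, fit_gamma_K(K_list, targets))
    }
  }
  models[conds$name]
}
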