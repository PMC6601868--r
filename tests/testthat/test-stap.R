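test_that("site affinity is the product of pseudocounted odds ratios", {
  uni <- pwm(matrix(0.25, 3, 4), pseudocount = 0)
  expect_equal(site_affinity(uni, "ACG"), 1)
  expect_equal(site_affinity(uni, "NNN"), 1)

  # point-mass motif, zero pseudocount: (1/0.25)^2
  pm <- pwm(rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)), pseudocount = 0)
  expect_equal(site_affinity(pm, "AC"), 16)
  expect_equal(site_affinity(pm, "TT"), 0)

  # arbitrary motif with pseudocount: matches a direct per-position
  # product
  set.seed(13)
  probs <- matrix(runif(12), 3, 4)
  probs <- probs / rowSums(probs)
  p <- pwm(probs, pseudocount = 0.01)
  win <- "GAT"
  padj <- (p$probs + 0.01) / (1 + 0.04)
  idx <- match(strsplit(win, "")[[1]], c("A", "C", "G", "T"))
  oracle <- prod(padj[cbind(1:3, idx)] / 0.25)
  expect_equal(site_affinity(p, win), oracle, tolerance = 1e-12)

  expect_error(site_affinity(p, "GATT"), "length")
  expect_error(pwm(matrix(0.3, 2, 4)), "sum to 1")
})

test_that("occupancy sums fractional site occupancies on both strands", {
  uni <- pwm(matrix(0.25, 2, 4), pseudocount = 0)
  expect_equal(occupancy(stap_model(uni, 1), "ACGTA"), 4)  # 8 x 1/2
  expect_equal(occupancy(stap_model(uni, 0), "ACGTA"), 0)
  expect_error(occupancy(stap_model(test_pwm(), 1), "ACG"), "shorter")

  # monotone in gamma, bounded by twice the window count
  p <- test_pwm()
  set.seed(4)
  s <- random_dna(60)
  occs <- vapply(c(0, 0.01, 0.1, 1, 10, 1e4),
                 function(g) occupancy(stap_model(p, g), s), numeric(1))
  expect_true(all(diff(occs) >= 0))
  expect_lt(max(occs), 2 * (60 - pwm_length(p) + 1) + 1e-9)

  # reverse complement leaves occupancy unchanged
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  m <- stap_model(p, 0.37)
  expect_equal(occupancy(m, s), occupancy(m, rc), tolerance = 1e-12)
})

test_that("occupancy equals exhaustive per-site enumeration", {
  set.seed(101)
  for (rep in 1:25) {
    L <- sample(2:8, 1)
    probs <- matrix(runif(4 * L), L, 4)
    probs <- probs / rowSums(probs)
    p <- pwm(probs, pseudocount = sample(c(0, 0.01, 0.1), 1))
    s <- random_dna(sample(L:100, 1))
    g <- exp(runif(1, -4, 2))
    expect_equal(occupancy(stap_model(p, g), s),
                 brute_force_occupancy(p, s, g), tolerance = 1e-9)
  }
})

test_that("gamma fitting recovers noiseless generative scores", {
  p <- test_pwm()
  set.seed(77)
  seqs <- vapply(1:120, function(i) random_dna(80), character(1))
  true_model <- stap_model(p, 2)
  occ <- vapply(seqs, function(s) occupancy(true_model, s), numeric(1))
  targets <- (occ - min(occ)) / (max(occ) - min(occ))
  train <- stap_training_set(seqs, targets)
  fit <- fit_gamma(train, p)
  pred <- vapply(seqs, function(s) occupancy(fit, s), numeric(1))
  expect_gte(cor(pred, targets), 0.999)

  # determinism
  fit2 <- fit_gamma(train, p)
  expect_identical(fit$gamma, fit2$gamma)

  expect_error(fit_gamma(stap_training_set(seqs, rep(0.5, 120)), p),
               "uninformative")
})

test_that("cross-validation aggregates honest out-of-fold predictions", {
  p <- test_pwm()
  set.seed(31)
  seqs <- vapply(1:80, function(i) random_dna(70), character(1))
  occ <- vapply(seqs, function(s) occupancy(stap_model(p, 2), s),
                numeric(1))
  targets <- (occ - min(occ)) / (max(occ) - min(occ))
  train <- stap_training_set(seqs, targets)
  cv <- crossval_stap(train, p, k = 4)
  expect_gte(cv$pcc, 0.999)
  expect_length(cv$fold_gamma, 4)
  # similar gamma across folds on clean data
  expect_lt(diff(range(log(cv$fold_gamma))), 1)

  # permuted targets carry no signal
  set.seed(32)
  shuf <- stap_training_set(seqs, sample(targets))
  expect_lt(abs(crossval_stap(shuf, p, k = 4)$pcc), 0.35)

  # leave-one-out is the k = n boundary
  small <- stap_training_set(seqs[1:12], targets[1:12])
  loo <- crossval_stap(small, p, k = 12)
  expect_length(loo$predictions, 12)
  expect_error(crossval_stap(small, p, k = 13), "more folds")
})

test_that("cohort motif scores respond to sequence divergence", {
  coh <- cached_cohort("tiny", simulation_config(
    n_pairs = 120, seq_length = 200, seed = 5))
  models <- fit_condition_staps(coh, c("Twi:TP1", "Bin:TP3"))

  # identical species sequences give identical score tables
  same <- coh$pairs
  same$seq_vir <- same$seq_mel
  st <- stap_score_table(models, same)
  expect_equal(st$mel$values, st$vir$values, tolerance = 1e-12)
  expect_true(all(st$mel$values >= 0 & st$mel$values <= 1))

  # heavy mutation of species 2 increases the interspecies change for
  # enhancers that carried sites
  set.seed(6)
  wrecked <- coh$pairs
  wrecked$seq_vir <- vapply(nchar(wrecked$seq_mel), random_dna,
                            character(1))
  st2 <- stap_score_table(models, wrecked)
  dstap <- st2$mel$values - st2$vir$values
  top_mel <- st2$mel$values[, "Twi:TP1"] > 0.8
  expect_gt(mean(dstap[top_mel, "Twi:TP1"]), 0)

  expect_error(stap_score_table(models,
    data.frame(id = "e1", seq_mel = "ACGT", seq_vir = "")),
    "missing sequence")
})

test_that("PWM files round-trip", {
  pwms <- default_mesoderm_pwms()
  f <- withr::local_tempfile(fileext = ".txt")
  write_pwm_file(pwms, f)
  back <- read_pwm_file(f)
  expect_identical(names(back), names(pwms))
  for (nm in names(pwms))
    expect_equal(back[[nm]]$probs, pwms[[nm]]$probs, tolerance = 1e-9,
                 ignore_attr = TRUE)
})
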