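test_that("configs are validated against their invariants", {
  expect_error(simulation_config(substitution_rate = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(acc_divergence_sd = -1), ">= 0")
  expect_error(simulation_config(seq_length = 5), "longest motif")
  expect_error(simulation_config(
    activity_rule = list(Meso = "Nope:TP1")), "unknown conditions")
  cfg <- simulation_config(n_pairs = 10)
  expect_s3_class(cfg, "simulation_config")
})

test_that("cohorts are deterministic in the seed and prefix-stable", {
  cfg <- function(n, seed) simulation_config(
    n_pairs = n, seq_length = 150, seed = seed)
  a <- generate_cohort(cfg(40, 7))
  b <- generate_cohort(cfg(40, 7))
  expect_identical(a$pairs, b$pairs)
  expect_identical(a$chip$mel$values, b$chip$mel$values)
  expect_identical(a$labels, b$labels)
  c8 <- generate_cohort(cfg(40, 8))
  expect_false(identical(a$pairs$seq_mel, c8$pairs$seq_mel))

  # hierarchical per-enhancer streams: a smaller cohort is a prefix of
  # a larger one
  big <- generate_cohort(cfg(60, 7))
  expect_identical(a$pairs$seq_mel, big$pairs$seq_mel[1:40])
  expect_identical(a$pairs$seq_vir, big$pairs$seq_vir[1:40])
})

test_that("zero divergence yields identical species", {
  coh <- generate_cohort(simulation_config(
    n_pairs = 30, seq_length = 150, substitution_rate = 0,
    acc_divergence_sd = 0, chip_noise_sd = 0, seed = 3))
  expect_identical(coh$pairs$seq_mel, coh$pairs$seq_vir)
  expect_true(all(coh$truth$delta_chip_true == 0))
  d <- delta_table(coh$chip$mel, coh$chip$vir)
  expect_equal(max(abs(d$values)), 0, tolerance = 1e-12)
})

test_that("cohorts satisfy the structural contracts", {
  coh <- cached_cohort("tiny", simulation_config(
    n_pairs = 120, seq_length = 200, seed = 5))
  ids <- coh$pairs$id
  expect_false(anyDuplicated(ids) > 0)
  for (sp in c("mel", "vir")) {
    expect_identical(rownames(coh$chip[[sp]]$values), ids)
    expect_identical(rownames(coh$acc[[sp]]$values), ids)
    expect_true(all(coh$chip[[sp]]$values >= 0 &
                    coh$chip[[sp]]$values <= 1))
    expect_true(all(coh$acc[[sp]]$values >= 0 &
                    coh$acc[[sp]]$values <= 1))
  }
  expect_true(all(coh$labels %in% c("Meso", "VM", "SM")))
  expect_identical(names(coh$labels), ids)
  # the label rule: class whose defining conditions have the largest
  # mean normalized species-1 ChIP
  rule <- coh$config$activity_rule
  means <- vapply(rule, function(cc)
    rowMeans(coh$chip$mel$values[, cc, drop = FALSE]),
    numeric(length(ids)))
  expect_identical(unname(coh$labels),
                   names(rule)[max.col(means, ties.method = "first")])
})

test_that("accessibility-driven binding change is recovered as a
           correlation between the planted deltas", {
  coh <- cached_cohort("acc_only_1000", simulation_config(
    n_pairs = 1000, seq_length = 150, seed = 11,
    chip_weights = c(w_occ = 0, w_acc = 0.8), chip_noise_sd = 0.05))
  d_acc <- coh$acc$mel$values[, "Acc:TP1"] -
    coh$acc$vir$values[, "Acc:TP1"]
  d_chip <- delta_table(coh$chip$mel, coh$chip$vir)$values[, "Twi:TP1"]
  r_low_noise <- cor(d_acc, d_chip)
  expect_gt(r_low_noise, 0.5)

  # the correlation weakens as the ChIP noise grows
  noisy <- generate_cohort(simulation_config(
    n_pairs = 1000, seq_length = 150, seed = 11,
    chip_weights = c(w_occ = 0, w_acc = 0.8), chip_noise_sd = 0.5))
  d_chip_noisy <- delta_table(noisy$chip$mel,
                              noisy$chip$vir)$values[, "Twi:TP1"]
  expect_gt(r_low_noise, cor(d_acc, d_chip_noisy))
})

test_that("species swap negates the interspecies differences", {
  coh <- cached_cohort("tiny", simulation_config(
    n_pairs = 120, seq_length = 200, seed = 5))
  d1 <- delta_table(coh$chip$mel, coh$chip$vir)$values
  d2 <- delta_table(coh$chip$vir, coh$chip$mel)$values
  expect_equal(d1, -d2)
})

test_that("sequence divergence dial moves motif-score concordance", {
  base <- function(rate) simulation_config(
    n_pairs = 150, seq_length = 150, substitution_rate = rate,
    seed = 19)
  conserved <- generate_cohort(base(0))
  diverged <- generate_cohort(base(0.5))
  models <- fit_condition_staps(conserved, "Twi:TP1")
  st_c <- stap_score_table(models, conserved$pairs)
  st_d <- stap_score_table(models, diverged$pairs)
  r_c <- cor(st_c$mel$values[, 1], st_c$vir$values[, 1])
  r_d <- cor(st_d$mel$values[, 1], st_d$vir$values[, 1])
  expect_gt(r_c, 0.99)   # identical sequences
  expect_gt(r_c, r_d)    # heavy substitution decays the concordance
})

test_that("cohorts round-trip through standard file formats", {
  coh <- generate_cohort(simulation_config(
    n_pairs = 25, seq_length = 120, seed = 23))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_identical(back$pairs$id, coh$pairs$id)
  expect_identical(back$pairs$seq_mel, coh$pairs$seq_mel)
  expect_identical(back$pairs$seq_vir, coh$pairs$seq_vir)
  expect_identical(back$labels, coh$labels)
  for (sp in c("mel", "vir")) {
    expect_equal(back$chip[[sp]]$values, coh$chip[[sp]]$values,
                 tolerance = 1e-10)
    expect_equal(back$acc[[sp]]$values, coh$acc[[sp]]$values,
                 tolerance = 1e-6)
    expect_identical(back$intervals[[sp]]$id, coh$intervals[[sp]]$id)
  }
  expect_equal(back$pwms$Twi$probs, coh$pwms$Twi$probs,
               tolerance = 1e-9, ignore_attr = TRUE)

  # an empty cohort writes valid, readable files
  empty <- generate_cohort(simulation_config(
    n_pairs = 0, seq_length = 120, seed = 1))
  dir2 <- withr::local_tempdir()
  write_cohort(empty, dir2)
  back2 <- read_cohort(dir2)
  expect_equal(nrow(back2$chip$mel$values), 0)
  expect_length(back2$labels, 0)
})
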