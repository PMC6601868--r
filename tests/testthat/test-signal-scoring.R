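make_track <- function(starts0, ends0, values, chrom = "chr2L") {
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = starts0 + 1, end = ends0))
  gr$score <- values
  gr
}

test_that("mean signal is the length-weighted average with zero fill", {
  tr <- make_track(c(0, 50), c(50, 100), c(1, 3))
  iv <- enhancer_intervals(rep("chr2L", 3), c(0, 40, 20), c(100, 55, 40),
                           c("a", "b", "c"))
  m <- mean_signal_over_interval(tr, iv)
  expect_equal(unname(m["a"]), 2)
  expect_equal(unname(m["b"]), 25 / 15)  # 10 bases at 1, 5 at 3
  expect_equal(unname(m["c"]), 1)

  # constant track gives the constant
  expect_equal(unname(mean_signal_over_interval(
    make_track(0, 1000, 2), enhancer_intervals("chr2L", 3, 97, "x"))), 2)

  # uncovered bases count as zero
  gap <- make_track(c(0, 80), c(20, 100), c(5, 5))
  expect_equal(unname(mean_signal_over_interval(
    gap, enhancer_intervals("chr2L", 0, 100, "x"))), 40 * 5 / 100)
  # entirely uncovered chromosome
  expect_equal(unname(mean_signal_over_interval(
    gap, enhancer_intervals("chrX", 0, 10, "y"))), 0)

  expect_error(enhancer_intervals("chr2L", 10, 10, "z"), "start < end")
})

test_that("mean signal is invariant to splitting equal-valued segments", {
  set.seed(3)
  for (rep in 1:5) {
    cuts <- sort(sample(10:490, 6))
    vals <- runif(7, 0, 5)
    bounds <- c(0, cuts, 500)
    whole <- make_track(bounds[-length(bounds)], bounds[-1], vals)
    # split every segment at its midpoint, duplicating the value
    mids <- floor((bounds[-length(bounds)] + bounds[-1]) / 2)
    split_tr <- make_track(
      as.vector(rbind(bounds[-length(bounds)], mids)),
      as.vector(rbind(mids, bounds[-1])),
      rep(vals, each = 2))
    iv <- enhancer_intervals("chr2L", c(7, 123), c(321, 456),
                             c("p", "q"))
    expect_equal(mean_signal_over_interval(whole, iv),
                 mean_signal_over_interval(split_tr, iv))
  }
})

test_that("capped min-max normalization follows the mu+3sigma rule", {
  st <- score_table(matrix(c(0, 5, 10), 3, 1,
                           dimnames = list(c("a", "b", "c"), "x")))
  expect_equal(unname(normalize_scores(st)$table$values[, 1]),
               c(0, 0.5, 1))

  # a single huge outlier is capped at mu + 3*sigma and becomes the max
  v <- c(rep(1, 19), 100)
  st <- score_table(matrix(v, 20, 1,
                           dimnames = list(sprintf("e%02d", 1:20), "x")))
  res <- normalize_scores(st)
  mu <- mean(v); sigma <- sqrt(mean((v - mu)^2))
  expect_equal(res$params$mu, mu)
  expect_equal(res$params$sigma, sigma)
  expect_equal(res$params$cap, mu + 3 * sigma)
  expect_equal(unname(res$table$values[, 1]), c(rep(0, 19), 1))

  # constant column degenerates to zeros with a warning
  st <- score_table(matrix(2, 4, 1, dimnames = list(letters[1:4], "x")))
  expect_warning(res <- normalize_scores(st), "constant column")
  expect_equal(unname(res$table$values[, 1]), rep(0, 4))

  # re-normalizing an already [0,1] outlier-free column changes nothing
  set.seed(5)
  v <- runif(50)
  v <- (v - min(v)) / (max(v) - min(v))
  st <- score_table(matrix(v, 50, 1,
                           dimnames = list(sprintf("e%02d", 1:50), "x")))
  n1 <- normalize_scores(st)$table
  n2 <- normalize_scores(score_table(n1$values))$table
  expect_equal(n1$values, n2$values, tolerance = 1e-12)

  expect_error(normalize_scores(n1), "already normalized")
})

test_that("delta tables are exact antisymmetric differences", {
  set.seed(9)
  ids <- sprintf("e%02d", 1:10)
  a <- score_table(matrix(runif(20), 10, 2,
                          dimnames = list(ids, c("c1", "c2"))),
                   species = "mel", normalized = TRUE)
  b <- score_table(matrix(runif(20), 10, 2,
                          dimnames = list(ids, c("c1", "c2"))),
                   species = "vir", normalized = TRUE)
  d <- delta_table(a, b)
  expect_equal(d$values, a$values - b$values)
  expect_equal(delta_table(b, a)$values, -d$values)
  expect_equal(delta_table(a, a)$values,
               matrix(0, 10, 2, dimnames = dimnames(a$values)))
  expect_true(all(d$values >= -1 & d$values <= 1))

  bad <- score_table(matrix(runif(20), 10, 2,
                            dimnames = list(rev(ids), c("c1", "c2"))),
                     normalized = TRUE)
  expect_error(delta_table(a, bad), "id mismatch")
  bad2 <- score_table(matrix(runif(20), 10, 2,
                             dimnames = list(ids, c("c1", "zz"))),
                      normalized = TRUE)
  expect_error(delta_table(a, bad2), "condition mismatch")
})

test_that("accessibility filter uses a strict threshold on the max", {
  ids <- c("lo", "edge", "hi")
  mk <- function(v) score_table(matrix(v, 3, 1,
                                       dimnames = list(ids, "Acc:TP1")),
                                normalized = TRUE)
  mel <- mk(c(0.1, 0.3, 0.31))
  vir <- mk(c(0.2, 0.3, 0.0))
  expect_equal(accessible_pairs(mel, vir, "Acc:TP1"), "hi")
  expect_error(accessible_pairs(mel, vir, "Acc:TP9"), "absent")

  # with uniform scores in both species the retained fraction is
  # 1 - threshold^2
  set.seed(21)
  n <- 1000
  ids <- sprintf("e%04d", 1:n)
  mel <- score_table(matrix(runif(n), n, 1,
                            dimnames = list(ids, "Acc:TP1")),
                     normalized = TRUE)
  vir <- score_table(matrix(runif(n), n, 1,
                            dimnames = list(ids, "Acc:TP1")),
                     normalized = TRUE)
  frac <- length(accessible_pairs(mel, vir, "Acc:TP1", 0.3)) / n
  expect_equal(frac, 1 - 0.3^2, tolerance = 0.05)
})

test_that("score tables round-trip through TSV", {
  set.seed(2)
  st <- score_table(matrix(runif(12), 4, 3,
                           dimnames = list(sprintf("e%d", 1:4),
                                           c("Twi:TP1", "Acc:TP3", "x"))),
                    species = "mel", normalized = TRUE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(st, f)
  back <- read_score_table(f, species = "mel", normalized = TRUE)
  expect_equal(back$values, st$values, tolerance = 1e-12)
})
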