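# cohort cache: expensive fixtures are generated once per test run
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, cfg) {
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(cfg)
  .cohort_cache[[key]]
}

# a short informative motif for fast unit tests
test_pwm <- function(dominant = 0.85) {
  probs <- matrix((1 - dominant) / 3, 5, 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
  consensus <- c("A", "C", "G", "T", "A")
  probs[cbind(1:5, match(consensus, c("A", "C", "G", "T")))] <- dominant
  pwm(probs, name = "testTF")
}

# brute-force occupancy oracle: per-window product of odds ratios on
# both strands, computed position by position without shared code paths
brute_force_occupancy <- function(p, seq_chr, gamma) {
  padj <- (p$probs + p$pseudocount) / (1 + 4 * p$pseudocount)
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  score_window <- function(win) {
    k <- 1
    for (i in seq_along(win)) {
      b <- win[i]
      k <- k * if (b %in% bases)
        padj[i, b] / p$background[match(b, bases)] else 1
    }
    k
  }
  chars <- strsplit(toupper(seq_chr), "")[[1]]
  L <- nrow(p$probs)
  total <- 0
  for (s in 1:(length(chars) - L + 1)) {
    win <- chars[s:(s + L - 1)]
    rc <- rev(unname(ifelse(win %in% bases, comp[win], win)))
    for (w in list(win, rc)) {
      k <- score_window(w)
      total <- total + gamma * k / (1 + gamma * k)
    }
  }
  unname(total)
}

random_dna <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
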