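#' Construct a position weight matrix
#'
#' A PWM is an L x 4 matrix of per-position base probabilities over
#' (A, C, G, T), with a pseudocount used when converting probabilities
#' to odds ratios, and a background base distribution (uniform by
#' default).
#'
#' @param probs Numeric L x 4 matrix; rows must sum to 1 (tolerance
#'   1e-9). Columns may be named A, C, G, T or are taken in that order.
#' @param name Motif name (e.g. the TF it models).
#' @param pseudocount Probability mass added to every cell before
#'   renormalizing rows; avoids zero affinities. Default 0.01.
#' @param background Background base probabilities (A, C, G, T);
#'   default uniform.
#' @return An object of class `pwm`.
#' @export
pwm <- function(probs, name = "motif", pseudocount = 0.01,
                background = rep(0.25, 4)) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) stop("PWM must have 4 columns (A, C, G, T)")
  if (nrow(probs) < 1) stop("PWM must have at least one position")
  if (!is.null(colnames(probs))) {
    if (!setequal(colnames(probs), c("A", "C", "G", "T")))
      stop("PWM columns must be A, C, G, T")
    probs <- probs[, c("A", "C", "G", "T"), drop = FALSE]
  } else colnames(probs) <- c("A", "C", "G", "T")
  if (any(probs < 0)) stop("PWM probabilities must be non-negative")
  if (any(abs(rowSums(probs) - 1) > 1e-9))
    stop("PWM rows must sum to 1")
  stopifnot(pseudocount >= 0, length(background) == 4,
            all(background > 0), abs(sum(background) - 1) < 1e-6)
  structure(list(name = name, probs = probs,
                 pseudocount = pseudocount,
                 background = as.numeric(background)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': %d positions, pseudocount %g\n",
              x$name, nrow(x$probs), x$pseudocount))
  invisible(x)
}

#' Motif length
#' @param x A `pwm`.
#' @return Integer number of positions.
#' @export
pwm_length <- function(x) nrow(x$probs)

# log odds-ratio matrix with a 5th column of zeros for ambiguous bases
# (N contributes background probability, i.e. odds factor 1)
pwm_log_odds <- function(x) {
  p <- (x$probs + x$pseudocount) / (1 + 4 * x$pseudocount)
  lo <- log(p) - matrix(log(x$background), nrow(p), 4, byrow = TRUE)
  cbind(lo, 0)
}

# DNA character vector -> integer codes A=1 C=2 G=3 T=4, other=5
dna_codes <- function(seq_chr) {
  codes <- match(strsplit(toupper(seq_chr), "")[[1]],
                 c("A", "C", "G", "T"))
  codes[is.na(codes)] <- 5L
  codes
}

# reverse-complement of a code vector (N stays N)
revcomp_codes <- function(codes) rev(c(4L, 3L, 2L, 1L, 5L)[codes])

#' Relative binding affinity of a single site
#'
#' Odds-ratio score of one window against the PWM:
#' \eqn{K = \prod_i p'_i(b_i) / q(b_i)} where \eqn{p'} is the
#' pseudocount-adjusted PWM and \eqn{q} the background. The consensus
#' window maximizes K; an ambiguous base (N) contributes a factor of 1.
#' Only the given strand of the window is scored.
#'
#' @param x A `pwm`.
#' @param window Character string of length exactly `pwm_length(x)`.
#' @return Non-negative relative affinity K.
#' @export
site_affinity <- function(x, window) {
  stopifnot(is(x, "pwm"), is.character(window), length(window) == 1)
  codes <- dna_codes(window)
  if (length(codes) != pwm_length(x))
    stop(sprintf("window length %d does not match motif length %d",
                 length(codes), pwm_length(x)))
  lo <- pwm_log_odds(x)
  exp(sum(lo[cbind(seq_along(codes), codes)]))
}

# relative affinities of every window on both strands of a sequence;
# returns c(forward windows, reverse-strand windows)
window_affinities <- function(x, seq_chr) {
  codes <- dna_codes(seq_chr)
  L <- pwm_length(x)
  n <- length(codes)
  if (n < L) stop("sequence shorter than motif")
  lo <- pwm_log_odds(x)
  scan <- function(cd) {
    nw <- length(cd) - L + 1L
    s <- numeric(nw)
    for (i in seq_len(L))
      s <- s + lo[i, cd[i:(i + nw - 1L)]]
    s
  }
  exp(c(scan(codes), scan(revcomp_codes(codes))))
}

#' Write PWMs to a text file
#'
#' Format: a `>name` header line followed by four whitespace-delimited
#' rows of probabilities for bases A, C, G, T (columns are motif
#' positions).
#'
#' @param pwms A `pwm` or list of `pwm`s.
#' @param path Output path.
#' @export
write_pwm_file <- function(pwms, path) {
  if (is(pwms, "pwm")) pwms <- list(pwms)
  lines <- unlist(lapply(pwms, function(p) {
    c(paste0(">", p$name),
      apply(t(p$probs), 1, function(r)
        paste(formatC(r, format = "g", digits = 10), collapse = " ")))
  }))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write PWM file to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read PWMs from a text file
#'
#' @param path File in the format written by [write_pwm_file()].
#' @param pseudocount,background Passed to [pwm()].
#' @return Named list of `pwm`s.
#' @export
read_pwm_file <- function(path, pseudocount = 0.01,
                          background = rep(0.25, 4)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no PWM records in ", path)
  out <- list()
  for (s in starts) {
    name <- sub("^>", "", lines[s])
    rows <- lines[(s + 1):(s + 4)]
    m <- t(vapply(rows, function(r)
      as.numeric(strsplit(r, "\\s+")[[1]]), numeric(
        length(strsplit(rows[1], "\\s+")[[1]]))))
    probs <- t(m)  # positions x bases
    colnames(probs) <- c("A", "C", "G", "T")
    out[[name]] <- pwm(probs, name = name, pseudocount = pseudocount,
                       background = background)
  }
  out
}
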