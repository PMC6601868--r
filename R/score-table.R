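#' Construct a per-enhancer score table
#'
#' A `score_table` holds one species' quantitative scores for a set of
#' enhancers across conditions (TF:time-point ChIP conditions,
#' accessibility time points, or motif-occupancy conditions). It wraps a
#' numeric matrix with enhancer ids as row names and condition names as
#' column names, plus a species tag and a normalization flag.
#'
#' @param values Numeric matrix (enhancers x conditions) with complete,
#'   finite cells.
#' @param ids Enhancer identifiers (defaults to rownames of `values`).
#' @param conditions Condition names (defaults to colnames).
#' @param species Species tag, e.g. `"mel"` or `"vir"`.
#' @param normalized Logical; `TRUE` once capped min-max normalization
#'   has been applied (all values then lie in \[0, 1\]).
#' @return An object of class `score_table`.
#' @export
score_table <- function(values, ids = rownames(values),
                        conditions = colnames(values),
                        species = "unknown", normalized = FALSE) {
  values <- as.matrix(values)
  if (is.null(ids) && nrow(values) == 0) ids <- character(0)
  if (is.null(conditions) && ncol(values) == 0) conditions <- character(0)
  if (is.null(ids) || is.null(conditions))
    stop("ids and conditions are required")
  stopifnot(length(ids) == nrow(values),
            length(conditions) == ncol(values))
  if (anyDuplicated(ids)) stop("duplicate enhancer ids")
  if (anyDuplicated(conditions)) stop("duplicate condition names")
  storage.mode(values) <- "double"
  if (length(values) && any(!is.finite(values)))
    stop("score table has missing or non-finite cells")
  if (normalized && length(values) &&
      (min(values) < 0 || max(values) > 1))
    stop("normalized score table must lie in [0, 1]")
  dimnames(values) <- list(as.character(ids), as.character(conditions))
  structure(list(values = values, species = species,
                 normalized = normalized),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score_table: %d enhancers x %d conditions [%s, %s]\n",
              nrow(x$values), ncol(x$values), x$species,
              if (x$normalized) "normalized" else "raw"))
  if (nrow(x$values)) print(head(x$values, 4))
  invisible(x)
}

#' @export
dim.score_table <- function(x) dim(x$values)

# R normalizes zero-length dimnames to NULL, so map that back to
# character(0) for a stable contract
st_ids <- function(x) {
  ids <- rownames(x$values)
  if (is.null(ids)) character(0) else ids
}
st_conditions <- function(x) {
  cc <- colnames(x$values)
  if (is.null(cc)) character(0) else cc
}

#' Capped min-max normalization of a score table
#'
#' Per column, values greater than \eqn{\mu + 3\sigma} (mean and
#' population standard deviation across all enhancers in the table) are
#' replaced by \eqn{\mu + 3\sigma}, and the capped column is then
#' min-max scaled to \[0, 1\]. The same rule is applied to ChIP,
#' accessibility and motif-occupancy columns alike. A constant column
#' maps to all zeros (with a warning), preserving the range contract.
#'
#' @param raw A raw (`normalized = FALSE`) `score_table`.
#' @return A list with `table` (the normalized `score_table`) and
#'   `params` (a data.frame of per-column `mu`, `sigma`, `cap`,
#'   `post_cap_min`, `post_cap_max`).
#' @examples
#' st <- score_table(matrix(c(0, 5, 10), 3, 1,
#'                   dimnames = list(paste0("e", 1:3), "Twi:TP1")))
#' normalize_scores(st)$table$values
#' @export
normalize_scores <- function(raw) {
  stopifnot(is(raw, "score_table"))
  if (raw$normalized) stop("score table already normalized")
  v <- raw$values
  params <- data.frame(condition = st_conditions(raw), mu = NA_real_,
                       sigma = NA_real_, cap = NA_real_,
                       post_cap_min = NA_real_, post_cap_max = NA_real_)
  for (j in seq_len(ncol(v))) {
    col <- v[, j]
    mu <- mean(col)
    sigma <- sqrt(mean((col - mu)^2))   # population sd
    cap <- mu + 3 * sigma
    col[col > cap] <- cap
    lo <- min(col); hi <- max(col)
    if (hi > lo) {
      col <- (col - lo) / (hi - lo)
    } else {
      warning(sprintf("constant column '%s': normalized to all zeros",
                      colnames(v)[j]))
      col[] <- 0
    }
    v[, j] <- col
    params[j, -1] <- c(mu, sigma, cap, lo, hi)
  }
  list(table = score_table(v, species = raw$species, normalized = TRUE),
       params = params)
}

#' Interspecies difference of two normalized score tables
#'
#' Computes `mel - vir` cell-wise: the per-enhancer, per-condition
#' interspecies change in normalized score (delta-ChIP, delta-Acc or
#' delta-STAP depending on the tables supplied). Values lie in
#' \[-1, 1\] and the operation is exactly antisymmetric in its
#' arguments.
#'
#' @param mel,vir Normalized `score_table`s with identical ids and
#'   conditions.
#' @return A `score_table` of differences (flagged `normalized = FALSE`
#'   since values may be negative), species tag `"<mel>-<vir>"`.
#' @export
delta_table <- function(mel, vir) {
  stopifnot(is(mel, "score_table"), is(vir, "score_table"))
  if (!mel$normalized || !vir$normalized)
    stop("delta_table requires normalized tables")
  if (!identical(st_ids(mel), st_ids(vir))) {
    d <- union(setdiff(st_ids(mel), st_ids(vir)),
               setdiff(st_ids(vir), st_ids(mel)))
    stop("id mismatch between tables: ",
         paste(head(d, 5), collapse = ", "),
         if (length(d) > 5) " ..." else "",
         if (!length(d)) " (same set, different order)" else "")
  }
  if (!identical(st_conditions(mel), st_conditions(vir))) {
    d <- union(setdiff(st_conditions(mel), st_conditions(vir)),
               setdiff(st_conditions(vir), st_conditions(mel)))
    stop("condition mismatch between tables: ",
         paste(d, collapse = ", "),
         if (!length(d)) " (same set, different order)" else "")
  }
  score_table(mel$values - vir$values,
              species = paste0(mel$species, "-", vir$species),
              normalized = FALSE)
}

#' Enhancer pairs accessible in at least one species
#'
#' Returns the ids whose normalized accessibility score at the given
#' time point exceeds `threshold` (strict inequality) in at least one of
#' the two species.
#'
#' @param acc_mel,acc_vir Normalized accessibility `score_table`s with a
#'   common id set.
#' @param tp Accessibility condition name (e.g. `"Acc:TP1"`).
#' @param threshold Accessibility cutoff; default 0.3.
#' @return Character vector of enhancer ids.
#' @export
accessible_pairs <- function(acc_mel, acc_vir, tp, threshold = 0.3) {
  stopifnot(is(acc_mel, "score_table"), is(acc_vir, "score_table"))
  if (!acc_mel$normalized || !acc_vir$normalized)
    stop("accessible_pairs requires normalized tables")
  if (!identical(st_ids(acc_mel), st_ids(acc_vir)))
    stop("id mismatch between accessibility tables")
  for (tab in list(acc_mel, acc_vir))
    if (!tp %in% st_conditions(tab))
      stop(sprintf("time point '%s' absent from %s table", tp, tab$species))
  keep <- pmax(acc_mel$values[, tp], acc_vir$values[, tp]) > threshold
  st_ids(acc_mel)[keep]
}

#' Write a score table to TSV
#'
#' Tab-separated with a header row; the first column (`id`) holds
#' enhancer ids, remaining columns the conditions.
#'
#' @param st A `score_table`.
#' @param path Output file path.
#' @export
write_score_table <- function(st, path) {
  stopifnot(is(st, "score_table"))
  df <- data.frame(id = st_ids(st), st$values, check.names = FALSE)
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write score table to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a score table from TSV
#'
#' @param path File written by [write_score_table()].
#' @param species Species tag to attach.
#' @param normalized Normalization flag to attach.
#' @return A `score_table`.
#' @export
read_score_table <- function(path, species = "unknown",
                             normalized = FALSE) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = c(id = "character"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  score_table(m, species = species, normalized = normalized)
}
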