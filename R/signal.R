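#' Enhancer intervals as a GRanges
#'
#' Convenience constructor turning 0-based half-open interval
#' coordinates (the BED convention) into a `GRanges` with enhancer ids
#' and a species tag. Internally all interval arithmetic uses the
#' 1-based closed `GRanges` convention.
#'
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open coordinates, `start < end`.
#' @param id Enhancer identifiers.
#' @param species Species tag.
#' @return A `GRanges` with metadata columns `id` and `species`.
#' @export
enhancer_intervals <- function(chrom, start, end, id, species = "unknown") {
  if (length(chrom) == 1) chrom <- rep_len(chrom, length(start))
  stopifnot(length(chrom) == length(start), length(start) == length(end),
            length(end) == length(id))
  if (any(start < 0) || any(start >= end))
    stop("intervals must satisfy 0 <= start < end")
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    id = as.character(id), species = rep_len(species, length(id)))
}

#' Read a bedGraph signal track
#'
#' Imports a 4-column bedGraph (chrom, start, end, value) as a sorted
#' `GRanges` with a `score` column. Segments must be non-overlapping.
#'
#' @param path bedGraph file path.
#' @return A `GRanges` signal track.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- GenomicRanges::sort(gr)
  if (length(gr) > 1 &&
      any(S4Vectors::queryHits(GenomicRanges::findOverlaps(gr, gr)) !=
          S4Vectors::subjectHits(GenomicRanges::findOverlaps(gr, gr))))
    stop("signal track has overlapping segments: ", path)
  if (any(!is.finite(gr$score))) stop("non-finite signal values: ", path)
  gr
}

#' Write a signal track to bedGraph
#'
#' @param track `GRanges` with a `score` column.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  ok <- tryCatch({
    rtracklayer::export(track, path, format = "bedGraph")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write bedGraph to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Length-weighted mean signal over intervals
#'
#' Computes, for each query interval, the mean of the track value over
#' every base of the interval. Bases not covered by any track segment
#' contribute 0, matching coverage-track semantics.
#'
#' @param track `GRanges` signal track with `score` (non-overlapping
#'   segments).
#' @param ivs `GRanges` of query intervals (e.g. from
#'   [enhancer_intervals()]); zero-width intervals are an error.
#' @return Numeric vector of mean signals, one per interval, named by
#'   the `id` column when present.
#' @examples
#' tr <- GenomicRanges::GRanges("chr2L",
#'         IRanges::IRanges(c(1, 51), c(50, 100)), score = c(1, 3))
#' iv <- enhancer_intervals("chr2L", 40, 55, "e1")
#' mean_signal_over_interval(tr, iv)  # 25/15
#' @export
mean_signal_over_interval <- function(track, ivs) {
  stopifnot(is(track, "GRanges"), is(ivs, "GRanges"))
  if (is.null(track$score)) stop("track has no score column")
  w <- GenomicRanges::width(ivs)
  if (any(w < 1)) stop("empty interval in query")
  # disjoint seqlevels are fine: uncovered chromosomes score zero
  hits <- suppressWarnings(GenomicRanges::findOverlaps(ivs, track))
  total <- numeric(length(ivs))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- GenomicRanges::pintersect(ivs[qh], track[sh])
    contrib <- GenomicRanges::width(ov) * track$score[sh]
    agg <- tapply(contrib, qh, sum)
    total[as.integer(names(agg))] <- agg
  }
  out <- total / w
  if (!is.null(ivs$id)) names(out) <- ivs$id
  out
}

#' Score a set of enhancers against several signal tracks
#'
#' Builds a raw `score_table` whose columns are the supplied tracks
#' (e.g. accessibility at each time point) and whose rows are the
#' enhancer intervals.
#'
#' @param tracks Named list of `GRanges` signal tracks; names become
#'   condition names.
#' @param ivs `GRanges` of enhancer intervals with an `id` column.
#' @param species Species tag for the resulting table.
#' @return A raw `score_table`.
#' @export
score_intervals <- function(tracks, ivs, species = "unknown") {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  if (is.null(ivs$id)) stop("intervals need an 'id' column")
  m <- vapply(tracks, function(tr) mean_signal_over_interval(tr, ivs),
              numeric(length(ivs)))
  m <- matrix(m, nrow = length(ivs),
              dimnames = list(ivs$id, names(tracks)))
  score_table(m, species = species, normalized = FALSE)
}
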