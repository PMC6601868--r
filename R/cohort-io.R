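#' Write a cohort to standard genomics file formats
#'
#' Emits, under `dir`: per-species FASTA sequences
#' (`sequences_<sp>.fasta`, record names `<id>|<sp>`), 6-column BED
#' intervals (`enhancers_<sp>.bed`, 0-based half-open), per-time-point
#' accessibility bedGraph tracks (`acc_<sp>_TPk.bedGraph`, constant
#' value over each enhancer), ChIP score TSV matrices
#' (`chip_<sp>.tsv`), activity labels (`labels.tsv`) and the motif set
#' (`pwms.txt`). All files round-trip losslessly through
#' [read_cohort()] and the package's readers.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(is(cohort, "synthetic_cohort"))
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create output directory: ", dir)
  paths <- c()
  for (sp in c("mel", "vir")) {
    seqs <- Biostrings::DNAStringSet(cohort$pairs[[paste0("seq_", sp)]])
    names(seqs) <- if (nrow(cohort$pairs))
      paste0(cohort$pairs$id, "|", sp) else character(0)
    f <- file.path(dir, sprintf("sequences_%s.fasta", sp))
    Biostrings::writeXStringSet(seqs, f)
    paths[basename(f)] <- f

    iv <- cohort$intervals[[sp]]
    f <- file.path(dir, sprintf("enhancers_%s.bed", sp))
    bed <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(iv)),
      start = GenomicRanges::start(iv) - 1L,
      end = GenomicRanges::end(iv),
      name = if (length(iv)) iv$id else character(0),
      score = if (length(iv)) 0L else integer(0),
      strand = if (length(iv)) "." else character(0))
    write.table(bed, f, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    paths[basename(f)] <- f

    acc <- cohort$acc[[sp]]
    for (col in colnames(acc$values)) {
      tpn <- sub("Acc:", "", col)
      f <- file.path(dir, sprintf("acc_%s_%s.bedGraph", sp, tpn))
      track <- GenomicRanges::granges(iv)
      track$score <- if (length(iv)) acc$values[iv$id, col] else numeric(0)
      write_bedgraph(track, f)
      paths[basename(f)] <- f
    }
    f <- file.path(dir, sprintf("chip_%s.tsv", sp))
    write_score_table(cohort$chip[[sp]], f)
    paths[basename(f)] <- f
  }
  f <- file.path(dir, "labels.tsv")
  write.table(data.frame(id = names(cohort$labels),
                         class = unname(cohort$labels)),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["labels.tsv"] <- f
  f <- file.path(dir, "pwms.txt")
  write_pwm_file(cohort$pwms, f)
  paths["pwms.txt"] <- f
  invisible(paths)
}

#' Read a cohort back from files written by [write_cohort()]
#'
#' Rebuilds the pairs, intervals, normalized ChIP and accessibility
#' score tables, labels and motifs (ground-truth latents are not
#' serialized). Accessibility scores are recovered by averaging the
#' bedGraph tracks over the enhancer intervals.
#'
#' @param dir Directory written by [write_cohort()].
#' @return A list with elements `pairs`, `chip`, `acc`, `labels`,
#'   `intervals`, `pwms`.
#' @export
read_cohort <- function(dir) {
  read_bed6 <- function(path, species) {
    cols <- c("character", "integer", "integer", "character",
              "numeric", "character")
    bed <- tryCatch(
      read.table(path, sep = "\t", colClasses = cols,
                 col.names = c("chrom", "start", "end", "name",
                               "score", "strand")),
      error = function(e)
        data.frame(chrom = character(0), start = integer(0),
                   end = integer(0), name = character(0)))
    enhancer_intervals(bed$chrom, bed$start, bed$end, bed$name, species)
  }
  pairs <- NULL; chip <- list(); acc <- list(); intervals <- list()
  for (sp in c("mel", "vir")) {
    seqs <- tryCatch(
      Biostrings::readDNAStringSet(
        file.path(dir, sprintf("sequences_%s.fasta", sp))),
      error = function(e) Biostrings::DNAStringSet())
    ids <- sub("\\|.*$", "", names(seqs))
    df <- data.frame(id = ids, stringsAsFactors = FALSE)
    df[[paste0("seq_", sp)]] <- as.character(seqs)
    pairs <- if (is.null(pairs)) df else merge(pairs, df, sort = FALSE)
    intervals[[sp]] <- read_bed6(
      file.path(dir, sprintf("enhancers_%s.bed", sp)), sp)
    chip[[sp]] <- read_score_table(
      file.path(dir, sprintf("chip_%s.tsv", sp)),
      species = sp, normalized = TRUE)
    tracks <- list()
    for (f in sort(list.files(dir, sprintf("^acc_%s_TP\\d+\\.bedGraph$", sp),
                              full.names = TRUE))) {
      tp <- sub("\\.bedGraph$", "", sub(sprintf("^acc_%s_", sp), "",
                                        basename(f)))
      tracks[[paste0("Acc:", tp)]] <- read_bedgraph(f)
    }
    acc[[sp]] <-
      if (length(intervals[[sp]]) == 0)
        score_table(matrix(numeric(0), 0, length(tracks),
                           dimnames = list(NULL, names(tracks))),
                    species = sp, normalized = TRUE)
      else score_table(
        score_intervals(tracks, intervals[[sp]], species = sp)$values,
        species = sp, normalized = TRUE)
  }
  lab <- read.table(file.path(dir, "labels.tsv"), sep = "\t",
                    header = TRUE, colClasses = "character")
  list(pairs = pairs, chip = chip, acc = acc,
       labels = setNames(lab$class, lab$id), intervals = intervals,
       pwms = read_pwm_file(file.path(dir, "pwms.txt")))
}
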