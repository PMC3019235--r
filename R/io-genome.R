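#' Load a genome with an optional repeat annotation
#'
#' Reads a (possibly soft-masked) FASTA.  Repeat intervals come either from an
#' explicit BED track or, when `repeats_from_case = TRUE`, from lowercase runs
#' in the sequence (the usual soft-masking convention of repeat-masked
#' assemblies).
#'
#' @param fasta path to a FASTA file.
#' @param repeat_bed optional BED file of repeat intervals.
#' @param repeats_from_case derive repeats from lowercase bases when no BED is
#'   given.
#' @return A list of class `genome_seq` with elements `seq` (a
#'   [Biostrings::DNAStringSet] of uppercase sequence) and `repeats` (a
#'   [GenomicRanges::GRanges], 0-based half-open internally but stored as
#'   GRanges in the usual 1-based closed convention).
#' @export
read_genome <- function(fasta, repeat_bed = NULL, repeats_from_case = is.null(repeat_bed)) {
  # read as BString first: DNAString-based readers normalise case, which
  # would lose the soft-masking information
  seq <- Biostrings::readBStringSet(fasta)
  names(seq) <- sub("\\s.*$", "", names(seq))
  if (anyDuplicated(names(seq)))
    stop("duplicate chromosome names in ", fasta)
  reps <- GRanges()
  if (!is.null(repeat_bed)) {
    reps <- rtracklayer::import(repeat_bed, format = "BED")
    reps <- granges(reps)
  } else if (repeats_from_case) {
    reps <- lowercase_runs(seq)
  }
  seq <- Biostrings::DNAStringSet(toupper(setNames(as.character(seq),
                                                   names(seq))))
  genome_seq(seq, reps)
}

#' Construct a genome object from sequence and repeats
#' @param seq named [Biostrings::DNAStringSet].
#' @param repeats [GenomicRanges::GRanges] of repeat intervals.
#' @return A `genome_seq` list.
#' @export
genome_seq <- function(seq, repeats = GRanges()) {
  stopifnot(is(seq, "DNAStringSet"), !is.null(names(seq)), is(repeats, "GRanges"))
  if (length(repeats)) {
    chr <- as.character(seqnames(repeats))
    if (!all(chr %in% names(seq)))
      stop("repeat intervals on unknown chromosome(s)")
    if (any(end(repeats) > width(seq)[match(chr, names(seq))]))
      stop("repeat intervals outside chromosome bounds")
  }
  structure(list(seq = seq, repeats = repeats), class = "genome_seq")
}

lowercase_runs <- function(seq) {
  res <- lapply(seq_along(seq), function(i) {
    s <- as.character(seq[[i]])
    low <- gregexpr("[acgtn]+", s)[[1L]]
    if (low[1L] == -1L) return(NULL)
    GRanges(names(seq)[i],
            IRanges(start = as.integer(low),
                    width = attr(low, "match.length")))
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) GRanges() else do.call(c, res)
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("genome_seq:", length(x$seq), "chromosome(s),",
      sum(as.numeric(width(x$seq))), "bp,",
      length(x$repeats), "repeat interval(s)\n")
  invisible(x)
}

# Extract genomic subsequence on a strand, 0-based half-open coordinates,
# clipped to chromosome bounds.  Returns a character scalar in transcript
# sense (reverse-complemented for "-").
genome_subseq <- function(genome, chrom, start0, end0, strand = "+") {
  len <- width(genome$seq)[[match(chrom, names(genome$seq))]]
  start0 <- max(start0, 0L)
  end0 <- min(end0, len)
  if (end0 <= start0) return("")
  s <- Biostrings::subseq(genome$seq[[chrom]], start = start0 + 1L, end = end0)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Read a per-base score track (conservation) from bedGraph or fixedStep wig
#'
#' Scores must lie in \[0, 1\]; bases absent from the track are treated as
#' missing (not zero).
#'
#' @param path bedGraph or wig file.
#' @return A [GenomicRanges::GRanges] with a numeric `score` column.
#' @export
read_score_track <- function(path) {
  fmt <- if (grepl("\\.wig$", path, ignore.case = TRUE)) "WIG" else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  if (any(gr$score < 0 | gr$score > 1))
    stop("conservation scores must be in [0, 1]")
  gr
}
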