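#' Aligned fragments
#'
#' One sequenced cDNA fragment, whether read from one or both ends, is a
#' single countable unit.  A fragment is represented by its aligned blocks
#' (a GRanges, sorted, non-overlapping, one chromosome); a collection is a
#' [GenomicRanges::GRangesList] with per-fragment metadata columns `sample`,
#' `unique` and `end_type`.
#'
#' @param blocks a GRangesList, one element per fragment.
#' @param sample sample label(s), recycled.
#' @param unique logical uniqueness flag(s), recycled.
#' @param end_type "single" or "paired", recycled.
#' @return A GRangesList of class use with all fragtools counting functions.
#' @export
aligned_fragments <- function(blocks, sample = "S", unique = TRUE,
                              end_type = "single") {
  stopifnot(is(blocks, "GRangesList"))
  blocks <- reduce(blocks)  # enforce sorted, non-overlapping (mates may overlap)
  n <- length(blocks)
  mcols(blocks)$sample <- rep_len(sample, n)
  mcols(blocks)$unique <- rep_len(unique, n)
  mcols(blocks)$end_type <- rep_len(end_type, n)
  blocks
}

#' Parse fragment alignments from SAM text or BED12
#'
#' Supports the SAM subset used by the pipeline (CIGAR operations M/N/I/D/S;
#' flags for unmapped, paired, mate, secondary).  Mate records sharing a QNAME
#' are merged into one fragment; `N` operations become block gaps and are
#' recorded as spanned junctions.  A fragment is "unique" unless any of its
#' records carries the configured multi-mapping flag bit (default: the SAM
#' secondary-alignment bit 256).
#'
#' @param path a `.sam` or BED12 file.
#' @param sample sample label to attach.
#' @param config a [pipeline_config()] (for `multimap_flag_bit`).
#' @return An [aligned_fragments()] GRangesList.
#' @export
parse_alignments <- function(path, sample = "S", config = pipeline_config()) {
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    parse_sam_fragments(path, sample, config)
  else
    parse_bed12_fragments(path, sample)
}

parse_sam_fragments <- function(path, sample, config) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(aligned_fragments(GRangesList(), sample)[0])
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 11L))
    stop("malformed SAM line(s): line ", paste(which(lengths(f) < 11L), collapse = ", "))
  qname <- vapply(f, `[[`, "", 1L)
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  rname <- vapply(f, `[[`, "", 3L)
  pos <- as.integer(vapply(f, `[[`, "", 4L))
  cigar <- vapply(f, `[[`, "", 6L)
  mapped <- bitwAnd(flag, 4L) == 0L & rname != "*"
  qname <- qname[mapped]; flag <- flag[mapped]; rname <- rname[mapped]
  pos <- pos[mapped]; cigar <- cigar[mapped]
  if (!length(qname))
    return(aligned_fragments(GRangesList(), sample)[0])
  ops <- unique(unlist(strsplit(gsub("[0-9]+", "", cigar), "")))
  bad_ops <- setdiff(ops, c("M", "N", "I", "D", "S"))
  if (length(bad_ops)) {
    bad <- grepl(paste0("[", paste(bad_ops, collapse = ""), "]"), cigar)
    warning("rejecting ", sum(bad), " read(s) with unsupported CIGAR op(s): ",
            paste(bad_ops, collapse = ", "))
    qname <- qname[!bad]; flag <- flag[!bad]; rname <- rname[!bad]
    pos <- pos[!bad]; cigar <- cigar[!bad]
  }
  blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = c("M", "D"), reduce.ranges = TRUE)
  multi <- bitwAnd(flag, as.integer(config$multimap_flag_bit)) != 0L
  paired <- bitwAnd(flag, 1L) != 0L
  # merge mates by QNAME (vectorized: flatten blocks, split once)
  fq <- factor(qname, levels = unique(qname))
  chrom_n <- tapply(rname, fq, function(x) length(unique(x)))
  if (any(chrom_n > 1L))
    stop("mate records of fragment on different chromosomes: ",
         paste(levels(fq)[chrom_n > 1L], collapse = ", "))
  gr <- GRanges(rep(rname, lengths(blocks)), unlist(blocks))
  frags <- split(gr, rep(fq, lengths(blocks)))
  aligned_fragments(
    frags, sample = sample,
    unique = !as.logical(tapply(multi, fq, any)),
    end_type = ifelse(as.logical(tapply(paired, fq, any)),
                      "paired", "single"))
}

parse_bed12_fragments <- function(path, sample) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(gr$blocks)) {
    rel <- gr$blocks
    abs <- shift(rel, start(gr) - 1L)
    g <- GRanges(rep(seqnames(gr), lengths(abs)), unlist(abs))
    frags <- relist(g, abs)
  } else {
    frags <- as(granges(gr), "GRangesList")
  }
  nm <- if (!is.null(gr$name)) gr$name else paste0("frag", seq_along(gr))
  names(frags) <- make.unique(nm)
  aligned_fragments(frags, sample = sample)
}

#' Junctions spanned by fragments
#'
#' Block gaps of spliced fragments, i.e. the introns the fragments jump.
#'
#' @param frags an [aligned_fragments()] GRangesList.
#' @return GRanges of spanned junction introns with a `fragment` index column.
#' @export
fragment_junctions <- function(frags) {
  gaps <- psetdiff(unlist(range(frags)), frags)
  gr <- unlist(gaps, use.names = FALSE)
  gr$fragment <- rep(seq_along(frags), lengths(gaps))
  gr
}

#' Tabulate junction support per sample
#'
#' @param frags an [aligned_fragments()] GRangesList with a `sample` column.
#' @param samples sample levels (column order of the output).
#' @return data.frame `chrom,start,end,strand` (0-based half-open intron)
#'   plus one `count_<sample>` column per sample.
#' @export
junction_counts <- function(frags, samples = unique(mcols(frags)$sample)) {
  j <- fragment_junctions(frags)
  if (!length(j)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character())
    for (s in samples) out[[paste0("count_", s)]] <- integer()
    return(out)
  }
  smp <- mcols(frags)$sample[j$fragment]
  key <- paste(seqnames(j), start(j) - 1L, end(j), sep = ":")
  keys <- sort(unique(key))
  out <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  out <- data.frame(chrom = out[, 1L], start = as.integer(out[, 2L]),
                    end = as.integer(out[, 3L]), strand = ".")
  for (s in samples)
    out[[paste0("count_", s)]] <-
      as.integer(table(factor(key[smp == s], levels = keys)))
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

#' Read a junction support table
#'
#' Tab-separated, columns `chrom,start,end,strand,count_<A>,count_<B>,...`
#' with 0-based half-open intron coordinates.
#'
#' @param path TSV file.
#' @return data.frame as in [junction_counts()].
#' @export
read_junctions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(df)),
            all(df$end > df$start))
  cnt <- grep("^count_", names(df))
  stopifnot(length(cnt) >= 1L, all(df[cnt] >= 0))
  df
}
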