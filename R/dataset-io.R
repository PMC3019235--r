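#' Simulate a complete dataset
#'
#' Convenience wrapper: genome + annotation + evidence tracks + fragments in
#' one call.  Identical config and seed give bit-identical results.
#'
#' @param config a [sim_config()].
#' @return list combining [simulate_genome_annotation()] output with `frags`,
#'   `polya_reads`, `junctions` and merged `truth` from
#'   [simulate_fragments()].
#' @export
simulate_dataset <- function(config = sim_config()) {
  ann <- simulate_genome_annotation(config)
  fr <- simulate_fragments(config, ann)
  ann$frags <- fr$frags
  ann$polya_reads <- fr$polya_reads
  ann$junctions <- fr$junctions
  ann$truth <- c(ann$truth, fr$truth)
  ann$config <- config
  ann
}

#' Write a simulated dataset to disk in standard formats
#'
#' Emits `genome.fa`, `annotation.gtf`, one SAM and one polyA FASTQ per
#' sample, `junctions.tsv`, `repeats.bed`, `ests.bed`,
#' `conservation.bedGraph`, `go_annotations.tsv` and the truth tables
#' (`truth_*.tsv`).  All text; deterministic for a fixed config.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome$seq, file.path(dir, "genome.fa"))
  write_gtf(sim$models, file.path(dir, "annotation.gtf"))
  for (s in sim$config$samples) {
    sel <- mcols(sim$frags)$sample == s
    write_sam(sim$frags[sel], sim$genome, file.path(dir, paste0(s, ".sam")))
    pa <- sim$polya_reads[sim$polya_reads$sample == s, , drop = FALSE]
    write_fastq(pa$seq, pa$id, file.path(dir, paste0(s, "_polya.fastq")))
  }
  write_results_table(sim$junctions, file.path(dir, "junctions.tsv"),
                      sort_by = c("chrom", "start", "end"))
  export_bed0 <- function(gr, path) {
    if (!length(gr)) { writeLines(character(), path); return(invisible()) }
    writeLines(sprintf("%s\t%d\t%d", as.character(seqnames(gr)),
                       start(gr) - 1L, end(gr)), path)
  }
  export_bed0(sim$genome$repeats, file.path(dir, "repeats.bed"))
  export_bed0(sim$ests, file.path(dir, "ests.bed"))
  sc <- sim$score_track
  writeLines(sprintf("%s\t%d\t%d\t%s", as.character(seqnames(sc)),
                     start(sc) - 1L, end(sc), format(sc$score, trim = TRUE)),
             file.path(dir, "conservation.bedGraph"))
  write_results_table(sim$go, file.path(dir, "go_annotations.tsv"))
  for (nm in names(sim$truth)) {
    x <- sim$truth[[nm]]
    if (is.matrix(x)) x <- data.frame(id = rownames(x), x, row.names = NULL)
    if (is.data.frame(x) || is.null(x)) {
      if (!is.null(x))
        write_results_table(x, file.path(dir, paste0("truth_", nm, ".tsv")),
                            sort_by = character())
    } else {
      writeLines(as.character(x), file.path(dir, paste0("truth_", nm, ".txt")))
    }
  }
  invisible(dir)
}

#' Write fragments as a SAM subset
#'
#' One record per fragment (single-end view of the full fragment extent),
#' CIGAR alternating M blocks and N gaps, SEQ/QUAL omitted (`*`).
#'
#' @param frags an [aligned_fragments()] GRangesList.
#' @param genome a [genome_seq()] (for the `@SQ` header).
#' @param path output `.sam` file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(frags, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome$seq),
                   width(genome$seq)))
  n <- length(frags)
  ul <- unlist(frags, use.names = FALSE)
  fi <- rep(seq_len(n), lengths(frags))
  first <- !duplicated(fi)
  chrom <- as.character(seqnames(ul))[first]
  pos1 <- start(ul)[first]
  gap <- c(0L, start(ul)[-1L] - end(ul)[-length(ul)] - 1L)
  gap[first] <- 0L
  piece <- ifelse(gap > 0L, paste0(gap, "N", width(ul), "M"),
                  paste0(width(ul), "M"))
  cigar <- vapply(split(piece, fi), paste, "", collapse = "")
  flag <- ifelse(mcols(frags)$unique, 0L, 256L)
  recs <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*",
                  names(frags), flag, chrom, pos1, cigar)
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Write reads as FASTQ (constant quality)
#' @param seqs read sequences (character).
#' @param ids read names.
#' @param path output `.fastq`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, ids, path) {
  if (!length(seqs)) { writeLines(character(), path); return(invisible(path)) }
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+",
                             strrep("I", nchar(seqs)))), path)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#' @param path `.fastq` file.
#' @return Named character vector of sequences.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) return(setNames(character(), character()))
  stopifnot(length(lines) %% 4L == 0L)
  ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1L, length(lines), 4L)]))
  setNames(lines[seq(2L, length(lines), 4L)], ids)
}
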