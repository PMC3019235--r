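#' Gene models: gene -> transcript -> exon hierarchy
#'
#' Internal representation of annotation.  Exon coordinates are 0-based
#' half-open (GRanges objects hold the usual 1-based closed view; conversion
#' happens only at text-format boundaries).
#'
#' @param exon_table data.frame with columns `gene_id`, `transcript_id`,
#'   `chrom`, `strand`, `start`, `end` (0-based half-open).
#' @return An object of class `gene_models`: list with `exons` (a
#'   [GenomicRanges::GRangesList] keyed by transcript), `tx2gene`
#'   (data.frame), and `genes` (GRanges of gene spans, names = gene ids).
#' @export
gene_models <- function(exon_table) {
  req <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  stopifnot(all(req %in% names(exon_table)))
  if (!nrow(exon_table)) {
    empty <- GRangesList()
    return(structure(list(exons = empty,
                          tx2gene = data.frame(transcript_id = character(),
                                               gene_id = character()),
                          genes = GRanges()),
                     class = "gene_models"))
  }
  gr <- GRanges(exon_table$chrom,
                IRanges(exon_table$start + 1L, exon_table$end),
                strand = exon_table$strand)
  gr$gene_id <- exon_table$gene_id
  gr$transcript_id <- exon_table$transcript_id
  exons <- split(gr, gr$transcript_id)
  exons <- endoapply(exons, sort)
  # reject transcripts whose exons overlap one another
  ok <- vapply(seq_along(exons), function(i) {
    e <- exons[[i]]
    length(e) < 2L || all(start(e)[-1L] > end(e)[-length(e)])
  }, TRUE)
  if (!all(ok)) {
    warning("rejecting transcript(s) with overlapping exons: ",
            paste(names(exons)[!ok], collapse = ", "))
    exons <- exons[ok]
  }
  tx2gene <- data.frame(
    transcript_id = names(exons),
    gene_id = vapply(exons, function(e) e$gene_id[1L], ""),
    row.names = NULL)
  ex <- unlist(exons, use.names = FALSE)
  by_gene <- split(ex, ex$gene_id)
  genes <- unlist(range(by_gene))
  names(genes) <- names(by_gene)
  structure(list(exons = exons, tx2gene = tx2gene, genes = genes),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", length(x$genes), "gene(s),",
      length(x$exons), "transcript(s)\n")
  invisible(x)
}

#' Parse gene models from GTF
#'
#' Reads `exon` features with `gene_id`/`transcript_id` attributes and
#' converts the 1-based inclusive GTF coordinates to the internal 0-based
#' half-open convention.  Malformed lines are reported with their line
#' numbers; transcripts with internally overlapping exons are rejected with a
#' diagnostic.
#'
#' @param path GTF file.
#' @return A [gene_models()] object.
#' @export
parse_gene_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- lengths(fields) < 9L
  if (any(bad))
    stop("malformed GTF line(s) (fewer than 9 fields): line ",
         paste(lineno[bad], collapse = ", "))
  m <- matrix(unlist(lapply(fields, `[`, 1:9)), ncol = 9L, byrow = TRUE)
  is_exon <- m[, 3L] == "exon"
  m <- m[is_exon, , drop = FALSE]
  lineno <- lineno[is_exon]
  if (!nrow(m)) stop("no exon features in ", path)
  gid <- attr_value(m[, 9L], "gene_id")
  tid <- attr_value(m[, 9L], "transcript_id")
  bad <- is.na(gid) | is.na(tid)
  if (any(bad))
    stop("GTF exon line(s) missing gene_id/transcript_id: line ",
         paste(lineno[bad], collapse = ", "))
  start1 <- suppressWarnings(as.integer(m[, 4L]))
  end1 <- suppressWarnings(as.integer(m[, 5L]))
  bad <- is.na(start1) | is.na(end1) | end1 < start1
  if (any(bad))
    stop("GTF exon line(s) with invalid coordinates: line ",
         paste(lineno[bad], collapse = ", "))
  tab <- data.frame(gene_id = gid, transcript_id = tid,
                    chrom = m[, 1L], strand = m[, 7L],
                    start = start1 - 1L, end = end1)
  # identical exon lines shared verbatim by two transcripts are distinct rows
  gene_models(unique(tab))
}

attr_value <- function(attr, key) {
  pat <- paste0(key, "\\s+\"([^\"]*)\"")
  m <- regexec(pat, attr)
  vapply(regmatches(attr, m),
         function(x) if (length(x) == 2L) x[[2L]] else NA_character_, "")
}

#' Write gene models as GTF (1-based inclusive)
#' @param models a [gene_models()] object.
#' @param path output file.
#' @param source feature source string.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path, source = "fragtools") {
  ex <- unlist(models$exons, use.names = FALSE)
  o <- order(as.character(seqnames(ex)), start(ex), ex$transcript_id)
  ex <- ex[o]
  lines <- sprintf(
    "%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    as.character(seqnames(ex)), source, start(ex), end(ex),
    as.character(strand(ex)), ex$gene_id, ex$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

# --- derived annotation views -------------------------------------------------

# union of exonic bases per gene -> GRangesList named by gene
exon_union_by_gene <- function(models) {
  ex <- unlist(models$exons, use.names = FALSE)
  reduce(split(granges(ex), ex$gene_id))
}

# introns per transcript (gaps between consecutive exons) -> GRanges
transcript_introns <- function(models) {
  res <- psetdiff(unlist(range(models$exons)), models$exons)
  gr <- unlist(res, use.names = FALSE)
  gr$transcript_id <- rep(names(res), lengths(res))
  gr
}
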