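#' Assemble transcribed regions from coverage and junctions
#'
#' A deliberately simple assembler standing in for graph-based transcript
#' assembly: maximal runs of bases with fragment coverage >= 1 become blocks,
#' and two blocks are joined into one multi-block transcript when a splice
#' junction supported by at least `min_junction_support` fragments connects
#' them (its intron endpoints each touching a block).  Fragment support of an
#' assembled transcript is the number of fragments overlapping its blocks.
#'
#' @param frags an [aligned_fragments()] GRangesList (uniquely mapped
#'   fragments are used).
#' @param junctions data.frame as from [junction_counts()]; counts are summed
#'   over `count_*` columns.
#' @param min_junction_support fragments required on a junction before it can
#'   join blocks (default 2).
#' @return list of class `assembled_tx` with `blocks` (GRangesList, one
#'   element per transcript) and `support` (integer fragment counts).
#' @export
assemble_transcripts <- function(frags, junctions = NULL,
                                 min_junction_support = 2L) {
  frags <- frags[mcols(frags)$unique]
  if (!length(frags))
    return(structure(list(blocks = GRangesList(), support = integer()),
                     class = "assembled_tx"))
  cov <- coverage(unlist(frags, use.names = FALSE))
  islands <- GRanges(slice(cov, lower = 1L, rangesOnly = TRUE))
  grp <- seq_along(islands)               # union-find over islands
  find <- function(i) { while (grp[i] != i) i <- grp[i]; i }
  if (!is.null(junctions) && nrow(junctions)) {
    cnt <- rowSums(junctions[, grep("^count_", names(junctions)), drop = FALSE])
    j <- junctions[cnt >= min_junction_support, , drop = FALSE]
    if (nrow(j)) {
      donor <- GRanges(j$chrom, IRanges(j$start, j$start))      # base left of intron
      accept <- GRanges(j$chrom, IRanges(j$end + 1L, j$end + 1L)) # base right of intron
      hd <- findOverlaps(donor, islands, select = "first")
      ha <- findOverlaps(accept, islands, select = "first")
      for (k in seq_len(nrow(j))) {
        if (!is.na(hd[k]) && !is.na(ha[k])) {
          a <- find(hd[k]); b <- find(ha[k])
          if (a != b) grp[max(a, b)] <- min(a, b)
        }
      }
    }
  }
  root <- vapply(seq_along(islands), find, 1L)
  tx_blocks <- split(islands, factor(root, levels = sort(unique(root))))
  names(tx_blocks) <- paste0("tx", seq_along(tx_blocks))
  # fragments overlapping the blocks themselves (not the span gaps), each
  # fragment counted once per transcript
  blocks <- unlist(frags, use.names = FALSE)
  frag_of_block <- rep(seq_along(frags), lengths(frags))
  island_of <- unlist(tx_blocks, use.names = FALSE)
  tx_of_island <- rep(seq_along(tx_blocks), lengths(tx_blocks))
  hit <- findOverlaps(blocks, island_of, ignore.strand = TRUE)
  pairs <- unique(data.frame(frag = frag_of_block[queryHits(hit)],
                             tx = tx_of_island[subjectHits(hit)]))
  support <- tabulate(pairs$tx, nbins = length(tx_blocks))
  structure(list(blocks = tx_blocks, support = as.integer(support)),
            class = "assembled_tx")
}

#' @export
print.assembled_tx <- function(x, ...) {
  cat("assembled_tx:", length(x$blocks), "transcript(s)\n")
  invisible(x)
}

#' Filter assembled transcripts into novel transcribed units
#'
#' A novel TU must satisfy all four criteria: (1) at least `min_distance`
#' (1000) bp from the nearest annotated gene boundary; (2) length (sum of
#' block widths) >= `min_length` (500) bp; (3) covered by at least
#' `min_frags_per_kb` (40) fragments per kb -- with 122 bp fragments this is
#' about 5 fragments per base -- or, under the absolute reading, by at least
#' that many fragments in total; (4) less than `max_repeat_frac` (50%)
#' repeat-masked sequence.
#'
#' @param asm an `assembled_tx` from [assemble_transcripts()].
#' @param models a [gene_models()] object.
#' @param repeats GRanges of repeat intervals (e.g. `genome$repeats`).
#' @param min_distance,min_length,min_frags_per_kb,max_repeat_frac thresholds.
#' @param density_absolute interpret the density criterion as an absolute
#'   fragment count instead of per kb.
#' @return data.frame, one row per retained TU: `tu_id, chrom, start, end,
#'   n_blocks, length, fragments, frags_per_kb, distance_to_gene,
#'   repeat_fraction` plus a `blocks` GRangesList attribute-free `blocks`
#'   column (comma-joined `start-end` pairs, 0-based half-open).
#' @export
filter_novel_tus <- function(asm, models, repeats = GRanges(),
                             min_distance = 1000L, min_length = 500L,
                             min_frags_per_kb = 40, max_repeat_frac = 0.5,
                             density_absolute = FALSE) {
  stats_df <- tu_stats(asm, models, repeats)
  dens_ok <- if (density_absolute) stats_df$fragments >= min_frags_per_kb
             else stats_df$frags_per_kb >= min_frags_per_kb
  keep <- stats_df$distance_to_gene >= min_distance &
    stats_df$length >= min_length & dens_ok &
    stats_df$repeat_fraction < max_repeat_frac
  out <- stats_df[keep, , drop = FALSE]
  out$tu_id <- if (nrow(out)) paste0("TU", seq_len(nrow(out))) else character(0)
  rownames(out) <- NULL
  out[, c("tu_id", setdiff(names(out), "tu_id"))]
}

# per-transcript audit statistics used by the filter (kept separate so the
# filter can be re-checked independently)
tu_stats <- function(asm, models, repeats = GRanges()) {
  spans <- unlist(range(asm$blocks))
  len <- sum(width(asm$blocks))
  if (length(models$genes)) {
    d <- distanceToNearest(spans, models$genes, ignore.strand = TRUE)
    dist <- rep(Inf, length(spans))
    dist[queryHits(d)] <- mcols(d)$distance
  } else dist <- rep(Inf, length(spans))
  repfrac <- if (length(repeats)) {
    vapply(seq_along(asm$blocks), function(i)
      sum(width(GenomicRanges::intersect(asm$blocks[[i]], repeats,
                                         ignore.strand = TRUE))), 1) /
      pmax(len, 1L)
  } else rep(0, length(spans))
  data.frame(
    chrom = as.character(seqnames(spans)),
    start = start(spans) - 1L, end = end(spans),
    n_blocks = lengths(asm$blocks),
    length = as.integer(len),
    fragments = asm$support,
    frags_per_kb = 1000 * asm$support / pmax(len, 1L),
    distance_to_gene = dist,
    repeat_fraction = repfrac,
    blocks = vapply(seq_along(asm$blocks), function(i)
      paste(sprintf("%d-%d", start(asm$blocks[[i]]) - 1L,
                    end(asm$blocks[[i]])), collapse = ","), ""),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Annotate novel TUs with external evidence
#'
#' PolyA support: at least one polyA site's representative cleavage position
#' falls inside the TU span.  EST support: spliced-EST alignments cover at
#' least `est_min_coverage` (50%) of the TU bases.  Conservation: the mean
#' per-base conservation score over the scored TU bases (missing bases are
#' excluded; NA when nothing is scored).
#'
#' @param tus data.frame from [filter_novel_tus()].
#' @param polya_sites data.frame with `chrom,position,strand` (optional).
#' @param ests GRanges of EST alignments (optional).
#' @param scores GRanges score track from [read_score_track()] (optional).
#' @param est_min_coverage EST support threshold.
#' @return `tus` with added `polya_supported`, `est_coverage`,
#'   `est_supported`, `mean_conservation`.
#' @export
annotate_tu_evidence <- function(tus, polya_sites = NULL, ests = NULL,
                                 scores = NULL, est_min_coverage = 0.5) {
  n <- nrow(tus)
  spans <- GRanges(tus$chrom, IRanges(tus$start + 1L, tus$end))
  blocks <- tu_blocks_granges(tus)
  tus$polya_supported <- rep(FALSE, n)
  if (!is.null(polya_sites) && nrow(polya_sites)) {
    pa <- GRanges(polya_sites$chrom,
                  IRanges(polya_sites$position + 1L, polya_sites$position + 1L))
    tus$polya_supported <- overlapsAny(spans, pa, ignore.strand = TRUE)
  }
  tus$est_coverage <- rep(0, n)
  if (!is.null(ests) && length(ests)) {
    cov <- vapply(seq_len(n), function(i)
      sum(width(GenomicRanges::intersect(blocks[[i]], reduce(ests),
                                         ignore.strand = TRUE))), 1)
    tus$est_coverage <- cov / pmax(tus$length, 1L)
  }
  tus$est_supported <- tus$est_coverage >= est_min_coverage
  tus$mean_conservation <- rep(NA_real_, n)
  if (!is.null(scores) && length(scores)) {
    tus$mean_conservation <- vapply(seq_len(n), function(i) {
      hit <- GenomicRanges::intersect(blocks[[i]], granges(scores),
                                      ignore.strand = TRUE)
      if (!sum(width(hit))) return(NA_real_)
      # weighted mean of scores over the scored TU bases
      ov <- findOverlaps(blocks[[i]], scores, ignore.strand = TRUE)
      w <- width(pintersect(blocks[[i]][queryHits(ov)], granges(scores)[subjectHits(ov)]))
      sum(w * scores$score[subjectHits(ov)]) / sum(w)
    }, 1)
  }
  tus
}

tu_blocks_granges <- function(tus) {
  GRangesList(lapply(seq_len(nrow(tus)), function(i) {
    parts <- strsplit(tus$blocks[i], ",", fixed = TRUE)[[1L]]
    se <- do.call(rbind, strsplit(parts, "-", fixed = TRUE))
    GRanges(tus$chrom[i],
            IRanges(as.integer(se[, 1L]) + 1L, as.integer(se[, 2L])))
  }))
}

#' Test novel TUs for differential expression alongside genes
#'
#' Row-binds TU fragment counts to the gene count matrix, quantile normalizes
#' the combined matrix, runs the negative-binomial exact test, and reports
#' the TU subset (normalizing jointly is what lets low-complexity TU counts
#' borrow the reference distribution of the gene counts).
#'
#' @param gene_counts genes x 2 count matrix.
#' @param tu_counts TUs x 2 count matrix (same sample order).
#' @param fdr FDR threshold.
#' @param round round normalized values before testing.
#' @return list `all` (full test table) and `tus` (TU rows only).
#' @export
test_tu_differential <- function(gene_counts, tu_counts, fdr = 0.01,
                                 round = TRUE) {
  stopifnot(ncol(gene_counts) == 2L, ncol(tu_counts) == 2L)
  comb <- rbind(as.matrix(gene_counts), as.matrix(tu_counts))
  norm <- quantile_normalize(comb, round = round)
  res <- nb_exact_test(norm, fdr = fdr)
  tu_rows <- nrow(gene_counts) + seq_len(nrow(tu_counts))
  list(all = res, tus = res[tu_rows, , drop = FALSE])
}
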