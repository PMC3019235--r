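#' Detect alternative-splicing events from junction counts
#'
#' Classifies the three junction-definable event classes.  All intron
#' coordinates are 0-based half-open.
#'
#' * Exon skipping: junctions J1 = \[d, a1) and J2 = \[d2, a) (inclusion)
#'   plus the exclusion junction J3 = \[d, a) with a1 < d2; the skipped exon
#'   is \[a1, d2).  All three junctions must be supported by at least
#'   `min_support` fragments.
#' * Alternative 5' splice site: two junctions sharing the acceptor end with
#'   distinct donor starts, both supported by at least `min_support`
#'   fragments, and every base between the two donor sites covered by at
#'   least one fragment (on a minus-strand junction pair this class becomes
#'   alternative 3', and vice versa; unstranded junctions use the plus-strand
#'   reading).
#' * Alternative 3' splice site: symmetric, sharing the donor start.
#'
#' First/last exons and intron retention are outside the classification by
#' construction.  Events are deduplicated by their defining coordinates.
#'
#' @param junctions data.frame as from [junction_counts()] /
#'   [read_junctions()]; detection uses the row sums of the `count_*`
#'   columns (the "combined dataset" when two samples are present).
#' @param coverage an [S4Vectors::RleList] of per-base fragment coverage (as
#'   from `GenomicRanges::coverage()`), required to check the 100%-coverage
#'   rule for alt-5'/3' events; `NULL` skips those classes.
#' @param min_support minimum fragments per defining junction (default 2).
#' @return data.frame, one row per event: `type, chrom, strand,
#'   region_start, region_end` (the alternative region: skipped exon or
#'   inter-splice-site segment) and the defining junction coordinates
#'   `j1_start, j1_end, j2_start, j2_end, j3_start, j3_end` (J3 is NA for alt
#'   events).
#' @export
detect_as_events <- function(junctions, coverage = NULL, min_support = 2L) {
  empty <- data.frame(type = character(), chrom = character(),
                      strand = character(),
                      region_start = integer(), region_end = integer(),
                      j1_start = integer(), j1_end = integer(),
                      j2_start = integer(), j2_end = integer(),
                      j3_start = integer(), j3_end = integer())
  if (!nrow(junctions)) return(empty)
  cnt <- rowSums(junctions[, grep("^count_", names(junctions)), drop = FALSE])
  j <- junctions[cnt >= min_support, , drop = FALSE]
  if (!nrow(j)) return(empty)
  res <- list()
  for (chr in unique(j$chrom)) {
    jc <- j[j$chrom == chr, , drop = FALSE]
    res[[length(res) + 1L]] <- detect_skipping_chr(jc, chr)
    res[[length(res) + 1L]] <- detect_alt_ss_chr(jc, chr, coverage)
  }
  out <- do.call(rbind, res)
  if (is.null(out) || !nrow(out)) return(empty)
  out <- unique(out)
  rownames(out) <- NULL
  out[order(out$type, out$chrom, out$region_start), , drop = FALSE]
}

detect_skipping_chr <- function(jc, chr) {
  n <- nrow(jc)
  if (n < 3L) return(NULL)
  out <- list()
  for (x in seq_len(n)) {               # candidate exclusion junction [d, a)
    d <- jc$start[x]; a <- jc$end[x]
    inc1 <- which(jc$start == d & jc$end < a)              # [d, a1)
    inc2 <- which(jc$end == a & jc$start > d)              # [d2, a)
    for (i1 in inc1) for (i2 in inc2) {
      a1 <- jc$end[i1]; d2 <- jc$start[i2]
      if (a1 < d2)                      # a skipped exon must exist between
        out[[length(out) + 1L]] <- data.frame(
          type = "exon_skipping", chrom = chr,
          strand = jc$strand[x],
          region_start = a1, region_end = d2,
          j1_start = d, j1_end = a1,
          j2_start = d2, j2_end = a,
          j3_start = d, j3_end = a)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

detect_alt_ss_chr <- function(jc, chr, coverage) {
  if (is.null(coverage) || !(chr %in% names(coverage))) return(NULL)
  cov <- coverage[[chr]]
  n <- nrow(jc)
  if (n < 2L) return(NULL)
  out <- list()
  pairs <- utils::combn(n, 2L)
  for (k in seq_len(ncol(pairs))) {
    x <- pairs[1L, k]; y <- pairs[2L, k]
    strand <- jc$strand[x]
    shared_end <- jc$end[x] == jc$end[y] && jc$start[x] != jc$start[y]
    shared_start <- jc$start[x] == jc$start[y] && jc$end[x] != jc$end[y]
    if (!shared_end && !shared_start) next
    if (shared_end) {                   # variable donor side (genomic left)
      lo <- min(jc$start[x], jc$start[y]); hi <- max(jc$start[x], jc$start[y])
      type <- if (strand == "-") "alt_3ss" else "alt_5ss"
    } else {                            # variable acceptor side (genomic right)
      lo <- min(jc$end[x], jc$end[y]); hi <- max(jc$end[x], jc$end[y])
      type <- if (strand == "-") "alt_5ss" else "alt_3ss"
    }
    # 100% coverage of the bases between the alternative splice sites
    if (hi > length(cov) || lo < 0L) next
    if (min(S4Vectors::window(cov, lo + 1L, hi)) < 1L) next
    # J1 = junction of the shorter intron (retains the longer exon, the
    # "inclusion" form); J2 = the longer-intron junction
    wx <- jc$end[x] - jc$start[x]; wy <- jc$end[y] - jc$start[y]
    i1 <- if (wx <= wy) x else y
    i2 <- if (wx <= wy) y else x
    out[[length(out) + 1L]] <- data.frame(
      type = type, chrom = chr, strand = strand,
      region_start = lo, region_end = hi,
      j1_start = jc$start[i1], j1_end = jc$end[i1],
      j2_start = jc$start[i2], j2_end = jc$end[i2],
      j3_start = NA_integer_, j3_end = NA_integer_)
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Attach per-sample inclusion/exclusion counts to events
#'
#' For exon skipping the inclusion count is the average of the two
#' inclusion-junction counts, rounded half away from zero, and the exclusion
#' count is the skip-junction count.  For alt-5'/3' events the two junction
#' counts are used directly (J1 = shorter-intron junction as "inclusion").
#'
#' @param events data.frame from [detect_as_events()].
#' @param junctions junction table with `count_<A>` and `count_<B>` columns.
#' @param samples the two sample labels, in (A, B) order.
#' @return `events` with `incA, excA, incB, excB` columns.
#' @export
event_counts <- function(events, junctions,
                         samples = sub("^count_", "",
                                       grep("^count_", names(junctions),
                                            value = TRUE))) {
  stopifnot(length(samples) == 2L)
  key <- paste(junctions$chrom, junctions$start, junctions$end)
  lookup <- function(chrom, s, e, col) {
    i <- match(paste(chrom, s, e), key)
    ifelse(is.na(i), 0L, junctions[[col]][i])
  }
  for (si in 1:2) {
    col <- paste0("count_", samples[si])
    c1 <- lookup(events$chrom, events$j1_start, events$j1_end, col)
    c2 <- lookup(events$chrom, events$j2_start, events$j2_end, col)
    c3 <- lookup(events$chrom, events$j3_start, events$j3_end, col)
    skip <- events$type == "exon_skipping"
    inc <- ifelse(skip, round_half_away((c1 + c2) / 2), c1)
    exc <- ifelse(skip, c3, c2)
    events[[paste0("inc", c("A", "B")[si])]] <- as.integer(inc)
    events[[paste0("exc", c("A", "B")[si])]] <- as.integer(exc)
  }
  events
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Fisher exact test for differential splicing
#'
#' For each event, tests the 2x2 table (inclusion/exclusion x sample A/B)
#' with a two-sided Fisher exact test.  The odds ratio is the sample OR
#' oriented as (incB/excB) / (incA/excA) -- higher inclusion in the second
#' sample gives OR > 1 -- with the Haldane 0.5 correction when any cell is
#' zero.  BH adjustment is applied within each event type; significance at
#' `fdr` (default 1%).  Events with a zero table margin get p = 1 and a
#' missing OR.
#'
#' @param events data.frame from [event_counts()].
#' @param fdr FDR threshold.
#' @return `events` with `odds_ratio, p, q, significant` columns.
#' @export
test_differential_splicing <- function(events, fdr = 0.01) {
  n <- nrow(events)
  p <- numeric(n); or <- numeric(n)
  for (i in seq_len(n)) {
    tab <- matrix(c(events$incA[i], events$excA[i],
                    events$incB[i], events$excB[i]), 2L)
    if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
      p[i] <- 1; or[i] <- NA_real_
    } else {
      p[i] <- stats::fisher.test(tab)$p.value
      t2 <- tab
      if (any(t2 == 0L)) t2 <- t2 + 0.5
      or[i] <- (t2[1L, 2L] / t2[2L, 2L]) / (t2[1L, 1L] / t2[2L, 1L])
    }
  }
  events$odds_ratio <- or
  events$p <- p
  events$q <- NA_real_
  for (ty in unique(events$type)) {
    sel <- events$type == ty
    events$q[sel] <- stats::p.adjust(events$p[sel], "BH")
  }
  events$significant <- !is.na(events$q) & events$q < fdr
  events
}

#' Assign events to genes by exclusion-junction containment
#'
#' An event is assigned to a gene when its outer junction (J3 for skipping,
#' J2 for alt events) lies entirely within exactly one gene span; otherwise
#' the gene id stays NA and the event keeps coordinates only.
#'
#' @param events data.frame from [detect_as_events()].
#' @param models a [gene_models()] object.
#' @return `events` with a `gene_id` column.
#' @export
assign_event_genes <- function(events, models) {
  events$gene_id <- NA_character_
  if (!nrow(events)) return(events)
  s <- ifelse(is.na(events$j3_start), events$j2_start, events$j3_start)
  e <- ifelse(is.na(events$j3_end), events$j2_end, events$j3_end)
  gr <- GRanges(events$chrom, IRanges(s + 1L, e))
  hit <- findOverlaps(gr, models$genes, type = "within", ignore.strand = TRUE)
  tab <- table(queryHits(hit))
  uniq <- as.integer(names(tab)[tab == 1L])
  hit <- hit[queryHits(hit) %in% uniq]
  events$gene_id[queryHits(hit)] <- names(models$genes)[subjectHits(hit)]
  events
}
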