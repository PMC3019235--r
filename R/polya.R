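#' Detect and trim polyA tails from unmapped reads
#'
#' Because the protocol is unstranded, a polyadenylated 3' end can present as
#' a run of As at the 3' end of the read or as a run of Ts at the 5' end (the
#' reverse-complement presentation).  A read qualifies when the maximal
#' uninterrupted terminal run is at least `min_run` (default 6) nucleotides;
#' the entire run is trimmed and the read is retained only if the trimmed
#' sequence is at least `min_trimmed` (default 25) nt.  When both ends
#' qualify, the longer run wins.
#'
#' @param seqs character vector (or DNAStringSet) of read sequences.
#' @param ids read identifiers.
#' @param min_run minimum terminal run length.
#' @param min_trimmed minimum retained length after trimming.
#' @return data.frame with one row per retained read: `id`, `tail_side`
#'   ("A3" or "T5"), `tail_length`, `trimmed` (sequence), `trimmed_length`.
#' @export
detect_polya_tails <- function(seqs, ids = names(seqs), min_run = 6L,
                               min_trimmed = 25L) {
  seqs <- toupper(as.character(seqs))
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  a3 <- terminal_run_length(seqs, "A", end = TRUE)
  t5 <- terminal_run_length(seqs, "T", end = FALSE)
  side <- ifelse(a3 >= t5, "A3", "T5")        # longer run wins; tie -> A3
  run <- pmax(a3, t5)
  keep <- run >= min_run
  n <- nchar(seqs)
  trimmed <- ifelse(side == "A3", substr(seqs, 1L, n - run),
                    substr(seqs, run + 1L, n))
  keep <- keep & nchar(trimmed) >= min_trimmed
  data.frame(id = ids[keep], tail_side = side[keep],
             tail_length = as.integer(run[keep]), trimmed = trimmed[keep],
             trimmed_length = nchar(trimmed[keep]),
             stringsAsFactors = FALSE)
}

terminal_run_length <- function(seqs, base, end) {
  pat <- if (end) paste0(base, "+$") else paste0("^", base, "+")
  m <- regexpr(pat, seqs)
  ifelse(m == -1L, 0L, attr(m, "match.length"))
}

#' Align trimmed polyA reads, forcing uniqueness
#'
#' A naive scanning aligner for toy genomes, standing in for a short-read
#' aligner run with "up to one mismatch, forcing uniqueness": a read is
#' placed only if exactly one location on either strand of the genome matches
#' with at most `max_mismatch` mismatches.  The cleavage position is the
#' tail-side end of the alignment and the transcript strand follows from tail
#' side and alignment orientation (A-tail, forward alignment = plus strand).
#'
#' The cleavage position convention is 0-based: the coordinate of the first
#' genomic base past the last transcribed base, in transcription direction
#' (for minus-strand sites this is one base left of the alignment start).
#'
#' For 0 or 1 mismatches the search is seed-and-verify by pigeonhole: any
#' qualifying alignment matches one read half exactly, so exact matches of
#' the two halves (fast Boyer-Moore scans) enumerate all candidate loci,
#' which are then Hamming-verified.  This is complete, not heuristic.
#'
#' @param tails data.frame from [detect_polya_tails()].
#' @param genome a [genome_seq()] object.
#' @param max_mismatch mismatches allowed (default 1; at most 1 supported).
#' @return list with `sites` (data.frame `chrom,position,strand,id`) and
#'   `tally` (placed / multi / unplaced read counts).
#' @export
align_polya_reads <- function(tails, genome, max_mismatch = 1L) {
  stopifnot(max_mismatch <= 1L)
  n <- nrow(tails)
  chrom <- character(n); posn <- integer(n); str <- character(n)
  placed <- logical(n); multi <- logical(n)
  for (i in seq_len(n)) {
    hits <- align_one_read(tails$trimmed[i], genome, max_mismatch)
    nh <- if (is.null(hits)) 0L else nrow(hits)
    if (nh == 0L) next
    if (nh > 1L) { multi[i] <- TRUE; next }
    placed[i] <- TRUE
    chrom[i] <- hits$chrom
    fwd <- hits$sense == "+"
    a3 <- tails$tail_side[i] == "A3"
    # transcript strand: A-tail forward or T-head reverse => "+"
    str[i] <- if (a3 == fwd) "+" else "-"
    if (str[i] == "+") {
      # tail side at the right end of the genomic alignment
      posn[i] <- hits$end          # 1-based end == 0-based first base past
    } else {
      posn[i] <- hits$start - 2L   # 0-based base left of alignment start
    }
  }
  list(sites = data.frame(chrom = chrom[placed], position = posn[placed],
                          strand = str[placed], id = tails$id[placed],
                          stringsAsFactors = FALSE),
       tally = c(placed = sum(placed), multi = sum(multi),
                 unplaced = n - sum(placed) - sum(multi)))
}

# all alignments of one read with <= max_mismatch mismatches, both strands;
# returns data.frame(chrom, start, end [1-based closed], sense) or NULL
align_one_read <- function(seq, genome, max_mismatch) {
  pat <- Biostrings::DNAString(seq)
  len <- length(pat)
  half <- max(len %/% 2L, 1L)
  found <- list()
  for (sense in c("+", "-")) {
    p <- if (sense == "+") pat else Biostrings::reverseComplement(pat)
    seeds <- list(list(sub = Biostrings::subseq(p, 1L, half), off = 0L),
                  list(sub = Biostrings::subseq(p, half + 1L, len),
                       off = half))
    if (max_mismatch == 0L) seeds <- seeds[1:2]  # both still fine, cheap
    for (ci in seq_along(genome$seq)) {
      subj <- genome$seq[[ci]]
      starts <- integer(0)
      for (sd in seeds) {
        m <- Biostrings::matchPattern(sd$sub, subj)
        if (length(m)) starts <- c(starts, start(m) - sd$off)
      }
      starts <- unique(starts)
      starts <- starts[starts >= 1L & starts + len - 1L <= length(subj)]
      if (!length(starts)) next
      mm <- Biostrings::neditStartingAt(p, subj, starting.at = starts,
                                        with.indels = FALSE)
      ok <- starts[mm <= max_mismatch]
      if (length(ok))
        found[[length(found) + 1L]] <- data.frame(
          chrom = names(genome$seq)[ci], start = ok, end = ok + len - 1L,
          sense = sense, stringsAsFactors = FALSE)
    }
  }
  if (!length(found)) return(NULL)
  unique(do.call(rbind, found))
}

#' Internal-priming filter
#'
#' Rejects putative cleavage sites where the genomic sequence immediately
#' downstream (transcript sense) contains a run of at least `min_run`
#' consecutive As within a `window`-nt scan: such alignments are explained by
#' oligo-dT priming on a genomic adenosine run, not by a polyA tail.
#'
#' @param sites data.frame with `chrom,position,strand` (cleavage convention
#'   of [align_polya_reads()]).
#' @param genome a [genome_seq()] object.
#' @param window downstream bases examined (default 10).
#' @param min_run A-run length that triggers rejection (default 6).
#' @return logical vector, `TRUE` = keep.
#' @export
internal_priming_keep <- function(sites, genome, window = 10L, min_run = 6L) {
  n <- nrow(sites)
  keep <- logical(n)
  run_pat <- strrep("A", min_run)
  for (i in seq_len(n)) {
    p <- sites$position[i]
    down <- if (sites$strand[i] == "+")
      genome_subseq(genome, sites$chrom[i], p, p + window, "+")
    else
      genome_subseq(genome, sites$chrom[i], p - window + 1L, p + 1L, "-")
    keep[i] <- !grepl(run_pat, down, fixed = TRUE)
  }
  keep
}

#' Cluster cleavage sites into polyA sites
#'
#' Single-linkage chaining: cleavage positions on the same chromosome and
#' strand within `gap` bp (default 15) of each other belong to one putative
#' polyA site.  The representative is the most-supported member (ties broken
#' leftmost); support is the sum over members.
#'
#' @param cleavage data.frame `chrom,position,strand` with one row per
#'   supporting read (or with a `support` column of per-position counts).
#' @param gap maximum chaining distance in bp.
#' @return data.frame `chrom,strand,position` (representative), `support`,
#'   `n_members`, `members` (comma-joined positions).
#' @export
cluster_cleavage_sites <- function(cleavage, gap = 15L) {
  if (!nrow(cleavage))
    return(data.frame(chrom = character(), strand = character(),
                      position = integer(), support = integer(),
                      n_members = integer(), members = character()))
  if (is.null(cleavage$support)) {
    agg <- stats::aggregate(list(support = rep(1L, nrow(cleavage))),
                            cleavage[c("chrom", "strand", "position")], sum)
  } else {
    agg <- cleavage
  }
  agg <- agg[order(agg$chrom, agg$strand, agg$position), , drop = FALSE]
  grp_key <- paste(agg$chrom, agg$strand)
  new_chain <- c(TRUE, diff(agg$position) > gap | grp_key[-1L] != grp_key[-nrow(agg)])
  cl <- cumsum(new_chain)
  out <- lapply(split(seq_len(nrow(agg)), cl), function(ii) {
    a <- agg[ii, , drop = FALSE]
    rep_i <- which.max(a$support)  # which.max returns first (leftmost) maximum
    data.frame(chrom = a$chrom[1L], strand = a$strand[1L],
               position = a$position[rep_i], support = sum(a$support),
               n_members = nrow(a),
               members = paste(a$position, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Annotate polyA signals
#'
#' Searches the `window` (default 50) bases upstream of each representative
#' cleavage position, on the transcript strand, for the two most frequent
#' polyA signal hexamers (AAUAAA and AUUAAA; AATAAA/ATTAAA in DNA sense).
#' The match nearest the cleavage site is reported, AAUAAA preferred on equal
#' distance.
#'
#' @param sites data.frame with `chrom,position,strand`.
#' @param genome a [genome_seq()] object.
#' @param window upstream search window in bp.
#' @param symmetric also search `window` bases downstream.
#' @return `sites` with added `signal` ("AAUAAA"/"AUUAAA"/"none") and
#'   `signal_offset` (distance from cleavage to the start of the hexamer in
#'   transcript sense, negative upstream; NA when none).
#' @export
annotate_polya_signal <- function(sites, genome, window = 50L,
                                  symmetric = FALSE) {
  hex <- c(AAUAAA = "AATAAA", AUUAAA = "ATTAAA")
  n <- nrow(sites)
  sig <- rep("none", n)
  off <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    p <- sites$position[i]
    plus <- sites$strand[i] == "+"
    up_to <- if (symmetric) window else 0L
    s <- if (plus)
      genome_subseq(genome, sites$chrom[i], p - window, p + up_to, "+")
    else
      genome_subseq(genome, sites$chrom[i], p + 1L - up_to, p + 1L + window, "-")
    # in transcript-sense string coordinates the cleavage site sits at
    # index nchar(s) - up_to; hexamer offset 0 would start at the cleavage base
    cand <- do.call(rbind, lapply(names(hex), function(h) {
      m <- gregexpr(hex[[h]], s, fixed = TRUE)[[1L]]
      if (m[1L] == -1L) return(NULL)
      data.frame(signal = h, offset = as.integer(m) - 1L - (nchar(s) - up_to))
    }))
    if (!is.null(cand) && nrow(cand)) {
      # nearest to cleavage wins; AAUAAA preferred on equal distance
      cand <- cand[order(abs(cand$offset), cand$signal), , drop = FALSE]
      sig[i] <- cand$signal[1L]
      off[i] <- cand$offset[1L]
    }
  }
  sites$signal <- sig
  sites$signal_offset <- off
  sites
}

#' Full polyA-site calling stage
#'
#' Chains tail detection, unique alignment, internal-priming filtering,
#' 15-bp clustering and signal annotation.  Both the unfiltered and the
#' signal-bearing site tallies are reported, since either can be the quantity
#' of interest.
#'
#' @param seqs unmapped read sequences (character or DNAStringSet).
#' @param genome a [genome_seq()] object.
#' @param config a [pipeline_config()].
#' @return list with `sites` (annotated polyA sites), `cleavage` (kept
#'   per-read cleavage sites), and `tally` (reads in, tailed, placed, multi,
#'   unplaced, primed-rejected, sites, sites_with_signal).
#' @export
call_polya_sites <- function(seqs, genome, config = pipeline_config()) {
  tails <- detect_polya_tails(seqs, min_run = config$tail_min_run,
                              min_trimmed = config$min_trimmed_length)
  aln <- align_polya_reads(tails, genome,
                           max_mismatch = config$max_align_mismatch)
  keep <- internal_priming_keep(aln$sites, genome,
                                window = config$priming_window,
                                min_run = config$priming_min_run)
  cleav <- aln$sites[keep, , drop = FALSE]
  sites <- cluster_cleavage_sites(cleav, gap = config$cluster_gap)
  sites <- annotate_polya_signal(sites, genome,
                                 window = config$signal_window,
                                 symmetric = config$signal_symmetric)
  list(sites = sites, cleavage = cleav,
       tally = c(reads = length(seqs), tailed = nrow(tails), aln$tally,
                 primed_rejected = sum(!keep), sites = nrow(sites),
                 sites_with_signal = sum(sites$signal != "none")))
}
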