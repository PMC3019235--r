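# Fragment-level simulation: mature mRNA with 3' bias, length-weighted
# pre-mRNA, novel-TU coverage, polyA-tailed reads, internal-priming traps.

# map transcript-coordinate fragments [st, en) (0-based) to genomic blocks.
# ex_start/ex_end: exon bounds, 0-based half-open, genomic order.
tx_to_genomic_blocks <- function(st, en, ex_start, ex_end, strand) {
  w <- ex_end - ex_start
  n_ex <- length(w)
  w_t <- if (strand == "-") rev(w) else w
  cum <- cumsum(c(0L, w_t))
  i1 <- findInterval(st, cum)          # first exon touched (transcript order)
  i2 <- findInterval(en - 1L, cum)
  reps <- i2 - i1 + 1L
  frag <- rep(seq_along(st), reps)
  j <- sequence(reps, from = i1)
  ts <- pmax(st[frag], cum[j])
  te <- pmin(en[frag], cum[j + 1L])
  if (strand == "+") {
    gs <- ex_start[j] + (ts - cum[j])
    ge <- ex_start[j] + (te - cum[j])
  } else {
    gi <- n_ex + 1L - j
    ge <- ex_end[gi] - (ts - cum[j])
    gs <- ex_end[gi] - (te - cum[j])
  }
  data.frame(frag = frag, start = gs, end = ge)
}

#' Simulate two-sample fragment sets, polyA reads and junction counts
#'
#' Mature-mRNA fragments are sampled per isoform with sampling weight
#' increasing exponentially towards the transcript 3' end (rate
#' `1/bias_lambda`), emulating the coverage bias of amplified RNA; pre-mRNA
#' fragments are sampled uniformly from gene spans, with the per-gene
#' pre-mRNA probability length-weighted:
#' q = p L_gene / (p L_gene + (1 - p) L_mature), which is what makes a small
#' molecule fraction p produce a disproportionally large intronic read
#' fraction.  PolyA-tailed reads are emitted at the true cleavage sites
#' (tail length 6 plus a truncated geometric; A-at-3' or T-at-5'
#' presentation with probability 1/2 each), plus internal-priming trap reads
#' at planted genomic A-runs.  Novel-TU fragments are sampled uniformly at
#' the configured density.
#'
#' @param config a [sim_config()].
#' @param ann output of [simulate_genome_annotation()] for the same config.
#' @return list with `frags` (an [aligned_fragments()] GRangesList, both
#'   samples, with `origin` and `entity` metadata), `polya_reads`
#'   (data.frame `id,sample,seq`), `junctions` (two-sample table as in
#'   [junction_counts()], strand filled from annotated introns), and `truth`
#'   (list: `expr` gene x sample realized fragment counts and expected
#'   rates, `tu_counts`, `as_events` with planted junction coordinates and
#'   inclusion probabilities, `polya_support` per planted cleavage site).
#' @export
simulate_fragments <- function(config, ann) {
  set.seed(config$seed + 1L)
  genes <- ann$truth$genes
  models <- ann$models
  samples <- config$samples
  stopifnot(length(samples) == 2L)
  n_genes <- nrow(genes)

  base_expr <- stats::rlnorm(n_genes, meanlog = 0, sdlog = config$expr_sdlog)
  base_expr[genes$role == "de"] <- config$de_base_expr
  fold <- config$de_fold ^ genes$de_dir            # 1 except DE genes
  scale <- config$n_fragments / sum(base_expr)     # per-sample rate scale
  # t1 ("full form") frequency per sample for two-isoform genes
  iso1_p <- cbind(rep(0.5, n_genes),
                  ifelse(genes$role == "skip", config$skip_odds /
                           (1 + config$skip_odds),
                         config$alt_odds / (1 + config$alt_odds)))
  two_iso <- genes$role %in% c("skip", "alt5", "alt3")
  iso1_p[!two_iso, ] <- 1

  ex_by_tx <- lapply(models$exons, function(e)
    list(start = start(e) - 1L, end = end(e)))
  tx_of <- split(models$tx2gene$transcript_id, models$tx2gene$gene_id)

  polya <- list()
  expr_truth <- list()
  fid <- 0L
  frag_rows <- list()   # per-fragment metadata, assembled at the end
  all_blocks <- list()

  emit <- function(block_df, sample, origin, entity, chrom) {
    # block_df$frag indexes fragments 1..k locally; renumber globally
    k <- max(block_df$frag)
    block_df$frag <- block_df$frag + fid
    block_df$chrom <- chrom
    all_blocks[[length(all_blocks) + 1L]] <<- block_df
    frag_rows[[length(frag_rows) + 1L]] <<- data.frame(
      id = seq_len(k) + fid, sample = sample, origin = origin,
      entity = entity)
    fid <<- fid + k
  }

  for (si in 1:2) {
    s <- samples[si]
    p_pre <- config$premrna_fraction[si]
    for (g in seq_len(n_genes)) {
      w <- base_expr[g] * (if (si == 2L) fold[g] else 1)
      n_gs <- stats::rpois(1L, scale[si] * w)
      if (n_gs == 0L) {
        expr_truth[[length(expr_truth) + 1L]] <- data.frame(
          gene_id = genes$gene_id[g], sample = s, expected = scale[si] * w,
          mature = 0L, premrna = 0L)
        next
      }
      txs <- tx_of[[genes$gene_id[g]]]
      exl <- ex_by_tx[txs]
      Lm <- vapply(exl, function(x) sum(x$end - x$start), 1)
      p1 <- iso1_p[g, si]
      iso_w <- if (length(txs) == 2L) c(p1, 1 - p1) else 1
      Lm_avg <- sum(Lm * iso_w)
      Lg <- genes$end[g] - genes$start[g]
      q <- p_pre * Lg / (p_pre * Lg + (1 - p_pre) * Lm_avg)
      n_pre <- stats::rbinom(1L, n_gs, q)
      n_mat <- n_gs - n_pre
      chrom <- genes$chrom[g]
      if (n_pre > 0L) {
        flen <- clip_lengths(n_pre, config, Lg)
        st <- floor(stats::runif(n_pre, 0, Lg - flen + 1))
        emit(data.frame(frag = seq_len(n_pre),
                        start = genes$start[g] + st,
                        end = genes$start[g] + st + flen),
             s, "premrna", genes$gene_id[g], chrom)
      }
      if (n_mat > 0L) {
        iso <- if (length(txs) == 2L)
          1L + stats::rbinom(n_mat, 1L, 1 - p1) else rep(1L, n_mat)
        for (ti in unique(iso)) {
          k <- sum(iso == ti)
          L <- Lm[ti]
          wts <- exp((seq_len(L) - L) / config$bias_lambda)
          en <- sample.int(L, k, replace = TRUE, prob = wts)
          flen <- clip_lengths(k, config, L)
          st <- pmax(en - flen, 0L)
          bad <- en <= st
          en[bad] <- st[bad] + 1L
          bl <- tx_to_genomic_blocks(st, en, exl[[ti]]$start, exl[[ti]]$end,
                                     genes$strand[g])
          emit(bl, s, "mature", genes$gene_id[g], chrom)
        }
      }
      expr_truth[[length(expr_truth) + 1L]] <- data.frame(
        gene_id = genes$gene_id[g], sample = s, expected = scale[si] * w,
        mature = n_mat, premrna = n_pre)
      # polyA reads at the gene's cleavage site
      n_pa <- stats::rpois(1L, config$polya_rate * n_gs)
      if (n_pa > 0L)
        polya[[length(polya) + 1L]] <- polya_reads_at(
          ann$genome, chrom,
          pos = if (genes$strand[g] == "+") genes$end[g] else genes$start[g] - 1L,
          strand = genes$strand[g], n = n_pa, config = config,
          sample = s, entity = genes$gene_id[g])
    }
  }

  ## ---- novel TU fragments --------------------------------------------------
  tus <- ann$truth$tus
  tu_counts <- matrix(0L, nrow(tus), 2L,
                      dimnames = list(tus$tu_id, samples))
  for (si in 1:2) {
    s <- samples[si]
    for (i in seq_len(nrow(tus))) {
      # decoy densities are per sample; the sparse decoy must stay under the
      # 40/kb filter even after the two samples are combined
      dens <- if (tus$reason[i] == "sparse") 10 else config$tu_frags_per_kb
      lam <- dens * tus$length[i] / 1000
      if (tus$b_only[i]) lam <- if (si == 2L) config$tu_b_only_depth else 2
      k <- stats::rpois(1L, lam)
      tu_counts[i, si] <- k
      if (k == 0L) next
      flen <- clip_lengths(k, config, tus$length[i])
      st <- floor(stats::runif(k, 0, tus$length[i] - flen + 1))
      emit(data.frame(frag = seq_len(k), start = tus$start[i] + st,
                      end = tus$start[i] + st + flen),
           s, "tu", tus$tu_id[i], tus$chrom[i])
      if (tus$polya[i]) {
        n_pa <- stats::rpois(1L, 6)
        if (n_pa > 0L)
          polya[[length(polya) + 1L]] <- polya_reads_at(
            ann$genome, tus$chrom[i], pos = tus$end[i] - 1L, strand = "+",
            n = n_pa, config = config, sample = s, entity = tus$tu_id[i])
      }
    }
  }

  ## ---- internal-priming trap reads ----------------------------------------
  fs <- ann$truth$false_sites
  for (si in 1:2) for (i in seq_len(nrow(fs))) {
    body_len <- config$read_len - 6L
    body <- genome_subseq(ann$genome, fs$chrom[i],
                          fs$position[i] - body_len, fs$position[i], "+")
    reads <- make_tailed_reads(body, rep(6L, config$ip_reads),
                               flip = stats::rbinom(config$ip_reads, 1L, 0.5) == 1L)
    polya[[length(polya) + 1L]] <- data.frame(
      id = sprintf("trap_%s_%d_%s_%d", fs$chrom[i], fs$position[i],
                   samples[si], seq_len(config$ip_reads)),
      sample = samples[si], seq = reads,
      entity = "internal_priming", stringsAsFactors = FALSE)
  }

  ## ---- assemble fragment container ----------------------------------------
  bl <- do.call(rbind, all_blocks)
  fr <- do.call(rbind, frag_rows)
  if (is.null(bl)) {   # requested depth 0: empty outputs, no error
    frags <- aligned_fragments(GRangesList())
    mcols(frags)$origin <- character(0)
    mcols(frags)$entity <- character(0)
    frags <- frags[0]
  } else {
    gr <- GRanges(bl$chrom, IRanges(bl$start + 1L, bl$end))
    grl <- split(gr, factor(bl$frag, levels = fr$id))
    names(grl) <- sprintf("frag%07d", fr$id)
    frags <- aligned_fragments(grl, sample = fr$sample)
    mcols(frags)$origin <- fr$origin
    mcols(frags)$entity <- fr$entity
  }

  jx <- junction_counts(frags, samples = samples)
  # fill strand from annotated introns where the junction matches one
  if (nrow(jx)) {
    intr <- transcript_introns(models)
    if (length(intr)) {
      key <- paste(seqnames(intr), start(intr) - 1L, end(intr))
      m <- match(paste(jx$chrom, jx$start, jx$end), key)
      jx$strand <- ifelse(is.na(m), ".", as.character(strand(intr))[m])
    }
  }

  polya_df <- if (length(polya)) do.call(rbind, polya) else
    data.frame(id = character(), sample = character(), seq = character(),
               entity = character())

  pa_support <- if (nrow(polya_df))
    stats::aggregate(list(reads = rep(1L, nrow(polya_df))),
                     polya_df[c("entity", "sample")], sum)
  else data.frame(entity = character(), sample = character(),
                  reads = integer())

  list(frags = frags, polya_reads = polya_df, junctions = jx,
       truth = list(expr = do.call(rbind, expr_truth),
                    tu_counts = tu_counts,
                    as_events = planted_as_events(config, ann),
                    polya_support = pa_support))
}

clip_lengths <- function(n, config, maxlen) {
  flen <- round(stats::rnorm(n, config$insert_mean, config$insert_sd))
  pmin(pmax(flen, 30L), maxlen)
}

# body sequence (transcript sense, ending at the cleavage site) + A-tail,
# presented as A-at-3' or, reverse-complemented, T-at-5'
polya_reads_at <- function(genome, chrom, pos, strand, n, config, sample,
                           entity) {
  tails <- pmin(6L + stats::rgeom(n, config$tail_p), config$tail_max)
  body_len <- config$read_len - tails
  bodies <- vapply(body_len, function(b) {
    if (strand == "+")
      genome_subseq(genome, chrom, pos - b, pos, "+")
    else
      genome_subseq(genome, chrom, pos + 1L, pos + 1L + b, "-")
  }, "")
  flip <- stats::rbinom(n, 1L, 0.5) == 1L
  data.frame(id = sprintf("pa_%s_%d_%s_%s_%d", chrom, pos, strand,
                          sample, seq_len(n)),
             sample = sample,
             seq = make_tailed_reads(bodies, tails, flip),
             entity = entity, stringsAsFactors = FALSE)
}

make_tailed_reads <- function(bodies, tails, flip) {
  reads <- paste0(bodies, strrep("A", tails))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads)))
  ifelse(flip, rc, reads)
}

# planted AS event truth: defining junction coordinates and per-sample
# inclusion-form probabilities
planted_as_events <- function(config, ann) {
  iso <- ann$truth$isoforms
  if (is.null(iso) || !nrow(iso)) return(NULL)
  genes <- ann$truth$genes
  out <- list()
  for (i in seq_len(nrow(iso))) {
    g <- genes[genes$gene_id == iso$gene_id[i], ]
    e1 <- ann$models$exons[[paste0(iso$gene_id[i], ".t1")]]
    st <- start(e1) - 1L; en <- end(e1)
    k <- iso$varied_exon[i]
    plus <- g$strand == "+"
    odds <- if (iso$role[i] == "skip") config$skip_odds else config$alt_odds
    p1 <- c(0.5, odds / (1 + odds))
    if (iso$role[i] == "skip") {
      rec <- data.frame(
        gene_id = g$gene_id, type = "exon_skipping", chrom = g$chrom,
        strand = g$strand,
        j1_start = en[k - 1L], j1_end = st[k],
        j2_start = en[k], j2_end = st[k + 1L],
        j3_start = en[k - 1L], j3_end = st[k + 1L],
        incl_p_A = p1[1L], incl_p_B = p1[2L],
        expected_or = odds)               # t1 carries the exon
    } else {
      d <- config$alt_delta
      donor_side <- (iso$role[i] == "alt5") == plus   # genomic-left variation
      if (donor_side) {
        js1 <- en[k] + d; je1 <- st[k + 1L]           # t2, shorter intron
        js2 <- en[k]; je2 <- st[k + 1L]               # t1, longer intron
      } else {
        js1 <- en[k - 1L]; je1 <- st[k] - d
        js2 <- en[k - 1L]; je2 <- st[k]
      }
      rec <- data.frame(
        gene_id = g$gene_id,
        type = if (iso$role[i] == "alt5") "alt_5ss" else "alt_3ss",
        chrom = g$chrom, strand = g$strand,
        j1_start = js1, j1_end = je1,    # inclusion = shorter intron (t2)
        j2_start = js2, j2_end = je2,
        j3_start = NA_integer_, j3_end = NA_integer_,
        incl_p_A = 1 - p1[1L], incl_p_B = 1 - p1[2L],
        expected_or = 1 / odds)           # t2 is rarer in sample B
    }
    out[[length(out) + 1L]] <- rec
  }
  do.call(rbind, out)
}
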