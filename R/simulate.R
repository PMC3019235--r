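#' Simulation configuration
#'
#' The stated world of the synthetic two-sample embryo design.  Defaults give
#' two 500 kb chromosomes carrying 60 non-overlapping genes whose exons make
#' up 1/20 of genic bases, 50,000 fragments per sample with mean insert size
#' 122 bp and moderate 3' bias, pre-mRNA molecule fractions chosen (via the
#' closed-form intronic model) to bracket the two samples' intronic-of-genic
#' fractions of roughly 18% and 34%, polyA reads at true cleavage sites with
#' planted AAUAAA signals, 12 intergenic novel TUs with cycling
#' polyA/EST/conservation evidence plus four decoys that each violate one TU
#' filter, and planted differential-expression, exon-skipping and
#' alt-5'/3' effects.
#'
#' @param seed integer seed fixing every random draw.
#' @param ... overrides of any default listed below.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_chrom = 2L, chrom_len = 5e5,
    n_genes = 60L, exons_per_gene = 5L, exon_len = c(60L, 120L),
    exon_base_fraction = 1 / 20,
    min_intron = 200L,
    gene_gap = c(4000L, 7000L),
    samples = c("blastocyst", "degenerative"),
    n_fragments = c(50000L, 50000L),
    # molecule fractions solving f(p, 1/20) = 0.179 and 0.339
    premrna_fraction = c(0.0115, 0.0270),
    insert_mean = 122, insert_sd = 20, read_len = 60L,
    bias_lambda = 150,
    expr_sdlog = 1, de_base_expr = 2,
    n_de = 6L, de_fold = 4,
    n_skip = 4L, skip_odds = 4,
    n_alt5 = 2L, n_alt3 = 2L, alt_delta = 30L, alt_odds = 3,
    polya_rate = 0.01, tail_p = 0.35, tail_max = 20L,
    n_internal_priming = 5L, ip_reads = 8L,
    n_tu = 12L, tu_len = c(600L, 1200L), tu_frags_per_kb = 150,
    tu_b_only = TRUE, tu_b_only_depth = 250L,
    decoys = TRUE,
    repeat_density = 0.03,
    n_go_terms = 30L, go_terms_per_gene = c(1L, 4L),
    go_enriched_term = "GO:DEV", go_de_rate = 0.8, go_bg_rate = 0.05
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown sim_config key(s): ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  stopifnot(all(cfg$premrna_fraction >= 0), all(cfg$premrna_fraction <= 1),
            cfg$de_fold > 0, cfg$polya_rate >= 0, cfg$polya_rate <= 1)
  structure(cfg, class = "sim_config")
}

#' Simulate genome, annotation and evidence tracks
#'
#' Lays out non-overlapping genes along the chromosomes (strand random),
#' plants a polyA signal hexamer ~20 bp upstream of every true cleavage site
#' and a non-A decamer just downstream of it, places intergenic novel TUs at
#' least 1 kb from any gene (plus decoys violating one filter each), plants
#' genomic A-runs as internal-priming traps, and writes repeat, EST,
#' conservation and GO-annotation tracks consistent with the planted truth.
#'
#' @param config a [sim_config()].
#' @return list with `genome` ([genome_seq()]), `models` ([gene_models()]),
#'   `score_track`, `ests` (GRanges), `go` (gene/term data.frame), and
#'   `truth` (list of truth tables: `genes`, `isoforms`, `cleavage`,
#'   `false_sites`, `tus`, `go_term`).
#' @export
simulate_genome_annotation <- function(config = sim_config()) {
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  seqs <- lapply(chroms, function(x)
    paste(sample(c("A", "C", "G", "T"), config$chrom_len, replace = TRUE),
          collapse = ""))
  names(seqs) <- chroms

  ## ---- gene layout ---------------------------------------------------------
  e <- config$exon_base_fraction
  genes <- list(); exon_rows <- list()
  gap_range <- config$gene_gap
  cursor <- 2000; ci <- 1L
  gaps <- list()   # record intergenic gaps for TU placement
  for (g in seq_len(config$n_genes)) {
    n_ex <- config$exons_per_gene
    ex_w <- sample(config$exon_len[1L]:config$exon_len[2L], n_ex, replace = TRUE)
    intron_total <- round(sum(ex_w) * (1 - e) / e)
    w <- stats::runif(n_ex - 1L, 0.6, 1.4)
    in_w <- pmax(round(intron_total * w / sum(w)), config$min_intron)
    glen <- sum(ex_w) + sum(in_w)
    if (cursor + glen + 2000 > config$chrom_len) {
      gaps[[length(gaps) + 1L]] <-
        list(chrom = chroms[ci], start = cursor, end = config$chrom_len - 1000)
      ci <- ci + 1L
      cursor <- 2000
      if (ci > config$n_chrom)
        stop("genome too small for ", config$n_genes,
             " genes; increase chrom_len or n_chrom, or shrink genes")
    }
    starts <- cursor + cumsum(c(0L, head(ex_w, -1L) + in_w))
    ends <- starts + ex_w
    strand <- sample(c("+", "-"), 1L)
    gid <- sprintf("gene%02d", g)
    genes[[g]] <- data.frame(gene_id = gid, chrom = chroms[ci],
                             strand = strand, start = cursor,
                             end = cursor + glen, n_ex = n_ex)
    exon_rows[[g]] <- data.frame(gene_id = gid, chrom = chroms[ci],
                                 strand = strand, start = starts, end = ends)
    gap <- sample(gap_range[1L]:gap_range[2L], 1L)
    gaps[[length(gaps) + 1L]] <-
      list(chrom = chroms[ci], start = cursor + glen, end = cursor + glen + gap)
    cursor <- cursor + glen + gap
  }
  genes <- do.call(rbind, genes)
  if (is.null(genes))
    genes <- data.frame(gene_id = character(), chrom = character(),
                        strand = character(), start = integer(),
                        end = integer(), n_ex = integer())

  ## ---- planted effects: assign roles to genes ------------------------------
  n_special <- config$n_skip + config$n_alt5 + config$n_alt3 + config$n_de
  stopifnot(n_special <= config$n_genes)
  roles <- rep("plain", config$n_genes)
  pick <- sample(config$n_genes, n_special)
  roles[pick[seq_len(config$n_skip)]] <- "skip"
  off <- config$n_skip
  roles[pick[off + seq_len(config$n_alt5)]] <- "alt5"
  off <- off + config$n_alt5
  roles[pick[off + seq_len(config$n_alt3)]] <- "alt3"
  off <- off + config$n_alt3
  de_idx <- pick[off + seq_len(config$n_de)]
  roles[de_idx] <- "de"
  genes$role <- roles
  genes$de_dir <- rep(0L, nrow(genes))
  if (config$n_de)
    genes$de_dir[de_idx] <- rep_len(c(1L, -1L), config$n_de)  # +1 = up in B

  ## ---- transcripts ---------------------------------------------------------
  iso_rows <- list(); iso_truth <- list()
  for (g in seq_len(config$n_genes)) {
    ex <- exon_rows[[g]]
    gid <- genes$gene_id[g]
    t1 <- transform(ex, transcript_id = paste0(gid, ".t1"))
    iso_rows[[length(iso_rows) + 1L]] <- t1
    role <- genes$role[g]
    if (role %in% c("skip", "alt5", "alt3")) {
      k <- 1L + (genes$n_ex[g] %/% 2L)   # a middle exon
      ex2 <- ex
      if (role == "skip") {
        ex2 <- ex[-k, , drop = FALSE]
      } else {
        d <- config$alt_delta
        plus <- genes$strand[g] == "+"
        # alt 5'SS varies the donor of intron k (transcript sense);
        # alt 3'SS varies the acceptor.  In genomic coordinates:
        if ((role == "alt5") == plus) ex2$end[k] <- ex2$end[k] + d
        else ex2$start[k] <- ex2$start[k] - d
      }
      t2 <- transform(ex2, transcript_id = paste0(gid, ".t2"))
      iso_rows[[length(iso_rows) + 1L]] <- t2
      iso_truth[[length(iso_truth) + 1L]] <- data.frame(
        gene_id = gid, role = role, varied_exon = k)
    }
  }
  exon_table <- do.call(rbind, iso_rows)
  if (is.null(exon_table))
    exon_table <- data.frame(gene_id = character(),
                             transcript_id = character(),
                             chrom = character(), strand = character(),
                             start = integer(), end = integer())
  exon_table <- exon_table[, c("gene_id", "transcript_id", "chrom", "strand",
                               "start", "end")]

  ## ---- polyA truth: cleavage sites, signals, downstream guards -------------
  plant <- function(chrom, at0, what) {   # overwrite genome bases, 0-based
    s <- seqs[[chrom]]
    substr(s, at0 + 1L, at0 + nchar(what)) <- what
    seqs[[chrom]] <<- s
  }
  cleav <- data.frame(entity = genes$gene_id, chrom = genes$chrom,
                      position = ifelse(genes$strand == "+",
                                        genes$end, genes$start - 1L),
                      strand = genes$strand, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cleav))) {
    p <- cleav$position[i]
    if (cleav$strand[i] == "+") {
      plant(cleav$chrom[i], p - 21L, "AATAAA")        # signal upstream
      plant(cleav$chrom[i], p, "GTCGATGCTG")          # non-A downstream guard
    } else {
      plant(cleav$chrom[i], p + 16L, "TTTATT")        # revcomp of AATAAA
      plant(cleav$chrom[i], p - 9L, "CAGCATCGAC")     # revcomp guard
    }
  }

  ## ---- novel TUs -----------------------------------------------------------
  usable <- Filter(function(gp) (gp$end - gp$start) >= 2 * 1100 + config$tu_len[2L],
                   gaps)
  need <- config$n_tu + if (config$decoys) 4L else 0L
  if (length(usable) < need)
    stop("not enough intergenic gaps for ", need, " TUs; enlarge genome")
  slots <- sample(length(usable), need)
  tus <- list()
  mk_tu <- function(slot, len, offset_from_gene = NULL) {
    gp <- usable[[slot]]
    if (is.null(offset_from_gene)) {
      lo <- gp$start + 1100
      hi <- gp$end - 1100 - len
      st <- if (hi > lo) sample(lo:hi, 1L) else lo
    } else st <- gp$start + offset_from_gene
    list(chrom = gp$chrom, start = st, end = st + len)
  }
  evid <- expand.grid(polya = c(TRUE, FALSE), est = c(TRUE, FALSE),
                      cons = c(TRUE, FALSE))
  for (t in seq_len(config$n_tu)) {
    len <- sample(config$tu_len[1L]:config$tu_len[2L], 1L)
    loc <- mk_tu(slots[t], len)
    ev <- evid[1L + (t - 1L) %% nrow(evid), ]
    tus[[t]] <- data.frame(
      tu_id = sprintf("novel%02d", t), chrom = loc$chrom,
      start = loc$start, end = loc$end, length = len,
      polya = ev$polya, est = ev$est, conserved = ev$cons,
      b_only = config$tu_b_only && t == 1L,
      passes = TRUE, reason = "ok", stringsAsFactors = FALSE)
  }
  if (config$decoys) {
    specs <- list(
      list(reason = "near_gene", len = 800L, off = 300L),
      list(reason = "short", len = 250L, off = NULL),
      list(reason = "repeat_rich", len = 800L, off = NULL),
      list(reason = "sparse", len = 800L, off = NULL))
    for (d in seq_along(specs)) {
      sp <- specs[[d]]
      loc <- mk_tu(slots[config$n_tu + d], sp$len, sp$off)
      tus[[config$n_tu + d]] <- data.frame(
        tu_id = sprintf("decoy_%s", sp$reason), chrom = loc$chrom,
        start = loc$start, end = loc$end, length = sp$len,
        polya = FALSE, est = FALSE, conserved = FALSE, b_only = FALSE,
        passes = FALSE, reason = sp$reason, stringsAsFactors = FALSE)
    }
  }
  tus <- do.call(rbind, tus)
  if (is.null(tus))
    tus <- data.frame(tu_id = character(), chrom = character(),
                      start = integer(), end = integer(), length = integer(),
                      polya = logical(), est = logical(),
                      conserved = logical(), b_only = logical(),
                      passes = logical(), reason = character())
  # polyA-supported TUs get a planted cleavage site (plus strand) at their
  # last transcribed base (end - 1, so the site lies inside the TU interval)
  for (i in which(tus$polya)) {
    p <- tus$end[i] - 1L
    plant(tus$chrom[i], p - 21L, "AATAAA")
    plant(tus$chrom[i], p, "GTCGATGCTG")
    cleav <- rbind(cleav, data.frame(entity = tus$tu_id[i],
                                     chrom = tus$chrom[i], position = p,
                                     strand = "+"))
  }

  ## ---- internal-priming traps ---------------------------------------------
  false_sites <- data.frame(chrom = character(), position = integer(),
                            strand = character())
  if (config$n_internal_priming > 0) {
    trap_slots <- setdiff(seq_along(usable), slots)
    trap_slots <- head(trap_slots, config$n_internal_priming)
    fs <- list()
    for (s in trap_slots) {
      gp <- usable[[s]]
      q <- gp$start + 1500L
      plant(gp$chrom, q, strrep("A", 8L))
      fs[[length(fs) + 1L]] <- data.frame(chrom = gp$chrom, position = q,
                                          strand = "+")
    }
    if (length(fs)) false_sites <- do.call(rbind, fs)
  }

  ## ---- repeat track --------------------------------------------------------
  tu_spans <- GRanges(tus$chrom, IRanges(tus$start + 1L, tus$end))
  n_rep <- round(config$repeat_density * config$n_chrom * config$chrom_len / 200)
  rep_gr <- GRanges()
  if (n_rep > 0) {
    rchrom <- sample(chroms, n_rep, replace = TRUE)
    rw <- sample(100:300, n_rep, replace = TRUE)
    rst <- vapply(seq_len(n_rep), function(i)
      sample.int(config$chrom_len - 400L, 1L), 1L)
    rep_gr <- GRanges(rchrom, IRanges(rst + 1L, rst + rw))
    rep_gr <- rep_gr[!overlapsAny(rep_gr, tu_spans, ignore.strand = TRUE)]
  }
  rich <- which(tus$reason == "repeat_rich")
  if (length(rich)) {  # cover 60% of the decoy
    w <- round(0.6 * tus$length[rich])
    rep_gr <- suppressWarnings(c(rep_gr, GRanges(tus$chrom[rich],
                                IRanges(tus$start[rich] + 1L,
                                        tus$start[rich] + w))))
  }
  rep_gr <- sort(reduce(rep_gr))

  ## ---- conservation + EST tracks ------------------------------------------
  bin <- 100L
  score_rows <- lapply(chroms, function(ch) {
    st <- seq(1L, config$chrom_len - bin + 1L, by = bin)
    GRanges(ch, IRanges(st, st + bin - 1L),
            score = round(stats::runif(length(st), 0.02, 0.25), 3))
  })
  score_track <- suppressWarnings(do.call(c, score_rows))
  cons_spans <- tu_spans[tus$conserved]
  hi <- overlapsAny(score_track, cons_spans, ignore.strand = TRUE)
  score_track$score[hi] <- round(stats::runif(sum(hi), 0.75, 0.95), 3)
  est_list <- lapply(which(tus$est), function(i) {
    len <- tus$length[i]
    st <- tus$start[i] + round(0.15 * len)
    GRanges(tus$chrom[i], IRanges(st + 1L, st + round(0.7 * len)))
  })
  n_bg_est <- 20L
  bg_est <- GRanges(sample(chroms, n_bg_est, replace = TRUE),
                    IRanges(sample.int(config$chrom_len - 1000L, n_bg_est),
                            width = sample(200:600, n_bg_est, replace = TRUE)))
  ests <- sort(suppressWarnings(
    c(do.call(c, c(est_list, list(GRanges()))), bg_est)))

  ## ---- GO annotations ------------------------------------------------------
  terms <- sprintf("GO:%04d", seq_len(config$n_go_terms))
  go <- data.frame(gene = character(), term = character())
  if (config$n_genes > 0L)
  go <- do.call(rbind, lapply(seq_len(config$n_genes), function(g) {
    k <- sample(config$go_terms_per_gene[1L]:config$go_terms_per_gene[2L], 1L)
    data.frame(gene = genes$gene_id[g], term = sample(terms, k))
  }))
  is_de <- genes$role == "de"
  enriched <- stats::runif(config$n_genes) <
    ifelse(is_de, config$go_de_rate, config$go_bg_rate)
  if (any(enriched))
    go <- rbind(go, data.frame(gene = genes$gene_id[enriched],
                               term = config$go_enriched_term))
  go <- unique(go[order(go$gene, go$term), ])

  genome <- genome_seq(Biostrings::DNAStringSet(unlist(seqs)), rep_gr)
  models <- gene_models(exon_table)
  list(genome = genome, models = models, score_track = score_track,
       ests = ests, go = go,
       truth = list(genes = genes,
                    isoforms = if (length(iso_truth)) do.call(rbind, iso_truth)
                               else NULL,
                    cleavage = cleav, false_sites = false_sites, tus = tus,
                    go_term = config$go_enriched_term))
}
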