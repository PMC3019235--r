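# polyadenylation: tail detection/trimming, unique alignment, internal
# priming, clustering, signal annotation

test_that("tail detection applies the 6-nt run and 25-nt trimmed-length thresholds", {
  r <- detect_polya_tails(c(a = paste0(strrep("C", 29), strrep("A", 6))))
  expect_equal(nrow(r), 1L)
  expect_equal(r$tail_side, "A3")
  expect_equal(r$tail_length, 6L)
  expect_equal(r$trimmed_length, 29L)
  # 28-mer ending in 6 As: trimmed 22 < 25 -> discarded
  expect_equal(nrow(detect_polya_tails(paste0(strrep("C", 22), strrep("A", 6)))), 0L)
  # 5 terminal As and 5 leading Ts: below both thresholds
  expect_equal(nrow(detect_polya_tails(
    paste0(strrep("T", 5), strrep("G", 30), strrep("A", 5)))), 0L)
  # empty sequence
  expect_equal(nrow(detect_polya_tails("")), 0L)
  # both ends qualify: the longer run wins
  r <- detect_polya_tails(paste0(strrep("T", 7), strrep("G", 30), strrep("A", 9)))
  expect_equal(r$tail_side, "A3")
  expect_equal(r$tail_length, 9L)
  r <- detect_polya_tails(paste0(strrep("T", 9), strrep("G", 30), strrep("A", 7)))
  expect_equal(r$tail_side, "T5")
  expect_equal(r$trimmed, paste0(strrep("G", 30), strrep("A", 7)))
})

test_that("trimming conserves length and is idempotent on clean bodies", {
  set.seed(11)
  for (i in 1:50) {
    body <- paste0("G", random_dna(40), "C")  # no terminal A/T runs
    tail_len <- sample(6:15, 1L)
    read <- if (runif(1) < 0.5) paste0(body, strrep("A", tail_len))
            else paste0(strrep("T", tail_len), body)
    r <- detect_polya_tails(read)
    expect_equal(r$tail_length + r$trimmed_length, nchar(read))
    expect_equal(r$trimmed_length, 42L)
    # maximality: re-detection on the trimmed sequence finds nothing
    expect_equal(nrow(detect_polya_tails(r$trimmed)), 0L)
  }
})

test_that("alignment forces uniqueness and allows one mismatch", {
  set.seed(5)
  core <- random_dna(30)
  # two exact copies of the same 30-mer -> non-unique -> dropped
  g2 <- toy_genome(chr1 = paste0(random_dna(50), core, random_dna(100),
                                 core, random_dna(50)))
  tails <- data.frame(id = "r", tail_side = "A3", tail_length = 6L,
                      trimmed = core, trimmed_length = 30L)
  res <- align_polya_reads(tails, g2)
  expect_equal(unname(res$tally["multi"]), 1L)
  expect_equal(nrow(res$sites), 0L)
  # single copy, read carries one mismatch -> placed at the right locus
  g1 <- toy_genome(chr1 = paste0(random_dna(50), core, random_dna(150)))
  mut <- core
  substr(mut, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                 substr(core, 15, 15))[1L]
  tails$trimmed <- mut
  res <- align_polya_reads(tails, g1)
  expect_equal(unname(res$tally["placed"]), 1L)
  expect_equal(res$sites$position, 80L)       # 0-based first base past
  expect_equal(res$sites$strand, "+")
})

test_that("cleavage position and strand follow tail side and orientation", {
  set.seed(6)
  body <- random_dna(30)
  g <- toy_genome(chr1 = paste0(random_dna(60), body, random_dna(60)))
  # A3 presentation, forward alignment: plus strand, cleavage at block end
  t1 <- detect_polya_tails(paste0(body, strrep("A", 8)))
  r1 <- align_polya_reads(t1, g)
  expect_equal(r1$sites$strand, "+")
  expect_equal(r1$sites$position, 90L)
  # same molecule read from the other side: T5 presentation of the
  # reverse complement must give the identical site
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(body, strrep("A", 8)))))
  t2 <- detect_polya_tails(rc)
  expect_equal(t2$tail_side, "T5")
  r2 <- align_polya_reads(t2, g)
  expect_equal(r2$sites$strand, "+")
  expect_equal(r2$sites$position, 90L)
  # a minus-strand transcript: tail As continue left of the body in
  # transcript sense = Ts in genome sense right at the alignment start
  body_rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(body)))
  t3 <- detect_polya_tails(paste0(body_rc, strrep("A", 8)))
  r3 <- align_polya_reads(t3, g)
  expect_equal(r3$sites$strand, "-")
  expect_equal(r3$sites$position, 59L)        # base left of alignment start
})

test_that("internal-priming filter scans the downstream decamer for A-runs", {
  up <- strrep("C", 50)
  mk <- function(decamer) toy_genome(chr1 = paste0(up, decamer, strrep("C", 40)))
  site <- data.frame(chrom = "chr1", position = 50L, strand = "+")
  expect_false(internal_priming_keep(site, mk("AAAAAAGTCA")))  # run of 6
  expect_true(internal_priming_keep(site, mk("AAAAAGTCAG")))   # run of 5
  expect_false(internal_priming_keep(site, mk("GAAAAAAGTC")))  # internal run
  # minus strand: downstream is leftwards, strand-sense As are genomic Ts
  gm <- toy_genome(chr1 = paste0(strrep("C", 40), strrep("T", 6), "GCGC",
                                 strrep("C", 50)))
  site_m <- data.frame(chrom = "chr1", position = 49L, strand = "-")
  expect_false(internal_priming_keep(site_m, gm))
  # near the chromosome end: examine what exists, no out-of-bounds
  g_end <- toy_genome(chr1 = paste0(strrep("C", 50), "AAA"))
  expect_true(internal_priming_keep(
    data.frame(chrom = "chr1", position = 50L, strand = "+"), g_end))
})

test_that("cleavage-site clustering is single linkage at 15 bp", {
  mk <- function(pos) data.frame(chrom = "chr1", strand = "+", position = pos)
  expect_equal(nrow(cluster_cleavage_sites(mk(c(1000L, 1010L)))), 1L)
  one <- cluster_cleavage_sites(mk(777L))
  expect_equal(one$position, 777L)
  expect_equal(one$support, 1L)
  # chaining: 100-114-128 joins though the extremes are 28 apart
  ch <- cluster_cleavage_sites(mk(c(100L, 114L, 128L)))
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$n_members, 3L)
  # gap of 16 breaks the chain
  expect_equal(nrow(cluster_cleavage_sites(mk(c(100L, 116L)))), 2L)
  # representative: most-supported member, leftmost on ties
  many <- data.frame(chrom = "chr1", strand = "+",
                     position = c(10L, 10L, 20L, 20L, 24L))
  cl <- cluster_cleavage_sites(many)
  expect_equal(cl$position, 10L)
  expect_equal(cl$support, 5L)
})

test_that("clustering matches an independent connected-components oracle", {
  set.seed(21)
  for (rep in 1:20) {
    pos <- sort(sample.int(500L, 25L))
    got <- cluster_cleavage_sites(
      data.frame(chrom = "chr1", strand = "+", position = pos))
    # oracle: transitive closure of the <=15 bp adjacency relation
    upos <- unique(pos)
    adj <- abs(outer(upos, upos, "-")) <= 15L
    reach <- adj
    for (k in seq_along(upos)) reach <- reach | (reach %*% reach) > 0
    n_comp <- length(unique(apply(reach, 1L, function(r) min(which(r)))))
    expect_equal(nrow(got), n_comp)
    expect_equal(sum(got$support), length(pos))
  }
})

test_that("polyA signal annotation picks the nearest hexamer in the upstream 50-mer", {
  plant_at <- function(offset, hex) {
    s <- strrep("C", 120)
    substr(s, 100 + offset + 1L, 100 + offset + 6L) <- hex
    toy_genome(chr1 = s)
  }
  site <- data.frame(chrom = "chr1", position = 100L, strand = "+")
  a <- annotate_polya_signal(site, plant_at(-20L, "AATAAA"))
  expect_equal(a$signal, "AAUAAA")
  expect_equal(a$signal_offset, -20L)
  expect_equal(annotate_polya_signal(site, toy_genome(chr1 = strrep("C", 120)))$signal,
               "none")
  # ATTAAA at -12 beats AATAAA at -40 (nearer wins)
  s <- strrep("C", 120)
  substr(s, 100 - 40 + 1L, 100 - 40 + 6L) <- "AATAAA"
  substr(s, 100 - 12 + 1L, 100 - 12 + 6L) <- "ATTAAA"
  a <- annotate_polya_signal(site, toy_genome(chr1 = s))
  expect_equal(a$signal, "AUUAAA")
  expect_equal(a$signal_offset, -12L)
  # equal distance prefers AAUAAA: place both at the same offset upstream
  # on a minus-strand site (strand-sense search)
  sm <- strrep("G", 120)
  substr(sm, 61, 66) <- "TTTATT"     # revcomp(AATAAA), transcript-sense -20
  site_m <- data.frame(chrom = "chr1", position = 40L, strand = "-")
  a <- annotate_polya_signal(site_m, toy_genome(chr1 = sm))
  expect_equal(a$signal, "AAUAAA")
})

test_that("full polyA stage recovers planted sites and rejects priming traps on the small dataset", {
  sim <- small_sim()
  reads <- setNames(sim$polya_reads$seq, sim$polya_reads$id)
  pa <- call_polya_sites(reads, sim$genome)
  tr <- sim$truth$cleavage
  sup <- table(sim$polya_reads$entity)
  strong <- tr[tr$entity %in% names(sup)[sup >= 5L], , drop = FALSE]
  hit <- vapply(seq_len(nrow(strong)), function(i)
    any(pa$sites$chrom == strong$chrom[i] &
          abs(pa$sites$position - strong$position[i]) <= 15L), TRUE)
  expect_true(all(hit))
  # every kept cleavage site is far from every planted A-run trap
  fs <- sim$truth$false_sites
  for (i in seq_len(nrow(fs)))
    expect_false(any(pa$cleavage$chrom == fs$chrom[i] &
                       abs(pa$cleavage$position - fs$position[i]) <= 15L))
  expect_gt(unname(pa$tally["primed_rejected"]), 0L)
  # planted signals annotate as AAUAAA at the planted offset
  expect_true(all(pa$sites$signal == "AAUAAA"))
})
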