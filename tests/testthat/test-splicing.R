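# splicing: event detection vs an exhaustive oracle, Fisher testing

full_cov <- function(chrom = "chr1", len = 10000L)
  RleList(setNames(list(Rle(5L, len)), chrom))

# independent brute-force enumeration over all junction pairs/triples
oracle_events <- function(j, cov, min_support = 2L) {
  cnt <- rowSums(j[, grep("^count_", names(j)), drop = FALSE])
  j <- j[cnt >= min_support, , drop = FALSE]
  out <- list()
  n <- nrow(j)
  if (n >= 3L) for (x in 1:n) for (y in 1:n) for (z in 1:n) {
    if (x == y || y == z || x == z) next
    # z = exclusion [d, a); x = [d, a1); y = [d2, a); a1 < d2
    if (j$chrom[x] != j$chrom[z] || j$chrom[y] != j$chrom[z]) next
    if (j$start[x] == j$start[z] && j$end[y] == j$end[z] &&
        j$end[x] < j$start[y] && j$end[x] > j$start[z] &&
        j$start[y] < j$end[z])
      out[[length(out) + 1L]] <- data.frame(
        type = "exon_skipping", chrom = j$chrom[z],
        region_start = j$end[x], region_end = j$start[y])
  }
  if (n >= 2L) for (x in 1:n) for (y in 1:n) {
    if (x >= y || j$chrom[x] != j$chrom[y]) next
    covr <- cov[[j$chrom[x]]]
    shared_end <- j$end[x] == j$end[y] && j$start[x] != j$start[y]
    shared_start <- j$start[x] == j$start[y] && j$end[x] != j$end[y]
    if (!shared_end && !shared_start) next
    if (shared_end) {
      lo <- min(j$start[c(x, y)]); hi <- max(j$start[c(x, y)])
      type <- if (j$strand[x] == "-") "alt_3ss" else "alt_5ss"
    } else {
      lo <- min(j$end[c(x, y)]); hi <- max(j$end[c(x, y)])
      type <- if (j$strand[x] == "-") "alt_5ss" else "alt_3ss"
    }
    if (hi <= length(covr) && min(as.integer(covr[(lo + 1L):hi])) >= 1L)
      out[[length(out) + 1L]] <- data.frame(
        type = type, chrom = j$chrom[x], region_start = lo, region_end = hi)
  }
  if (!length(out)) return(data.frame(type = character(),
                                      chrom = character(),
                                      region_start = integer(),
                                      region_end = integer()))
  u <- unique(do.call(rbind, out))
  u[order(u$type, u$chrom, u$region_start), , drop = FALSE]
}

test_that("exon skipping requires all three junctions at support >= 2", {
  j <- rbind(jrow("chr1", 1000, 1500, 5),    # [d, a1)
             jrow("chr1", 1600, 2000, 4),    # [d2, a)
             jrow("chr1", 1000, 2000, 3))    # exclusion
  # realistic coverage: the introns flanking the skipped exon are uncovered,
  # so the junction pairs sharing one boundary do not double as alt events
  cov <- full_cov()
  cov[["chr1"]][c(1100:1200, 1700:1800)] <- 0L
  ev <- detect_as_events(j, cov)
  expect_equal(ev$type, "exon_skipping")
  expect_equal(ev$region_start, 1500L)
  expect_equal(ev$region_end, 1600L)
  j$count_A[3L] <- 1L
  expect_equal(nrow(detect_as_events(j, cov)), 0L)
})

test_that("alt splice sites need the 100%-coverage rule between the alternatives", {
  j <- rbind(jrow("chr1", 1000, 2000, 5),
             jrow("chr1", 1030, 2000, 6))    # shared acceptor, donors differ
  ev <- detect_as_events(j, full_cov())
  expect_equal(ev$type, "alt_5ss")
  expect_equal(c(ev$region_start, ev$region_end), c(1000L, 1030L))
  # inclusion junction J1 is the shorter intron
  expect_equal(ev$j1_start, 1030L)
  # coverage gap between the alternative sites kills the event
  gap <- full_cov()
  gap[["chr1"]][1010:1015] <- 0L
  expect_equal(nrow(detect_as_events(j, gap)), 0L)
  # minus-strand labelling flips the class
  jm <- j; jm$strand <- "-"
  expect_equal(detect_as_events(jm, full_cov())$type, "alt_3ss")
  # shared donor, differing acceptors: alt 3' on plus strand
  j3 <- rbind(jrow("chr1", 3000, 3970, 5),
              jrow("chr1", 3000, 4000, 6))
  expect_equal(detect_as_events(j3, full_cov())$type, "alt_3ss")
})

test_that("detection equals the exhaustive oracle on random toy junction sets", {
  set.seed(41)
  cov <- full_cov()
  for (rep in 1:15) {
    # 12 junctions over a small coordinate grid to force shared boundaries
    anchors <- sort(sample(seq(500L, 5000L, by = 100L), 8L))
    j <- do.call(rbind, lapply(1:12, function(i) {
      se <- sort(sample(anchors, 2L))
      jrow("chr1", se[1L], se[2L], sample(0:5, 1L), sample(0:5, 1L))
    }))
    j <- j[!duplicated(j[c("start", "end")]), , drop = FALSE]
    got <- detect_as_events(j, cov)
    want <- oracle_events(j, cov)
    key <- function(d) sort(unique(paste(d$type, d$chrom, d$region_start,
                                         d$region_end)))
    expect_identical(key(got), key(want))
  }
})

test_that("detection is monotone in junction counts and combined covers per-sample", {
  set.seed(43)
  for (rep in 1:10) {
    anchors <- sort(sample(seq(500L, 4000L, by = 100L), 6L))
    j <- do.call(rbind, lapply(1:10, function(i) {
      se <- sort(sample(anchors, 2L))
      jrow("chr1", se[1L], se[2L], sample(0:4, 1L), sample(0:4, 1L))
    }))
    j <- j[!duplicated(j[c("start", "end")]), , drop = FALSE]
    cov <- full_cov()
    key <- function(ev) paste(ev$type, ev$region_start, ev$region_end)
    base <- detect_as_events(j, cov)
    jup <- j; jup$count_A <- jup$count_A + 2L
    expect_true(all(key(base) %in% key(detect_as_events(jup, cov))))
    # per-sample detection implies combined detection
    jA <- j; jA$count_B <- 0L
    expect_true(all(key(detect_as_events(jA, cov)) %in% key(base)))
  }
})

# two-sided Fisher p by direct hypergeometric enumeration
fisher_oracle <- function(tab) {
  m <- sum(tab[1L, ]); n <- sum(tab[2L, ]); k <- sum(tab[, 1L])
  x <- tab[1L, 1L]
  probs <- dhyper(max(0L, k - n):min(k, m), m, n, k)
  obs <- dhyper(x, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

test_that("event testing reproduces the worked 2x2 example", {
  ev <- data.frame(type = "exon_skipping", chrom = "chr1", strand = "+",
                   region_start = 1500L, region_end = 1600L,
                   j1_start = 1000L, j1_end = 1500L,
                   j2_start = 1600L, j2_end = 2000L,
                   j3_start = 1000L, j3_end = 2000L)
  j <- rbind(jrow("chr1", 1000, 1500, 10, 30),
             jrow("chr1", 1600, 2000, 12, 34),
             jrow("chr1", 1000, 2000, 20, 10))
  names(j)[5:6] <- c("count_A", "count_B")
  ev <- event_counts(ev, j, samples = c("A", "B"))
  # inclusion = rounded mean of the two inclusion junctions
  expect_equal(c(ev$incA, ev$excA, ev$incB, ev$excB), c(11L, 20L, 32L, 10L))
  res <- test_differential_splicing(ev)
  expect_equal(res$odds_ratio, (32 / 10) / (11 / 20), tolerance = 1e-9)
  expect_equal(res$odds_ratio, 5.818182, tolerance = 1e-6)
  expect_equal(res$p, fisher_oracle(matrix(c(11, 20, 32, 10), 2L)),
               tolerance = 1e-9)
  # equal inclusion ratios: OR = 1, p = 1
  ev2 <- ev
  ev2[c("incA", "excA", "incB", "excB")] <- c(10L, 20L, 10L, 20L)
  res2 <- test_differential_splicing(ev2)
  expect_equal(res2$odds_ratio, 1)
  expect_equal(res2$p, 1)
  # zero margin: p = 1, OR missing
  ev3 <- ev
  ev3[c("incA", "excA", "incB", "excB")] <- c(0L, 20L, 0L, 10L)
  res3 <- test_differential_splicing(ev3)
  expect_equal(res3$p, 1)
  expect_true(is.na(res3$odds_ratio))
})

test_that("Fisher p equals enumeration for 50 random small tables; symmetries hold", {
  set.seed(47)
  mk_ev <- function(cells) data.frame(
    type = "exon_skipping", chrom = "chr1", strand = "+",
    region_start = 1L, region_end = 2L,
    j1_start = NA, j1_end = NA, j2_start = NA, j2_end = NA,
    j3_start = NA, j3_end = NA,
    incA = cells[1L], excA = cells[2L], incB = cells[3L], excB = cells[4L])
  for (i in 1:50) {
    cells <- rpois(4L, 12) + 1L
    res <- test_differential_splicing(mk_ev(cells))
    expect_equal(res$p, fisher_oracle(matrix(cells, 2L)), tolerance = 1e-9)
    # simultaneous row and column swap preserves p; column swap inverts OR
    swapped <- test_differential_splicing(mk_ev(cells[c(4L, 3L, 2L, 1L)]))
    expect_equal(swapped$p, res$p, tolerance = 1e-12)
    colsw <- test_differential_splicing(mk_ev(cells[c(3L, 4L, 1L, 2L)]))
    expect_equal(colsw$odds_ratio, 1 / res$odds_ratio, tolerance = 1e-12)
    expect_equal(colsw$p, res$p, tolerance = 1e-12)
  }
})

test_that("events are assigned to genes by outer-junction containment", {
  m <- toy_models(list(g1 = list(t1 = rbind(c(500, 800), c(2500, 3000)))))
  ev <- data.frame(type = "exon_skipping", chrom = "chr1", strand = "+",
                   region_start = 1500L, region_end = 1600L,
                   j1_start = 800L, j1_end = 1500L,
                   j2_start = 1600L, j2_end = 2500L,
                   j3_start = 800L, j3_end = 2500L)
  expect_equal(assign_event_genes(ev, m)$gene_id, "g1")
  ev$j3_start <- 100L  # sticks out of the gene span
  expect_true(is.na(assign_event_genes(ev, m)$gene_id))
})

test_that("planted events on simulated data are detected with correct classes", {
  sim <- small_sim()
  cov <- coverage(unlist(sim$frags, use.names = FALSE))
  ev <- detect_as_events(sim$junctions, cov)
  ev <- event_counts(ev, sim$junctions, samples = sim$config$samples)
  ev <- test_differential_splicing(ev)
  tr <- sim$truth$as_events
  m <- match(paste(tr$chrom, tr$j1_start, tr$j1_end, tr$j2_start, tr$j2_end),
             paste(ev$chrom, ev$j1_start, ev$j1_end, ev$j2_start, ev$j2_end))
  expect_true(all(!is.na(m)))
  expect_equal(ev$type[m], tr$type)
})
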