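#' Derive constitutive exon sets
#'
#' For each gene, the base-level intersection of exonic bases across all its
#' transcripts, expressed as maximal intervals; any resulting interval that
#' overlaps another gene's exonic base (any isoform) is then removed whole.
#' Whole-interval removal (rather than base subtraction) follows the
#' exon-level reading of "filter out exons that overlap between genes".
#'
#' @param models a [gene_models()] object.
#' @return A [GenomicRanges::GRangesList] named by gene id; genes whose
#'   constitutive set is empty keep an empty element.
#' @export
derive_constitutive_exons <- function(models) {
  tx_by_gene <- split(models$tx2gene$transcript_id, models$tx2gene$gene_id)
  zero <- setdiff(names(models$genes), names(tx_by_gene))
  if (length(zero))
    warning("gene(s) with zero transcripts: ", paste(zero, collapse = ", "))
  const <- lapply(tx_by_gene, function(txs) {
    Reduce(function(a, b) GenomicRanges::intersect(a, b, ignore.strand = TRUE),
           lapply(models$exons[txs], granges))
  })
  exon_union <- exon_union_by_gene(models)
  all_exons <- unlist(exon_union)
  gene_of_exon <- rep(names(exon_union), lengths(exon_union))
  out <- GRangesList(lapply(names(const), function(g) {
    ce <- const[[g]]
    if (!length(ce)) return(ce)
    other <- all_exons[gene_of_exon != g]
    ce[!overlapsAny(ce, other, ignore.strand = TRUE)]
  }))
  names(out) <- names(const)
  out
}

#' Count fragments entirely within constitutive exons
#'
#' A fragment increments gene G if and only if every aligned base of every
#' block lies within G's constitutive bases; fragments touching any base
#' outside (intron, UTR of a non-constitutive isoform, another gene) are not
#' counted.  A fragment counts for at most one gene and once only, regardless
#' of paired/single sequencing.  Only uniquely mapped fragments are used.
#'
#' @param frags an [aligned_fragments()] GRangesList.
#' @param const_exons output of [derive_constitutive_exons()].
#' @param samples sample levels (column order).
#' @return Integer count matrix, genes x samples.
#' @export
count_constitutive_fragments <- function(frags, const_exons,
                                         samples = unique(mcols(frags)$sample)) {
  frags <- frags[mcols(frags)$unique]
  genes <- names(const_exons)
  mat <- matrix(0L, length(genes), length(samples),
                dimnames = list(genes, samples))
  if (!length(frags)) return(mat)
  flat <- unlist(const_exons)          # adjacent intervals of one gene
  flat <- flat[width(flat) > 0L]
  gene_of <- rep(names(const_exons), lengths(const_exons))[width(unlist(const_exons)) > 0L]
  red_by_gene <- reduce(split(flat, gene_of))  # merge adjacency within a gene
  flat2 <- unlist(red_by_gene)
  gene2 <- rep(names(red_by_gene), lengths(red_by_gene))
  blocks <- unlist(frags, use.names = FALSE)
  frag_of_block <- rep(seq_along(frags), lengths(frags))
  hit <- findOverlaps(blocks, flat2, type = "within", ignore.strand = TRUE)
  # gene candidates per fragment; fragment assigned iff ALL blocks within one gene's set
  if (length(hit)) {
    df <- unique(data.frame(frag = frag_of_block[queryHits(hit)],
                            block = queryHits(hit),
                            gene = gene2[subjectHits(hit)]))
    nblocks <- lengths(frags)
    agg <- stats::aggregate(list(nb = df$block),
                            df[c("frag", "gene")],
                            function(x) length(unique(x)))
    agg <- agg[agg$nb == nblocks[agg$frag], , drop = FALSE]
    # at most one gene can fully contain a fragment after the overlap filter;
    # if adjacency ever allows two, assign to none
    tab <- table(agg$frag)
    agg <- agg[agg$frag %in% as.integer(names(tab)[tab == 1L]), , drop = FALSE]
    if (nrow(agg)) {
      smp <- mcols(frags)$sample[agg$frag]
      t2 <- table(factor(agg$gene, levels = genes),
                  factor(smp, levels = samples))
      mat <- mat + unclass(t2)
    }
  }
  storage.mode(mat) <- "integer"
  mat
}

#' Genic fragment accounting
#'
#' Classifies every uniquely mapped fragment as exonic (entirely within the
#' exonic-base union of some gene, any isoform), intronic (overlapping a gene
#' span but not exonic), or intergenic; the categories are mutually
#' exclusive and exhaustive.  Reports the intronic-of-genic fraction, the
#' study's diagnostic for pre-mRNA contamination.
#'
#' @param frags an [aligned_fragments()] GRangesList.
#' @param models a [gene_models()] object.
#' @param samples sample levels.
#' @return data.frame, one row per sample: `sample, total, exonic, intronic,
#'   genic, intergenic, intronic_fraction` (NA when genic = 0).
#' @export
genic_accounting <- function(frags, models,
                             samples = unique(mcols(frags)$sample)) {
  frags <- frags[mcols(frags)$unique]
  exon_union <- reduce(unlist(exon_union_by_gene(models)), ignore.strand = TRUE)
  spans <- models$genes
  blocks <- unlist(frags, use.names = FALSE)
  frag_of_block <- rep(seq_along(frags), lengths(frags))
  in_exon_block <- overlapsAny(blocks, exon_union, type = "within",
                               ignore.strand = TRUE)
  exonic <- as.logical(tapply(in_exon_block,
                              factor(frag_of_block, levels = seq_along(frags)),
                              all))
  if (!length(frags)) exonic <- logical(0)
  touches_gene <- overlapsAny(frags, spans, ignore.strand = TRUE)
  intronic <- touches_gene & !exonic
  # a fragment entirely exonic but not touching a span cannot occur
  intergenic <- !touches_gene
  smp <- factor(mcols(frags)$sample, levels = samples)
  out <- data.frame(
    sample = samples,
    total = as.integer(table(smp)),
    exonic = as.integer(table(smp[exonic & touches_gene])),
    intronic = as.integer(table(smp[intronic])),
    stringsAsFactors = FALSE)
  out$genic <- out$exonic + out$intronic
  out$intergenic <- out$total - out$genic
  out$intronic_fraction <- ifelse(out$genic > 0, out$intronic / out$genic, NA)
  out
}

#' Intronic-of-genic fraction from printed counts
#'
#' The arithmetic of the accounting table: genic = exonic + intronic and the
#' fraction = intronic / genic, reported as a percentage at 0.1 resolution.
#'
#' @param exonic,intronic fragment counts.
#' @return list with `genic` and `fraction_pct` (rounded to 0.1).
#' @export
intronic_fraction <- function(exonic, intronic) {
  genic <- exonic + intronic
  list(genic = genic,
       fraction_pct = round(100 * intronic / genic, 1))
}

#' Quantile normalize a count matrix
#'
#' After normalization every column has the same sorted value multiset (the
#' row-wise mean of the sorted columns); tied values receive the mean of the
#' reference values at the tied ranks.  Delegates to
#' [limma::normalizeQuantiles()] with tie handling.
#'
#' @param counts numeric matrix, features x samples.
#' @param round round the normalized values to integers (required before the
#'   count-based differential test).
#' @return Matrix of normalized values, same dimnames.
#' @export
quantile_normalize <- function(counts, round = FALSE) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) {
    warning("single sample: quantile normalization is the identity")
    return(counts)
  }
  norm <- limma::normalizeQuantiles(counts, ties = TRUE)
  dimnames(norm) <- dimnames(counts)
  if (round) norm <- round(norm)
  norm
}

#' Negative-binomial exact test for a two-sample, no-replicate design
#'
#' Models each feature's counts in the two samples as independent draws from
#' a negative binomial with common mean m = (kA+kB)/2 and variance w(m) from
#' a variance--mean trend fitted across all features: w(q) = q + alpha q^2,
#' with alpha >= 0 estimated by least squares of (variance - mean) on mean^2
#' over features with positive mean (alpha = 0 recovers Poisson).  The
#' two-sided p-value conditions on the total s = kA+kB and sums the joint
#' probabilities of all splits (a, b = s-a) no more likely than the observed
#' one, divided by the total probability of the conditioning event.  Features
#' with s = 0 are excluded from testing and from the BH denominator.
#'
#' This is the exact test of the no-replicate negative-binomial framework for
#' count data, re-implemented for exactly two samples.
#'
#' @param counts matrix of (normalized, integer) counts with exactly 2
#'   columns.
#' @param fdr FDR threshold for the significance flag (default 0.01).
#' @param alpha overdispersion; `NULL` (default) fits it from the data.
#' @return data.frame `feature, kA, kB, mean, log2fc, alpha, p, q, significant`;
#'   untestable features carry NA p/q.
#' @export
nb_exact_test <- function(counts, fdr = 0.01, alpha = NULL) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 2L)
  kA <- counts[, 1L]; kB <- counts[, 2L]
  if (is.null(alpha)) alpha <- fit_dispersion(kA, kB)
  s <- kA + kB
  m <- s / 2
  p <- rep(NA_real_, nrow(counts))
  testable <- s > 0
  p[testable] <- vapply(which(testable), function(i)
    nb_split_pvalue(kA[i], kB[i], alpha), 0)
  q <- rep(NA_real_, length(p))
  q[testable] <- stats::p.adjust(p[testable], "BH")
  log2fc <- log2((kB + 0.5) / (kA + 0.5))
  data.frame(feature = rownames(counts) %||% as.character(seq_along(kA)),
             kA = kA, kB = kB, mean = m, log2fc = log2fc, alpha = alpha,
             p = p, q = q,
             significant = !is.na(q) & q < fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fit of v = q + alpha q^2 across features, with per-feature two-sample
# mean q and variance estimate v = (kA - kB)^2 / 2 (unbiased for the NB
# variance).  Plain least squares is dominated by the few highest-count
# features, whose v has variance ~2 (q + alpha q^2)^2; three rounds of
# inverse-variance reweighting stabilise alpha.  Clamped at 0 (Poisson).
fit_dispersion <- function(kA, kB) {
  q <- (kA + kB) / 2
  v <- (kA - kB)^2 / 2
  use <- q > 0
  q <- q[use]; v <- v[use]
  if (!length(q)) return(0)
  alpha <- max(sum(q^2 * (v - q)) / sum(q^4), 0)
  # under the null v / (q + alpha q^2) ~ chi-square(1); features far in the
  # upper tail are (planted or real) differential features, not dispersion
  # information, and would otherwise dominate the fit on small matrices.
  cut <- stats::qchisq(0.99, 1)
  k <- stats::pchisq(cut, 3) / stats::pchisq(cut, 1)  # E[X | X <= cut], chisq(1)
  for (it in 1:4) {
    mu2 <- q + alpha * q^2
    keep <- v / mu2 <= cut
    w <- 1 / mu2[keep]^2
    alpha <- max(sum(w * q[keep]^2 * (v[keep] / k - q[keep])) /
                   sum(w * q[keep]^4), 0)
  }
  alpha
}

# exact conditional two-sided p for the split (kA, kB) of s = kA + kB
nb_split_pvalue <- function(kA, kB, alpha) {
  s <- kA + kB
  m <- s / 2
  a <- 0:s
  lp <- if (alpha > 0)
    stats::dnbinom(a, size = 1 / alpha, mu = m, log = TRUE)
  else
    stats::dpois(a, m, log = TRUE)
  ljoint <- lp + rev(lp)                     # log P(a) P(s - a)
  lobs <- lp[kA + 1L] + lp[kB + 1L]
  sel <- ljoint <= lobs + 1e-8               # tolerate fp ties
  lse <- function(x) { mx <- max(x); mx + log(sum(exp(x - mx))) }
  exp(lse(ljoint[sel]) - lse(ljoint))
}

#' Expected intronic-of-genic read fraction under pre-mRNA contamination
#'
#' With a molecule fraction p of unspliced pre-mRNA and exons making up a
#' fraction e of genic bases (default 1/20), length-weighted sampling of
#' reads gives an intronic-of-genic fraction
#' f(p) = p (1 - e) / (p + (1 - p) e).  Because introns dominate gene length
#' (the derivative at p = 0 is (1 - e)/e, i.e. 19 for e = 1/20), a slight
#' increase in pre-mRNA fraction increases intronic reads disproportionally.
#'
#' @param p pre-mRNA molecule fraction in \[0, 1\].
#' @param e exon base fraction of genes in \[0, 1\].
#' @return Expected intronic fraction among genic reads.
#' @export
premrna_intronic_model <- function(p, e = 1 / 20) {
  stopifnot(all(p >= 0 & p <= 1), all(e >= 0 & e <= 1))
  denom <- p + (1 - p) * e
  ifelse(denom == 0, 0, p * (1 - e) / denom)
}

#' Pre-mRNA fraction that yields a target intronic fraction
#'
#' Inverse of [premrna_intronic_model()]: the molecule fraction p such that
#' f(p, e) = f.
#'
#' @param f target intronic-of-genic fraction.
#' @param e exon base fraction.
#' @return p in \[0, 1\].
#' @export
premrna_fraction_for <- function(f, e = 1 / 20) {
  stopifnot(all(f >= 0 & f < 1))
  f * e / ((1 - e) * (1 - f))
}

#' Log-scale Pearson correlation between two samples
#'
#' Computed on log2(count + offset) over features with nonzero counts in both
#' samples; a descriptive utility for between-sample agreement.
#'
#' @param x,y count vectors.
#' @param offset pseudo-count.
#' @return Pearson correlation.
#' @export
log_expression_cor <- function(x, y, offset = 0) {
  use <- x > 0 & y > 0
  stats::cor(log2(x[use] + offset), log2(y[use] + offset))
}
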