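suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# Shared fixtures, built in code.  The small simulated dataset is cached for
# the whole run; the default-scale dataset is built lazily by the acceptance
# suite only.

.fixture_cache <- new.env(parent = emptyenv())

small_cfg <- function(seed = 42L, ...) {
  sim_config(seed = seed, n_genes = 12L, chrom_len = 2e5,
             n_fragments = c(6000L, 6000L), n_tu = 4L, n_de = 2L,
             n_skip = 2L, n_alt5 = 1L, n_alt3 = 1L,
             n_internal_priming = 2L, ...)
}

small_sim <- function() {
  if (is.null(.fixture_cache$small))
    .fixture_cache$small <- simulate_dataset(small_cfg())
  .fixture_cache$small
}

# toy gene models from a compact spec: list(gene = list(tx = matrix of
# 0-based half-open exon rows))
toy_models <- function(spec, chrom = "chr1", strand = "+") {
  rows <- list()
  for (g in names(spec)) for (tx in names(spec[[g]])) {
    m <- spec[[g]][[tx]]
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, transcript_id = paste(g, tx, sep = "."),
      chrom = chrom, strand = strand, start = m[, 1L], end = m[, 2L])
  }
  gene_models(do.call(rbind, rows))
}

# toy fragments: each element of `blocks` is a 2-column matrix of 0-based
# half-open block coordinates
toy_frags <- function(blocks, chrom = "chr1", sample = "S", unique = TRUE) {
  grl <- GenomicRanges::GRangesList(lapply(blocks, function(m)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(m[, 1L] + 1L, m[, 2L]))))
  if (length(grl)) names(grl) <- paste0("f", seq_along(grl))
  aligned_fragments(grl, sample = sample, unique = unique)
}

# genome from plain strings
toy_genome <- function(...) {
  seqs <- c(...)
  genome_seq(Biostrings::DNAStringSet(seqs))
}

# a junction table row
jrow <- function(chrom, start, end, cA, cB = 0L, strand = ".") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             count_A = cA, count_B = cB)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
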