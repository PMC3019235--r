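#' Hypergeometric GO-term enrichment
#'
#' Tests each term for over-representation of a selected gene set against an
#' annotated background by the one-sided hypergeometric upper tail.  With N
#' annotated background genes, n selected (annotated) genes, and K background
#' genes carrying the term, of which x are selected:
#' expected = n K / N and p = P(X >= x), X ~ Hypergeometric(N, K, n).
#' BH adjustment runs over all terms with at least one annotated gene.  No
#' ontology-graph propagation is performed; supply a pre-propagated map if
#' parent counting is wanted.
#'
#' @param selected character vector of selected gene ids.
#' @param gene2term data.frame with columns `gene` and `term` (one row per
#'   annotation), or a two-column data.frame in that order.
#' @return data.frame sorted by p: `term, N, n, K, observed, expected, p, q`.
#' @export
test_go_enrichment <- function(selected, gene2term) {
  if (ncol(gene2term) < 2L) stop("gene2term needs two columns")
  names(gene2term)[1:2] <- c("gene", "term")
  gene2term <- unique(gene2term[c("gene", "term")])
  background <- unique(gene2term$gene)
  N <- length(background)
  selected <- intersect(unique(selected), background)
  n <- length(selected)
  if (!n) {
    warning("empty (annotated) selection")
    return(data.frame(term = character(), N = integer(), n = integer(),
                      K = integer(), observed = integer(),
                      expected = numeric(), p = numeric(), q = numeric()))
  }
  K <- table(gene2term$term)
  obs <- table(gene2term$term[gene2term$gene %in% selected])
  terms <- names(K)
  x <- as.integer(obs[terms]); x[is.na(x)] <- 0L
  Kv <- as.integer(K)
  p <- stats::phyper(x - 1L, Kv, N - Kv, n, lower.tail = FALSE)
  out <- data.frame(term = terms, N = N, n = n, K = Kv, observed = x,
                    expected = n * Kv / N, p = p,
                    q = stats::p.adjust(p, "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p, out$term), , drop = FALSE]
}

#' Select genes for enrichment from a differential table
#'
#' The study's selection rule: features nominally significant at `p_cut`
#' (default 0.05) that carry at least one annotation.
#'
#' @param de data.frame from [nb_exact_test()].
#' @param gene2term annotation map as in [test_go_enrichment()].
#' @param p_cut nominal p threshold.
#' @return Character vector of selected gene ids.
#' @export
select_de_genes <- function(de, gene2term, p_cut = 0.05) {
  annotated <- unique(gene2term[[1L]])
  de$feature[!is.na(de$p) & de$p < p_cut & de$feature %in% annotated]
}
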