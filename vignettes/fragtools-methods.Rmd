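---
title: "fragtools: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fragtools: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

fragtools re-implements, as tested and reusable code, the bespoke
computational stages of a two-sample bulk RNA-seq analysis of early embryos
sequenced without replicates: one "normal" sample (blastocysts) and one
"abnormal" sample (degenerative embryos), each a pool of amplified RNA.  The
unit of all counting is the *fragment* — one sequenced cDNA molecule,
whether read from one or both ends.  This vignette explains the models and
the choices behind them; it states no empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## Coordinates and containers

All internal coordinates are 0-based half-open.  GTF (1-based inclusive) and
SAM (1-based) are converted at the parsing boundary and restored on export;
BED is native.  Fragments are held as a `GRangesList` of aligned blocks with
per-fragment metadata (sample, uniqueness, end type); mates sharing a QNAME
are merged into one fragment so that paired-end data is never double
counted.  The protocol is unstranded, so fragment strand is never inferred
from alignments; strand enters only through annotation or junction fields.

## PolyA-site calling

Unmapped reads are screened for a maximal uninterrupted terminal run of at
least 6 As at the 3' end or 6 Ts at the 5' end (the reverse-complement
presentation of the same tail).  The run is trimmed entirely and reads
shorter than 25 nt after trimming are discarded.  The tail is required to be
a pure run — the minimal reading of "contains at least six As" — so a single
non-A base ends the tail.

Trimmed reads are placed by a small exact aligner that is complete for the
configured mismatch budget (at most 1): any alignment with ≤1 mismatch
matches one half of the read exactly, so exact matches of both halves
enumerate every candidate locus, which are then Hamming-verified.  A read is
used only when exactly one locus on either strand qualifies ("forcing
uniqueness").  The cleavage position is the first genomic base past the last
transcribed base, in transcription direction; tail side plus alignment
orientation determine the strand.

Internal-priming artifacts — alignments explained by a genomic adenosine run
rather than a tail — are removed by scanning the 10 nt immediately
downstream (transcript sense) for a run of ≥6 As.  The source protocol says
only "downstream"; 10 nt bounds the scan while catching any run adjacent to
the cleavage site, and the window is configurable.  Kept cleavage sites are
clustered by single linkage at ≤15 bp; the cluster representative is its
most-supported position (leftmost on ties).  The canonical polyA signal
hexamers (AAUAAA, AUUAAA) are sought in the 50 bases upstream of the
representative position on the transcript strand — upstream only, because
that is where functional signals sit; a symmetric window is available by
configuration.  The nearest hexamer wins, AAUAAA on distance ties.  Both the
signal-bearing and total site tallies are reported, since the upstream
protocol left the precedence of signal filtering ambiguous.

## Digital expression and the accounting table

Constitutive exons are the per-gene base-level intersection of exonic bases
across all isoforms, expressed as maximal intervals; any interval that
overlaps another gene's exonic base (any isoform) is then removed *whole*,
which is the exon-level reading of "filtered out exons that overlapped
between genes".  A fragment counts for a gene only when every aligned base
of every block lies inside that gene's constitutive set, and for at most one
gene.  Fragment accounting classifies each uniquely mapped fragment as
exonic (entirely within the exonic-base union of some gene), intronic
(touching a gene span but not exonic), or intergenic; the three classes are
exhaustive and mutually exclusive, and the intronic-of-genic fraction is the
contamination diagnostic reported per sample.  Fragments touching two genes'
annotation are classified exonic only if fully contained in one gene's
exonic union; containment in none leaves them intronic if they touch a span.

Counts are quantile normalized (limma's implementation, tie ranks receiving
the mean of the reference values) rather than scaled by total mapped reads:
when the intronic fraction differs between samples, total-count scaling
would systematically bias exonic expression.  Normalized values are rounded
to integers before testing (configurable), since the exact test needs
count-like input.

## The no-replicate negative-binomial exact test

With one library per condition, biological dispersion cannot be estimated
per gene.  The test models the two counts of a feature as independent
negative binomials with shared mean m = (kA+kB)/2 and a variance taken from
a trend fitted across features, w(q) = q + αq² with α ≥ 0.  Conditioning on
the total s = kA + kB, the two-sided p-value sums the probabilities of all
splits (a, s−a) no more likely than the observed one, normalized by the
total probability of the conditioning event; α = 0 recovers the conditional
binomial (Poisson) test.  Benjamini–Hochberg adjustment over testable
features (s > 0) gives the 1% FDR calls.

Fitting α: the per-feature variance estimate v = (kA−kB)²/2 is unbiased but
extremely noisy (one degree of freedom), and its sampling variance scales as
2(q+αq²)².  A plain least-squares fit of v on (q, q²) is therefore dominated
by the few highest-count features, and on small matrices the planted (or
real) differential features themselves inflate α.  The package fits the same
parametric form by iterated inverse-variance-weighted least squares,
excluding features whose standardized ratio v/w(q) exceeds the 99th
percentile of its null χ²₁ distribution and correcting the retained mean for
that truncation analytically.  This keeps the null type-I error of the exact
test at its nominal level while making the fit robust to a moderate fraction
of truly differential features; it is the one place the implementation
deliberately refines the plain least-squares prescription, for the reasons
above.

## Pre-mRNA and the intronic read fraction

If a fraction p of molecules are unspliced pre-mRNA and exons make up a
fraction e of genic bases (1/20 by default), then sampling reads
proportionally to molecule length gives an expected intronic-of-genic read
fraction f(p) = p(1−e) / (p + (1−p)e).  The derivative at p = 0 is
(1−e)/e = 19: a small rise in pre-mRNA raises intronic reads
disproportionally, because introns dominate gene length.  The generator
inverts this model to pick its two default molecule fractions (≈0.0115 and
≈0.0270) so the two synthetic samples bracket intronic fractions of roughly
18% and 34%.  Note one deliberate simplification mismatch: in the generator
a pre-mRNA fragment is called intronic if it overlaps *any* intronic base,
so with 122 bp fragments and ~100 bp exons the realized fraction sits
slightly above f(p); the tests account for this with their stated
tolerances.

## Novel transcribed units

The assembler is deliberately simple — coverage islands (maximal runs of
covered bases) joined when a junction supported by ≥2 fragments connects
two islands.  The statistically-scored path assembly of the original
toolchain is *not* re-implemented: the reusable contribution here is the
filter and evidence stack, and the assembler is an upstream dependency.
A novel TU must pass all four filters: ≥1000 bp from the nearest annotated
gene boundary, length ≥500 bp, ≥40 fragments per kb, and <50% repeat
overlap.  The per-kb reading of the density criterion is the default (it
matches the "about 5 fragments per base" arithmetic at 122 bp fragments);
the absolute-count reading is available by configuration.  Evidence
annotation: polyA support requires a called site's representative position
*inside* the TU interval (minimal reading; a window is configurable), EST
support requires ≥50% base coverage, and conservation is the mean score
over scored bases only.  TU differential expression row-binds TU counts to
the gene matrix before joint quantile normalization, so the sparse TU
counts borrow the genes' reference distribution.

## Alternative splicing

Only the three junction-definable classes are analyzed — exon skipping and
alternative 5'/3' splice sites — because intronic reads and assembled
first/last exons are distrusted.  Exon skipping needs all three junctions at
≥2 fragments; alt events need both junctions at ≥2 fragments plus 100%
coverage of the bases between the alternative splice sites, evaluated in
the same dataset in which detection is claimed.  On minus-strand junctions
the donor/acceptor roles swap, so a shared genomic-right boundary is an alt
5' event on the plus strand and an alt 3' event on the minus strand;
unstranded junctions default to the plus-strand reading, and both junction
counts are always reported so the orientation convention is auditable.
"Inclusion" for an alt event is the shorter-intron junction (the longer
retained exon).  Differential splicing is a two-sided Fisher exact test on
the 2×2 table of inclusion/exclusion × sample, inclusion for skipping being
the rounded (half away from zero) mean of the two inclusion junctions.  The
reported odds ratio is the sample OR oriented second-sample over first with
the Haldane 0.5 correction when a cell is zero; BH runs within event type.

## GO enrichment

A one-sided hypergeometric upper-tail test per term, against the background
of all annotated genes, with expected count nK/N and BH adjustment over all
terms with at least one annotated gene.  No ontology-graph propagation is
performed — the input map is taken as given, so parent terms are counted
only if the map is pre-propagated.

## The synthetic world

The generator emulates the study design, not sequencing physics: two ~500 kb
chromosomes; 60 non-overlapping five-exon genes whose exons are 1/20 of
genic bases; 50,000 fragments per sample at insert size 122 ± 20 bp; mature
fragments drawn per isoform with sampling weight exp(position/λ) toward the
transcript 3' end (λ = 150 bp — a free parameter chosen to give a clearly
visible but not degenerate bias; the real bias profile is unknown);
pre-mRNA fragments uniform over gene spans at the length-weighted molecule
fraction; polyA reads at the true cleavage sites with planted AAUAAA
hexamers ~20 bp upstream, tail lengths 6 plus a truncated geometric, both
tail presentations equally likely; five genomic A-run traps with matching
internal-priming reads; 12 intergenic TUs with cycling
polyA/EST/conservation evidence plus four decoys each violating exactly one
TU filter; and planted effects — six 4-fold DE genes, four exon-skipping
events at inclusion-odds 4, two alt-5' and two alt-3' events at odds 3.
What a green test establishes is therefore recovery of *planted structure
under the model's own assumptions*; it says nothing about sequencing error,
mappability, annotation error, or amplification chemistry, none of which
are simulated.

## Numerical choices and degenerate inputs

Conditional p-values are computed on the log scale with a log-sum-exp
reduction; ties in the split probability are admitted with a 1e-8 additive
log tolerance.  Features with zero total count are excluded from testing
and from the BH denominator.  Zero-margin 2×2 tables give p = 1 and a
missing OR.  Sites within a window of a chromosome end scan only the bases
that exist.  Cluster representatives break support ties leftmost.  The
empty gene set, empty fragment set, zero-depth simulation, and single-sample
normalization all return well-formed empty or identity results rather than
errors (with a warning where the spec asks for one).

Two statistical limits of the design surface in testing and are worth
naming.  First, the Fisher exact test simply has limited power at moderate
depth: at an inclusion odds ratio of 3 and 100–200 fragments per event,
two-sided power at p < 0.01 is well below 1, so planted events near that
depth are not reliably called significant even though they are always
*detected*.  Second, quantile normalization on very small feature sets can
erase a true effect outright: a feature that occupies the same rank in both
samples is mapped to identical normalized values by construction, which is
why differential recovery is benchmarked on the 60-gene default world and
not on the 12-gene test miniature.

## Known limitations

The aligner is for toy genomes (it is complete but quadratic in genome
size); the assembler does not model paths through overlapping isoforms;
intron retention and mutually exclusive exons are out of scope; annotation
sources are taken from a single GTF without merging; and the no-replicate
test's significance statements concern these two particular samples, not
population-level differences — exactly the caveat the underlying design
carries.
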