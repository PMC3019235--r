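#' Run the full pipeline on a directory of standard-format inputs
#'
#' Expects the layout written by [write_dataset()]: `genome.fa`,
#' `annotation.gtf`, `<sample>.sam` and `<sample>_polya.fastq` per sample,
#' `junctions.tsv`, and optionally `repeats.bed`, `ests.bed`,
#' `conservation.bedGraph`, `go_annotations.tsv`.  Stages run in dependency
#' order (polya, count, accounting, diffexp, novel-tu, splice, enrich); each
#' writes its TSV outputs into `out_dir` and the run ends with a `MANIFEST`
#' and a run log whose per-stage tallies mirror the accounting-table shape.
#'
#' @param input_dir directory of inputs.
#' @param out_dir results directory (created).
#' @param config a [pipeline_config()].
#' @param stages subset of stages to run (dependencies are loaded from
#'   earlier outputs where needed).
#' @param samples the two sample labels; by default inferred from the
#'   `*.sam` files present (alphabetical order).
#' @return Invisibly, a named list of result objects.
#' @export
run_pipeline <- function(input_dir, out_dir,
                         config = pipeline_config(),
                         stages = c("polya", "count", "accounting", "diffexp",
                                    "novel-tu", "splice", "enrich"),
                         samples = NULL) {
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  need <- function(f) {
    p <- file.path(input_dir, f)
    if (!file.exists(p))
      stop("missing input for requested stage: ", f)
    p
  }
  if (is.null(samples)) {
    sams <- sort(list.files(input_dir, "\\.sam$"))
    samples <- sub("\\.sam$", "", sams)
  }
  stopifnot(length(samples) == 2L)
  log <- c(sprintf("fragtools run %s", format(t0)),
           sprintf("config seed=%d", config$seed),
           sprintf("samples: %s", paste(samples, collapse = ", ")))
  res <- list()

  genome <- read_genome(need("genome.fa"),
                        repeat_bed = if (file.exists(file.path(input_dir, "repeats.bed")))
                          file.path(input_dir, "repeats.bed") else NULL)
  models <- parse_gene_models(need("annotation.gtf"))

  frags <- NULL
  load_frags <- function() {
    if (is.null(frags)) {
      fl <- lapply(samples, function(s)
        parse_alignments(need(paste0(s, ".sam")), sample = s, config = config))
      frags <<- suppressWarnings(do.call(c, fl))
    }
    frags
  }

  if ("polya" %in% stages) {
    reads <- unlist(lapply(samples, function(s)
      read_fastq(need(paste0(s, "_polya.fastq")))))
    pa <- call_polya_sites(reads, genome, config)
    res$polya <- pa
    write_polya_bed(pa$sites, file.path(out_dir, "polya_sites.bed"))
    write_results_table(pa$sites, file.path(out_dir, "polya_sites.tsv"),
                        sort_by = c("chrom", "position"))
    log <- c(log, "stage polya:",
             sprintf("  %s\t%d", names(pa$tally), pa$tally))
  }
  if (any(c("count", "diffexp", "novel-tu", "enrich") %in% stages)) {
    const <- derive_constitutive_exons(models)
    counts <- count_constitutive_fragments(load_frags(), const,
                                           samples = samples)
    res$counts <- counts
    write_results_table(data.frame(feature = rownames(counts), counts,
                                   check.names = FALSE),
                        file.path(out_dir, "counts.tsv"))
    log <- c(log, sprintf("stage count: %d genes, %s fragments counted",
                          nrow(counts),
                          paste(colSums(counts), collapse = "/")))
  }
  if ("accounting" %in% stages) {
    acc <- genic_accounting(load_frags(), models, samples = samples)
    res$accounting <- acc
    write_results_table(acc, file.path(out_dir, "accounting.tsv"),
                        sort_by = character())
    log <- c(log, "stage accounting (per sample):",
             sprintf("  %s\ttotal=%d exonic=%d intronic=%d genic=%d intronic/genic=%.1f%%",
                     acc$sample, acc$total, acc$exonic, acc$intronic,
                     acc$genic, 100 * acc$intronic_fraction))
  }
  if ("diffexp" %in% stages) {
    norm <- quantile_normalize(res$counts, round = config$round_normalized)
    de <- nb_exact_test(norm, fdr = config$de_fdr)
    res$diffexp <- de
    write_results_table(de, file.path(out_dir, "diffexp.tsv"))
    log <- c(log, sprintf("stage diffexp: %d significant at FDR %g",
                          sum(de$significant), config$de_fdr))
  }
  if ("novel-tu" %in% stages) {
    jx <- read_junctions(need("junctions.tsv"))
    asm <- assemble_transcripts(load_frags(), jx,
                                min_junction_support = config$junction_min_support)
    tus <- filter_novel_tus(asm, models, genome$repeats,
                            min_distance = config$tu_min_distance,
                            min_length = config$tu_min_length,
                            min_frags_per_kb = config$tu_min_frags_per_kb,
                            max_repeat_frac = config$tu_max_repeat_frac,
                            density_absolute = config$tu_density_absolute)
    ests <- if (file.exists(file.path(input_dir, "ests.bed")))
      rtracklayer::import(file.path(input_dir, "ests.bed"), format = "BED")
    scores <- if (file.exists(file.path(input_dir, "conservation.bedGraph")))
      read_score_track(file.path(input_dir, "conservation.bedGraph"))
    pa_sites <- if (!is.null(res$polya)) res$polya$sites
      else if (file.exists(file.path(out_dir, "polya_sites.bed")))
        read_polya_bed(file.path(out_dir, "polya_sites.bed"))
    tus <- annotate_tu_evidence(tus, pa_sites, ests, scores,
                                est_min_coverage = config$est_min_coverage)
    res$novel_tus <- tus
    write_results_table(tus, file.path(out_dir, "novel_tus.tsv"))
    # TU differential expression alongside genes
    if (nrow(tus)) {
      spans <- GRanges(tus$chrom, IRanges(tus$start + 1L, tus$end))
      fr <- load_frags()
      hit <- findOverlaps(fr, spans, ignore.strand = TRUE)
      tu_counts <- matrix(0L, nrow(tus), 2L,
                          dimnames = list(tus$tu_id, samples))
      if (length(hit)) {
        t2 <- table(factor(tus$tu_id[subjectHits(hit)], levels = tus$tu_id),
                    factor(mcols(fr)$sample[queryHits(hit)], levels = samples))
        tu_counts <- tu_counts + unclass(t2)
      }
      tude <- test_tu_differential(res$counts, tu_counts, fdr = config$de_fdr,
                                   round = config$round_normalized)
      res$tu_diffexp <- tude$tus
      write_results_table(tude$tus, file.path(out_dir, "tu_diffexp.tsv"))
    }
    log <- c(log, sprintf("stage novel-tu: %d assembled, %d retained",
                          length(asm$blocks), nrow(tus)))
  }
  if ("splice" %in% stages) {
    jx <- read_junctions(need("junctions.tsv"))
    cov <- coverage(unlist(load_frags()[mcols(load_frags())$unique],
                           use.names = FALSE))
    ev <- detect_as_events(jx, cov, min_support = config$junction_min_support)
    ev <- event_counts(ev, jx, samples = samples)
    ev <- assign_event_genes(ev, models)
    ev <- test_differential_splicing(ev, fdr = config$as_fdr)
    res$splicing <- ev
    write_results_table(ev, file.path(out_dir, "splicing.tsv"),
                        sort_by = c("type", "chrom", "region_start"))
    log <- c(log, sprintf("stage splice: %d events (%s), %d significant",
                          nrow(ev),
                          paste(names(table(ev$type)), table(ev$type),
                                sep = "=", collapse = ", "),
                          sum(ev$significant)))
  }
  if ("enrich" %in% stages) {
    go_path <- file.path(input_dir, "go_annotations.tsv")
    if (!file.exists(go_path))
      stop("missing input for requested stage: go_annotations.tsv")
    go <- utils::read.delim(go_path, stringsAsFactors = FALSE)
    de <- res$diffexp
    if (is.null(de) && file.exists(file.path(out_dir, "diffexp.tsv")))
      de <- read_results_table(file.path(out_dir, "diffexp.tsv"))
    if (is.null(de)) stop("missing input for requested stage: diffexp results")
    sel <- select_de_genes(de, go, p_cut = config$go_selection_p)
    enr <- test_go_enrichment(sel, go)
    res$enrichment <- enr
    write_results_table(enr, file.path(out_dir, "enrichment.tsv"),
                        sort_by = character())
    log <- c(log, sprintf("stage enrich: %d selected genes, %d terms tested",
                          length(sel), nrow(enr)))
  }
  out_files <- sort(setdiff(list.files(out_dir), c("MANIFEST", "run_log.txt")))
  writeLines(out_files, file.path(out_dir, "MANIFEST"))
  log <- c(log, sprintf("elapsed %.1f s",
                        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(res)
}
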