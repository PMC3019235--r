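#' Pipeline configuration with study defaults
#'
#' Every numeric threshold used by the pipeline, with the defaults of the
#' original embryo study.  Thresholds: polyA tail minimum run 6 nt, minimum
#' trimmed read length 25 nt, cleavage-site cluster gap 15 bp, polyA-signal
#' search window 50 bp, internal-priming downstream window 10 nt; novel-TU
#' distance-to-gene 1000 bp, minimum length 500 bp, minimum density 40
#' fragments/kb, maximum repeat fraction 0.5, EST support coverage 0.5;
#' junction minimum support 2 fragments; DE and AS FDR 1%; GO selection at
#' nominal p = 0.05; exon base fraction 1/20; mean insert size 122 bp.
#'
#' @param ... named overrides of any default.
#' @return A named list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(tu_min_length = 300)
#' cfg$tail_min_run
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    tail_min_run          = 6L,
    min_trimmed_length    = 25L,
    max_align_mismatch    = 1L,
    cluster_gap           = 15L,
    signal_window         = 50L,
    signal_symmetric      = FALSE,
    priming_window        = 10L,
    priming_min_run       = 6L,
    tu_min_distance       = 1000L,
    tu_min_length         = 500L,
    tu_min_frags_per_kb   = 40,
    tu_density_absolute   = FALSE,  # Methods' absolute-count reading, off by default
    tu_max_repeat_frac    = 0.5,
    est_min_coverage      = 0.5,
    junction_min_support  = 2L,
    de_fdr                = 0.01,
    as_fdr                = 0.01,
    go_selection_p        = 0.05,
    exon_base_fraction    = 1 / 20,
    insert_size_mean      = 122,
    round_normalized      = TRUE,
    multimap_flag_bit     = 256L,   # SAM secondary-alignment bit marks multireads
    seed                  = 1L
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  stopifnot(cfg$exon_base_fraction >= 0, cfg$exon_base_fraction <= 1,
            cfg$tu_max_repeat_frac >= 0, cfg$tu_max_repeat_frac <= 1,
            cfg$de_fdr > 0, cfg$as_fdr > 0)
  structure(cfg, class = "pipeline_config")
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; values are parsed
#' as numbers where possible, `true`/`false` as logicals.  Keys must be valid
#' [pipeline_config()] names.
#'
#' @param path file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  vals <- lapply(kv, function(x) {
    v <- x[[2L]]
    if (tolower(v) %in% c("true", "false")) return(as.logical(toupper(v)))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  do.call(pipeline_config, setNames(vals, vapply(kv, `[[`, "", 1L)))
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}
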