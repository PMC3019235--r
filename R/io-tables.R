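#' Write a results table as TSV
#'
#' Deterministic output: rows sorted by the given keys, columns in the given
#' order, floats at fixed precision.  Round-trips through [read_results_table()].
#'
#' @param df data.frame of results.
#' @param path destination file.
#' @param sort_by column names to sort rows by (default: first column).
#' @param digits decimal places for numeric (non-integer) columns.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(df, path, sort_by = names(df)[1L], digits = 6L) {
  ok <- dir.exists(dirname(path))
  if (!ok) stop("unwritable destination: ", path)
  if (nrow(df) && length(sort_by))
    df <- df[do.call(order, df[sort_by]), , drop = FALSE]
  num <- vapply(df, function(x) is.numeric(x) && !is.integer(x), TRUE)
  df[num] <- lapply(df[num], function(x) {
    x <- round(x, digits)
    x[abs(x) < .Machine$double.eps] <- 0  # avoid "-0"
    x
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_results_table()]
#' @param path file path.
#' @return data.frame.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write polyA sites as BED6
#'
#' One line per site: the representative cleavage position as a 1-bp interval
#' (0-based half-open, BED native), name = polyA signal (`AAUAAA`, `AUUAAA`
#' or `none`), score = total supporting read count.
#'
#' @param sites data.frame from [call_polya_sites()].
#' @param path destination BED file.
#' @return `path`, invisibly.
#' @export
write_polya_bed <- function(sites, path) {
  if (!dir.exists(dirname(path))) stop("unwritable destination: ", path)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   sites$chrom, sites$position, sites$position + 1L,
                   sites$signal, sites$support, sites$strand)
  writeLines(lines[order(sites$chrom, sites$position)], path)
  invisible(path)
}

#' Read polyA sites from BED6 written by [write_polya_bed()]
#' @param path BED file.
#' @return data.frame with `chrom,position,strand,support,signal`.
#' @export
read_polya_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = df$V1, position = as.integer(df$V2),
             strand = df$V6, support = as.integer(df$V5), signal = df$V4)
}
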