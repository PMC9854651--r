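# label-free quantification (LFQ) intensity tables

#' Construct an expression table
#'
#' Long-format per-replicate LFQ intensities: one row per (protein, cell
#' line, replicate). An intensity of 0 (or NA, normalized to 0) means the
#' protein was not quantified in that run; intensities are arbitrary LFQ
#' units and must be non-negative.
#'
#' @param protein,cell_line Character vectors.
#' @param replicate Integer replicate index within a cell line.
#' @param intensity Non-negative numeric LFQ intensities.
#' @return An `expression_table` data frame.
#' @export
expression_table <- function(protein, cell_line, replicate, intensity) {
  intensity <- as.numeric(intensity)
  intensity[is.na(intensity)] <- 0
  if (any(intensity < 0)) {
    pn_stop("LFQ intensities must be non-negative", "pigmentnet_format_error")
  }
  df <- data.frame(protein = canonical_symbol(protein),
                   cell_line = as.character(cell_line),
                   replicate = as.integer(replicate),
                   intensity = intensity,
                   stringsAsFactors = FALSE)
  class(df) <- c("expression_table", "data.frame")
  df
}

#' Read an LFQ expression table from TSV
#'
#' Accepts either the long layout (`protein`, `cell_line`, `replicate`,
#' `intensity`) or a wide per-line layout (`protein`, `cell_line`, then one
#' intensity column per replicate), detected from the header.
#'
#' @param path TSV file.
#' @return An `expression_table`.
#' @export
read_expression_table <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("protein", "cell_line"), path)
  if (all(c("replicate", "intensity") %in% names(df))) {
    return(expression_table(df$protein, df$cell_line, df$replicate, df$intensity))
  }
  reps <- setdiff(names(df), c("protein", "cell_line"))
  if (!length(reps)) {
    pn_stop(sprintf("%s: no replicate intensity columns found", path),
            "pigmentnet_format_error")
  }
  long <- do.call(rbind, lapply(seq_along(reps), function(i) {
    data.frame(protein = df$protein, cell_line = df$cell_line,
               replicate = i,
               intensity = suppressWarnings(as.numeric(df[[reps[i]]])),
               stringsAsFactors = FALSE)
  }))
  expression_table(long$protein, long$cell_line, long$replicate, long$intensity)
}

#' Write an expression table (long format) to TSV
#' @param table An `expression_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(table, path) {
  write_tsv(as.data.frame(table), path)
}
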