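# scored PPI edge table ingest (STRING dialects)

#' Construct a scored edge table
#'
#' Undirected protein-protein interactions with a combined confidence score
#' in \[0, 1\]. Pairs are stored in canonical lexical order (`protein_a <
#' protein_b`); duplicate pairs collapse to the maximum score; self-loops are
#' dropped with a warning (PPI self-interactions play no role in any analysis
#' here).
#'
#' @param protein_a,protein_b Character vectors of interactor symbols.
#' @param score Numeric confidence scores in \[0, 1\].
#' @return A `scored_edge_table` data frame with columns `protein_a`,
#'   `protein_b`, `score`.
#' @export
scored_edge_table <- function(protein_a = character(),
                              protein_b = character(),
                              score = numeric()) {
  a <- canonical_symbol(protein_a)
  b <- canonical_symbol(protein_b)
  score <- as.numeric(score)
  if (length(a) != length(b) || length(a) != length(score)) {
    pn_stop("protein_a, protein_b and score must have equal length",
            "pigmentnet_format_error")
  }
  if (length(score) && (any(is.na(score)) || any(score < 0) || any(score > 1))) {
    pn_stop("edge scores must lie in [0, 1]", "pigmentnet_format_error")
  }
  self <- a == b
  if (any(self)) {
    warning(sprintf("dropped %d self-loop edge(s)", sum(self)), call. = FALSE)
    a <- a[!self]; b <- b[!self]; score <- score[!self]
  }
  cp <- canonical_pairs(a, b)
  df <- data.frame(protein_a = cp$a, protein_b = cp$b, score = score,
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    key <- paste(df$protein_a, df$protein_b, sep = "\r")
    # duplicate pair -> keep max score (STRING exports are symmetric)
    df <- df[order(key, -df$score), , drop = FALSE]
    df <- df[!duplicated(paste(df$protein_a, df$protein_b, sep = "\r")), ,
             drop = FALSE]
    df <- df[order(df$protein_a, df$protein_b), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("scored_edge_table", "data.frame")
  df
}

#' Read a scored PPI edge table from TSV
#'
#' Handles both common STRING score dialects: `UNIT_INTERVAL` scores already
#' in \[0, 1\], or `STRING_0_1000` integer scores in \[0, 1000\] which are
#' divided by 1000 on ingest.
#'
#' @param path TSV with columns `protein_a`, `protein_b`, `combined_score`
#'   (remappable via `dialect_columns`).
#' @param score_dialect `"UNIT_INTERVAL"` or `"STRING_0_1000"`.
#' @param dialect_columns Named character vector mapping the canonical column
#'   names to the file's.
#' @return A `scored_edge_table`.
#' @export
read_scored_edges <- function(path,
                              score_dialect = c("UNIT_INTERVAL", "STRING_0_1000"),
                              dialect_columns = c(protein_a = "protein_a",
                                                  protein_b = "protein_b",
                                                  combined_score = "combined_score")) {
  score_dialect <- match.arg(score_dialect)
  df <- read_tsv(path)
  require_columns(df, unname(dialect_columns), path)
  a <- df[[dialect_columns[["protein_a"]]]]
  b <- df[[dialect_columns[["protein_b"]]]]
  s <- suppressWarnings(as.numeric(df[[dialect_columns[["combined_score"]]]]))

  hi <- if (score_dialect == "STRING_0_1000") 1000 else 1
  bad <- which(is.na(s) | s < 0 | s > hi)
  if (length(bad)) {
    pn_stop(sprintf("%s: score outside %s range at data row %d (value '%s')",
                    path, score_dialect, bad[1],
                    df[[dialect_columns[["combined_score"]]]][bad[1]]),
            "pigmentnet_format_error")
  }
  if (score_dialect == "STRING_0_1000") s <- s / 1000
  scored_edge_table(a, b, s)
}

#' Write a scored edge table to TSV
#' @param edges A `scored_edge_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scored_edges <- function(edges, path) {
  write_tsv(as.data.frame(edges), path)
}
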