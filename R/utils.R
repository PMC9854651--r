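# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
pn_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "pigmentnet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# HGNC symbols are upper case; strip whitespace on ingest
canonical_symbol <- function(x) toupper(trimws(as.character(x)))

# round-half-up (base round() is banker's); reproduces integer-percent
# conventions like 169/243 -> 70%
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# canonical undirected pair ordering: a < b lexically
canonical_pairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  list(a = a, b = b)
}

stopifnot_file <- function(path) {
  if (!file.exists(path)) {
    pn_stop(sprintf("input file does not exist: %s", path), "pigmentnet_io_error")
  }
}

# tab-delimited reader used by all TSV ingests; consistent quoting/encoding
read_tsv <- function(path) {
  stopifnot_file(path)
  if (file.size(path) == 0) {
    pn_stop(sprintf("empty input file: %s", path), "pigmentnet_format_error")
  }
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, quote = "", comment.char = "",
             fileEncoding = "UTF-8")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

require_columns <- function(df, cols, path = "<data>") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    pn_stop(sprintf("%s: missing required column(s): %s",
                    path, paste(missing, collapse = ", ")),
            "pigmentnet_format_error")
  }
  invisible(df)
}
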