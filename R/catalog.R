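#' Official gene-symbol catalog
#'
#' A catalog of official (HGNC-style) protein-coding gene symbols used to
#' validate curated gene symbols: unmatched symbols are removed during
#' curation. Symbols are upper-cased and whitespace-stripped, and duplicates
#' collapsed.
#'
#' @param symbols Character vector of gene symbols.
#' @return A `gene_catalog` object.
#' @export
gene_catalog <- function(symbols) {
  symbols <- canonical_symbol(symbols)
  symbols <- symbols[nzchar(symbols) & !is.na(symbols)]
  symbols <- unique(symbols)
  if (!length(symbols)) {
    pn_stop("gene catalog is empty", "pigmentnet_config_error")
  }
  structure(list(symbols = symbols), class = "gene_catalog")
}

#' Read a gene-symbol catalog from a TSV file
#'
#' @param path TSV with a header; the symbol column defaults to `symbol`.
#' @param column Name of the column holding gene symbols.
#' @return A `gene_catalog`.
#' @export
read_gene_catalog <- function(path, column = "symbol") {
  df <- read_tsv(path)
  require_columns(df, column, path)
  gene_catalog(df[[column]])
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("gene_catalog: %d protein-coding symbols\n", length(x$symbols)))
  invisible(x)
}

#' @export
length.gene_catalog <- function(x) length(x$symbols)
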