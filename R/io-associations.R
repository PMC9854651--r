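# gene-disease association ingest

PHENOTYPE_CLASSES <- c("HYPER", "HYPO", "MIXED", "PHENOTYPE")
ASSOCIATION_SOURCES <- c("YAMAGUCHI", "OPENTARGETS", "BAXTER")

#' Construct a gene-disease association table
#'
#' One row per (gene, disease) association with its phenotype class
#' (`HYPER`, `HYPO`, `MIXED`, `PHENOTYPE`) and curation source. Gene symbols
#' are canonicalized (upper case, trimmed); disease names are trimmed but
#' otherwise kept verbatim, so disease subtypes with distinct names stay
#' distinct diseases.
#'
#' @param gene,disease,phenotype_class,source Character vectors of equal
#'   length.
#' @param omim_note Optional free-text phenotype notes.
#' @return An `association_table` data frame.
#' @export
association_table <- function(gene, disease, phenotype_class, source,
                              omim_note = NA_character_) {
  n <- length(gene)
  rec <- function(x) if (length(x) == 1 && n != 1) rep(x, n) else x
  df <- data.frame(
    gene = canonical_symbol(gene),
    disease = trimws(as.character(rec(disease))),
    phenotype_class = toupper(trimws(as.character(rec(phenotype_class)))),
    source = toupper(trimws(as.character(rec(source)))),
    omim_note = as.character(rec(omim_note)),
    stringsAsFactors = FALSE
  )
  class(df) <- c("association_table", "data.frame")
  df
}

#' Read a gene-disease association table from TSV
#'
#' Column names in the file are mapped onto the canonical fields through
#' `dialect`, so supplementary tables with arbitrary headers can be ingested
#' without editing. Malformed rows (blank gene, disease or class) are dropped
#' with a warning rather than aborting the run.
#'
#' @param path TSV file with a header row.
#' @param dialect Named character vector mapping canonical fields
#'   (`gene`, `disease`, `class`, `source`, optionally `omim_note`) to the
#'   file's column names.
#' @return An `association_table`.
#' @export
read_association_table <- function(path,
                                   dialect = c(gene = "gene",
                                               disease = "disease",
                                               class = "class",
                                               source = "source")) {
  required <- c("gene", "disease", "class", "source")
  if (!all(required %in% names(dialect))) {
    pn_stop("dialect must map fields: gene, disease, class, source",
            "pigmentnet_config_error")
  }
  df <- read_tsv(path)
  require_columns(df, unname(dialect[required]), path)

  tab <- association_table(
    gene = df[[dialect[["gene"]]]],
    disease = df[[dialect[["disease"]]]],
    phenotype_class = df[[dialect[["class"]]]],
    source = df[[dialect[["source"]]]],
    omim_note = if ("omim_note" %in% names(dialect) &&
                    dialect[["omim_note"]] %in% names(df)) {
      df[[dialect[["omim_note"]]]]
    } else NA_character_
  )

  bad <- !nzchar(tab$gene) | is.na(tab$gene) |
    !nzchar(tab$disease) | is.na(tab$disease) |
    !nzchar(tab$phenotype_class) | is.na(tab$phenotype_class)
  if (any(bad)) {
    warning(sprintf("%s: dropped %d malformed row(s) (blank gene/disease/class)",
                    path, sum(bad)), call. = FALSE)
    tab <- tab[!bad, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Write an association table to TSV
#' @param table An `association_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(table, path) {
  write_tsv(as.data.frame(table), path)
}
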