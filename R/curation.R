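# curation of gene-disease associations and the bipartite diseasome

# review classification outranks the database pulls when sources disagree
SOURCE_PRECEDENCE <- c(YAMAGUCHI = 1, BAXTER = 2, OPENTARGETS = 3)

#' Curate a raw association table against a gene catalog
#'
#' Gene symbols are matched to the official catalog and unmatched genes
#' removed; duplicate (gene, disease) pairs collapse to one association with
#' all contributing sources recorded. When duplicated associations disagree
#' on the phenotype class, the class from the highest-precedence source wins
#' (manual review > curated appendix > database pull) with a warning.
#'
#' @param raw An `association_table`.
#' @param catalog A `gene_catalog`.
#' @return A curated `association_table` with attributes `n_associations`,
#'   `n_genes`, `n_diseases` and `n_unmatched` (genes removed).
#' @export
curate <- function(raw, catalog) {
  if (!inherits(catalog, "gene_catalog") || !length(catalog$symbols)) {
    pn_stop("a non-empty gene catalog is required", "pigmentnet_config_error")
  }
  tab <- as.data.frame(raw)
  matched <- tab$gene %in% catalog$symbols
  n_unmatched <- length(unique(tab$gene[!matched]))
  tab <- tab[matched, , drop = FALSE]

  if (nrow(tab)) {
    key <- paste(tab$gene, tab$disease, sep = "\r")
    prec <- SOURCE_PRECEDENCE[tab$source]
    prec[is.na(prec)] <- max(SOURCE_PRECEDENCE) + 1
    ord <- order(key, prec)
    tab <- tab[ord, , drop = FALSE]
    key <- key[ord]

    groups <- split(seq_len(nrow(tab)), factor(key, levels = unique(key)))
    rows <- lapply(groups, function(idx) {
      first <- tab[idx[1], , drop = FALSE]  # highest-precedence source first
      cls <- unique(tab$phenotype_class[idx])
      if (length(cls) > 1) {
        warning(sprintf(
          "conflicting phenotype class for (%s, %s): keeping '%s' from %s",
          first$gene, first$disease, first$phenotype_class, first$source),
          call. = FALSE)
      }
      first$source <- paste(sort(unique(tab$source[idx])), collapse = ",")
      first
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$gene, tab$disease), , drop = FALSE]
    rownames(tab) <- NULL
  }
  class(tab) <- c("association_table", "data.frame")
  attr(tab, "n_associations") <- nrow(tab)
  attr(tab, "n_genes") <- length(unique(tab$gene))
  attr(tab, "n_diseases") <- length(unique(tab$disease))
  attr(tab, "n_unmatched") <- n_unmatched
  tab
}

# one class per unique disease; precedence resolves cross-record conflicts
disease_class_map <- function(table) {
  tab <- as.data.frame(table)
  unknown <- !(tab$phenotype_class %in% PHENOTYPE_CLASSES)
  if (any(unknown)) {
    pn_stop(sprintf("unknown phenotype class '%s' at row %d",
                    tab$phenotype_class[which(unknown)[1]], which(unknown)[1]),
            "pigmentnet_validation_error")
  }
  prec <- SOURCE_PRECEDENCE[vapply(strsplit(tab$source, ","), `[[`, "", 1L)]
  prec[is.na(prec)] <- max(SOURCE_PRECEDENCE) + 1
  ord <- order(tab$disease, prec)
  tab <- tab[ord, , drop = FALSE]
  first <- !duplicated(tab$disease)
  setNames(tab$phenotype_class[first], tab$disease[first])
}

#' Count diseases per phenotype class
#'
#' Partitions the unique diseases of a curated table into the four phenotype
#' classes (hyperpigmentation, hypopigmentation, mixed, pigmentation
#' phenotype without disease).
#'
#' @param table A curated `association_table`.
#' @return Named integer vector over `HYPER`, `HYPO`, `MIXED`, `PHENOTYPE`;
#'   entries sum to the number of unique diseases.
#' @export
classify_diseases <- function(table) {
  map <- disease_class_map(table)
  counts <- setNames(integer(length(PHENOTYPE_CLASSES)), PHENOTYPE_CLASSES)
  tb <- table(factor(map, levels = PHENOTYPE_CLASSES))
  counts[names(tb)] <- as.integer(tb)
  counts
}

#' Assign a single network class to every gene
#'
#' A gene linked only to diseases of one phenotype class takes that class;
#' a gene whose diseases span two or more classes is labeled `MULTIPLE`.
#'
#' @param table A curated `association_table`.
#' @return Data frame with columns `gene`, `network_class`, plus an attribute
#'   `exclusive_counts` (genes per exclusive class and `MULTIPLE`).
#' @export
assign_gene_classes <- function(table) {
  tab <- as.data.frame(table)
  map <- disease_class_map(table)
  cls_by_gene <- tapply(map[tab$disease], tab$gene,
                        function(x) unique(x), simplify = FALSE)
  genes <- names(cls_by_gene)
  network_class <- vapply(cls_by_gene, function(x) {
    if (length(x) == 1) x else "MULTIPLE"
  }, "")
  out <- data.frame(gene = genes, network_class = unname(network_class),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  counts <- table(factor(out$network_class,
                         levels = c(PHENOTYPE_CLASSES, "MULTIPLE")))
  attr(out, "exclusive_counts") <- setNames(as.integer(counts), names(counts))
  out
}

#' Build the bipartite diseasome
#'
#' Genes and diseases become the two node sets; every curated association
#' becomes one bipartite link.
#'
#' @param table A curated `association_table`.
#' @return A `diseasome` object: `genes`, `diseases` (with class), `links`.
#' @export
build_diseasome <- function(table) {
  tab <- as.data.frame(table)
  map <- disease_class_map(table)
  structure(list(
    genes = sort(unique(tab$gene)),
    diseases = data.frame(disease = names(map),
                          phenotype_class = unname(map),
                          stringsAsFactors = FALSE),
    links = data.frame(gene = tab$gene, disease = tab$disease,
                       stringsAsFactors = FALSE)
  ), class = "diseasome")
}

#' @export
print.diseasome <- function(x, ...) {
  cat(sprintf("diseasome: %d genes, %d diseases/phenotypes, %d links\n",
              length(x$genes), nrow(x$diseases), nrow(x$links)))
  tb <- table(x$diseases$phenotype_class)
  cat("  disease classes:",
      paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' Convert a diseasome to a bipartite igraph graph
#' @param diseasome A `diseasome`.
#' @return Bipartite `igraph` graph (`type` FALSE for genes, TRUE diseases).
#' @export
diseasome_igraph <- function(diseasome) {
  verts <- data.frame(
    name = c(diseasome$genes, diseasome$diseases$disease),
    type = c(rep(FALSE, length(diseasome$genes)),
             rep(TRUE, nrow(diseasome$diseases))),
    phenotype_class = c(rep("GENE", length(diseasome$genes)),
                        diseasome$diseases$phenotype_class),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(diseasome$links, directed = FALSE,
                                vertices = verts)
}

#' Exclusive gene-overlap counts for an upset plot
#'
#' For every gene linked to at least one disease in `disease_subset`, its
#' pattern is the exact subset of those diseases it links to; patterns are
#' exclusive, so their counts partition the covered genes.
#'
#' @param diseasome A `diseasome`.
#' @param disease_subset Character vector of disease names to intersect.
#' @return Data frame with columns `pattern` (disease names joined by `&`,
#'   in `disease_subset` order), `degree` (pattern size), `gene_count`.
#' @export
upset_counts <- function(diseasome, disease_subset) {
  missing <- setdiff(disease_subset, diseasome$diseases$disease)
  if (length(missing)) {
    pn_stop(sprintf("unknown disease name(s): %s",
                    paste(missing, collapse = "; ")),
            "pigmentnet_lookup_error")
  }
  links <- diseasome$links[diseasome$links$disease %in% disease_subset, ,
                           drop = FALSE]
  if (!nrow(links)) {
    return(data.frame(pattern = character(), degree = integer(),
                      gene_count = integer(), stringsAsFactors = FALSE))
  }
  pat <- tapply(links$disease, links$gene, function(d) {
    paste(disease_subset[disease_subset %in% d], collapse = " & ")
  })
  tb <- table(unlist(pat))
  out <- data.frame(pattern = names(tb),
                    degree = lengths(strsplit(names(tb), " & ", fixed = TRUE)),
                    gene_count = as.integer(tb),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$gene_count, out$degree, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}
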