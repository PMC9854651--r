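# functional class profiling and hypergeometric over-representation analysis

#' Profile a gene list against the functional class annotation
#'
#' Counts (and percentages of the list) per functional class at the chosen
#' nesting level. Genes absent from the annotation fall into the `"Unknown"`
#' class, which is part of the level-3 vocabulary.
#'
#' @param genes Character vector of gene symbols.
#' @param annotation A `functional_annotation`.
#' @param level Annotation level: 1 (finest), 2, or 3 (coarsest, 15 classes).
#' @return Data frame `class`, `count`, `percent`; counts sum to
#'   `length(unique(genes))` and percentages to 100 (up to rounding).
#' @export
class_profile <- function(genes, annotation, level = 3) {
  if (!level %in% 1:3) {
    pn_stop("level must be 1, 2 or 3", "pigmentnet_config_error")
  }
  genes <- unique(canonical_symbol(genes))
  col <- paste0("class_l", level)
  if (!length(genes)) {
    return(data.frame(class = character(), count = integer(),
                      percent = numeric(), stringsAsFactors = FALSE))
  }
  hit <- match(genes, annotation$gene)
  cls <- annotation[[col]][hit]
  cls[is.na(cls)] <- "Unknown"
  tb <- table(cls)
  out <- data.frame(class = names(tb), count = as.integer(tb),
                    stringsAsFactors = FALSE)
  out$percent <- 100 * out$count / length(genes)
  out <- out[order(-out$count, out$class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation analysis
#'
#' For each term, tests whether the query gene set overlaps the term's gene
#' set more than expected when drawing `|query|` genes uniformly from the
#' universe: the upper-tail hypergeometric probability P(X >= k). P-values
#' are Benjamini-Hochberg adjusted across all tested terms.
#'
#' @param query Character vector of query genes (must lie in the universe).
#' @param terms Named list of term gene sets (e.g. from [read_gmt()]).
#' @param universe Background gene set; term sets are intersected with it.
#' @param alpha Adjusted-p significance level (default 0.05).
#' @return Data frame sorted by adjusted p: `term`, `overlap` (k),
#'   `query_size` (n), `term_size` (K), `universe_size` (N), `p_value`,
#'   `adjusted_p`, `significant`.
#' @export
hypergeometric_ora <- function(query, terms, universe, alpha = 0.05) {
  universe <- unique(canonical_symbol(universe))
  query <- unique(canonical_symbol(query))
  if (!length(query)) {
    warning("empty query: returning no results", call. = FALSE)
    return(data.frame(term = character(), overlap = integer(),
                      query_size = integer(), term_size = integer(),
                      universe_size = integer(), p_value = numeric(),
                      adjusted_p = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  outside <- setdiff(query, universe)
  if (length(outside)) {
    pn_stop(sprintf("query genes outside the universe: %s",
                    paste(utils::head(outside, 10), collapse = ", ")),
            "pigmentnet_validation_error")
  }
  term_sets <- lapply(terms, function(g) intersect(canonical_symbol(g), universe))
  keep <- lengths(term_sets) > 0
  term_sets <- term_sets[keep]

  N <- length(universe)
  n <- length(query)
  k <- vapply(term_sets, function(g) length(intersect(query, g)), 0L)
  K <- lengths(term_sets)
  # upper tail P(X >= k) for X ~ Hypergeometric(N, K, n)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  adj <- benjamini_hochberg(unname(p))
  out <- data.frame(term = names(term_sets), overlap = unname(k),
                    query_size = n, term_size = unname(K), universe_size = N,
                    p_value = unname(p), adjusted_p = adj,
                    significant = adj <= alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$adjusted_p, out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment controlling the false discovery rate; output is aligned
#' to the input order and capped at 1. Delegates to
#' `stats::p.adjust(method = "BH")` after validating the inputs.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) && (any(is.na(p)) || any(p < 0) || any(p > 1))) {
    pn_stop("p-values must lie in [0, 1]", "pigmentnet_validation_error")
  }
  p.adjust(p, method = "BH")
}
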