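# functional annotation (three-level class scheme) and GMT term sets

#' The fixed level-3 functional class vocabulary
#'
#' The coarsest level of the three-level functional annotation scheme used
#' for class profiling assigns every protein-coding gene to exactly one of 15
#' broad groups (the finer levels use 58 groups and 321 classes).
#'
#' @return Character vector of the 15 level-3 class names.
#' @export
functional_level3_classes <- function() {
  c("Signaling",
    "Metabolism",
    "Protein translation, folding, modification and degradation",
    "Transcription",
    "Unknown",
    "Cytoskeleton",
    "Organelles",
    "Other",
    "Immune system and Inflammation",
    "Chromatin organization and DNA repair",
    "Neuronal System, synapses, channels",
    "ECM organization",
    "Cell junction and adhesion",
    "Developmental",
    "DNA Replication")
}

#' Read a gene-to-functional-class annotation table
#'
#' Expects one row per gene with its class at each of the three nesting
#' levels (finest `class_l1`, intermediate `class_l2`, coarsest `class_l3`,
#' whose vocabulary is [functional_level3_classes()]).
#'
#' @param path TSV with columns `gene`, `class_l1`, `class_l2`, `class_l3`.
#' @return A `functional_annotation` data frame (one row per gene).
#' @export
read_functional_annotation <- function(path) {
  df <- read_tsv(path)
  require_columns(df, c("gene", "class_l1", "class_l2", "class_l3"), path)
  df$gene <- canonical_symbol(df$gene)
  if (anyDuplicated(df$gene)) {
    pn_stop(sprintf("%s: duplicate gene annotations", path),
            "pigmentnet_format_error")
  }
  bad <- setdiff(unique(df$class_l3), functional_level3_classes())
  if (length(bad)) {
    pn_stop(sprintf("%s: unknown level-3 class(es): %s", path,
                    paste(bad, collapse = "; ")),
            "pigmentnet_format_error")
  }
  class(df) <- c("functional_annotation", "data.frame")
  df
}

#' Write a functional annotation table to TSV
#' @param annotation A `functional_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_functional_annotation <- function(annotation, path) {
  write_tsv(as.data.frame(annotation), path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one term per line, `term_id<TAB>description<TAB>gene1<TAB>...`.
#'
#' @param path GMT file.
#' @return Named list of character gene vectors; the `description` attribute
#'   holds term descriptions in the same order.
#' @export
read_gmt <- function(path) {
  stopifnot_file(path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 1L) < 3
  if (any(short)) {
    pn_stop(sprintf("%s: GMT line %d has fewer than 3 fields", path,
                    which(short)[1]),
            "pigmentnet_format_error")
  }
  sets <- lapply(parts, function(p) unique(canonical_symbol(p[3:length(p)])))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "description") <- vapply(parts, `[[`, "", 2L)
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of gene vectors.
#' @param path Output path.
#' @param description Optional descriptions (recycled `"NA"` if missing).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) {
    description <- attr(sets, "description") %||% rep("na", length(sets))
  }
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  con <- file(path, open = "wt", encoding = "UTF-8")
  writeLines(lines, con)
  close(con)
  invisible(path)
}
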