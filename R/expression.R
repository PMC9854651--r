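# LFQ detection, coverage, fold changes, and network overlay

#' Detected protein sets per cell line
#'
#' A protein counts as detected in a cell line when it was quantified
#' (intensity > 0) in at least `min_replicates` of that line's replicates;
#' the default, 2 of 3 triplicates, is the usual majority rule and is
#' configurable.
#'
#' @param table An `expression_table`.
#' @param min_replicates Minimum quantified replicates (default 2).
#' @return Named list (per cell line) of detected protein symbol vectors.
#' @export
detect <- function(table, min_replicates = 2) {
  tab <- as.data.frame(table)
  if (!nrow(tab)) {
    pn_stop("expression table is empty", "pigmentnet_config_error")
  }
  out <- lapply(split(tab, tab$cell_line), function(d) {
    n_rep <- max(tapply(d$replicate, d$protein, function(r) length(unique(r))))
    if (min_replicates > n_rep) {
      pn_stop(sprintf(
        "min_replicates (%d) exceeds the %d replicate(s) available",
        min_replicates, n_rep), "pigmentnet_config_error")
    }
    hits <- tapply(d$intensity > 0, d$protein, sum)
    sort(names(hits)[hits >= min_replicates])
  })
  out
}

#' Detection coverage of a reference protein list
#'
#' @param detected Character vector of detected proteins.
#' @param reference Reference gene/protein list.
#' @return Integer percent (half-up): 100 * |detected n reference| /
#'   |reference|.
#' @export
coverage <- function(detected, reference) {
  reference <- unique(canonical_symbol(reference))
  if (!length(reference)) {
    pn_stop("reference list must be non-empty", "pigmentnet_config_error")
  }
  detected <- unique(canonical_symbol(detected))
  as.integer(round_half_up(
    100 * length(intersect(detected, reference)) / length(reference)))
}

#' Fold changes between two cell lines
#'
#' Per-line mean LFQ intensity is the mean over quantified (non-zero)
#' replicates. For proteins detected in both lines, `fold_change` is the
#' larger mean over the smaller (so always >= 1) and `direction` names the
#' higher line; a protein is `differential` when the fold change strictly
#' exceeds the threshold. Proteins detected in only one line are flagged
#' `exclusive` and excluded from ratio calls.
#'
#' @param table An `expression_table` containing both lines.
#' @param line_a,line_b Cell-line identifiers.
#' @param threshold Fold-change call threshold (strict >; default 2).
#' @param min_replicates Detection rule passed to [detect()].
#' @return Data frame of overlay attributes: `protein`, `mean_a`, `mean_b`,
#'   `log10_a`, `log10_b`, `detected_a`, `detected_b`, `exclusive`,
#'   `fold_change`, `direction`, `differential`.
#' @export
fold_changes <- function(table, line_a, line_b, threshold = 2,
                         min_replicates = 2) {
  tab <- as.data.frame(table)
  for (ln in c(line_a, line_b)) {
    if (!ln %in% tab$cell_line) {
      pn_stop(sprintf("cell line '%s' absent from expression table", ln),
              "pigmentnet_config_error")
    }
  }
  det <- detect(table, min_replicates = min_replicates)
  da <- det[[line_a]]
  db <- det[[line_b]]

  mean_quantified <- function(line) {
    d <- tab[tab$cell_line == line & tab$intensity > 0, , drop = FALSE]
    tapply(d$intensity, d$protein, mean)
  }
  ma <- mean_quantified(line_a)
  mb <- mean_quantified(line_b)

  proteins <- sort(unique(tab$protein))
  out <- data.frame(protein = proteins, stringsAsFactors = FALSE)
  out$mean_a <- unname(ma[proteins])
  out$mean_b <- unname(mb[proteins])
  out$log10_a <- ifelse(is.na(out$mean_a), NA_real_, log10(out$mean_a))
  out$log10_b <- ifelse(is.na(out$mean_b), NA_real_, log10(out$mean_b))
  out$detected_a <- proteins %in% da
  out$detected_b <- proteins %in% db
  out$exclusive <- xor(out$detected_a, out$detected_b)
  both <- out$detected_a & out$detected_b
  fc <- rep(NA_real_, length(proteins))
  dir <- rep(NA_character_, length(proteins))
  hi <- pmax(out$mean_a, out$mean_b)
  lo <- pmin(out$mean_a, out$mean_b)
  fc[both] <- hi[both] / lo[both]
  dir[both] <- ifelse(out$mean_a[both] >= out$mean_b[both], line_a, line_b)
  out$fold_change <- fc
  out$direction <- dir
  out$differential <- both & !is.na(fc) & fc > threshold
  attr(out, "lines") <- c(a = line_a, b = line_b)
  out
}

#' Attach LFQ overlay attributes to a network
#'
#' Adds per-node mean and log-transformed LFQ intensities and detection
#' flags as node attributes; proteins absent from the expression table keep
#' missing values (never -Inf) and stay in the network.
#'
#' @param network A `ppi_network`.
#' @param attrs Overlay attributes from [fold_changes()].
#' @param transform Log base for reporting (default 10).
#' @return List with `network` (unchanged topology) and `node_attrs`, a data
#'   frame ready for [write_network()]'s `extra_node_attrs`.
#' @export
attach_to_network <- function(network, attrs, transform = 10) {
  lines <- attr(attrs, "lines") %||% c(a = "a", b = "b")
  logb <- function(x) ifelse(is.na(x) | x <= 0, NA_real_, log(x, base = transform))
  na <- data.frame(symbol = attrs$protein, stringsAsFactors = FALSE)
  na[[paste0("lfq_", lines[["a"]])]] <- attrs$mean_a
  na[[paste0("lfq_", lines[["b"]])]] <- attrs$mean_b
  na[[paste0("log_lfq_", lines[["a"]])]] <- logb(attrs$mean_a)
  na[[paste0("log_lfq_", lines[["b"]])]] <- logb(attrs$mean_b)
  na[[paste0("detected_", lines[["a"]])]] <- attrs$detected_a
  na[[paste0("detected_", lines[["b"]])]] <- attrs$detected_b
  na$fold_change <- attrs$fold_change
  na$differential <- attrs$differential
  na <- na[na$symbol %in% network$nodes$symbol, , drop = FALSE]
  rownames(na) <- NULL
  list(network = network, node_attrs = na)
}
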