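#' Analysis configuration
#'
#' Bundles the thresholds shared across the pipeline: the minimum STRING-style
#' combined confidence score for an interaction to count as high confidence,
#' the MCL inflation parameter controlling cluster granularity, the FDR level
#' for over-representation calls, the fold-change cut-off for differential
#' protein expression, the realized-edge target for network expansion, and the
#' random seed.
#'
#' @param score_threshold Minimum interaction confidence in \[0, 1\];
#'   interactions with score >= the threshold are kept (inclusive). Default
#'   0.700, the conventional "high confidence" STRING cut-off.
#' @param mcl_inflation MCL inflation exponent, must be > 1; larger values
#'   give more, smaller clusters. Default 2.5.
#' @param fdr_alpha Benjamini-Hochberg adjusted-p significance level.
#'   Default 0.05.
#' @param fold_change_threshold Ratio of cell-line mean LFQ intensities above
#'   which (strictly) a protein is called differentially expressed. Default 2.
#' @param expansion_edge_target Expansion stops at the first state whose edge
#'   count exceeds this. Default 2000.
#' @param rng_seed Integer seed for all stochastic steps.
#' @return A `pigmentnet_config` list.
#' @export
pigmentnet_config <- function(score_threshold = 0.700,
                              mcl_inflation = 2.5,
                              fdr_alpha = 0.05,
                              fold_change_threshold = 2.0,
                              expansion_edge_target = 2000,
                              rng_seed = 1L) {
  cfg <- list(
    score_threshold = as.numeric(score_threshold),
    mcl_inflation = as.numeric(mcl_inflation),
    fdr_alpha = as.numeric(fdr_alpha),
    fold_change_threshold = as.numeric(fold_change_threshold),
    expansion_edge_target = as.numeric(expansion_edge_target),
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "pigmentnet_config")
}

validate_config <- function(cfg) {
  num <- c("score_threshold", "mcl_inflation", "fdr_alpha",
           "fold_change_threshold")
  for (f in num) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      pn_stop(sprintf("config field '%s' must be a single positive number", f),
              "pigmentnet_config_error")
    }
  }
  if (cfg$score_threshold > 1) {
    pn_stop("score_threshold must lie in (0, 1]", "pigmentnet_config_error")
  }
  if (cfg$mcl_inflation <= 1) {
    pn_stop("mcl_inflation must be > 1", "pigmentnet_config_error")
  }
  if (cfg$expansion_edge_target < 0) {
    pn_stop("expansion_edge_target must be non-negative",
            "pigmentnet_config_error")
  }
  invisible(cfg)
}

#' Read a YAML configuration file
#'
#' Keys mirror the arguments of [pigmentnet_config()]; absent keys fall back
#' to the defaults, and `overrides` (e.g. from a caller) win over the file.
#'
#' @param path YAML file path.
#' @param overrides Named list overriding file values.
#' @return A `pigmentnet_config`.
#' @export
read_config <- function(path, overrides = list()) {
  stopifnot_file(path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pigmentnet_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    pn_stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
            "pigmentnet_config_error")
  }
  vals[names(overrides)] <- overrides
  do.call(pigmentnet_config, vals)
}

#' @export
print.pigmentnet_config <- function(x, ...) {
  cat("pigmentnet configuration\n")
  for (f in names(x)) cat(sprintf("  %-22s %s\n", f, format(x[[f]])))
  invisible(x)
}
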