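.MARKER_GENES <- c(XIST = "female_high", KDM5D = "male_high",
                   RPS4Y1 = "male_high")

#' Construct a sex-marker probeset panel
#'
#' A panel maps probesets to the three sex-specific marker genes and their
#' expected direction: XIST is expressed from the inactive X chromosome and
#' is female-specific (\code{female_high}); KDM5D and RPS4Y1 are
#' Y-chromosome genes and male-specific (\code{male_high}).
#'
#' @param probe_id Character vector of probeset identifiers.
#' @param gene Character vector (same length) with values in
#'   \code{XIST}, \code{KDM5D}, \code{RPS4Y1}.
#' @param platform Free-text platform label (e.g. \code{"GPL570"}).
#' @return A \code{marker_panel}: a data.frame with columns
#'   \code{probe_id}, \code{gene}, \code{direction} and a \code{platform}
#'   attribute.
#' @export
marker_panel <- function(probe_id, gene, platform = "custom") {
  probe_id <- as.character(probe_id)
  gene <- as.character(gene)
  stopifnot(length(probe_id) == length(gene))
  bad <- setdiff(unique(gene), names(.MARKER_GENES))
  if (length(bad)) {
    stop("unknown marker gene(s): ", paste(bad, collapse = ", "),
         " (panel genes are XIST, KDM5D, RPS4Y1)")
  }
  dup <- unique(probe_id[duplicated(probe_id)])
  if (length(dup)) {
    stop("duplicate probe_id(s) in panel: ", paste(dup, collapse = ", "))
  }
  panel <- data.frame(probe_id = probe_id, gene = gene,
                      direction = unname(.MARKER_GENES[gene]),
                      stringsAsFactors = FALSE)
  validate_panel(panel)
  structure(panel, platform = platform,
            class = c("marker_panel", "data.frame"))
}

validate_panel <- function(panel) {
  if (!any(panel$direction == "female_high") ||
      !any(panel$direction == "male_high")) {
    stop("invalid panel: need at least one female_high (XIST) and one ",
         "male_high (KDM5D/RPS4Y1) probeset")
  }
  invisible(panel)
}

#' Load a marker panel for a platform from a config file
#'
#' The config is a TSV with columns \code{platform}, \code{gene},
#' \code{probe_id}, one row per probeset. The package ships defaults for
#' the Affymetrix HG-U133A (GPL96) and HG-U133 Plus 2.0 (GPL570) platforms,
#' taken from the platform annotation: on GPL96 XIST has two probesets and
#' on GPL570 seven, while KDM5D and RPS4Y1 each have a single probeset on
#' both.
#'
#' @param platform Platform label to select (e.g. \code{"GPL96"}).
#' @param config Optional path to a panel config TSV; defaults to the
#'   shipped file.
#' @return A \code{\link{marker_panel}}.
#' @export
load_panel <- function(platform, config = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "marker_panels.tsv",
                          package = "sexcheck", mustWork = TRUE)
  }
  df <- utils::read.delim(config, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("platform", "gene", "probe_id") %in% names(df))) {
    stop("panel config must have columns platform, gene, probe_id")
  }
  df <- df[df$platform == platform, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop("unknown platform '", platform, "' (not in panel config)")
  }
  missing_genes <- setdiff(names(.MARKER_GENES), unique(df$gene))
  if (length(missing_genes)) {
    stop("platform '", platform, "' has no probesets for gene(s): ",
         paste(missing_genes, collapse = ", "))
  }
  marker_panel(df$probe_id, df$gene, platform = platform)
}

#' Correlation-based quality filter for panel probesets
#'
#' A well-behaved marker probeset tracks its gene: across samples of a
#' mixed-sex dataset it is strongly positively correlated with probesets of
#' the same direction and negatively correlated with probesets of the
#' opposite direction. A probeset failing either expectation (a
#' hybridization-poor probeset, like XIST's 221728_x_at on these Affymetrix
#' platforms) would dilute the cluster separation, so it is excluded before
#' inference.
#'
#' All pairwise Pearson correlations are computed on the full panel once and
#' exclusions applied simultaneously (no iterative re-filtering). A probe is
#' excluded if its mean correlation with same-direction probes is below
#' \code{min_r}, or its mean correlation with opposite-direction probes is
#' above 0. A probe with no same-direction partner is judged only on the
#' opposite-direction criterion.
#'
#' @param m Normalized expression matrix (probes x samples) containing all
#'   panel probes; at least 3 samples.
#' @param panel A \code{\link{marker_panel}}.
#' @param min_r Minimum mean within-direction correlation (default 0.3).
#' @return A list with \code{panel} (the retained entries) and
#'   \code{exclusions}, a data.frame with one row per input probe:
#'   \code{probe_id}, \code{gene}, \code{direction}, \code{mean_r_same},
#'   \code{mean_r_opposite}, \code{excluded}.
#' @export
filter_probesets <- function(m, panel, min_r = 0.3) {
  stopifnot(inherits(panel, "marker_panel"))
  missing <- setdiff(panel$probe_id, rownames(m))
  if (length(missing)) {
    stop("panel probe(s) missing from matrix: ",
         paste(missing, collapse = ", "))
  }
  if (ncol(m) < 3L) {
    stop("probeset filtering needs at least 3 samples")
  }
  x <- t(m[panel$probe_id, , drop = FALSE])   # samples x probes
  cc <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  same <- outer(panel$direction, panel$direction, "==")
  diag(same) <- NA  # self-correlation never counts
  mean_r_same <- vapply(seq_len(nrow(cc)), function(i) {
    mean(cc[i, which(same[i, ])], na.rm = TRUE)
  }, 0)
  mean_r_opp <- vapply(seq_len(nrow(cc)), function(i) {
    mean(cc[i, which(!same[i, ])], na.rm = TRUE)
  }, 0)
  excluded <- (!is.nan(mean_r_same) & mean_r_same < min_r) |
    (!is.nan(mean_r_opp) & mean_r_opp > 0)
  excluded[is.na(excluded)] <- FALSE
  report <- data.frame(probe_id = panel$probe_id, gene = panel$gene,
                       direction = panel$direction,
                       mean_r_same = mean_r_same,
                       mean_r_opposite = mean_r_opp,
                       excluded = excluded,
                       stringsAsFactors = FALSE)
  kept <- panel[!excluded, , drop = FALSE]
  if (!any(kept$direction == "female_high") ||
      !any(kept$direction == "male_high")) {
    stop("panel invalid after filtering: all probesets of one direction ",
         "were excluded")
  }
  list(
    panel = structure(kept, platform = attr(panel, "platform"),
                      class = c("marker_panel", "data.frame")),
    exclusions = report
  )
}
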