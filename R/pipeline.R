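#' Audit one dataset for sex misannotation
#'
#' The full per-dataset pipeline: normalize the matrix
#' (\code{\link{log2_quantile_normalize}}), quality-filter the marker panel
#' (\code{\link{filter_probesets}}), infer gene-based sex
#' (\code{\link{infer_sex}}) and compare against the annotations
#' (\code{\link{compare_annotations}}).
#'
#' Datasets whose annotations contain only one sex are skipped with a
#' warning (returning \code{NULL}): two-cluster sex inference is
#' uninformative there, and any expression cluster structure would reflect
#' something other than sex.
#'
#' @param expr Probe-by-sample expression matrix.
#' @param metadata Sample metadata (\code{sample_id}, \code{annotated_sex},
#'   optional \code{subject_id}).
#' @param panel A \code{\link{marker_panel}}.
#' @param dataset_id Identifier for the report.
#' @param normalize Apply log2/quantile normalization first (default TRUE).
#' @param filter Apply the correlation-based probeset filter (default TRUE;
#'   skipped automatically below 3 samples, where correlations are
#'   meaningless).
#' @param min_r Probeset filter threshold (see \code{\link{filter_probesets}}).
#' @param restarts,seed Passed to \code{\link{cluster_samples}}.
#' @return A \code{dataset_report}, or \code{NULL} for a skipped
#'   single-sex dataset. The probeset exclusion table is attached as
#'   attribute \code{"probeset_exclusions"}.
#' @export
audit_dataset <- function(expr, metadata, panel, dataset_id = "dataset",
                          normalize = TRUE, filter = TRUE, min_r = 0.3,
                          restarts = 25, seed = 0) {
  sexes <- unique(metadata$annotated_sex[metadata$annotated_sex != "unknown"])
  if (length(sexes) < 2L) {
    warning("dataset '", dataset_id, "' has single-sex annotations (",
            paste(sexes, collapse = ""), "); skipping sex inference")
    return(NULL)
  }
  if (normalize) expr <- log2_quantile_normalize(expr)
  exclusions <- NULL
  if (filter && ncol(expr) >= 3L) {
    flt <- filter_probesets(expr, panel, min_r = min_r)
    panel <- flt$panel
    exclusions <- flt$exclusions
  }
  calls <- infer_sex(expr, panel, restarts = restarts, seed = seed)
  report <- compare_annotations(calls, metadata, dataset_id = dataset_id)
  attr(report, "probeset_exclusions") <- exclusions
  report
}

#' Audit a corpus of datasets and bound the misannotation prevalence
#'
#' Runs \code{\link{audit_dataset}} over every dataset, aggregates with
#' \code{\link{summarize_corpus}}, and bounds the population fraction of
#' affected studies (those with at least one mismatched sample) with
#' one-sided binomial bounds at the 0.95 and 0.99 levels
#' (\code{\link{prevalence_estimate}}).
#'
#' @param datasets List of dataset objects, each a list with \code{expr},
#'   \code{metadata}, \code{panel} and optionally \code{dataset_id} — the
#'   shape produced by \code{\link{generate_dataset}} /
#'   \code{\link{generate_corpus}}.
#' @param strata Optional named vector dataset_id -> stratum label.
#' @param seed Base seed; dataset i is clustered with seed + i.
#' @param ... Further arguments to \code{\link{audit_dataset}}.
#' @return List with \code{reports}, \code{summary} (a
#'   \code{corpus_summary}), \code{n_affected} (datasets with >= 1
#'   mismatch), and \code{prevalence} (list of
#'   \code{prevalence_estimate} at levels 0.95 and 0.99).
#' @export
audit_corpus <- function(datasets, strata = NULL, seed = 0, ...) {
  reports <- vector("list", length(datasets))
  kept <- logical(length(datasets))
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    id <- if (!is.null(d$dataset_id)) d$dataset_id else sprintf("DS%03d", i)
    rep_i <- audit_dataset(d$expr, d$metadata, d$panel, dataset_id = id,
                           seed = seed + i, ...)
    if (!is.null(rep_i)) {
      reports[[i]] <- rep_i
      kept[i] <- TRUE
    }
  }
  reports <- reports[kept]
  summary <- summarize_corpus(reports, strata = strata)
  n_affected <- sum(vapply(reports,
                           function(r) r$counts[["n_mismatch"]] > 0L,
                           NA))
  list(reports = reports,
       summary = summary,
       n_affected = n_affected,
       prevalence = list(
         level_0.95 = prevalence_estimate(n_affected, length(reports), 0.95),
         level_0.99 = prevalence_estimate(n_affected, length(reports), 0.99)))
}
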