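#' Compare gene-based sex calls with sample annotations
#'
#' Per-sample status: \code{unclassified} when the final call is ambiguous
#' or the annotation is unknown (a mismatch claim requires both a definite
#' call and a definite annotation); otherwise \code{mismatch} when the call
#' contradicts the annotation, else \code{match}. A dataset is
#' \code{correctly_annotated} only when it has zero mismatched and zero
#' unclassified samples; otherwise it is \code{affected}.
#'
#' Ambiguous samples whose cluster assignment nonetheless contradicts the
#' annotation are not counted as mismatches, but their count is surfaced
#' separately (\code{n_ambiguous_cluster_discrepant}): they are suggestive
#' of a problem without supporting a confident claim.
#'
#' @param calls Data.frame of sex calls from \code{\link{infer_sex}}.
#' @param metadata Data.frame with \code{sample_id}, \code{annotated_sex}
#'   (see \code{\link{read_metadata}}).
#' @param dataset_id Identifier recorded in the report.
#' @return A \code{dataset_report}: list with \code{dataset_id},
#'   \code{samples} (per-sample table with \code{status}), \code{counts},
#'   \code{dataset_status}, \code{mismatched_ids}, \code{unclassified_ids},
#'   \code{n_ambiguous_cluster_discrepant}.
#' @export
compare_annotations <- function(calls, metadata, dataset_id = "dataset") {
  missing <- setdiff(calls$sample_id, metadata$sample_id)
  if (length(missing)) {
    stop("sex call(s) without metadata: ", paste(missing, collapse = ", "))
  }
  idx <- match(calls$sample_id, metadata$sample_id)
  annotated <- metadata$annotated_sex[idx]
  status <- ifelse(calls$final_call == "ambiguous" | annotated == "unknown",
                   "unclassified",
                   ifelse(calls$final_call == annotated, "match", "mismatch"))
  samples <- data.frame(sample_id = calls$sample_id,
                        annotated_sex = annotated,
                        cluster_sex = calls$cluster_sex,
                        D = calls$D,
                        final_call = calls$final_call,
                        status = status,
                        stringsAsFactors = FALSE)
  if ("subject_id" %in% names(metadata)) {
    samples$subject_id <- metadata$subject_id[idx]
  }
  n_mismatch <- sum(status == "mismatch")
  n_unclassified <- sum(status == "unclassified")
  ambiguous_discrepant <- calls$final_call == "ambiguous" &
    !is.na(calls$cluster_sex) & annotated %in% c("female", "male") &
    calls$cluster_sex != annotated
  structure(list(
    dataset_id = dataset_id,
    samples = samples,
    counts = c(n_samples = nrow(samples),
               n_mismatch = n_mismatch,
               n_unclassified = n_unclassified),
    dataset_status = if (n_mismatch == 0L && n_unclassified == 0L)
      "correctly_annotated" else "affected",
    mismatched_ids = samples$sample_id[status == "mismatch"],
    unclassified_ids = samples$sample_id[status == "unclassified"],
    n_ambiguous_cluster_discrepant = sum(ambiguous_discrepant)
  ), class = "dataset_report")
}

#' @export
print.dataset_report <- function(x, ...) {
  cat("Dataset ", x$dataset_id, ": ", x$dataset_status, "\n",
      "  samples: ", x$counts[["n_samples"]],
      ", mismatched: ", x$counts[["n_mismatch"]],
      ", unclassified: ", x$counts[["n_unclassified"]], "\n", sep = "")
  invisible(x)
}

# Percentage/count arithmetic shared by the report- and count-based paths.
# Dataset-level fractions are conventionally printed as whole percent;
# sample-level fractions keep decimals. Both exact and rounded values are
# stored so the caller picks the precision.
corpus_stratum_summary <- function(n_datasets, n_with_mismatch,
                                   n_with_unclassified, n_both,
                                   n_samples, n_sample_mismatch,
                                   n_sample_unclassified) {
  n_correct <- n_datasets - (n_with_mismatch + n_with_unclassified - n_both)
  n_sample_match <- n_samples - n_sample_mismatch - n_sample_unclassified
  pct <- function(k, n) if (n > 0) 100 * k / n else NA_real_
  list(
    datasets = c(total = n_datasets,
                 correctly_annotated = n_correct,
                 with_mismatch = n_with_mismatch,
                 with_unclassified = n_with_unclassified,
                 both = n_both),
    samples = c(total = n_samples,
                match = n_sample_match,
                mismatch = n_sample_mismatch,
                unclassified = n_sample_unclassified),
    pct_datasets = c(correctly_annotated = pct(n_correct, n_datasets),
                     with_mismatch = pct(n_with_mismatch, n_datasets),
                     with_unclassified = pct(n_with_unclassified, n_datasets)),
    pct_samples = c(match = pct(n_sample_match, n_samples),
                    mismatch = pct(n_sample_mismatch, n_samples),
                    unclassified = pct(n_sample_unclassified, n_samples))
  )
}

#' Corpus-level summary from printed counts
#'
#' Computes the corpus accounting directly from counts — useful when only a
#' published summary table is available, and the backbone of
#' \code{\link{summarize_corpus}}. The number of correctly annotated
#' datasets follows by inclusion-exclusion:
#' \code{total - (with_mismatch + with_unclassified - both)}.
#'
#' @param n_datasets,n_with_mismatch,n_with_unclassified,n_both Dataset
#'   counts: total; with >= 1 mismatched sample; with >= 1 unclassified
#'   sample; with both.
#' @param n_samples,n_sample_mismatch,n_sample_unclassified Sample counts.
#' @return List with \code{datasets} and \code{samples} count vectors and
#'   exact percentage vectors \code{pct_datasets}, \code{pct_samples}.
#' @export
corpus_summary_from_counts <- function(n_datasets, n_with_mismatch,
                                       n_with_unclassified, n_both,
                                       n_samples, n_sample_mismatch,
                                       n_sample_unclassified) {
  stopifnot(n_both <= min(n_with_mismatch, n_with_unclassified),
            n_with_mismatch <= n_datasets,
            n_with_unclassified <= n_datasets,
            n_sample_mismatch + n_sample_unclassified <= n_samples)
  corpus_stratum_summary(n_datasets, n_with_mismatch, n_with_unclassified,
                         n_both, n_samples, n_sample_mismatch,
                         n_sample_unclassified)
}

#' Summarize a corpus of dataset reports
#'
#' Aggregates per-dataset reports into dataset- and sample-level counts and
#' percentages, overall and per stratum (e.g. cancer vs non-cancer, a
#' distinction supplied by the caller, not inferred).
#'
#' @param reports List of \code{dataset_report} objects.
#' @param strata Optional named character vector mapping dataset_id to a
#'   stratum label. Every report's dataset_id must be present when given.
#' @return A \code{corpus_summary}: list of per-stratum summaries (always
#'   including \code{"all"}), each as produced by
#'   \code{\link{corpus_summary_from_counts}}, plus
#'   \code{n_ambiguous_cluster_discrepant} totals.
#' @export
summarize_corpus <- function(reports, strata = NULL) {
  stopifnot(length(reports) >= 1L)
  ids <- vapply(reports, function(r) r$dataset_id, "")
  if (!is.null(strata)) {
    unknown <- setdiff(ids, names(strata))
    if (length(unknown)) {
      stop("dataset(s) without a stratum label: ",
           paste(unknown, collapse = ", "))
    }
  }
  summarize_subset <- function(rs) {
    n_mis <- vapply(rs, function(r) r$counts[["n_mismatch"]], 0L)
    n_unc <- vapply(rs, function(r) r$counts[["n_unclassified"]], 0L)
    s <- corpus_stratum_summary(
      n_datasets = length(rs),
      n_with_mismatch = sum(n_mis > 0L),
      n_with_unclassified = sum(n_unc > 0L),
      n_both = sum(n_mis > 0L & n_unc > 0L),
      n_samples = sum(vapply(rs, function(r) r$counts[["n_samples"]], 0L)),
      n_sample_mismatch = sum(n_mis),
      n_sample_unclassified = sum(n_unc))
    s$n_ambiguous_cluster_discrepant <-
      sum(vapply(rs, function(r) r$n_ambiguous_cluster_discrepant, 0L))
    s
  }
  out <- list(all = summarize_subset(reports))
  if (!is.null(strata)) {
    for (lab in unique(strata[ids])) {
      out[[lab]] <- summarize_subset(reports[strata[ids] == lab])
    }
  }
  structure(out, class = "corpus_summary")
}

#' @export
print.corpus_summary <- function(x, ...) {
  for (lab in names(x)) {
    s <- x[[lab]]
    cat(sprintf(
      "[%s] datasets: %d total, %d correctly annotated (%.0f%%), %d with mismatch (%.0f%%), %d with unclassified (%.0f%%)\n",
      lab, s$datasets[["total"]], s$datasets[["correctly_annotated"]],
      s$pct_datasets[["correctly_annotated"]], s$datasets[["with_mismatch"]],
      s$pct_datasets[["with_mismatch"]], s$datasets[["with_unclassified"]],
      s$pct_datasets[["with_unclassified"]]))
    cat(sprintf(
      "      samples: %d total, %d mismatched (%.2f%%), %d unclassified (%.2f%%)\n",
      s$samples[["total"]], s$samples[["mismatch"]],
      s$pct_samples[["mismatch"]], s$samples[["unclassified"]],
      s$pct_samples[["unclassified"]]))
  }
  invisible(x)
}

#' Cross-study concordance: sample mix-up vs metadata error
#'
#' When several studies assay the same subjects, a wrong recorded sex must
#' reproduce in every study of that subject, while a physical tube swap in
#' one laboratory shows up only there. Per subject: mismatched in every
#' study where present (and present in >= 2) is a
#' \code{consistent_metadata_error}; mismatched in at least one but not all
#' is a \code{study_specific_mixup}; a subject seen in a single study is
#' \code{indeterminate}; a subject never mismatched anywhere is
#' \code{no_discrepancy}.
#'
#' @param reports List of \code{dataset_report} objects whose per-sample
#'   tables carry a \code{subject_id} column (propagated from metadata by
#'   \code{\link{compare_annotations}}).
#' @return Data.frame with one row per subject: \code{subject_id},
#'   \code{n_studies}, \code{n_mismatched}, \code{classification}.
#' @export
cross_study_concordance <- function(reports) {
  tabs <- lapply(reports, function(r) {
    if (!"subject_id" %in% names(r$samples)) {
      stop("report '", r$dataset_id, "' has no subject_id column; ",
           "cross-study concordance needs subject-linked metadata")
    }
    data.frame(subject_id = r$samples$subject_id,
               dataset_id = r$dataset_id,
               mismatch = r$samples$status == "mismatch",
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  tab <- tab[!is.na(tab$subject_id) & nzchar(tab$subject_id), , drop = FALSE]
  if (nrow(tab) == 0L) stop("no subjects present in any study")
  subjects <- unique(tab$subject_id)
  n_studies <- vapply(subjects, function(s) {
    length(unique(tab$dataset_id[tab$subject_id == s]))
  }, 0L)
  n_mism <- vapply(subjects, function(s) {
    sub <- tab[tab$subject_id == s, ]
    length(unique(sub$dataset_id[sub$mismatch]))
  }, 0L)
  classification <- ifelse(
    n_studies < 2L, "indeterminate",
    ifelse(n_mism == 0L, "no_discrepancy",
           ifelse(n_mism == n_studies, "consistent_metadata_error",
                  "study_specific_mixup")))
  data.frame(subject_id = subjects,
             n_studies = n_studies,
             n_mismatched = n_mism,
             classification = classification,
             stringsAsFactors = FALSE, row.names = NULL)
}
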