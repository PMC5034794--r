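mk_calls <- function(...) {
  rows <- list(...)
  data.frame(sample_id = vapply(rows, `[[`, "", 1),
             cluster_sex = vapply(rows, `[[`, "", 2),
             D = as.numeric(vapply(rows, `[[`, "", 3)),
             final_call = vapply(rows, `[[`, "", 4),
             stringsAsFactors = FALSE)
}

test_that("per-sample status follows the definitions", {
  calls <- mk_calls(c("a", "male", "-4", "male"),
                    c("b", "male", "-4", "male"),
                    c("c", "male", "2", "ambiguous"),
                    c("d", "female", "3", "female"))
  md <- data.frame(sample_id = c("a", "b", "c", "d"),
                   annotated_sex = c("female", "male", "male", "unknown"),
                   stringsAsFactors = FALSE)
  rep <- compare_annotations(calls, md, "D1")
  st <- setNames(rep$samples$status, rep$samples$sample_id)
  expect_identical(unname(st[c("a", "b", "c", "d")]),
                   c("mismatch", "match", "unclassified", "unclassified"))
  expect_identical(rep$dataset_status, "affected")
  # ambiguous sample c clusters male vs annotated male: not discrepant;
  # flip its annotation and the sub-count moves
  expect_identical(rep$n_ambiguous_cluster_discrepant, 0L)
  md$annotated_sex[3] <- "female"
  expect_identical(compare_annotations(calls, md)$
                     n_ambiguous_cluster_discrepant, 1L)

  md_clean <- data.frame(sample_id = c("a", "b"),
                         annotated_sex = c("male", "male"))
  expect_identical(compare_annotations(calls[1:2, ], md_clean)$dataset_status,
                   "correctly_annotated")
  expect_error(compare_annotations(calls, md[1:2, ]), "without metadata")
})

test_that("corpus accounting reproduces the published summary-table arithmetic", {
  # 70 datasets / 4160 samples overall; 32 datasets with mismatches, 15
  # with unclassified, 8 with both; 83 mismatched and 34 unclassified
  # samples
  s <- corpus_summary_from_counts(70, 32, 15, 8, 4160, 83, 34)
  expect_equal(s$datasets[["correctly_annotated"]], 31)
  expect_equal(round(s$pct_datasets[["correctly_annotated"]]), 44)
  expect_equal(round(s$pct_datasets[["with_mismatch"]]), 46)
  expect_equal(round(s$pct_datasets[["with_unclassified"]]), 21)
  expect_equal(s$samples[["match"]], 4043)
  expect_equal(round(s$pct_samples[["match"]]), 97)
  expect_equal(round(s$pct_samples[["mismatch"]]), 2)
  expect_equal(round(s$pct_samples[["unclassified"]], 1), 0.8)

  # strata: non-cancer 55 datasets / 2937 samples, cancer 15 / 1223
  nc <- corpus_summary_from_counts(55, 24, 7, 5, 2937, 58, 11)
  expect_equal(nc$datasets[["correctly_annotated"]], 29)
  expect_equal(round(nc$pct_samples[["mismatch"]], 2), 1.97)
  expect_equal(round(nc$pct_samples[["unclassified"]], 1), 0.4)
  ca <- corpus_summary_from_counts(15, 8, 8, 3, 1223, 25, 23)
  expect_equal(ca$datasets[["correctly_annotated"]], 2)
  expect_equal(round(ca$pct_samples[["mismatch"]], 2), 2.04)
  expect_equal(round(ca$pct_samples[["unclassified"]], 1), 1.9)
})

test_that("summarize_corpus matches the counts path and ignores ordering", {
  set.seed(5)
  reports <- lapply(1:12, function(i) {
    status <- sample(c("match", "mismatch", "unclassified"), 20,
                     replace = TRUE, prob = c(0.9, 0.06, 0.04))
    report_from_status(status, dataset_id = sprintf("D%02d", i))
  })
  s1 <- summarize_corpus(reports)
  # inclusion-exclusion identity
  d <- s1$all$datasets
  expect_equal(d[["correctly_annotated"]],
               d[["total"]] - (d[["with_mismatch"]] +
                                 d[["with_unclassified"]] - d[["both"]]))
  s2 <- summarize_corpus(rev(reports))
  expect_equal(s1$all, s2$all)

  strata <- setNames(rep(c("cancer", "non_cancer"), 6),
                     sprintf("D%02d", 1:12))
  s3 <- summarize_corpus(reports, strata)
  expect_equal(s3$cancer$datasets[["total"]], 6)
  expect_equal(s3$cancer$samples[["total"]] + s3$non_cancer$samples[["total"]],
               s3$all$samples[["total"]])
  expect_error(summarize_corpus(reports, strata[-1]), "without a stratum")
})

test_that("a clean single-dataset corpus is 100% correctly annotated", {
  s <- summarize_corpus(list(report_from_status(rep("match", 10))))
  expect_equal(s$all$pct_datasets[["correctly_annotated"]], 100)
})

test_that("cross-study concordance separates mix-ups from metadata errors", {
  mk_rep <- function(id, subjects, mismatched) {
    n <- length(subjects)
    status <- ifelse(subjects %in% mismatched, "mismatch", "match")
    r <- report_from_status(status, dataset_id = id)
    r$samples$subject_id <- subjects
    r
  }
  subj <- sprintf("P%d", 1:6)
  reports <- list(
    mk_rep("ST1", subj, c("P1", "P2")),
    mk_rep("ST2", subj, "P2"),
    mk_rep("ST3", subj, "P2"),
    mk_rep("ST4", subj[1:5], "P2")  # P6 present in ST1-ST3 only
  )
  cc <- cross_study_concordance(reports)
  cls <- setNames(cc$classification, cc$subject_id)
  expect_identical(unname(cls["P1"]), "study_specific_mixup")
  expect_identical(unname(cls["P2"]), "consistent_metadata_error")
  expect_identical(unname(cls["P3"]), "no_discrepancy")

  solo <- mk_rep("ST5", "P9", character(0))
  cc2 <- cross_study_concordance(list(solo))
  expect_identical(cc2$classification, "indeterminate")

  no_subj <- report_from_status(rep("match", 3))
  expect_error(cross_study_concordance(list(no_subj)), "subject_id")
})
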