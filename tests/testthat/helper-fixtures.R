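# Shared fixtures and independent oracles, built in code at test time.

# Write a probe-by-sample table as plain TSV; returns the path.
write_tsv_matrix <- function(m, path = tempfile(fileext = ".tsv")) {
  header <- paste(c("ID_REF", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], trim = TRUE)), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  path
}

# Same table in the GEO series-matrix dialect, with quoted identifiers and
# metadata comment lines, as the repository distributes it.
write_series_matrix <- function(m, path = tempfile(fileext = ".txt")) {
  q <- function(x) paste0('"', x, '"')
  header <- paste(c(q("ID_REF"), q(colnames(m))), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(q(rownames(m)[i]), format(m[i, ], trim = TRUE)), collapse = "\t")
  }, "")
  writeLines(c("!Series_title\t\"synthetic fixture\"",
               "!Sample_geo_accession\t\"GSM1\"\t\"GSM2\"",
               "!series_matrix_table_begin",
               header, rows,
               "!series_matrix_table_end"), path)
  path
}

write_metadata_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A minimal well-separated dataset: 4-probe panel, n_f females then n_m
# males, noiseless unless sd given.
tiny_panel <- function() {
  marker_panel(c("x1", "x2", "k1", "r1"),
               c("XIST", "XIST", "KDM5D", "RPS4Y1"))
}

tiny_matrix <- function(n_f = 3, n_m = 3, on = 10, off = 5, sd = 0,
                        seed = 1) {
  panel <- tiny_panel()
  ids <- c(sprintf("F%d", seq_len(n_f)), sprintf("M%d", seq_len(n_m)))
  mu <- sapply(ids, function(s) {
    female <- startsWith(s, "F")
    ifelse(panel$direction == "female_high",
           ifelse(female, on, off), ifelse(female, off, on))
  })
  rownames(mu) <- panel$probe_id
  if (sd > 0) {
    set.seed(seed)
    mu <- mu + matrix(rnorm(length(mu), 0, sd), nrow(mu))
  }
  mu
}

# Independent oracle for two-cluster k-means: exhaustive search over all
# 2-partitions, minimizing the total within-cluster sum of squares.
best_two_partition <- function(x) {
  n <- nrow(x)
  best <- NULL
  for (code in seq_len(2^(n - 1)) - 1L) {
    grp <- c(0L, as.integer(intToBits(code))[seq_len(n - 1)])
    if (all(grp == 0L)) next
    ss <- 0
    for (g in 0:1) {
      xs <- x[grp == g, , drop = FALSE]
      ctr <- colMeans(xs)
      ss <- ss + sum(sweep(xs, 2, ctr)^2)
    }
    if (is.null(best) || ss < best$ss) best <- list(grp = grp, ss = ss)
  }
  best
}

# Build a dataset_report directly from status labels (report-layer tests
# that don't need the inference machinery).
report_from_status <- function(status, dataset_id = "D",
                               n_amb_discrepant = 0L) {
  n <- length(status)
  structure(list(
    dataset_id = dataset_id,
    samples = data.frame(sample_id = sprintf("s%d", seq_len(n)),
                         annotated_sex = "female", cluster_sex = "female",
                         D = 1, final_call = "female", status = status,
                         stringsAsFactors = FALSE),
    counts = c(n_samples = n,
               n_mismatch = sum(status == "mismatch"),
               n_unclassified = sum(status == "unclassified")),
    dataset_status = if (all(status == "match")) "correctly_annotated"
    else "affected",
    mismatched_ids = sprintf("s%d", which(status == "mismatch")),
    unclassified_ids = sprintf("s%d", which(status == "unclassified")),
    n_ambiguous_cluster_discrepant = n_amb_discrepant
  ), class = "dataset_report")
}
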