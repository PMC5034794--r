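#' Read a probe-by-sample expression matrix
#'
#' Reads a tab-separated expression table with probes in rows and samples in
#' columns. Two dialects are supported: plain TSV (header row of sample
#' identifiers, first column of probe identifiers) and the GEO series-matrix
#' dialect, where the table is bounded by the literal lines
#' \code{!series_matrix_table_begin} and \code{!series_matrix_table_end} and
#' all other lines starting with \code{!} are metadata to be skipped.
#' Identifiers wrapped in double quotes are unquoted.
#'
#' Values are taken as-is: whether they are linear-scale or log2-scale is the
#' business of \code{\link{log2_quantile_normalize}}, not the reader.
#'
#' @param path Path to the file.
#' @param dialect Either \code{"tsv"} or \code{"series_matrix"}.
#' @return A numeric matrix (rows = probes, columns = samples) with probe
#'   identifiers as rownames and sample identifiers as colnames, in file
#'   order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("probe\ts1\ts2", "p1\t1.0\t2.0", "p2\t3.0\t4.0"), tf)
#' m <- read_expression_matrix(tf)
#' dim(m)
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "series_matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("expression matrix file not found: ", path)
  }
  lines <- readLines(path)
  if (dialect == "series_matrix") {
    begin <- which(lines == "!series_matrix_table_begin")
    end <- which(lines == "!series_matrix_table_end")
    if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
      stop("malformed series-matrix file: missing or empty ",
           "!series_matrix_table_begin/!series_matrix_table_end block")
    }
    lines <- lines[(begin + 1L):(end - 1L)]
  } else {
    lines <- lines[!startsWith(lines, "!")]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop("expression table is empty (need a header row and at least one probe row)")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- lengths(fields)
  if (any(width != width[1L])) {
    bad <- which(width != width[1L])[1L]
    stop("ragged expression table: row ", bad, " has ", width[bad],
         " fields, expected ", width[1L])
  }
  unquote <- function(x) gsub('^"|"$', "", x)
  header <- unquote(fields[[1L]])
  sample_ids <- header[-1L]
  if (length(sample_ids) < 1L) stop("expression table has no sample columns")
  body <- fields[-1L]
  probe_ids <- unquote(vapply(body, `[[`, "", 1L))
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup)) {
    stop("duplicate sample id(s) in expression table: ",
         paste(dup, collapse = ", "))
  }
  dup <- unique(probe_ids[duplicated(probe_ids)])
  if (length(dup)) {
    stop("duplicate probe id(s) in expression table: ",
         paste(dup, collapse = ", "))
  }
  values <- matrix(NA_real_, nrow = length(body), ncol = length(sample_ids),
                   dimnames = list(probe_ids, sample_ids))
  for (i in seq_along(body)) {
    row <- unquote(body[[i]][-1L])
    row[row %in% c("", "NA", "null")] <- NA
    values[i, ] <- as.numeric(row)
  }
  values
}

.SEX_SYNONYMS <- stats::setNames(
  c("female", "female", "male", "male", "unknown", "unknown", "unknown"),
  c("f", "female", "m", "male", "", "na", "unknown")
)

#' Normalize a vector of annotated-sex tokens
#'
#' Maps the vocabulary found in sample annotations (F/f/Female/female,
#' M/m/Male/male, blank/NA) onto \code{female}, \code{male}, \code{unknown}.
#' Any other token is a hard error: silently coercing unrecognized labels
#' would hide exactly the annotation defects this package hunts for.
#'
#' @param x Character vector of raw sex tokens.
#' @return Character vector with values in \code{female}, \code{male},
#'   \code{unknown}.
#' @export
normalize_sex <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  key <- tolower(trimws(x))
  key[key == ""] <- "na"  # "" never matches as a vector-lookup name
  out <- .SEX_SYNONYMS[key]
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unrecognized sex token(s): ", paste(shQuote(bad), collapse = ", "),
         " (accepted: F/f/Female/female, M/m/Male/male, blank/NA)")
  }
  unname(out)
}

#' Read a sample metadata table
#'
#' Reads a TSV with at least the columns \code{sample_id} and \code{sex};
#' optional columns \code{subject_id} (used for cross-study linking) and
#' \code{group} are carried through. Sex tokens are normalized with
#' \code{\link{normalize_sex}}.
#'
#' @param path Path to the TSV.
#' @return A data.frame with columns \code{sample_id}, \code{annotated_sex}
#'   and, when present in the input, \code{subject_id} and \code{group}.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("sample_id", "sex") %in% names(df))) {
    stop("metadata must have columns 'sample_id' and 'sex'; found: ",
         paste(names(df), collapse = ", "))
  }
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) {
    stop("duplicate sample_id(s) in metadata: ", paste(dup, collapse = ", "))
  }
  out <- data.frame(sample_id = df$sample_id,
                    annotated_sex = normalize_sex(df$sex),
                    stringsAsFactors = FALSE)
  for (col in c("subject_id", "group")) {
    if (col %in% names(df)) out[[col]] <- df[[col]]
  }
  out
}

#' Write a dataset report to disk
#'
#' Writes the per-sample table (sample_id, annotated_sex, cluster_sex, D,
#' final_call, status) as a TSV at \code{path}, and a machine-readable
#' summary sidecar in DCF (Debian-control / key: value) format at
#' \code{paste0(path, ".summary.dcf")} with keys \code{dataset_id},
#' \code{dataset_status}, \code{n_samples}, \code{n_mismatch},
#' \code{n_unclassified}, \code{n_ambiguous_cluster_discrepant}.
#'
#' @param report A \code{dataset_report}, see \code{\link{compare_annotations}}.
#' @param path Output TSV path.
#' @return Invisibly, the sidecar path.
#' @seealso \code{\link{read_report}} for the round-trip reader.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "dataset_report"))
  utils::write.table(report$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sidecar <- paste0(path, ".summary.dcf")
  summary_rec <- data.frame(
    dataset_id = report$dataset_id,
    dataset_status = report$dataset_status,
    n_samples = report$counts[["n_samples"]],
    n_mismatch = report$counts[["n_mismatch"]],
    n_unclassified = report$counts[["n_unclassified"]],
    n_ambiguous_cluster_discrepant = report$n_ambiguous_cluster_discrepant
  )
  write.dcf(summary_rec, sidecar)
  invisible(sidecar)
}

#' Read back a dataset report written by write_report
#'
#' @param path The TSV path given to \code{\link{write_report}}.
#' @return A \code{dataset_report} equivalent to the one written.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("report file not found: ", path)
  samples <- utils::read.delim(path, stringsAsFactors = FALSE)
  samples$sample_id <- as.character(samples$sample_id)
  samples$D <- as.numeric(samples$D)
  sidecar <- paste0(path, ".summary.dcf")
  if (!file.exists(sidecar)) stop("summary sidecar not found: ", sidecar)
  rec <- as.data.frame(read.dcf(sidecar), stringsAsFactors = FALSE)
  structure(list(
    dataset_id = rec$dataset_id,
    samples = samples,
    counts = c(n_samples = as.integer(rec$n_samples),
               n_mismatch = as.integer(rec$n_mismatch),
               n_unclassified = as.integer(rec$n_unclassified)),
    dataset_status = rec$dataset_status,
    mismatched_ids = samples$sample_id[samples$status == "mismatch"],
    unclassified_ids = samples$sample_id[samples$status == "unclassified"],
    n_ambiguous_cluster_discrepant =
      as.integer(rec$n_ambiguous_cluster_discrepant)
  ), class = "dataset_report")
}
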