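#' Quantile-normalize the columns of a matrix
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' reference distribution is the mean, across columns, of each order
#' statistic; each value is then replaced by the reference value at its
#' within-column rank. After normalization every column holds the identical
#' multiset of values and within-column rank order is preserved.
#'
#' Ties receive the mean of the rank-means they span (the usual convention).
#' Missing values stay missing; a column's non-missing values are ranked
#' among themselves and mapped onto the reference by linear interpolation of
#' quantile position, so partially observed samples are still normalized
#' against the rest.
#'
#' @param m Numeric matrix, rows = probes, columns = samples (>= 2 columns).
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) {
    stop("quantile normalization needs at least 2 samples (columns)")
  }
  n <- nrow(m)
  # reference: mean of order statistics; columns with missing values are
  # interpolated onto the common length-n grid first
  sorted <- matrix(NA_real_, nrow = n, ncol = ncol(m))
  for (j in seq_len(ncol(m))) {
    v <- sort(m[, j])          # drops NA
    nobs <- length(v)
    if (nobs < 2L) stop("column ", j, " has fewer than 2 observed values")
    if (nobs == n) {
      sorted[, j] <- v
    } else {
      sorted[, j] <- stats::approx(seq(1, n, length.out = nobs), v,
                                   xout = seq_len(n))$y
    }
  }
  ref <- rowMeans(sorted)
  out <- m
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    obs <- which(!is.na(v))
    nobs <- length(obs)
    ref_j <- if (nobs == n) ref else {
      stats::approx(seq_len(n), ref, xout = seq(1, n, length.out = nobs))$y
    }
    o <- order(v[obs])
    newv <- numeric(nobs)
    newv[o] <- ref_j
    # tied input values share the mean of the reference values they span
    newv <- stats::ave(newv, match(v[obs], v[obs]), FUN = mean)
    out[obs, j] <- newv
  }
  out
}

#' Bring an expression matrix to the analysis scale
#'
#' The sex-inference procedure expects log2-scale, quantile-normalized
#' intensities. This applies an optional log2 transform followed by
#' \code{\link{quantile_normalize}}. In \code{"auto"} mode the matrix is
#' assumed to be linear-scale (and is log2-transformed) when its maximum
#' exceeds \code{log_detect_threshold}: log2 microarray intensities live
#' roughly in [0, 16], so a maximum above 30 is a reliable sign of
#' linear-scale data.
#'
#' @param m Numeric matrix, rows = probes, columns = samples.
#' @param force_log One of \code{"auto"}, \code{"always"}, \code{"never"}.
#' @param log_detect_threshold Maximum-value heuristic for auto mode
#'   (default 30, log2 units vs linear units boundary).
#' @return The normalized matrix; attribute \code{"logged"} records whether
#'   a log2 transform was applied.
#' @export
log2_quantile_normalize <- function(m,
                                    force_log = c("auto", "always", "never"),
                                    log_detect_threshold = 30) {
  force_log <- match.arg(force_log)
  stopifnot(log_detect_threshold > 0)
  m <- as.matrix(m)
  do_log <- switch(force_log,
    always = TRUE,
    never = FALSE,
    auto = {
      mx <- suppressWarnings(max(m, na.rm = TRUE))
      is.finite(mx) && mx > log_detect_threshold
    }
  )
  if (do_log) {
    if (any(m <= 0, na.rm = TRUE)) {
      stop("cannot log2-transform: matrix contains non-positive values")
    }
    m <- log2(m)
  }
  out <- quantile_normalize(m)
  attr(out, "logged") <- do_log
  out
}
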