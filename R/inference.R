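# Run code under a fixed RNG seed without disturbing the caller's RNG state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Two-cluster k-means over the marker probesets
#'
#' Partitions samples into two clusters with Lloyd's algorithm on the
#' unscaled log2 marker values (probes are the dimensions, Euclidean
#' distance). The best of \code{restarts} random initializations by total
#' within-cluster sum of squares is kept; given the same seed the result is
#' identical. No feature scaling is applied: the log2 marker values of the
#' two sexes separate on an absolute scale and rescaling would distort the
#' centroid geometry.
#'
#' Samples with any missing marker value are excluded from clustering (the
#' caller forces them ambiguous downstream).
#'
#' @param m Expression matrix restricted to panel probes (probes x samples).
#' @param restarts Number of random initializations (default 25).
#' @param seed RNG seed (default 0).
#' @return A \code{cluster_result}: list with \code{assignment} (named
#'   integer vector in \{1, 2\} over complete samples), \code{centers}
#'   (2 x probes), \code{tot_withinss}, \code{excluded_samples},
#'   \code{n_restarts}, \code{seed}.
#' @export
cluster_samples <- function(m, restarts = 25, seed = 0) {
  x <- t(as.matrix(m))                    # samples x probes
  complete <- stats::complete.cases(x)
  excluded <- rownames(x)[!complete]
  x <- x[complete, , drop = FALSE]
  if (nrow(x) < 2L) {
    stop("need at least 2 samples with complete marker data to cluster")
  }
  if (all(stats::dist(x) == 0)) {
    stop("degenerate clustering: all samples are numerically identical ",
         "(likely a single-sex dataset)")
  }
  best <- NULL
  local_seed(seed, {
    for (r in seq_len(restarts)) {
      init <- x[sample.int(nrow(x), 2L), , drop = FALSE]
      if (any(stats::dist(init) == 0)) next  # coincident centers: skip draw
      fit <- tryCatch(
        stats::kmeans(x, centers = init, algorithm = "Lloyd", iter.max = 100),
        error = function(e) NULL, warning = function(w) {
          # Lloyd often flags non-convergence at iter.max; keep the fit
          tryCatch(suppressWarnings(
            stats::kmeans(x, centers = init, algorithm = "Lloyd",
                          iter.max = 100)), error = function(e) NULL)
        })
      if (is.null(fit) || any(fit$size == 0L)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best)) {
    stop("degenerate clustering: no valid 2-cluster solution found")
  }
  structure(list(
    assignment = stats::setNames(as.integer(best$cluster), rownames(x)),
    centers = best$centers,
    tot_withinss = best$tot.withinss,
    excluded_samples = excluded,
    n_restarts = restarts,
    seed = seed
  ), class = "cluster_result")
}

#' Assign male/female labels to the two clusters
#'
#' Each probeset votes by centroid geometry: a female_high (XIST) probeset
#' votes for the cluster with the higher centroid value to be the female
#' cluster; a male_high (KDM5D/RPS4Y1) probeset votes for the cluster with
#' the lower centroid value. A probeset with exactly equal centroids
#' abstains. The majority decides; a tied (or empty) vote is an error and
#' the dataset should be flagged rather than called.
#'
#' @param cr A \code{cluster_result} from \code{\link{cluster_samples}}.
#' @param panel The \code{\link{marker_panel}} used for clustering.
#' @return Named character vector mapping cluster index ("1", "2") to
#'   \code{"female"} / \code{"male"}.
#' @export
label_clusters <- function(cr, panel) {
  stopifnot(inherits(cr, "cluster_result"))
  centers <- cr$centers
  probes <- colnames(centers)
  dir <- stats::setNames(panel$direction, panel$probe_id)[probes]
  if (anyNA(dir)) {
    stop("cluster centers contain probes absent from the panel: ",
         paste(probes[is.na(dir)], collapse = ", "))
  }
  votes <- integer(2)  # votes[i]: probes voting "cluster i is female"
  for (j in seq_along(probes)) {
    d <- centers[1L, j] - centers[2L, j]
    if (d == 0) next
    hi <- if (d > 0) 1L else 2L
    fem <- if (dir[j] == "female_high") hi else 3L - hi
    votes[fem] <- votes[fem] + 1L
  }
  if (votes[1L] == votes[2L]) {
    stop("cluster labeling failed: probeset votes are tied (",
         votes[1L], ":", votes[2L], "); dataset flagged, no calls emitted")
  }
  female <- which.max(votes)
  stats::setNames(c("female", "male")[order(c(female, 3L - female))],
                  c("1", "2"))[as.character(1:2)]
}

#' Median-difference sex score
#'
#' D = median(XIST probeset values) - median(pooled KDM5D and RPS4Y1
#' probeset values) for one sample, on the log2 scale. Positive D is the
#' female pattern, negative D the male pattern; D near zero means the
#' markers are intermediate and no confident call should be made.
#'
#' @param values Named numeric vector of one sample's panel-probe values.
#' @param panel The \code{\link{marker_panel}}.
#' @return D, or \code{NA_real_} if either direction has no observed value
#'   (the sample cannot be scored and is ambiguous downstream).
#' @export
median_sex_score <- function(values, panel) {
  f <- values[panel$probe_id[panel$direction == "female_high"]]
  m <- values[panel$probe_id[panel$direction == "male_high"]]
  f <- f[!is.na(f)]
  m <- m[!is.na(m)]
  if (!length(f) || !length(m)) return(NA_real_)
  stats::median(f) - stats::median(m)
}

#' Final per-sample sex call
#'
#' The cluster assignment and the median-difference score must agree:
#' \code{female} iff the cluster says female and D > 0; \code{male} iff the
#' cluster says male and D < 0; anything else (including D == 0, missing D,
#' or a sample excluded from clustering) is \code{ambiguous} and yields no
#' confident gene-based sex.
#'
#' @param cluster_sex Character vector in \{"female", "male", NA\}.
#' @param D Numeric vector of median-difference scores.
#' @return Character vector in \{"female", "male", "ambiguous"\}.
#' @export
call_sample_sex <- function(cluster_sex, D) {
  stopifnot(length(cluster_sex) == length(D))
  out <- rep("ambiguous", length(D))
  ok <- !is.na(cluster_sex) & !is.na(D)
  out[ok & cluster_sex == "female" & D > 0] <- "female"
  out[ok & cluster_sex == "male" & D < 0] <- "male"
  out
}

#' Gene-based sex inference for one dataset
#'
#' Runs the full inference chain on a normalized expression matrix:
#' restrict to panel probes, two-cluster k-means
#' (\code{\link{cluster_samples}}), centroid-vote labeling
#' (\code{\link{label_clusters}}), per-sample median-difference score
#' (\code{\link{median_sex_score}}) and the concordance-gated final call
#' (\code{\link{call_sample_sex}}).
#'
#' @param m Normalized expression matrix (probes x samples) containing the
#'   panel probes.
#' @param panel A \code{\link{marker_panel}} (after quality filtering).
#' @param restarts,seed Passed to \code{\link{cluster_samples}}.
#' @return A data.frame of sex calls: \code{sample_id}, \code{cluster_sex},
#'   \code{D}, \code{final_call}.
#' @export
infer_sex <- function(m, panel, restarts = 25, seed = 0) {
  stopifnot(inherits(panel, "marker_panel"))
  missing <- setdiff(panel$probe_id, rownames(m))
  if (length(missing)) {
    stop("panel probe(s) missing from matrix: ",
         paste(missing, collapse = ", "))
  }
  mm <- m[panel$probe_id, , drop = FALSE]
  cr <- cluster_samples(mm, restarts = restarts, seed = seed)
  lab <- label_clusters(cr, panel)
  samples <- colnames(mm)
  cluster_sex <- rep(NA_character_, length(samples))
  names(cluster_sex) <- samples
  cluster_sex[names(cr$assignment)] <- lab[as.character(cr$assignment)]
  D <- vapply(samples, function(s) median_sex_score(mm[, s], panel), 0)
  data.frame(sample_id = samples,
             cluster_sex = unname(cluster_sex),
             D = unname(D),
             final_call = call_sample_sex(unname(cluster_sex), unname(D)),
             stringsAsFactors = FALSE, row.names = NULL)
}
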