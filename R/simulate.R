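#' Configuration for the synthetic expression generator
#'
#' The generator emulates the bimodal sex-marker pattern of log2-scale
#' microarray data: XIST high (\code{mu_on}) in females and silent
#' (\code{mu_off}) in males, KDM5D/RPS4Y1 the reverse, with Gaussian noise
#' of sd \code{sigma} in log2 units. Defaults (on 10, off 5, sigma 0.3)
#' give the ~5 log2-unit separation with tight within-sex bands typical of
#' these markers on Affymetrix platforms.
#'
#' Planted defects: \code{n_mislabels} samples have their *annotation*
#' flipped while expression follows the true sex (a tube-swap signature —
#' exactly what the detector targets); \code{n_ambiguous} samples have all
#' markers at the midpoint \code{(mu_on + mu_off) / 2} (an idealized mixed
#' sample / marker-dysregulation signature); \code{bad_probe} plants one
#' extra XIST-assigned probeset whose values are independent of sex, which
#' the correlation filter should remove.
#'
#' @param n_samples Number of samples (default 50).
#' @param p_female Probability a sample is female (default 0.5).
#' @param mu_on,mu_off Log2 means for the expressed and silent marker state.
#' @param sigma Noise sd, log2 units (> 0).
#' @param probes_per_gene Named integer vector of probeset counts per gene
#'   (default XIST = 2, KDM5D = 1, RPS4Y1 = 1, the GPL96 panel shape).
#' @param n_mislabels Number of annotation flips to plant.
#' @param n_ambiguous Number of intermediate-expression samples to plant.
#' @param bad_probe Plant an uncorrelated XIST-assigned probeset?
#' @param n_background_probes Sex-independent filler probes (default 20).
#' @param noise \code{"gaussian"} (default) or \code{"t"} for heavier tails.
#' @param t_df Degrees of freedom when \code{noise = "t"}.
#' @param seed RNG seed.
#' @return A validated \code{sim_config} list.
#' @export
sim_config <- function(n_samples = 50, p_female = 0.5,
                       mu_on = 10, mu_off = 5, sigma = 0.3,
                       probes_per_gene = c(XIST = 2, KDM5D = 1, RPS4Y1 = 1),
                       n_mislabels = 0, n_ambiguous = 0,
                       bad_probe = FALSE, n_background_probes = 20,
                       noise = c("gaussian", "t"), t_df = 3,
                       seed = 0) {
  noise <- match.arg(noise)
  stopifnot(n_samples >= 1, p_female >= 0, p_female <= 1,
            mu_on > mu_off, sigma > 0,
            all(names(.MARKER_GENES) %in% names(probes_per_gene)),
            all(probes_per_gene >= 1),
            n_mislabels >= 0, n_ambiguous >= 0,
            n_background_probes >= 0)
  if (n_mislabels + n_ambiguous > n_samples) {
    stop("infeasible: n_mislabels + n_ambiguous exceeds n_samples")
  }
  structure(list(n_samples = n_samples, p_female = p_female,
                 mu_on = mu_on, mu_off = mu_off, sigma = sigma,
                 probes_per_gene = probes_per_gene,
                 n_mislabels = n_mislabels, n_ambiguous = n_ambiguous,
                 bad_probe = bad_probe,
                 n_background_probes = n_background_probes,
                 noise = noise, t_df = t_df, seed = seed),
            class = "sim_config")
}

sim_noise <- function(cfg, n) {
  if (cfg$noise == "gaussian") stats::rnorm(n, 0, cfg$sigma)
  else cfg$sigma * stats::rt(n, cfg$t_df) / sqrt(cfg$t_df / (cfg$t_df - 2))
}

#' Generate one synthetic dataset with known ground truth
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param dataset_id Identifier stamped on the outputs.
#' @return List with \code{expr} (probes x samples log2 matrix),
#'   \code{metadata} (sample_id, annotated_sex), \code{panel} (the matching
#'   \code{\link{marker_panel}}, including the planted bad probe if any) and
#'   \code{truth} (list: \code{true_sex} named vector, \code{mislabeled},
#'   \code{ambiguous}, \code{bad_probe_id}).
#' @export
generate_dataset <- function(cfg, dataset_id = "SIM") {
  stopifnot(inherits(cfg, "sim_config"))
  local_seed(cfg$seed, {
    n <- cfg$n_samples
    sample_ids <- sprintf("%s_S%03d", dataset_id, seq_len(n))
    true_sex <- ifelse(stats::runif(n) < cfg$p_female, "female", "male")
    names(true_sex) <- sample_ids

    ambiguous <- sample(sample_ids, cfg$n_ambiguous)
    mislabeled <- sample(setdiff(sample_ids, ambiguous), cfg$n_mislabels)

    genes <- rep(names(cfg$probes_per_gene),
                 cfg$probes_per_gene[names(cfg$probes_per_gene)])
    probe_ids <- unlist(lapply(names(cfg$probes_per_gene), function(g) {
      sprintf("%s_%d_at", g, seq_len(cfg$probes_per_gene[[g]]))
    }))
    bad_id <- NULL
    if (isTRUE(cfg$bad_probe)) {
      bad_id <- "XIST_bad_at"
      probe_ids <- c(probe_ids, bad_id)
      genes <- c(genes, "XIST")
    }
    panel <- marker_panel(probe_ids, genes, platform = "synthetic")
    mid <- (cfg$mu_on + cfg$mu_off) / 2

    n_marker <- length(probe_ids)
    n_bg <- cfg$n_background_probes
    expr <- matrix(NA_real_, nrow = n_marker + n_bg, ncol = n)
    rownames(expr) <- c(probe_ids,
                        if (n_bg) sprintf("BG_%04d_at", seq_len(n_bg)))
    colnames(expr) <- sample_ids

    for (j in seq_len(n)) {
      s <- sample_ids[j]
      is_amb <- s %in% ambiguous
      mu <- vapply(seq_len(n_marker), function(i) {
        if (!is.null(bad_id) && probe_ids[i] == bad_id) return(mid)
        if (is_amb) return(mid)
        female_marker <- panel$direction[i] == "female_high"
        on <- (true_sex[s] == "female") == female_marker
        if (on) cfg$mu_on else cfg$mu_off
      }, 0)
      noise <- sim_noise(cfg, n_marker)
      # planted ambiguous samples sit exactly at the midpoint so that the
      # median-difference score is exactly zero (the idealized mixed sample)
      if (is_amb) noise[seq_len(n_marker)] <- 0
      if (!is.null(bad_id)) {
        k <- which(probe_ids == bad_id)
        noise[k] <- sim_noise(cfg, 1)   # bad probe keeps its noise always
      }
      expr[seq_len(n_marker), j] <- mu + noise
      if (n_bg) {
        expr[n_marker + seq_len(n_bg), j] <-
          cfg$mu_off + sim_noise(cfg, n_bg)
      }
    }

    annotated <- true_sex
    annotated[mislabeled] <- ifelse(annotated[mislabeled] == "female",
                                    "male", "female")
    metadata <- data.frame(sample_id = sample_ids,
                           annotated_sex = unname(annotated),
                           stringsAsFactors = FALSE)
    list(dataset_id = dataset_id, expr = expr, metadata = metadata,
         panel = panel,
         truth = list(true_sex = true_sex,
                      mislabeled = mislabeled,
                      ambiguous = ambiguous,
                      bad_probe_id = bad_id))
  })
}

# Deterministic per-dataset child seed, kept inside 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
}

#' Generate a synthetic corpus of datasets
#'
#' Exactly \code{affected} of the \code{n_datasets} datasets receive
#' planted mislabels (\code{max(1, cfg$n_mislabels)} each); the rest
#' receive none. Which datasets are affected, and each dataset's own seed,
#' derive deterministically from \code{seed}.
#'
#' @param n_datasets Number of datasets.
#' @param affected Number of datasets to plant mislabels in.
#' @param cfg Template \code{\link{sim_config}} for every dataset.
#' @param seed Corpus-level seed.
#' @return List of dataset objects as from \code{\link{generate_dataset}},
#'   with dataset_ids \code{"DS001"...}; attribute \code{"affected_ids"}
#'   lists the datasets holding planted mislabels.
#' @export
generate_corpus <- function(n_datasets, affected, cfg = sim_config(),
                            seed = 0) {
  stopifnot(n_datasets >= 1, affected >= 0, affected <= n_datasets)
  ids <- sprintf("DS%03d", seq_len(n_datasets))
  affected_ids <- local_seed(derive_seed(seed, 0L),
                             sample(ids, affected))
  out <- lapply(seq_len(n_datasets), function(i) {
    cfg_i <- cfg
    cfg_i$n_mislabels <- if (ids[i] %in% affected_ids)
      max(1L, cfg$n_mislabels) else 0L
    cfg_i$seed <- derive_seed(seed, i)
    generate_dataset(cfg_i, dataset_id = ids[i])
  })
  attr(out, "affected_ids") <- sort(affected_ids)
  out
}

#' Generate a multi-study cohort with shared subjects
#'
#' Emulates the situation of several laboratories assaying the same brain
#' collection: the subjects (and hence the metadata) are common to all
#' studies, while defects are planted either as study-specific swaps
#' (expression in one study follows the wrong sex — a laboratory mix-up)
#' or as metadata errors (the recorded sex is wrong, so every study of
#' that subject shows the same discrepancy).
#'
#' @param n_studies Number of studies (default 4).
#' @param n_subjects Number of shared subjects (default 35).
#' @param swaps_per_study Integer vector of length \code{n_studies}: number
#'   of study-specific swaps to plant in each study (default
#'   \code{c(1, 0, 5, 0)}, i.e. two affected studies).
#' @param n_metadata_errors Subjects whose recorded sex is wrong everywhere.
#' @param cfg Template \code{\link{sim_config}} (sample counts are taken
#'   from \code{n_subjects}, not the template).
#' @param seed Seed.
#' @return List with \code{studies} (per-study dataset objects whose
#'   metadata carries \code{subject_id}) and \code{truth} (data.frame:
#'   \code{subject_id}, \code{planted} in \{study_specific_mixup,
#'   consistent_metadata_error, none\}).
#' @export
generate_cohort <- function(n_studies = 4, n_subjects = 35,
                            swaps_per_study = c(1, 0, 5, 0),
                            n_metadata_errors = 0,
                            cfg = sim_config(), seed = 0) {
  stopifnot(length(swaps_per_study) == n_studies,
            all(swaps_per_study >= 0),
            sum(swaps_per_study) + n_metadata_errors <= n_subjects)
  subj <- sprintf("SUBJ%03d", seq_len(n_subjects))
  plan <- local_seed(derive_seed(seed, 0L), {
    true_sex <- stats::setNames(
      ifelse(stats::runif(n_subjects) < cfg$p_female, "female", "male"),
      subj)
    pool <- sample(subj)  # swap/error subjects drawn disjointly
    meta_err <- if (n_metadata_errors) pool[seq_len(n_metadata_errors)] else
      character(0)
    pool <- setdiff(pool, meta_err)
    swaps <- vector("list", n_studies)
    for (st in seq_len(n_studies)) {
      k <- swaps_per_study[st]
      swaps[[st]] <- if (k) pool[seq_len(k)] else character(0)
      if (k > 0) pool <- pool[-seq_len(k)]
    }
    list(true_sex = true_sex, meta_err = meta_err, swaps = swaps)
  })
  annotated <- plan$true_sex
  annotated[plan$meta_err] <- ifelse(annotated[plan$meta_err] == "female",
                                     "male", "female")
  studies <- lapply(seq_len(n_studies), function(st) {
    id <- sprintf("STUDY%d", st)
    cfg_st <- cfg
    cfg_st$n_samples <- n_subjects
    cfg_st$n_mislabels <- 0L
    cfg_st$n_ambiguous <- 0L
    cfg_st$seed <- derive_seed(seed, st)
    ds <- generate_dataset(cfg_st, dataset_id = id)
    # expression follows the true sex except for study-specific swaps;
    # annotation is the shared (possibly wrong) cohort record
    expr_sex <- plan$true_sex
    sw <- plan$swaps[[st]]
    expr_sex[sw] <- ifelse(expr_sex[sw] == "female", "male", "female")
    ds$expr[ds$panel$probe_id, ] <- local_seed(derive_seed(seed, 1000L + st), {
      block <- matrix(0, nrow(ds$panel), n_subjects,
                      dimnames = list(ds$panel$probe_id, colnames(ds$expr)))
      for (j in seq_len(n_subjects)) {
        for (i in seq_len(nrow(ds$panel))) {
          female_marker <- ds$panel$direction[i] == "female_high"
          on <- (expr_sex[[j]] == "female") == female_marker
          block[i, j] <- (if (on) cfg$mu_on else cfg$mu_off) +
            sim_noise(cfg, 1)
        }
      }
      block
    })
    ds$metadata <- data.frame(sample_id = colnames(ds$expr),
                              annotated_sex = unname(annotated),
                              subject_id = subj,
                              stringsAsFactors = FALSE)
    ds$truth <- list(true_sex = plan$true_sex,
                     swapped_subjects = sw,
                     metadata_error_subjects = plan$meta_err)
    ds
  })
  planted <- rep("none", n_subjects)
  names(planted) <- subj
  planted[unlist(plan$swaps)] <- "study_specific_mixup"
  planted[plan$meta_err] <- "consistent_metadata_error"
  list(studies = studies,
       truth = data.frame(subject_id = subj, planted = unname(planted),
                          stringsAsFactors = FALSE))
}
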