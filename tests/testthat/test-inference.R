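test_that("k-means recovers the planted partition found by exhaustive search", {
  m <- tiny_matrix(n_f = 3, n_m = 3, sd = 0.1, seed = 2)
  cr <- cluster_samples(m, restarts = 25, seed = 0)
  oracle <- best_two_partition(t(m))
  # same partition up to cluster index flip
  got <- cr$assignment - 1L
  expect_true(all(got == oracle$grp) || all(got == 1L - oracle$grp))
  expect_equal(cr$tot_withinss, oracle$ss, tolerance = 1e-9)
})

test_that("clustering is deterministic given the seed", {
  m <- tiny_matrix(n_f = 5, n_m = 5, sd = 0.4, seed = 3)
  a <- cluster_samples(m, seed = 42)
  b <- cluster_samples(m, seed = 42)
  expect_identical(a$assignment, b$assignment)
  expect_identical(a$centers, b$centers)
})

test_that("degenerate inputs error out", {
  m <- matrix(5, nrow = 4, ncol = 6,
              dimnames = list(letters[1:4], LETTERS[1:6]))
  expect_error(cluster_samples(m), "identical")
  expect_error(cluster_samples(m[, 1, drop = FALSE]), "at least 2 samples")
})

test_that("samples with missing marker values are excluded from clustering", {
  m <- tiny_matrix(n_f = 3, n_m = 3, sd = 0.1, seed = 4)
  m["x1", "F1"] <- NA
  cr <- cluster_samples(m)
  expect_identical(cr$excluded_samples, "F1")
  expect_false("F1" %in% names(cr$assignment))
  # excluded from clustering means no cluster sex, so forced ambiguous,
  # even though the median score alone still looks female
  calls <- infer_sex(m, tiny_panel())
  f1 <- calls[calls$sample_id == "F1", ]
  expect_identical(f1$final_call, "ambiguous")
  expect_true(is.na(f1$cluster_sex) && f1$D > 0)
  # drop the male markers too: D becomes undefined as well
  m["k1", "F1"] <- NA
  m["r1", "F1"] <- NA
  calls <- infer_sex(m, tiny_panel())
  expect_true(is.na(calls$D[calls$sample_id == "F1"]))
  expect_identical(calls$final_call[calls$sample_id == "F1"], "ambiguous")
})

test_that("cluster labeling follows the centroid vote", {
  fake_cr <- function(centers) {
    structure(list(assignment = c(a = 1L, b = 2L), centers = centers),
              class = "cluster_result")
  }
  panel <- tiny_panel()
  cent <- rbind(c(10.1, 9.8, 4.2, 4.5), c(5.0, 5.2, 9.1, 9.7))
  colnames(cent) <- panel$probe_id
  expect_identical(label_clusters(fake_cr(cent), panel),
                   c("1" = "female", "2" = "male"))
  # one XIST probe votes against three concordant probes: majority wins
  cent2 <- cent
  cent2[, "x2"] <- c(5.2, 9.8)
  expect_identical(label_clusters(fake_cr(cent2), panel),
                   c("1" = "female", "2" = "male"))
  # two votes each way: labeling failure
  cent3 <- cent
  cent3[, c("x2", "k1")] <- cent3[2:1, c("x2", "k1")]
  expect_error(label_clusters(fake_cr(cent3), panel), "tied")
  # equal centroids abstain
  cent4 <- cent
  cent4[, "x1"] <- 7
  expect_identical(label_clusters(fake_cr(cent4), panel),
                   c("1" = "female", "2" = "male"))
})

test_that("median-difference score pools the male markers", {
  panel <- marker_panel(c("x1", "x2", "x3", "k1", "r1"),
                        c("XIST", "XIST", "XIST", "KDM5D", "RPS4Y1"))
  v <- c(x1 = 9, x2 = 10, x3 = 11, k1 = 4, r1 = 6)
  expect_equal(median_sex_score(v, panel), 10 - 5)
  p2 <- marker_panel(c("x1", "k1", "r1"), c("XIST", "KDM5D", "RPS4Y1"))
  expect_equal(median_sex_score(c(x1 = 5, k1 = 9, r1 = 10), p2), -4.5)
  expect_equal(median_sex_score(c(x1 = 7, k1 = 7, r1 = 7), p2), 0)
  expect_true(is.na(median_sex_score(c(x1 = NA, k1 = 7, r1 = 7), p2)))
})

test_that("final call requires cluster/score agreement", {
  expect_identical(
    call_sample_sex(c("female", "female", "male", "male", "male", NA),
                    c(5, -2, -3, 0, 2, 4)),
    c("female", "ambiguous", "male", "ambiguous", "ambiguous", "ambiguous"))
})

test_that("final calls are invariant to sample order and cluster relabeling", {
  d <- generate_dataset(sim_config(n_samples = 30, n_mislabels = 1,
                                   seed = 21), "S")
  calls <- infer_sex(d$expr, d$panel, seed = 7)
  for (perm_seed in 1:3) {
    set.seed(perm_seed)
    perm <- sample(ncol(d$expr))
    calls_p <- infer_sex(d$expr[, perm], d$panel, seed = 7)
    reord <- calls_p[match(calls$sample_id, calls_p$sample_id), ]
    expect_identical(reord$final_call, calls$final_call)
    expect_equal(reord$D, calls$D)
  }
})

test_that("ambiguous-call fraction rises with the planted ambiguous fraction", {
  frac <- vapply(c(0, 5, 15), function(k) {
    d <- generate_dataset(sim_config(n_samples = 40, n_ambiguous = k,
                                     seed = 31), "A")
    calls <- infer_sex(d$expr, d$panel, seed = 1)
    mean(calls$final_call == "ambiguous")
  }, 0)
  expect_true(all(diff(frac) > 0))
})
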