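# shared small benchmark for the ensemble tests
ens_data <- local({
  st <- simulate_study(n_per_class = 60, p = 80, n_informative = 15,
                       delta = 2, block_size = 10, rho = 0.2,
                       flip_fraction = 0.05, seed = 41)
  st
})

test_that("full ensemble: planted flips concentrate at the top of the RP ranking", {
  st <- ens_data
  ens <- suppressWarnings(outlier_ensemble(st$X, st$y_observed, seed = 41))
  expect_s3_class(ens, "outlier_ensemble")
  expect_equal(dim(ens$D), c(120L, 3L))
  rk <- match(ens$rp_table$sample_id, rownames(st$X))
  nf <- length(st$flipped_ids)
  ev <- evaluate_topk(rk, st$flipped_ids, n = 120, k_list = nf)
  expect_lte(ev$false_negatives, ceiling(0.5 * nf))
  # misclassification fractions are proper fractions; outliers subset of samples
  expect_true(all(rowMeans(ens$misclassified) >= 0 &
                    rowMeans(ens$misclassified) <= 1))
  expect_true(all(ens$outliers %in% rownames(st$X)))
})

test_that("ensembles are bit-reproducible under a fixed master seed", {
  st <- ens_data
  e1 <- suppressWarnings(outlier_ensemble(st$X, st$y_observed, seed = 7))
  e2 <- suppressWarnings(outlier_ensemble(st$X, st$y_observed, seed = 7))
  expect_identical(e1$D, e2$D)
  expect_identical(e1$rp_table$p_value, e2$rp_table$p_value)
})

test_that("two identical members give RP = rank squared; member failure aborts", {
  st <- ens_data
  members <- list(a = list(method = "splsda", alpha = 0.5, L = 2),
                  b = list(method = "splsda", alpha = 0.5, L = 2))
  ens <- suppressWarnings(outlier_ensemble(st$X, st$y_observed,
                                           members = members, seed = 1))
  R <- attr(ens$rp_table, "ranks")
  expect_identical(R[, 1], R[, 2])
  expect_equal(ens$rp_table$rp, as.numeric(R[, 1])^2)

  bad <- list(a = list(method = "logit_en", alpha = 0.5, lambda = -2),
              b = list(method = "splsda", alpha = 0.5, L = 2))
  expect_error(suppressWarnings(
    outlier_ensemble(st$X, st$y_observed, members = bad, seed = 1)),
    "member 'a' failed")
  expect_error(outlier_ensemble(st$X, st$y_observed,
                                members = list(list(method = "splsda"))),
               "at least 2 members")
})

test_that("consensus genes: frequencies, common and frequent sets", {
  sels <- list(c(1L, 2L, 3L), c(2L, 3L), c(3L, 5L))
  cg <- rpoutliers:::consensus_genes(sels, p = 6, freq_threshold = 0.6)
  expect_equal(unname(cg$frequency), c(1, 2, 3, 0, 1, 0) / 3)
  expect_equal(cg$common, "3")
  expect_setequal(cg$frequent, c("2", "3"))
  # disjoint selections: empty common set
  cg2 <- rpoutliers:::consensus_genes(list(1L, 2L), p = 3)
  expect_length(cg2$common, 0)
})

test_that("random-patients: runs reduce correctly and training sets cover all samples", {
  st <- ens_data
  rp1 <- suppressWarnings(run_random_patients(st$X, st$y_observed, runs = 2,
                                              lambda = 0.05, seed = 5))
  expect_equal(dim(rp1$D), c(120L, 2L))
  expect_true(all(is.finite(rp1$D)))
  # coverage: with runs = 25 and fraction = 0.8 every sample is trained on
  # at least once with overwhelming probability
  counts <- integer(120)
  for (r in 1:25) {
    rng <- rpoutliers:::local_rng(derive_seed(5, r))
    idx <- sort(sample.int(120, floor(0.8 * 120)))
    rng()
    counts[idx] <- counts[idx] + 1L
  }
  expect_true(all(counts > 0))
})

test_that("random-variables: full draw with one run equals the single full fit", {
  st <- ens_data
  rv <- suppressWarnings(run_random_variables(st$X, st$y_observed, runs = 2,
                                              n_features = 80, lambda = 0.05,
                                              seed = 6))
  single <- fit_logit_en(st$X, st$y_observed, alpha = 0.7, lambda = 0.05)
  cd <- cooks_distance_model(single, st$X, st$y_observed)
  expect_equal(unname(rv$D[, 1]), cd$D, tolerance = 1e-10)
  expect_error(run_random_variables(st$X, st$y_observed, n_features = 1000),
               "n_features")
  # gene frequency denominators equal draw counts: full draws -> all finite
  expect_true(all(is.finite(rv$consensus$frequency)))
})

test_that("outlier report carries labels, ranks and misclassification fractions", {
  st <- ens_data
  ens <- suppressWarnings(outlier_ensemble(st$X, st$y_observed, seed = 41))
  ids <- rownames(st$X)
  labels <- data.frame(sample_id = ids, y = st$y_observed,
                       her2_source = "ihc_status",
                       suspect = seq_along(ids) %in% st$flipped_ids[1:2])
  rep1 <- outlier_report(ens, labels = labels)
  expect_equal(rep1$sample_id, ens$rp_table$sample_id[ens$rp_table$outlier])
  expect_true(all(diff(rep1$rp) >= 0))
  expect_true(all(rep1$misclassified_fraction >= 0 &
                    rep1$misclassified_fraction <= 1))
  expect_true(all(c("rank.logit_en", "rank.splsda", "rank.sgpls") %in%
                    colnames(rep1)))
  # missing clinical rows are noted, not dropped
  rep2 <- outlier_report(ens, labels = labels[-match(rep1$sample_id[1],
                                                     labels$sample_id), ])
  expect_equal(rep2$note[1], "no clinical row")
  # report round-trips through a TSV
  tf <- tempfile(fileext = ".tsv")
  write.table(rep1, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read.delim(tf, check.names = FALSE)
  expect_equal(back$sample_id, rep1$sample_id)
  expect_equal(back$rp, rep1$rp)
})

test_that("relabel_and_refit: empty flip set reproduces the fit; flips reduce influence", {
  st <- ens_data
  ens <- suppressWarnings(outlier_ensemble(st$X, st$y_observed, seed = 41))
  same <- suppressWarnings(relabel_and_refit(ens, character(0)))
  expect_identical(same$refit$D, ens$D)
  expect_equal(same$common_gene_overlap, 1)

  # flipping a detected planted outlier back to its true label shrinks its D
  top <- ens$rp_table$sample_id[1]
  idx <- match(top, rownames(st$X))
  if (idx %in% st$flipped_ids) {
    rf <- suppressWarnings(relabel_and_refit(ens, top))
    expect_lt(median(rf$refit$D[top, ] / ens$D[top, ]), 1)
    expect_gte(rf$common_gene_overlap, 0)
    expect_lte(rf$common_gene_overlap, 1)
  }
  expect_error(relabel_and_refit(ens, "nope"), "unknown sample ids")
})
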