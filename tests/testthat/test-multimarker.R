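test_that("select_markers applies all filters and ranks by paired difference", {
  gen <- generate_beta_matrix(seed = 3)
  sel <- select_markers(gen$beta, k = 2, candidate_regions = list(gen$region))
  # only the planted probes pass; clean probes rank first
  expect_setequal(sel$probe_id, gen$truth$planted)
  expect_true(all(sel$median_paired_diff > 0.5))
  # the decoy (one normal at 0.3) is excluded by the normal ceiling
  expect_false(gen$truth$decoy %in% sel$probe_id)
  # asking for more than pass returns all passing, with a warning
  expect_warning(
    sel_all <- select_markers(gen$beta, k = 5,
                              candidate_regions = list(gen$region)),
    "only 2")
  expect_equal(sel_all$probe_id, sel$probe_id)
  # SNP blocklist removes a planted probe
  sel2 <- select_markers(gen$beta, k = 1, candidate_regions = list(gen$region),
                         snp_blocklist = gen$truth$planted[1])
  expect_false(gen$truth$planted[1] %in% sel2$probe_id)
  # region with no overlap: empty with warning
  far <- marker_region("chrX:1-100")
  expect_warning(none <- select_markers(gen$beta, 3,
                                        candidate_regions = list(far)),
                 "no probe")
  expect_equal(nrow(none), 0)
  # invariance to probe and sample permutation
  set.seed(1)
  b2 <- gen$beta
  pp <- sample(nrow(b2$values)); ss <- sample(ncol(b2$values))
  b2$values <- b2$values[pp, ss]
  b2$sample_class <- b2$sample_class[colnames(b2$values)]
  sel3 <- select_markers(b2, 2, candidate_regions = list(gen$region))
  expect_equal(sel3$probe_id, sel$probe_id)
})

test_that("make_splits stratifies, reproduces from seed, and partitions", {
  ids <- sprintf("s%02d", 1:66)
  labels <- stats::setNames(rep(c("case", "control"), c(30, 36)), ids)
  plan <- make_splits(ids, labels, n_runs = 10, seed = 4)
  expect_length(plan$runs, 10)
  for (run in plan$runs) {
    expect_length(intersect(run$train, run$test), 0)
    expect_setequal(c(run$train, run$test), ids)
    expect_equal(sum(labels[run$train] == "case"), 15)
    expect_equal(sum(labels[run$train] == "control"), 18)
  }
  plan2 <- make_splits(ids, labels, n_runs = 10, seed = 4)
  expect_identical(plan$runs, plan2$runs)
  # odd class size: partitions differ by at most one
  labels3 <- stats::setNames(rep(c("case", "control"), c(7, 6)), ids[1:13])
  plan3 <- make_splits(ids[1:13], labels3, n_runs = 3, seed = 1)
  for (run in plan3$runs) {
    expect_lte(abs(length(run$train) - length(run$test)), 1)
  }
})

test_that("the linear SVM is monotone in 1-D and separates separable toys", {
  set.seed(6)
  x <- matrix(rnorm(40), ncol = 1, dimnames = list(NULL, "m1"))
  y <- ifelse(x[, 1] + rnorm(40, 0, 0.5) > 0, "case", "control")
  fit <- train_combined(x, y)
  dv <- predict(fit, x)
  expect_equal(order(dv), order(x[, 1]))  # monotone transform of the marker
  # separable 2-marker toy
  x2 <- rbind(matrix(rnorm(40, 3), ncol = 2), matrix(rnorm(40, -3), ncol = 2))
  y2 <- rep(c("case", "control"), each = 20)
  fit2 <- train_combined(x2, y2)
  dv2 <- predict(fit2, x2)
  expect_equal(auc_u_statistic(dv2[y2 == "case"], dv2[y2 == "control"]), 1)
  expect_error(train_combined(x2, rep("case", 40)), "both classes")
})

test_that("label-permuted training yields chance-level test AUC", {
  set.seed(7)
  n <- 60
  x <- cbind(m1 = c(rnorm(n / 2, 2), rnorm(n / 2)), m2 = rnorm(n))
  y <- rep(c("case", "control"), each = n / 2)
  train <- c(1:15, 31:45); test <- setdiff(seq_len(n), train)
  aucs <- vapply(1:20, function(i) {
    yp <- sample(y[train])
    fit <- train_combined(x[train, ], yp)
    dv <- predict(fit, x[test, ])
    auc_u_statistic(dv[y[test] == "case"], dv[y[test] == "control"])
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
})

test_that("evaluate_runs averages ROC curves vertically and compares AUC sets", {
  ids <- sprintf("s%02d", 1:20)
  labels <- stats::setNames(rep(c("case", "control"), each = 10), ids)
  score <- stats::setNames(ifelse(labels == "case", 1, 0) +
                             seq_along(ids) * 1e-3, ids)
  plan <- make_splits(ids, labels, n_runs = 10, seed = 2)
  res <- evaluate_runs(plan, labels, function(train, test) score[test])
  expect_length(res$aucs, 10)
  expect_true(all(res$aucs == 1))
  # separable constant builder: zero SD band
  expect_true(all(res$mean_roc$tpr_sd == 0))
  expect_equal(res$mean_roc$tpr_mean[res$mean_roc$fpr == 1], 1)
  # rank-sum of an AUC list against itself: no difference
  expect_equal(compare_auc_sets(res$aucs, res$aucs), 1)
})

test_that("multimarker_run learns cutoffs inside the training partition only", {
  spec <- cohort_spec(n_cases = 12, n_controls = 12, reads_per_sample = 150,
                      tumor_mix = list(fraction = 0.08, high_shape1 = 8.5,
                                       high_shape2 = 1.5), seed = 13)
  coh1 <- generate_cohort(spec)
  spec2 <- cohort_spec(n_cases = 12, n_controls = 12, reads_per_sample = 150,
                       tumor_mix = list(fraction = 0.08, high_shape1 = 8.5,
                                        high_shape2 = 1.5), seed = 14)
  coh2 <- generate_cohort(spec2)
  markers <- list(marker_a = coh1$tables, marker_b = coh2$tables)
  labels <- coh1$labels
  ids <- names(labels)
  plan <- make_splits(ids, labels, n_runs = 2, seed = 5)
  run <- plan$runs[[1]]
  dv <- multimarker_run(markers, labels, run$train, run$test)
  expect_setequal(names(dv), run$test)
  expect_length(attr(dv, "md_stars"), 2)
  # leakage check: corrupting test labels must not move the learned cutoffs
  labels_bad <- labels
  labels_bad[run$test] <- rev(labels[run$test])
  dv2 <- multimarker_run(markers, labels_bad, run$train, run$test)
  expect_identical(attr(dv, "md_stars"), attr(dv2, "md_stars"))
  expect_equal(unname(dv), unname(dv2))
})

test_that("with one marker the combined model reproduces the raw-score ROC", {
  spec <- cohort_spec(n_cases = 10, n_controls = 10, reads_per_sample = 150,
                      tumor_mix = list(fraction = 0.1, high_shape1 = 8.5,
                                       high_shape2 = 1.5), seed = 17)
  coh <- generate_cohort(spec)
  labels <- coh$labels
  ids <- names(labels)
  plan <- make_splits(ids, labels, n_runs = 1, seed = 6)
  run <- plan$runs[[1]]
  dv <- multimarker_run(list(m = coh$tables), labels, run$train, run$test)
  md_star <- attr(dv, "md_stars")[["m"]]
  sc <- score_samples(split_samples(coh$tables), labels = labels,
                      measure = "normalized_read_count")
  raw <- sc$scores[run$test, which(abs(sc$md - md_star) < 1e-12)]
  expect_equal(
    auc_u_statistic(dv[labels[run$test] == "case"],
                    dv[labels[run$test] == "control"]),
    auc_u_statistic(raw[labels[run$test] == "case"],
                    raw[labels[run$test] == "control"]))
})
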