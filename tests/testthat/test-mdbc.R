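test_that("score_samples computes measure-specific scores over the md grid", {
  tabs <- list(s = tiny_table("s", list(c(0, 14, 98), c(12, 14, 2))))
  sc <- score_samples(tabs, measure = "fraction")
  on_band <- sc$md <= 12 / 14 + 1e-9
  expect_equal(unname(sc$scores[1, on_band]), rep(0.02, sum(on_band)))
  expect_equal(unname(sc$scores[1, !on_band]), rep(0, sum(!on_band)))

  # per-mL counts: 2 passing epialleles in 0.5 mL assessed -> 4 per mL
  sc2 <- score_samples(tabs, measure = "per_ml_count",
                       normalizers = c(s = 0.5))
  expect_equal(unname(sc2$scores[1, on_band & sc2$md > 0]),
               rep(4, sum(on_band & sc2$md > 0)))
  expect_error(score_samples(tabs, measure = "per_ml_count"), "normalizers")
  expect_error(score_samples(tabs, grid = numeric(0)), "empty md grid")

  # rows are non-increasing along the grid
  expect_true(all(diff(sc$scores[1, ]) <= 1e-12))
})

test_that("build_cutoff_grid counts TPR/FPR over observed EF candidates", {
  # 3 cases scoring 0.1/0.2/0.3 at md = 0.5 via CpG-weighted fractions:
  tabs <- c(
    stats::setNames(lapply(1:3, function(i)
      tiny_table(paste0("case", i),
                 list(c(10, 10, i), c(0, 10, 10 - i)))), paste0("case", 1:3)),
    list(ctrl1 = tiny_table("ctrl1", list(c(0, 10, 10))))
  )
  labels <- c(case1 = "case", case2 = "case", case3 = "case", ctrl1 = "control")
  grid <- build_cutoff_grid(score_samples(tabs, labels = labels, grid = 0.5))
  row <- grid$grid[abs(grid$grid$ef - 0.2) < 1e-9, ]
  expect_equal(row$tpr, 2 / 3)
  expect_equal(row$fpr, 0)

  # separable cohort: some cell reaches TPR 1 / FPR 0; +Inf row has FPR 0
  expect_true(any(grid$grid$tpr == 1 & grid$grid$fpr == 0))
  expect_true(any(is.infinite(grid$grid$ef) & grid$grid$fpr == 0))

  # identical case and control score sets -> TPR == FPR everywhere
  tabs2 <- list(a = tiny_table("a", list(c(5, 10, 1))),
                b = tiny_table("b", list(c(5, 10, 1))))
  g2 <- build_cutoff_grid(score_samples(tabs2,
                                        labels = c(a = "case", b = "control")))
  expect_equal(g2$grid$tpr, g2$grid$fpr)
  expect_error(build_cutoff_grid(score_samples(tabs2, labels = c(a = "case", b = "case"))),
               "control")
})

test_that("optimize_cutoffs matches the exhaustive oracle and reports ties", {
  for (seed in 1:30) {
    mc <- random_micro_cohort(seed)
    sc <- score_samples(mc$tables, labels = mc$labels)
    opt <- optimize_cutoffs(build_cutoff_grid(sc))
    oracle <- oracle_optimum(sc$scores, mc$labels, sc$md)
    expect_equal(opt$j_star, oracle$j, tolerance = 1e-12)
    # canonical pair must be one of the oracle's tied cells
    expect_true(any(abs(oracle$cells$md - opt$md_star) < 1e-12 &
                      (oracle$cells$ef == opt$ef_star |
                         (is.infinite(oracle$cells$ef) & is.infinite(opt$ef_star)))))
    # all reported ties attain J* and the canonical rule holds
    expect_true(all(abs(opt$ties$j - opt$j_star) <= 1e-12))
    expect_equal(opt$md_star, min(opt$ties$md))
  }
  # degenerate: cases identical to controls -> J* = 0
  tabs <- list(a = tiny_table("a", list(c(5, 10, 2))),
               b = tiny_table("b", list(c(5, 10, 2))))
  sc <- score_samples(tabs, labels = c(a = "case", b = "control"))
  expect_equal(optimize_cutoffs(build_cutoff_grid(sc))$j_star, 0)
})

test_that("J* is invariant under strictly monotone score transforms", {
  mc <- random_micro_cohort(99)
  sc <- score_samples(mc$tables, labels = mc$labels)
  opt1 <- optimize_cutoffs(build_cutoff_grid(sc))
  sc2 <- sc
  sc2$scores <- exp(3 * sc$scores)   # strictly increasing
  opt2 <- optimize_cutoffs(build_cutoff_grid(sc2))
  expect_equal(opt1$j_star, opt2$j_star, tolerance = 1e-12)
  expect_equal(opt1$md_star, opt2$md_star)
})

test_that("roc_at_md equals the all-pairs U-statistic oracle", {
  for (seed in 31:45) {
    mc <- random_micro_cohort(seed)
    sc <- score_samples(mc$tables, labels = mc$labels)
    for (md in c(0, 0.5, 1)) {
      r <- roc_at_md(sc, md)
      k <- which(abs(sc$md - md) < 1e-12)
      v <- sc$scores[, k]
      expect_equal(r$auc, oracle_auc(v[mc$labels == "case"],
                                     v[mc$labels == "control"]))
    }
  }
  # separable and all-ties endpoints
  expect_equal(auc_u_statistic(c(2, 3), c(0, 1)), 1)
  expect_equal(auc_u_statistic(c(1, 1), c(1, 1)), 0.5)
})

test_that("performance_profile is self-consistent and flags the optimum", {
  spec <- cohort_spec(n_cases = 8, n_controls = 8, reads_per_sample = 100,
                      tumor_mix = list(fraction = 0.2, high_shape1 = 8.5,
                                       high_shape2 = 1.5), seed = 11)
  coh <- generate_cohort(spec)
  sc <- score_samples(split_samples(coh$tables), labels = coh$labels)
  prof <- performance_profile(sc)
  expect_equal(nrow(prof), length(sc$md))
  for (i in c(1, 7, 13)) {
    expect_equal(prof$auc[i], roc_at_md(sc, prof$md[i])$auc)
  }
  expect_true(any(prof$optimal))
  expect_equal(max(prof$j), optimize_cutoffs(build_cutoff_grid(sc))$j_star)
  # strongly separated cohort: AUC 1 across the separating band
  spec2 <- cohort_spec(n_cases = 5, n_controls = 5, reads_per_sample = 100,
                       background_mix = list(weight_zero = 1, low_shape1 = 1,
                                             low_shape2 = 19),
                       tumor_mix = list(fraction = 0.5, high_shape1 = 200,
                                        high_shape2 = 2), seed = 12)
  coh2 <- generate_cohort(spec2)
  sc2 <- score_samples(split_samples(coh2$tables), labels = coh2$labels)
  prof2 <- performance_profile(sc2)
  expect_true(all(prof2$auc[prof2$md >= 0.5 & prof2$md <= 0.9] == 1))
})

test_that("classify applies the at-least rule and reproduces grid TPR", {
  t_case <- tiny_table("x", list(c(9, 10, 3), c(0, 10, 7)))
  # score at md 0.6 (read fraction of passing reads via fraction measure)
  sc <- epiallelic_fraction(t_case, 0.6)
  expect_equal(as.character(classify(t_case, 0.6, sc)), "positive") # at EF
  expect_equal(as.character(classify(t_case, 0.6, sc + 1e-9)), "negative")
  t_zero <- tiny_table("z", list(c(0, 10, 5)))
  expect_equal(as.character(classify(t_zero, 0.3, 0.01)), "negative")

  # training positive-rate at the optimum equals grid TPR
  mc <- random_micro_cohort(77)
  sc_all <- score_samples(mc$tables, labels = mc$labels)
  opt <- optimize_cutoffs(build_cutoff_grid(sc_all))
  calls <- vapply(names(mc$tables)[mc$labels == "case"], function(id) {
    classify(mc$tables[[id]], opt$md_star, opt$ef_star)
  }, character(1))
  expect_equal(mean(calls == "positive"), opt$tpr)
})

test_that("adding sub-cutoff reads never changes the score at a cutoff", {
  t1 <- tiny_table("s", list(c(8, 10, 2), c(9, 10, 1)))
  t2 <- tiny_table("s", list(c(8, 10, 2), c(9, 10, 1), c(3, 10, 5)))
  for (md in c(0.5, 0.8)) {
    # locality holds for the passing count, i.e. the per-mL measure
    n1 <- sum(t1$count[t1$n_meth / t1$n_cpgs >= md])
    n2 <- sum(t2$count[t2$n_meth / t2$n_cpgs >= md])
    expect_equal(n1, n2)
    s1 <- score_samples(list(s = t1), grid = md, measure = "per_ml_count",
                        normalizers = c(s = 2))
    s2 <- score_samples(list(s = t2), grid = md, measure = "per_ml_count",
                        normalizers = c(s = 2))
    expect_equal(s1$scores[1, 1], s2$scores[1, 1])
  }
})

test_that("baseline scores: mean methylation and the MSP-like 95% cutoff", {
  b <- baseline_scores(tiny_table("s", list(c(14, 14, 1), c(0, 14, 99))))
  expect_equal(unname(b["msp_like"]), 0.01)
  b0 <- baseline_scores(tiny_table("s", list(c(0, 10, 5))))
  expect_equal(unname(b0), c(0, 0))
  bu <- baseline_scores(tiny_table("s", list(c(5, 10, 4))))
  expect_equal(unname(bu["mean_meth"]), 0.5)
  expect_equal(unname(bu["msp_like"]), 0)
})

test_that("stratified bootstrap CI brackets the point AUC and is reproducible", {
  set.seed(5)
  cases <- rnorm(20, 1); controls <- rnorm(25)
  ci1 <- auc_bootstrap_ci(cases, controls, n_boot = 200, seed = 42)
  ci2 <- auc_bootstrap_ci(cases, controls, n_boot = 200, seed = 42)
  expect_equal(ci1, ci2)
  expect_true(ci1$lower <= ci1$auc && ci1$auc <= ci1$upper)
  expect_error(auc_bootstrap_ci(cases, controls), "seed")
})

test_that("published presets are data with the reported values", {
  p <- epiclass_presets()
  expect_equal(p$md_star[p$preset == "znf154_plasma_dreaming"], 0.60)
  expect_equal(p$ef_star[p$preset == "znf154_plasma_dreaming"], 6.7)
  expect_equal(p$md_star[p$preset == "hcc_plasma_wgbs"], 0.45)
})
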