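# shared fixtures and independent oracles

# build a single-sample density table from a list of c(n_meth, n_cpgs, count)
tiny_table <- function(id, tallies) {
  m <- do.call(rbind, tallies)
  density_table(data.frame(sample_id = id, n_meth = m[, 1],
                           n_cpgs = m[, 2], count = m[, 3]))
}

# all-pairs AUC oracle: P(case > control) + 0.5 P(tie)
oracle_auc <- function(cases, controls) {
  cmp <- outer(cases, controls, ">") + 0.5 * outer(cases, controls, "==")
  mean(cmp)
}

# exhaustive double-loop (MD, EF) Youden search, independent of the package's
# grid code: recomputes scores cell by cell from the raw score matrix
oracle_optimum <- function(score_matrix, labels, grid) {
  best <- list(j = -Inf, cells = NULL)
  for (k in seq_along(grid)) {
    v <- score_matrix[, k]
    for (ef in c(sort(unique(v)), Inf)) {
      tpr <- mean(v[labels == "case"] >= ef)
      fpr <- mean(v[labels == "control"] >= ef)
      j <- tpr - fpr
      cell <- data.frame(md = grid[k], ef = ef, j = j)
      if (j > best$j + 1e-12) {
        best <- list(j = j, cells = cell)
      } else if (abs(j - best$j) <= 1e-12) {
        best$cells <- rbind(best$cells, cell)
      }
    }
  }
  best
}

# random micro-cohort of single-sample tables + labels (small, fast)
random_micro_cohort <- function(seed, n_samples = 6, max_reads = 20) {
  set.seed(seed)
  n_case <- sample(1:(n_samples - 1), 1)
  ids <- sprintf("s%02d", seq_len(n_samples))
  labels <- stats::setNames(
    rep(c("case", "control"), c(n_case, n_samples - n_case)), ids)
  tabs <- lapply(ids, function(id) {
    n <- sample(2:max_reads, 1)
    n_cpgs <- sample(2:10, n, replace = TRUE)
    density_table(data.frame(
      sample_id = id, n_cpgs = n_cpgs,
      n_meth = vapply(n_cpgs, function(k) sample(0:k, 1), integer(1)),
      count = 1L))
  })
  list(tables = stats::setNames(tabs, ids), labels = labels)
}
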