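#' Simulate a tumor-in-background spike-in sample
#'
#' Draws `round(ratio * depth)` reads from the tumor sample's CpG-weighted
#' methylation-density distribution and the remainder from the background's,
#' with replacement; sampled reads inherit an observed `(n_meth, n_cpgs)`
#' pair from their source class. Fixed (rounded) tumor read counts make the
#' dilution ratio exact per replicate; `count_mode = "binomial"` draws the
#' tumor count from Binomial(depth, ratio) instead.
#'
#' @param tumor_table,background_table single-sample `density_table`s.
#' @param ratio tumor fraction in `[0, 1]`.
#' @param depth total simulated reads.
#' @param seed required integer seed.
#' @param sample_id id of the simulated sample.
#' @param count_mode `"fixed"` (default) or `"binomial"`.
#' @return a single-sample `density_table`; attribute `n_tumor` records the
#'   tumor read count actually drawn.
#' @export
spike_in <- function(tumor_table, background_table, ratio, depth, seed,
                     sample_id = "spikein", count_mode = c("fixed", "binomial")) {
  count_mode <- match.arg(count_mode)
  if (missing(seed)) stop("seed is required for spike-in sampling", call. = FALSE)
  if (ratio < 0 || ratio > 1) stop("ratio must be in [0, 1]", call. = FALSE)
  if (nrow(tumor_table) == 0L || nrow(background_table) == 0L) {
    stop("source tables must be nonempty", call. = FALSE)
  }
  if (ratio > 0 && ratio * depth < 1) {
    warning(sprintf("ratio * depth = %.3g < 1: expected tumor reads round to %d",
                    ratio * depth, round(ratio * depth)), call. = FALSE)
  }
  set.seed(seed)
  n_tumor <- switch(count_mode,
    fixed = as.integer(round(ratio * depth)),
    binomial = stats::rbinom(1L, depth, ratio)
  )
  n_bg <- depth - n_tumor
  draw <- function(tab, n) {
    if (n == 0L) return(NULL)
    idx <- sample.int(nrow(tab), n, replace = TRUE,
                      prob = tab$count * tab$n_cpgs)  # cpg-weighted fractions
    data.frame(n_meth = tab$n_meth[idx], n_cpgs = tab$n_cpgs[idx])
  }
  reads <- rbind(draw(tumor_table, n_tumor), draw(background_table, n_bg))
  out <- density_table(data.frame(sample_id = sample_id,
                                  n_meth = reads$n_meth,
                                  n_cpgs = reads$n_cpgs, count = 1L))
  attr(out, "n_tumor") <- n_tumor
  out
}

#' Build a spike-in case/control cohort
#'
#' One spike-in sample is made per background sample, each paired with a
#' tumor sample drawn uniformly at random (with replacement, so fewer tumors
#' than backgrounds is fine). Controls are the unmodified background tables.
#'
#' @param tumor_tables,background_tables named lists of single-sample
#'   `density_table`s.
#' @param ratio,depth,count_mode passed to [spike_in()].
#' @param seed required integer seed.
#' @return list with `cases`, `controls` (named lists of tables), `labels`
#'   (named vector), and `pairing` (background id -> tumor id).
#' @export
build_spikein_cohort <- function(tumor_tables, background_tables, ratio,
                                 depth, seed, count_mode = "fixed") {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  bg_ids <- names(background_tables)
  tumor_pick <- sample(names(tumor_tables), length(bg_ids), replace = TRUE)
  sub_seeds <- sample.int(.Machine$integer.max, length(bg_ids))
  cases <- stats::setNames(lapply(seq_along(bg_ids), function(i) {
    spike_in(tumor_tables[[tumor_pick[i]]], background_tables[[bg_ids[i]]],
             ratio, depth, seed = sub_seeds[i],
             sample_id = paste0("spike_", bg_ids[i]), count_mode = count_mode)
  }), paste0("spike_", bg_ids))
  labels <- c(stats::setNames(rep("case", length(cases)), names(cases)),
              stats::setNames(rep("control", length(bg_ids)), bg_ids))
  list(cases = cases, controls = background_tables, labels = labels,
       pairing = stats::setNames(tumor_pick, bg_ids))
}

#' @noRd
.default_depth <- function(ratio, depths = c(100, 1000, 10000)) {
  ok <- depths[depths * ratio >= 1]
  if (length(ok)) min(ok) else max(depths)
}

#' In-silico dilution experiment
#'
#' For each dilution ratio and iteration: build a spike-in cohort, score all
#' samples over the MD grid, and record (i) the best AUC attained by any
#' density cutoff and (ii) the mean-locus-methylation AUC. Summaries report
#' the mean AUC per ratio with a percentile 95% CI over iterations.
#'
#' @param tumor_tables,background_tables named lists of single-sample tables.
#' @param ratios tumor fractions to simulate.
#' @param n_iterations replicates per ratio (50 in the original design).
#' @param depth reads per simulated sample; `NULL` picks the smallest of
#'   100/1000/10000 with `depth * ratio >= 1`.
#' @param grid MD cutoffs for scoring.
#' @param seed required integer seed.
#' @param count_mode passed to [spike_in()].
#' @return list with `iterations` (tidy data frame: ratio, iteration, depth,
#'   auc_epiclass, best_md, auc_mean_meth) and `summary` (per-ratio means and
#'   95% CIs).
#' @export
dilution_experiment <- function(tumor_tables, background_tables, ratios,
                                n_iterations = 50, depth = NULL,
                                grid = md_grid(), seed,
                                count_mode = "fixed") {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  master <- sample.int(.Machine$integer.max, length(ratios) * n_iterations)
  rows <- list()
  k <- 0L
  for (ri in seq_along(ratios)) {
    ratio <- ratios[ri]
    d <- if (is.null(depth)) .default_depth(ratio) else depth
    for (it in seq_len(n_iterations)) {
      k <- k + 1L
      cohort <- build_spikein_cohort(tumor_tables, background_tables,
                                     ratio, d, seed = master[k],
                                     count_mode = count_mode)
      tabs <- c(cohort$cases, cohort$controls)
      sc <- score_samples(tabs, labels = cohort$labels, grid = grid)
      is_case <- sc$labels == "case"
      aucs <- vapply(seq_along(grid), function(j) {
        auc_u_statistic(sc$scores[is_case, j], sc$scores[!is_case, j])
      }, numeric(1))
      mm <- vapply(tabs, mean_locus_methylation, numeric(1))
      auc_mm <- auc_u_statistic(mm[is_case], mm[!is_case])
      best <- which.max(aucs)
      rows[[k]] <- data.frame(ratio = ratio, iteration = it, depth = d,
                              auc_epiclass = aucs[best], best_md = grid[best],
                              auc_mean_meth = auc_mm)
    }
  }
  iterations <- do.call(rbind, rows)
  summarise <- function(v) {
    q <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
    c(mean = mean(v), lower = q[1], upper = q[2])
  }
  summary <- do.call(rbind, lapply(split(iterations, iterations$ratio), function(d) {
    e <- summarise(d$auc_epiclass); m <- summarise(d$auc_mean_meth)
    data.frame(ratio = d$ratio[1], depth = d$depth[1],
               auc_epiclass_mean = e["mean"], auc_epiclass_lo = e["lower"],
               auc_epiclass_hi = e["upper"], auc_mean_meth_mean = m["mean"],
               auc_mean_meth_lo = m["lower"], auc_mean_meth_hi = m["upper"])
  }))
  rownames(summary) <- NULL
  list(iterations = iterations, summary = summary, seed = seed)
}

#' Probability that a density cutoff outperforms mean methylation
#'
#' Treats the per-iteration AUCs of a density cutoff as "case" test results
#' and the mean-methylation AUCs as "control" test results; the AUC of that
#' comparison — the Mann-Whitney probability with ties one half — is the
#' probability that the cutoff yields the higher AUC.
#'
#' @param aucs_md numeric vector (or list of vectors, one per cutoff).
#' @param aucs_mean numeric vector of mean-methylation AUCs.
#' @return probability (or named vector of probabilities).
#' @export
probability_of_improvement <- function(aucs_md, aucs_mean) {
  if (is.list(aucs_md)) {
    return(vapply(aucs_md, auc_u_statistic, numeric(1),
                  control_scores = aucs_mean))
  }
  auc_u_statistic(aucs_md, aucs_mean)
}
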