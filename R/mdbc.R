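#' Default methylation-density cutoff grid
#'
#' Candidate MD_min values from 0 to 1 in steps of `step` (default 0.05).
#'
#' @param step grid increment.
#' @return numeric vector of cutoffs.
#' @export
md_grid <- function(step = 0.05) {
  g <- seq(0, 1, by = step)
  if (g[length(g)] < 1) g <- c(g, 1)
  g
}

#' Score samples on a methylation-density cutoff grid
#'
#' For every sample and every MD cutoff, computes the epiallelic measure used
#' for classification. At `md = 0` the strict zero convention applies: only
#' fragments with density strictly above zero count, so the zero-cutoff
#' column measures "any methylation" rather than the trivial constant 1.
#'
#' Measures:
#' \describe{
#'   \item{`fraction`}{CpG-weighted epiallelic fraction C / C_tot (the
#'     sequencing default).}
#'   \item{`per_ml_count`}{passing fragments per mL of plasma; requires
#'     `normalizers`, the per-sample volume of plasma assessed (mL).}
#'   \item{`normalized_read_count`}{passing fragments over total fragments at
#'     the locus (read-count fraction).}
#' }
#'
#' @param tables a multi-sample `density_table` or a named list of
#'   single-sample tables.
#' @param labels named character/factor vector (`case`/`control`) keyed by
#'   sample id; optional, attached when given.
#' @param grid MD cutoffs; defaults to [md_grid()].
#' @param measure score type, see above.
#' @param normalizers named numeric vector of per-sample normalizing volumes
#'   (mL of plasma assessed), required for `per_ml_count`.
#' @return object of class `sample_scores`: list with `md` (grid), `scores`
#'   (samples x cutoffs matrix), `labels`, `measure`. Scores are
#'   non-increasing along each row.
#' @export
score_samples <- function(tables, labels = NULL, grid = md_grid(),
                          measure = c("fraction", "per_ml_count",
                                      "normalized_read_count"),
                          normalizers = NULL) {
  measure <- match.arg(measure)
  if (length(grid) == 0L) stop("empty md grid", call. = FALSE)
  if (is.unsorted(grid)) grid <- sort(grid)
  if (inherits(tables, "density_table")) tables <- split_samples(tables)
  ids <- names(tables)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("tables must be named by sample id", call. = FALSE)
  }
  if (measure == "per_ml_count") {
    if (is.null(normalizers) || !all(ids %in% names(normalizers))) {
      stop("per_ml_count requires a named 'normalizers' entry (mL assessed) ",
           "for every sample", call. = FALSE)
    }
  }
  raw <- vapply(ids, function(id) {
    t1 <- tables[[id]]
    vapply(grid, function(md) {
      strict <- md == 0
      pass <- .passes_md(t1$n_meth, t1$n_cpgs, md, strict = strict)
      switch(measure,
        fraction = {
          w <- t1$n_cpgs * t1$count
          sum(w[pass]) / sum(w)
        },
        per_ml_count = sum(t1$count[pass]) / normalizers[[id]],
        normalized_read_count = sum(t1$count[pass]) / sum(t1$count)
      )
    }, numeric(1))
  }, numeric(length(grid)))
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = length(grid))
  scores <- t(raw)
  dimnames(scores) <- list(ids, format(grid, trim = TRUE))
  if (!is.null(labels)) {
    labels <- as.character(labels[ids])
    if (any(is.na(labels))) stop("labels missing for some samples", call. = FALSE)
    if (!all(labels %in% c("case", "control"))) {
      stop("labels must be 'case' or 'control'", call. = FALSE)
    }
    names(labels) <- ids
  }
  structure(list(md = grid, scores = scores, labels = labels,
                 measure = measure),
            class = "sample_scores")
}

#' @export
print.sample_scores <- function(x, ...) {
  cat(sprintf("<sample_scores> %d samples x %d md cutoffs (measure=%s)\n",
              nrow(x$scores), length(x$md), x$measure))
  invisible(x)
}

#' @noRd
.require_two_classes <- function(scores) {
  if (is.null(scores$labels)) stop("labels are required", call. = FALSE)
  n_case <- sum(scores$labels == "case")
  n_ctrl <- sum(scores$labels == "control")
  if (n_case < 1L || n_ctrl < 1L) {
    stop("need at least one case and one control", call. = FALSE)
  }
  invisible(c(case = n_case, control = n_ctrl))
}

#' Build the TPR/FPR surface over (MD, EF) cutoff pairs
#'
#' For each MD cutoff the EF candidates are the full set of epiallelic
#' measures observed in the training data at that cutoff, plus `+Inf` (the
#' "no sample called positive" row, guaranteeing an FPR = 0 operating
#' point). `TPR(md, ef)` is the fraction of cases scoring at least `ef`;
#' `FPR(md, ef)` likewise for controls.
#'
#' @param scores a `sample_scores` with labels.
#' @return object of class `cutoff_grid`: tidy data frame (`md`, `ef`,
#'   `tpr`, `fpr`, `j`) plus the input metadata.
#' @export
build_cutoff_grid <- function(scores) {
  .require_two_classes(scores)
  is_case <- scores$labels == "case"
  cells <- lapply(seq_along(scores$md), function(k) {
    v <- scores$scores[, k]
    ef <- c(sort(unique(v)), Inf)
    tpr <- vapply(ef, function(e) mean(v[is_case] >= e), numeric(1))
    fpr <- vapply(ef, function(e) mean(v[!is_case] >= e), numeric(1))
    data.frame(md = scores$md[k], ef = ef, tpr = tpr, fpr = fpr,
               j = tpr - fpr)
  })
  grid <- do.call(rbind, cells)
  rownames(grid) <- NULL
  structure(list(grid = grid, md = scores$md, measure = scores$measure),
            class = "cutoff_grid")
}

#' @export
print.cutoff_grid <- function(x, ...) {
  cat(sprintf("<cutoff_grid> %d (md, ef) cells over %d md cutoffs\n",
              nrow(x$grid), length(x$md)))
  invisible(x)
}

#' Jointly optimal (MD_min, EF_min) by exhaustive Youden-J search
#'
#' Scans every (MD, EF) cell of the grid for the maximum of Youden's
#' J = TPR - FPR. All ties (within 1e-12) are reported — tied optima are
#' real, meaningful outputs, not noise — and a canonical pair is chosen as
#' the smallest MD, then the smallest EF, among the ties (favoring
#' sensitivity).
#'
#' @param grid a `cutoff_grid`.
#' @return object of class `optimal_cutoffs`: `md_star`, `ef_star` (the
#'   canonical pair), `j_star`, `tpr`, `fpr` at the canonical optimum, and
#'   `ties`, a data frame of all tied cells.
#' @export
optimize_cutoffs <- function(grid) {
  stopifnot(inherits(grid, "cutoff_grid"))
  g <- grid$grid
  j_star <- max(g$j)
  ties <- g[g$j >= j_star - 1e-12, , drop = FALSE]
  ties <- ties[order(ties$md, ties$ef), , drop = FALSE]
  rownames(ties) <- NULL
  canonical <- ties[1L, ]
  structure(list(md_star = canonical$md, ef_star = canonical$ef,
                 j_star = j_star, tpr = canonical$tpr, fpr = canonical$fpr,
                 ties = ties, measure = grid$measure),
            class = "optimal_cutoffs")
}

#' @export
print.optimal_cutoffs <- function(x, ...) {
  cat(sprintf("<optimal_cutoffs> MD_min=%.3g, EF_min=%.4g (J*=%.4g; TPR=%.3g, FPR=%.3g; %d tie(s))\n",
              x$md_star, x$ef_star, x$j_star, x$tpr, x$fpr, nrow(x$ties)))
  invisible(x)
}

#' AUC as the Mann-Whitney U statistic
#'
#' AUC is computed as U / (n1 * n2) with ties counted one half — the exact
#' probability that a randomly chosen case scores above a randomly chosen
#' control.
#'
#' @param case_scores,control_scores numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc_u_statistic <- function(case_scores, control_scores) {
  n1 <- length(case_scores); n2 <- length(control_scores)
  if (n1 < 1L || n2 < 1L) stop("both classes must be nonempty", call. = FALSE)
  r <- rank(c(case_scores, control_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' ROC curve and AUC at a fixed methylation-density cutoff
#'
#' @param scores a `sample_scores` with labels.
#' @param md one cutoff from the score grid.
#' @return list with `auc`, `points` (data frame `threshold`, `tpr`, `fpr`
#'   sweeping the observed scores), `md`.
#' @export
roc_at_md <- function(scores, md) {
  .require_two_classes(scores)
  k <- which(abs(scores$md - md) < 1e-12)
  if (length(k) != 1L) stop("md = ", md, " is not on the score grid", call. = FALSE)
  v <- scores$scores[, k]
  is_case <- scores$labels == "case"
  thr <- c(Inf, sort(unique(v), decreasing = TRUE))
  pts <- data.frame(
    threshold = thr,
    tpr = vapply(thr, function(e) mean(v[is_case] >= e), numeric(1)),
    fpr = vapply(thr, function(e) mean(v[!is_case] >= e), numeric(1))
  )
  list(auc = auc_u_statistic(v[is_case], v[!is_case]), points = pts, md = md)
}

#' Stratified bootstrap confidence interval for an AUC
#'
#' Cases and controls are resampled independently (stratified bootstrap,
#' default 2000 replicates); the percentile interval of the replicate AUCs is
#' returned.
#'
#' @param case_scores,control_scores score vectors.
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @param seed required integer seed (reproducibility is contractual).
#' @return list `auc`, `lower`, `upper`, `n_boot`.
#' @export
auc_bootstrap_ci <- function(case_scores, control_scores, n_boot = 2000,
                             conf = 0.95, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(i) {
    auc_u_statistic(sample(case_scores, replace = TRUE),
                    sample(control_scores, replace = TRUE))
  }, numeric(1))
  q <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       names = FALSE)
  list(auc = auc_u_statistic(case_scores, control_scores),
       lower = q[1], upper = q[2], n_boot = n_boot)
}

#' Classification performance profile across the MD grid
#'
#' One row per MD cutoff: the ROC AUC of the scores at that cutoff, and the
#' TPR, 1 - FPR and Youden J at the cutoff's best EF. The row attaining the
#' global J maximum is flagged. The `md = 0` row is the mean-methylation
#' proxy baseline (strict zero scoring counts all methylated fragments).
#'
#' @param scores a `sample_scores` with labels.
#' @return data frame `md`, `auc`, `tpr`, `one_minus_fpr`, `j`, `optimal`.
#' @export
performance_profile <- function(scores) {
  .require_two_classes(scores)
  grid <- build_cutoff_grid(scores)
  g <- grid$grid
  rows <- lapply(scores$md, function(md) {
    gm <- g[g$md == md, , drop = FALSE]
    best <- gm[which.max(gm$j), ]
    data.frame(md = md, auc = roc_at_md(scores, md)$auc,
               tpr = best$tpr, one_minus_fpr = 1 - best$fpr, j = best$j)
  })
  out <- do.call(rbind, rows)
  out$optimal <- out$j >= max(out$j) - 1e-12
  rownames(out) <- NULL
  out
}

#' Classify a sample with fixed cutoffs
#'
#' A sample is positive if at least `ef_star` of its fragments (in the chosen
#' measure) are methylated at a density at or above `md_star`.
#'
#' @param table single-sample `density_table`.
#' @param md_star methylation-density cutoff.
#' @param ef_star epiallelic-fraction cutoff (same units as `measure`).
#' @param measure score measure, as in [score_samples()].
#' @param normalizer volume assessed (mL), for `per_ml_count`.
#' @return `"positive"` or `"negative"`, with the score as attribute.
#' @export
classify <- function(table, md_star, ef_star,
                     measure = c("fraction", "per_ml_count",
                                 "normalized_read_count"),
                     normalizer = NULL) {
  measure <- match.arg(measure)
  id <- unique(table$sample_id)
  tabs <- stats::setNames(list(one_sample(table)), id)
  norm <- if (!is.null(normalizer)) stats::setNames(normalizer, id)
  s <- score_samples(tabs, grid = md_star, measure = measure,
                     normalizers = norm)
  val <- s$scores[1, 1]
  out <- if (val >= ef_star) "positive" else "negative"
  attr(out, "score") <- val
  out
}

#' Baseline scores: mean methylation and an MSP-like count
#'
#' `mean_meth` is the weighted mean locus methylation; `msp_like` is the
#' CpG-weighted fraction of fragments with density >= 0.95, emulating
#' methylation-specific PCR which only detects heavily methylated molecules.
#'
#' @param table single-sample `density_table`.
#' @return named numeric vector `mean_meth`, `msp_like`.
#' @export
baseline_scores <- function(table) {
  t1 <- one_sample(table)
  c(mean_meth = mean_locus_methylation(t1),
    msp_like = epiallelic_fraction(t1, 0.95, weighting = "cpg_weighted"))
}

#' Published cutoff presets
#'
#' Optimal cutoffs reported for the ZNF154 locus in the original cohorts,
#' shipped as named presets for reuse. They are data, not defaults: nothing
#' in the package applies them unless asked.
#'
#' @return data frame of presets with columns `preset`, `md_star`,
#'   `ef_star`, `measure`, `note`.
#' @export
epiclass_presets <- function() {
  data.frame(
    preset = c("znf154_plasma_dreaming", "hcc_plasma_wgbs"),
    md_star = c(0.60, 0.45),
    ef_star = c(6.7, NA),
    measure = c("per_ml_count", "normalized_read_count"),
    note = c("plasma DREAMing training cohort: 60% density, 6.7 epialleles/mL",
             "WGBS plasma marker training: 45% density; EF learned per split"),
    stringsAsFactors = FALSE
  )
}
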