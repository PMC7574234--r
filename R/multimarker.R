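#' Construct a beta-value matrix object
#'
#' Array-style methylation data: probes x samples beta values in `[0, 1]`,
#' probe genomic coordinates, and a class per sample (`tumor`, `normal`,
#' `plasma`). Tumor/normal pairing (for paired differences) is positional by
#' default or given explicitly.
#'
#' @param values numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param probe_info data frame `probe_id`, `chrom`, `start`, `end`
#'   (1-based).
#' @param sample_class named character vector over samples.
#' @param pairs optional data frame `tumor_id`, `normal_id`; defaults to
#'   pairing tumors and normals in column order.
#' @return object of class `beta_matrix`.
#' @export
beta_matrix <- function(values, probe_info, sample_class, pairs = NULL) {
  if (any(values < 0 | values > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]", call. = FALSE)
  }
  if (!all(rownames(values) %in% probe_info$probe_id)) {
    stop("every probe needs coordinates in probe_info", call. = FALSE)
  }
  sample_class <- sample_class[colnames(values)]
  if (any(is.na(sample_class))) stop("sample_class missing entries", call. = FALSE)
  if (is.null(pairs)) {
    tum <- names(sample_class)[sample_class == "tumor"]
    nor <- names(sample_class)[sample_class == "normal"]
    n <- min(length(tum), length(nor))
    pairs <- data.frame(tumor_id = tum[seq_len(n)], normal_id = nor[seq_len(n)])
  }
  structure(list(values = values, probe_info = probe_info,
                 sample_class = sample_class, pairs = pairs),
            class = "beta_matrix")
}

#' Read a beta matrix from TSV/CSV plus a sample sheet
#'
#' @param values_path probe x sample table (first column probe id).
#' @param probe_path probe coordinate table (`probe_id`, `chrom`, `start`,
#'   `end`).
#' @param sheet_path sample sheet (`sample_id`, `class`).
#' @param sep field separator (default tab).
#' @return a `beta_matrix`.
#' @export
read_beta_matrix <- function(values_path, probe_path, sheet_path, sep = "\t") {
  v <- utils::read.table(values_path, sep = sep, header = TRUE,
                         row.names = 1, check.names = FALSE)
  p <- utils::read.table(probe_path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE)
  s <- utils::read.table(sheet_path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE)
  beta_matrix(as.matrix(v), p, stats::setNames(s$class, s$sample_id))
}

#' Select hypermethylated marker probes
#'
#' Filters probes, then ranks the survivors by the median paired
#' tumor-minus-normal beta difference, descending. A probe survives when it
#' (1) is not on the SNP blocklist, (2) has maximum beta below 0.2 across
#' all normals (quiet in healthy tissue), (3) is hypermethylated in tumors
#' (positive median paired difference), and (4) overlaps a candidate region.
#'
#' @param beta a `beta_matrix`.
#' @param k number of top probes to return; if more than pass, all passing
#'   probes are returned with a warning.
#' @param candidate_regions list of [marker_region()]s (or `NULL` to skip
#'   the region filter).
#' @param snp_blocklist character vector of probe ids to exclude (external
#'   annotation; none is bundled).
#' @param max_normal_beta normal-tissue ceiling (default 0.2).
#' @return data frame `probe_id`, `median_paired_diff`, `max_normal_beta`,
#'   ranked; zero rows (with a warning) when nothing passes.
#' @export
select_markers <- function(beta, k, candidate_regions = NULL,
                           snp_blocklist = character(0),
                           max_normal_beta = 0.2) {
  v <- beta$values
  cls <- beta$sample_class
  normals <- names(cls)[cls == "normal"]
  keep <- !(rownames(v) %in% snp_blocklist)
  max_norm <- apply(v[, normals, drop = FALSE], 1, max, na.rm = TRUE)
  keep <- keep & (max_norm < max_normal_beta)
  diff <- apply(v, 1, function(row) {
    stats::median(row[beta$pairs$tumor_id] - row[beta$pairs$normal_id],
                  na.rm = TRUE)
  })
  keep <- keep & (diff > 0)
  if (!is.null(candidate_regions)) {
    pi <- beta$probe_info[match(rownames(v), beta$probe_info$probe_id), ]
    in_region <- vapply(seq_len(nrow(pi)), function(i) {
      any(vapply(candidate_regions, function(r) {
        pi$chrom[i] == r$chrom && pi$end[i] >= r$start1 && pi$start[i] <= r$end1
      }, logical(1)))
    }, logical(1))
    keep <- keep & in_region
  }
  out <- data.frame(probe_id = rownames(v)[keep],
                    median_paired_diff = diff[keep],
                    max_normal_beta = max_norm[keep])
  out <- out[order(-out$median_paired_diff, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning("no probe passed the marker filters", call. = FALSE)
    return(out)
  }
  if (k > nrow(out)) {
    warning(sprintf("requested k = %d but only %d probes pass; returning all",
                    k, nrow(out)), call. = FALSE)
    return(out)
  }
  out[seq_len(k), , drop = FALSE]
}

#' Stratified repeated train/test splits
#'
#' @param sample_ids character vector of sample ids.
#' @param labels named `case`/`control` vector over the ids.
#' @param n_runs number of independent splits (default 10).
#' @param train_fraction fraction per class assigned to training (default
#'   0.5; odd class sizes differ by one between partitions).
#' @param seed required integer seed.
#' @return object of class `split_plan`: list of runs, each with `train` and
#'   `test` id vectors.
#' @export
make_splits <- function(sample_ids, labels, n_runs = 10,
                        train_fraction = 0.5, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  labels <- labels[sample_ids]
  if (any(is.na(labels))) stop("labels missing for some ids", call. = FALSE)
  set.seed(seed)
  runs <- lapply(seq_len(n_runs), function(i) {
    train <- unlist(lapply(split(sample_ids, labels), function(ids) {
      sample(ids, round(length(ids) * train_fraction))
    }), use.names = FALSE)
    list(train = sort(train), test = sort(setdiff(sample_ids, train)))
  })
  structure(list(runs = runs, n_runs = n_runs,
                 train_fraction = train_fraction, seed = seed),
            class = "split_plan")
}

# ---- linear SVM (squared hinge, L2) -----------------------------------------
# No SVM library ships with the supported environment, so the linear-kernel
# model is solved directly: minimize
#   0.5 * ||w||^2 + C * sum_i max(0, 1 - y_i (w.x_i + b))^2
# by BFGS. The objective is smooth and strictly convex in w, so the fit is
# deterministic; features are standardized internally.

#' Train a linear support-vector model on per-marker scores
#'
#' Combines per-marker EpiClass scores into one decision value per sample
#' with an L2-regularized squared-hinge linear SVM. The continuous decision
#' value (signed distance to the separating hyperplane) is used for ROC
#' construction; with a single marker it is a monotone transform of that
#' marker's score.
#'
#' @param x numeric matrix, samples x markers (training scores, each marker
#'   already evaluated at its training-set-optimal MD cutoff).
#' @param labels `case`/`control` vector over the rows of `x`.
#' @param cost soft-margin constant C (conventional default 1, recorded in
#'   the model).
#' @param seed integer recorded with the model; the fit itself is
#'   deterministic.
#' @return object of class `linear_svm` with `w`, `b`, scaling, and
#'   metadata.
#' @export
train_combined <- function(x, labels, cost = 1, seed = 1L) {
  x <- as.matrix(x)
  y <- ifelse(labels == "case", 1, -1)
  if (length(unique(y)) < 2L) stop("need both classes to train", call. = FALSE)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sd, "/")
  d <- ncol(xs)
  obj <- function(th) {
    w <- th[seq_len(d)]; b <- th[d + 1L]
    m <- pmax(0, 1 - y * (xs %*% w + b))
    0.5 * sum(w^2) + cost * sum(m^2)
  }
  grad <- function(th) {
    w <- th[seq_len(d)]; b <- th[d + 1L]
    m <- pmax(0, 1 - y * (drop(xs %*% w) + b))
    gw <- w - 2 * cost * drop(t(xs) %*% (m * y))
    gb <- -2 * cost * sum(m * y)
    c(gw, gb)
  }
  fit <- stats::optim(rep(0, d + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  structure(list(w = fit$par[seq_len(d)], b = fit$par[d + 1L],
                 center = mu, scale = sd, cost = cost, seed = seed,
                 converged = fit$convergence == 0L,
                 markers = colnames(x)),
            class = "linear_svm")
}

#' @rdname train_combined
#' @param object a `linear_svm`.
#' @param newdata samples x markers matrix.
#' @param ... unused.
#' @return `predict`: numeric decision values (higher = more case-like).
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  xs <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale, "/")
  drop(xs %*% object$w + object$b)
}

#' Evaluate a model builder over repeated splits
#'
#' Calls `builder(train_ids, test_ids)` for every run of the plan; the
#' builder must return named test-set decision values. Per-run ROC curves
#' are interpolated onto a common 101-point FPR grid and averaged vertically
#' (mean curve with an SD band).
#'
#' @param plan a `split_plan`.
#' @param labels `case`/`control` named vector over all samples.
#' @param builder function `(train_ids, test_ids) -> named numeric scores`.
#' @param fpr_grid common FPR grid for vertical averaging.
#' @return list `aucs` (per run), `mean_roc` (data frame `fpr`, `tpr_mean`,
#'   `tpr_sd`), `per_run` (list of ROC point sets).
#' @export
evaluate_runs <- function(plan, labels, builder,
                          fpr_grid = seq(0, 1, length.out = 101)) {
  per_run <- lapply(plan$runs, function(run) {
    sc <- builder(run$train, run$test)
    lab <- labels[names(sc)]
    thr <- c(Inf, sort(unique(sc), decreasing = TRUE))
    tpr <- vapply(thr, function(e) mean(sc[lab == "case"] >= e), numeric(1))
    fpr <- vapply(thr, function(e) mean(sc[lab == "control"] >= e), numeric(1))
    list(auc = auc_u_statistic(sc[lab == "case"], sc[lab == "control"]),
         points = data.frame(threshold = thr, tpr = tpr, fpr = fpr))
  })
  curves <- vapply(per_run, function(r) {
    # step-function interpolation of TPR at each grid FPR
    stats::approx(r$points$fpr, r$points$tpr, xout = fpr_grid,
                  method = "constant", ties = max, yleft = 0, yright = 1,
                  rule = 2)$y
  }, numeric(length(fpr_grid)))
  list(
    aucs = vapply(per_run, `[[`, numeric(1), "auc"),
    mean_roc = data.frame(fpr = fpr_grid,
                          tpr_mean = rowMeans(curves),
                          tpr_sd = apply(curves, 1, stats::sd)),
    per_run = per_run
  )
}

#' Compare two AUC sets with a rank-sum test
#'
#' @param aucs_a,aucs_b numeric AUC vectors (e.g. from two methods over the
#'   same runs).
#' @return two-sided Wilcoxon rank-sum p-value.
#' @export
compare_auc_sets <- function(aucs_a, aucs_b) {
  if (length(unique(c(aucs_a, aucs_b))) == 1L) return(1)  # all tied: no signal
  stats::wilcox.test(aucs_a, aucs_b, exact = FALSE)$p.value
}

#' One full multimarker train/test run
#'
#' For a single split: per marker, learn the optimal MD cutoff on the
#' training samples (normalized read counts), extract every sample's score
#' at that cutoff, train the combined linear model on the training scores,
#' and return test decision values. Cutoffs are learned strictly inside the
#' training partition.
#'
#' @param marker_tables named list (one per marker) of multi-sample
#'   `density_table`s covering all samples.
#' @param labels `case`/`control` named vector.
#' @param train_ids,test_ids the split.
#' @param measure score measure (default `normalized_read_count`).
#' @param cost SVM cost.
#' @return named test decision values; attributes `md_stars` (per marker)
#'   and `model`.
#' @export
multimarker_run <- function(marker_tables, labels, train_ids, test_ids,
                            measure = "normalized_read_count", cost = 1) {
  feats <- lapply(marker_tables, function(tab) {
    tabs <- split_samples(tab)
    sc_all <- score_samples(tabs, labels = labels[names(tabs)],
                            measure = measure)
    train_sc <- sc_all
    train_sc$scores <- sc_all$scores[train_ids, , drop = FALSE]
    train_sc$labels <- sc_all$labels[train_ids]
    opt <- optimize_cutoffs(build_cutoff_grid(train_sc))
    list(md_star = opt$md_star,
         column = sc_all$scores[, which(abs(sc_all$md - opt$md_star) < 1e-12)])
  })
  md_stars <- vapply(feats, `[[`, numeric(1), "md_star")
  x <- do.call(cbind, lapply(feats, `[[`, "column"))
  colnames(x) <- names(marker_tables)
  model <- train_combined(x[train_ids, , drop = FALSE], labels[train_ids],
                          cost = cost)
  out <- predict(model, x[test_ids, , drop = FALSE])
  names(out) <- test_ids
  attr(out, "md_stars") <- md_stars
  attr(out, "model") <- model
  out
}
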