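#' Read a DREAMing melt-well table
#'
#' Expected CSV schema: one row per well with columns `sample_id`, `well_id`,
#' `peak_temp_c` (secondary melt-peak temperature in Celsius, empty/NA for
#' negative wells; several peaks in one well are separated by `;`),
#' `ge_loaded` (genomic equivalents loaded for the sample), `ge_total`
#' (beta-actin copies in the full elution) and `plasma_ml` (starting plasma
#' volume). Peak calling itself happens upstream in instrument software.
#'
#' @param path CSV file.
#' @return named list of `melt_well_set` objects, one per sample.
#' @export
read_melt_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "well_id", "peak_temp_c", "ge_loaded", "ge_total",
           "plasma_ml")
  if (!all(req %in% names(df))) {
    stop("melt table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  by_sample <- split(df, df$sample_id)
  out <- lapply(by_sample, function(d) {
    temps <- lapply(as.character(d$peak_temp_c), function(x) {
      if (is.na(x) || !nzchar(x)) return(numeric(0))
      as.numeric(strsplit(x, ";", fixed = TRUE)[[1]])
    })
    melt_well_set(sample_id = d$sample_id[1], peak_temps = temps,
                  ge_loaded = d$ge_loaded[1], ge_total = d$ge_total[1],
                  plasma_ml = d$plasma_ml[1])
  })
  out
}

#' Construct a melt-well set
#'
#' A DREAMing run partitions a plasma sample's genomic equivalents across
#' wells; each well with a methylated molecule produces a secondary melt
#' peak whose temperature encodes that molecule's methylation density.
#'
#' @param sample_id sample label.
#' @param peak_temps list (one element per well) of numeric vectors of
#'   secondary melt-peak temperatures; empty vector = negative well.
#' @param ge_loaded genomic equivalents loaded into the assay.
#' @param ge_total beta-actin copies measured in the whole elution.
#' @param plasma_ml starting plasma volume (mL).
#' @return object of class `melt_well_set`.
#' @export
melt_well_set <- function(sample_id, peak_temps, ge_loaded, ge_total,
                          plasma_ml) {
  if (plasma_ml <= 0) stop("plasma_ml must be > 0", call. = FALSE)
  if (ge_total <= 0) stop("ge_total must be > 0", call. = FALSE)
  if (ge_loaded > ge_total) {
    stop("ge_loaded cannot exceed ge_total", call. = FALSE)
  }
  lambda <- sum(lengths(peak_temps)) / max(length(peak_temps), 1L)
  if (lambda > 0.3) {
    warning(sprintf(
      "mean positive peaks per well is %.2f (> 0.3): the one-molecule-per-peak assumption may undercount; consider the Poisson occupancy correction",
      lambda), call. = FALSE)
  }
  structure(list(sample_id = sample_id, peak_temps = peak_temps,
                 ge_loaded = ge_loaded, ge_total = ge_total,
                 plasma_ml = plasma_ml),
            class = "melt_well_set")
}

#' @export
print.melt_well_set <- function(x, ...) {
  cat(sprintf("<melt_well_set> %s: %d wells, %d peaks, %g GE of %g loaded, %g mL plasma\n",
              x$sample_id, length(x$peak_temps), sum(lengths(x$peak_temps)),
              x$ge_loaded, x$ge_total, x$plasma_ml))
  invisible(x)
}

#' Bisulfite conversion-efficiency QC filter
#'
#' A sequenced amplicon pattern whose non-CpG cytosine conversion rate is
#' below the threshold is discarded (incomplete conversion inflates apparent
#' methylation). The boundary is kept: exactly 95% passes, because only
#' "less than" the threshold is discarded.
#'
#' @param patterns data frame with column `conversion_efficiency` (plus any
#'   others, e.g. `density`, `abundance`).
#' @param threshold minimum efficiency retained (default 0.95).
#' @return the retained rows.
#' @export
conversion_efficiency_filter <- function(patterns, threshold = 0.95) {
  keep <- patterns$conversion_efficiency >= threshold
  patterns[keep, , drop = FALSE]
}

#' Match sequenced methylation patterns to melt-peak temperatures by rank
#'
#' Patterns are ordered by methylation density, then abundance, descending;
#' peak temperatures are ordered descending; the two lists are paired
#' positionally (highest density to hottest peak — melt temperature rises
#' with methylation). Unmatched surplus on either side is dropped with a
#' warning.
#'
#' @param patterns data frame with columns `density` and `abundance`.
#' @param peak_temps numeric vector of peak temperatures.
#' @return data frame `temp`, `density` of matched pairs.
#' @export
rank_match <- function(patterns, peak_temps) {
  ord <- order(-patterns$density, -patterns$abundance)
  ranked <- patterns[ord, , drop = FALSE]
  temps <- sort(peak_temps, decreasing = TRUE)
  n <- min(nrow(ranked), length(temps))
  if (nrow(ranked) != length(temps)) {
    warning(sprintf("%d pattern(s) and %d temp(s): dropping %d unmatched",
                    nrow(ranked), length(temps),
                    abs(nrow(ranked) - length(temps))), call. = FALSE)
  }
  out <- cbind(temp = temps[seq_len(n)], ranked[seq_len(n), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Calibrate melt temperature to methylation density
#'
#' Ordinary least squares of density on temperature over rank-matched pairs.
#'
#' @param pairs data frame `temp`, `density` (from [rank_match()]).
#' @param n_cpgs CpG count of the amplicon, the quantization denominator
#'   (14 for the ZNF154 amplicon).
#' @return object of class `calibration_model`: `slope` (density per deg C),
#'   `intercept`, `n_cpgs`, `r_squared`, `residuals`.
#' @export
fit_temp_to_density <- function(pairs, n_cpgs = 14) {
  if (nrow(pairs) < 2L || length(unique(pairs$temp)) < 2L) {
    stop("calibration needs >= 2 pairs with distinct temperatures",
         call. = FALSE)
  }
  fit <- stats::lm(density ~ temp, data = pairs)
  structure(list(slope = unname(stats::coef(fit)["temp"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 n_cpgs = n_cpgs,
                 r_squared = summary(fit)$r.squared,
                 residuals = unname(stats::residuals(fit)),
                 slope_se = summary(fit)$coefficients["temp", "Std. Error"]),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> density = %.5f * temp + %.3f (R^2 = %.4f; lattice 1/%d)\n",
              x$slope, x$intercept, x$r_squared, x$n_cpgs))
  invisible(x)
}

#' Density quantization step of an amplicon
#'
#' Each additional methylated CpG raises the per-molecule density by one
#' lattice step, `1 / n_cpgs` (about 7% for a 14-CpG amplicon), so converted
#' densities are rounded to this lattice; there are `n_cpgs + 1` attainable
#' values.
#'
#' @param n_cpgs CpG count of the amplicon.
#' @return the lattice step `1 / n_cpgs`.
#' @export
quantization_step <- function(n_cpgs) {
  if (n_cpgs < 1) stop("n_cpgs must be >= 1", call. = FALSE)
  1 / n_cpgs
}

#' Convert melt-peak temperatures to quantized methylation densities
#'
#' Applies the calibration line, clips to `[0, 1]`, then rounds to the
#' nearest multiple of `1 / n_cpgs`. Half-way cases round up (deterministic;
#' documented rather than banker's rounding).
#'
#' @param model a `calibration_model`.
#' @param temp numeric vector of peak temperatures.
#' @return quantized densities on the `k / n_cpgs` lattice.
#' @export
temp_to_density <- function(model, temp) {
  raw <- pmin(pmax(model$slope * temp + model$intercept, 0), 1)
  floor(raw * model$n_cpgs + 0.5) / model$n_cpgs
}

#' Normalize epiallele counts to counts per mL of plasma
#'
#' The plasma volume actually assessed is the loaded fraction of the elution
#' times the starting plasma volume:
#' `(ge_loaded / ge_total) * plasma_ml`. Counts are divided by this volume.
#'
#' @param counts numeric epiallele counts (scalar or vector, e.g. counts per
#'   density).
#' @param well_set a `melt_well_set` carrying the loading metadata.
#' @return counts per mL of plasma.
#' @export
epialleles_per_ml <- function(counts, well_set) {
  v <- volume_assessed(well_set)
  counts / v
}

#' @rdname epialleles_per_ml
#' @export
volume_assessed <- function(well_set) {
  (well_set$ge_loaded / well_set$ge_total) * well_set$plasma_ml
}

#' Reduce a melt-well set to a density table
#'
#' Each secondary melt peak is one methylated epiallele at its converted,
#' quantized density; the unmethylated background accounts for the remaining
#' genomic equivalents loaded (density 0). The result uses the package's
#' density-table interchange format, so melt data feed the classifier
#' unchanged; `n_cpgs` is the amplicon CpG count for every row.
#'
#' @param well_set a `melt_well_set`.
#' @param model a `calibration_model`.
#' @param poisson_correction if `TRUE`, the count of methylated molecules is
#'   corrected for multi-molecule wells via the Poisson occupancy estimate
#'   `-n_wells * log(fraction of negative wells)` (an extension beyond the
#'   one-peak-one-molecule reading; off by default).
#' @return a single-sample `density_table`.
#' @export
melt_to_density_table <- function(well_set, model, poisson_correction = FALSE) {
  temps <- unlist(well_set$peak_temps)
  dens <- if (length(temps)) temp_to_density(model, temps) else numeric(0)
  n_meth_units <- as.integer(round(dens * model$n_cpgs))
  pos <- table(n_meth_units)
  counts <- data.frame(n_meth = as.integer(names(pos)),
                       count = as.integer(pos))
  counts <- counts[counts$n_meth > 0, , drop = FALSE]
  if (poisson_correction && length(well_set$peak_temps) > 0) {
    n_wells <- length(well_set$peak_temps)
    neg <- sum(lengths(well_set$peak_temps) == 0L)
    if (neg > 0 && neg < n_wells && sum(counts$count) > 0) {
      est <- -n_wells * log(neg / n_wells)
      counts$count <- as.integer(round(counts$count * est / sum(counts$count)))
    }
  }
  n_background <- max(well_set$ge_loaded - sum(counts$count), 0)
  tab <- rbind(
    if (n_background > 0)
      data.frame(n_meth = 0L, count = as.integer(n_background)) else NULL,
    counts
  )
  density_table(data.frame(sample_id = well_set$sample_id,
                           n_meth = tab$n_meth, n_cpgs = model$n_cpgs,
                           count = tab$count))
}

#' Mean-methylation proxy for DREAMing samples
#'
#' The fraction of assessed genomic equivalents that carry any methylation
#' (density strictly above 0). Because every molecule of the amplicon covers
#' the same CpGs, this fraction is proportional to the mean locus
#' methylation, and coincides with the CpG-weighted epiallelic fraction at a
#' strict zero cutoff.
#'
#' @param table single-sample `density_table` from
#'   [melt_to_density_table()].
#' @return fraction in `[0, 1]`.
#' @export
dreaming_mean_methylation_proxy <- function(table) {
  epiallelic_fraction(table, 0, weighting = "read_count", zero_mode = "strict")
}
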