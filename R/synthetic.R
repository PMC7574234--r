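#' Specification of a synthetic epiallele cohort
#'
#' The generative family is beta-binomial: each read draws a latent
#' methylation density from a class mixture, then its methylated-CpG count
#' from Binomial(n_cpgs, density). The background mixture is a point mass at
#' zero plus a low-density Beta component (the near-zero mode with
#' low-density noise seen in healthy cfDNA); cases add, with probability
#' `tumor_fraction`, a high-density Beta component (rare, densely methylated
#' tumor-derived fragments).
#'
#' Defaults describe the stated world the generators emulate: 90% fully
#' unmethylated background, 10% low-density noise with mean 0.05, tumor
#' component mean 0.85, one tumor fragment per hundred reads in cases.
#'
#' @param n_cases,n_controls cohort sizes.
#' @param reads_per_sample reads per sample.
#' @param cpgs_per_read either a single count (14 emulates a fixed-length
#'   amplicon) or an integer vector sampled uniformly per read (e.g. `4:20`
#'   for RRBS-like variable coverage).
#' @param background_mix list `weight_zero`, `low_shape1`, `low_shape2`.
#' @param tumor_mix list `fraction`, `high_shape1`, `high_shape2`.
#' @param seed required integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 20, n_controls = 20,
                        reads_per_sample = 200,
                        cpgs_per_read = 14,
                        background_mix = list(weight_zero = 0.9,
                                              low_shape1 = 1,
                                              low_shape2 = 19),
                        tumor_mix = list(fraction = 0.01,
                                         high_shape1 = 8.5,
                                         high_shape2 = 1.5),
                        seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(background_mix$weight_zero >= 0, background_mix$weight_zero <= 1,
            tumor_mix$fraction >= 0, tumor_mix$fraction <= 1,
            background_mix$low_shape1 > 0, background_mix$low_shape2 > 0,
            tumor_mix$high_shape1 > 0, tumor_mix$high_shape2 > 0)
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 reads_per_sample = reads_per_sample,
                 cpgs_per_read = cpgs_per_read,
                 background_mix = background_mix, tumor_mix = tumor_mix,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @noRd
.draw_reads <- function(n, cpgs_per_read, bg, tumor_fraction, tm) {
  n_cpgs <- if (length(cpgs_per_read) == 1L) rep(cpgs_per_read, n) else
    sample(cpgs_per_read, n, replace = TRUE)
  is_tumor <- stats::runif(n) < tumor_fraction
  is_zero <- !is_tumor & (stats::runif(n) < bg$weight_zero)
  d <- numeric(n)
  n_low <- sum(!is_tumor & !is_zero)
  d[!is_tumor & !is_zero] <- stats::rbeta(n_low, bg$low_shape1, bg$low_shape2)
  d[is_tumor] <- stats::rbeta(sum(is_tumor), tm$high_shape1, tm$high_shape2)
  data.frame(n_cpgs = n_cpgs,
             n_meth = stats::rbinom(n, n_cpgs, d),
             source = ifelse(is_tumor, "tumor", "background"))
}

#' Generate a labeled synthetic cohort with known ground truth
#'
#' @param spec a [cohort_spec()].
#' @return list: `tables` (multi-sample `density_table`), `labels` (named
#'   `case`/`control` vector), `truth` (per-sample tumor read counts and the
#'   echoed generative parameters).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  ids <- c(sprintf("case_%02d", seq_len(spec$n_cases)),
           sprintf("ctrl_%02d", seq_len(spec$n_controls)))
  labels <- stats::setNames(rep(c("case", "control"),
                                c(spec$n_cases, spec$n_controls)), ids)
  per_sample <- lapply(ids, function(id) {
    f <- if (labels[[id]] == "case") spec$tumor_mix$fraction else 0
    r <- .draw_reads(spec$reads_per_sample, spec$cpgs_per_read,
                     spec$background_mix, f, spec$tumor_mix)
    r$sample_id <- id
    r
  })
  all_reads <- do.call(rbind, per_sample)
  tables <- density_table(data.frame(sample_id = all_reads$sample_id,
                                     n_meth = all_reads$n_meth,
                                     n_cpgs = all_reads$n_cpgs, count = 1L))
  truth <- list(
    tumor_reads = vapply(split(all_reads$source == "tumor",
                               all_reads$sample_id)[ids], sum, numeric(1)),
    params = unclass(spec)
  )
  list(tables = tables, labels = labels, truth = truth)
}

#' Generate single-class source tables for spike-in simulations
#'
#' Convenience wrapper producing pure tumor-like or background-like samples
#' (the spike-in sources): tumor samples draw every read from the
#' high-density Beta component, background samples from the background
#' mixture alone.
#'
#' @param n_samples number of samples.
#' @param class `"tumor"` or `"background"`.
#' @param spec a [cohort_spec()] supplying mixture shapes, read counts and
#'   the seed.
#' @return named list of single-sample `density_table`s.
#' @export
generate_source_tables <- function(n_samples,
                                   class = c("tumor", "background"), spec) {
  class <- match.arg(class)
  set.seed(spec$seed + (class == "tumor"))
  f <- if (class == "tumor") 1 else 0
  ids <- sprintf("%s_%02d", class, seq_len(n_samples))
  out <- lapply(ids, function(id) {
    r <- .draw_reads(spec$reads_per_sample, spec$cpgs_per_read,
                     spec$background_mix, f, spec$tumor_mix)
    density_table(data.frame(sample_id = id, n_meth = r$n_meth,
                             n_cpgs = r$n_cpgs, count = 1L))
  })
  stats::setNames(out, ids)
}

#' Generate a synthetic DREAMing melt dataset with known calibration
#'
#' Methylated molecules arrive per well as Poisson(`lambda`); each draws a
#' lattice density (uniform over `1..n_cpgs / n_cpgs`) and reports a melt
#' temperature from the inverse of the true affine map
#' `density = slope * temp + intercept`, plus Gaussian noise.
#'
#' @param n_samples samples to generate.
#' @param slope,intercept true calibration (density per degree C and
#'   density at 0 C). Defaults place densities 0..1 over roughly 77-91 C.
#' @param sigma temperature noise SD (degrees C).
#' @param n_wells wells per sample.
#' @param lambda expected methylated molecules per well.
#' @param ge_per_well genomic equivalents loaded per well.
#' @param plasma_ml starting plasma volume per sample.
#' @param loaded_fraction fraction of the elution loaded.
#' @param n_cpgs amplicon CpG count.
#' @param seed required integer seed.
#' @return list: `well_sets` (named list of `melt_well_set`), `truth`
#'   (true map, per-peak true densities per sample).
#' @export
generate_melt_dataset <- function(n_samples, slope = 1 / 14, intercept = -5.5,
                                  sigma = 0.1, n_wells = 24, lambda = 0.1,
                                  ge_per_well = 400, plasma_ml = 2,
                                  loaded_fraction = 0.5, n_cpgs = 14, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  ids <- sprintf("plasma_%02d", seq_len(n_samples))
  truth_dens <- list()
  well_sets <- lapply(ids, function(id) {
    n_per_well <- stats::rpois(n_wells, lambda)
    dens <- lapply(n_per_well, function(m) {
      if (m == 0L) return(numeric(0))
      sample.int(n_cpgs, m, replace = TRUE) / n_cpgs
    })
    temps <- lapply(dens, function(d) {
      if (!length(d)) return(numeric(0))
      (d - intercept) / slope + stats::rnorm(length(d), 0, sigma)
    })
    truth_dens[[id]] <<- dens
    ge_loaded <- n_wells * ge_per_well
    melt_well_set(id, temps, ge_loaded = ge_loaded,
                  ge_total = ge_loaded / loaded_fraction,
                  plasma_ml = plasma_ml)
  })
  list(well_sets = stats::setNames(well_sets, ids),
       truth = list(slope = slope, intercept = intercept, sigma = sigma,
                    n_cpgs = n_cpgs, densities = truth_dens))
}

#' Write a melt-well set list to the melt CSV schema
#'
#' @param well_sets named list of `melt_well_set`s.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_melt_csv <- function(well_sets, path) {
  rows <- do.call(rbind, lapply(well_sets, function(ws) {
    data.frame(
      sample_id = ws$sample_id,
      well_id = sprintf("%s_w%02d", ws$sample_id, seq_along(ws$peak_temps)),
      peak_temp_c = vapply(ws$peak_temps, function(t)
        paste(format(t, digits = 10), collapse = ";"), character(1)),
      ge_loaded = ws$ge_loaded, ge_total = ws$ge_total,
      plasma_ml = ws$plasma_ml
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write epiallele records as a Bismark-style SAM fixture
#'
#' Each record becomes one single-end alignment whose XM string interleaves
#' CpG calls (`Z` methylated, `z` unmethylated) with non-cytosine positions
#' (`.`), so a record with `n_cpgs` CpGs yields a read of length
#' `2 * n_cpgs`. Reads are laid down at `pos` when given, else packed from
#' the region start.
#'
#' @param records data frame `n_meth`, `n_cpgs` and optional `pos` (1-based
#'   leftmost mapping position) and `qname`.
#' @param path output SAM path.
#' @param region a [marker_region()] providing the reference name and a
#'   header length.
#' @return `path`, invisibly.
#' @export
write_sam_fixture <- function(records, path, region) {
  ref_len <- region$end1 + 10000L
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", region$chrom, ref_len))
  lines <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    n_cpgs <- records$n_cpgs[i]
    n_meth <- records$n_meth[i]
    calls <- c(rep("Z", n_meth), rep("z", n_cpgs - n_meth))
    xm <- paste(rbind(calls, "."), collapse = "")
    seq <- paste(rbind(ifelse(calls == "Z", "C", "T"), "A"), collapse = "")
    len <- 2L * n_cpgs
    pos <- if (!is.null(records$pos)) records$pos[i] else
      region$start1 + ((i - 1L) * 4L) %% max(region$end1 - region$start1 - len, 1L)
    qname <- if (!is.null(records$qname)) records$qname[i] else
      sprintf("read_%05d", i)
    lines[i] <- paste(qname, 0L, region$chrom, pos, 42L,
                      sprintf("%dM", len), "*", 0L, 0L, seq,
                      strrep("I", len), paste0("XM:Z:", xm), sep = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Generate SAM alignment fixtures from density tables
#'
#' One SAM file per sample; a round trip through [read_epialleles()] and
#' [build_density_table()] reproduces the input tallies exactly.
#'
#' @param tables multi-sample `density_table` (or named list).
#' @param region a [marker_region()].
#' @param dir output directory (created if needed).
#' @return named character vector of SAM paths.
#' @export
generate_alignment_fixture <- function(tables, region, dir = tempfile()) {
  if (inherits(tables, "density_table")) tables <- split_samples(tables)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(tables), function(id) {
    t1 <- tables[[id]]
    recs <- t1[rep(seq_len(nrow(t1)), t1$count), c("n_meth", "n_cpgs")]
    p <- file.path(dir, paste0(id, ".sam"))
    write_sam_fixture(recs, p, region)
    p
  }, character(1))
  paths
}

#' Generate a synthetic beta matrix with planted markers
#'
#' Planted marker probes sit inside the candidate region with quiet normals
#' (beta < 0.15) and hypermethylated tumors (beta ~ 0.7-0.95). Decoys
#' include probes with one noisy normal above the 0.2 ceiling, probes
#' outside the region, and flat probes.
#'
#' @param n_probes total probes.
#' @param n_planted planted true markers.
#' @param n_pairs tumor/normal pairs.
#' @param seed required integer seed.
#' @return list: `beta` (a `beta_matrix`), `region` (candidate
#'   [marker_region()]), `truth` (planted probe ids, decoy ids).
#' @export
generate_beta_matrix <- function(n_probes = 40, n_planted = 2, n_pairs = 10,
                                 seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  probes <- sprintf("cg%08d", seq_len(n_probes))
  tum_ids <- sprintf("tumor_%02d", seq_len(n_pairs))
  nor_ids <- sprintf("normal_%02d", seq_len(n_pairs))
  v <- matrix(stats::runif(n_probes * 2 * n_pairs, 0.3, 0.5),
              nrow = n_probes, dimnames = list(probes, c(tum_ids, nor_ids)))
  planted <- probes[seq_len(n_planted)]
  v[planted, nor_ids] <- stats::runif(n_planted * n_pairs, 0, 0.15)
  v[planted, tum_ids] <- stats::runif(n_planted * n_pairs, 0.7, 0.95)
  # decoy: marker-like but one normal too high
  decoy <- probes[n_planted + 1L]
  v[decoy, nor_ids] <- stats::runif(n_pairs, 0, 0.15)
  v[decoy, tum_ids] <- stats::runif(n_pairs, 0.7, 0.95)
  v[decoy, nor_ids[1]] <- 0.3
  region <- marker_region("chr19:58220000-58220800", name = "candidate")
  inside <- c(planted, decoy)
  probe_info <- data.frame(
    probe_id = probes,
    chrom = ifelse(probes %in% inside, region$chrom, "chr1"),
    start = ifelse(probes %in% inside,
                   region$start1 + 10L * seq_len(n_probes), 1000L),
    end = ifelse(probes %in% inside,
                 region$start1 + 10L * seq_len(n_probes) + 1L, 1001L)
  )
  cls <- stats::setNames(rep(c("tumor", "normal"), each = n_pairs),
                         c(tum_ids, nor_ids))
  list(beta = beta_matrix(v, probe_info, cls), region = region,
       truth = list(planted = planted, decoy = decoy))
}
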