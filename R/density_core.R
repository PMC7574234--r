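#' Per-molecule methylation density
#'
#' The methylation density of a sequenced DNA fragment is the number of
#' methylated CpG dinucleotides out of the total CpGs covered by that
#' fragment. Vectorized over both arguments.
#'
#' @param n_meth count of methylated CpGs per read.
#' @param n_cpgs total CpGs per read; must be >= 1 (a read carrying no CpG
#'   has no defined density and must be dropped by the caller).
#' @return densities in `[0, 1]`.
#' @examples
#' methylation_density(7, 14) # 0.5
#' @export
methylation_density <- function(n_meth, n_cpgs) {
  if (any(n_cpgs < 1L)) {
    stop("n_cpgs must be >= 1: a read with no CpG-context calls has no ",
         "methylation density; drop it before calling", call. = FALSE)
  }
  if (any(n_meth < 0L) || any(n_meth > n_cpgs)) {
    stop("n_meth must satisfy 0 <= n_meth <= n_cpgs", call. = FALSE)
  }
  n_meth / n_cpgs
}

#' Construct a methylation-density table
#'
#' The density table is the central data structure of the package: a tidy
#' tally of epialleles keyed by `(n_meth, n_cpgs)` per sample. All
#' classifiers consume this table; both sequencing (SAM/BAM) and melt-curve
#' (DREAMing) inputs are reduced to it.
#'
#' @param df data frame with columns `sample_id`, `n_meth`, `n_cpgs`,
#'   `count`.
#' @return the same data, aggregated over duplicate keys, with class
#'   `density_table`.
#' @export
density_table <- function(df) {
  req <- c("sample_id", "n_meth", "n_cpgs", "count")
  if (!all(req %in% names(df))) {
    stop("density table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, req, drop = FALSE]
  df$sample_id <- as.character(df$sample_id)
  df$n_meth <- as.integer(df$n_meth)
  df$n_cpgs <- as.integer(df$n_cpgs)
  df$count <- as.integer(df$count)
  if (nrow(df)) {
    if (any(df$n_cpgs < 1L)) stop("n_cpgs must be >= 1", call. = FALSE)
    if (any(df$n_meth < 0L | df$n_meth > df$n_cpgs)) {
      stop("0 <= n_meth <= n_cpgs violated", call. = FALSE)
    }
    if (any(df$count < 0L)) stop("counts must be >= 0", call. = FALSE)
    df <- stats::aggregate(count ~ sample_id + n_meth + n_cpgs, df, sum)
    df <- df[df$count > 0L, c("sample_id", "n_meth", "n_cpgs", "count")]
    df <- df[order(df$sample_id, df$n_cpgs, df$n_meth), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("density_table", "data.frame")
  df
}

#' @export
print.density_table <- function(x, ...) {
  cat(sprintf("<density_table> %d sample(s), %d distinct (n_meth, n_cpgs) rows, %d reads\n",
              length(unique(x$sample_id)), nrow(x), sum(x$count)))
  NextMethod()
}

#' Tally epiallele records into per-sample density tables
#'
#' Records from replicate libraries of the same biological sample are pooled
#' through `pooling_map` before tallying. Samples named in the pooling map
#' (or present in the records) that end up with zero reads at the locus are
#' excluded from the table and listed in the `dropped` attribute with a
#' warning — absence at the locus is information, never silent.
#'
#' @param records data frame of epiallele records with columns `sample_id`,
#'   `n_meth`, `n_cpgs` (one row per read).
#' @param pooling_map optional named character vector mapping library ids to
#'   pooled sample ids; unmapped ids pass through unchanged.
#' @return a `density_table`; attribute `dropped` lists zero-read samples.
#' @export
build_density_table <- function(records, pooling_map = NULL) {
  expected <- character(0)
  if (!is.null(pooling_map)) expected <- unique(unname(pooling_map))
  if (nrow(records) == 0L) {
    warning("no epiallele records supplied; returning empty density table",
            call. = FALSE)
    out <- density_table(data.frame(sample_id = character(0),
                                    n_meth = integer(0), n_cpgs = integer(0),
                                    count = integer(0)))
    attr(out, "dropped") <- expected
    if (length(expected)) {
      warning("samples with zero reads at locus: ",
              paste(expected, collapse = ", "), call. = FALSE)
    }
    return(out)
  }
  ids <- as.character(records$sample_id)
  if (!is.null(pooling_map)) {
    hit <- ids %in% names(pooling_map)
    ids[hit] <- unname(pooling_map[ids[hit]])
  }
  tab <- data.frame(sample_id = ids, n_meth = records$n_meth,
                    n_cpgs = records$n_cpgs, count = 1L)
  out <- density_table(tab)
  dropped <- setdiff(expected, unique(out$sample_id))
  attr(out, "dropped") <- dropped
  if (length(dropped)) {
    warning("samples with zero reads at locus: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  out
}

#' @noRd
one_sample <- function(table, sample_id = NULL) {
  if (!is.null(sample_id)) table <- table[table$sample_id == sample_id, , drop = FALSE]
  if (nrow(table) == 0L) stop("empty density table", call. = FALSE)
  if (length(unique(table$sample_id)) > 1L) {
    stop("table holds several samples; pass sample_id", call. = FALSE)
  }
  table
}

#' Mean locus methylation (weighted methylation level)
#'
#' Total methylated CpGs over total CpGs sequenced across all reads at the
#' locus — the classical weighted methylation level, and the baseline that
#' density-cutoff classification is compared against.
#'
#' @param table a `density_table` (one sample, or pass `sample_id`).
#' @param sample_id optional sample selector.
#' @return fraction in `[0, 1]`.
#' @export
mean_locus_methylation <- function(table, sample_id = NULL) {
  t1 <- one_sample(table, sample_id)
  sum(t1$n_meth * t1$count) / sum(t1$n_cpgs * t1$count)
}

# A read of density n_meth/n_cpgs passes cutoff md iff n_meth/n_cpgs >= md.
# Comparison is done as n_meth >= md * n_cpgs with a small guard so that grid
# values such as 0.6 (not exactly representable in binary) never flip a read
# sitting exactly on the boundary.
.passes_md <- function(n_meth, n_cpgs, md, strict = FALSE) {
  eps <- 1e-9
  if (strict) n_meth > md * n_cpgs + eps else n_meth >= md * n_cpgs - eps
}

#' Epiallelic fraction at a methylation-density cutoff
#'
#' The fraction of a sample's epialleles whose methylation density meets
#' `md_cutoff`. Two weightings are supported: `read_count` (passing reads /
#' total reads) and `cpg_weighted` (CpGs covered by passing reads over total
#' CpGs, i.e. C / C_tot), which corrects for reads covering different numbers
#' of CpGs. With `zero_mode = "strict"` and `md_cutoff = 0` only fragments
#' with density strictly above zero count — the convention used when a zero
#' cutoff stands in for "any methylation at all".
#'
#' @param table a `density_table` (single sample, or use `sample_id`).
#' @param md_cutoff density cutoff in `[0, 1]`.
#' @param weighting `"cpg_weighted"` (default) or `"read_count"`.
#' @param zero_mode `"inclusive"` (density >= cutoff everywhere) or
#'   `"strict"` (at cutoff 0, require density > 0).
#' @param sample_id optional sample selector.
#' @return fraction in `[0, 1]`.
#' @export
epiallelic_fraction <- function(table, md_cutoff,
                                weighting = c("cpg_weighted", "read_count"),
                                zero_mode = c("inclusive", "strict"),
                                sample_id = NULL) {
  weighting <- match.arg(weighting)
  zero_mode <- match.arg(zero_mode)
  if (md_cutoff < 0 || md_cutoff > 1) stop("md_cutoff must be in [0, 1]", call. = FALSE)
  t1 <- one_sample(table, sample_id)
  strict <- (zero_mode == "strict" && md_cutoff == 0)
  pass <- .passes_md(t1$n_meth, t1$n_cpgs, md_cutoff, strict = strict)
  w <- if (weighting == "cpg_weighted") t1$n_cpgs * t1$count else t1$count
  sum(w[pass]) / sum(w)
}

#' Read and write density tables in the interchange CSV format
#'
#' Columns: `sample_id, n_meth, n_cpgs, count`. This is the format every
#' downstream module consumes, for sequencing- and melt-derived data alike.
#'
#' @param path CSV file.
#' @return `read_density_csv`: a `density_table`.
#' @export
read_density_csv <- function(path) {
  density_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_density_csv
#' @param table a `density_table` to serialize.
#' @export
write_density_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a multi-sample density table into per-sample tables
#'
#' @param table a `density_table`.
#' @return named list of single-sample `density_table`s.
#' @export
split_samples <- function(table) {
  lapply(split(as.data.frame(table), table$sample_id), density_table)
}
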