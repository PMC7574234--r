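#' Define a marker region
#'
#' A marker region is a genomic interval over which per-read methylation
#' densities are tallied. Coordinates are given in the 1-based fully-closed
#' convention used in region strings such as `"chr19:58220000-58220800"`;
#' internally the region is stored 0-based half-open, which makes overlap
#' arithmetic with alignment coordinates exact.
#'
#' @param region either a region string `"chrom:start-end"` (1-based, closed)
#'   or a chromosome name when `start`/`end` are given.
#' @param start,end 1-based closed interval bounds (ignored when `region`
#'   contains coordinates).
#' @param name label for the region; defaults to the region string.
#' @param overlap_mode how reads are matched to the region:
#'   `"full_containment"` keeps only reads lying entirely within the region
#'   (conservative, guarantees comparable CpG counts); `"any_overlap"` keeps
#'   any read with at least one aligned base inside. There is no silent
#'   default at the point of use: the mode travels with the region object.
#' @return an object of class `marker_region` with fields `name`, `chrom`,
#'   `start0` (0-based), `end0` (half-open exclusive), `start1`, `end1`
#'   (1-based closed, as written) and `overlap_mode`.
#' @examples
#' marker_region("chr19:58220000-58220800", overlap_mode = "any_overlap")
#' @export
marker_region <- function(region, start = NULL, end = NULL, name = NULL,
                          overlap_mode = c("full_containment", "any_overlap")) {
  overlap_mode <- match.arg(overlap_mode)
  if (grepl(":", region, fixed = TRUE)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
    if (length(m) != 4L) {
      stop("cannot parse region string '", region,
           "'; expected 'chrom:start-end'", call. = FALSE)
    }
    chrom <- m[2]
    start <- as.numeric(gsub(",", "", m[3], fixed = TRUE))
    end <- as.numeric(gsub(",", "", m[4], fixed = TRUE))
  } else {
    chrom <- region
    if (is.null(start) || is.null(end)) {
      stop("start and end are required when 'region' is a bare chromosome",
           call. = FALSE)
    }
  }
  if (!(start < end)) stop("region start must be < end", call. = FALSE)
  structure(
    list(
      name = if (is.null(name)) sprintf("%s:%d-%d", chrom, start, end) else name,
      chrom = chrom,
      start1 = as.integer(start), end1 = as.integer(end),
      start0 = as.integer(start) - 1L, end0 = as.integer(end),
      overlap_mode = overlap_mode
    ),
    class = "marker_region"
  )
}

#' @export
print.marker_region <- function(x, ...) {
  cat(sprintf("<marker_region> %s (%s:%d-%d, 1-based closed; mode=%s)\n",
              x$name, x$chrom, x$start1, x$end1, x$overlap_mode))
  invisible(x)
}

#' Read marker regions from a BED file
#'
#' BED intervals are 0-based half-open; they are converted to the package's
#' internal representation directly.
#'
#' @param path BED file (3+ columns; column 4, if present, names the region).
#' @inheritParams marker_region
#' @return list of `marker_region` objects.
#' @export
read_regions_bed <- function(path,
                             overlap_mode = c("full_containment", "any_overlap")) {
  overlap_mode <- match.arg(overlap_mode)
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(bed) < 3L) stop("BED file needs at least 3 columns", call. = FALSE)
  lapply(seq_len(nrow(bed)), function(i) {
    nm <- if (ncol(bed) >= 4L) as.character(bed[i, 4]) else NULL
    # BED start is 0-based: +1 gives the 1-based closed start
    marker_region(as.character(bed[i, 1]), start = bed[i, 2] + 1L,
                  end = bed[i, 3], name = nm, overlap_mode = overlap_mode)
  })
}

#' @noRd
region_granges <- function(region) {
  GenomicRanges::GRanges(
    region$chrom,
    IRanges::IRanges(start = region$start1, end = region$end1)
  )
}
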