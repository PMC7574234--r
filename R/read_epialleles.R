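#' Extract per-read methylation densities from a bisulfite alignment
#'
#' Reads a Bismark-style SAM/BAM file and returns one epiallele record per
#' retained DNA fragment over the marker region. Methylation calls are taken
#' from the `XM` tag (one character per read base; `Z`/`z` methylated /
#' unmethylated CpG; other contexts and `.` are ignored). The call string is
#' projected into reference space through the CIGAR, so insertions are
#' dropped and deleted positions contribute nothing — a read's CpG count is
#' the number of aligned CpG-context calls only.
#'
#' When the file carries mate information, the two mates of a pair are merged
#' into a single fragment: CpG calls are keyed by reference position and
#' deduplicated across mates (the unit of the method is the DNA molecule, not
#' the sequencing read). Retention follows the region's `overlap_mode`:
#' `any_overlap` keeps every read with at least one aligned base in the
#' region; `full_containment` keeps only reads aligned entirely within it.
#'
#' @param alignment_source path to a SAM or BAM file (SAM is converted on the
#'   fly).
#' @param region a [marker_region()]; its `overlap_mode` decides retention.
#' @param sample_id sample label attached to the records; defaults to the
#'   file name without extension.
#' @return data frame of epiallele records: `sample_id`, `n_meth`, `n_cpgs`,
#'   `density`, one row per fragment carrying at least one CpG call.
#' @export
read_epialleles <- function(alignment_source, region,
                            sample_id = NULL) {
  stopifnot(inherits(region, "marker_region"))
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(sam|bam)$", "", basename(alignment_source),
                     ignore.case = TRUE)
  }
  bam <- .as_bam(alignment_source)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!(region$chrom %in% names(hdr))) {
    stop("chromosome '", region$chrom, "' absent from alignment header of ",
         alignment_source, call. = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    tag = "XM", what = c("qname", "flag"),
    which = region_granges(region)
  )
  aln <- GenomicAlignments::readGAlignments(bam, param = param, use.names = FALSE)
  if (length(aln) == 0L) {
    return(data.frame(sample_id = character(0), n_meth = integer(0),
                      n_cpgs = integer(0), density = numeric(0)))
  }
  xm <- S4Vectors::mcols(aln)$XM
  qname <- S4Vectors::mcols(aln)$qname
  if (any(is.na(xm))) {
    bad <- qname[which(is.na(xm))[1]]
    stop("read '", bad, "' lacks the XM methylation-call tag; ",
         "input must be Bismark-style aligned bisulfite data", call. = FALSE)
  }
  if (region$overlap_mode == "full_containment") {
    keep <- GenomicAlignments::start(aln) >= region$start1 &
      GenomicAlignments::end(aln) <= region$end1
    aln <- aln[keep]
    xm <- xm[keep]
    qname <- qname[keep]
    if (length(aln) == 0L) {
      return(data.frame(sample_id = character(0), n_meth = integer(0),
                        n_cpgs = integer(0), density = numeric(0)))
    }
  }
  # project XM into reference space so indels cannot shift CpG positions
  ref_xm <- GenomicAlignments::sequenceLayer(
    Biostrings::BStringSet(xm), GenomicAlignments::cigar(aln),
    from = "query", to = "reference"
  )
  starts <- GenomicAlignments::start(aln)
  calls <- lapply(seq_along(aln), function(i) {
    s <- strsplit(as.character(ref_xm[[i]]), "", fixed = TRUE)[[1]]
    idx <- which(s %in% c("z", "Z"))
    if (!length(idx)) {
      return(data.frame(pos = integer(0), meth = logical(0)))
    }
    data.frame(pos = starts[i] + idx - 1L, meth = s[idx] == "Z")
  })
  frag <- split(seq_along(aln), qname)
  rows <- lapply(frag, function(ii) {
    cc <- do.call(rbind, calls[ii])
    if (nrow(cc) == 0L) return(NULL)
    cc <- cc[!duplicated(cc$pos), , drop = FALSE]  # first mate's call wins
    c(n_meth = sum(cc$meth), n_cpgs = nrow(cc))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(sample_id = character(0), n_meth = integer(0),
                      n_cpgs = integer(0), density = numeric(0)))
  }
  m <- do.call(rbind, rows)
  out <- data.frame(sample_id = sample_id,
                    n_meth = as.integer(m[, "n_meth"]),
                    n_cpgs = as.integer(m[, "n_cpgs"]))
  out$density <- methylation_density(out$n_meth, out$n_cpgs)
  rownames(out) <- NULL
  out
}

#' @noRd
.as_bam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!file.exists(paste0(path, ".bai"))) Rsamtools::indexBam(path)
    return(path)
  }
  dest <- tempfile(fileext = "")
  bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}
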