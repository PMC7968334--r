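# Genomic interval masks (e.g. segmental duplications) backed by IRanges.
# BED input is 0-based half-open; internally intervals are stored 1-based
# inclusive, so BED [s, e) covers VCF positions s+1 .. e.

#' Construct a genome mask from intervals
#'
#' @param chrom character vector of chromosome labels.
#' @param start,end integer vectors, 0-based half-open (BED convention).
#' @return object of class `genome_mask`.
#' @export
genome_mask <- function(chrom = character(), start = integer(), end = integer()) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(start >= end)) stop("mask intervals must satisfy start < end")
  chrom <- normalize_chrom(chrom)
  by_chrom <- split(seq_along(chrom), chrom)
  ranges <- lapply(by_chrom, function(idx)
    IRanges::IRanges(start = start[idx] + 1L, end = end[idx]))
  structure(list(ranges = ranges), class = "genome_mask")
}

#' Read a BED3+ file as a genome mask
#' @param path path to a BED file (optionally gzipped); extra columns ignored.
#' @return a [genome_mask()].
#' @export
read_bed_mask <- function(path) {
  dt <- fread(path, header = FALSE)
  if (ncol(dt) < 3L) stop("BED format error: expected >= 3 columns in ", path)
  genome_mask(as.character(dt[[1]]), as.integer(dt[[2]]), as.integer(dt[[3]]))
}

#' Does a 1-based inclusive span overlap the mask?
#'
#' @param mask a [genome_mask()].
#' @param chrom chromosome label.
#' @param start,end 1-based inclusive span (e.g. `pos .. pos + nchar(ref) - 1`).
#' @return logical.
#' @export
mask_overlaps <- function(mask, chrom, start, end = start) {
  r <- mask$ranges[[normalize_chrom(chrom)]]
  if (is.null(r)) return(FALSE)
  IRanges::countOverlaps(IRanges::IRanges(start, end), r) > 0L
}

#' Does a variant's reference span overlap the mask?
#' @param mask a [genome_mask()].
#' @param record a [variant_record()].
#' @return logical.
#' @export
mask_overlaps_record <- function(mask, record) {
  mask_overlaps(mask, record$chrom, record$pos,
                record$pos + nchar(record$ref) - 1L)
}
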