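# Transcript coverage completeness: mean depth, completeness at cutoffs and
# fully-covered transcript counts from a sparse per-interval depth track.
# Bases absent from the track count as depth 0.

#' Construct a depth track
#'
#' Intervals are 0-based half-open (BED4 convention) and must be
#' non-overlapping per chromosome.
#'
#' @param chrom,start,end,depth parallel vectors.
#' @return object of class `depth_track` (a sorted data.frame).
#' @export
depth_track <- function(chrom, start, end, depth) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(start))
  stopifnot(length(chrom) == length(start), length(start) == length(end),
            length(end) == length(depth))
  if (any(start >= end)) stop("depth track: start must be < end")
  if (any(depth < 0)) stop("depth track: depth must be >= 0")
  df <- data.frame(chrom = normalize_chrom(chrom), start = as.integer(start),
                   end = as.integer(end), depth = as.integer(depth),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, ]
    if (nrow(d) > 1L && any(d$start[-1] < d$end[-nrow(d)]))
      stop("depth track: overlapping intervals on ", ch)
  }
  rownames(df) <- NULL
  class(df) <- c("depth_track", "data.frame")
  df
}

#' Read a BED4 depth track (`chrom start end depth`)
#' @param path path (optionally gzipped).
#' @return a [depth_track()].
#' @export
read_depth_track <- function(path) {
  dt <- fread(path, header = FALSE)
  if (ncol(dt) < 4L) stop("depth track error: expected 4 columns in ", path)
  depth_track(as.character(dt[[1]]), dt[[2]], dt[[3]], dt[[4]])
}

#' Construct a transcript model
#'
#' @param transcript_id,gene identifiers.
#' @param exons `data.frame` with columns chrom, start, end (0-based
#'   half-open), non-overlapping within the transcript.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene, exons) {
  stopifnot(all(c("chrom", "start", "end") %in% names(exons)))
  exons$chrom <- normalize_chrom(exons$chrom)
  if (any(exons$start >= exons$end)) stop("transcript exons: start < end required")
  for (ch in unique(exons$chrom)) {
    e <- exons[exons$chrom == ch, ]
    e <- e[order(e$start), ]
    if (nrow(e) > 1L && any(e$start[-1] < e$end[-nrow(e)]))
      stop("transcript exons overlap within ", transcript_id)
  }
  structure(list(transcript_id = transcript_id, gene = toupper(gene),
                 exons = exons),
            class = "transcript_model")
}

# depth segments of one exon: data.frame(len, depth) covering the whole exon
exon_depth_segments <- function(track, chrom, start, end) {
  t <- track[track$chrom == chrom & track$end > start & track$start < end, ,
             drop = FALSE]
  if (nrow(t) == 0L) return(data.frame(len = end - start, depth = 0L))
  t$start <- pmax(t$start, start)
  t$end <- pmin(t$end, end)
  covered <- sum(t$end - t$start)
  out <- data.frame(len = t$end - t$start, depth = t$depth)
  if (covered < end - start)
    out <- rbind(out, data.frame(len = end - start - covered, depth = 0L))
  out
}

#' Coverage completeness of one transcript
#'
#' `completeness[c]` is the fraction of transcript bases with depth >= c;
#' `fully_covered[c]` is true when that fraction is exactly 1; the mean is
#' the length-weighted depth mean over all transcript bases (uncovered
#' bases count as depth 0).
#'
#' @param track a [depth_track()].
#' @param transcript a [transcript_model()].
#' @param cutoffs integer depth cutoffs (default `c(10, 20, 30)`).
#' @return list with `transcript_id`, `gene`, `length`, `mean_coverage`,
#'   `completeness` (named numeric) and `fully_covered` (named logical).
#' @export
completeness <- function(track, transcript, cutoffs = c(10L, 20L, 30L)) {
  ex <- transcript$exons
  total_len <- sum(ex$end - ex$start)
  if (total_len <= 0L) stop("completeness: zero-length transcript ",
                            transcript$transcript_id)
  segs <- do.call(rbind, lapply(seq_len(nrow(ex)), function(i)
    exon_depth_segments(track, ex$chrom[i], ex$start[i], ex$end[i])))
  mean_cov <- sum(as.numeric(segs$len) * segs$depth) / total_len
  comp <- vapply(cutoffs, function(cc)
    sum(segs$len[segs$depth >= cc]) / total_len, numeric(1))
  names(comp) <- as.character(cutoffs)
  list(transcript_id = transcript$transcript_id, gene = transcript$gene,
       length = total_len, mean_coverage = mean_cov,
       completeness = comp,
       fully_covered = setNames(comp == 1, names(comp)))
}

#' Panel-wide coverage report
#'
#' @param track a [depth_track()].
#' @param transcripts list of [transcript_model()] objects.
#' @param panel a [gene_panel()]; only its transcripts are reported.
#' @param cutoff reporting cutoff (default 10).
#' @return list with `table` (per-transcript data.frame) and `summary`
#'   (`n_transcripts`, `n_fully_covered`, `mean_coverage` length-weighted
#'   across the panel).
#' @export
panel_coverage_report <- function(track, transcripts, panel, cutoff = 10L) {
  sel <- Filter(function(tr) tr$gene %in% panel$genes, transcripts)
  if (!length(sel)) stop("coverage report: no transcripts in panel ",
                         panel$name)
  rows <- lapply(sel, function(tr) {
    cc <- completeness(track, tr, cutoffs = cutoff)
    data.frame(transcript_id = cc$transcript_id, gene = cc$gene,
               length = cc$length, mean_coverage = cc$mean_coverage,
               completeness = unname(cc$completeness),
               fully_covered = unname(cc$fully_covered),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       summary = list(
         cutoff = cutoff,
         n_transcripts = nrow(tab),
         n_fully_covered = sum(tab$fully_covered),
         mean_coverage = sum(tab$mean_coverage * tab$length) / sum(tab$length)))
}
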