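# Family-level QC: trio Mendelian concordance, SNP-fingerprint check,
# STR expansion classification and trio-based uniparental disomy screening.
#
# Trio genotype inputs to these functions are plain data.frames with one row
# per biallelic autosomal site: columns chrom, pos, index, mother, father
# holding alt-allele dosages (0/1/2, NA = missing). trio_genotypes() builds
# such a table from variant records.

#' Build a trio genotype table from variant records
#'
#' @param records list of [variant_record()].
#' @param ped a [pedigree()] whose index has two recorded parents.
#' @return `data.frame` with chrom, pos, index, mother, father dosages.
#' @export
trio_genotypes <- function(records, ped) {
  idx <- ped$individuals[[ped$index_id]]
  if (is.na(idx$mother_id) || is.na(idx$father_id))
    stop("trio_genotypes: index has no recorded parents")
  dose <- function(r, id) {
    call <- r$per_sample[[id]]
    if (is.null(call)) NA_integer_ else gt_dosage(call)
  }
  data.frame(
    chrom = vapply(records, `[[`, character(1), "chrom"),
    pos = vapply(records, `[[`, integer(1), "pos"),
    index = vapply(records, dose, integer(1), id = ped$index_id),
    mother = vapply(records, dose, integer(1), id = idx$mother_id),
    father = vapply(records, dose, integer(1), id = idx$father_id),
    stringsAsFactors = FALSE)
}

# possible child dosages given two parental dosages (autosomal, biallelic)
mendelian_consistent <- function(child, mother, father) {
  tm <- switch(as.character(mother), "0" = 0L, "1" = c(0L, 1L), "2" = 1L)
  tf <- switch(as.character(father), "0" = 0L, "1" = c(0L, 1L), "2" = 1L)
  child %in% unique(as.vector(outer(tm, tf, `+`)))
}

#' Trio relationship concordance from Mendelian transmission
#'
#' The Mendelian-error fraction is the share of informative sites (all three
#' members genotyped, autosomal) whose child dosage is impossible under
#' biparental transmission. Sex chromosomes and MT are excluded.
#'
#' @param geno trio genotype `data.frame` (see [trio_genotypes()]).
#' @param threshold maximum error fraction for confirmation (default 0.02).
#' @param min_sites minimum informative sites (default 200); fewer yields an
#'   inconclusive verdict, not a pass.
#' @return list with `n_informative`, `mendelian_error_fraction`,
#'   `relationship_confirmed`, `status` (`"confirmed"`, `"failed"`,
#'   `"inconclusive"`).
#' @export
trio_concordance <- function(geno, threshold = 0.02, min_sites = 200L) {
  auto <- !(normalize_chrom(geno$chrom) %in% c("X", "Y", "MT"))
  ok <- auto & !is.na(geno$index) & !is.na(geno$mother) & !is.na(geno$father)
  g <- geno[ok, , drop = FALSE]
  n <- nrow(g)
  if (n < min_sites)
    return(list(n_informative = n, mendelian_error_fraction = NA_real_,
                relationship_confirmed = FALSE, status = "inconclusive"))
  errs <- !mapply(mendelian_consistent, g$index, g$mother, g$father)
  frac <- sum(errs) / n
  list(n_informative = n, mendelian_error_fraction = frac,
       relationship_confirmed = frac <= threshold,
       status = if (frac <= threshold) "confirmed" else "failed")
}

#' Compare WGS genotypes against an orthogonal fingerprint panel
#'
#' @param wgs,array named vectors of genotype strings or dosages over the
#'   fingerprint sites (names = site ids); `NA` = no call in that source.
#' @param min_sites minimum comparable sites (default 30); fewer is
#'   inconclusive.
#' @param match_threshold minimum match fraction for a pass (default 0.95).
#' @return list with `n_compared`, `n_match`, `match_fraction`, `verdict`
#'   (`"pass"`, `"fail"`, `"inconclusive"`).
#' @export
fingerprint_check <- function(wgs, array, min_sites = 30L,
                              match_threshold = 0.95) {
  sites <- intersect(names(wgs), names(array))
  w <- wgs[sites]; a <- array[sites]
  comparable <- !is.na(w) & !is.na(a)
  n <- sum(comparable)
  if (n < min_sites)
    return(list(n_compared = n, n_match = NA_integer_,
                match_fraction = NA_real_, verdict = "inconclusive"))
  n_match <- sum(w[comparable] == a[comparable])
  frac <- n_match / n
  list(n_compared = n, n_match = n_match, match_fraction = frac,
       verdict = if (frac >= match_threshold) "pass" else "fail")
}

#' Read an STR catalog TSV
#'
#' Columns: locus_id, gene, repeat_unit, normal_max, pathologic_min,
#' inheritance (AD/AR/XR). The shipped catalog
#' (`system.file("extdata", "str_catalog.tsv", package = "clinwgs")`) is an
#' editable example with no claim of matching any production thresholds.
#'
#' @param path path to the TSV.
#' @return `data.frame` catalog.
#' @export
read_str_catalog <- function(path) {
  dt <- as.data.frame(fread(path, header = TRUE, sep = "\t"))
  req <- c("locus_id", "gene", "repeat_unit", "normal_max", "pathologic_min",
           "inheritance")
  if (!all(req %in% names(dt)))
    stop("STR catalog error: expected columns ", paste(req, collapse = ", "))
  if (any(dt$normal_max >= dt$pathologic_min))
    stop("STR catalog error: normal_max must be < pathologic_min")
  dt
}

#' Classify STR allele sizes against a catalog
#'
#' Per-allele status: `normal` (size <= normal_max), `expanded`
#' (size >= pathologic_min), else `intermediate`. The case-level
#' `reportable` flag is true when an AD locus has at least one expanded
#' allele, an AR locus has two expanded alleles, or an XR locus has all
#' (one hemizygous or two) alleles expanded.
#'
#' @param call list with `locus_id` and `allele_sizes` (one or two repeat
#'   counts).
#' @param catalog a [read_str_catalog()] data.frame.
#' @return list with `locus_id`, `statuses`, `reportable`.
#' @export
classify_str <- function(call, catalog) {
  row <- catalog[catalog$locus_id == call$locus_id, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("STR error: unknown locus '", call$locus_id, "'; catalog has: ",
         paste(catalog$locus_id, collapse = ", "))
  sizes <- as.integer(call$allele_sizes)
  stopifnot(all(sizes >= 0L))
  statuses <- ifelse(sizes <= row$normal_max, "normal",
                     ifelse(sizes >= row$pathologic_min, "expanded",
                            "intermediate"))
  n_exp <- sum(statuses == "expanded")
  reportable <- switch(row$inheritance,
    AD = n_exp >= 1L,
    AR = n_exp >= 2L,
    XR = n_exp == length(sizes) && n_exp >= 1L,
    stop("STR catalog error: inheritance must be AD/AR/XR"))
  list(locus_id = call$locus_id, statuses = statuses, reportable = reportable)
}

# runs of child homozygosity: >= min_run_sites consecutive homozygous sites
# spanning >= min_run_bp
roh_fraction <- function(pos, child, min_run_sites = 50L, min_run_bp = 1e6) {
  ord <- order(pos)
  pos <- pos[ord]; child <- child[ord]
  hom <- child %in% c(0L, 2L)
  r <- rle(hom)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  span_total <- 0
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] < min_run_sites) next
    span <- pos[ends[k]] - pos[starts[k]]
    if (span >= min_run_bp) span_total <- span_total + span
  }
  denom <- max(pos) - min(pos)
  if (denom <= 0) 0 else span_total / denom
}

#' Screen a trio for uniparental disomy on one chromosome
#'
#' Signal sites are opposite-homozygote-parent sites (one parent 0/0, the
#' other 1/1) where the child is homozygous instead of the obligate
#' heterozygote; the parent of origin is the one whose allele the child is
#' homozygous for. A call is emitted when at least `min_signal` signal sites
#' exist and the fraction of opposite-homozygote sites signalling toward one
#' parent is at least `signal_threshold`. Subtype is isodisomy-suggestive
#' when the chromosome's run-of-homozygosity fraction reaches `roh_threshold`,
#' else heterodisomy-suggestive when the child/other-parent duo shows at
#' least `min_signal` Mendelian-inconsistent sites, else undetermined.
#' The statistic and thresholds are this package's own design.
#'
#' @param geno trio genotype `data.frame` (see [trio_genotypes()]).
#' @param chrom chromosome to screen.
#' @param min_informative minimum opposite-homozygote sites to attempt a
#'   screen (default 10).
#' @param min_signal minimum signal sites for a call (default 10).
#' @param signal_threshold minimum one-parent signal fraction (default 0.9).
#' @param roh_threshold ROH fraction for the isodisomy subtype (default 0.8).
#' @return an `upd_call` list (`chrom`, `parent_of_origin`, `subtype`,
#'   `n_signal_sites`, `signal_fraction`) or `NULL` when no call.
#' @export
detect_upd <- function(geno, chrom, min_informative = 10L, min_signal = 10L,
                       signal_threshold = 0.9, roh_threshold = 0.8) {
  g <- geno[normalize_chrom(geno$chrom) == normalize_chrom(chrom) &
              !is.na(geno$index) & !is.na(geno$mother) & !is.na(geno$father), ,
            drop = FALSE]
  opp <- (g$mother == 0L & g$father == 2L) | (g$mother == 2L & g$father == 0L)
  n_opp <- sum(opp)
  if (n_opp < min_informative) return(NULL)
  go <- g[opp, , drop = FALSE]
  hom <- go$index %in% c(0L, 2L)
  toward_mother <- hom & go$index == go$mother
  toward_father <- hom & go$index == go$father
  n_m <- sum(toward_mother); n_f <- sum(toward_father)
  n_signal <- n_m + n_f
  if (n_signal < min_signal) return(NULL)
  parent <- if (n_m >= n_f) "maternal" else "paternal"
  frac <- max(n_m, n_f) / n_opp
  if (frac < signal_threshold) return(NULL)
  roh <- roh_fraction(g$pos, g$index)
  subtype <- if (roh >= roh_threshold) {
    "isodisomy_suggestive"
  } else {
    other <- if (parent == "maternal") g$father else g$mother
    # duo inconsistency: child homozygous for an allele the other parent
    # provably lacks
    duo_bad <- (g$index == 2L & other == 0L) | (g$index == 0L & other == 2L)
    if (sum(duo_bad) >= min_signal) "heterodisomy_suggestive" else "undetermined"
  }
  structure(list(chrom = normalize_chrom(chrom), parent_of_origin = parent,
                 subtype = subtype, n_signal_sites = n_signal,
                 signal_fraction = frac, roh_fraction = roh),
            class = "upd_call")
}
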