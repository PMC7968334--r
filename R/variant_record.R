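#' @importFrom data.table fread fwrite data.table as.data.table setorder :=
#' @importFrom stats setNames rbinom runif
#' @importFrom utils head tail
NULL

# -- chromosome handling ------------------------------------------------------

#' Normalize a chromosome label
#'
#' Strips a leading "chr" prefix and maps the common mitochondrial aliases
#' ("M", "chrM") to "MT". Both dialects are accepted on read; all internal
#' keys use the bare labels.
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @export
normalize_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom))
  x[x == "M"] <- "MT"
  x
}

# hg19 pseudoautosomal regions on X (1-based, inclusive)
PAR_REGIONS <- list(c(60001L, 2699520L), c(154931044L, 155260560L))

#' Is a chrX position inside a pseudoautosomal region?
#'
#' Variants in PAR1/PAR2 behave as autosomal (diploid in both sexes).
#'
#' @param chrom chromosome label (any dialect).
#' @param pos 1-based position.
#' @return logical.
#' @export
in_par <- function(chrom, pos) {
  if (normalize_chrom(chrom) != "X") return(FALSE)
  any(vapply(PAR_REGIONS, function(r) pos >= r[1] && pos <= r[2], logical(1)))
}

# -- sample-level call --------------------------------------------------------

#' Per-sample genotype call
#'
#' @param gt integer vector of allele indices (0 = ref, 1 = alt), length 2 for
#'   diploid, length 1 for hemizygous, or `NA` when the genotype is missing.
#' @param dp read depth (`NA` when absent; missing never defaults to 0).
#' @param gq genotype quality (`NA` when absent).
#' @param ad integer vector `c(ref_depth, alt_depth)` or `NULL`.
#' @param phased logical; was the genotype phased ("|" separator).
#' @return an object of class `sample_call`.
#' @export
sample_call <- function(gt = NA_integer_, dp = NA_integer_, gq = NA_integer_,
                        ad = NULL, phased = FALSE) {
  if (!is.null(ad)) {
    ad <- as.integer(ad)
    stopifnot(all(ad >= 0L, na.rm = TRUE))
  }
  structure(list(gt = as.integer(gt), dp = as.integer(dp), gq = as.integer(gq),
                 ad = ad, phased = isTRUE(phased)),
            class = "sample_call")
}

#' Alt-allele dosage of a call
#'
#' Number of alternate alleles carried (0/1/2 diploid, 0/1 hemizygous);
#' `NA` when any allele is missing.
#'
#' @param call a [sample_call()].
#' @return integer or `NA`.
#' @export
gt_dosage <- function(call) {
  g <- call$gt
  if (length(g) == 0L || anyNA(g)) return(NA_integer_)
  sum(g == 1L)
}

#' Does a call carry at least one alternate allele?
#' @param call a [sample_call()].
#' @return logical, `NA` when the genotype is missing.
#' @export
gt_carrier <- function(call) {
  d <- gt_dosage(call)
  if (is.na(d)) NA else d >= 1L
}

is_genotyped <- function(call) !is.null(call) && !anyNA(call$gt) && length(call$gt) > 0L

# -- annotations --------------------------------------------------------------

#' Variant annotation set
#'
#' @param gene_symbols character vector of gene symbols (uppercased).
#' @param consequence most-severe consequence term or `NA`.
#' @param population_af population allele fraction in `[0, 1]` or `NA`.
#' @param conservation_score,deleteriousness_score numeric or `NA`.
#' @param clinical_significance term or `NA`.
#' @param local_obs integer count of observing families or `NA`.
#' @param local_frequency local cohort frequency or `NA`.
#' @param artifact logical local-artifact flag.
#' @param inspection_status one of `"good"`, `"uncertain"`, `"bad"`, `"unset"`.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(gene_symbols = character(), consequence = NA_character_,
                           population_af = NA_real_, conservation_score = NA_real_,
                           deleteriousness_score = NA_real_,
                           clinical_significance = NA_character_,
                           local_obs = NA_integer_, local_frequency = NA_real_,
                           artifact = FALSE, inspection_status = "unset") {
  if (!is.na(population_af) && (population_af < 0 || population_af > 1))
    stop("population_af must lie in [0, 1]")
  inspection_status <- match.arg(inspection_status,
                                 c("unset", "good", "uncertain", "bad"))
  structure(list(gene_symbols = toupper(as.character(gene_symbols)),
                 consequence = consequence, population_af = population_af,
                 conservation_score = conservation_score,
                 deleteriousness_score = deleteriousness_score,
                 clinical_significance = clinical_significance,
                 local_obs = as.integer(local_obs),
                 local_frequency = local_frequency,
                 artifact = isTRUE(artifact),
                 inspection_status = inspection_status),
            class = "annotation_set")
}

# -- variant record -----------------------------------------------------------

classify_variant <- function(chrom, ref, alt) {
  chrom <- normalize_chrom(chrom)
  if (chrom == "MT") return("MT")
  if (grepl("^<STR", alt)) return("STR")
  if (grepl("^<", alt) || grepl("\\[|\\]", alt)) return("SV")
  if (nchar(ref) == 1L && nchar(alt) == 1L) "SNV" else "INDEL"
}

#' One normalized biallelic variant call
#'
#' Multi-allelic sites are split on ingest; each record carries exactly one
#' alternate allele. Chromosome labels are stored without a "chr" prefix.
#'
#' @param chrom chromosome label.
#' @param pos 1-based position.
#' @param ref,alt reference and (single) alternate allele strings.
#' @param filter_status upstream caller FILTER string (e.g. `"PASS"`).
#' @param per_sample named list mapping sample id to [sample_call()].
#' @param annotations an [annotation_set()].
#' @param id variant identifier (VCF ID column), optional.
#' @return an object of class `variant_record`.
#' @export
variant_record <- function(chrom, pos, ref, alt, filter_status = "PASS",
                           per_sample = list(), annotations = annotation_set(),
                           id = ".") {
  pos <- as.integer(pos)
  stopifnot(pos >= 1L, nzchar(ref), nzchar(alt))
  if (identical(ref, alt)) stop("ref and alt must differ")
  chrom <- normalize_chrom(chrom)
  structure(list(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 variant_class = classify_variant(chrom, ref, alt),
                 filter_status = filter_status, per_sample = per_sample,
                 annotations = annotations, id = id),
            class = "variant_record")
}

#' @export
print.variant_record <- function(x, ...) {
  cat(sprintf("<variant_record> %s:%d %s>%s [%s] filter=%s samples=%d\n",
              x$chrom, x$pos, x$ref, x$alt, x$variant_class,
              x$filter_status, length(x$per_sample)))
  invisible(x)
}

#' Canonical string key of a (normalized) variant
#' @param record a [variant_record()].
#' @return character key `"chrom-pos-ref-alt"`.
#' @export
variant_key <- function(record) {
  paste(record$chrom, record$pos, record$ref, record$alt, sep = "-")
}

#' Trim shared allele sequence from a biallelic record
#'
#' Removes the shared suffix, then the shared prefix (always keeping at least
#' one base of each allele), adjusting `pos` for trimmed prefix bases. The
#' operation is idempotent and is a no-op on symbolic (SV) alleles.
#' Reference-guided left alignment is out of scope.
#'
#' @param record a [variant_record()].
#' @return the normalized [variant_record()].
#' @export
normalize_variant <- function(record) {
  ref <- record$ref; alt <- record$alt
  if (grepl("^<", alt) || grepl("\\[|\\]", alt)) return(record)
  # shared suffix
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  # shared prefix
  shift <- 0L
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    shift <- shift + 1L
  }
  if (shift == 0L && ref == record$ref && alt == record$alt) return(record)
  out <- record
  out$pos <- record$pos + shift
  out$ref <- ref
  out$alt <- alt
  out$variant_class <- classify_variant(out$chrom, ref, alt)
  out
}
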