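# Secondary-verification triage: a reported SNV may skip orthogonal
# (Sanger) confirmation only when all six criteria hold --
#   single base pair substitution,
#   sequence depth >= 20x at the position (inclusive),
#   genotype quality at the caller maximum (99 for GATK),
#   caller FILTER "PASS",
#   not in a segmental duplication region,
#   good quality on visual inspection.
# Missing depth/quality/inspection conservatively fail their criterion;
# non-SNV classes always require confirmation.

TRIAGE_CRITERIA <- c("is_snv", "depth_ok", "gq_max", "filter_pass",
                     "outside_segdup", "inspection_good")

#' Decide whether secondary verification can be skipped for one variant
#'
#' @param record a [variant_record()].
#' @param sample_id sample whose call is being reported.
#' @param mask a [genome_mask()] of segmental duplication regions.
#' @param min_depth inclusive depth threshold (default 20 reads).
#' @param gq_max genotype-quality value treated as the caller maximum
#'   (equality required; default 99, GATK).
#' @return object of class `triage_decision` with fields `key`,
#'   `skip_verification`, `criteria` (named logical) and `reasons`
#'   (names of failed criteria).
#' @export
triage_variant <- function(record, sample_id, mask, min_depth = 20L,
                           gq_max = 99L) {
  call <- record$per_sample[[sample_id]]
  if (is.null(call))
    stop("pairing error: sample '", sample_id, "' absent from record ",
         variant_key(record))
  criteria <- c(
    is_snv = record$variant_class == "SNV",
    depth_ok = !is.na(call$dp) && call$dp >= min_depth,
    gq_max = !is.na(call$gq) && call$gq == gq_max,
    filter_pass = identical(record$filter_status, "PASS"),
    outside_segdup = !mask_overlaps_record(mask, record),
    inspection_good = identical(record$annotations$inspection_status, "good"))
  structure(list(key = variant_key(record),
                 skip_verification = all(criteria),
                 criteria = criteria,
                 reasons = names(criteria)[!criteria]),
            class = "triage_decision")
}

#' Summarize a set of triage decisions
#'
#' @param decisions list of [triage_variant()] results.
#' @return list with `n_total`, `n_skip`, `n_confirm`, `pct_skip` (percent,
#'   rounded half away from zero) and `per_criterion_failures` (failure
#'   counts over the confirm set).
#' @export
triage_summary <- function(decisions) {
  if (!length(decisions)) stop("triage_summary: empty decision set")
  skip <- vapply(decisions, `[[`, logical(1), "skip_verification")
  confirm <- decisions[!skip]
  fails <- setNames(integer(length(TRIAGE_CRITERIA)), TRIAGE_CRITERIA)
  for (d in confirm) fails[d$reasons] <- fails[d$reasons] + 1L
  list(n_total = length(decisions),
       n_skip = sum(skip),
       n_confirm = sum(!skip),
       pct_skip = round_half_away(100 * sum(skip) / length(decisions)),
       per_criterion_failures = fails)
}

# round-half-away-from-zero to integer (base round() is round-half-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
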