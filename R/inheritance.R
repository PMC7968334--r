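# Deduction of compatible Mendelian inheritance models per variant and
# family, with de novo sub-models, mosaic flagging and compound-heterozygote
# pairing.
#
# Semantics (full detail in the methods vignette):
#  * only genotyped members constrain the model set; ungenotyped members and
#    members of unknown affection status impose no constraint;
#  * a plain model requires (a) every affected genotyped member to carry the
#    model's causal configuration, (b) no unaffected genotyped member to
#    carry it (relaxable for dominant models via reduced_penetrance), and
#    (c) a pure-transmission explanation: the alt alleles of each affected
#    member with genotyped parents must be obtainable from those parents;
#  * a *_dn sub-model requires (a) and (b) plus the alt allele being absent
#    from every genotyped parent of every affected member.

#' The inheritance model vocabulary
#' @export
INHERITANCE_MODELS <- c("AD", "AD_dn", "AR_hom", "AR_hom_dn", "AR_comp",
                        "AR_comp_dn", "XD", "XD_dn", "XR", "XR_dn", "MT")

#' Default options for model deduction
#'
#' @param min_parent_depth minimum parental read depth (both parents) for a
#'   de novo call to be flagged confident; default 10 reads.
#' @param mosaic_af alt-allele fraction below which the index call is flagged
#'   as a possible mosaic; default 0.20.
#' @param reduced_penetrance when `TRUE`, unaffected carriers do not exclude
#'   dominant (AD/XD) models.
#' @return named list of options.
#' @export
inheritance_options <- function(min_parent_depth = 10L, mosaic_af = 0.20,
                                reduced_penetrance = FALSE) {
  list(min_parent_depth = as.integer(min_parent_depth),
       mosaic_af = mosaic_af,
       reduced_penetrance = isTRUE(reduced_penetrance))
}

# Effective genotype of a member on the region under test. On non-PAR chrX
# a diploid male call is coerced to hemizygous (alt wins on a het call, with
# a warning); elsewhere calls are used as stored.
effective_call <- function(call, sex, region) {
  if (is.null(call) || !is_genotyped(call)) return(NULL)
  if (region == "X" && identical(sex, "male") && length(call$gt) == 2L) {
    warning("diploid chrX genotype in male sample coerced to hemizygous",
            call. = FALSE)
    call$gt <- if (any(call$gt == 1L)) 1L else 0L
  }
  call
}

# causal-configuration predicates, NA-free (only called on genotyped calls)
carries_config <- function(model, call, sex, region) {
  d <- gt_dosage(call)
  hemi <- length(call$gt) == 1L
  switch(model,
    AD = d == 1L,
    AR_hom = if (hemi) d == 1L else d == 2L,
    XD = if (identical(sex, "male") || hemi) d >= 1L else d == 1L,
    XR = if (identical(sex, "male") || hemi) d >= 1L else d == 2L,
    stop("unknown model ", model))
}

is_carrier <- function(call) {
  isTRUE(gt_carrier(call))
}

# pattern check over all genotyped members with known affection status
pattern_ok <- function(model, members, calls, opts, region) {
  dominant <- model %in% c("AD", "XD")
  for (id in names(calls)) {
    m <- members[[id]]
    call <- calls[[id]]
    if (m$affected == "affected") {
      if (!carries_config(model, call, m$sex, region)) return(FALSE)
    } else if (m$affected == "unaffected") {
      if (dominant) {
        if (!opts$reduced_penetrance && is_carrier(call)) return(FALSE)
      } else {
        # recessive: unaffected must not carry the full causal configuration
        if (carries_config(model, call, m$sex, region)) return(FALSE)
      }
    }
  }
  TRUE
}

# pure-transmission feasibility for one affected member
transmission_ok <- function(model, member, calls, members, region) {
  mo <- member$mother_id; fa <- member$father_id
  mo_call <- if (!is.na(mo)) calls[[mo]] else NULL
  fa_call <- if (!is.na(fa)) calls[[fa]] else NULL
  mo_typed <- !is.null(mo_call); fa_typed <- !is.null(fa_call)
  if (region == "X") {
    if (identical(member$sex, "male")) {
      # a son's X comes from the mother
      if (mo_typed && !is_carrier(mo_call)) return(FALSE)
      return(TRUE)
    }
    if (model == "XR") { # affected female hom: one allele from each parent
      if (mo_typed && !is_carrier(mo_call)) return(FALSE)
      if (fa_typed && !is_carrier(fa_call)) return(FALSE)
      return(TRUE)
    }
    # XD het female: one alt from either parent
    if (mo_typed && fa_typed && !is_carrier(mo_call) && !is_carrier(fa_call))
      return(FALSE)
    return(TRUE)
  }
  if (model == "AR_hom") { # both alleles transmitted
    if (mo_typed && !is_carrier(mo_call)) return(FALSE)
    if (fa_typed && !is_carrier(fa_call)) return(FALSE)
    return(TRUE)
  }
  # AD het: the single alt must come from some parent
  if (mo_typed && fa_typed && !is_carrier(mo_call) && !is_carrier(fa_call))
    return(FALSE)
  TRUE
}

# de novo condition: alt absent from every genotyped parent of every
# genotyped affected member
denovo_ok <- function(calls, members) {
  for (id in names(calls)) {
    m <- members[[id]]
    if (m$affected != "affected") next
    for (p in c(m$mother_id, m$father_id)) {
      if (!is.na(p) && !is.null(calls[[p]]) && is_carrier(calls[[p]]))
        return(FALSE)
    }
  }
  TRUE
}

variant_region <- function(record) {
  if (record$chrom == "MT") "MT"
  else if (record$chrom == "X" && !in_par(record$chrom, record$pos)) "X"
  else "AUTO"
}

#' Deduce compatible inheritance models for one variant in one family
#'
#' Returns the set of Mendelian models (see [INHERITANCE_MODELS]) under which
#' the observed genotypes are consistent with the family's affection pattern.
#' Compound-heterozygous models are handled separately by
#' [pair_compound_hets()]. Mitochondrial variants carried by the index get
#' model `MT` with a maternal / de novo / undetermined sub-classification.
#'
#' @param record a [variant_record()].
#' @param ped a [pedigree()].
#' @param opts options from [inheritance_options()].
#' @return object of class `model_assignment` with fields `key`, `models`,
#'   `confident_de_novo`, `mosaic_suspect` and (for MT) `mt_origin`.
#' @export
deduce_models <- function(record, ped, opts = inheritance_options()) {
  ids <- names(ped$individuals)
  if (length(record$per_sample) &&
      !any(names(record$per_sample) %in% ids))
    stop("pairing error: record samples disjoint from pedigree ",
         ped$family_id)
  region <- variant_region(record)
  members <- ped$individuals
  calls <- list()
  for (id in ids) {
    call <- effective_call(record$per_sample[[id]], members[[id]]$sex, region)
    if (!is.null(call)) calls[[id]] <- call
  }
  index_call <- calls[[ped$index_id]]
  mosaic <- FALSE
  if (!is.null(index_call) && !is.null(index_call$ad)) {
    tot <- sum(index_call$ad)
    if (tot > 0 && index_call$ad[2] > 0 &&
        index_call$ad[2] / tot < opts$mosaic_af && isTRUE(gt_carrier(index_call)))
      mosaic <- TRUE
  }
  models <- character()
  mt_origin <- NULL
  if (region == "MT") {
    if (!is.null(index_call) && is_carrier(index_call)) {
      models <- "MT"
      mother <- members[[ped$index_id]]$mother_id
      mo_call <- if (!is.na(mother)) calls[[mother]] else NULL
      mt_origin <- if (is.null(mo_call)) "undetermined"
                   else if (is_carrier(mo_call)) "maternal" else "de_novo"
    }
  } else {
    candidates <- if (region == "X") c("XD", "XR") else c("AD", "AR_hom")
    for (base in candidates) {
      if (pattern_ok(base, members, calls, opts, region)) {
        plain_ok <- all(vapply(names(calls), function(id) {
          m <- members[[id]]
          if (m$affected != "affected") return(TRUE)
          transmission_ok(base, m, calls, members, region)
        }, logical(1)))
        if (plain_ok) models <- c(models, base)
        if (denovo_ok(calls, members)) models <- c(models, paste0(base, "_dn"))
      }
    }
  }
  confident <- FALSE
  if (any(endsWith(models, "_dn"))) {
    idx <- members[[ped$index_id]]
    parents <- c(idx$mother_id, idx$father_id)
    parents <- parents[!is.na(parents)]
    if (length(parents) == 2L &&
        all(vapply(parents, function(p) !is.null(calls[[p]]), logical(1)))) {
      dps <- vapply(parents, function(p) {
        d <- calls[[p]]$dp
        if (is.na(d)) -1L else d
      }, integer(1))
      confident <- all(dps >= opts$min_parent_depth)
    }
  }
  structure(list(key = variant_key(record), models = unique(models),
                 confident_de_novo = confident, mosaic_suspect = mosaic,
                 mt_origin = mt_origin),
            class = "model_assignment")
}

# parental origin of an index het variant:
#  "maternal"/"paternal" (exactly one genotyped parent carries),
#  "de_novo" (both genotyped, neither carries),
#  "ambiguous" (both carry, or any parent ungenotyped)
variant_origin <- function(record, ped) {
  idx <- ped$individuals[[ped$index_id]]
  origin_of <- function(pid) {
    if (is.na(pid)) return(NA)
    call <- record$per_sample[[pid]]
    if (is.null(call) || !is_genotyped(call)) return(NA)
    isTRUE(gt_carrier(call))
  }
  mo <- origin_of(idx$mother_id)
  fa <- origin_of(idx$father_id)
  if (is.na(mo) || is.na(fa)) return("ambiguous")
  if (mo && !fa) "maternal"
  else if (!mo && fa) "paternal"
  else if (!mo && !fa) "de_novo"
  else "ambiguous"
}

#' Pair candidate compound-heterozygous variants within one gene
#'
#' Given index-heterozygous variants annotated to the same gene, returns the
#' unordered pairs compatible with a trans (one allele per parental
#' haplotype) configuration. With informative parental genotypes, pairs
#' proven cis (both variants transmitted by the same single parent) are
#' dropped and trans pairs have `phase_known = TRUE`; a pair with a de novo
#' side is labelled `AR_comp_dn`. Without parental information all het pairs
#' are returned with `phase_known = FALSE`.
#'
#' @param records list of [variant_record()] within one gene.
#' @param ped a [pedigree()].
#' @return list of candidate pairs, each a list with `a`, `b` (variant
#'   keys), `model` (`"AR_comp"` or `"AR_comp_dn"`) and `phase_known`.
#' @export
pair_compound_hets <- function(records, ped) {
  het <- Filter(function(r) {
    call <- r$per_sample[[ped$index_id]]
    !is.null(call) && is_genotyped(call) && identical(gt_dosage(call), 1L) &&
      length(call$gt) == 2L
  }, records)
  n <- length(het)
  if (n < 2L) return(list())
  genes <- Reduce(intersect, lapply(het, function(r) r$annotations$gene_symbols))
  if (!length(genes))
    warning("compound-het candidates share no gene symbol", call. = FALSE)
  origins <- vapply(het, variant_origin, character(1), ped = ped)
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      oi <- origins[i]; oj <- origins[j]
      single <- c("maternal", "paternal")
      if (oi %in% single && oj %in% single) {
        if (oi == oj) next # proven cis
        out[[length(out) + 1L]] <- list(a = variant_key(het[[i]]),
                                        b = variant_key(het[[j]]),
                                        model = "AR_comp", phase_known = TRUE)
      } else if (oi == "de_novo" || oj == "de_novo") {
        out[[length(out) + 1L]] <- list(a = variant_key(het[[i]]),
                                        b = variant_key(het[[j]]),
                                        model = "AR_comp_dn", phase_known = TRUE)
      } else {
        out[[length(out) + 1L]] <- list(a = variant_key(het[[i]]),
                                        b = variant_key(het[[j]]),
                                        model = "AR_comp", phase_known = FALSE)
      }
    }
  }
  out
}
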