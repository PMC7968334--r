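# Shared fixture builders and independent oracles.

# genotype shorthand: "0/0" -> c(0L,0L); "1" -> 1L (hemizygous); NULL/"." -> missing
gt_of <- function(s) {
  if (is.null(s) || identical(s, ".")) return(NA_integer_)
  as.integer(strsplit(s, "/", fixed = TRUE)[[1]])
}

mk_call <- function(gt, dp = 30L, gq = 99L, ad = NULL) {
  sample_call(gt = gt_of(gt), dp = dp, gq = gq, ad = ad)
}

# standard trio pedigree: affected child (sex configurable), unaffected parents
mk_trio_ped <- function(child_sex = "female", mother_aff = "unaffected",
                        father_aff = "unaffected", fam = "F1") {
  pedigree(fam, list(
    individual("kid", sex = child_sex, affected = "affected",
               mother_id = "mom", father_id = "dad"),
    individual("mom", sex = "female", affected = mother_aff),
    individual("dad", sex = "male", affected = father_aff)),
    index_id = "kid")
}

mk_singleton_ped <- function(sex = "male", fam = "F1") {
  pedigree(fam, list(individual("kid", sex = sex, affected = "affected")),
           index_id = "kid")
}

# trio variant record; genotype strings as in gt_of(); NULL = sample absent
mk_trio_record <- function(kid, mom, dad, chrom = "1", pos = 1000L,
                           ref = "A", alt = "G", gene = "GENE1", ...) {
  per <- list()
  if (!is.null(kid)) per$kid <- mk_call(kid, ...)
  if (!is.null(mom)) per$mom <- mk_call(mom)
  if (!is.null(dad)) per$dad <- mk_call(dad)
  variant_record(chrom, pos, ref, alt, per_sample = per,
                 annotations = annotation_set(gene_symbols = gene))
}

# ---------------------------------------------------------------------------
# Independent brute-force oracle for trio model deduction: enumerates the
# actually transmissible allele combinations instead of using rule
# shortcuts. Genotypes are integer vectors or NULL (ungenotyped).
oracle_trio_models <- function(cg, mg, fg, chrom = "1",
                               child_sex = "female",
                               mother_aff = "unaffected",
                               father_aff = "unaffected") {
  is_x <- chrom == "X"
  avail <- function(g) if (is.null(g)) c(0L, 1L) else unique(g)
  pattern_one <- function(model, g, sex, aff) {
    if (is.null(g)) return(TRUE)
    d <- sum(g == 1L); hemi <- length(g) == 1L
    config <- switch(model,
      AD = d == 1L,
      AR_hom = if (hemi) d == 1L else d == 2L,
      XD = if (sex == "male" || hemi) d >= 1L else d == 1L,
      XR = if (sex == "male" || hemi) d >= 1L else d == 2L)
    if (aff == "affected") config
    else if (model %in% c("AD", "XD")) d == 0L
    else !config
  }
  pattern <- function(model) {
    pattern_one(model, cg, child_sex, "affected") &&
      pattern_one(model, mg, "female", mother_aff) &&
      pattern_one(model, fg, "male", father_aff)
  }
  transmissible <- function() {
    if (is.null(cg)) return(TRUE)
    if (is_x && child_sex == "male") {
      return(any(avail(mg) %in% cg))
    }
    for (am in avail(mg)) for (af in avail(fg)) {
      if (identical(sort(c(am, af)), sort(cg))) return(TRUE)
    }
    FALSE
  }
  dn_ok <- if (is.null(cg)) TRUE else {
    !(!is.null(mg) && any(mg == 1L)) && !(!is.null(fg) && any(fg == 1L))
  }
  models <- character()
  for (b in if (is_x) c("XD", "XR") else c("AD", "AR_hom")) {
    if (!pattern(b)) next
    if (transmissible()) models <- c(models, b)
    if (dn_ok) models <- c(models, paste0(b, "_dn"))
  }
  models
}

# deduce_models on an explicit trio genotype configuration
deduce_trio <- function(cg, mg, fg, chrom = "1", child_sex = "female",
                        mother_aff = "unaffected", father_aff = "unaffected") {
  per <- list()
  if (!is.null(cg)) per$kid <- sample_call(gt = cg, dp = 30L, gq = 99L)
  if (!is.null(mg)) per$mom <- sample_call(gt = mg, dp = 30L, gq = 99L)
  if (!is.null(fg)) per$dad <- sample_call(gt = fg, dp = 30L, gq = 99L)
  rec <- variant_record(chrom, 5000000L, "A", "G", per_sample = per)
  ped <- mk_trio_ped(child_sex = child_sex, mother_aff = mother_aff,
                     father_aff = father_aff)
  deduce_models(rec, ped)
}

# brute-force allele trimmer used as the normalization oracle: per-base
# character arithmetic, no early exits
oracle_trim <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  while (length(r) > 1L && length(a) > 1L && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

random_allele <- function(maxlen = 6L) {
  n <- sample(1:maxlen, 1L)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rha <- function(x) sign(x) * floor(abs(x) + 0.5) # round half away from zero
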