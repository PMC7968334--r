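# Deterministic synthetic fixtures: trio/singleton VCF+PED with planted
# inheritance models, triage sets realizing a stated criterion composition,
# matrix-level trio genotype simulations for QC, and cohort case-result
# tables realizing printed study marginals. Every generator is a pure
# function of its seed/spec; the same seed yields byte-identical files.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

BENIGN_CSQ <- c("synonymous_variant", "intron_variant", "missense_variant",
                "splice_region_variant")
DAMAGING_CSQ <- c("stop_gained", "frameshift_variant", "splice_donor_variant",
                  "missense_variant")

#' Configuration for the trio generator
#'
#' Defaults state the simulated world once: 800 background autosomal sites
#' per trio, an allele-frequency spectrum of point masses
#' {0.5, 0.1, 0.01, 0.001}, a 0.5% per-allele child genotyping error rate,
#' and read depths around 30x with GQ 99 typical of a clinical 30x genome.
#'
#' @param seed integer RNG seed.
#' @param n_sites number of background sites.
#' @param af_spectrum allele-frequency point masses for background sites.
#' @param planted list of plants, each `list(model =, gene =)` with model in
#'   AD, AD_dn, AR_hom, XR, XD_dn, MT, AR_comp.
#' @param trio_error_rate per-allele child genotype error probability.
#' @param upd `NULL` or `list(chrom =, parent = "maternal"/"paternal")` to
#'   emulate an isodisomic chromosome in the child.
#' @param family_id family identifier.
#' @return config list.
#' @export
synth_config <- function(seed = 1L, n_sites = 800L,
                         af_spectrum = c(0.5, 0.1, 0.01, 0.001),
                         planted = list(), trio_error_rate = 0.005,
                         upd = NULL, family_id = "FAM1") {
  list(seed = as.integer(seed), n_sites = as.integer(n_sites),
       af_spectrum = af_spectrum, planted = planted,
       trio_error_rate = trio_error_rate, upd = upd, family_id = family_id)
}

rand_call <- function(gt, dp = NULL, gq = NULL) {
  dp <- dp %||% sample(25:40, 1L)
  gq <- gq %||% 99L
  nalt <- sum(gt == 1L)
  ad <- c(round(dp * (1 - nalt / length(gt))), round(dp * nalt / length(gt)))
  sample_call(gt = gt, dp = dp, gq = gq, ad = ad)
}

plant_genotypes <- function(model) {
  # per-member genotypes realizing one unambiguous planting; NULL entries
  # inherit the member defaults (child affected, parents unaffected)
  switch(model,
    AD     = list(chrom = "2", child = c(0L, 1L), mother = c(0L, 1L),
                  father = c(0L, 0L), mother_affected = TRUE),
    AD_dn  = list(chrom = "2", child = c(0L, 1L), mother = c(0L, 0L),
                  father = c(0L, 0L)),
    AR_hom = list(chrom = "3", child = c(1L, 1L), mother = c(0L, 1L),
                  father = c(0L, 1L)),
    XR     = list(chrom = "X", child = 1L, mother = c(0L, 1L), father = 0L,
                  child_sex = "male"),
    XD_dn  = list(chrom = "X", child = c(0L, 1L), mother = c(0L, 0L),
                  father = 0L, child_sex = "female"),
    MT     = list(chrom = "MT", child = 1L, mother = 1L, father = 0L),
    stop("no planting recipe for model ", model))
}

#' Generate a synthetic trio with planted ground truth
#'
#' Background parental genotypes are drawn in Hardy-Weinberg proportions
#' from the configured frequency spectrum and the child inherits one allele
#' from each parent, subject to the configured error rate. Planted variants
#' are inserted with genotypes realizing the requested inheritance model
#' (compound-het plants insert a trans pair); an optional UPD mode makes one
#' chromosome isodisomic for one parent. Files are written to `dir` and the
#' truth table lists every planted key with its model.
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if needed).
#' @return list with `vcf`, `ped` (paths), `pedigree`, `truth`
#'   (`data.frame` key/model/gene) and `sample_ids`.
#' @export
generate_trio <- function(config, dir = tempfile("synthtrio")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fam <- config$family_id
  ids <- paste0(fam, c("_idx", "_mo", "_fa"))
  with_seed(config$seed, {
    child_sex <- "female"
    for (p in config$planted) {
      rec <- plant_genotypes(if (p$model == "AR_comp") "AR_hom" else p$model)
      if (!is.null(rec$child_sex)) child_sex <- rec$child_sex
    }
    records <- list()
    truth <- list()
    # background sites
    n <- config$n_sites
    chroms <- as.character(sample(1:22, n, replace = TRUE))
    if (!is.null(config$upd)) {
      # dedicate a quarter of background sites to the disomic chromosome,
      # at a common frequency so opposite-homozygote parents occur
      k <- max(200L, n %/% 4L)
      chroms[seq_len(k)] <- normalize_chrom(config$upd$chrom)
    }
    pos_by_chrom <- new.env(parent = emptyenv())
    genes <- sprintf("BG%04d", sample(1:200, n, replace = TRUE))
    for (i in seq_len(n)) {
      ch <- chroms[i]
      af <- if (!is.null(config$upd) && ch == normalize_chrom(config$upd$chrom))
        0.5 else sample(config$af_spectrum, 1L)
      last <- get0(ch, envir = pos_by_chrom, ifnotfound = 0L)
      pos <- last + sample(50000:900000, 1L)
      assign(ch, pos, envir = pos_by_chrom)
      draw <- function() rbinom(2L, 1L, af)
      mo <- draw(); fa <- draw()
      child <- c(sample(mo, 1L), sample(fa, 1L))
      err <- runif(2L) < config$trio_error_rate
      child[err] <- 1L - child[err]
      if (!is.null(config$upd) && ch == normalize_chrom(config$upd$chrom)) {
        src <- if (config$upd$parent == "maternal") mo else fa
        child <- rep(sample(src, 1L), 2L)
      }
      ref <- sample(c("A", "C", "G", "T"), 1L)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      ann <- annotation_set(gene_symbols = genes[i],
                            consequence = sample(BENIGN_CSQ, 1L),
                            population_af = af)
      records[[length(records) + 1L]] <- variant_record(
        ch, pos, ref, alt, filter_status = "PASS",
        per_sample = setNames(list(rand_call(sort(child)), rand_call(sort(mo)),
                                   rand_call(sort(fa))), ids),
        annotations = ann)
    }
    # planted variants
    mother_affected <- FALSE
    plant_one <- function(model, gene, gts, pos) {
      ann <- annotation_set(gene_symbols = gene,
                            consequence = sample(DAMAGING_CSQ[1:3], 1L),
                            conservation_score = 4.2,
                            deleteriousness_score = 32)
      variant_record(gts$chrom, pos, "C", "T", filter_status = "PASS",
                     per_sample = setNames(list(rand_call(gts$child),
                                                rand_call(gts$mother),
                                                rand_call(gts$father)), ids),
                     annotations = ann)
    }
    for (p in config$planted) {
      if (p$model == "AR_comp") {
        a <- list(chrom = "5", child = c(0L, 1L), mother = c(0L, 1L),
                  father = c(0L, 0L))
        b <- list(chrom = "5", child = c(0L, 1L), mother = c(0L, 0L),
                  father = c(0L, 1L))
        pa <- 10000000L + sample(1:1000, 1L) * 10L
        pb <- pa + 5000L
        ra <- plant_one("AR_comp", p$gene, a, pa)
        rb <- plant_one("AR_comp", p$gene, b, pb)
        records <- c(records, list(ra, rb))
        truth[[length(truth) + 1L]] <- data.frame(
          key = c(variant_key(ra), variant_key(rb)), model = "AR_comp",
          gene = p$gene, stringsAsFactors = FALSE)
      } else {
        gts <- plant_genotypes(p$model)
        if (isTRUE(gts$mother_affected)) mother_affected <- TRUE
        pos <- 20000000L + sample(1:1000, 1L) * 10L
        r <- plant_one(p$model, p$gene, gts, pos)
        records[[length(records) + 1L]] <- r
        truth[[length(truth) + 1L]] <- data.frame(
          key = variant_key(r), model = p$model, gene = p$gene,
          stringsAsFactors = FALSE)
      }
    }
    ped <- pedigree(fam, list(
      individual(ids[1], sex = child_sex, affected = "affected",
                 mother_id = ids[2], father_id = ids[3]),
      individual(ids[2], sex = "female",
                 affected = if (mother_affected) "affected" else "unaffected"),
      individual(ids[3], sex = "male", affected = "unaffected")),
      index_id = ids[1])
    vcf_path <- file.path(dir, paste0(fam, ".vcf"))
    ped_path <- file.path(dir, paste0(fam, ".ped"))
    ord <- order(chrom_order_key(vapply(records, `[[`, character(1), "chrom")),
                 vapply(records, `[[`, integer(1), "pos"))
    records <- records[ord]
    write_scored_vcf(records, vcf_path)
    write_ped(ped, ped_path)
    truth_df <- if (length(truth)) do.call(rbind, truth)
                else data.frame(key = character(), model = character(),
                                gene = character())
    fwrite(truth_df, file.path(dir, paste0(fam, "_truth.tsv")), sep = "\t")
    list(vcf = vcf_path, ped = ped_path, pedigree = ped, truth = truth_df,
         sample_ids = ids, records = records)
  })
}

#' Simulate a trio genotype dosage table (no files)
#'
#' Matrix-level fast path for QC simulations: biparental transmission with a
#' per-allele child error rate, or an unrelated child
#' (`child = "unrelated"`), on one or more chromosomes.
#'
#' @param n_sites sites per chromosome.
#' @param chroms chromosome labels.
#' @param af allele frequency of every site (default 0.5, maximally
#'   informative).
#' @param error_rate per-allele child genotype error probability.
#' @param child `"biparental"`, `"unrelated"`, or `"upd"` (isodisomy for
#'   `upd_parent` on all listed chromosomes).
#' @param upd_parent `"maternal"` or `"paternal"`.
#' @return trio genotype `data.frame` (chrom, pos, index, mother, father).
#' @export
sim_trio_genotypes <- function(n_sites = 500L, chroms = "1", af = 0.5,
                               error_rate = 0.005, child = "biparental",
                               upd_parent = "maternal") {
  child <- match.arg(child, c("biparental", "unrelated", "upd"))
  out <- lapply(chroms, function(ch) {
    mo <- matrix(rbinom(2L * n_sites, 1L, af), ncol = 2L)
    fa <- matrix(rbinom(2L * n_sites, 1L, af), ncol = 2L)
    pick <- function(m) m[cbind(seq_len(n_sites), sample(1:2, n_sites, TRUE))]
    kid <- switch(child,
      biparental = {
        k <- cbind(pick(mo), pick(fa))
        err <- matrix(runif(2L * n_sites) < error_rate, ncol = 2L)
        k[err] <- 1L - k[err]
        k
      },
      unrelated = matrix(rbinom(2L * n_sites, 1L, af), ncol = 2L),
      upd = {
        src <- if (upd_parent == "maternal") mo else fa
        a <- pick(src)
        cbind(a, a)
      })
    data.frame(chrom = ch,
               pos = sort(sample.int(150000000L, n_sites)),
               index = rowSums(kid), mother = rowSums(mo),
               father = rowSums(fa), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# -- triage set ---------------------------------------------------------------

#' The retrospective confirmation-cohort composition
#'
#' Strata realizing the published 721-variant retrospective evaluation:
#' 503 single-base substitutions at the caller-maximum genotype quality, of
#' which 493 PASS and 484 additionally clear depth, inspection and
#' segmental-duplication criteria. The split of the 218 excluded records
#' (INDEL vs below-maximum GQ) and of the 9 post-filter failures is not
#' published; one fixed split is stated here.
#'
#' @return `data.frame` of strata (n, is_snv, depth, gq, filter, segdup,
#'   inspection).
#' @export
confirmation_strata <- function() {
  data.frame(
    stratum = c("all_good", "fail_depth", "fail_inspection", "fail_segdup",
                "fail_filter", "indel", "low_gq"),
    n = c(484L, 3L, 3L, 3L, 10L, 180L, 38L),
    is_snv = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    depth = c(30L, 12L, 30L, 30L, 30L, 30L, 30L),
    gq = c(99L, 99L, 99L, 99L, 99L, 99L, 87L),
    filter = c("PASS", "PASS", "PASS", "PASS", "LowQual", "PASS", "PASS"),
    segdup = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    inspection = c("good", "good", "unset", "good", "good", "good", "good"),
    stringsAsFactors = FALSE)
}

#' Generate a variant set realizing a per-criterion triage composition
#'
#' @param strata a strata `data.frame` as returned by
#'   [confirmation_strata()].
#' @return list with `records`, `mask` (segmental-duplication
#'   [genome_mask()]) and `sample_id`.
#' @export
generate_triage_set <- function(strata = confirmation_strata()) {
  mask <- genome_mask("1", 10000000L, 20000000L)
  records <- list()
  pos <- 30000000L
  for (i in seq_len(nrow(strata))) {
    s <- strata[i, ]
    for (j in seq_len(s$n)) {
      pos <- pos + 100L
      p <- if (s$segdup) 10000000L + 100L * (length(records) + 1L) else pos
      ref <- if (s$is_snv) "A" else "AT"
      records[[length(records) + 1L]] <- variant_record(
        "1", p, ref, "G" , filter_status = s$filter,
        per_sample = list(S1 = sample_call(gt = c(0L, 1L), dp = s$depth,
                                           gq = s$gq)),
        annotations = annotation_set(gene_symbols = "TRIAGE",
                                     inspection_status = s$inspection))
    }
  }
  list(records = records, mask = mask, sample_id = "S1")
}

# -- cohort case results ------------------------------------------------------

#' The published cohort marginals used as generator inputs
#'
#' Printed study-level tables restated as a machine-readable spec: the
#' per-panel analysis/solved counts, case and relative totals, the
#' mode-of-inheritance component counts, the gene-recurrence profile, the
#' non-SNV screening counts and the reanalysis counts.
#'
#' @return spec list consumed by [generate_case_results()].
#' @export
cohort_spec_default <- function() {
  table1 <- data.frame(
    panel = c("IEM", "NMD", "HPO", "EP", "PID", "OMIM", "ID", "CTD", "SKD",
              "IC", "DSD", "PEDHEP", "CIL", "NDD", "FETHYD"),
    n_analyses = c(849L, 455L, 429L, 327L, 300L, 281L, 304L, 245L, 212L,
                   147L, 68L, 53L, 36L, 32L, 12L),
    n_solved = c(274L, 189L, 124L, 101L, 88L, 116L, 119L, 68L, 115L,
                 29L, 17L, 18L, 19L, 6L, 6L),
    stringsAsFactors = FALSE)
  list(
    table1 = table1,
    trio_panels = c("EP", "OMIM"),
    n_cases = 3219L,
    n_solved_cases = 1285L,
    n_relatives = 1218L,
    inheritance_determined = c(AR = 468L, de_novo = 235L, AD_inherited = 107L,
                               XL_inherited = 48L, MT = 11L),
    inheritance_assumed = c(assumed_AD = 347L, assumed_AR = 36L,
                            assumed_XL = 33L),
    top_genes = c(COL2A1 = 12L, FKRP = 12L, MECP2 = 11L, DYNC1H1 = 10L,
                  COL1A2 = 9L, COL5A1 = 9L, FBN1 = 9L, KCNQ2 = 9L,
                  STXBP1 = 9L, ARID1B = 8L, RYR1 = 8L, SCN1A = 8L),
    n_genes = 754L,
    n_single_case_genes = 496L,
    nonsnv = list(referred = 285L, positive = 35L,
                  findings = c(CNV_deletion = 36L, CNV_duplication = 9L,
                               balanced = 5L, CGR = 2L, UPD = 1L, STR = 10L,
                               other = 1L)),
    reanalysis = list(n_cases = 130L, n_solved = 25L))
}

# deterministic gene multiset realizing the recurrence profile
recurrence_genes <- function(spec) {
  n_findings <- sum(spec$inheritance_determined) + sum(spec$inheritance_assumed)
  top <- spec$top_genes
  n_rest <- spec$n_genes - length(top) - spec$n_single_case_genes
  budget <- n_findings - sum(top) - spec$n_single_case_genes
  # remaining recurrent genes get counts 2 or 3 to exhaust the budget
  n3 <- budget - 2L * n_rest
  stopifnot(n3 >= 0L, n3 <= n_rest)
  rest <- setNames(c(rep(3L, n3), rep(2L, n_rest - n3)),
                   sprintf("RG%04d", seq_len(n_rest)))
  singles <- setNames(rep(1L, spec$n_single_case_genes),
                      sprintf("SG%04d", seq_len(spec$n_single_case_genes)))
  counts <- c(top, rest, singles)
  rep(names(counts), times = counts)
}

#' Generate cohort case results realizing printed marginals
#'
#' Builds a [case_results()] object (cases, per-panel analyses, findings)
#' whose recounted marginals equal the spec: per-panel analysis and solved
#' counts, total and solved cases, the mode-of-inheritance split, and the
#' gene-recurrence profile. Positive panel analyses exceeding the number of
#' distinct solved cases are assigned as additional findings of
#' already-solved cases (dual diagnoses). Deterministic; no RNG.
#'
#' @param spec a [cohort_spec_default()]-shaped spec.
#' @return list with `case_results`, `individuals` (`data.frame` of patients
#'   and relatives), `nonsnv`, `reanalysis` (a small [case_results()]).
#' @export
generate_case_results <- function(spec = cohort_spec_default()) {
  t1 <- spec$table1
  if (nrow(t1) == 0L || spec$n_cases == 0L) {
    empty_cases <- data.frame(case_id = character(),
                              analysis_type = character(), solved = logical())
    return(list(case_results = case_results(empty_cases),
                individuals = data.frame(id = character(), role = character()),
                nonsnv = NULL, reanalysis = NULL))
  }
  stopifnot(sum(t1$n_analyses) >= spec$n_cases,
            spec$n_solved_cases <= spec$n_cases)
  case_ids <- sprintf("C%05d", seq_len(spec$n_cases))
  solved <- seq_len(spec$n_cases) <= spec$n_solved_cases
  # positive analyses consume solved case ids; the overflow wraps onto the
  # first solved cases (dual diagnoses)
  n_pos <- sum(t1$n_solved)
  pos_pool <- case_ids[((seq_len(n_pos) - 1L) %% spec$n_solved_cases) + 1L]
  n_neg <- sum(t1$n_analyses) - n_pos
  unsolved_ids <- case_ids[!solved]
  neg_pool <- unsolved_ids[((seq_len(n_neg) - 1L) %% length(unsolved_ids)) + 1L]
  rows <- list(); ip <- 0L; ineg <- 0L
  for (i in seq_len(nrow(t1))) {
    np <- t1$n_solved[i]; nn <- t1$n_analyses[i] - np
    rows[[i]] <- data.frame(
      case_id = c(pos_pool[ip + seq_len(np)], neg_pool[ineg + seq_len(nn)]),
      panel = t1$panel[i],
      positive = rep(c(TRUE, FALSE), c(np, nn)),
      stringsAsFactors = FALSE)
    ip <- ip + np; ineg <- ineg + nn
  }
  analyses <- do.call(rbind, rows)
  trio_cases <- unique(analyses$case_id[analyses$panel %in% spec$trio_panels])
  cases <- data.frame(
    case_id = case_ids,
    analysis_type = ifelse(case_ids %in% trio_cases, "trio_family",
                           "singleton"),
    solved = solved, stringsAsFactors = FALSE)
  # findings: one causative finding per solved case
  cat_vec <- rep(c(names(spec$inheritance_determined),
                   names(spec$inheritance_assumed)),
                 times = c(spec$inheritance_determined,
                           spec$inheritance_assumed))
  genes <- recurrence_genes(spec)
  n_findings <- length(cat_vec)
  stopifnot(length(genes) == n_findings,
            n_findings == spec$n_solved_cases)
  findings <- data.frame(
    case_id = case_ids[seq_len(n_findings)],
    gene = genes,
    variant_key = sprintf("1-%d-A-G", 1000L + seq_len(n_findings)),
    inheritance_category = cat_vec,
    determined = cat_vec %in% names(spec$inheritance_determined),
    stringsAsFactors = FALSE)
  cr <- case_results(cases, analyses, findings)
  # individuals: every patient plus relatives attached to trio/family cases
  n_fam <- length(trio_cases)
  rel_per_fam <- rep(2L, n_fam)
  extra <- spec$n_relatives - sum(rel_per_fam)
  if (extra > 0L) rel_per_fam[seq_len(extra)] <- rel_per_fam[seq_len(extra)] + 1L
  individuals <- rbind(
    data.frame(id = case_ids, role = "patient", stringsAsFactors = FALSE),
    data.frame(id = sprintf("R%05d", seq_len(spec$n_relatives)),
               role = "relative", stringsAsFactors = FALSE))
  nonsnv <- list(
    referred = spec$nonsnv$referred,
    positive = spec$nonsnv$positive,
    findings = data.frame(
      case_id = sprintf("NS%03d", seq_len(sum(spec$nonsnv$findings))),
      category = rep(names(spec$nonsnv$findings),
                     times = spec$nonsnv$findings),
      stringsAsFactors = FALSE))
  re_ids <- sprintf("RE%04d", seq_len(spec$reanalysis$n_cases))
  reanalysis <- case_results(data.frame(
    case_id = re_ids, analysis_type = "singleton",
    solved = seq_along(re_ids) <= spec$reanalysis$n_solved,
    stringsAsFactors = FALSE))
  list(case_results = cr, individuals = individuals, nonsnv = nonsnv,
       reanalysis = reanalysis)
}
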