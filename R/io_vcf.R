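# VCF 4.2 reading and writing.
#
# The reader is deliberately small and strict about the semantics this
# toolkit depends on: multi-allelic sites are split into one record per alt
# (per-allele AD travels with the matching alt), hemizygous genotypes are
# kept as single-index, and missing DP/GQ/AD stay missing -- never zero.
# INFO annotation keys recognized on read/write:
#   GENE, CSQ, POPAF, CONSV, DELSC, CLNSIG, OBS, LFQ, ARTIFACT, INSP,
#   RankScore, RankResult, GeneticModels.

vcf_open <- function(path) {
  con <- gzfile(path, open = "rt")
  con
}

info_to_annotations <- function(info) {
  kv <- list()
  if (!is.na(info) && nzchar(info) && info != ".") {
    for (tok in strsplit(info, ";", fixed = TRUE)[[1]]) {
      eq <- regexpr("=", tok, fixed = TRUE)
      if (eq > 0) {
        kv[[substr(tok, 1, eq - 1)]] <- substr(tok, eq + 1, nchar(tok))
      } else kv[[tok]] <- TRUE
    }
  }
  num <- function(k) if (is.null(kv[[k]])) NA_real_ else as.numeric(kv[[k]])
  chr <- function(k) if (is.null(kv[[k]])) NA_character_ else kv[[k]]
  ann <- annotation_set(
    gene_symbols = if (is.null(kv$GENE)) character() else strsplit(kv$GENE, ",", fixed = TRUE)[[1]],
    consequence = chr("CSQ"),
    population_af = num("POPAF"),
    conservation_score = num("CONSV"),
    deleteriousness_score = num("DELSC"),
    clinical_significance = chr("CLNSIG"),
    local_obs = if (is.null(kv$OBS)) NA_integer_ else as.integer(kv$OBS),
    local_frequency = num("LFQ"),
    artifact = isTRUE(kv$ARTIFACT) || identical(kv$ARTIFACT, "1"),
    inspection_status = if (is.null(kv$INSP)) "unset" else kv$INSP)
  extra <- list(
    rank_score = if (is.null(kv$RankScore)) NA_integer_ else as.integer(kv$RankScore),
    rank_result = chr("RankResult"),
    genetic_models = if (is.null(kv$GeneticModels)) character()
                     else strsplit(kv$GeneticModels, ",", fixed = TRUE)[[1]])
  list(annotations = ann, extra = extra)
}

parse_gt_string <- function(gt, alt_index, line_no) {
  phased <- grepl("|", gt, fixed = TRUE)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (length(alleles) > 2L)
    stop(sprintf("VCF format error at line %d: ploidy > 2 in GT '%s'",
                 line_no, gt))
  idx <- suppressWarnings(ifelse(alleles == ".", NA_integer_, as.integer(alleles)))
  # remap to the split biallelic record: this alt -> 1, ref -> 0,
  # any other alt of the original site -> missing
  remap <- function(a) {
    if (is.na(a)) NA_integer_
    else if (a == 0L) 0L
    else if (a == alt_index) 1L
    else NA_integer_
  }
  list(gt = vapply(idx, remap, integer(1)), phased = phased)
}

#' Read a VCF file into a list of variant records
#'
#' Multi-allelic sites are split into one biallelic record per alternate
#' allele; genotype allele indices are remapped accordingly (alleles
#' referring to a different alt become missing). Per-sample DP/GQ/AD are
#' taken from FORMAT when declared; absent fields stay `NA`. Plain and
#' gzipped files are accepted, as are "chr"-prefixed chromosome labels.
#'
#' @param path path to a VCF (optionally gzipped).
#' @param pedigree optional [pedigree()]; when given, sample columns are
#'   checked to cover at least one pedigree member.
#' @return list of [variant_record()] objects, attribute `"samples"` carries
#'   the sample column names.
#' @export
read_vcf <- function(path, pedigree = NULL) {
  con <- vcf_open(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) stop("VCF format error: empty file: ", path)
  if (!startsWith(lines[1], "##fileformat=VCF"))
    stop("VCF format error at line 1: missing ##fileformat header")
  header_idx <- which(startsWith(lines, "#CHROM"))
  if (length(header_idx) != 1L)
    stop("VCF format error: expected exactly one #CHROM header line")
  header <- strsplit(lines[header_idx], "\t", fixed = TRUE)[[1]]
  if (length(header) < 8L)
    stop(sprintf("VCF format error at line %d: truncated #CHROM line", header_idx))
  samples <- if (length(header) > 9L) header[10:length(header)] else character()
  if (!is.null(pedigree)) {
    ids <- vapply(pedigree$individuals, `[[`, character(1), "id")
    if (length(samples) && !any(samples %in% ids))
      stop("pairing error: no VCF sample matches the pedigree ", pedigree$family_id)
  }
  records <- list()
  body <- which(!startsWith(lines, "#"))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L)
      stop(sprintf("VCF format error at line %d: fewer than 8 columns", i))
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    fmt <- if (length(f) >= 9L) strsplit(f[9], ":", fixed = TRUE)[[1]] else character()
    for (k in seq_along(alts)) {
      per_sample <- list()
      if (length(samples)) {
        for (s in seq_along(samples)) {
          sv <- strsplit(f[9L + s], ":", fixed = TRUE)[[1]]
          val <- function(key) {
            j <- match(key, fmt)
            if (is.na(j) || j > length(sv) || sv[j] %in% c(".", "")) NA_character_ else sv[j]
          }
          gtv <- val("GT")
          if (is.na(gtv)) gtv <- "./."
          g <- parse_gt_string(gtv, k, i)
          adv <- val("AD")
          ad <- NULL
          if (!is.na(adv)) {
            adn <- suppressWarnings(as.integer(strsplit(adv, ",", fixed = TRUE)[[1]]))
            if (length(adn) >= k + 1L && !anyNA(adn[c(1L, k + 1L)]))
              ad <- c(adn[1L], adn[k + 1L])
          }
          per_sample[[samples[s]]] <- sample_call(
            gt = g$gt,
            dp = if (is.na(val("DP"))) NA_integer_ else as.integer(val("DP")),
            gq = if (is.na(val("GQ"))) NA_integer_ else as.integer(val("GQ")),
            ad = ad, phased = g$phased)
        }
      }
      parsed <- info_to_annotations(f[8])
      rec <- variant_record(chrom = f[1], pos = as.integer(f[2]),
                            ref = f[4], alt = alts[k],
                            filter_status = f[7], per_sample = per_sample,
                            annotations = parsed$annotations, id = f[3])
      rec$rank_score <- parsed$extra$rank_score
      rec$rank_result <- parsed$extra$rank_result
      rec$genetic_models <- parsed$extra$genetic_models
      records[[length(records) + 1L]] <- rec
    }
  }
  attr(records, "samples") <- samples
  records
}

annotations_to_info <- function(record) {
  a <- record$annotations
  parts <- character()
  add <- function(key, value) {
    if (length(value) == 1L && is.na(value)) return(invisible())
    if (length(value) == 0L) return(invisible())
    parts[[length(parts) + 1L]] <<- paste0(key, "=", paste(value, collapse = ","))
  }
  add("GENE", if (length(a$gene_symbols)) a$gene_symbols else NA)
  add("CSQ", a$consequence)
  add("POPAF", a$population_af)
  add("CONSV", a$conservation_score)
  add("DELSC", a$deleteriousness_score)
  add("CLNSIG", a$clinical_significance)
  add("OBS", a$local_obs)
  add("LFQ", a$local_frequency)
  if (isTRUE(a$artifact)) parts[[length(parts) + 1L]] <- "ARTIFACT"
  if (!identical(a$inspection_status, "unset")) add("INSP", a$inspection_status)
  add("GeneticModels", if (length(record$genetic_models)) record$genetic_models else NA)
  add("RankScore", record$rank_score)
  add("RankResult", record$rank_result)
  if (!length(parts)) "." else paste(parts, collapse = ";")
}

format_sample_call <- function(call) {
  gt <- if (!is_genotyped(call)) {
    if (length(call$gt) == 1L) "." else "./."
  } else paste(call$gt, collapse = if (call$phased) "|" else "/")
  dp <- if (is.na(call$dp)) "." else as.character(call$dp)
  gq <- if (is.na(call$gq)) "." else as.character(call$gq)
  ad <- if (is.null(call$ad)) "." else paste(call$ad, collapse = ",")
  paste(gt, dp, gq, ad, sep = ":")
}

#' Write variant records as a VCF 4.2 file
#'
#' Emits rank score (`RankScore`), per-category result token (`RankResult`)
#' and deduced inheritance models (`GeneticModels`) as INFO keys alongside
#' the annotation fields, preserving per-sample GT/DP/GQ/AD.
#'
#' @param records list of [variant_record()] (one sample set across records).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scored_vcf <- function(records, path) {
  samples <- if (length(records)) names(records[[1]]$per_sample) else character()
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=clinwgs",
    '##INFO=<ID=GENE,Number=.,Type=String,Description="Gene symbols">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="Most severe consequence">',
    '##INFO=<ID=POPAF,Number=1,Type=Float,Description="Population allele frequency">',
    '##INFO=<ID=CONSV,Number=1,Type=Float,Description="Conservation score">',
    '##INFO=<ID=DELSC,Number=1,Type=Float,Description="Deleteriousness score">',
    '##INFO=<ID=CLNSIG,Number=1,Type=String,Description="Clinical significance">',
    '##INFO=<ID=OBS,Number=1,Type=Integer,Description="Local observation count">',
    '##INFO=<ID=LFQ,Number=1,Type=Float,Description="Local observation frequency">',
    '##INFO=<ID=ARTIFACT,Number=0,Type=Flag,Description="Local artifact flag">',
    '##INFO=<ID=INSP,Number=1,Type=String,Description="Visual inspection status">',
    '##INFO=<ID=GeneticModels,Number=.,Type=String,Description="Compatible inheritance models">',
    '##INFO=<ID=RankScore,Number=1,Type=Integer,Description="Weighted-sum rank score">',
    '##INFO=<ID=RankResult,Number=1,Type=String,Description="Per-category points, colon separated">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t"))
  rows <- vapply(records, function(r) {
    base <- c(r$chrom, r$pos, r$id, r$ref, r$alt, ".", r$filter_status,
              annotations_to_info(r))
    if (length(samples))
      base <- c(base, "GT:DP:GQ:AD",
                vapply(r$per_sample[samples], format_sample_call, character(1)))
    paste(base, collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
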