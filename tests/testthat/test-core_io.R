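# Core I/O: VCF parse/split/write, normalization, PED, BED coordinates.

write_fixture_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               '##INFO=<ID=GENE,Number=.,Type=String,Description="g">',
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="d">',
               '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="q">',
               '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="a">',
               lines), path)
  path
}

test_that("read_vcf parses biallelic records and splits multi-allelic sites", {
  path <- write_fixture_vcf(c(
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t100\t.\tG\tA\t.\tPASS\tGENE=PKD1\tGT:DP:GQ:AD\t0/1:35:99:20,15",
    "2\t200\t.\tC\tA,T\t.\tPASS\t.\tGT:DP:GQ:AD\t1/2:40:80:10,18,12",
    "X\t5000000\t.\tT\tC\t.\tPASS\t.\tGT\t1"))
  recs <- read_vcf(path)
  expect_length(recs, 4L)
  # biallelic SNV, chr prefix stripped, fields mapped
  r1 <- recs[[1]]
  expect_equal(r1$chrom, "1")
  expect_equal(r1$variant_class, "SNV")
  expect_equal(r1$annotations$gene_symbols, "PKD1")
  expect_equal(r1$per_sample$S1$gt, c(0L, 1L))
  expect_equal(r1$per_sample$S1$dp, 35L)
  expect_equal(r1$per_sample$S1$ad, c(20L, 15L))
  # multi-allelic split shares chrom/pos/ref; per-allele AD follows its alt
  r2 <- recs[[2]]; r3 <- recs[[3]]
  expect_equal(c(r2$chrom, r3$chrom), c("2", "2"))
  expect_equal(c(r2$pos, r3$pos), c(200L, 200L))
  expect_equal(c(r2$alt, r3$alt), c("A", "T"))
  expect_equal(r2$per_sample$S1$ad, c(10L, 18L))
  expect_equal(r3$per_sample$S1$ad, c(10L, 12L))
  # GT 1/2 remaps per split record: own alt -> 1, other alt -> missing
  expect_equal(r2$per_sample$S1$gt, c(1L, NA_integer_))
  expect_equal(r3$per_sample$S1$gt, c(NA_integer_, 1L))
  # hemizygous single-index genotype on chrX; missing DP stays missing
  r4 <- recs[[4]]
  expect_equal(r4$per_sample$S1$gt, 1L)
  expect_true(is.na(r4$per_sample$S1$dp))
})

test_that("splitting preserves the (pos, ref, alt) multiset of a site", {
  path <- write_fixture_vcf(c(
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "4\t1234\t.\tGA\tG,GT,TA\t.\tPASS\t."))
  recs <- read_vcf(path)
  got <- sort(vapply(recs, function(r) paste(r$pos, r$ref, r$alt), character(1)))
  expect_equal(got, sort(c("1234 GA G", "1234 GA GT", "1234 GA TA")))
})

test_that("malformed input yields line-numbered format errors", {
  bad <- tempfile(fileext = ".vcf")
  writeLines(c("no header here", "1\t1\t.\tA\tG\t.\t.\t."), bad)
  expect_error(read_vcf(bad), "line 1")
  path <- write_fixture_vcf(c(
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1/1"))
  expect_error(read_vcf(path), "ploidy")
})

test_that("read_vcf agrees with VariantAnnotation on a shared fixture", {
  skip_if_not_installed("VariantAnnotation")
  tr <- generate_trio(synth_config(seed = 11L, n_sites = 40L))
  mine <- read_vcf(tr$vcf)
  va <- VariantAnnotation::readVcf(tr$vcf, genome = "hg19")
  va <- VariantAnnotation::expand(va)
  rr <- SummarizedExperiment::rowRanges(va)
  expect_length(mine, length(rr))
  expect_equal(vapply(mine, `[[`, integer(1), "pos"),
               unname(BiocGenerics::start(rr)))
  expect_equal(vapply(mine, `[[`, character(1), "ref"),
               as.character(rr$REF))
  expect_equal(vapply(mine, `[[`, character(1), "alt"),
               as.character(rr$ALT))
  gt <- VariantAnnotation::geno(va)$GT
  mine_gt <- vapply(mine, function(r)
    paste(r$per_sample[[tr$sample_ids[1]]]$gt, collapse = "/"), character(1))
  expect_equal(mine_gt, unname(gt[, tr$sample_ids[1]]))
})

test_that("normalize_variant trims suffix then prefix and is idempotent", {
  r <- normalize_variant(variant_record("1", 100L, "CAG", "CAT"))
  expect_equal(list(r$pos, r$ref, r$alt), list(102L, "G", "T"))
  # identity on an already-minimal SNV
  r2 <- normalize_variant(variant_record("1", 100L, "A", "T"))
  expect_equal(list(r2$pos, r2$ref, r2$alt), list(100L, "A", "T"))
  # symbolic alleles untouched
  sv <- variant_record("1", 500L, "N", "<DEL>")
  expect_identical(normalize_variant(sv)$alt, "<DEL>")
  # property: agreement with brute-force trimmer + idempotence, 500 random
  # allele pairs (scaled from the spec sketch of 1000 for test budget)
  set.seed(101)
  for (i in 1:500) {
    ref <- random_allele(); alt <- random_allele()
    if (ref == alt) next
    v <- variant_record("2", 1000L, ref, alt)
    n1 <- normalize_variant(v)
    o <- oracle_trim(1000L, ref, alt)
    expect_equal(list(n1$pos, n1$ref, n1$alt), list(o$pos, o$ref, o$alt))
    n2 <- normalize_variant(n1)
    expect_equal(list(n2$pos, n2$ref, n2$alt), list(n1$pos, n1$ref, n1$alt))
  }
})

test_that("read_ped builds trios with the affected child as index", {
  path <- tempfile(fileext = ".ped")
  writeLines(c("FAM1\tkid\tdad\tmom\t2\t2",
               "FAM1\tmom\t0\t0\t2\t1",
               "FAM1\tdad\t0\t0\t1\t1"), path)
  peds <- read_ped(path)
  expect_length(peds, 1L)
  expect_equal(peds$FAM1$index_id, "kid")
  expect_equal(peds$FAM1$individuals$kid$mother_id, "mom")
  expect_equal(peds$FAM1$individuals$kid$sex, "female")
  # unknown parent id is a structural error naming the id
  writeLines(c("FAM2\tkid\tghost\t0\t1\t2"), path)
  expect_error(read_ped(path), "ghost")
})

test_that("pedigree rejects ancestry cycles", {
  expect_error(pedigree("F", list(
    individual("a", mother_id = "b"),
    individual("b", mother_id = "a"))), "ancestor")
})

test_that("BED masks use 0-based half-open coordinates", {
  path <- tempfile(fileext = ".bed")
  writeLines("1\t999\t1100", path)
  mask <- read_bed_mask(path)
  expect_false(mask_overlaps(mask, "1", 999L))   # BED start is exclusive 1-based
  expect_true(mask_overlaps(mask, "1", 1000L))
  expect_true(mask_overlaps(mask, "1", 1100L))
  expect_false(mask_overlaps(mask, "1", 1101L))
  expect_false(mask_overlaps(mask, "2", 1000L))
  # a deletion's reference span can reach into the mask
  del <- variant_record("1", 995L, "AAAAAAA", "A")
  expect_true(mask_overlaps_record(mask, del))
})

test_that("scored VCF round-trips records losslessly", {
  tr <- generate_trio(synth_config(seed = 5L, n_sites = 30L,
                                   planted = list(list(model = "AD_dn",
                                                       gene = "PKD1"))))
  recs <- read_vcf(tr$vcf)
  out <- tempfile(fileext = ".vcf")
  write_scored_vcf(recs, out)
  back <- read_vcf(out)
  expect_length(back, length(recs))
  for (i in seq_along(recs)) {
    expect_equal(variant_key(back[[i]]), variant_key(recs[[i]]))
    expect_equal(back[[i]]$filter_status, recs[[i]]$filter_status)
    expect_equal(back[[i]]$annotations, recs[[i]]$annotations)
    expect_equal(back[[i]]$per_sample, recs[[i]]$per_sample)
  }
})
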