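# Family QC: STR classification, trio concordance, fingerprinting, UPD.

catalog <- read_str_catalog(system.file("extdata", "str_catalog.tsv",
                                        package = "clinwgs"))

test_that("STR classification follows the rule table", {
  cat2 <- data.frame(locus_id = c("AD1", "AR1"), gene = c("g", "h"),
                     repeat_unit = "CAG", normal_max = 35L,
                     pathologic_min = 40L,
                     inheritance = c("AD", "AR"), stringsAsFactors = FALSE)
  expect_equal(classify_str(list(locus_id = "AD1", allele_sizes = c(30L, 20L)),
                            cat2)$statuses, c("normal", "normal"))
  # intermediate zone
  r <- classify_str(list(locus_id = "AD1", allele_sizes = c(37L, 10L)), cat2)
  expect_equal(r$statuses[1], "intermediate")
  expect_false(r$reportable)
  # biallelic expansion at an AR locus is reportable
  expect_true(classify_str(list(locus_id = "AR1", allele_sizes = c(45L, 46L)),
                           cat2)$reportable)
  # monoallelic expansion: reportable at AD, not at AR
  expect_true(classify_str(list(locus_id = "AD1", allele_sizes = c(45L, 12L)),
                           cat2)$reportable)
  expect_false(classify_str(list(locus_id = "AR1", allele_sizes = c(45L, 12L)),
                            cat2)$reportable)
  expect_error(classify_str(list(locus_id = "nope", allele_sizes = 1L), cat2),
               "unknown locus")
  # piecewise-constant and monotone in allele size
  stat_of <- function(s) classify_str(list(locus_id = "AD1",
                                           allele_sizes = s), cat2)$statuses
  levels_seen <- vapply(1:60, function(s) stat_of(s), character(1))
  expect_equal(unique(levels_seen), c("normal", "intermediate", "expanded"))
  expect_true(all(diff(match(levels_seen,
                             c("normal", "intermediate", "expanded"))) >= 0))
})

test_that("the shipped catalog validates", {
  expect_true(all(catalog$normal_max < catalog$pathologic_min))
})

test_that("trio concordance confirms real trios and flags swaps", {
  set.seed(4)
  good <- sim_trio_genotypes(n_sites = 1000L, error_rate = 0)
  r <- trio_concordance(good)
  expect_equal(r$mendelian_error_fraction, 0)
  expect_true(r$relationship_confirmed)
  # an unrelated child shows errors far above threshold; with AF 0.5 the
  # per-site inconsistency probability is 1/8 + 1/16 + ... ~ 0.19 by
  # enumeration of HWE genotype combinations
  swap <- sim_trio_genotypes(n_sites = 1000L, child = "unrelated")
  r2 <- trio_concordance(swap)
  expect_equal(r2$status, "failed")
  expect_gt(r2$mendelian_error_fraction, 0.10)
  # too few informative sites is inconclusive, not a pass
  few <- sim_trio_genotypes(n_sites = 100L)
  expect_equal(trio_concordance(few)$status, "inconclusive")
  expect_false(trio_concordance(few)$relationship_confirmed)
})

test_that("fingerprint comparison passes, fails and abstains correctly", {
  sites <- sprintf("rs%02d", 1:51)
  wgs <- setNames(sample(c("AA", "AB", "BB"), 51L, TRUE), sites)
  expect_equal(fingerprint_check(wgs, wgs)$verdict, "pass")
  arr <- wgs
  arr[1:11] <- ifelse(arr[1:11] == "AA", "BB", "AA")
  r <- fingerprint_check(wgs, arr)   # 40/51 = 0.784 < 0.95
  expect_equal(r$verdict, "fail")
  expect_equal(r$n_match, 40L)
  # missing calls leave the denominator
  arr2 <- wgs; arr2[1:25] <- NA
  expect_equal(fingerprint_check(wgs, arr2)$n_compared, 26L)
  expect_equal(fingerprint_check(wgs, arr2)$verdict, "inconclusive")
})

test_that("detect_upd flags a planted isodisomy with thresholds as stated", {
  set.seed(8)
  g <- sim_trio_genotypes(n_sites = 400L, chroms = "7", child = "upd",
                          upd_parent = "maternal")
  call <- detect_upd(g, "7")
  expect_false(is.null(call))
  expect_equal(call$parent_of_origin, "maternal")
  expect_equal(call$subtype, "isodisomy_suggestive")
  expect_gte(call$signal_fraction, 0.9)
  expect_gte(call$n_signal_sites, 10L)
  # paternal direction detected symmetrically
  gp <- sim_trio_genotypes(n_sites = 400L, chroms = "7", child = "upd",
                           upd_parent = "paternal")
  expect_equal(detect_upd(gp, "7")$parent_of_origin, "paternal")
  # no signal sites -> no call; too few informative sites -> no call
  expect_null(detect_upd(sim_trio_genotypes(n_sites = 400L, chroms = "7",
                                            error_rate = 0), "7"))
  expect_null(detect_upd(sim_trio_genotypes(n_sites = 20L, chroms = "7"), "7"))
})

test_that("a planted maternal chr7 UPD survives the full trio generator", {
  tr <- generate_trio(synth_config(seed = 19L, n_sites = 600L,
                                   upd = list(chrom = "7",
                                              parent = "maternal")))
  recs <- read_vcf(tr$vcf)
  geno <- trio_genotypes(recs, tr$pedigree)
  call <- detect_upd(geno, "7")
  expect_equal(call$parent_of_origin, "maternal")
  # other chromosomes stay silent
  expect_null(detect_upd(geno, "1"))
})
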