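# Inheritance model deduction and compound-het pairing.

test_that("trio examples deduce the expected model sets", {
  # de novo dominant: het child, hom-ref well-covered parents
  a <- deduce_trio(c(0L, 1L), c(0L, 0L), c(0L, 0L))
  expect_setequal(a$models, "AD_dn")
  expect_true(a$confident_de_novo)
  # recessive: hom child, carrier parents
  b <- deduce_trio(c(1L, 1L), c(0L, 1L), c(0L, 1L))
  expect_setequal(b$models, "AR_hom")
  expect_false(b$confident_de_novo)
  # inherited dominant needs an affected transmitting parent
  rec <- mk_trio_record("0/1", "0/1", "0/0")
  ped <- mk_trio_ped(mother_aff = "affected")
  expect_setequal(deduce_models(rec, ped)$models, "AD")
  # ... and is excluded by an unaffected carrier unless penetrance is reduced
  ped2 <- mk_trio_ped()
  expect_length(deduce_models(rec, ped2)$models, 0L)
  opts <- inheritance_options(reduced_penetrance = TRUE)
  expect_true("AD" %in% deduce_models(rec, ped2, opts)$models)
})

test_that("affected singleton male on chrX lists all X models", {
  rec <- variant_record("X", 5000000L, "A", "G",
                        per_sample = list(kid = mk_call("1")))
  asn <- deduce_models(rec, mk_singleton_ped(sex = "male"))
  expect_setequal(asn$models, c("XR", "XR_dn", "XD", "XD_dn"))
  # PAR positions behave as autosomal
  par_rec <- variant_record("X", 61000L, "A", "G",
                            per_sample = list(kid = mk_call("0/1")))
  expect_setequal(deduce_models(par_rec, mk_singleton_ped(sex = "male"))$models,
                  c("AD", "AD_dn"))
})

test_that("mosaic alt fractions below threshold are flagged", {
  rec <- mk_trio_record("0/1", "0/0", "0/0", ad = c(29L, 4L), dp = 33L)
  asn <- deduce_models(rec, mk_trio_ped())
  expect_true(asn$mosaic_suspect)   # 4/33 ~ 0.12 < 0.20
  expect_true("AD_dn" %in% asn$models)
  rec2 <- mk_trio_record("0/1", "0/0", "0/0", ad = c(15L, 15L), dp = 30L)
  expect_false(deduce_models(rec2, mk_trio_ped())$mosaic_suspect)
})

test_that("de novo confidence requires parental depth", {
  per <- list(kid = mk_call("0/1"),
              mom = sample_call(gt = c(0L, 0L), dp = 5L, gq = 99L),
              dad = mk_call("0/0"))
  rec <- variant_record("1", 1000L, "A", "G", per_sample = per)
  asn <- deduce_models(rec, mk_trio_ped())
  expect_true("AD_dn" %in% asn$models)
  expect_false(asn$confident_de_novo)
})

test_that("deduction matches the brute-force oracle on all autosomal trios", {
  gts <- list(NULL, c(0L, 0L), c(0L, 1L), c(1L, 1L))
  for (cg in gts) for (mg in gts) for (fg in gts) {
    got <- deduce_trio(cg, mg, fg)$models
    want <- oracle_trio_models(cg, mg, fg)
    expect_setequal(got, want)
  }
})

test_that("deduction matches the brute-force oracle on chrX with sexes", {
  dip <- list(NULL, c(0L, 0L), c(0L, 1L), c(1L, 1L))
  hemi <- list(NULL, 0L, 1L)
  for (sex in c("male", "female")) {
    kid_gts <- if (sex == "male") hemi else dip
    for (cg in kid_gts) for (mg in dip) for (fg in hemi) {
      got <- deduce_trio(cg, mg, fg, chrom = "X", child_sex = sex)$models
      want <- oracle_trio_models(cg, mg, fg, chrom = "X", child_sex = sex)
      expect_setequal(got, want)
    }
  }
})

test_that("removing a genotyped relative never shrinks the model set", {
  gts <- list(c(0L, 0L), c(0L, 1L), c(1L, 1L))
  for (cg in gts) for (mg in gts) for (fg in gts) {
    full <- deduce_trio(cg, mg, fg)$models
    no_dad <- deduce_trio(cg, mg, NULL)$models
    no_mom <- deduce_trio(cg, NULL, fg)$models
    expect_true(all(full %in% no_dad))
    expect_true(all(full %in% no_mom))
  }
})

test_that("mitochondrial variants classify maternal/de novo/undetermined", {
  mk_mt <- function(mom_gt) {
    per <- list(kid = mk_call("1"))
    if (!is.null(mom_gt)) per$mom <- mk_call(mom_gt)
    per$dad <- mk_call("0")
    variant_record("MT", 3243L, "A", "G", per_sample = per)
  }
  ped <- mk_trio_ped()
  a <- deduce_models(mk_mt("1"), ped)
  expect_equal(a$models, "MT"); expect_equal(a$mt_origin, "maternal")
  b <- deduce_models(mk_mt("0"), ped)
  expect_equal(b$mt_origin, "de_novo")
  d <- deduce_models(mk_mt(NULL), ped)
  expect_equal(d$mt_origin, "undetermined")
})

test_that("compound-het pairing resolves trans, cis and unknown phase", {
  ped <- mk_trio_ped()
  a <- mk_trio_record("0/1", "0/1", "0/0", pos = 100L, gene = "NPHS1")
  b <- mk_trio_record("0/1", "0/0", "0/1", pos = 200L, gene = "NPHS1")
  c_ <- mk_trio_record("0/1", "0/1", "0/0", pos = 300L, gene = "NPHS1")
  d <- mk_trio_record("0/1", "0/0", "0/0", pos = 400L, gene = "NPHS1")
  # trans pair
  p <- pair_compound_hets(list(a, b), ped)
  expect_length(p, 1L)
  expect_equal(p[[1]]$model, "AR_comp")
  expect_true(p[[1]]$phase_known)
  # both maternal: proven cis, no pair
  expect_length(pair_compound_hets(list(a, c_), ped), 0L)
  # one side de novo
  p2 <- pair_compound_hets(list(a, d), ped)
  expect_equal(p2[[1]]$model, "AR_comp_dn")
  # singleton: all C(3,2) pairs, phase unknown
  sped <- mk_singleton_ped(sex = "female")
  recs <- lapply(c(10L, 20L, 30L), function(p)
    variant_record("1", p, "A", "G",
                   per_sample = list(kid = mk_call("0/1")),
                   annotations = annotation_set(gene_symbols = "NPHS1")))
  p3 <- pair_compound_hets(recs, sped)
  expect_length(p3, 3L)
  expect_true(all(!vapply(p3, `[[`, logical(1), "phase_known")))
  # a variant never pairs with itself
  expect_length(pair_compound_hets(recs[1], sped), 0L)
})

test_that("disjoint sample ids raise a pairing error", {
  rec <- variant_record("1", 10L, "A", "G",
                        per_sample = list(other = mk_call("0/1")))
  expect_error(deduce_models(rec, mk_trio_ped()), "pairing error")
})
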