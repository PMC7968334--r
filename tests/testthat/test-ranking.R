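# Rank model loading, validation, scoring and ordering.

test_that("the shipped default config loads with the expected categories", {
  cfg <- load_rank_model(default_rank_model_path())
  expect_s3_class(cfg, "rank_model_config")
  expect_setequal(vapply(cfg$categories, `[[`, character(1), "name"),
                  c("frequency", "consequence", "conservation",
                    "deleteriousness", "inheritance", "clinical_significance",
                    "local_observations", "call_quality"))
})

write_cfg <- function(lines) {
  path <- tempfile(fileext = ".ini")
  writeLines(lines, path)
  path
}

test_that("the validator rejects broken configs", {
  # frequency points increasing with AF
  expect_error(load_rank_model(write_cfg(c(
    "[category.frequency]", "default = 0",
    "rule.1 = population_af in [0,0.01) => 1",
    "rule.2 = population_af in [0.01,1) => 5"))), "non-increasing")
  # duplicate category
  expect_error(load_rank_model(write_cfg(c(
    "[category.frequency]", "default = 0",
    "[category.frequency]", "default = 1"))), "duplicate category")
  # duplicate rule index = ambiguous order
  expect_error(load_rank_model(write_cfg(c(
    "[category.consequence]", "default = 0",
    "rule.1 = consequence is stop_gained => 5",
    "rule.1 = consequence is stop_lost => 3"))), "ambiguous")
  # unknown field key fails at load time, not score time
  expect_error(load_rank_model(write_cfg(c(
    "[category.frequency]", "default = 0",
    "rule.1 = no_such_field missing => 2"))), "field_key")
})

test_that("scoring is first-match per category with defaults as fallback", {
  cfg <- load_rank_model(default_rank_model_path())
  rec <- variant_record("1", 100L, "A", "G", filter_status = "PASS",
                        per_sample = list(S1 = mk_call("0/1")),
                        annotations = annotation_set(
                          gene_symbols = "PKD1", consequence = "stop_gained"))
  asn <- structure(list(models = "AD_dn"), class = "model_assignment")
  s <- score_variant(rec, asn, cfg)
  # hand evaluation of the shipped config on this fixture:
  # frequency: POPAF missing -> 4; consequence stop_gained -> 8;
  # conservation missing (no rule matches) -> default 0; deleteriousness 0;
  # inheritance AD_dn -> 4; clnsig default 0; local_obs missing -> 1;
  # call_quality PASS -> 1. Total 18.
  expect_equal(unname(s$per_category),
               c(4L, 8L, 0L, 0L, 4L, 0L, 1L, 1L))
  expect_equal(s$total, 18L)
  expect_equal(s$rank_result_token, "4:8:0:0:4:0:1:1")
  # empty category rules: every variant gets the default
  cfg2 <- load_rank_model(write_cfg(c("[category.consequence]", "default = 7")))
  expect_equal(score_variant(rec, NULL, cfg2)$total, 7L)
  # pure function: identical inputs, identical result
  expect_identical(score_variant(rec, asn, cfg), s)
})

test_that("all-missing annotations score the sum of category defaults", {
  cfg <- load_rank_model(default_rank_model_path())
  rec <- variant_record("1", 100L, "A", "G", filter_status = ".")
  s <- score_variant(rec, NULL, cfg)
  # defaults 2+0+0+0+0+0+1+0, plus first-match 'missing' rules for
  # frequency (4) and local_obs (1) which fire on absent values
  expect_equal(s$total, 4L + 0L + 0L + 0L + 0L + 0L + 1L + 0L)
})

test_that("decreasing population_af never decreases the total", {
  cfg <- load_rank_model(default_rank_model_path())
  mk <- function(af) variant_record("1", 100L, "A", "G",
    annotations = annotation_set(population_af = af, consequence = "missense_variant"))
  afs <- c(0.5, 0.05, 0.01, 0.004, 0.0005, 0.00005, 0)
  totals <- vapply(afs, function(af) score_variant(mk(af), NULL, cfg)$total,
                   integer(1))
  expect_true(all(diff(totals) >= 0))
})

test_that("a local-observation penalty can only lower or preserve rank", {
  cfg <- load_rank_model(default_rank_model_path())
  mk <- function(obs) variant_record("1", 100L, "A", "G",
    annotations = annotation_set(local_obs = obs))
  expect_true(score_variant(mk(20L), NULL, cfg)$total <=
                score_variant(mk(0L), NULL, cfg)$total)
})

test_that("rank_case orders by score with positional tie-breaks", {
  cfg <- load_rank_model(default_rank_model_path())
  mk <- function(chrom, pos, csq) {
    r <- variant_record(chrom, pos, "A", "G",
                        annotations = annotation_set(population_af = 0.5,
                                                     consequence = csq))
    r$rank_score_obj <- score_variant(r, NULL, cfg)
    r
  }
  # scores: missense twice (tied), stop_gained (top), synonymous (last)
  recs <- list(mk("2", 500L, "missense_variant"), mk("1", 900L, "stop_gained"),
               mk("1", 700L, "missense_variant"), mk("3", 100L, "synonymous_variant"))
  ranked <- rank_case(recs)
  expect_equal(ranked$key[1], "1-900-A-G")
  expect_equal(ranked$key[2], "1-700-A-G")   # tie: lower chrom/pos first
  expect_equal(ranked$key[3], "2-500-A-G")
  expect_equal(ranked$rank, 1:4)
  # single record ranks 1
  expect_equal(rank_case(recs[2])$rank, 1L)
  # permutation invariance
  set.seed(9)
  for (i in 1:5) {
    perm <- sample(seq_along(recs))
    expect_equal(rank_case(recs[perm])$key, ranked$key)
  }
  # top-N cutoff keeps the full ordering as an attribute
  top <- rank_case(recs, top_n = 2L)
  expect_equal(nrow(top), 2L)
  expect_equal(attr(top, "full")$key, ranked$key)
})
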