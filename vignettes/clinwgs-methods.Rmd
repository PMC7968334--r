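---
title: "clinwgs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clinwgs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinwgs)
```

`clinwgs` models the downstream, interpretation-side stages of a clinical
rare-disease WGS workflow. This vignette is the package's own account of
the science it implements: the procedures and their assumptions, every
tunable parameter with its default and rationale, what the synthetic data
emulates (and what it does not), and the choices made where the design was
genuinely open. No empirical claim is made here that the test suite or
`scripts/acceptance.R` does not itself compute.

## Variant representation and normalization

All logic is biallelic: multi-allelic VCF sites are split on ingest into
one record per alternate allele, with the matching per-allele AD carried
along and genotype indices remapped (an allele pointing at a *different*
alt becomes missing in the split record). Missing DP/GQ/AD stay missing —
they never default to zero, because downstream triage must treat "no
evidence" as failing a criterion, not as evidence of failure. Chromosome
labels are stored without a `chr` prefix; both dialects parse.

`normalize_variant()` trims the shared allele suffix, then the shared
prefix (keeping at least one base of each allele, adjusting the position),
and is idempotent. **Limitation:** reference-guided left alignment is out
of scope — two representations of the same indel separated by a repeat
tract will not be unified, which can fragment local-observation counts at
such loci.

## Inheritance model deduction

For each variant and family, `deduce_models()` returns the subset of
{AD, AD_dn, AR_hom, AR_hom_dn, XD, XD_dn, XR, XR_dn, MT} consistent with
the observed genotypes. The semantics, stated once:

* Only *genotyped* members constrain the result; ungenotyped members and
  members of unknown affection status impose no constraint. A singleton
  therefore returns every model consistent with the index genotype alone.
* A **plain model** requires (a) every affected genotyped member to carry
  the model's causal configuration — heterozygous for AD/XD, homozygous
  alt for AR_hom, hemizygous/homozygous alt for XR; (b) no unaffected
  genotyped member to carry it (for dominant models, any alt allele
  excludes; for recessive models, carriers are tolerated and only the full
  causal configuration excludes); and (c) transmissibility: the affected
  members' alt alleles must be obtainable from their genotyped parents (a
  het child with both parents genotyped hom-ref cannot be *inherited*
  dominant).
* A **`_dn` sub-model** requires (a) and (b) plus the alt allele being
  absent from every genotyped parent of every affected member. This is the
  classical "variant not seen in the parents" rule. A consequence accepted
  as part of the contract: a homozygous child with one carrier and one
  non-carrier parent matches neither AR_hom (untransmittable) nor
  AR_hom_dn (a parent carries) — a deliberate conservative gap rather than
  a silent guess.

Tunables: `min_parent_depth = 10` reads — below it a de novo call is still
listed but `confident_de_novo` stays `FALSE` (absence of evidence is not
evidence of absence; the source workflow does not state a value, so a
conventional trio-analysis floor was chosen). `mosaic_af = 0.20` — an
index alt-allele fraction below this flags `mosaic_suspect` while keeping
dominant models, because genuinely causal mosaics at fractions near 0.1
occur in practice. `reduced_penetrance = FALSE` — when enabled, unaffected
carriers no longer exclude dominant models. The hg19 pseudoautosomal
regions (X:60001–2,699,520 and X:154,931,044–155,260,560) are treated as
autosomal; a diploid male chrX call outside them is coerced to hemizygous
with a warning (alt wins), accommodating caller heterogeneity.

Mitochondrial variants carried by the index get model `MT`, sub-classified
maternal (mother carries), de novo (mother genotyped and negative) or
undetermined (mother ungenotyped).

**Compound heterozygotes.** `pair_compound_hets()` pairs index-het
variants within a gene. With informative parents, a pair proven *trans*
(one maternal-only, one paternal-only) is `AR_comp` with known phase; a
pair with a de novo side is `AR_comp_dn`; a pair proven *cis* (both from
the same single parent) is dropped. Ambiguous parental patterns (e.g. a
parent carrying both variants) and parentless cases return the pair with
`phase_known = FALSE` — candidates for inspection, not assertions.

## The rank model

Scoring is a weighted sum over ordered categories; within a category the
*first* matching rule wins, else the category default applies.
First-match-in-declared-order was chosen over max-of-matches because it is
the simplest semantics that is still fully deterministic and
hand-auditable; scores are integers for exact, stable ordering. Ties in
`rank_case()` break by (chrom, pos, ref, alt), so ranking is invariant
under input permutation.

The shipped config (`inst/extdata/rank_model_snv.ini`) covers rarity,
protein consequence, conservation, deleteriousness, inheritance support,
prior clinical assertions, cohort-local observations and call quality.
Its point values are this package's own defaults, chosen for sane
out-of-box behaviour — they are *not* any production laboratory's weights,
which live outside this package. The loader validates configs: unknown
field keys and duplicate categories fail at load time (never at score
time), duplicate rule indices are rejected as ambiguous ordering, and the
frequency category must have non-increasing points as the interval lower
bound increases, which guarantees the "rarer never scores lower"
monotonicity the tests assert. Phenotype terms deliberately do not enter
the score. A separate SV rank model is supported only in the sense that
any number of config files can be loaded; no SV-specific default ships.

## Local observation database

One individual — the family index — is counted per family, so recurrence
reflects *families observed*, not sequenced genomes. Keys are normalized
`(chrom, pos, ref, alt)`; homozygous and hemizygous alt index calls also
increment the hom counter (whether a production system counts hemizygotes
separately is unstated; here they count as obs + hom). Loading is
idempotent per family id, making stores invariant to load order. The
artifact flag fires at local frequency ≥ 0.05 — no published value
exists, so the default is conservative and configurable; a variant seen in
5% of a local cohort is either common (and caught by population
frequency) or a pipeline artifact, and both deserve down-weighting.
Persistence is a flat TSV, one line per key: desk-scale reproducibility
over server infrastructure.

## Panels and HPO

Gene matching is by uppercased symbol string; alias resolution would need
a user-supplied table and is off by default, since no identifier system is
mandated by the inputs. HPO-generated panels are the plain union of the
term→gene map over the supplied terms (`min_terms = k` tightens to genes
hit by ≥ k terms); ontology-descendant closure is *not* applied — it
would require shipping an ontology file, and whether production panels
closed over descendants is unknown. Filtering keeps records with ≥ 1
panel gene and reports the dropped count.

## Confirmation triage

`triage_variant()` is the conjunction of six criteria: single-base
substitution; depth ≥ 20 (the stated "20x" read as inclusive, and
documented as such); genotype quality *equal to* the caller maximum 99
(equality, not ≥, mirroring the stated criterion; configurable for other
callers); FILTER `PASS`; reference span outside segmental duplications;
and visual inspection recorded as good. The inspection criterion is an
input flag, not image analysis; its default `unset` fails the criterion,
so un-reviewed variants are always confirmed — clinical conservatism.
Missing depth or quality likewise fail. Non-SNV classes always confirm.
The "wrong nomenclature" false-positive class described for INDELs is a
representation issue that cannot be decided from a single call record and
is excluded from the logic.

## Family QC, STR and UPD

**Trio concordance** counts Mendelian-impossible child dosages over
autosomal sites with all three members genotyped; ≥ 200 informative sites
are required (fewer is *inconclusive*, never a pass) and the default
failure threshold is an error fraction of 0.02. **Fingerprinting**
compares WGS genotypes to an orthogonal panel (≥ 30 comparable sites,
pass at ≥ 95% matches). **STR calls** are classified per allele against a
catalog (`normal ≤ normal_max < pathologic_min ≤ expanded`); the shipped
catalog is an editable example with no claim of matching production
thresholds.

**UPD screening** is this package's own statistic — the upstream
capability is named but not specified, so the method is stated here in
full: at sites where the parents are opposite homozygotes the child must
be heterozygous; a *signal site* is such a site where the child is instead
homozygous, and the parent of origin is the one whose allele the child is
homozygous for. A call needs ≥ 10 signal sites and ≥ 90% of
opposite-homozygote sites signalling toward one parent. Subtype:
isodisomy-suggestive when the chromosome's run-of-homozygosity fraction
(runs of ≥ 50 consecutive homozygous child sites spanning ≥ 1 Mb) reaches
0.8; otherwise heterodisomy-suggestive when the child/other-parent duo
alone shows ≥ 10 impossible sites; otherwise undetermined. At these
thresholds the detector emits no call on 1000 simulated biparental trios
(an acceptance criterion), trading sensitivity to partial/segmental UPD
for desk-scale specificity.

## Coverage

Completeness at cutoff *c* is the fraction of transcript bases at depth
≥ *c*, from a sparse BED4 track in which absent bases count as depth 0
(sparse tracks are the norm; erroring would make every report fail).
`fully_covered` demands completeness exactly 1. Defaults report cutoffs
{10, 20, 30} with 10 as the headline — no production cutoff is published,
and 10x is a common clinical floor. Integer base arithmetic makes the
equality in `fully_covered` exact.

## Cohort reporting and its fixtures

Percentages are integers, rounded half away from zero, and every table
carries its numerators and denominators. Grouped yields partition the
totals; a case analyzed with several panels counts once per panel in
panel-grouped yields.

`generate_case_results()` realizes *printed study marginals* as case-level
records: per-panel analysis and solved counts, 3219 cases of which 1285
solved, 3750 panel analyses, the determined inheritance split
(468/235/107/48/11), a recurrence profile with 754 genes of which 496
single-case, and 4437 individuals. Where the printed numbers are
internally inconsistent the component counts win: the per-panel solved
counts sum to 1289, so four positive analyses are assigned to
already-solved cases (dual diagnoses); the determined-inheritance
components sum to 869, and the published non-SNV categories sum to 63
against a stated total of 64, so one finding of category "other" is
added. The split of assumed inheritance (347/36/33) is chosen to match
the published combined totals. These fixtures exercise the *reporting
arithmetic*; they are not evidence about any real cohort.

The confirmation-triage fixture realizes the published composition of the
721 retrospectively evaluated findings: 503 SNVs at GQ 99, 493 of them
PASS, 484 finally skippable. The unpublished splits (INDEL vs low-GQ
among the 218 excluded; depth/inspection/segdup among the 9 post-PASS
failures) are fixed once at 180/38 and 3/3/3; the 67% skip fraction is
invariant to those choices.

## The synthetic trio generator

`generate_trio()` draws parental genotypes in Hardy–Weinberg proportions
from a point-mass frequency spectrum {0.5, 0.1, 0.01, 0.001} (simple,
controllable informativeness for trio QC), transmits one allele per
parent to the child with a 0.5% per-allele error rate, and inserts
planted variants whose genotypes realize the requested model — including
trans compound-het pairs and an isodisomic-chromosome mode. Same seed,
same bytes. What it does **not** emulate: linkage disequilibrium, realistic
site spacing, sequencing-error profiles, population structure, structural
variants, or annotation noise. A green end-to-end test therefore
establishes that the *logic* recovers planted configurations, not that
the workflow performs at any particular level on real genomes. Plantings
used for the recovery criterion are the six unambiguous ones (AD, AD_dn,
AR_hom, XR, XD_dn, MT); a hemizygous de novo (XR_dn) is inherently
indistinguishable from XD_dn in a male trio and is excluded from the
uniqueness count.

## Known limitations

* No reference-guided left alignment; obsdb keys can fragment in repeats.
* X-model deduction ignores X-inactivation skew; imprinting and digenic
  models are out of scope.
* The UPD screen targets whole-chromosome disomy; segmental UPD and
  heterodisomy with few informative sites will be missed.
* Gene symbols are matched as strings; no alias/ID resolution by default.
* The shipped rank weights and STR thresholds are illustrative defaults,
  not clinically validated values.
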