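# Cohort-level diagnostic reporting: yields, inheritance distribution and
# gene recurrence. All percentages are integer, rounded half away from
# zero, and every table carries its raw numerator/denominator so results
# are recomputable.

INHERITANCE_CATEGORIES <- c("AR", "de_novo", "AD_inherited", "XL_inherited",
                            "MT", "assumed_AD", "assumed_AR", "assumed_XL")

#' Assemble cohort case results
#'
#' @param cases `data.frame` with columns `case_id`, `analysis_type`
#'   (`"singleton"`/`"trio_family"`), `solved` (logical).
#' @param analyses `data.frame` with columns `case_id`, `panel`, `positive`
#'   (logical); one row per panel analysis (a case analyzed with several
#'   panels contributes several rows).
#' @param findings `data.frame` with columns `case_id`, `gene`,
#'   `variant_key`, `inheritance_category` (see `INHERITANCE_CATEGORIES`),
#'   `determined` (logical).
#' @return object of class `case_results`.
#' @export
case_results <- function(cases, analyses = NULL, findings = NULL) {
  stopifnot(all(c("case_id", "analysis_type", "solved") %in% names(cases)))
  if (anyDuplicated(cases$case_id)) stop("duplicate case ids")
  if (!is.null(findings) && nrow(findings)) {
    bad <- setdiff(findings$inheritance_category, INHERITANCE_CATEGORIES)
    if (length(bad)) stop("unknown inheritance categories: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(cases = cases, analyses = analyses, findings = findings),
            class = "case_results")
}

#' Diagnostic yield summary
#'
#' Ungrouped: case-level solved fraction. `group_by = "panel"`: one row per
#' panel from the analyses table (a case analyzed with several panels counts
#' once per panel). `group_by = "analysis_type"`: case-level, split by
#' singleton vs trio/family.
#'
#' @param cr a [case_results()].
#' @param group_by `NULL`, `"panel"` or `"analysis_type"`.
#' @return `data.frame` with `group`, `n_cases`, `n_solved`, `pct_solved`;
#'   ungrouped results also carry attributes `panels_per_case` (2 decimals)
#'   and `n_analyses`.
#' @export
yield_summary <- function(cr, group_by = NULL) {
  if (nrow(cr$cases) == 0L) stop("yield_summary: no cases")
  pct <- function(num, den) round_half_away(100 * num / den)
  if (is.null(group_by)) {
    out <- data.frame(group = "all", n_cases = nrow(cr$cases),
                      n_solved = sum(cr$cases$solved),
                      stringsAsFactors = FALSE)
    out$pct_solved <- pct(out$n_solved, out$n_cases)
    if (!is.null(cr$analyses)) {
      attr(out, "n_analyses") <- nrow(cr$analyses)
      attr(out, "panels_per_case") <-
        round(nrow(cr$analyses) / length(unique(cr$analyses$case_id)), 2)
      attr(out, "pct_positive_analyses") <-
        pct(sum(cr$cases$solved), nrow(cr$analyses))
    }
    return(out)
  }
  group_by <- match.arg(group_by, c("panel", "analysis_type"))
  if (group_by == "panel") {
    if (is.null(cr$analyses)) stop("yield_summary: no analyses table")
    sp <- split(cr$analyses, cr$analyses$panel)
    out <- do.call(rbind, lapply(names(sp), function(p)
      data.frame(group = p, n_cases = nrow(sp[[p]]),
                 n_solved = sum(sp[[p]]$positive), stringsAsFactors = FALSE)))
  } else {
    sp <- split(cr$cases, cr$cases$analysis_type)
    out <- do.call(rbind, lapply(names(sp), function(t)
      data.frame(group = t, n_cases = nrow(sp[[t]]),
                 n_solved = sum(sp[[t]]$solved), stringsAsFactors = FALSE)))
  }
  out$pct_solved <- pct(out$n_solved, out$n_cases)
  rownames(out) <- NULL
  out
}

#' Inheritance-mode distribution of positive findings
#'
#' Percentages of the determined categories use the determined-only
#' denominator; the combined block totals over all findings (determined plus
#' assumed).
#'
#' @param cr a [case_results()] with a findings table.
#' @return list with `determined` (data.frame category/n/pct),
#'   `n_determined`, `combined` (data.frame over all categories) and
#'   `n_total`.
#' @export
inheritance_distribution <- function(cr) {
  f <- cr$findings
  if (is.null(f) || nrow(f) == 0L) stop("inheritance_distribution: no findings")
  det <- f[f$determined, , drop = FALSE]
  n_det <- nrow(det)
  det_cat <- c("AR", "de_novo", "AD_inherited", "XL_inherited", "MT")
  determined <- data.frame(
    category = det_cat,
    n = vapply(det_cat, function(k) sum(det$inheritance_category == k),
               integer(1)),
    stringsAsFactors = FALSE)
  determined$pct <- round_half_away(100 * determined$n / n_det)
  combined <- data.frame(
    category = INHERITANCE_CATEGORIES,
    n = vapply(INHERITANCE_CATEGORIES,
               function(k) sum(f$inheritance_category == k), integer(1)),
    stringsAsFactors = FALSE)
  combined$pct <- round_half_away(100 * combined$n / nrow(f))
  rownames(determined) <- rownames(combined) <- NULL
  list(determined = determined, n_determined = n_det,
       combined = combined, n_total = nrow(f))
}

#' Gene recurrence across the cohort
#'
#' @param cr a [case_results()] with a findings table.
#' @return list with `table` (gene, n_cases; descending count, ties
#'   alphabetical), `n_genes`, `n_single_case` and `pct_single_case`.
#' @export
gene_recurrence <- function(cr) {
  f <- cr$findings
  if (is.null(f) || nrow(f) == 0L)
    return(list(table = data.frame(gene = character(), n_cases = integer()),
                n_genes = 0L, n_single_case = 0L, pct_single_case = NA_real_))
  counts <- tapply(f$case_id, toupper(f$gene),
                   function(x) length(unique(x)))
  tab <- data.frame(gene = names(counts), n_cases = as.integer(counts),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$n_cases, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  n_single <- sum(tab$n_cases == 1L)
  list(table = tab, n_genes = nrow(tab), n_single_case = n_single,
       pct_single_case = round_half_away(100 * n_single / nrow(tab)))
}
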