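# Weighted-sum rank model: ordered scoring rules per category, first-match
# aggregation, integer points, deterministic totals.
#
# Config format (INI-like, shipped example in inst/extdata/rank_model_snv.ini):
#   [category.<name>]
#   default = <points>
#   rule.<i> = <field_key> missing => <points>
#   rule.<i> = <field_key> in [<lo>,<hi>) => <points>
#   rule.<i> = <field_key> is <v1>,<v2>,... => <points>
# Rules are evaluated in declared order; the first match wins, otherwise the
# category default applies. `inf`/`-inf` are accepted as interval bounds.

RANK_FIELD_KEYS <- c("population_af", "consequence", "conservation_score",
                     "deleteriousness_score", "clinical_significance",
                     "local_obs", "local_frequency", "genetic_models",
                     "filter_status", "genotype_quality", "artifact")

parse_rule <- function(text, where) {
  m <- regmatches(text, regexec(
    "^\\s*(\\S+)\\s+(missing|in|is)\\s*(.*?)\\s*=>\\s*(-?\\d+)\\s*$", text))[[1]]
  if (!length(m))
    stop("rank model config error at ", where, ": cannot parse rule '", text, "'")
  field <- m[2]; op <- m[3]; arg <- m[4]; points <- as.integer(m[5])
  if (!(field %in% RANK_FIELD_KEYS))
    stop("rank model config error at ", where, ": unknown field_key '", field,
         "' (known: ", paste(RANK_FIELD_KEYS, collapse = ", "), ")")
  rule <- list(field = field, op = op, points = points)
  if (op == "in") {
    im <- regmatches(arg, regexec(
      "^\\[\\s*(-?(?:\\d*\\.?\\d+(?:[eE]-?\\d+)?|inf))\\s*,\\s*(-?(?:\\d*\\.?\\d+(?:[eE]-?\\d+)?|inf))\\s*\\)$",
      arg))[[1]]
    if (!length(im))
      stop("rank model config error at ", where,
           ": interval must look like [lo,hi) in '", text, "'")
    lo <- if (grepl("inf", im[2])) (if (startsWith(im[2], "-")) -Inf else Inf) else as.numeric(im[2])
    hi <- if (grepl("inf", im[3])) (if (startsWith(im[3], "-")) -Inf else Inf) else as.numeric(im[3])
    if (!(lo < hi))
      stop("rank model config error at ", where, ": empty interval in '", text, "'")
    rule$lo <- lo; rule$hi <- hi
  } else if (op == "is") {
    vals <- trimws(strsplit(arg, ",", fixed = TRUE)[[1]])
    if (!length(vals) || any(!nzchar(vals)))
      stop("rank model config error at ", where, ": empty value set in '", text, "'")
    rule$values <- vals
  } else if (nzchar(arg)) {
    stop("rank model config error at ", where, ": 'missing' takes no argument")
  }
  rule
}

validate_rank_model <- function(config) {
  nms <- vapply(config$categories, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("rank model config error: duplicate category '",
         nms[duplicated(nms)][1], "'")
  freq <- config$categories[nms == "frequency"]
  if (length(freq)) {
    rules <- freq[[1]]$rules
    iv <- Filter(function(r) r$op == "in" && r$field == "population_af", rules)
    if (length(iv) > 1L) {
      lo <- vapply(iv, `[[`, numeric(1), "lo")
      pts <- vapply(iv, `[[`, numeric(1), "points")
      ord <- order(lo)
      if (any(diff(pts[ord]) > 0))
        stop("rank model config error: frequency points must be ",
             "non-increasing as the interval lower bound increases")
    }
  }
  config
}

#' Load and validate a rank model configuration
#'
#' @param path path to an INI-like rank model file (see the package vignette
#'   for the grammar); the shipped default is
#'   `system.file("extdata", "rank_model_snv.ini", package = "clinwgs")`.
#' @return object of class `rank_model_config`.
#' @export
load_rank_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  categories <- list()
  current <- NULL
  flush <- function() {
    if (!is.null(current)) categories[[length(categories) + 1L]] <<- current
  }
  for (i in seq_along(lines)) {
    line <- sub("(^|\\s)[#;].*$", "", lines[i])
    line <- trimws(line)
    if (!nzchar(line)) next
    sec <- regmatches(line, regexec("^\\[category\\.([A-Za-z0-9_]+)\\]$", line))[[1]]
    if (length(sec)) {
      flush()
      current <- list(name = sec[2], default_points = 0L, rules = list(),
                      rule_ids = integer())
      next
    }
    if (is.null(current))
      stop("rank model config error at line ", i, ": key outside any category")
    kv <- regmatches(line, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", line))[[1]]
    if (!length(kv))
      stop("rank model config error at line ", i, ": cannot parse '", line, "'")
    key <- kv[2]; value <- kv[3]
    if (key == "default") {
      current$default_points <- as.integer(value)
    } else if (grepl("^rule\\.[0-9]+$", key)) {
      rid <- as.integer(sub("^rule\\.", "", key))
      if (rid %in% current$rule_ids)
        stop("rank model config error at line ", i, ": duplicate rule index ",
             rid, " in category '", current$name,
             "' leaves rule order ambiguous")
      current$rule_ids <- c(current$rule_ids, rid)
      current$rules[[length(current$rules) + 1L]] <-
        parse_rule(value, paste0("line ", i))
    } else {
      stop("rank model config error at line ", i, ": unknown key '", key, "'")
    }
  }
  flush()
  if (!length(categories)) stop("rank model config error: no categories in ", path)
  # rules in declared numeric order
  categories <- lapply(categories, function(cat) {
    ord <- order(cat$rule_ids)
    cat$rules <- cat$rules[ord]
    cat$rule_ids <- NULL
    cat
  })
  validate_rank_model(structure(list(categories = categories, path = path),
                                class = "rank_model_config"))
}

# field value extraction for scoring; returns NA for missing
score_field_value <- function(field, record, assignment, sample_id) {
  a <- record$annotations
  switch(field,
    population_af = a$population_af,
    consequence = a$consequence,
    conservation_score = a$conservation_score,
    deleteriousness_score = a$deleteriousness_score,
    clinical_significance = a$clinical_significance,
    local_obs = a$local_obs,
    local_frequency = a$local_frequency,
    artifact = if (isTRUE(a$artifact)) "true" else "false",
    filter_status = record$filter_status,
    genetic_models = if (is.null(assignment) || !length(assignment$models))
                       NA_character_ else assignment$models,
    genotype_quality = {
      call <- if (!is.null(sample_id)) record$per_sample[[sample_id]]
              else if (length(record$per_sample)) record$per_sample[[1]] else NULL
      if (is.null(call)) NA_integer_ else call$gq
    })
}

rule_matches <- function(rule, value) {
  if (rule$op == "missing")
    return(length(value) == 0L || all(is.na(value)))
  if (length(value) == 0L || all(is.na(value))) return(FALSE)
  if (rule$op == "in") {
    v <- suppressWarnings(as.numeric(value[1]))
    return(!is.na(v) && v >= rule$lo && v < rule$hi)
  }
  any(value %in% rule$values)
}

#' Score one variant with a rank model
#'
#' Evaluates each category's rules in order; the first matching rule's points
#' are used, else the category default. The total is the integer sum over
#' categories. Scoring is a pure function of its inputs.
#'
#' @param record an annotated [variant_record()].
#' @param assignment a `model_assignment` from [deduce_models()], or `NULL`.
#' @param config a [load_rank_model()] result.
#' @param sample_id sample whose call quality is scored; defaults to the
#'   first sample on the record.
#' @return object of class `rank_score`: `per_category` (named integer),
#'   `total`, and `rank_result_token` (colon-joined points in category order).
#' @export
score_variant <- function(record, assignment, config, sample_id = NULL) {
  stopifnot(inherits(config, "rank_model_config"))
  pts <- vapply(config$categories, function(cat) {
    for (rule in cat$rules) {
      value <- score_field_value(rule$field, record, assignment, sample_id)
      if (rule_matches(rule, value)) return(rule$points)
    }
    cat$default_points
  }, integer(1))
  names(pts) <- vapply(config$categories, `[[`, character(1), "name")
  structure(list(per_category = pts, total = sum(pts),
                 rank_result_token = paste(pts, collapse = ":")),
            class = "rank_score")
}

chrom_order_key <- function(chrom) {
  map <- c(X = 23, Y = 24, MT = 25)
  v <- suppressWarnings(as.numeric(chrom))
  v[is.na(v)] <- map[chrom[is.na(v)]]
  v[is.na(v)] <- 99
  v
}

#' Order scored variants into a ranked case list
#'
#' Descending total score; ties broken by (chrom, pos, ref, alt) with
#' numeric-aware chromosome order, making the result stable under input
#' permutation.
#'
#' @param records list of [variant_record()], each carrying a `rank_score`
#'   element (as attached by [annotate_and_rank()]) or paired via `scores`.
#' @param scores optional list of [score_variant()] results aligned with
#'   `records`; defaults to `record$rank_score_obj`.
#' @param top_n optional cutoff; the full ordering is kept in the attribute
#'   `"full"` when a cutoff is applied ("all prioritized variants are kept").
#' @return `data.frame` with key, chrom, pos, ref, alt, score and rank.
#' @export
rank_case <- function(records, scores = NULL, top_n = NULL) {
  if (is.null(scores)) scores <- lapply(records, `[[`, "rank_score_obj")
  if (any(vapply(scores, is.null, logical(1))))
    stop("rank_case: all records must be scored")
  cfgs <- unique(vapply(scores, function(s) paste(names(s$per_category),
                                                  collapse = "|"), character(1)))
  if (length(cfgs) > 1L)
    stop("rank_case: refusing to rank records scored under different configs")
  df <- data.frame(
    key = vapply(records, variant_key, character(1)),
    chrom = vapply(records, `[[`, character(1), "chrom"),
    pos = vapply(records, `[[`, integer(1), "pos"),
    ref = vapply(records, `[[`, character(1), "ref"),
    alt = vapply(records, `[[`, character(1), "alt"),
    score = vapply(scores, `[[`, integer(1), "total"),
    stringsAsFactors = FALSE)
  ord <- order(-df$score, chrom_order_key(df$chrom), df$pos, df$ref, df$alt)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  if (!is.null(top_n) && nrow(df) > top_n) {
    full <- df
    df <- df[seq_len(top_n), , drop = FALSE]
    attr(df, "full") <- full
  }
  df
}

#' Path of the shipped default SNV/INDEL rank model
#' @return file path.
#' @export
default_rank_model_path <- function() {
  system.file("extdata", "rank_model_snv.ini", package = "clinwgs",
              mustWork = TRUE)
}
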