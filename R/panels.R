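# In-silico gene panels: load, build from HPO terms, merge, apply.

#' Construct a gene panel
#'
#' @param name panel name (non-empty).
#' @param genes character vector of gene symbols (uppercase-normalized).
#' @param version date string or integer version.
#' @param source one of `"precompiled"`, `"hpo_generated"`, `"merged"`.
#' @return object of class `gene_panel`.
#' @export
gene_panel <- function(name, genes, version = 1L, source = "precompiled") {
  if (!nzchar(name)) stop("panel name must be non-empty")
  source <- match.arg(source, c("precompiled", "hpo_generated", "merged"))
  structure(list(name = name, version = version,
                 genes = sort(unique(toupper(as.character(genes)))),
                 source = source),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel> %s (v%s, %s): %d genes\n",
              x$name, x$version, x$source, length(x$genes)))
  invisible(x)
}

#' Load a gene panel from TSV
#'
#' Expects a `gene_symbol` column (optional `inheritance`, `comment`
#' columns); duplicate rows are deduplicated and logged.
#'
#' @param path path to the TSV (optionally gzipped).
#' @param name panel name; defaults to the file name.
#' @param version panel version.
#' @return a [gene_panel()].
#' @export
load_panel <- function(path, name = NULL, version = 1L) {
  dt <- fread(path, header = TRUE, sep = "\t")
  if (nrow(dt) == 0L) stop("panel error: empty panel file ", path)
  col <- if ("gene_symbol" %in% names(dt)) "gene_symbol" else names(dt)[1]
  syms <- toupper(as.character(dt[[col]]))
  ndup <- sum(duplicated(syms))
  if (ndup > 0L) message("panel: ", ndup, " duplicate rows in ", path)
  gene_panel(name %||% basename(path), syms, version = version)
}

#' Build a panel from HPO terms
#'
#' Union of the genes mapped to the supplied terms; `min_terms = k` keeps
#' only genes linked to at least `k` of the terms (1 = pure union). No
#' ontology-descendant closure is applied (see the vignette).
#'
#' @param hpo_terms character vector of HPO term ids.
#' @param hpo_gene_map `data.frame` with columns `term_id`, `gene_symbol`,
#'   or a path to such a TSV.
#' @param min_terms minimum number of supplied terms a gene must be linked to.
#' @param name panel name.
#' @return a [gene_panel()] with source `"hpo_generated"`.
#' @export
build_hpo_panel <- function(hpo_terms, hpo_gene_map, min_terms = 1L,
                            name = "hpo_panel") {
  if (is.character(hpo_gene_map) && length(hpo_gene_map) == 1L)
    hpo_gene_map <- fread(hpo_gene_map, header = TRUE, sep = "\t")
  map <- as.data.frame(hpo_gene_map)
  stopifnot(all(c("term_id", "gene_symbol") %in% names(map)))
  if (!length(hpo_terms)) {
    warning("build_hpo_panel: empty term list; returning empty panel")
    return(gene_panel(name, character(), source = "hpo_generated"))
  }
  missing <- setdiff(hpo_terms, unique(map$term_id))
  if (length(missing))
    warning("build_hpo_panel: terms absent from map: ",
            paste(missing, collapse = ", "))
  hits <- map[map$term_id %in% hpo_terms, , drop = FALSE]
  hits$gene_symbol <- toupper(hits$gene_symbol)
  per_gene <- tapply(hits$term_id, hits$gene_symbol,
                     function(t) length(unique(t)))
  genes <- names(per_gene)[per_gene >= min_terms]
  gene_panel(name, genes, source = "hpo_generated")
}

#' Filter variant records to a panel
#'
#' Keeps records annotated with at least one panel gene; intergenic records
#' (no gene annotation) are dropped. The number of dropped records is
#' reported via message and the `"n_dropped"` attribute.
#'
#' @param records list of [variant_record()].
#' @param panel a [gene_panel()].
#' @return filtered list with attribute `n_dropped`.
#' @export
filter_to_panel <- function(records, panel) {
  keep <- vapply(records, function(r) {
    g <- r$annotations$gene_symbols
    length(g) > 0L && any(toupper(g) %in% panel$genes)
  }, logical(1))
  out <- records[keep]
  n_dropped <- sum(!keep)
  message("panel filter (", panel$name, "): kept ", sum(keep), ", dropped ",
          n_dropped, " records")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Merge gene panels
#'
#' Union of genes with per-gene provenance (which input panels contributed
#' each gene) recorded in the `"provenance"` attribute.
#'
#' @param panels list of [gene_panel()] objects.
#' @param name merged panel name.
#' @return a [gene_panel()] with source `"merged"`.
#' @export
merge_panels <- function(panels, name = "merged") {
  stopifnot(length(panels) >= 1L)
  genes <- sort(unique(unlist(lapply(panels, `[[`, "genes"))))
  prov <- lapply(setNames(genes, genes), function(g)
    vapply(Filter(function(p) g %in% p$genes, panels), `[[`, character(1), "name"))
  out <- gene_panel(name, genes, source = "merged")
  attr(out, "provenance") <- prov
  out
}
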