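# Local observation database: counts, per normalized variant key, the number
# of observing families (and hom-alt index observations), exposing
# cohort-specific rarity and systematic artifacts. One individual -- the
# index -- is counted per family; re-loading a family is a no-op.

#' Create an empty local observation store
#'
#' @param artifact_threshold local frequency at or above which the artifact
#'   flag is set by [annotate_local_obs()]; default 0.05.
#' @return object of class `obs_store` (reference semantics: the entry table
#'   lives in an environment, so loads update the store in place and also
#'   return it).
#' @export
obs_store <- function(artifact_threshold = 0.05) {
  e <- new.env(parent = emptyenv())
  meta <- new.env(parent = emptyenv())
  meta$loaded_cases <- 0L
  meta$families <- character()
  structure(list(entries = e, meta = meta,
                 artifact_threshold = artifact_threshold),
            class = "obs_store")
}

#' @export
print.obs_store <- function(x, ...) {
  cat(sprintf("<obs_store> %d variant keys from %d loaded families\n",
              length(ls(x$entries)), x$meta$loaded_cases))
  invisible(x)
}

#' Number of families loaded into a store
#' @param store an [obs_store()].
#' @return integer.
#' @export
obs_loaded_cases <- function(store) store$meta$loaded_cases

#' Look up a variant key in the store
#' @param store an [obs_store()].
#' @param key a [variant_key()] string.
#' @return integer vector `c(obs, hom)` (zeros when absent).
#' @export
obs_counts <- function(store, key) {
  v <- get0(key, envir = store$entries, inherits = FALSE)
  if (is.null(v)) c(obs = 0L, hom = 0L) else v
}

#' Load one family's index variants into the store
#'
#' Only variants carried by the family's index individual increment counts;
#' each distinct normalized key counts once per family; homozygous-alt (and
#' hemizygous-alt) index genotypes additionally increment the hom count.
#' Re-loading an already-registered family id is a logged no-op.
#'
#' @param records list of normalized [variant_record()] objects.
#' @param ped the family's [pedigree()].
#' @param store an [obs_store()].
#' @return the updated store, invisibly.
#' @export
load_case <- function(records, ped, store) {
  if (ped$family_id %in% store$meta$families) {
    message("obsdb: family ", ped$family_id, " already loaded; skipping")
    return(invisible(store))
  }
  seen <- character()
  for (rec in records) {
    call <- rec$per_sample[[ped$index_id]]
    if (is.null(call) || !isTRUE(gt_carrier(call))) next
    key <- variant_key(normalize_variant(rec))
    if (key %in% seen) next
    seen <- c(seen, key)
    hom <- length(call$gt) >= 1L && all(call$gt == 1L)
    cur <- obs_counts(store, key)
    assign(key, c(obs = cur[["obs"]] + 1L, hom = cur[["hom"]] + as.integer(hom)),
           envir = store$entries)
  }
  store$meta$families <- c(store$meta$families, ped$family_id)
  store$meta$loaded_cases <- store$meta$loaded_cases + 1L
  invisible(store)
}

#' Annotate a record with local observation fields
#'
#' Sets `local_obs` (0 when absent), `local_frequency = obs / loaded_cases`
#' and the artifact flag when the local frequency reaches the store's
#' threshold.
#'
#' @param record a [variant_record()] (normalized for keying).
#' @param store a non-empty [obs_store()].
#' @return the annotated [variant_record()].
#' @export
annotate_local_obs <- function(record, store) {
  n <- obs_loaded_cases(store)
  if (n == 0L) stop("obsdb error: no cases loaded in store")
  key <- variant_key(normalize_variant(record))
  cnt <- obs_counts(store, key)
  record$annotations$local_obs <- cnt[["obs"]]
  record$annotations$local_frequency <- cnt[["obs"]] / n
  record$annotations$artifact <-
    record$annotations$local_frequency >= store$artifact_threshold
  record
}

#' Write an observation store to a portable flat file
#'
#' TSV with one line per key plus a header carrying the loaded-case count
#' and family registry.
#'
#' @param store an [obs_store()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obs_store <- function(store, path) {
  keys <- sort(ls(store$entries))
  lines <- c(
    paste0("#loaded_cases=", store$meta$loaded_cases),
    paste0("#families=", paste(store$meta$families, collapse = ",")),
    paste0("#artifact_threshold=", store$artifact_threshold),
    "key\tobs_count\thom_count",
    vapply(keys, function(k) {
      v <- obs_counts(store, k)
      paste(k, v[["obs"]], v[["hom"]], sep = "\t")
    }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read an observation store from its flat file
#' @param path path written by [write_obs_store()].
#' @return an [obs_store()].
#' @export
read_obs_store <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  get_meta <- function(key, default) {
    hit <- hdr[startsWith(hdr, paste0("#", key, "="))]
    if (!length(hit)) return(default)
    sub(paste0("^#", key, "="), "", hit[1])
  }
  thr <- as.numeric(get_meta("artifact_threshold", "0.05"))
  store <- obs_store(artifact_threshold = thr)
  store$meta$loaded_cases <- as.integer(get_meta("loaded_cases", "0"))
  fams <- get_meta("families", "")
  store$meta$families <- if (nzchar(fams)) strsplit(fams, ",", fixed = TRUE)[[1]]
                         else character()
  body <- lines[!startsWith(lines, "#")]
  body <- body[-1] # column header
  for (line in body) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    assign(f[1], c(obs = as.integer(f[2]), hom = as.integer(f[3])),
           envir = store$entries)
  }
  store
}
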