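# Pedigree types and 6-column PED parsing.

#' A pedigree member
#'
#' @param id individual identifier (the VCF sample name).
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param affected `"affected"`, `"unaffected"` or `"unknown"`.
#' @param mother_id,father_id parental ids or `NA` for founders.
#' @return object of class `individual`.
#' @export
individual <- function(id, sex = "unknown", affected = "unknown",
                       mother_id = NA_character_, father_id = NA_character_) {
  sex <- match.arg(sex, c("unknown", "male", "female"))
  affected <- match.arg(affected, c("unknown", "affected", "unaffected"))
  structure(list(id = as.character(id), sex = sex, affected = affected,
                 mother_id = as.character(mother_id),
                 father_id = as.character(father_id)),
            class = "individual")
}

choose_index <- function(individuals) {
  # the proband: prefer an affected non-founder (child with recorded
  # parents), then any affected member, then the first listed individual
  aff <- vapply(individuals, function(i) i$affected == "affected", logical(1))
  nonf <- vapply(individuals, function(i) !is.na(i$mother_id) || !is.na(i$father_id),
                 logical(1))
  pick <- which(aff & nonf)
  if (!length(pick)) pick <- which(aff)
  if (!length(pick)) pick <- 1L
  individuals[[pick[1]]]$id
}

#' A family pedigree
#'
#' @param family_id family identifier.
#' @param individuals list of [individual()] objects.
#' @param index_id id of the proband; defaults to the affected non-founder.
#' @return object of class `pedigree`.
#' @export
pedigree <- function(family_id, individuals, index_id = NULL) {
  ids <- vapply(individuals, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate individual ids in family ", family_id)
  for (ind in individuals) {
    for (p in c(ind$mother_id, ind$father_id)) {
      if (!is.na(p) && !(p %in% ids))
        stop(sprintf("structural error in family %s: unknown parent id '%s'",
                     family_id, p))
    }
  }
  # no individual may be its own ancestor
  parent_of <- setNames(lapply(individuals, function(i) {
    p <- c(i$mother_id, i$father_id); p[!is.na(p)]
  }), ids)
  for (id in ids) {
    seen <- character(); frontier <- parent_of[[id]]
    while (length(frontier)) {
      if (id %in% frontier)
        stop(sprintf("structural error in family %s: '%s' is its own ancestor",
                     family_id, id))
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(parent_of[frontier])), seen)
    }
  }
  if (is.null(index_id)) index_id <- choose_index(individuals)
  if (!(index_id %in% ids)) stop("index individual not present in pedigree")
  structure(list(family_id = as.character(family_id),
                 individuals = setNames(individuals, ids),
                 index_id = index_id),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> family %s: %d individuals, index %s\n",
              x$family_id, length(x$individuals), x$index_id))
  invisible(x)
}

ped_member <- function(ped, id) ped$individuals[[id]]

#' Read a 6-column PED file
#'
#' Standard columns: family, individual, father, mother, sex (1 = male,
#' 2 = female, 0 = unknown), phenotype (2 = affected, 1 = unaffected,
#' 0 = unknown). "0" parent entries mean founder. Gzipped files accepted.
#'
#' @param path path to the PED file.
#' @return named list of [pedigree()] objects, one per family.
#' @export
read_ped <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = "character",
              fill = TRUE)
  if (ncol(dt) < 6L) {
    dt <- fread(path, header = FALSE, colClasses = "character")
  }
  if (ncol(dt) < 6L) stop("PED format error: expected 6 columns in ", path)
  names(dt)[1:6] <- c("family", "id", "father", "mother", "sex", "phen")
  out <- list()
  for (fam in unique(dt$family)) {
    rows <- dt[dt$family == fam, ]
    inds <- lapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      individual(
        id = r$id,
        sex = c("0" = "unknown", "1" = "male", "2" = "female")[[r$sex]] %||% "unknown",
        affected = c("0" = "unknown", "1" = "unaffected", "2" = "affected")[[r$phen]] %||% "unknown",
        mother_id = if (r$mother == "0") NA_character_ else r$mother,
        father_id = if (r$father == "0") NA_character_ else r$father)
    })
    out[[fam]] <- pedigree(fam, inds)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Write pedigrees to a 6-column PED file
#' @param pedigrees list of [pedigree()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(pedigrees, path) {
  if (inherits(pedigrees, "pedigree")) pedigrees <- list(pedigrees)
  rows <- unlist(lapply(pedigrees, function(ped) {
    vapply(ped$individuals, function(i) {
      paste(ped$family_id, i$id,
            if (is.na(i$father_id)) "0" else i$father_id,
            if (is.na(i$mother_id)) "0" else i$mother_id,
            c(unknown = "0", male = "1", female = "2")[[i$sex]],
            c(unknown = "0", unaffected = "1", affected = "2")[[i$affected]],
            sep = "\t")
    }, character(1))
  }), use.names = FALSE)
  writeLines(rows, path)
  invisible(path)
}
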