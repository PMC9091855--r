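#' Read and validate a pedigree table
#'
#' Reads a delimited file with columns `id`, `sire`, `dam`, `sex` and
#' `birth_year`, validates its structure and returns a `Pedigree` object.
#' Unknown parents are encoded as `"0"`, `NA` or the empty string.
#'
#' Validation enforces the invariants a numerator-relationship matrix and a
#' gene-dropping simulation both rely on: unique ids, an acyclic
#' parent-offspring graph, sex-consistent parent usage (every sire male, every
#' dam female) and parents born strictly before their offspring.
#'
#' @param path Path to a headered CSV/TSV file (delimiter auto-detected).
#' @return A `Pedigree`: a `data.frame` with columns `id`, `sire`, `dam`
#'   (character, `NA` for unknown), `sex` (`"M"`/`"F"`) and `birth_year`
#'   (integer), sorted so that parents precede offspring.
#' @export
read_pedigree <- function(path) {
  df <- read_table_auto(path)
  need <- c("id", "sire", "dam", "sex", "birth_year")
  if (!all(need %in% names(df))) {
    stop("pedigree file must have columns: ", paste(need, collapse = ", "))
  }
  as_pedigree(df[need])
}

#' Construct a Pedigree from a data frame
#'
#' @param df Data frame with columns `id`, `sire`, `dam`, `sex`, `birth_year`.
#' @return A validated `Pedigree` (see [read_pedigree()]).
#' @export
as_pedigree <- function(df) {
  ped <- data.frame(
    id = as.character(df$id),
    sire = clean_parent(df$sire),
    dam = clean_parent(df$dam),
    sex = toupper(as.character(df$sex)),
    birth_year = as.integer(df$birth_year),
    stringsAsFactors = FALSE
  )
  validate_pedigree(ped)
  ped <- ped[order(ped$birth_year, ped$id), , drop = FALSE]
  rownames(ped) <- NULL
  class(ped) <- c("Pedigree", "data.frame")
  ped
}

clean_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "0" | x == "" | x == "NA"] <- NA_character_
  x
}

validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id)) {
    stop("duplicated pedigree ids: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  }
  if (!all(ped$sex %in% c("M", "F"))) {
    stop("sex must be M or F")
  }
  if (anyNA(ped$birth_year)) stop("birth_year must be non-missing")
  idx <- match_parents(ped)
  sex_of <- ped$sex
  bad_sire <- !is.na(idx$sire) & sex_of[idx$sire] != "M"
  if (any(bad_sire)) {
    stop("sire(s) recorded with female sex: ",
         paste(ped$sire[which(bad_sire)][1], collapse = ", "))
  }
  bad_dam <- !is.na(idx$dam) & sex_of[idx$dam] != "F"
  if (any(bad_dam)) {
    stop("dam(s) recorded with male sex: ",
         paste(ped$dam[which(bad_dam)][1], collapse = ", "))
  }
  check_acyclic(ped, idx)
  for (slot in c("sire", "dam")) {
    p <- idx[[slot]]
    has <- !is.na(p)
    late <- has & ped$birth_year[p] >= ped$birth_year
    if (any(late)) {
      stop("parent born in or after offspring's birth year for id ",
           ped$id[which(late)[1]])
    }
  }
  invisible(ped)
}

match_parents <- function(ped) {
  list(
    sire = ifelse(is.na(ped$sire), NA_integer_, match(ped$sire, ped$id)),
    dam = ifelse(is.na(ped$dam), NA_integer_, match(ped$dam, ped$id))
  )
}

# Kahn-style peel: repeatedly remove individuals whose parents are all
# removed; anything left sits on (or descends from) a cycle.
check_acyclic <- function(ped, idx = match_parents(ped)) {
  n <- nrow(ped)
  done <- logical(n)
  parent_done <- function(p) is.na(p) | done[replace(p, is.na(p), 1L)]
  repeat {
    ready <- !done & parent_done(idx$sire) & parent_done(idx$dam)
    if (!any(ready)) break
    done[ready] <- TRUE
  }
  if (!all(done)) {
    stop("pedigree contains a cycle involving id ", ped$id[which(!done)[1]])
  }
  invisible(TRUE)
}

#' Topological order of a pedigree
#'
#' @param ped A `Pedigree`.
#' @return Integer permutation of rows such that every parent precedes its
#'   offspring. Because validation enforces parent birth years strictly before
#'   offspring birth years, birth-year order suffices.
#' @keywords internal
pedigree_order <- function(ped) {
  order(ped$birth_year, ped$id)
}

#' Write a pedigree to a TSV file
#'
#' @param ped A `Pedigree`.
#' @param path Output path; unknown parents written as `0`.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE,
                    comment.char = "", quote = "\"")
}
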