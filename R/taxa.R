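# Species-name harmonization across taxonomic nomenclatures.
#
# Literature compound tables carry free-text species names; these are mapped
# to a single namespaced identifier under a fixed nomenclature priority
# (NCBITaxon > ITIS > WFO), and the working set is then restricted to the
# plant kingdom (Viridiplantae, NCBITaxon:33090) using NCBI ancestry.

VIRIDIPLANTAE_ID <- 33090L

.norm_name <- function(x) tolower(gsub("[[:space:]]+", " ", trimws(x)))

#' Assemble taxonomy lookup tables
#'
#' @param ncbi data.frame with columns `name`, `id` (integer NCBI taxids).
#' @param itis,wfo data.frames with columns `name`, `id` and optionally
#'   `is_plant` (logical); only NCBI carries ancestry, so plant status for
#'   the other nomenclatures comes from this column (default `TRUE`).
#' @param ncbi_ancestry data.frame with columns `child_id`, `parent_id`
#'   giving the NCBI taxonomy as an edge list.
#' @param synonyms optional data.frame with columns `synonym`, `accepted`
#'   mapping alternative names to accepted ones; applied before resolution
#'   when `use_synonyms = TRUE` in [resolve_species()].
#' @return a `taxa_lookup` list.
#' @export
taxa_lookup <- function(ncbi = NULL, itis = NULL, wfo = NULL,
                        ncbi_ancestry = NULL, synonyms = NULL) {
  chk <- function(tab, nm) {
    if (is.null(tab)) return(NULL)
    if (!all(c("name", "id") %in% names(tab))) {
      stop(sprintf("%s lookup table needs columns 'name' and 'id'", nm))
    }
    tab$name <- .norm_name(tab$name)
    if (is.null(tab$is_plant)) tab$is_plant <- TRUE
    tab[!duplicated(tab$name), , drop = FALSE]
  }
  if (!is.null(ncbi_ancestry) &&
      !all(c("child_id", "parent_id") %in% names(ncbi_ancestry))) {
    stop("ancestry table needs columns 'child_id' and 'parent_id'")
  }
  structure(list(ncbi = chk(ncbi, "NCBITaxon"), itis = chk(itis, "ITIS"),
                 wfo = chk(wfo, "WFO"), ncbi_ancestry = ncbi_ancestry,
                 synonyms = synonyms),
            class = "taxa_lookup")
}

#' Read taxonomy lookup tables from delimited files
#'
#' Each file is a TSV with header columns `name`, `id` and optionally
#' `is_plant`; the ancestry file has `child_id`, `parent_id`.
#'
#' @param ncbi_path,itis_path,wfo_path,ancestry_path file paths (`NULL` to
#'   omit a nomenclature).
#' @return a `taxa_lookup` list.
#' @export
read_taxa_lookup <- function(ncbi_path = NULL, itis_path = NULL,
                             wfo_path = NULL, ancestry_path = NULL) {
  rd <- function(p) if (is.null(p)) NULL else
    utils::read.delim(p, stringsAsFactors = FALSE)
  taxa_lookup(ncbi = rd(ncbi_path), itis = rd(itis_path), wfo = rd(wfo_path),
              ncbi_ancestry = rd(ancestry_path))
}

#' Resolve species names to namespaced taxon identifiers
#'
#' Names are whitespace-normalized and matched case-insensitively, exactly
#' (no fuzzy matching). A name found in several nomenclatures is assigned
#' exclusively to the highest-priority one: NCBITaxon, then ITIS, then WFO.
#'
#' @param names character vector of free-text species names.
#' @param lookup a [taxa_lookup()] object.
#' @param use_synonyms apply the lookup's synonym table before matching
#'   (default `FALSE`).
#' @return data.frame with one row per input: `input_name`, `resolved_id`
#'   (e.g. `"NCBITaxon:1234"`, `NA` when unresolved), `nomenclature`,
#'   `is_plant`.
#' @export
resolve_species <- function(names, lookup, use_synonyms = FALSE) {
  stopifnot(inherits(lookup, "taxa_lookup"))
  key <- .norm_name(names)
  if (use_synonyms && !is.null(lookup$synonyms)) {
    syn <- lookup$synonyms
    i <- match(key, .norm_name(syn$synonym))
    key[!is.na(i)] <- .norm_name(syn$accepted)[i[!is.na(i)]]
  }
  out <- data.frame(input_name = names, resolved_id = NA_character_,
                    nomenclature = NA_character_, is_plant = NA,
                    stringsAsFactors = FALSE)
  for (nom in c("ncbi", "itis", "wfo")) {
    tab <- lookup[[nom]]
    if (is.null(tab)) next
    todo <- is.na(out$resolved_id)
    i <- match(key[todo], tab$name)
    hit <- !is.na(i)
    ns <- c(ncbi = "NCBITaxon", itis = "ITIS", wfo = "WFO")[[nom]]
    out$resolved_id[todo][hit] <- paste0(ns, ":", tab$id[i[hit]])
    out$nomenclature[todo][hit] <- ns
    out$is_plant[todo][hit] <- as.logical(tab$is_plant[i[hit]])
  }
  # NCBI plant status is decided by ancestry, not by the lookup column
  ncbi_rows <- !is.na(out$nomenclature) & out$nomenclature == "NCBITaxon"
  if (any(ncbi_rows) && !is.null(lookup$ncbi_ancestry)) {
    ids <- as.integer(sub("^NCBITaxon:", "", out$resolved_id[ncbi_rows]))
    out$is_plant[ncbi_rows] <- is_under_taxon(ids, lookup$ncbi_ancestry,
                                              VIRIDIPLANTAE_ID)
  }
  out
}

#' Test NCBI taxa for descent from an ancestor
#'
#' Walks parent chains in an edge-list taxonomy.
#'
#' @param ids integer vector of NCBI taxids.
#' @param ancestry data.frame with `child_id`, `parent_id`.
#' @param ancestor taxid of the ancestor (default Viridiplantae, 33090).
#' @return logical vector; `NA` when an id is absent from the table.
#' @export
is_under_taxon <- function(ids, ancestry, ancestor = VIRIDIPLANTAE_ID) {
  parent <- ancestry$parent_id
  names(parent) <- as.character(ancestry$child_id)
  vapply(ids, function(id) {
    if (is.na(id)) return(NA)
    if (id == ancestor) return(TRUE)
    if (!as.character(id) %in% names(parent)) return(NA)
    seen <- integer(0)
    cur <- id
    while (!is.na(cur)) {
      if (cur == ancestor) return(TRUE)
      if (cur %in% seen) return(FALSE)  # defensive: cycle in a bad table
      seen <- c(seen, cur)
      nxt <- parent[as.character(cur)]
      if (is.na(nxt) || nxt == cur) return(FALSE)
      cur <- unname(nxt)
    }
    FALSE
  }, logical(1))
}

#' Restrict resolved taxa to the plant kingdom
#'
#' NCBITaxon records are kept when their ancestor chain reaches
#' Viridiplantae (NCBITaxon:33090); ITIS/WFO records are kept when the
#' lookup tables flagged them as plants. Records whose id is missing from
#' the ancestry table are dropped with a warning.
#'
#' @param records data.frame from [resolve_species()].
#' @param lookup a [taxa_lookup()] object (for the NCBI ancestry).
#' @return the plant subset of `records`; the number of rows dropped for
#'   missing ancestry is attached as attribute `"n_unplaceable"`.
#' @export
restrict_to_plants <- function(records, lookup = NULL) {
  is_pl <- records$is_plant
  if (!is.null(lookup) && !is.null(lookup$ncbi_ancestry)) {
    ncbi_rows <- !is.na(records$nomenclature) & records$nomenclature == "NCBITaxon"
    ids <- as.integer(sub("^NCBITaxon:", "", records$resolved_id[ncbi_rows]))
    is_pl[ncbi_rows] <- is_under_taxon(ids, lookup$ncbi_ancestry)
  }
  unplaceable <- sum(is.na(is_pl) & !is.na(records$resolved_id))
  if (unplaceable > 0) {
    warning(sprintf("%d resolved records dropped: id missing from ancestry table",
                    unplaceable), call. = FALSE)
  }
  out <- records[!is.na(is_pl) & is_pl, , drop = FALSE]
  attr(out, "n_unplaceable") <- unplaceable
  out
}
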