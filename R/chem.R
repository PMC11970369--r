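# Mass of a proton in Da (CODATA); prices the [M+H]+ shift.
PROTON_MASS <- 1.007276466

#' Lightweight SMILES well-formedness check
#'
#' OpenBabel accepts some malformed SMILES silently (e.g. an unbalanced
#' parenthesis), so structurally broken input is screened out before any
#' conversion. This checks token legality, balanced parentheses and brackets,
#' and paired ring-closure digits; it does not attempt valence chemistry,
#' which is left to the toolkit.
#'
#' @param smiles character vector.
#' @return logical vector, `TRUE` where the string is acceptable.
#' @keywords internal
smiles_well_formed <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s) || grepl("[[:space:]]", s)) return(FALSE)
    chars <- strsplit(s, "")[[1]]
    allowed <- c(LETTERS, letters, as.character(0:9), "@", "+", "-", "(", ")",
                 "[", "]", "=", "#", "$", ":", "/", "\\", "%", ".", "*")
    if (!all(chars %in% allowed)) return(FALSE)
    # balanced () and [], never negative depth; brackets cannot nest
    pdepth <- 0L; bdepth <- 0L
    for (ch in chars) {
      if (ch == "(") pdepth <- pdepth + 1L
      else if (ch == ")") pdepth <- pdepth - 1L
      else if (ch == "[") bdepth <- bdepth + 1L
      else if (ch == "]") bdepth <- bdepth - 1L
      if (pdepth < 0L || bdepth < 0L || bdepth > 1L) return(FALSE)
    }
    if (pdepth != 0L || bdepth != 0L) return(FALSE)
    if (grepl("\\[\\]", s)) return(FALSE)
    # ring-closure labels must each be opened and closed (appear an even
    # number of times); %nn labels counted separately from bare digits
    body <- gsub("\\[[^]]*\\]", "A", s)   # bracket atoms may contain digits (isotopes, H counts)
    two <- regmatches(body, gregexpr("%[0-9]{2}", body))[[1]]
    body2 <- gsub("%[0-9]{2}", "", body)
    digs <- regmatches(body2, gregexpr("[0-9]", body2))[[1]]
    counts <- table(c(two, digs))
    if (length(counts) && any(counts %% 2L != 0L)) return(FALSE)
    # a bond symbol cannot open the string or dangle before ) or end
    bond <- c("=", "#", "$", "/", "\\")
    n <- length(chars)
    if (chars[1] %in% bond || chars[n] %in% bond) return(FALSE)
    if (n > 1 && any(chars[-n] %in% bond & chars[-1] == ")")) return(FALSE)
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

.convert_smiles <- function(smiles, to) {
  # batch conversion; ChemmineOB writes one output line per molecule
  out <- ChemmineOB::convertFormat("SMI", to, source = paste(smiles, collapse = "\n"))
  res <- strsplit(out, "\n", fixed = TRUE)[[1]]
  if (length(res) != length(smiles)) {
    # fall back to per-molecule conversion so a single failure cannot shift rows
    res <- vapply(smiles, function(s) {
      r <- tryCatch(ChemmineOB::convertFormat("SMI", to, source = s),
                    error = function(e) "")
      sub("\n.*$", "", r)
    }, character(1), USE.NAMES = FALSE)
  }
  res[!nzchar(res)] <- NA_character_
  res
}

#' Stereochemistry-free structure key (first InChIKey block)
#'
#' Parses SMILES and returns the first 14 characters of the standard
#' InChIKey. The first block hashes skeleton and connectivity only, so two
#' stereoisomers map to the same key by construction; this is the unit in
#' which unique structures are counted throughout the package.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of 14-character keys; `NA` for strings that do
#'   not parse. Rejected inputs are reported in the `"rejected"` attribute
#'   and via a warning.
#' @examples
#' structure_key("CCO")
#' structure_key(c("C[C@@H](N)C(=O)O", "C[C@H](N)C(=O)O"))  # identical keys
#' @export
structure_key <- function(smiles) {
  stopifnot(is.character(smiles))
  ok <- smiles_well_formed(smiles)
  keys <- rep(NA_character_, length(smiles))
  if (any(ok)) {
    full <- .convert_smiles(smiles[ok], "INCHIKEY")
    keys[ok] <- substr(full, 1L, 14L)
  }
  bad <- smiles[is.na(keys)]
  if (length(bad)) {
    warning(sprintf("%d SMILES could not be keyed (e.g. %s)",
                    length(bad), utils::head(bad, 1)), call. = FALSE)
    attr(keys, "rejected") <- bad
  }
  keys
}

#' Monoisotopic mass of a neutral molecule
#'
#' Sum of the most-abundant-isotope atomic masses, via OpenBabel.
#'
#' @param smiles character vector of SMILES strings.
#' @return numeric vector of masses in Da; `NA` for unparseable input.
#' @examples
#' monoisotopic_mass("CCO")  # 46.04186
#' @export
monoisotopic_mass <- function(smiles) {
  stopifnot(is.character(smiles))
  ok <- smiles_well_formed(smiles)
  mass <- rep(NA_real_, length(smiles))
  if (any(ok)) {
    mols <- ChemmineOB::forEachMol("SMILES", paste(smiles[ok], collapse = "\n"),
                                   identity)
    m <- ChemmineOB::exactMass_OB(mols)
    if (length(m) == sum(ok)) mass[ok] <- m
  }
  if (anyNA(mass)) {
    warning(sprintf("%d SMILES could not be parsed for mass", sum(is.na(mass))),
            call. = FALSE)
  }
  mass
}

# --- Murcko scaffold ---------------------------------------------------------

# Parse the first structure of a V2000 MOL block into atoms/bonds/properties.
.parse_molblock <- function(mol) {
  lines <- strsplit(mol, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  atom_lines <- lines[5:(4 + natoms)]
  bonds <- if (nbonds > 0) {
    bl <- lines[(5 + natoms):(4 + natoms + nbonds)]
    cbind(from  = as.integer(substr(bl, 1, 3)),
          to    = as.integer(substr(bl, 4, 6)),
          order = as.integer(substr(bl, 7, 9)))
  } else {
    matrix(integer(0), ncol = 3, dimnames = list(NULL, c("from", "to", "order")))
  }
  props <- grep("^M  (CHG|ISO|RAD)", lines, value = TRUE)
  list(natoms = natoms, atom_lines = atom_lines, bonds = bonds, props = props)
}

# Reassemble a V2000 MOL block for a subset of atoms (1-based indices kept).
.subset_molblock <- function(parsed, keep) {
  keep <- sort(keep)
  remap <- integer(parsed$natoms)
  remap[keep] <- seq_along(keep)
  b <- parsed$bonds
  bkeep <- b[, "from"] %in% keep & b[, "to"] %in% keep
  b <- b[bkeep, , drop = FALSE]
  bond_lines <- sprintf("%3d%3d%3d  0  0  0  0",
                        remap[b[, "from"]], remap[b[, "to"]], b[, "order"])
  prop_lines <- character(0)
  for (p in parsed$props) {
    tag <- substr(p, 1, 6)
    n <- as.integer(substr(p, 7, 9))
    ent <- lapply(seq_len(n), function(i) {
      off <- 10 + (i - 1) * 8
      c(as.integer(substr(p, off, off + 2)), as.integer(substr(p, off + 4, off + 6)))
    })
    ent <- Filter(function(e) e[1] %in% keep, ent)
    if (length(ent)) {
      prop_lines <- c(prop_lines, paste0(
        tag, sprintf("%3d", length(ent)),
        paste(vapply(ent, function(e) sprintf(" %3d %3d", remap[e[1]], e[2]),
                     character(1)), collapse = "")))
    }
  }
  paste(c("", "  phytospace scaffold", "",
          sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                  length(keep), nrow(b)),
          parsed$atom_lines[keep], bond_lines, prop_lines, "M  END"),
        collapse = "\n")
}

.scaffold_atoms <- function(parsed) {
  # prune terminal atoms until fixed point: what survives is the union of
  # ring systems and the linkers between them (isolated remnants of pruned
  # chains are dropped too -- they were never part of a ring)
  alive <- rep(TRUE, parsed$natoms)
  b <- parsed$bonds
  repeat {
    deg <- tabulate(c(b[alive[b[, "from"]] & alive[b[, "to"]], c("from", "to")]),
                    nbins = parsed$natoms)
    drop <- which(alive & deg <= 1L)
    if (!length(drop)) break
    alive[drop] <- FALSE
  }
  which(alive)
}

#' Murcko scaffold key
#'
#' Reduces each molecule to its Murcko framework -- ring systems plus the
#' linker atoms connecting them, side chains removed, exocyclic
#' multiple-bonded atoms retained -- and returns its stereochemistry-free
#' structure key. Acyclic molecules have no scaffold and return `NA` (an
#' empty scaffold would spuriously merge all acyclic compounds).
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector: 14-character scaffold key, or `NA` for acyclic
#'   or unparseable molecules (unparseable ones are additionally reported in
#'   the `"rejected"` attribute).
#' @examples
#' scaffold_key("Cc1ccccc1") == scaffold_key("c1ccccc1")  # TRUE
#' scaffold_key("CCO")  # NA: no ring system
#' @export
scaffold_key <- function(smiles) {
  stopifnot(is.character(smiles))
  ok <- smiles_well_formed(smiles)
  out <- rep(NA_character_, length(smiles))
  scaf_mols <- character(0)
  scaf_idx <- integer(0)
  for (i in which(ok)) {
    molblock <- tryCatch(ChemmineOB::convertFormat("SMI", "SDF", source = smiles[i]),
                         error = function(e) NULL)
    if (is.null(molblock) || !nzchar(molblock)) { ok[i] <- FALSE; next }
    parsed <- .parse_molblock(molblock)
    core <- .scaffold_atoms(parsed)
    if (!length(core)) next  # acyclic: scaffold absent
    # re-attach atoms multiple-bonded directly to the framework (exocyclic
    # =O, =N- etc. are part of the Murcko framework)
    b <- parsed$bonds
    exo <- b[, "order"] >= 2L &
      xor(b[, "from"] %in% core, b[, "to"] %in% core)
    keep <- union(core, c(b[exo, "from"], b[exo, "to"]))
    scaf_mols <- c(scaf_mols, .subset_molblock(parsed, keep))
    scaf_idx <- c(scaf_idx, i)
  }
  if (length(scaf_mols)) {
    keys <- vapply(scaf_mols, function(m) {
      k <- tryCatch(ChemmineOB::convertFormat("SDF", "INCHIKEY",
                                              source = paste0(m, "\n$$$$\n")),
                    error = function(e) "")
      sub("\n.*$", "", k)
    }, character(1), USE.NAMES = FALSE)
    keys[!nzchar(keys)] <- NA_character_
    out[scaf_idx] <- substr(keys, 1L, 14L)
  }
  bad <- smiles[!ok]
  if (length(bad)) {
    warning(sprintf("%d SMILES could not be parsed for scaffolds", length(bad)),
            call. = FALSE)
    attr(out, "rejected") <- bad
  }
  out
}

# --- compound tables ---------------------------------------------------------

#' Load a literature compound-species table
#'
#' Reads a delimited table of structure-species associations (the shape of
#' COCONUT / LOTUS exports reduced to two columns), keys every valid SMILES,
#' computes scaffold keys and monoisotopic masses, and collapses duplicate
#' (structure_key, species) pairs -- stereoisomers of one compound reported
#' for one species count once.
#'
#' @param path delimited text file with a header.
#' @param source_label label recorded in the `source` column.
#' @param smiles_col,species_col column names (defaults `"smiles"`,
#'   `"species"`).
#' @param sep field separator, default tab.
#' @return list with `records` (data.frame: smiles, structure_key,
#'   scaffold_key, monoisotopic_mass, species, source) and `rejections`
#'   (data.frame of rejected rows with a reason), plus collapsed-duplicate
#'   count in `n_collapsed`.
#' @export
load_compound_table <- function(path, source_label,
                                smiles_col = "smiles", species_col = "species",
                                sep = "\t") {
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!all(c(smiles_col, species_col) %in% names(tab))) {
    stop(sprintf("compound table must have columns '%s' and '%s'",
                 smiles_col, species_col))
  }
  smiles <- as.character(tab[[smiles_col]])
  species <- as.character(tab[[species_col]])
  keys <- suppressWarnings(structure_key(smiles))
  bad <- is.na(keys) | is.na(species) | !nzchar(species)
  rejections <- data.frame(row = which(bad), smiles = smiles[bad],
                           species = species[bad],
                           reason = ifelse(is.na(keys[bad]),
                                           "invalid_smiles", "missing_species"),
                           stringsAsFactors = FALSE)
  keep <- !bad
  rec <- data.frame(smiles = smiles[keep], structure_key = keys[keep],
                    species = species[keep], stringsAsFactors = FALSE)
  dup <- duplicated(rec[c("structure_key", "species")])
  n_collapsed <- sum(dup)
  rec <- rec[!dup, , drop = FALSE]
  rec$scaffold_key <- suppressWarnings(scaffold_key(rec$smiles))
  rec$monoisotopic_mass <- suppressWarnings(monoisotopic_mass(rec$smiles))
  rec$source <- source_label
  rownames(rec) <- NULL
  list(records = rec, rejections = rejections, n_collapsed = n_collapsed)
}

#' Write a normalized compound table
#'
#' @param records data.frame as produced by [load_compound_table()].
#' @param path output TSV path.
#' @export
write_compound_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
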