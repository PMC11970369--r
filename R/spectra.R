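# MS2 spectrum container and MGF I/O, plus the quality and adduct filters
# applied before any estimation: minimum peak count, dominating-peak flag,
# [M+H]+ adduct restriction, and the known/unknown confidence split.

#' Construct an MS2 spectrum
#'
#' @param feature_id,sample_id,species identifiers carried with the spectrum.
#' @param precursor_mz precursor m/z in Th (> 0).
#' @param peaks two-column matrix (`mz`, `intensity`); rows are sorted by
#'   m/z and zero-intensity peaks dropped.
#' @param adduct adduct label such as `"[M+H]+"`, or `NA`.
#' @return an object of class `ms2_spectrum`.
#' @export
ms2_spectrum <- function(feature_id, precursor_mz, peaks,
                         sample_id = NA_character_, species = NA_character_,
                         adduct = NA_character_) {
  stopifnot(is.numeric(precursor_mz), length(precursor_mz) == 1,
            precursor_mz > 0)
  peaks <- matrix(as.numeric(peaks), ncol = 2,
                  dimnames = list(NULL, c("mz", "intensity")))
  peaks <- peaks[peaks[, "intensity"] > 0, , drop = FALSE]
  if (nrow(peaks) == 0) stop("spectrum must have at least one non-zero peak")
  peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  structure(list(feature_id = as.character(feature_id),
                 sample_id = as.character(sample_id),
                 species = as.character(species),
                 precursor_mz = precursor_mz,
                 adduct = as.character(adduct),
                 peaks = peaks),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum %s: precursor %.4f Th, %d peaks, species %s>\n",
              x$feature_id, x$precursor_mz, nrow(x$peaks), x$species))
  invisible(x)
}

#' Number of peaks in a spectrum
#' @param spectrum an `ms2_spectrum`.
#' @export
n_peaks <- function(spectrum) nrow(spectrum$peaks)

# --- MGF I/O -----------------------------------------------------------------

#' Read MS2 spectra from an MGF file
#'
#' One spectrum per `BEGIN IONS`/`END IONS` block. Feature, sample and
#' species identifiers are carried as `key=value` pairs on the TITLE line
#' (`TITLE feature=F1 sample=S1 species=NCBITaxon:1`), the convention this
#' package's writer uses; `PEPMASS` gives the precursor and `ION` the adduct.
#' Peaks are returned sorted by m/z with zero-intensity peaks dropped.
#'
#' @param path MGF file path.
#' @return list of [ms2_spectrum()] objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop(sprintf("malformed MGF: %d BEGIN IONS vs %d END IONS blocks",
                 length(begins), length(ends)))
  }
  lapply(seq_along(begins), function(bi) {
    block <- lines[(begins[bi] + 1):(ends[bi] - 1)]
    is_param <- grepl("^[A-Z]+=", block) | grepl("^TITLE", block)
    params <- block[is_param]
    getp <- function(key) {
      hit <- grep(paste0("^", key, "="), params, value = TRUE)
      if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NA_character_
    }
    title <- {
      hit <- grep("^TITLE", params, value = TRUE)
      if (length(hit)) sub("^TITLE[= ]", "", hit[1]) else ""
    }
    getkv <- function(key) {
      m <- regmatches(title, regexec(paste0(key, "=([^ ]+)"), title))[[1]]
      if (length(m) == 2) m[2] else NA_character_
    }
    pep <- getp("PEPMASS")
    if (is.na(pep)) stop(sprintf("MGF block %d has no PEPMASS", bi))
    peak_lines <- block[!is_param & nzchar(trimws(block))]
    fields <- strsplit(trimws(peak_lines), "[ \t]+")
    if (!length(fields)) stop(sprintf("MGF block %d has no peaks", bi))
    pk <- t(vapply(fields, function(f) as.numeric(f[1:2]), numeric(2)))
    if (anyNA(pk)) stop(sprintf("MGF block %d has an unreadable peak line", bi))
    ms2_spectrum(feature_id = getkv("feature"), sample_id = getkv("sample"),
                 species = getkv("species"),
                 precursor_mz = as.numeric(strsplit(pep, "[ \t]+")[[1]][1]),
                 adduct = getp("ION"), peaks = pk)
  })
}

#' Write MS2 spectra to an MGF file
#'
#' Counterpart of [read_mgf()]; identifiers go on the TITLE line.
#'
#' @param spectra list of `ms2_spectrum` objects.
#' @param path output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 sprintf("TITLE feature=%s sample=%s species=%s",
                         s$feature_id, s$sample_id, s$species),
                 sprintf("PEPMASS=%.6f", s$precursor_mz),
                 if (!is.na(s$adduct)) sprintf("ION=%s", s$adduct),
                 "CHARGE=1+",
                 sprintf("%.5f %.6g", s$peaks[, "mz"], s$peaks[, "intensity"]),
                 "END IONS", ""), con)
  }
  invisible(path)
}

# --- filters -----------------------------------------------------------------

#' Remove spectra with fewer than k peaks
#'
#' Spectra with very few fragment peaks are generally uninformative and are
#' removed before curve building; a spectrum with exactly `k` peaks is kept.
#'
#' @param spectra list of `ms2_spectrum` objects.
#' @param k minimum peak count (default 5).
#' @return the kept subset.
#' @export
filter_min_peaks <- function(spectra, k = 5) {
  stopifnot(k >= 1)
  Filter(function(s) n_peaks(s) >= k, spectra)
}

#' Fraction of total intensity in the largest peak
#'
#' Spectra whose largest peak carries more than 90% of the total intensity
#' are dominated by a single fragment and carry little structural
#' information; callers flag spectra with fraction strictly above
#' `flag_above`.
#'
#' @param spectrum an `ms2_spectrum` (or a list of them, vectorized).
#' @param flag_above dominance threshold used by the `"flagged"` attribute
#'   (strict inequality; default 0.9).
#' @return numeric fraction(s) in (0, 1] with a logical `"flagged"`
#'   attribute.
#' @export
dominant_peak_fraction <- function(spectrum, flag_above = 0.9) {
  one <- function(s) {
    tot <- sum(s$peaks[, "intensity"])
    if (tot <= 0) stop("spectrum has zero total intensity")
    max(s$peaks[, "intensity"]) / tot
  }
  fr <- if (inherits(spectrum, "ms2_spectrum")) one(spectrum)
        else vapply(spectrum, one, numeric(1))
  attr(fr, "flagged") <- fr > flag_above
  fr
}

#' Keep spectra whose feature is predicted as a given adduct
#'
#' Restricting to one adduct (the predominant `[M+H]+`) avoids counting the
#' same molecule once per ionization form. Adduct predictions come from the
#' formula-prediction annotations; features with no prediction are removed,
#' as are negative-mode features by construction.
#'
#' @param spectra list of `ms2_spectrum` objects.
#' @param annotations annotation data.frame (see [read_annotations()]);
#'   rows with `source == "formula"` carry the adduct prediction. When a
#'   feature has no formula row, any row for the feature is consulted.
#' @param adduct adduct label to keep (default `"[M+H]+"`).
#' @return the kept subset of `spectra`.
#' @export
select_adduct <- function(spectra, annotations, adduct = "[M+H]+") {
  pred <- adduct_predictions(annotations)
  Filter(function(s) {
    a <- pred[s$feature_id]
    !is.na(a) && a == adduct
  }, spectra)
}

#' Per-feature predicted adduct
#'
#' @param annotations annotation data.frame.
#' @return named character vector feature_id -> adduct (formula-source rows
#'   take precedence).
#' @export
adduct_predictions <- function(annotations) {
  ann <- annotations[!is.na(annotations$adduct), , drop = FALSE]
  ann <- ann[order(ann$source != "formula"), , drop = FALSE]  # formula rows first
  ann <- ann[!duplicated(ann$feature_id), , drop = FALSE]
  stats::setNames(ann$adduct, ann$feature_id)
}

#' Split annotated features into known and unknown by confidence
#'
#' Library-search structure annotations with a confidence score at or above
#' the threshold are "known"; the rest, including records with a missing
#' confidence, are "unknown" (the unknowns are the ones later annotated by
#' the de novo model in the hybrid strategy).
#'
#' @param annotations annotation data.frame; only
#'   `source == "library_search"` rows participate.
#' @param threshold confidence cutoff in `[0, 1]`, inclusive on the known
#'   side (default 0.5).
#' @return list with character vectors `known`, `unknown`, and the
#'   `threshold`; class `feature_split`.
#' @export
split_known_unknown <- function(annotations, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  lib <- annotations[annotations$source == "library_search", , drop = FALSE]
  if (anyDuplicated(lib$feature_id)) {
    lib <- lib[!duplicated(lib$feature_id), , drop = FALSE]
  }
  miss <- is.na(lib$confidence)
  if (any(miss)) {
    warning(sprintf("%d library-search records without confidence treated as unknown",
                    sum(miss)), call. = FALSE)
  }
  known <- lib$feature_id[!miss & lib$confidence >= threshold]
  unknown <- setdiff(lib$feature_id, known)
  structure(list(known = known, unknown = unknown, threshold = threshold),
            class = "feature_split")
}

#' Read a per-feature annotation table
#'
#' TSV with columns `feature_id`, `source` (`library_search`, `de_novo` or
#' `formula`), `smiles`, `formula`, `adduct`, `confidence`; a
#' `structure_key` column is accepted and used directly when present,
#' otherwise keys are derived from SMILES on demand.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("feature_id", "source", "adduct")
  if (!all(need %in% names(ann))) {
    stop(sprintf("annotation table needs columns %s", paste(need, collapse = ", ")))
  }
  bad <- !ann$source %in% c("library_search", "de_novo", "formula")
  if (any(bad)) stop("unknown annotation source(s): ",
                     paste(unique(ann$source[bad]), collapse = ", "))
  if (!is.null(ann$confidence)) ann$confidence <- as.numeric(ann$confidence)
  ann
}
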