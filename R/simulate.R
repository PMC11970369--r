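# Synthetic plant metabolomes with planted ground truth. The generator
# emulates the study design the estimation pipeline consumes: a
# species-by-compound incidence built from a shared core pool plus
# species-specific specialized metabolites, replicate MS2 acquisitions with
# intensity/mass noise, and annotation tables with controllable correctness
# and confidence-score behaviour. Everything is deterministic under a fixed
# (parameters, seed) pair.
#
# Synthetic compounds are abstract entities: they carry a synthetic
# 14-letter structure key, a formula and a mass, but no real structure.
# True keys start with a letter in A-M and perturbed (wrong-annotation)
# keys with a letter in N-Z, so wrong keys can never collide with truth.

.synthetic_key <- function(n, alphabet = LETTERS[1:13]) {
  first <- sample(alphabet, n, replace = TRUE)
  rest <- matrix(sample(LETTERS, n * 13, replace = TRUE), nrow = n)
  paste0(first, apply(rest, 1, paste0, collapse = ""))
}

.synthetic_formula <- function(n) {
  c_ct <- sample(8:40, n, replace = TRUE)
  h_ct <- pmax(4, c_ct + sample(-4:14, n, replace = TRUE))
  o_ct <- sample(0:12, n, replace = TRUE)
  n_ct <- sample(0:4, n, replace = TRUE)
  paste0("C", c_ct, "H", h_ct,
         ifelse(n_ct > 0, paste0("N", n_ct), ""),
         ifelse(o_ct > 0, paste0("O", o_ct), ""))
}

#' Generate a synthetic plant-metabolome universe
#'
#' Each species carries `core_per_species` compounds drawn from a shared
#' core pool of size `core_pool_size` (the primary metabolites recurring
#' across species) plus `Poisson(novel_per_species_mean)` species-unique
#' specialized metabolites. Compound masses are uniform in 100-1500 Da and
#' each compound owns a deterministic fragment template of 5-30 peaks below
#' its precursor, so replicate spectra of one compound are recognizably
#' similar wherever it occurs.
#'
#' The defaults (200 species, pool 500, 8 core + ~22 specialized per
#' species) plant roughly 5,000 unique compounds.
#'
#' @param n_species number of species.
#' @param core_pool_size size of the shared compound pool.
#' @param core_per_species core compounds drawn per species (without
#'   replacement; must not exceed `core_pool_size`).
#' @param novel_per_species_mean Poisson mean of species-unique compounds.
#' @param seed RNG seed; the truth is reproducible bit-for-bit from
#'   (parameters, seed).
#' @return object of class `plantome_truth`: list with `species`, `catalog`
#'   (data.frame: compound_id, structure_key, formula, monoisotopic_mass),
#'   `incidence` (species -> compound ids), `templates` (compound ->
#'   two-column peak matrix), `params`, `seed`.
#' @export
generate_universe <- function(n_species = 200, core_pool_size = 500,
                              core_per_species = 8,
                              novel_per_species_mean = 22, seed = 1) {
  stopifnot(n_species >= 1, core_pool_size >= 0, core_per_species >= 0,
            novel_per_species_mean >= 0)
  if (core_per_species > core_pool_size) {
    stop("core_per_species cannot exceed core_pool_size")
  }
  withr_seed(seed, {
    species <- sprintf("SP%04d", seq_len(n_species))
    n_novel <- stats::rpois(n_species, novel_per_species_mean)
    n_total <- core_pool_size + sum(n_novel)
    catalog <- data.frame(
      compound_id = sprintf("CPD%06d", seq_len(n_total)),
      structure_key = .synthetic_key(n_total),
      formula = .synthetic_formula(n_total),
      monoisotopic_mass = stats::runif(n_total, 100, 1500),
      stringsAsFactors = FALSE)
    # keys must be unique: resample any collision (vanishingly rare)
    while (anyDuplicated(catalog$structure_key)) {
      d <- duplicated(catalog$structure_key)
      catalog$structure_key[d] <- .synthetic_key(sum(d))
    }
    core_ids <- catalog$compound_id[seq_len(core_pool_size)]
    novel_ids <- if (core_pool_size > 0) {
      catalog$compound_id[-seq_len(core_pool_size)]
    } else catalog$compound_id
    offsets <- cumsum(c(0, n_novel))
    incidence <- lapply(seq_len(n_species), function(i) {
      core <- if (core_per_species > 0) sample(core_ids, core_per_species)
              else character(0)
      nov <- if (n_novel[i] > 0)
        novel_ids[(offsets[i] + 1):offsets[i + 1]] else character(0)
      c(core, nov)
    })
    names(incidence) <- species
    # per-compound deterministic fragment templates: each compound seeds its
    # own generator from the global seed and its index, so spectra are
    # reproducible compound by compound
    templates <- lapply(seq_len(n_total), function(i) {
      cs <- (seed * 1000003L + i) %% .Machine$integer.max
      withr_seed(cs, {
        npk <- sample(5:30, 1)
        prec <- catalog$monoisotopic_mass[i] + 1.007276
        mz <- sort(stats::runif(npk, 50, prec - 1))
        ints <- stats::rexp(npk)
        cbind(mz = mz, intensity = ints / sum(ints))
      })
    })
    names(templates) <- catalog$compound_id
    structure(list(species = species, catalog = catalog,
                   incidence = incidence, templates = templates,
                   params = list(n_species = n_species,
                                 core_pool_size = core_pool_size,
                                 core_per_species = core_per_species,
                                 novel_per_species_mean = novel_per_species_mean),
                   seed = seed),
              class = "plantome_truth")
  })
}

#' @export
print.plantome_truth <- function(x, ...) {
  cat(sprintf("<plantome_truth: %d species, %d compounds in catalog, %d planted uniques (seed %d)>\n",
              length(x$species), nrow(x$catalog),
              length(unique(unlist(x$incidence))), x$seed))
  invisible(x)
}

#' Planted number of unique compounds
#' @param truth a `plantome_truth`.
#' @export
n_true_uniques <- function(truth) length(unique(unlist(truth$incidence)))

#' Default spectrum-noise parameters
#'
#' Multiplicative log-normal intensity noise (sdlog 0.2), uniform fragment
#' m/z jitter of at most 0.01 Th (half the default peak-match tolerance),
#' 2 ppm precursor jitter, and 3% chances of dropping or gaining a peak per
#' replicate -- the scale of variation seen between replicate LC-MS/MS
#' acquisitions of one compound.
#'
#' @return list of noise parameters.
#' @export
default_noise <- function() {
  list(intensity_sdlog = 0.2, mz_jitter = 0.01, ppm_jitter = 2,
       p_drop = 0.03, p_add = 0.03)
}

#' Generate replicate MS2 spectra from a planted universe
#'
#' For every (species, compound) occurrence, emits `replicates_per_compound`
#' spectra: the compound's template peaks with log-normal intensity noise,
#' bounded m/z jitter, occasional dropped or spurious peaks, and a
#' ppm-jittered precursor. A configurable fraction of features is assigned
#' a non-`[M+H]+` adduct (with the matching precursor shift), emulating the
#' adduct mix of real acquisitions; peak dropping never takes a spectrum
#' below 5 peaks, the template minimum.
#'
#' @param truth a `plantome_truth`.
#' @param replicates_per_compound spectra per occurrence (default 3).
#' @param noise_params list as [default_noise()].
#' @param other_adduct_frac fraction of features assigned `[M+Na]+` instead
#'   of `[M+H]+` (default 0.1).
#' @param seed RNG seed.
#' @return list with `spectra` (list of [ms2_spectrum()]) and `features`
#'   (data.frame: feature_id, sample_id, species, compound_id, adduct,
#'   precursor_mz).
#' @export
generate_spectra <- function(truth, replicates_per_compound = 3,
                             noise_params = default_noise(),
                             other_adduct_frac = 0.1, seed = 1) {
  stopifnot(inherits(truth, "plantome_truth"), replicates_per_compound >= 1)
  np <- utils::modifyList(default_noise(), noise_params)
  mass_of <- stats::setNames(truth$catalog$monoisotopic_mass,
                             truth$catalog$compound_id)
  withr_seed(seed + 1L, {
    occ <- data.frame(
      species = rep(names(truth$incidence),
                    lengths(truth$incidence)),
      compound_id = unlist(truth$incidence, use.names = FALSE),
      stringsAsFactors = FALSE)
    rows <- occ[rep(seq_len(nrow(occ)), each = replicates_per_compound), ]
    rows$replicate <- rep(seq_len(replicates_per_compound), nrow(occ))
    n <- nrow(rows)
    rows$feature_id <- sprintf("F%07d", seq_len(n))
    rows$sample_id <- sprintf("%s_r%d", rows$species, rows$replicate)
    other <- stats::runif(n) < other_adduct_frac
    rows$adduct <- ifelse(other, "[M+Na]+", "[M+H]+")
    shift <- ifelse(other, 22.989218, 1.007276)
    base_mz <- mass_of[rows$compound_id] + shift
    rows$precursor_mz <- base_mz *
      (1 + stats::rnorm(n, 0, np$ppm_jitter) * 1e-6)
    spectra <- vector("list", n)
    for (r in seq_len(n)) {
      tpl <- truth$templates[[rows$compound_id[r]]]
      npk <- nrow(tpl)
      keep <- stats::runif(npk) >= np$p_drop
      if (sum(keep) < 5) keep[!keep][seq_len(5 - sum(keep))] <- TRUE
      mz <- tpl[keep, "mz"] + stats::runif(sum(keep), -np$mz_jitter, np$mz_jitter)
      ints <- tpl[keep, "intensity"] *
        stats::rlnorm(sum(keep), 0, np$intensity_sdlog)
      if (stats::runif(1) < np$p_add) {
        mz <- c(mz, stats::runif(1, 50, rows$precursor_mz[r] - 1))
        ints <- c(ints, stats::quantile(tpl[, "intensity"], 0.2))
      }
      spectra[[r]] <- ms2_spectrum(
        feature_id = rows$feature_id[r], sample_id = rows$sample_id[r],
        species = rows$species[r], precursor_mz = rows$precursor_mz[r],
        adduct = rows$adduct[r], peaks = cbind(mz, ints))
    }
    rownames(rows) <- NULL
    list(spectra = spectra,
         features = rows[c("feature_id", "sample_id", "species",
                           "compound_id", "adduct", "precursor_mz")])
  })
}

#' Generate synthetic annotation tables
#'
#' Emulates the three consumed annotation sources per feature:
#' library search (correct with probability `q_library`, confidence drawn
#' from a Beta that is high when the annotation is correct and low when it
#' is wrong), de novo structure prediction (correct with probability
#' `q_denovo`, otherwise a perturbed key guaranteed disjoint from the
#' truth), and formula prediction (correct with probability `q_formula`).
#' The adduct column copies the feature's true adduct.
#'
#' @param truth a `plantome_truth`.
#' @param features feature table from [generate_spectra()].
#' @param q_library,q_denovo,q_formula correctness probabilities in `[0,1]`.
#' @param conf_params list with Beta shape pairs `correct` and `incorrect`
#'   for the library-search confidence (defaults `c(8, 2)` and `c(2, 8)`).
#' @param seed RNG seed.
#' @return annotation data.frame with columns `feature_id`, `source`,
#'   `structure_key`, `formula`, `adduct`, `confidence`.
#' @export
generate_annotations <- function(truth, features, q_library = 0.7,
                                 q_denovo = 0.6, q_formula = 0.9,
                                 conf_params = list(correct = c(8, 2),
                                                    incorrect = c(2, 8)),
                                 seed = 1) {
  stopifnot(inherits(truth, "plantome_truth"),
            all(c(q_library, q_denovo, q_formula) >= 0),
            all(c(q_library, q_denovo, q_formula) <= 1))
  key_of <- stats::setNames(truth$catalog$structure_key,
                            truth$catalog$compound_id)
  formula_of <- stats::setNames(truth$catalog$formula,
                                truth$catalog$compound_id)
  withr_seed(seed + 2L, {
    n <- nrow(features)
    true_key <- unname(key_of[features$compound_id])
    true_formula <- unname(formula_of[features$compound_id])
    perturbed <- function(m) .synthetic_key(m, alphabet = LETTERS[14:26])
    lib_ok <- stats::runif(n) < q_library
    lib_key <- ifelse(lib_ok, true_key, perturbed(n))
    lib_conf <- ifelse(lib_ok,
                       stats::rbeta(n, conf_params$correct[1], conf_params$correct[2]),
                       stats::rbeta(n, conf_params$incorrect[1], conf_params$incorrect[2]))
    dn_ok <- stats::runif(n) < q_denovo
    dn_key <- ifelse(dn_ok, true_key, perturbed(n))
    fm_ok <- stats::runif(n) < q_formula
    fm <- ifelse(fm_ok, true_formula,
                 paste0(true_formula, "O", sample(13:19, n, replace = TRUE)))
    rbind(
      data.frame(feature_id = features$feature_id, source = "library_search",
                 structure_key = lib_key, formula = NA_character_,
                 adduct = features$adduct, confidence = lib_conf,
                 stringsAsFactors = FALSE),
      data.frame(feature_id = features$feature_id, source = "de_novo",
                 structure_key = dn_key, formula = NA_character_,
                 adduct = features$adduct, confidence = NA_real_,
                 stringsAsFactors = FALSE),
      data.frame(feature_id = features$feature_id, source = "formula",
                 structure_key = NA_character_, formula = fm,
                 adduct = features$adduct, confidence = NA_real_,
                 stringsAsFactors = FALSE))
  })
}

#' Write a complete simulated dataset to disk
#'
#' Writes the MGF spectra, the annotation TSV, a literature-style compound
#' TSV (structure_key, species, monoisotopic_mass -- synthetic keys stand in
#' for SMILES-derived ones), the feature table, and a ground-truth JSON.
#'
#' @param truth a `plantome_truth`.
#' @param sim output of [generate_spectra()].
#' @param annotations output of [generate_annotations()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(truth, sim, annotations, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mgf(sim$spectra, file.path(dir, "spectra.mgf"))
  utils::write.table(sim$features, file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  lit <- data.frame(
    structure_key = truth$catalog$structure_key[
      match(unlist(truth$incidence, use.names = FALSE),
            truth$catalog$compound_id)],
    species = rep(names(truth$incidence), lengths(truth$incidence)),
    monoisotopic_mass = truth$catalog$monoisotopic_mass[
      match(unlist(truth$incidence, use.names = FALSE),
            truth$catalog$compound_id)],
    stringsAsFactors = FALSE)
  utils::write.table(lit, file.path(dir, "literature.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = truth$seed, params = truth$params,
         n_true_uniques = n_true_uniques(truth),
         incidence = truth$incidence),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
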