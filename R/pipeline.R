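# End-to-end orchestration: filter -> cluster -> curves -> fit -> holdout ->
# project, with a manifest recording every filter count and seed so a run
# can be reproduced exactly from its config snapshot.

#' Default pipeline configuration
#'
#' All thresholds of the estimation pipeline in one place: minimum peak
#' count (5), dominance flag (0.9), adduct (`[M+H]+`), known/unknown
#' confidence threshold (0.5), clustering ppm window (10) and similarity
#' threshold (0.7), holdout fractions (0.1/0.2/0.3), and the projection
#' target (400,000 species).
#'
#' @return named list of settings.
#' @export
default_config <- function() {
  list(simulate = TRUE, seed = 1,
       n_species = 200, core_pool_size = 500, core_per_species = 8,
       novel_per_species_mean = 22, replicates = 3, other_adduct_frac = 0.1,
       q_library = 0.7, q_denovo = 0.6, q_formula = 0.9,
       spectra_mgf = NA_character_, annotations_tsv = NA_character_,
       min_peaks = 5, dominance_flag = 0.9, adduct = "[M+H]+",
       confidence_threshold = 0.5,
       ppm_window = 10, peak_mz_tol = 0.02, cluster_threshold = 0.7,
       weighted = TRUE,
       methods = c("formula", "de_novo", "hybrid", "cluster"),
       holdout_fracs = c(0.1, 0.2, 0.3), projection_n = 400000,
       out_dir = NA_character_)
}

#' Read a pipeline config file
#'
#' Plain `key = value` text (one setting per line, `#` comments); values
#' are coerced to the type of the corresponding [default_config()] entry,
#' comma-separated lists to vectors. Settings not in the file keep their
#' defaults.
#'
#' @param path config file path.
#' @return full config list.
#' @export
read_run_config <- function(path) {
  cfg <- default_config()
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (!key %in% names(cfg)) {
      warning(sprintf("unknown config key '%s' ignored", key), call. = FALSE)
      next
    }
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    cfg[[key]] <- if (is.logical(cfg[[key]])) as.logical(parts)
                  else if (is.numeric(cfg[[key]])) as.numeric(parts)
                  else parts
  }
  cfg
}

#' Run the full chemical-space estimation pipeline
#'
#' Executes filter, clustering, curve building, power-law fitting, holdout
#' validation and projection, either on a simulated dataset with planted
#' ground truth (`config$simulate = TRUE`) or on MGF + annotation inputs.
#' The formula curve is built on quality-filtered features without the
#' adduct restriction (formula prediction accounts for adducts itself); the
#' structure and cluster curves use the `[M+H]+`-restricted set.
#'
#' @param config list as [default_config()]; partial lists are completed
#'   with defaults.
#' @return list with `manifest` (config snapshot, per-stage counts, seeds),
#'   `curves`, `models`, `holdout`, `projections`, `clusters`, and --
#'   for simulated runs -- `truth`. If `config$out_dir` is set, curve TSVs,
#'   model JSONs, cluster assignments and `manifest.json` are written there.
#' @export
run_full_estimate <- function(config = list()) {
  cfg <- utils::modifyList(default_config(), config)
  manifest <- list(config = cfg, counts = list(), seed = cfg$seed,
                   version = as.character(utils::packageVersion("phytospace")),
                   started = format(Sys.time(), tz = "UTC"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  truth <- NULL
  if (isTRUE(cfg$simulate)) {
    truth <- stage("simulate", generate_universe(
      n_species = cfg$n_species, core_pool_size = cfg$core_pool_size,
      core_per_species = cfg$core_per_species,
      novel_per_species_mean = cfg$novel_per_species_mean, seed = cfg$seed))
    sim <- stage("simulate", generate_spectra(
      truth, replicates_per_compound = cfg$replicates,
      other_adduct_frac = cfg$other_adduct_frac, seed = cfg$seed))
    spectra <- sim$spectra
    annotations <- stage("simulate", generate_annotations(
      truth, sim$features, q_library = cfg$q_library,
      q_denovo = cfg$q_denovo, q_formula = cfg$q_formula, seed = cfg$seed))
    feature_species <- sim$features[c("feature_id", "species")]
  } else {
    spectra <- stage("read", read_mgf(cfg$spectra_mgf))
    annotations <- stage("read", read_annotations(cfg$annotations_tsv))
    feature_species <- data.frame(
      feature_id = vapply(spectra, function(s) s$feature_id, character(1)),
      species = vapply(spectra, function(s) s$species, character(1)),
      stringsAsFactors = FALSE)
  }
  if (!length(spectra)) stop("pipeline stage 'filter' failed: no input spectra")
  manifest$counts$raw_spectra <- length(spectra)

  dom <- stage("filter", dominant_peak_fraction(spectra, cfg$dominance_flag))
  manifest$counts$dominant_flagged <- sum(attr(dom, "flagged"))
  manifest$counts$dominant_fraction_pct <-
    100 * mean(attr(dom, "flagged"))

  kept <- stage("filter", filter_min_peaks(spectra, cfg$min_peaks))
  manifest$counts$after_min_peaks <- length(kept)

  kept_adduct <- stage("filter", select_adduct(kept, annotations, cfg$adduct))
  manifest$counts$after_adduct <- length(kept_adduct)

  split <- stage("split", split_known_unknown(annotations,
                                              cfg$confidence_threshold))
  manifest$counts$known <- length(split$known)
  manifest$counts$unknown <- length(split$unknown)

  clusters <- NULL
  if ("cluster" %in% cfg$methods) {
    clusters <- stage("cluster", build_clusters(
      kept_adduct, ppm_window = cfg$ppm_window, mz_tol = cfg$peak_mz_tol,
      threshold = cfg$cluster_threshold, weighted = cfg$weighted))
    manifest$counts$n_clusters <- clusters$n_clusters
  }

  ids_all <- vapply(kept, function(s) s$feature_id, character(1))
  ids_adduct <- vapply(kept_adduct, function(s) s$feature_id, character(1))
  feats_all <- feature_species[feature_species$feature_id %in% ids_all, ]
  feats_adduct <- feature_species[feature_species$feature_id %in% ids_adduct, ]

  curves <- list(); models <- list(); holdout <- list(); projections <- list()
  for (m in cfg$methods) {
    feats <- if (m == "formula") feats_all else feats_adduct
    keys <- stage(paste0("curves:", m), method_keys(
      feats, annotations, method = m, split = split, clusters = clusters))
    curves[[m]] <- stage(paste0("curves:", m),
                         saturation_curve(keys, method = m))
    models[[m]] <- stage(paste0("fit:", m), fit_power_law(curves[[m]]))
    holdout[[m]] <- stage(paste0("holdout:", m),
                          holdout_validate(curves[[m]], cfg$holdout_fracs))
    projections[[m]] <- project(models[[m]], cfg$projection_n)
  }
  manifest$counts$final_curve_values <-
    lapply(curves, function(cv) cv$y[nrow(cv)])
  manifest$finished <- format(Sys.time(), tz = "UTC")

  if (!is.na(cfg$out_dir)) {
    .write_run_outputs(cfg$out_dir, curves, models, holdout, projections,
                       clusters, manifest)
  }
  res <- list(manifest = manifest, curves = curves, models = models,
              holdout = holdout, projections = projections,
              clusters = clusters)
  if (!is.null(truth)) res$truth <- truth
  res
}

.write_run_outputs <- function(dir, curves, models, holdout, projections,
                               clusters, manifest) {
  for (d in c("curves", "models", "clusters")) {
    dir.create(file.path(dir, d), showWarnings = FALSE, recursive = TRUE)
  }
  for (m in names(curves)) {
    utils::write.table(as.data.frame(curves[[m]]),
                       file.path(dir, "curves", paste0(m, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(method = m, a = models[[m]]$a, b = models[[m]]$b,
           fit_domain = models[[m]]$fit_domain, rss = models[[m]]$rss,
           projection = projections[[m]],
           holdout = holdout[[m]]),
      file.path(dir, "models", paste0(m, ".json")),
      auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  if (!is.null(clusters)) {
    utils::write.table(clusters$assignments,
                       file.path(dir, "clusters", "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
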