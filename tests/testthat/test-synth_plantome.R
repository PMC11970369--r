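# The synthetic metabolome generator: determinism, planted statistics, and
# the guarantees the downstream estimators rely on.

test_that("the universe is reproducible bit-for-bit from (params, seed)", {
  u1 <- generate_universe(n_species = 20, core_pool_size = 50,
                          core_per_species = 4, novel_per_species_mean = 3,
                          seed = 5)
  u2 <- generate_universe(n_species = 20, core_pool_size = 50,
                          core_per_species = 4, novel_per_species_mean = 3,
                          seed = 5)
  expect_identical(u1$catalog, u2$catalog)
  expect_identical(u1$incidence, u2$incidence)
  expect_identical(u1$templates, u2$templates)
  u3 <- generate_universe(n_species = 20, core_pool_size = 50,
                          core_per_species = 4, novel_per_species_mean = 3,
                          seed = 6)
  expect_false(identical(u1$catalog, u3$catalog))
  expect_error(generate_universe(core_per_species = 10, core_pool_size = 5),
               "cannot exceed")
})

test_that("every incident compound exists in the catalog with a valid template", {
  u <- generate_universe(n_species = 15, seed = 2)
  inc <- unique(unlist(u$incidence))
  expect_true(all(inc %in% u$catalog$compound_id))
  npk <- vapply(u$templates, nrow, numeric(1))
  expect_true(all(npk >= 5 & npk <= 30))
  prec <- u$catalog$monoisotopic_mass + 1.007276
  maxmz <- vapply(u$templates, function(t) max(t[, "mz"]), numeric(1))
  expect_true(all(maxmz < prec))
  expect_true(all(u$catalog$monoisotopic_mass >= 100 &
                    u$catalog$monoisotopic_mass <= 1500))
  expect_true(all(grepl("^[A-Z]{14}$", u$catalog$structure_key)))
})

test_that("with no specialized metabolites the curve flattens at the pool size", {
  u <- generate_universe(n_species = 30, core_pool_size = 40,
                         core_per_species = 10, novel_per_species_mean = 0,
                         seed = 3)
  keys <- lapply(u$incidence, function(ids)
    u$catalog$structure_key[match(ids, u$catalog$compound_id)])
  cv <- saturation_curve(keys)
  expect_lte(cv$y[30], 40)
  expect_lte(n_true_uniques(u), 40)
})

test_that("with only specialized metabolites the total is a Poisson sum", {
  # sum of n Poisson(5) has mean 5n, sd sqrt(5n); check within 3 SD over seeds
  n <- 100; mean_novel <- 5
  tot <- vapply(1:5, function(s) {
    n_true_uniques(generate_universe(n_species = n, core_pool_size = 0,
                                     core_per_species = 0,
                                     novel_per_species_mean = mean_novel,
                                     seed = s))
  }, numeric(1))
  expect_true(all(abs(tot - n * mean_novel) <= 3 * sqrt(n * mean_novel)))
})

test_that("noise-free single replicates reproduce their template exactly", {
  u <- generate_universe(n_species = 5, core_pool_size = 10,
                         core_per_species = 2, novel_per_species_mean = 2,
                         seed = 4)
  sim <- generate_spectra(u, replicates_per_compound = 1,
                          noise_params = list(intensity_sdlog = 0,
                                              mz_jitter = 0, ppm_jitter = 0,
                                              p_drop = 0, p_add = 0),
                          other_adduct_frac = 0, seed = 4)
  for (r in seq_len(nrow(sim$features))) {
    tpl <- u$templates[[sim$features$compound_id[r]]]
    expect_equal(entropy_similarity(sim$spectra[[r]], tpl), 1)
    expect_equal(sim$spectra[[r]]$precursor_mz,
                 u$catalog$monoisotopic_mass[
                   u$catalog$compound_id == sim$features$compound_id[r]] +
                   1.007276, tolerance = 1e-9)
  }
})

test_that("within-compound similarity exceeds between-compound similarity", {
  u <- generate_universe(n_species = 10, core_pool_size = 30,
                         core_per_species = 3, novel_per_species_mean = 3,
                         seed = 8)
  sim <- generate_spectra(u, replicates_per_compound = 3, seed = 8)
  cid <- sim$features$compound_id
  set.seed(8)
  within <- numeric(0); between <- numeric(0)
  for (k in 1:200) {
    i <- sample(length(sim$spectra), 1)
    same <- setdiff(which(cid == cid[i]), i)
    diff_ <- which(cid != cid[i])
    if (length(same)) within <- c(within,
      entropy_similarity(sim$spectra[[i]], sim$spectra[[sample(same, 1)]]))
    between <- c(between,
      entropy_similarity(sim$spectra[[i]], sim$spectra[[sample(diff_, 1)]]))
  }
  expect_gt(median(within), median(between))
  expect_gt(median(within), 0.8)
  expect_lt(median(between), 0.2)
})

test_that("annotation correctness and confidence behave as parameterized", {
  u <- generate_universe(n_species = 30, seed = 9)
  sim <- generate_spectra(u, seed = 9)
  key_of <- setNames(u$catalog$structure_key, u$catalog$compound_id)
  truth_keys <- unname(key_of[sim$features$compound_id])

  # perfect library annotations reproduce the truth keys exactly
  ann1 <- generate_annotations(u, sim$features, q_library = 1, seed = 9)
  lib <- ann1[ann1$source == "library_search", ]
  expect_identical(lib$structure_key, truth_keys)

  # fully wrong de novo keys never collide with any true key
  ann0 <- generate_annotations(u, sim$features, q_denovo = 0, seed = 9)
  dn <- ann0[ann0$source == "de_novo", ]
  expect_length(intersect(dn$structure_key, u$catalog$structure_key), 0)

  # intermediate q: known fraction matches the Beta-mixture expectation
  # within 3 binomial SDs; P(conf >= 0.5) is ~0.9496 for Beta(8,2) and
  # ~0.0504 for Beta(2,8)
  q <- 0.7
  ann <- generate_annotations(u, sim$features, q_library = q, seed = 10)
  sp <- split_known_unknown(ann, 0.5)
  p_known <- q * (1 - pbeta(0.5, 8, 2)) + (1 - q) * (1 - pbeta(0.5, 2, 8))
  n <- nrow(sim$features)
  expect_lt(abs(length(sp$known) - n * p_known),
            3 * sqrt(n * p_known * (1 - p_known)))
})

test_that("a written simulation round-trips through the file readers", {
  u <- generate_universe(n_species = 6, core_pool_size = 12,
                         core_per_species = 2, novel_per_species_mean = 2,
                         seed = 12)
  sim <- generate_spectra(u, seed = 12)
  ann <- generate_annotations(u, sim$features, seed = 12)
  dir <- withr::local_tempdir()
  write_simulation(u, sim, ann, dir)
  back <- read_mgf(file.path(dir, "spectra.mgf"))
  expect_length(back, length(sim$spectra))
  expect_equal(vapply(back, function(s) s$feature_id, character(1)),
               sim$features$feature_id)
  ann_back <- read_annotations(file.path(dir, "annotations.tsv"))
  expect_equal(nrow(ann_back), nrow(ann))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$n_true_uniques, n_true_uniques(u))
})
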