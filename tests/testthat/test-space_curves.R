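# Saturation curves, adduct arithmetic, coverage, MS1 folds, power-law
# fitting, holdouts, projections and set overlap.

test_that("saturation curve accumulates unique keys in order", {
  keys <- list(sp1 = c("k1", "k2"), sp2 = c("k2", "k3"))
  cv <- saturation_curve(keys, ordering = c("sp1", "sp2"))
  expect_equal(cv$y, c(2, 3))
  same <- list(a = c("x", "y"), b = c("x", "y"), c = c("y", "x"))
  expect_equal(saturation_curve(same)$y, c(2, 2, 2))
  expect_error(saturation_curve(keys, ordering = c("sp1", "nope")),
               "permutation")
})

test_that("saturation curve equals brute-force unions on a 200-species incidence", {
  set.seed(19)
  pool <- sprintf("K%05d", 1:3000)
  keys <- random_incidence(200, pool, mean_keys = 25)
  ord <- sample(names(keys))
  cv <- saturation_curve(keys, ord)
  brute <- vapply(seq_along(ord), function(k)
    length(unique(unlist(keys[ord[seq_len(k)]]))), numeric(1))
  expect_equal(cv$y, brute)
  expect_true(all(diff(cv$y) >= 0))
  expect_equal(cv$y[200], length(unique(unlist(keys))))
})

test_that("adduct precursor m/z is (mass + shift) / charge", {
  expect_equal(adduct_precursor_mz(46.04186, "[M+H]+"), 47.04914,
               tolerance = 1e-5)
  expect_equal(adduct_precursor_mz(46.04186, "[M+Na]+"), 69.03108,
               tolerance = 1e-5)
  expect_error(adduct_precursor_mz(0, "[M+H]+"), "positive")
  expect_error(adduct_precursor_mz(100, "[M+Xx]+"), "unknown adduct")
})

test_that("coverage ratio counts adduct-matchable literature compounds", {
  cmp1 <- data.frame(structure_key = sprintf("K%02d", 1:20), species = "sp1",
                     monoisotopic_mass = seq(100, 480, length.out = 20))
  feats <- data.frame(species = "sp1",
                      precursor_mz = adduct_precursor_mz(cmp1$monoisotopic_mass[1],
                                                         "[M+H]+"))
  cov <- coverage_ratio(cmp1, feats, min_structures = 20)
  expect_equal(cov$n_matched, 1)
  expect_equal(cov$ratio, 1 / 20)
  # all compounds observed exactly -> ratio 1
  feats_all <- data.frame(species = "sp1",
                          precursor_mz = adduct_precursor_mz(cmp1$monoisotopic_mass,
                                                             "[M+H]+"))
  expect_equal(coverage_ratio(cmp1, feats_all)$ratio, 1)
  # no features -> ratio 0
  none <- data.frame(species = character(0), precursor_mz = numeric(0))
  expect_equal(coverage_ratio(cmp1, none)$ratio, 0)
  # species below the minimum size are not reported
  cmp_small <- cmp1[1:5, ]
  expect_equal(nrow(coverage_ratio(cmp_small, feats_all)), 0)
  expect_error(coverage_ratio(cmp1, feats_all, adducts = NULL), "empty adduct")
})

test_that("coverage matches a brute-force all-pairs match with planted detectability", {
  set.seed(29)
  masses <- runif(50, 100, 900)
  detectable <- rep(c(TRUE, FALSE), c(15, 35))  # planted 30%
  cmp <- data.frame(structure_key = sprintf("K%02d", 1:50), species = "spX",
                    monoisotopic_mass = masses)
  feats <- data.frame(species = "spX",
                      precursor_mz = adduct_precursor_mz(masses[detectable],
                                                         "[M+Na]+"))
  cov <- coverage_ratio(cmp, feats, tol_ppm = 10)
  ad <- default_adducts()
  brute <- vapply(masses, function(m) {
    any(vapply(seq_len(nrow(ad)), function(ai) {
      mz <- (m + ad$mass_shift[ai]) / ad$charge[ai]
      any(abs(mz - feats$precursor_mz) / mz * 1e6 <= 10)
    }, logical(1)))
  }, logical(1))
  expect_equal(cov$n_matched, sum(brute))
  expect_gte(cov$n_matched, 15)  # planted matches are found
})

test_that("MS1 fold curve rounds to 2 decimals and scales from the first sample", {
  # six pairwise-disjoint equal-size samples -> folds 1..6
  samples <- lapply(0:5, function(k) 100 + k * 50 + seq(0, 9))
  expect_equal(ms1_fold_curve(samples), 1:6)
  # identical samples -> all 1
  expect_equal(ms1_fold_curve(list(c(100.1, 200.2), c(100.1, 200.2))), c(1, 1))
  # 150.004 and 150.0049 round to the same 2-decimal mass
  expect_equal(ms1_fold_curve(list(150.004, 150.0049)), c(1, 1))
  expect_equal(ms1_fold_curve(list(150.004, 150.006)), c(1, 2))
  expect_error(ms1_fold_curve(list(numeric(0), 1)), "first sample")
})

test_that("power-law fit recovers exact curves to high precision", {
  x <- 1:1000
  m <- fit_power_law(12 * x^0.8)
  expect_equal(m$a, 12, tolerance = 1e-6)
  expect_equal(m$b, 0.8, tolerance = 1e-6)
  lin <- fit_power_law(5 * (1:100))
  expect_equal(lin$a, 5, tolerance = 1e-6)
  expect_equal(lin$b, 1, tolerance = 1e-6)
  expect_error(fit_power_law(c(1, 2)), "at least 3")
  expect_error(fit_power_law(c(0, 1, 2)), "positive")
})

test_that("exponent recovery under 1% noise is unbiased within 0.02", {
  x <- 1:200
  bs <- vapply(1:100, function(r) {
    set.seed(1000 + r)
    y <- 12 * x^0.8 * rlnorm(length(x), 0, 0.01)
    fit_power_law(y)$b
  }, numeric(1))
  expect_lt(abs(mean(bs) - 0.8), 0.02)
})

test_that("projection follows the closed form and its monotonicities", {
  m <- structure(list(a = 2, b = 1, fit_domain = c(1, 10), rss = 0,
                      method = NA_character_), class = "power_law_model")
  expect_equal(project(m, 10), 20)
  m2 <- structure(list(a = 1, b = 0.5, fit_domain = c(1, 10), rss = 0,
                       method = NA_character_), class = "power_law_model")
  expect_equal(project(m2, 400000), sqrt(400000), tolerance = 1e-9)
  fitted <- fit_power_law(12 * (1:500)^0.8)
  expect_equal(project(fitted, 400000), 12 * 400000^0.8, tolerance = 1e-4)
  # monotone in n and b; linear in a
  expect_lt(project(m2, 100), project(m2, 200))
  m3 <- m2; m3$b <- 0.7
  expect_gt(project(m3, 400000), project(m2, 400000))
  m4 <- m2; m4$a <- 2
  expect_equal(project(m4, 1000), 2 * project(m2, 1000))
})

test_that("holdout error is zero on exact power laws and grows on plateaus", {
  rep <- holdout_validate(7 * (1:200)^0.6)
  expect_equal(nrow(rep), 3)
  expect_equal(rep$mape, rep(0, 3), tolerance = 1e-6)
  expect_equal(rep$rmse, rep(0, 3), tolerance = 1e-4)
  # hard plateau: extrapolation error grows as more tail is withheld
  y <- c(10 * (1:70)^0.9, rep(10 * 70^0.9, 130))
  rep2 <- holdout_validate(y, c(0.1, 0.2, 0.3))
  expect_true(all(diff(rep2$mape) > 0))
})

test_that("ordering permutations share the final value and a tight envelope", {
  set.seed(43)
  keys <- random_incidence(40, sprintf("K%04d", 1:500), mean_keys = 12)
  ps <- permutation_stability(keys, n_perm = 100, seed = 99)
  expect_length(unique(ps$final_values), 1)
  expect_equal(ps$final_values[1], length(unique(unlist(keys))))
  expect_true(all(ps$envelope$ymin <= ps$envelope$ymedian))
  expect_true(all(ps$envelope$ymedian <= ps$envelope$ymax))
  # seeded: same call twice is identical
  ps2 <- permutation_stability(keys, n_perm = 100, seed = 99)
  expect_identical(ps$envelope, ps2$envelope)
  # envelope matches brute-force recomputation at a few positions
  set.seed(99)
  ys <- replicate(100, saturation_curve(keys, sample(names(keys)))$y)
  expect_equal(ps$envelope$ymax, apply(ys, 1, max))
})

test_that("set overlap reports counts and Jaccard", {
  expect_equal(set_overlap(c("a", "b"), c("a", "b"))$jaccard, 1)
  expect_equal(set_overlap("a", "b")$jaccard, 0)
  ov <- set_overlap(c("1", "2", "3"), c("3", "4"))
  expect_equal(ov$jaccard, 0.25)
  expect_equal(ov$n_common, 1)
  expect_equal(ov$n_a_only, 2)
  expect_warning(z <- set_overlap(character(0), character(0)), "empty")
  expect_equal(z$jaccard, 0)
})

test_that("formula normalization canonicalizes to Hill order", {
  expect_equal(normalize_formula("H12C6O6"), "C6H12O6")
  expect_equal(normalize_formula("C6H12O6"), "C6H12O6")
  expect_equal(normalize_formula(c("OH2", "ClNa")), c("H2O", "ClNa"))
  expect_true(is.na(normalize_formula(NA)))
})
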