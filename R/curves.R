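# Cumulative unique-structure curves, literature-vs-MS coverage, MS1 fold
# curves, power-law fitting, holdout validation, and richness projection.
# Every curve counts distinct keys (structure keys, scaffold keys, formulas
# or cluster ids) as species are added in a fixed order, and the fitted
# y = a x^b extrapolates that accumulation to the full plant kingdom.

#' Cumulative unique-key saturation curve
#'
#' `y[k]` is the number of distinct keys over the first `k` species of the
#' ordering, so the curve is non-decreasing and ends at the global distinct
#' count regardless of order.
#'
#' @param keys_by_species named list: species id -> character vector of keys.
#' @param ordering permutation of `names(keys_by_species)`; default
#'   lexicographic by species id, the package's fixed arbitrary ordering.
#' @param method label stored on the curve (e.g. `"cluster"`,
#'   `"literature"`).
#' @return object of class `cumulative_curve`: data.frame with `index`,
#'   `species`, `y`, plus attribute `method`.
#' @export
saturation_curve <- function(keys_by_species, ordering = NULL,
                             method = "literature") {
  if (is.null(ordering)) ordering <- sort(names(keys_by_species))
  if (!setequal(ordering, names(keys_by_species)) ||
      length(ordering) != length(keys_by_species)) {
    stop("ordering must be a permutation of the species in keys_by_species")
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  total <- 0L
  y <- integer(length(ordering))
  for (k in seq_along(ordering)) {
    for (key in unique(as.character(keys_by_species[[ordering[k]]]))) {
      if (is.null(seen[[key]])) { seen[[key]] <- TRUE; total <- total + 1L }
    }
    y[k] <- total
  }
  out <- data.frame(index = seq_along(ordering), species = ordering, y = y,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  class(out) <- c("cumulative_curve", "data.frame")
  out
}

#' Per-species key sets under an annotation strategy
#'
#' Assembles the species -> key-set map that feeds [saturation_curve()] for
#' each estimation strategy:
#' \describe{
#'   \item{formula}{unique predicted molecular formulas (Hill-normalized);
#'     computed on all features, since formula prediction accounts for
#'     adducts itself.}
#'   \item{de_novo}{structure keys of de novo predictions for the supplied
#'     (adduct- and quality-filtered) features.}
#'   \item{hybrid}{library-search keys for features in `split$known`, de
#'     novo keys for the rest.}
#'   \item{cluster}{cluster ids from a [build_clusters()] assignment.}
#' }
#'
#' @param features data.frame with `feature_id` and `species` for the
#'   features to count (already filtered as appropriate for the method).
#' @param annotations annotation data.frame; structure rows may carry
#'   `structure_key` directly, otherwise keys are derived from `smiles`.
#' @param method one of `"formula"`, `"de_novo"`, `"hybrid"`, `"cluster"`.
#' @param split a `feature_split` (required for `"hybrid"`).
#' @param clusters a `cluster_assignment` (required for `"cluster"`).
#' @return named list species -> character vector of keys.
#' @export
method_keys <- function(features, annotations, method,
                        split = NULL, clusters = NULL) {
  method <- match.arg(method, c("formula", "de_novo", "hybrid", "cluster"))
  species_of <- stats::setNames(features$species, features$feature_id)
  key_rows <- function(src) {
    ann <- annotations[annotations$source == src &
                         annotations$feature_id %in% features$feature_id, ,
                       drop = FALSE]
    if (src == "formula") {
      data.frame(feature_id = ann$feature_id,
                 key = normalize_formula(ann$formula),
                 stringsAsFactors = FALSE)
    } else {
      key <- if (!is.null(ann$structure_key) && !all(is.na(ann$structure_key)))
        ann$structure_key
      else suppressWarnings(structure_key(ann$smiles))
      data.frame(feature_id = ann$feature_id, key = key,
                 stringsAsFactors = FALSE)
    }
  }
  tab <- switch(method,
    formula = key_rows("formula"),
    de_novo = key_rows("de_novo"),
    hybrid = {
      if (is.null(split)) stop("hybrid method needs a feature_split")
      lib <- key_rows("library_search")
      dn <- key_rows("de_novo")
      rbind(lib[lib$feature_id %in% split$known, , drop = FALSE],
            dn[!dn$feature_id %in% split$known, , drop = FALSE])
    },
    cluster = {
      if (is.null(clusters)) stop("cluster method needs a cluster_assignment")
      a <- clusters$assignments
      a <- a[a$feature_id %in% features$feature_id, , drop = FALSE]
      data.frame(feature_id = a$feature_id,
                 key = paste0("CL", a$cluster_id), stringsAsFactors = FALSE)
    })
  tab <- tab[!is.na(tab$key), , drop = FALSE]
  tab$species <- species_of[tab$feature_id]
  split_keys <- split(tab$key, tab$species)
  lapply(split_keys, unique)
}

#' Normalize a molecular formula to Hill order
#'
#' Carbon first, hydrogen second, remaining elements alphabetically (all
#' elements alphabetical when there is no carbon), with counts of 1 left
#' implicit -- so `"H12C6O6"` and `"C6H12O6"` count as one formula.
#'
#' @param formula character vector.
#' @return normalized character vector (`NA` propagated).
#' @export
normalize_formula <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(NA_character_)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    if (!length(toks) || sum(attr(m, "match.length")) != nchar(f)) {
      return(NA_character_)
    }
    el <- sub("[0-9]+$", "", toks)
    ct <- as.integer(ifelse(grepl("[0-9]+$", toks),
                            sub("^[A-Za-z]+", "", toks), "1"))
    agg <- tapply(ct, el, sum)
    els <- names(agg)
    ord <- if ("C" %in% els) {
      c("C"[TRUE], "H"[("H" %in% els)], sort(setdiff(els, c("C", "H"))))
    } else sort(els)
    ord <- ord[ord %in% els]
    paste0(ord, ifelse(agg[ord] > 1, agg[ord], ""), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# --- adducts and coverage ----------------------------------------------------

#' Default positive-mode adduct table
#'
#' Mass shifts in Da for the common positive electrospray adducts
#' (`[M+H]+`, `[M+Na]+`, `[M+K]+`, `[M+NH4]+`, `[M+H-H2O]+`), all singly
#' charged. Shifts are cation masses (electron mass accounted for).
#'
#' @return data.frame with `name`, `mass_shift`, `charge`.
#' @export
default_adducts <- function() {
  data.frame(name = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M+NH4]+", "[M+H-H2O]+"),
             mass_shift = c(1.007276, 22.989218, 38.963158, 18.033823,
                            -17.002740),
             charge = 1L, stringsAsFactors = FALSE)
}

#' Read an adduct table from a TSV
#' @param path TSV with columns `name`, `mass_shift`, `charge`.
#' @return data.frame.
#' @export
read_adducts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "mass_shift", "charge") %in% names(tab))) {
    stop("adduct table needs columns name, mass_shift, charge")
  }
  if (anyDuplicated(tab$name)) stop("adduct names must be unique")
  tab
}

#' Precursor m/z of a neutral mass under an adduct
#'
#' `(mass + mass_shift) / charge`.
#'
#' @param mass neutral monoisotopic mass in Da (> 0), vectorized.
#' @param adduct one row of an adduct table, or an adduct name looked up in
#'   `table`.
#' @param table adduct table (default [default_adducts()]).
#' @return precursor m/z in Th.
#' @export
adduct_precursor_mz <- function(mass, adduct = "[M+H]+",
                                table = default_adducts()) {
  if (is.character(adduct)) {
    i <- match(adduct, table$name)
    if (is.na(i)) stop(sprintf("unknown adduct '%s'", adduct))
    adduct <- table[i, ]
  }
  if (any(mass <= 0)) stop("neutral mass must be positive")
  (mass + adduct$mass_shift) / adduct$charge
}

#' Literature-compound coverage by observed precursor m/z
#'
#' For each species with at least `min_structures` unique literature
#' structures, counts the fraction of those structures for which some
#' adduct-shifted m/z lies within `tol_ppm` of some observed feature
#' precursor m/z from the same species -- an upper bound on how much of the
#' literature chemistry the MS dataset could contain.
#'
#' @param compounds data.frame with `structure_key`, `species`,
#'   `monoisotopic_mass` (one row per structure-species pair).
#' @param feature_mzs data.frame with `species`, `precursor_mz`.
#' @param adducts adduct table (default [default_adducts()]).
#' @param tol_ppm match tolerance in ppm (default 10).
#' @param min_structures minimum unique structures per species (default 20).
#' @return data.frame with `species`, `n_literature`, `n_matched`, `ratio`.
#' @export
coverage_ratio <- function(compounds, feature_mzs, adducts = default_adducts(),
                           tol_ppm = 10, min_structures = 20) {
  if (is.null(adducts) || nrow(adducts) == 0) stop("empty adduct table")
  cmp <- compounds[!is.na(compounds$monoisotopic_mass), , drop = FALSE]
  cmp <- cmp[!duplicated(cmp[c("structure_key", "species")]), , drop = FALSE]
  counts <- table(cmp$species)
  eligible <- names(counts)[counts >= min_structures]
  out <- lapply(eligible, function(sp) {
    masses <- cmp$monoisotopic_mass[cmp$species == sp]
    obs <- sort(feature_mzs$precursor_mz[feature_mzs$species == sp])
    matched <- if (length(obs) == 0) rep(FALSE, length(masses)) else {
      Reduce(`|`, lapply(seq_len(nrow(adducts)), function(ai) {
        mz <- adduct_precursor_mz(masses, adducts[ai, ])
        lo <- findInterval(mz * (1 - tol_ppm * 1e-6), obs)
        hi <- findInterval(mz * (1 + tol_ppm * 1e-6), obs)
        hi > lo
      }))
    }
    data.frame(species = sp, n_literature = length(masses),
               n_matched = sum(matched),
               ratio = sum(matched) / length(masses),
               stringsAsFactors = FALSE)
  })
  if (!length(out)) {
    return(data.frame(species = character(0), n_literature = integer(0),
                      n_matched = integer(0), ratio = numeric(0)))
  }
  do.call(rbind, out)
}

#' Fold increase in unique MS1 masses as samples accumulate
#'
#' Precursor masses are rounded to 2 decimals (round-half-even); `u[k]` is
#' the number of distinct rounded masses over the first `k` samples and the
#' reported fold is `u[k] / u[1]` -- how many times the metabolome coverage
#' of a single sample is multiplied by screening more samples.
#'
#' @param samples list (one element per sample, in acquisition order) of
#'   numeric precursor m/z vectors.
#' @return numeric vector of fold increases, same length as `samples`.
#' @export
ms1_fold_curve <- function(samples) {
  stopifnot(length(samples) >= 1)
  if (length(samples[[1]]) == 0) stop("first sample has no precursor masses")
  rounded <- lapply(samples, function(x) unique(round(x, 2)))
  u <- numeric(length(samples))
  seen <- character(0)
  for (k in seq_along(rounded)) {
    seen <- union(seen, sprintf("%.2f", rounded[[k]]))
    u[k] <- length(seen)
  }
  u / u[1]
}

# --- power-law fitting and projection ----------------------------------------

#' Fit a power law to a cumulative curve
#'
#' Fits \eqn{y = a x^b} by nonlinear least squares over the species index
#' `x = 1..N`, initialized from ordinary least squares on `log y ~ log x`.
#'
#' @param curve a `cumulative_curve`, or a numeric vector of y values.
#' @return object of class `power_law_model` with elements `a`, `b`,
#'   `fit_domain`, `rss`, `method`.
#' @export
fit_power_law <- function(curve) {
  y <- if (inherits(curve, "cumulative_curve")) curve$y else as.numeric(curve)
  if (length(y) < 3) stop("need at least 3 points to fit a power law")
  if (any(y <= 0)) stop("power-law fit requires positive y values")
  x <- seq_along(y)
  ols <- stats::lm(log(y) ~ log(x))
  start <- list(a = exp(unname(stats::coef(ols)[1])),
                b = unname(stats::coef(ols)[2]))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * x^b, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("power-law fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 fit_domain = c(1, length(y)),
                 rss = sum(stats::resid(fit)^2),
                 method = if (inherits(curve, "cumulative_curve"))
                   attr(curve, "method") else NA_character_),
            class = "power_law_model")
}

#' @export
print.power_law_model <- function(x, ...) {
  cat(sprintf("<power_law_model%s: y = %.4g * x^%.4g, fit on x in [%g, %g]>\n",
              if (!is.na(x$method)) paste0(" (", x$method, ")") else "",
              x$a, x$b, x$fit_domain[1], x$fit_domain[2]))
  invisible(x)
}

#' @export
predict.power_law_model <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) seq(object$fit_domain[1], object$fit_domain[2])
       else if (is.list(newdata)) newdata$x else as.numeric(newdata)
  object$a * x^object$b
}

#' Project richness to a larger number of species
#'
#' Evaluates the fitted accumulation law at `n_species`, e.g. the estimated
#' number of unique plant metabolites if 400,000 species were profiled.
#'
#' @param model a `power_law_model`.
#' @param n_species projection target (default 400000).
#' @return estimated unique-key count.
#' @export
project <- function(model, n_species = 400000) {
  stopifnot(inherits(model, "power_law_model"))
  model$a * n_species^model$b
}

#' Holdout validation of a power-law fit
#'
#' For each fraction `f`, fits on the first `(1 - f)` of the curve and
#' reports mean absolute percentage error and RMSE on the held-out suffix --
#' a check on how stable the extrapolation is as the newest species are
#' withheld.
#'
#' @param curve a `cumulative_curve` or numeric y vector.
#' @param holdout_fracs fractions of the tail to withhold
#'   (default `c(0.1, 0.2, 0.3)`).
#' @return data.frame with `frac`, `n_train`, `n_test`, `mape`, `rmse`,
#'   `a`, `b`.
#' @export
holdout_validate <- function(curve, holdout_fracs = c(0.1, 0.2, 0.3)) {
  y <- if (inherits(curve, "cumulative_curve")) curve$y else as.numeric(curve)
  n <- length(y)
  out <- lapply(holdout_fracs, function(f) {
    n_train <- floor((1 - f) * n)
    if (n_train < 3) stop(sprintf("training prefix too short at fraction %g", f))
    m <- fit_power_law(y[seq_len(n_train)])
    xt <- (n_train + 1):n
    pred <- m$a * xt^m$b
    obs <- y[xt]
    data.frame(frac = f, n_train = n_train, n_test = length(xt),
               mape = mean(abs(pred - obs) / obs) * 100,
               rmse = sqrt(mean((pred - obs)^2)), a = m$a, b = m$b)
  })
  do.call(rbind, out)
}

#' Order-stability of a saturation curve
#'
#' Re-draws species orderings with a seeded generator and summarizes the
#' spread of the cumulative curve at each position. The final value is
#' order-free (a set union), which the summary confirms.
#'
#' @param keys_by_species named list species -> key vector.
#' @param n_perm number of random orderings (default 100).
#' @param seed RNG seed.
#' @return list with `envelope` (data.frame `index`, `ymin`, `ymedian`,
#'   `ymax`), `final_values` (one per permutation), `n_perm`, `seed`.
#' @export
permutation_stability <- function(keys_by_species, n_perm = 100, seed = 1) {
  stopifnot(n_perm >= 1)
  sp <- names(keys_by_species)
  ys <- withr_seed(seed, {
    replicate(n_perm, saturation_curve(keys_by_species, sample(sp))$y)
  })
  ys <- matrix(ys, nrow = length(sp))
  list(envelope = data.frame(index = seq_along(sp),
                             ymin = apply(ys, 1, min),
                             ymedian = apply(ys, 1, stats::median),
                             ymax = apply(ys, 1, max)),
       final_values = ys[nrow(ys), ], n_perm = n_perm, seed = seed)
}

# evaluate an expression under a temporary RNG seed, restoring RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

#' Overlap between two key sets
#'
#' @param keys_a,keys_b character vectors (duplicates ignored).
#' @return list with `n_a`, `n_b`, `n_common`, `n_a_only`, `n_b_only`,
#'   `jaccard`.
#' @export
set_overlap <- function(keys_a, keys_b) {
  a <- unique(keys_a); b <- unique(keys_b)
  common <- length(intersect(a, b))
  uni <- length(union(a, b))
  if (uni == 0) {
    warning("both key sets are empty; Jaccard defined as 0", call. = FALSE)
    jac <- 0
  } else jac <- common / uni
  list(n_a = length(a), n_b = length(b), n_common = common,
       n_a_only = length(setdiff(a, b)), n_b_only = length(setdiff(b, a)),
       jaccard = jac)
}
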