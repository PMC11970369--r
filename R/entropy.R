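# Spectral-entropy similarity and connected-component clustering of MS2
# spectra. Pairwise comparison is restricted to precursor m/z blocks within
# a ppm window (all other pairs score zero by definition); edges at or above
# the similarity threshold define a graph whose connected components are the
# clusters, each component standing in for one chemical structure.

#' Shannon entropy of a spectrum
#'
#' Entropy of the intensity-normalized peak distribution,
#' \eqn{S = -\sum_i p_i \ln p_i} with \eqn{p_i = I_i / \sum_j I_j}, in nats.
#' A single-peak spectrum has entropy 0.
#'
#' @param peaks an `ms2_spectrum`, a two-column (`mz`, `intensity`) matrix,
#'   or a bare numeric vector of intensities.
#' @return entropy in nats (\eqn{\ge 0}).
#' @export
spectral_entropy <- function(peaks) {
  ints <- .peak_intensities(peaks)
  tot <- sum(ints)
  if (tot <= 0) stop("spectrum has zero total intensity")
  p <- ints[ints > 0] / tot
  -sum(p * log(p))
}

.peak_intensities <- function(peaks) {
  if (inherits(peaks, "ms2_spectrum")) peaks$peaks[, "intensity"]
  else if (is.matrix(peaks)) peaks[, 2]
  else as.numeric(peaks)
}

.peak_matrix <- function(x) {
  if (inherits(x, "ms2_spectrum")) x$peaks
  else matrix(as.numeric(x), ncol = 2, dimnames = list(NULL, c("mz", "intensity")))
}

# Intensity weighting for low-entropy spectra (the convention of the
# entropy-similarity metric): spectra with S < 3 are reweighted
# p <- p^(0.25 + 0.25 S) and renormalized, damping the dominance of single
# large peaks before comparison.
.entropy_weight <- function(p) {
  S <- -sum(p[p > 0] * log(p[p > 0]))
  if (S >= 3) return(p)
  w <- 0.25 + 0.25 * S
  p <- p^w
  p / sum(p)
}

# Greedy nearest match of peaks of b onto peaks of a within mz_tol;
# returns for each row of b the matched row of a or NA. Both inputs sorted.
.match_peaks <- function(mza, mzb, mz_tol) {
  used <- rep(FALSE, length(mza))
  match_of <- rep(NA_integer_, length(mzb))
  for (j in seq_along(mzb)) {
    d <- abs(mza - mzb[j])
    d[used] <- Inf
    i <- which.min(d)
    if (length(i) && d[i] <= mz_tol) {
      match_of[j] <- i
      used[i] <- TRUE
    }
  }
  match_of
}

#' Entropy similarity between two spectra
#'
#' Both spectra are intensity-normalized (and, when `weighted = TRUE`,
#' low-entropy spectra reweighted, see below). Peaks are matched greedily
#' within `mz_tol`; the merged spectrum puts intensity \eqn{(p_A + p_B)/2}
#' on the matched union of peaks. The score is
#' \deqn{1 - (2 S_{AB} - S_A - S_B) / \ln 4,}
#' which is 1 for identical spectra and exactly 0 for peak-disjoint ones.
#'
#' With `weighted = TRUE` (the metric's standard form) each spectrum with
#' entropy \eqn{S < 3} is first reweighted \eqn{p_i \leftarrow p_i^{0.25 +
#' 0.25 S}} and renormalized, which damps spectra dominated by few peaks.
#'
#' @param spec_a,spec_b `ms2_spectrum` objects or two-column peak matrices.
#' @param mz_tol peak-match tolerance in Th (default 0.02).
#' @param weighted apply the low-entropy reweighting (default `TRUE`).
#' @return similarity in `[0, 1]`.
#' @export
entropy_similarity <- function(spec_a, spec_b, mz_tol = 0.02, weighted = TRUE) {
  a <- .peak_matrix(spec_a); b <- .peak_matrix(spec_b)
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty spectrum")
  pa <- a[, 2] / sum(a[, 2]); pb <- b[, 2] / sum(b[, 2])
  if (weighted) { pa <- .entropy_weight(pa); pb <- .entropy_weight(pb) }
  Sa <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  Sb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  m <- .match_peaks(a[, 1], b[, 1], mz_tol)
  merged <- c((pa[m[!is.na(m)]] + pb[!is.na(m)]) / 2,   # matched pairs
              pa[setdiff(seq_along(pa), m)] / 2,         # a-only peaks
              pb[is.na(m)] / 2)                          # b-only peaks
  merged <- merged[merged > 0]
  Sab <- -sum(merged * log(merged))
  sim <- 1 - (2 * Sab - Sa - Sb) / log(4)
  min(max(sim, 0), 1)
}

#' Candidate spectrum pairs within a precursor ppm window
#'
#' All unordered pairs whose precursor m/z differ by at most `ppm_window`
#' parts per million of the pair mean; every other pair is defined to have
#' similarity zero and is never compared. Implemented as a sort-and-sweep
#' over precursor m/z.
#'
#' @param spectra list of `ms2_spectrum` objects.
#' @param ppm_window relative tolerance in ppm (default 10).
#' @return data.frame with integer columns `i`, `j` (indices into `spectra`,
#'   `i < j`) and `ppm`, the realized difference.
#' @export
candidate_pairs <- function(spectra, ppm_window = 10) {
  stopifnot(ppm_window > 0)
  mz <- vapply(spectra, function(s) s$precursor_mz, numeric(1))
  o <- order(mz)
  s_mz <- mz[o]
  n <- length(mz)
  acc <- vector("list", max(n - 1, 0))
  if (n >= 2) {
    half <- ppm_window / 2e6
    # with the ppm computed against the pair mean, partner m2 of m1 obeys
    # m2 <= m1 (1 + p/2e6) / (1 - p/2e6)
    hi <- findInterval(s_mz * (1 + half) / (1 - half), s_mz)
    for (a in seq_len(n - 1)) {
      if (hi[a] <= a) next
      b <- (a + 1):hi[a]
      ppm <- (s_mz[b] - s_mz[a]) / ((s_mz[a] + s_mz[b]) / 2) * 1e6
      ok <- ppm <= ppm_window  # guard against rounding at the bound
      if (!any(ok)) next
      ii <- pmin(o[a], o[b[ok]]); jj <- pmax(o[a], o[b[ok]])
      acc[[a]] <- data.frame(i = ii, j = jj, ppm = ppm[ok])
    }
  }
  acc <- acc[!vapply(acc, is.null, logical(1))]
  if (!length(acc)) return(data.frame(i = integer(0), j = integer(0),
                                      ppm = numeric(0)))
  do.call(rbind, acc)
}

#' Cluster MS2 spectra by entropy similarity
#'
#' Computes entropy similarity for every candidate pair (precursors within
#' `ppm_window`), keeps edges with similarity at or above `threshold`, and
#' returns the connected components of the resulting graph as clusters.
#' Spectra with no retained edge are singleton clusters. Cluster ids are
#' dense from 0 and assigned in ascending order of each cluster's minimum
#' feature id, so the labelling is invariant to input order.
#'
#' @param spectra list of `ms2_spectrum` objects with unique feature ids.
#' @param ppm_window precursor blocking window in ppm (default 10).
#' @param mz_tol peak-match tolerance in Th (default 0.02).
#' @param threshold similarity threshold in `[0, 1]`; an edge at exactly the
#'   threshold is kept (default 0.7).
#' @param weighted passed to [entropy_similarity()].
#' @return object of class `cluster_assignment`: list with `assignments`
#'   (data.frame `feature_id`, `cluster_id`), `n_clusters`, `threshold`,
#'   `ppm_window`, and `edges` (the thresholded similarity edges).
#' @export
build_clusters <- function(spectra, ppm_window = 10, mz_tol = 0.02,
                           threshold = 0.7, weighted = TRUE) {
  stopifnot(threshold >= 0, threshold <= 1)
  ids <- vapply(spectra, function(s) s$feature_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate feature ids in spectra")
  pairs <- candidate_pairs(spectra, ppm_window)
  sims <- if (nrow(pairs)) {
    vapply(seq_len(nrow(pairs)), function(r) {
      entropy_similarity(spectra[[pairs$i[r]]], spectra[[pairs$j[r]]],
                         mz_tol = mz_tol, weighted = weighted)
    }, numeric(1))
  } else numeric(0)
  keep <- sims >= threshold
  edges <- data.frame(feature_a = ids[pairs$i[keep]],
                      feature_b = ids[pairs$j[keep]],
                      similarity = sims[keep], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership[ids]
  # relabel: dense ids from 0, ordered by each cluster's smallest feature id
  first <- tapply(ids, comp, min)
  relabel <- stats::setNames(seq_along(first) - 1L,
                             names(first)[order(first)])
  cluster_id <- unname(relabel[as.character(comp)])
  structure(list(assignments = data.frame(feature_id = ids,
                                          cluster_id = cluster_id,
                                          stringsAsFactors = FALSE),
                 n_clusters = length(first), threshold = threshold,
                 ppm_window = ppm_window, edges = edges),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment: %d spectra, %d clusters (threshold %.2f, %g ppm)>\n",
              nrow(x$assignments), x$n_clusters, x$threshold, x$ppm_window))
  invisible(x)
}

#' Cluster counts across a sweep of similarity thresholds
#'
#' @param spectra list of `ms2_spectrum` objects.
#' @param thresholds numeric vector (default `c(0.5, 0.6, 0.7, 0.8, 0.9)`).
#' @param ... passed to [build_clusters()].
#' @return data.frame with `threshold` and `n_clusters`.
#' @export
threshold_sweep <- function(spectra, thresholds = c(0.5, 0.6, 0.7, 0.8, 0.9),
                            ...) {
  data.frame(threshold = thresholds,
             n_clusters = vapply(thresholds, function(t) {
               build_clusters(spectra, threshold = t, ...)$n_clusters
             }, numeric(1)))
}
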