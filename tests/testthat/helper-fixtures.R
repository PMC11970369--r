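# Fixture builders shared across tests. Everything is generated in code
# under fixed seeds; no binary fixtures.

# a random but reproducible MS2 spectrum
random_spectrum <- function(feature_id, precursor_mz = NULL, n_peaks = 10,
                            species = "SP0001", sample_id = "S1") {
  if (is.null(precursor_mz)) precursor_mz <- runif(1, 100, 1000)
  mz <- sort(runif(n_peaks, 50, precursor_mz - 1))
  ints <- rexp(n_peaks)
  ms2_spectrum(feature_id, precursor_mz, cbind(mz, ints),
               sample_id = sample_id, species = species)
}

# independent flood-fill over an explicit edge list: the naive clustering
# oracle (BFS over an adjacency list, no igraph)
flood_fill_components <- function(ids, edges_a, edges_b) {
  comp <- setNames(rep(NA_integer_, length(ids)), ids)
  adj <- setNames(vector("list", length(ids)), ids)
  for (k in seq_along(edges_a)) {
    adj[[edges_a[k]]] <- c(adj[[edges_a[k]]], edges_b[k])
    adj[[edges_b[k]]] <- c(adj[[edges_b[k]]], edges_a[k])
  }
  cl <- 0L
  for (id in ids) {
    if (!is.na(comp[id])) next
    queue <- id
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[cur])) next
      comp[cur] <- cl
      queue <- c(queue, adj[[cur]])
    }
    cl <- cl + 1L
  }
  comp
}

# check two partitions are identical up to label renaming
same_partition <- function(p1, p2) {
  stopifnot(length(p1) == length(p2))
  key1 <- split(names(p1), p1)
  key2 <- split(names(p2), p2)
  setequal(lapply(key1, sort), lapply(key2, sort))
}

# a small synthetic species -> key-set incidence
random_incidence <- function(n_species, pool, mean_keys = 10) {
  keys <- lapply(seq_len(n_species), function(i) {
    sample(pool, min(length(pool), rpois(1, mean_keys) + 1))
  })
  names(keys) <- sprintf("SP%04d", seq_len(n_species))
  keys
}
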