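# Small in-code fixtures shared across test files.

# Profiles built directly from named k-mer sets (character vectors).
toy_profiles <- function(sets, k = 5L, n_pairs = NULL) {
  if (is.null(n_pairs)) n_pairs <- rep(20L, length(sets))
  tbl <- tibble::tibble(
    barcode = names(sets),
    n_pairs = n_pairs,
    n_kmers = lengths(sets),
    n_unique = lengths(sets),
    unique_fraction = 1,
    kmers = lapply(sets, function(s) sort(encode_kmers(s)))
  )
  structure(tbl,
    class = c("lfr_profiles", class(tibble::tibble())),
    k = k, freq_lo = 1L, freq_hi = .Machine$integer.max
  )
}

# Random k-mer sets over a small alphabet of k-mers, so overlaps occur.
random_profiles <- function(n_barcodes, pool_size = 400L, set_size = 60L, k = 6L) {
  pool <- unique(canonicalize(random_kmers(pool_size, k)))
  sets <- lapply(seq_len(n_barcodes), function(i) {
    sample(pool, min(set_size, length(pool)))
  })
  names(sets) <- sprintf("B%03d", seq_len(n_barcodes))
  toy_profiles(sets, k = k)
}

random_kmers <- function(n, k) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
  }, character(1))
}

# O(n^2) oracle: exact pairwise intersection sizes, pairs >= floor.
brute_adjacency <- function(profiles, store_floor) {
  n <- nrow(profiles)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      w <- length(intersect(profiles$kmers[[i]], profiles$kmers[[j]]))
      if (w >= store_floor) {
        out[[length(out) + 1L]] <- tibble::tibble(
          barcode1 = min(profiles$barcode[i], profiles$barcode[j]),
          barcode2 = max(profiles$barcode[i], profiles$barcode[j]),
          weight = w
        )
      }
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), barcode1, barcode2)
}

# Edge tibble for clique-structured graphs: `sizes` cliques with uniform
# intra-clique weight; optional single bridge edge between cliques 1 and 2.
clique_graph <- function(sizes, intra = 10L, bridge = NULL) {
  stopifnot(length(sizes) >= 1)
  nodes <- split(
    sprintf("N%03d", seq_len(sum(sizes))),
    rep(seq_along(sizes), sizes)
  )
  edges <- list()
  for (cl in nodes) {
    if (length(cl) < 2) next
    pr <- t(utils::combn(cl, 2))
    edges[[length(edges) + 1L]] <- tibble::tibble(
      barcode1 = pr[, 1], barcode2 = pr[, 2], weight = intra
    )
  }
  g <- dplyr::bind_rows(edges)
  if (!is.null(bridge)) {
    g <- dplyr::bind_rows(g, tibble::tibble(
      barcode1 = nodes[[1]][1], barcode2 = nodes[[2]][1], weight = bridge
    ))
  }
  attr(g, "cliques") <- lapply(nodes, sort)
  g
}

# A quick simulated dataset for unit tests (seconds, ~80 barcodes).
small_sim <- function(seed = 7L, ...) {
  simulate_linked_reads(sim_config(
    genome_length = 2e5, fragment_coverage = 10, seed = seed, ...
  ))
}

# Barcode k-mer profiles + graph for a simulated dataset at the desk
# analysis parameters (rescaled thresholds for small genomes via ...).
sim_profiles_graph <- function(sim, n_min = 800L, store_floor = 10L) {
  pp <- preset_params("desk", n_min = n_min, store_floor = store_floor)
  reads <- filter_small_barcodes(sim$reads, pp$min_pairs)
  freq <- count_kmers(c(reads$seq1, reads$seq2), k = pp$k, decode = FALSE)
  uniq <- select_unique_kmers(freq, pp$freq_lo, pp$freq_hi)
  profiles <- build_barcode_profiles(reads, uniq)
  graph <- barcode_adjacency(profiles, store_floor = pp$store_floor)
  list(params = pp, profiles = profiles, graph = graph)
}
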