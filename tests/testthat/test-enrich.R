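test_that("seed candidates satisfy both thresholds, ordered by signal", {
  p <- toy_profiles(list(b1 = "AAAAC", b2 = "AAACC", b3 = "AACCC"))
  p$n_unique <- c(4000L, 2000L, 5000L)
  p$unique_fraction <- c(0.5, 0.9, 0.2)
  cand <- select_seed_candidates(p, n_min = 3000, r_min = 0.3)
  expect_equal(cand$barcode, "b1") # b2 fails n_min, b3 fails r_min
  all_c <- select_seed_candidates(p, n_min = 0, r_min = 0)
  expect_equal(all_c$barcode, c("b3", "b1", "b2")) # by n_unique descending
  expect_equal(select_seed_candidates(p, 0, 0, exclude = "b3")$barcode, c("b1", "b2"))
  # recheck oracle on simulated profiles
  sim <- small_sim()
  pg <- sim_profiles_graph(sim)
  cand <- select_seed_candidates(pg$profiles, 800, 0.3)
  i <- match(cand$barcode, pg$profiles$barcode)
  expect_true(all(pg$profiles$n_unique[i] > 800))
  expect_true(all(pg$profiles$unique_fraction[i] >= 0.3))
  expect_true(all(diff(cand$n_unique) <= 0))
})

test_that("feature selection counts member support with a strict threshold", {
  sets <- lapply(1:5, function(i) c("AAAAC", if (i <= 4) "AAACC", if (i <= 2) "AACCC"))
  names(sets) <- sprintf("m%d", 1:5)
  p <- toy_profiles(sets)
  f3 <- select_feature_kmers(p, names(sets), f_min = 3)
  expect_setequal(f3$code, encode_kmers(c("AAAAC", "AAACC"))) # support 5 and 4
  expect_equal(f3$support[match(encode_kmers("AAACC"), f3$code)], 4L)
  f0 <- select_feature_kmers(p, names(sets), f_min = 0)
  expect_setequal(f0$code, encode_kmers(c("AAAAC", "AAACC", "AACCC"))) # plain union
  expect_warning(select_feature_kmers(p, names(sets), f_min = 10), "stall")
})

test_that("capture is strict and matches a full scan", {
  p <- toy_profiles(list(
    b1 = c("AAAAC", "AAACC", "AACCC"),
    b2 = c("AAAAC", "AAACC"),
    b3 = c("AAAAC"),
    b4 = c("GGGGT")
  ))
  F3 <- encode_kmers(c("AAAAC", "AAACC", "AACCC"))
  expect_equal(capture_targets(p, F3, g = 1), c("b1", "b2")) # b3 shares 1, not > 1
  expect_equal(capture_targets(p, F3, g = 3), character(0)) # g >= |F|
  expect_equal(capture_targets(p, F3, g = 1, exclude = "b1"), "b2")
  # optional-set restriction loses nothing when candidates cover the hits
  set.seed(21)
  pr <- random_profiles(50)
  g <- barcode_adjacency(pr, store_floor = 1)
  feats <- pr$kmers[[1]]
  full <- capture_targets(pr, feats, g = 5, exclude = pr$barcode[1])
  # any barcode sharing > 5 feature k-mers is a floor-1 neighbor of the
  # seed, so restricting to the optional set loses nothing here
  restricted <- capture_targets(pr, feats, g = 5, exclude = pr$barcode[1],
    candidates = lfrclust:::graph_neighbors(g, pr$barcode[1])
  )
  expect_identical(full, restricted)
  # brute-force oracle
  brute <- sort(setdiff(
    pr$barcode[vapply(pr$kmers, function(s) length(intersect(s, feats)), integer(1)) > 5],
    pr$barcode[1]
  ))
  expect_identical(full, brute)
})

test_that("an isolated seed yields a singleton cluster", {
  p <- toy_profiles(list(s = c("AAAAC", "AAACC"), b = c("GGGGT")))
  g <- tibble::tibble(barcode1 = character(0), barcode2 = character(0), weight = integer(0))
  cl <- enrich_cluster(p, g, "s", g = 1, f_min = 0, k_iters = 3)
  expect_equal(cl$members$barcode, "s")
  expect_equal(cl$members$iteration, 0L)
})

test_that("k_iters = 0 reduces to direct capture from the graph", {
  sim <- small_sim()
  pg <- sim_profiles_graph(sim)
  seed <- select_seed_candidates(pg$profiles, 800, 0.3)$barcode[1]
  cl0 <- enrich_cluster(pg$profiles, pg$graph, seed, g = pg$params$g, k_iters = 0)
  direct <- lfrclust:::seed_neighbors(pg$graph, seed, pg$params$g)
  expect_setequal(cl0$members$barcode, c(seed, direct))
  expect_true(all(cl0$members$iteration <= 1))
})

test_that("members and features grow monotonically and deterministically", {
  sim <- small_sim()
  pg <- sim_profiles_graph(sim)
  seeds <- head(select_seed_candidates(pg$profiles, 800, 0.3)$barcode, 3)
  for (seed in seeds) {
    cl <- enrich_cluster(pg$profiles, pg$graph, seed, g = pg$params$g, k_iters = 3)
    m <- cl$members
    # provenance iterations imply nested member sets across rounds
    for (i in 0:2) {
      expect_true(all(m$barcode[m$iteration <= i] %in% m$barcode[m$iteration <= i + 1]))
    }
    expect_false(any(duplicated(m[c("barcode", "subcluster")])))
    expect_true(all(cl$features$iteration_added >= 1))
    # determinism: identical inputs give identical clusters
    cl2 <- enrich_cluster(pg$profiles, pg$graph, seed, g = pg$params$g, k_iters = 3)
    expect_identical(tidy(cl), tidy(cl2))
  }
})

test_that("every captured member shares > g features with the prior round's set", {
  sim <- small_sim()
  pg <- sim_profiles_graph(sim)
  seed <- select_seed_candidates(pg$profiles, 800, 0.3)$barcode[1]
  gthr <- pg$params$g
  cl <- enrich_cluster(pg$profiles, pg$graph, seed, g = gthr, f_min = 3, k_iters = 2)
  m <- dplyr::filter(cl$members, subcluster == 1)
  f <- dplyr::filter(cl$features, subcluster == 1)
  for (it in 2:max(m$iteration)) {
    new_members <- m$barcode[m$iteration == it]
    f_prior <- f$code[f$iteration_added < it]
    for (b in new_members) {
      kb <- pg$profiles$kmers[[match(b, pg$profiles$barcode)]]
      expect_gt(length(intersect(kb, f_prior)), gthr)
    }
  }
})

test_that("multi-seed runs never reuse a consumed barcode as a seed", {
  sim <- small_sim()
  pg <- sim_profiles_graph(sim)
  res <- cluster_barcodes(pg$profiles, pg$graph,
    n_min = 800, r_min = 0.3, g = pg$params$g, k_iters = 2, use_mcl = TRUE
  )
  expect_gt(length(res$clusters), 1)
  seen <- character(0)
  for (cl in res$clusters) {
    expect_false(cl$seed %in% seen)
    seen <- union(seen, cl$members$barcode)
  }
  manifest <- tidy(res)
  expect_true(all(c("cluster_id", "seed", "barcode", "subcluster", "capture_iteration")
    %in% names(manifest)))
})
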