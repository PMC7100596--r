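toy_truth <- function() {
  # seed S: one valid fragment at [10000, 50000) with 40 pairs
  # in-region barcodes: T01..T09 (6+ pairs each), plus weak W (5 pairs) and
  # distant D01..D02
  tibble::tibble(
    barcode = c("S", sprintf("T%02d", 1:9), "W", "D01", "D02"),
    chrom = "c1",
    start = c(10000, seq(12000, 44000, by = 4000), 20000, 900000, 950000),
    end = c(50000, seq(12000, 44000, by = 4000) + 8000, 26000, 920000, 970000),
    n_pairs = c(40L, rep(10L, 9), 5L, 50L, 50L)
  )
}

test_that("truth tables load with validation and row-level errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(toy_truth(), path)
  tt <- read_truth(path)
  expect_s3_class(tt, "lfr_truth")
  expect_equal(nrow(tt), 13)
  bad <- toy_truth()
  bad$end[3] <- bad$start[3] # empty interval
  readr::write_tsv(bad, path)
  expect_error(read_truth(path), "row\\(s\\) 3")
})

test_that("seed-fragment validity is strict on both span and support", {
  fr <- tibble::tibble(
    start = c(0, 0, 0), end = c(600, 600, 400), n_pairs = c(31L, 30L, 100L)
  )
  expect_equal(valid_seed_fragment(fr), c(TRUE, FALSE, FALSE))
})

test_that("region membership requires overlap and > 5 pairs", {
  tt <- toy_truth()
  region <- list(chrom = "c1", start = 10000, end = 50000)
  inr <- barcodes_in_region(tt, region)
  expect_true(all(sprintf("T%02d", 1:9) %in% inr))
  expect_false("W" %in% inr) # overlapping but only 5 pairs
  expect_false("D01" %in% inr) # 50 pairs but outside
  # fully inside with 6 pairs counts
  tt2 <- dplyr::bind_rows(tt, tibble::tibble(
    barcode = "X", chrom = "c1", start = 20000, end = 30000, n_pairs = 6L
  ))
  expect_true("X" %in% barcodes_in_region(tt2, region))
})

test_that("target regions extend the seed span and drop invalid seeds", {
  tt <- toy_truth()
  reg <- target_regions(tt, "S", ext = 5000)
  expect_equal(reg$start, 5000)
  expect_equal(reg$end, 55000)
  expect_equal(nrow(target_regions(tt, "W", ext = 5000)), 0) # no valid fragment
  # extension clips at zero
  reg0 <- target_regions(tt, "S", ext = 50000)
  expect_equal(reg0$start, 0)
})

test_that("precision and recall follow the TP/FP/FN formulas exactly", {
  tt <- toy_truth()
  # members: seed + 7 in-region + 2 distal -> TP 8, FP 2
  members <- c("S", sprintf("T%02d", 1:7), "D01", "D02")
  pr <- cluster_precision_recall(members, "S", tt, ext = 0)
  expect_equal(pr$tp, 8)
  expect_equal(pr$fp, 2)
  expect_equal(pr$fn, 2) # T08, T09 missed
  expect_equal(pr$precision, 0.8)
  expect_equal(pr$recall, 0.8)
  # perfect cluster: exactly the in-region set
  perfect <- barcodes_in_region(tt, list(chrom = "c1", start = 10000, end = 50000))
  pr2 <- cluster_precision_recall(perfect, "S", tt, ext = 0)
  expect_equal(pr2$precision, 1)
  expect_equal(pr2$recall, 1)
})

test_that("adding a true in-region member never lowers precision or recall", {
  tt <- toy_truth()
  members <- c("S", sprintf("T%02d", 1:4), "D01")
  base <- cluster_precision_recall(members, "S", tt, ext = 0)
  grown <- cluster_precision_recall(c(members, "T05"), "S", tt, ext = 0)
  expect_gte(grown$precision, base$precision)
  expect_gte(grown$recall, base$recall)
})

test_that("P/R on simulated clusters matches an independent recount", {
  sim <- small_sim()
  pg <- sim_profiles_graph(sim)
  seeds <- head(intersect(
    select_seed_candidates(pg$profiles, 800, 0.3)$barcode,
    unique(sim$truth$barcode[valid_seed_fragment(sim$truth)])
  ), 5)
  cls <- enrich_seeds(pg$profiles, pg$graph, seeds, g = pg$params$g, k_iters = 2)
  for (cl in cls$clusters) {
    members <- unique(cl$members$barcode)
    pr <- cluster_precision_recall(members, cl$seed, sim$truth, ext = 3e4)
    # brute recount with plain loops
    for (ri in seq_len(nrow(pr))) {
      inr <- character(0)
      for (b in unique(sim$truth$barcode)) {
        fr <- sim$truth[sim$truth$barcode == b, ]
        hit <- any(fr$chrom == pr$chrom[ri] & fr$start < pr$end[ri] &
          fr$end > pr$start[ri] & fr$n_pairs > 5)
        if (hit) inr <- c(inr, b)
      }
      tp <- length(intersect(members, inr))
      expect_equal(pr$tp[ri], tp)
      expect_equal(pr$fp[ri], length(members) - tp)
      expect_equal(pr$fn[ri], length(setdiff(inr, members)))
    }
  }
})

test_that("pr_sweep covers the parameter grid and matches single evaluations", {
  sim <- small_sim()
  pg <- sim_profiles_graph(sim)
  seed <- intersect(
    select_seed_candidates(pg$profiles, 800, 0.3)$barcode,
    unique(sim$truth$barcode[valid_seed_fragment(sim$truth)])
  )[1]
  cl <- enrich_seeds(pg$profiles, pg$graph, seed, g = pg$params$g, k_iters = 2)
  sweep <- pr_sweep(cl, sim$truth, ext = c(2e4, 4e4), k_iters = c(0, 2))
  expect_equal(nrow(sweep), 4) # |grid|
  one <- pr_sweep(cl, sim$truth, ext = 2e4)
  direct <- cluster_precision_recall(
    unique(cl$clusters[[1]]$members$barcode), seed, sim$truth, ext = 2e4
  )
  expect_equal(one$mean_precision, mean(direct$precision))
  expect_equal(one$mean_recall, mean(direct$recall))
  expect_true(all(sweep$mean_precision >= 0 & sweep$mean_precision <= 1, na.rm = TRUE))
  expect_true(all(sweep$mean_recall >= 0 & sweep$mean_recall <= 1, na.rm = TRUE))
})
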