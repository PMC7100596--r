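# Precision/recall evaluation of clusters against a truth table of barcode
# fragment positions (alignment-derived for real data, exact for simulated
# data). All coordinates are 0-based half-open.
#
# Protocol: a seed's target region is the union extent of its valid
# fragments per chromosome (span > 500 bp and > 30 read pairs), extended by
# `ext` bases on both sides. A barcode belongs to the region when it has a
# fragment overlapping the region with more than 5 read pairs. Precision =
# TP/(TP+FP) over cluster members, recall = TP/(TP+FN) over in-region
# barcodes; seeds with fragments on several chromosomes are scored per
# region and macro-averaged.

truth_cols <- c("barcode", "chrom", "start", "end", "n_pairs")

validate_truth <- function(tbl, src = "truth table") {
  missing <- setdiff(truth_cols, names(tbl))
  if (length(missing) > 0L) {
    stop(src, " lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(!(tbl$start < tbl$end) | tbl$n_pairs < 1)
  if (length(bad) > 0L) {
    stop(sprintf(
      "%s: invalid fragment row(s) %s (need start < end and n_pairs >= 1)",
      src, paste(head(bad, 5L), collapse = ", ")
    ))
  }
  structure(tibble::as_tibble(as.data.frame(tbl))[truth_cols],
    class = c("lfr_truth", class(tibble::tibble()))
  )
}

#' Read a barcode-fragment truth table
#'
#' A TSV with header columns `barcode`, `chrom`, `start`, `end`, `n_pairs`
#' (0-based half-open intervals), one row per fragment of each barcode.
#' For real data, such a table is produced externally from a bwa alignment
#' (e.g. grouping read positions by barcode); the simulator writes it
#' directly.
#'
#' @param path TSV path.
#' @return A validated tibble classed `lfr_truth`.
#' @export
read_truth <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    barcode = readr::col_character(), chrom = readr::col_character(),
    start = readr::col_double(), end = readr::col_double(),
    n_pairs = readr::col_integer()
  ))
  validate_truth(tbl, src = path)
}

#' Is a fragment valid as a seed-region anchor?
#'
#' A fragment anchors a target region only when its read support is solid:
#' span strictly greater than 500 bp and strictly more than 30 read pairs.
#'
#' @param truth A truth tibble (or any tibble with `start`, `end`,
#'   `n_pairs`).
#' @return Logical vector, one element per row.
#' @export
valid_seed_fragment <- function(truth) {
  (truth$end - truth$start) > 500 & truth$n_pairs > 30
}

#' Target regions of a seed barcode
#'
#' One region per chromosome carrying at least one valid fragment of the
#' seed: the union extent of those fragments extended by `ext` bases on
#' both sides (clipped at 0).
#'
#' @param truth A truth tibble.
#' @param seed Seed barcode id.
#' @param ext Extension in bases on each side (default 200000; the
#'   evaluation protocol sweeps 80000--400000).
#' @return A tibble `chrom`, `start`, `end`; zero rows when the seed has no
#'   valid fragment.
#' @export
target_regions <- function(truth, seed, ext = 200000) {
  fr <- dplyr::filter(truth, .data$barcode == seed)
  fr <- fr[valid_seed_fragment(fr), , drop = FALSE]
  if (nrow(fr) == 0L) {
    return(tibble::tibble(chrom = character(0), start = numeric(0), end = numeric(0)))
  }
  fr |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      start = pmax(0, min(.data$start) - ext),
      end = max(.data$end) + ext,
      .groups = "drop"
    )
}

#' Barcodes belonging to a target region
#'
#' A barcode belongs to a region when it has a fragment overlapping the
#' region with strictly more than 5 read pairs (weaker barcodes cannot be
#' expected to aggregate).
#'
#' @param truth A truth tibble.
#' @param region One-row tibble or list with `chrom`, `start`, `end`.
#' @return Sorted character vector of in-region barcode ids.
#' @export
barcodes_in_region <- function(truth, region) {
  hit <- truth$chrom == region$chrom &
    truth$start < region$end & truth$end > region$start &
    truth$n_pairs > 5
  sort(unique(truth$barcode[hit]))
}

#' Precision and recall of one cluster
#'
#' Scores a cluster's member set against each target region of its seed.
#' TP = members in the region, FP = members outside it, FN = in-region
#' barcodes missed. Undefined ratios (empty denominator) are `NA`.
#'
#' @param members Character vector of member barcode ids (seed included).
#' @param seed Seed barcode id.
#' @param truth A truth tibble.
#' @param ext Region extension, see [target_regions()].
#' @return A tibble with one row per region: `seed`, `chrom`, `start`,
#'   `end`, `tp`, `fp`, `fn`, `precision`, `recall`; zero rows when the
#'   seed has no valid fragment.
#' @export
cluster_precision_recall <- function(members, seed, truth, ext = 200000) {
  regions <- target_regions(truth, seed, ext)
  purrr::pmap_dfr(regions, function(chrom, start, end) {
    region <- list(chrom = chrom, start = start, end = end)
    in_region <- barcodes_in_region(truth, region)
    tp <- sum(members %in% in_region)
    fp <- length(members) - tp
    fn <- length(setdiff(in_region, members))
    tibble::tibble(
      seed = seed, chrom = chrom, start = start, end = end,
      tp = tp, fp = fp, fn = fn,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_
    )
  })
}

cluster_members_at <- function(cluster, k_iters = NULL) {
  m <- cluster$members
  if (!is.null(k_iters)) m <- dplyr::filter(m, .data$iteration <= k_iters + 1L)
  unique(m$barcode)
}

#' Sweep precision/recall over evaluation parameters
#'
#' Evaluates every cluster at each combination of region extension and
#' (optionally) iteration cutoff, macro-averaging per seed and then across
#' seeds. Because member provenance records the capture iteration, the
#' cutoff re-reads a single `k_iters = K` run at any smaller number of
#' rounds (0 = direct capture only) without re-clustering.
#'
#' @param clusters An `lfr_clusters` object or list of `lfr_cluster`.
#' @param truth A truth tibble.
#' @param ext Numeric vector of region extensions to sweep.
#' @param k_iters Integer vector of iteration cutoffs, or `NULL` for the
#'   full member sets.
#' @return A tibble classed `lfr_pr`: `ext`, `k_iters` (`NA` = full),
#'   `n_seeds` (seeds with at least one valid region), `mean_precision`,
#'   `mean_recall`, `mean_fp_rate`.
#' @export
pr_sweep <- function(clusters, truth, ext = 200000, k_iters = NULL) {
  if (inherits(clusters, "lfr_clusters")) clusters <- clusters$clusters
  grid <- tidyr::expand_grid(
    ext = ext,
    k_iters = if (is.null(k_iters)) NA_integer_ else as.integer(k_iters)
  )
  out <- purrr::pmap_dfr(grid, function(ext, k_iters) {
    per_seed <- purrr::map_dfr(clusters, function(cl) {
      members <- cluster_members_at(cl, if (is.na(k_iters)) NULL else k_iters)
      pr <- cluster_precision_recall(members, cl$seed, truth, ext)
      if (nrow(pr) == 0L) return(NULL)
      tibble::tibble(
        seed = cl$seed,
        precision = mean(pr$precision, na.rm = TRUE),
        recall = mean(pr$recall, na.rm = TRUE)
      )
    })
    tibble::tibble(
      ext = ext, k_iters = k_iters, n_seeds = nrow(per_seed),
      mean_precision = mean(per_seed$precision, na.rm = TRUE),
      mean_recall = mean(per_seed$recall, na.rm = TRUE),
      mean_fp_rate = 1 - mean(per_seed$precision, na.rm = TRUE)
    )
  })
  structure(out, class = c("lfr_pr", class(tibble::tibble())))
}
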