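# Depth-based removal of non-target reads from a finished cluster.
#
# Within a cluster, reads from the target region pile up: their k-mers are
# carried by many member barcodes and reach the cluster's modal depth.
# A member's non-target fragments are scattered over the genome, so their
# reads' k-mers occur only once or twice within the cluster. Scoring each
# read pair by the mean within-cluster depth of its k-mers separates the
# two populations.

new_depth_table <- function(tbl, k) {
  structure(tbl,
    class = c("lfr_depth", class(tibble::tibble())),
    k = k
  )
}

#' Count k-mer depth within a cluster's reads
#'
#' Canonical k-mer counts computed exclusively from the cluster members'
#' reads (both mates; N-containing windows skipped).
#'
#' @param reads Reads tibble restricted to the cluster's members.
#' @param k K-mer length (default 17).
#' @return A tibble `code`, `count`, classed `lfr_depth`.
#' @export
cluster_kmer_depth <- function(reads, k = 17L) {
  stopifnot(nrow(reads) >= 1L)
  dt <- kmer_window_codes(c(reads$seq1, reads$seq2), k)
  cnt <- dt[, .N, by = code]
  data.table::setorder(cnt, code)
  new_depth_table(tibble::tibble(code = cnt$code, count = cnt$N), k = as.integer(k))
}

#' Score read pairs by mean within-cluster k-mer depth
#'
#' Each pair's score is the arithmetic mean, over all valid k-mer windows of
#' both mates, of the depth-table count of the window's canonical k-mer
#' (k-mers absent from the table count 0). Pairs with no valid window score
#' 0.
#'
#' @param reads Reads tibble (the cluster's reads, or any reads to score
#'   against the cluster).
#' @param depth An `lfr_depth` table from [cluster_kmer_depth()].
#' @return `reads` with a `score` column appended.
#' @export
score_read_pairs <- function(reads, depth) {
  k <- attr(depth, "k")
  n <- nrow(reads)
  if (n == 0L) return(dplyr::mutate(reads, score = numeric(0)))
  dt <- kmer_window_codes(c(reads$seq1, reads$seq2), k)
  dt[, pair := (read - 1L) %% n + 1L]
  dtab <- data.table::data.table(code = depth$code, d = depth$count)
  dt <- dtab[dt, on = "code"]
  dt[is.na(d), d := 0L]
  sc <- dt[, .(score = mean(d)), by = pair]
  score <- numeric(n) # pairs with zero valid windows keep score 0
  score[sc$pair] <- sc$score
  dplyr::mutate(reads, score = score)
}

#' Filter low-depth read pairs from a cluster
#'
#' Keeps pairs whose mean within-cluster k-mer depth is at least
#' `min_mean_depth`; both mates are kept or removed together. The default
#' threshold is data-driven: one third of the mean pair score over the
#' cluster. A pair's own k-mers count themselves, so scores are bounded
#' below by ~1; a third of the mean lands in the valley between the
#' contaminant mode (singleton depth plus background) and the target mode
#' (the cluster's modal depth), whereas smaller fractions can fall below
#' the score floor and degenerate to a no-op on moderate-depth clusters.
#'
#' @param reads The cluster's reads tibble.
#' @param depth An `lfr_depth` table; computed from `reads` when `NULL`.
#' @param min_mean_depth Score threshold; `NULL` (default) uses the
#'   auto-threshold above.
#' @param k K-mer length used when `depth` must be computed.
#' @return `reads` with `score` and `kept` (logical) columns; attributes
#'   `min_mean_depth` (the threshold applied) and `k`.
#' @export
filter_cluster_reads <- function(reads, depth = NULL, min_mean_depth = NULL, k = 17L) {
  if (is.null(depth)) depth <- cluster_kmer_depth(reads, k)
  scored <- score_read_pairs(reads, depth)
  if (is.null(min_mean_depth)) min_mean_depth <- mean(scored$score) / 3
  stopifnot(min_mean_depth >= 0)
  out <- dplyr::mutate(scored, kept = .data$score >= min_mean_depth)
  structure(out,
    class = class(scored),
    min_mean_depth = min_mean_depth, k = attr(depth, "k")
  )
}
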