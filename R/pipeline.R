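# End-to-end pipeline: unique k-mers -> profiles -> adjacency -> clusters
# (-> evaluation when truth is supplied), with analysis-parameter presets.

#' Analysis parameter presets
#'
#' Bundles the tunable parameters of every stage. `"stlfr"` and `"tenx"`
#' carry the published settings for 56x stLFR and 50x 10X human data;
#' `"desk"` rescales the depth-dependent thresholds to the simulator's
#' default ~6x global coverage (unique window ~0.4--5x the modal k-mer
#' depth of ~5; seed and capture thresholds scaled by the same coverage
#' ratio).
#'
#' @param preset `"stlfr"`, `"tenx"` or `"desk"`.
#' @param ... Field overrides.
#' @return Named list: `k`, `freq_lo`, `freq_hi`, `min_pairs`,
#'   `store_floor`, `n_min`, `r_min`, `g`, `f_min`, `k_iters`, `use_mcl`,
#'   `use_freq_model`, `s`, `r`, `mcl_iters`, `ext`.
#' @export
preset_params <- function(preset = c("stlfr", "tenx", "desk"), ...) {
  preset <- match.arg(preset)
  p <- switch(preset,
    stlfr = list(
      k = 17L, freq_lo = 20L, freq_hi = 80L, min_pairs = 10L, store_floor = 10L,
      n_min = 3000L, r_min = 0.3, g = 200L, f_min = 3L, k_iters = 3L
    ),
    tenx = list(
      k = 17L, freq_lo = 20L, freq_hi = 60L, min_pairs = 0L, store_floor = 10L,
      n_min = 20000L, r_min = 0.3, g = 130L, f_min = 3L, k_iters = 2L
    ),
    desk = list(
      k = 17L, freq_lo = 2L, freq_hi = 24L, min_pairs = 10L, store_floor = 10L,
      n_min = 1500L, r_min = 0.3, g = 50L, f_min = 3L, k_iters = 3L
    )
  )
  p <- c(p, list(
    preset = preset, use_mcl = TRUE, use_freq_model = TRUE,
    s = 2L, r = 2, mcl_iters = 20L, ext = 200000
  ))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0L) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  p
}

#' Run the full clustering pipeline
#'
#' Chains k-mer counting, unique-k-mer selection, barcode QC and profiling,
#' adjacency construction, seeded clustering (with Markov splitting), and,
#' when a truth table is supplied, precision/recall evaluation. All stages
#' are deterministic for fixed inputs; the `threads` argument only sets
#' data.table's thread count and never changes any output.
#'
#' @param reads A reads tibble from [read_barcoded_fastq()] or
#'   [simulate_linked_reads()].
#' @param params Parameter list from [preset_params()].
#' @param truth Optional truth tibble for evaluation.
#' @param max_seeds Cap on the number of clusters grown.
#' @param out_dir Optional directory; when set, writes `adjacency.tsv`,
#'   `clusters.tsv`, `profiles.tsv` and (with truth) `pr.tsv`.
#' @param threads data.table thread count (results are identical at any
#'   value).
#' @param quiet Suppress stage messages.
#' @return A list classed `lfr_pipeline`: `unique_kmers`, `profiles`,
#'   `graph`, `clusters`, `pr` (or `NULL`), `params`.
#' @export
run_linked_pipeline <- function(reads, params = preset_params("desk"),
                                truth = NULL, max_seeds = Inf, out_dir = NULL,
                                threads = 1L, quiet = TRUE) {
  old_threads <- data.table::getDTthreads()
  data.table::setDTthreads(threads)
  on.exit(data.table::setDTthreads(old_threads), add = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  reads <- filter_small_barcodes(reads, params$min_pairs)
  say("barcode QC: %d pairs in %d barcodes", nrow(reads), dplyr::n_distinct(reads$barcode))
  freq <- count_kmers(c(reads$seq1, reads$seq2), k = params$k, decode = FALSE)
  uniq <- select_unique_kmers(freq, params$freq_lo, params$freq_hi)
  say("unique %d-mers: %d of %d in [%d, %d]", params$k, nrow(uniq), nrow(freq),
    params$freq_lo, params$freq_hi)
  profiles <- build_barcode_profiles(reads, uniq)
  graph <- barcode_adjacency(profiles, store_floor = params$store_floor)
  say("adjacency: %d edges at floor %d", nrow(graph), params$store_floor)
  clusters <- cluster_barcodes(profiles, graph,
    n_min = params$n_min, r_min = params$r_min, g = params$g,
    f_min = params$f_min, k_iters = params$k_iters,
    use_freq_model = params$use_freq_model, use_mcl = params$use_mcl,
    s = params$s, r = params$r, mcl_iters = params$mcl_iters,
    max_seeds = max_seeds, quiet = quiet
  )
  say("clusters: %d", length(clusters$clusters))
  pr <- NULL
  if (!is.null(truth)) {
    pr <- pr_sweep(clusters, truth, ext = params$ext)
  }
  out <- structure(
    list(
      unique_kmers = uniq, profiles = profiles, graph = graph,
      clusters = clusters, pr = pr, params = params
    ),
    class = "lfr_pipeline"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_adjacency(graph, file.path(out_dir, "adjacency.tsv"))
    write_cluster_manifest(clusters, file.path(out_dir, "clusters.tsv"))
    readr::write_tsv(
      dplyr::select(tibble::as_tibble(profiles), -"kmers"),
      file.path(out_dir, "profiles.tsv")
    )
    if (!is.null(pr)) readr::write_tsv(tibble::as_tibble(pr), file.path(out_dir, "pr.tsv"))
  }
  out
}

#' @export
print.lfr_pipeline <- function(x, ...) {
  cat(sprintf(
    "# Pipeline result: %d barcodes, %d edges, %d cluster(s)\n",
    nrow(x$profiles), nrow(x$graph), length(x$clusters$clusters)
  ))
  if (!is.null(x$pr)) print(tibble::as_tibble(x$pr))
  invisible(x)
}
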