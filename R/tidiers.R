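# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' Tidy a single cluster
#'
#' @param x An `lfr_cluster`.
#' @param ... Unused.
#' @return Tibble `seed`, `barcode`, `subcluster`, `capture_iteration`.
#' @method tidy lfr_cluster
#' @export
tidy.lfr_cluster <- function(x, ...) {
  tibble::tibble(
    seed = x$seed,
    barcode = x$members$barcode,
    subcluster = x$members$subcluster,
    capture_iteration = x$members$iteration
  )
}

#' Tidy a multi-seed clustering into the flat manifest
#'
#' @param x An `lfr_clusters`.
#' @param ... Unused.
#' @return Tibble `cluster_id`, `seed`, `barcode`, `subcluster`,
#'   `capture_iteration`, ordered for byte-stable serialization.
#' @method tidy lfr_clusters
#' @export
tidy.lfr_clusters <- function(x, ...) {
  purrr::imap_dfr(x$clusters, function(cl, i) {
    dplyr::mutate(tidy(cl), cluster_id = i, .before = 1L)
  }) |>
    dplyr::arrange(.data$cluster_id, .data$subcluster, .data$capture_iteration, .data$barcode)
}

#' One-row-per-cluster summary
#'
#' @param x An `lfr_clusters`.
#' @param ... Unused.
#' @return Tibble `cluster_id`, `seed`, `n_members`, `n_subclusters`,
#'   `n_iterations`, `n_features`.
#' @method glance lfr_clusters
#' @export
glance.lfr_clusters <- function(x, ...) {
  purrr::imap_dfr(x$clusters, function(cl, i) {
    tibble::tibble(
      cluster_id = i, seed = cl$seed,
      n_members = nrow(cl$members),
      n_subclusters = max(cl$members$subcluster),
      n_iterations = max(cl$members$iteration),
      n_features = nrow(cl$features)
    )
  })
}

#' One-row pipeline summary
#'
#' @param x An `lfr_pipeline`.
#' @param ... Unused.
#' @return Tibble with barcode, unique-k-mer, edge and cluster counts (plus
#'   mean precision/recall when evaluation ran).
#' @method glance lfr_pipeline
#' @export
glance.lfr_pipeline <- function(x, ...) {
  out <- tibble::tibble(
    n_barcodes = nrow(x$profiles),
    n_unique_kmers = nrow(x$unique_kmers),
    n_edges = nrow(x$graph),
    n_clusters = length(x$clusters$clusters)
  )
  if (!is.null(x$pr) && nrow(x$pr) > 0L) {
    out$mean_precision <- x$pr$mean_precision[1L]
    out$mean_recall <- x$pr$mean_recall[1L]
  }
  out
}

#' Plot the k-mer frequency spectrum
#'
#' Histogram of genome-wide k-mer counts on a log10 y scale; the unique
#' frequency window is chosen from the valley below the main depth peak and
#' the repeat tail above it.
#'
#' @param object An `lfr_kmer_freq` table.
#' @param max_count Truncate the x axis (default 100).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lfr_kmer_freq
#' @export
autoplot.lfr_kmer_freq <- function(object, max_count = 100L, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$count <= max_count)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_bar() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = sprintf("genome-wide %d-mer count", attr(object, "k")),
      y = "distinct k-mers",
      title = "Canonical k-mer frequency spectrum"
    )
}

#' Plot cluster sizes by capture iteration
#'
#' @param object An `lfr_clusters`.
#' @param ... Unused.
#' @return A ggplot: stacked bars of member counts per cluster, filled by
#'   the iteration at which each member was captured.
#' @method autoplot lfr_clusters
#' @export
autoplot.lfr_clusters <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$cluster_id),
    fill = factor(.data$capture_iteration)
  )) +
    ggplot2::geom_bar() +
    ggplot2::labs(
      x = "cluster", y = "members", fill = "iteration",
      title = "Cluster growth by enrichment iteration"
    )
}

#' Plot a precision-recall sweep
#'
#' @param object An `lfr_pr` table from [pr_sweep()].
#' @param ... Unused.
#' @return A ggplot of mean recall vs mean precision, one point per
#'   parameter combination, colored by iteration cutoff when swept.
#' @method autoplot lfr_pr
#' @export
autoplot.lfr_pr <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_recall, y = .data$mean_precision))
  if (length(unique(df$k_iters)) > 1L) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = factor(.data$k_iters)), size = 3) +
      ggplot2::labs(color = "k iterations")
  } else {
    p <- p + ggplot2::geom_point(size = 3)
  }
  p + ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::labs(
      x = "mean recall", y = "mean precision",
      title = "Cluster evaluation (macro-averaged over seeds)"
    )
}
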