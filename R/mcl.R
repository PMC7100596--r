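# Markov clustering (MCL) over a cluster's member barcodes.
#
# A preliminary capture from a seed carrying fragments of several genomic
# regions mixes barcodes of all those regions. Barcodes of one region are
# densely interconnected while cross-region connections are sparse, so
# alternating random-walk expansion (matrix powering) and inflation
# (entrywise powering + column renormalization) concentrates the walk
# inside regions and separates them into subclusters.

STOCHASTIC_TOL <- 1e-9

#' Build a column-stochastic transition matrix over barcodes
#'
#' Off-diagonal entries come from the adjacency graph's shared-unique-k-mer
#' weights; each node also receives a self-loop equal to its maximum
#' incident weight (1 for isolated nodes), which prevents the parity
#' oscillation of loop-free random walks while keeping the coupling scale of
#' the node's edges. Columns are then normalized to sum to 1.
#'
#' @param barcodes Character vector of member barcode ids (the matrix order).
#' @param graph An `lfr_adjacency` edge tibble.
#' @return A dense column-stochastic matrix with barcode dimnames.
#' @export
build_transition_matrix <- function(barcodes, graph) {
  n <- length(barcodes)
  stopifnot(n >= 1)
  M <- matrix(0, n, n, dimnames = list(barcodes, barcodes))
  e <- dplyr::filter(graph, .data$barcode1 %in% barcodes, .data$barcode2 %in% barcodes)
  if (nrow(e) > 0L) {
    i <- match(e$barcode1, barcodes)
    j <- match(e$barcode2, barcodes)
    M[cbind(i, j)] <- e$weight
    M[cbind(j, i)] <- e$weight
  }
  loop <- apply(M, 2, max)
  diag(M) <- pmax(loop, 1)
  sweep(M, 2, colSums(M), "/")
}

#' Expansion: power the transition matrix
#'
#' Simulates `s` steps of the random walk; a column-stochastic matrix stays
#' column-stochastic.
#'
#' @param M Column-stochastic matrix.
#' @param s Integer expansion coefficient (default 2).
#' @return `M` raised to the `s`-th power.
#' @export
mcl_expand <- function(M, s = 2L) {
  stopifnot(s >= 1)
  out <- M
  for (i in seq_len(s - 1L)) out <- out %*% M
  out
}

#' Inflation: entrywise power and column renormalization
#'
#' Raises every entry to the power `r` and renormalizes each column to sum
#' to 1, sharpening strong transitions and suppressing weak ones.
#'
#' @param M Nonnegative matrix with no all-zero column.
#' @param r Inflation coefficient (> 0, default 2).
#' @return The inflated column-stochastic matrix.
#' @export
mcl_inflate <- function(M, r = 2) {
  stopifnot(r > 0)
  P <- M^r
  cs <- colSums(P)
  if (any(cs == 0)) stop("all-zero column during inflation: matrix is not a valid transition matrix")
  sweep(P, 2, cs, "/")
}

#' Extract subclusters from a converged MCL matrix
#'
#' Rows retaining any mass above `attractor_tol` are attractors; every
#' column (barcode) is assigned to the attractor row holding its largest
#' entry, ties broken toward the lowest-indexed attractor. Attractors that
#' end up assigned to the same attractor row form one subcluster.
#'
#' @param M Converged matrix from the expand/inflate iteration.
#' @param attractor_tol Mass threshold defining attractor rows.
#' @return List of sorted character vectors partitioning the barcodes.
#' @export
extract_subclusters <- function(M, attractor_tol = 1e-6) {
  barcodes <- colnames(M)
  if (is.null(barcodes)) barcodes <- as.character(seq_len(ncol(M)))
  attractors <- which(apply(M, 1, max) > attractor_tol)
  if (length(attractors) == 0L) attractors <- seq_len(nrow(M))
  sub <- M[attractors, , drop = FALSE]
  owner <- attractors[apply(sub, 2, which.max)] # which.max takes the first max: lowest index wins ties
  groups <- split(barcodes, owner)
  unname(lapply(groups, function(g) sort(unname(g))))
}

#' Run Markov clustering
#'
#' Alternates expansion and inflation for up to `max_iter` rounds, stopping
#' early when the maximum entrywise change drops below `tol`, then extracts
#' subclusters. Singleton subclusters with nonzero original adjacency to the
#' largest subcluster are merged into it; fully isolated singletons are
#' emitted as-is.
#'
#' @param M Column-stochastic matrix from [build_transition_matrix()].
#' @param s Expansion coefficient (default 2).
#' @param r Inflation coefficient (default 2).
#' @param max_iter Maximum expand/inflate rounds (default 20).
#' @param tol Convergence threshold on the max entrywise change.
#' @param attractor_tol Passed to [extract_subclusters()].
#' @return List of sorted character vectors partitioning the input
#'   barcodes, largest first; attribute `iterations` records the rounds run.
#' @export
run_mcl <- function(M, s = 2L, r = 2, max_iter = 20L, tol = 1e-6,
                    attractor_tol = 1e-6) {
  M0 <- M
  iters <- 0L
  for (i in seq_len(max_iter)) {
    M2 <- mcl_inflate(mcl_expand(M, s), r)
    delta <- max(abs(M2 - M))
    M <- M2
    iters <- i
    if (delta < tol) break
  }
  parts <- extract_subclusters(M, attractor_tol)
  parts <- merge_stray_singletons(parts, M0)
  parts <- parts[order(-lengths(parts), vapply(parts, min, character(1)))]
  structure(parts, iterations = iters)
}

# Singletons are merged into the largest subcluster only when the original
# matrix shows nonzero (off-diagonal) coupling between them.
merge_stray_singletons <- function(parts, M0) {
  if (length(parts) < 2L) return(parts)
  sizes <- lengths(parts)
  main <- which.max(sizes)
  if (sizes[main] < 2L) return(parts)
  keep <- rep(TRUE, length(parts))
  for (i in seq_along(parts)) {
    if (i == main || sizes[i] >= 2L) next
    b <- parts[[i]]
    if (any(M0[parts[[main]], b] > 0)) {
      parts[[main]] <- sort(c(parts[[main]], b))
      keep[i] <- FALSE
    }
  }
  parts[keep]
}
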