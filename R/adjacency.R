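# Sparse barcode-barcode adjacency from an inverted k-mer index.
#
# The similarity between two barcodes is the number of unique k-mers they
# share, |K(b1) n K(b2)|. Rather than intersecting every pair of barcodes
# (O(n^2)), each unique k-mer's posting list (the barcodes containing it) is
# enumerated: every pair within a posting list gains one shared k-mer, and
# posting lists are short (bounded by sequencing depth), so accumulation is
# linear in the number of unique k-mers.

new_adjacency <- function(tbl, store_floor) {
  structure(tbl,
    class = c("lfr_adjacency", class(tibble::tibble())),
    store_floor = store_floor
  )
}

#' Build the inverted k-mer-to-barcode index
#'
#' Maps every unique k-mer to the sorted list of barcodes whose profile
#' contains it. Each posting list of length d implies d(d-1)/2 barcode
#' pairs that share that k-mer.
#'
#' @param profiles An `lfr_profiles` tibble.
#' @return A tibble with columns `code` (packed k-mer code) and `barcodes`
#'   (list-column of sorted barcode ids), classed `lfr_inverted_index`.
#' @export
build_inverted_index <- function(profiles) {
  stopifnot(nrow(profiles) > 0L)
  dt <- profiles_long(profiles)
  data.table::setorder(dt, code, barcode)
  idx <- dt[, .(barcodes = list(barcode)), by = code]
  structure(
    tibble::tibble(code = idx$code, barcodes = idx$barcodes),
    class = c("lfr_inverted_index", class(tibble::tibble())),
    k = attr(profiles, "k")
  )
}

# Pair accumulation over a long (barcode, code) table. Returns the edge
# tibble; used by both accumulate_adjacency() and barcode_adjacency().
accumulate_pairs <- function(dt, store_floor, max_posting) {
  lens <- dt[, .(d = .N), by = code]
  if (is.null(max_posting)) {
    max_posting <- max(20L, 10L * as.integer(ceiling(mean(lens$d))))
  }
  n_skip <- sum(lens$d > max_posting)
  if (n_skip > 0L) {
    warning(sprintf(
      "%d posting list(s) longer than %d skipped as repeat-derived", n_skip, max_posting
    ))
  }
  keep <- lens[d >= 2L & d <= max_posting, code]
  dt <- dt[code %in% keep]
  if (nrow(dt) == 0L) {
    return(tibble::tibble(barcode1 = character(0), barcode2 = character(0), weight = integer(0)))
  }
  lev <- sort(unique(dt$barcode))
  dt[, bi := match(barcode, lev)]
  pairs <- dt[dt, on = "code", allow.cartesian = TRUE][bi < i.bi]
  w <- pairs[, .N, by = .(bi, i.bi)][N >= store_floor]
  data.table::setorder(w, bi, i.bi)
  tibble::tibble(barcode1 = lev[w$bi], barcode2 = lev[w$i.bi], weight = w$N)
}

#' Accumulate the adjacency graph from an inverted index
#'
#' Traverses every posting list and counts, for each barcode pair, the
#' number of k-mers shared. Pairs whose exact count is at least
#' `store_floor` are stored; smaller counts are computed but discarded to
#' keep the graph sparse. Posting lists longer than `max_posting` are
#' skipped with a warning: a unique k-mer can occur in at most roughly
#' sequencing-depth barcodes, so an over-long list marks a repeat that
#' leaked through the frequency window.
#'
#' @param index An `lfr_inverted_index` from [build_inverted_index()].
#' @param store_floor Minimum stored edge weight (default 10).
#' @param max_posting Posting-list sanity cap; `NULL` (default) uses 10x the
#'   mean posting length (at least 20).
#' @return An edge tibble `barcode1`, `barcode2`, `weight` with
#'   `barcode1 < barcode2`, classed `lfr_adjacency`.
#' @export
accumulate_adjacency <- function(index, store_floor = 10L, max_posting = NULL) {
  dt <- data.table::data.table(
    code = rep.int(index$code, lengths(index$barcodes)),
    barcode = unlist(index$barcodes, use.names = FALSE)
  )
  new_adjacency(accumulate_pairs(dt, store_floor, max_posting), store_floor)
}

#' One-shot adjacency graph from profiles
#'
#' Equivalent to `accumulate_adjacency(build_inverted_index(profiles), ...)`
#' without materializing the posting lists; preferred at scale.
#'
#' @inheritParams accumulate_adjacency
#' @param profiles An `lfr_profiles` tibble.
#' @return An `lfr_adjacency` edge tibble.
#' @export
barcode_adjacency <- function(profiles, store_floor = 10L, max_posting = NULL) {
  new_adjacency(accumulate_pairs(profiles_long(profiles), store_floor, max_posting), store_floor)
}

#' Number of unique k-mers shared by two barcodes
#'
#' The pairwise barcode distance |K(b1) n K(b2)|: symmetric, and equal to
#' |K(b)| when both arguments name the same barcode.
#'
#' @param profiles An `lfr_profiles` tibble.
#' @param b1,b2 Barcode ids.
#' @return Integer count of shared unique k-mers.
#' @export
pair_distance <- function(profiles, b1, b2) {
  i <- match(c(b1, b2), profiles$barcode)
  if (anyNA(i)) stop("unknown barcode: ", paste(c(b1, b2)[is.na(i)], collapse = ", "))
  length(intersect(profiles$kmers[[i[1L]]], profiles$kmers[[i[2L]]]))
}

#' Write / read an adjacency edge list
#'
#' Serializes the graph as a 3-column TSV (`barcode1`, `barcode2`,
#' `weight`) with `barcode1 < barcode2`, with a header line.
#'
#' @param graph An `lfr_adjacency` tibble.
#' @param path Output TSV path.
#' @return `write_adjacency()`: the input, invisibly. `read_adjacency()`:
#'   an `lfr_adjacency` tibble.
#' @export
write_adjacency <- function(graph, path) {
  readr::write_tsv(tibble::as_tibble(graph), path)
  invisible(graph)
}

#' @rdname write_adjacency
#' @param store_floor Storage floor recorded on the reloaded graph.
#' @export
read_adjacency <- function(path, store_floor = 10L) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    barcode1 = readr::col_character(), barcode2 = readr::col_character(),
    weight = readr::col_integer()
  ))
  new_adjacency(tibble::as_tibble(as.data.frame(tbl)), store_floor)
}

# Neighbors (weight >= floor, i.e. any stored edge) of a set of barcodes.
graph_neighbors <- function(graph, barcodes) {
  sel1 <- graph$barcode1 %in% barcodes
  sel2 <- graph$barcode2 %in% barcodes
  unique(c(graph$barcode2[sel1], graph$barcode1[sel2]))
}

# Edge weights from `barcodes` (any side) restricted to weight > g,
# returned as a tibble(barcode, weight) of the other endpoints of `b`.
seed_neighbors <- function(graph, b, g) {
  sel1 <- graph$barcode1 == b & graph$weight > g
  sel2 <- graph$barcode2 == b & graph$weight > g
  unique(c(graph$barcode2[sel1], graph$barcode1[sel2]))
}
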