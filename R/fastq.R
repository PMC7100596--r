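# Barcoded FASTQ parsing, barcode-level QC, and per-barcode unique-k-mer
# profiles. Two barcode dialects are supported:
#   - "stlfr": the barcode is appended to the read name after the final "#"
#     (e.g. "read1#12_34_56"); the placeholder barcode (default "0_0_0")
#     marks reads whose barcode could not be resolved upstream.
#   - "sidecar": barcodes live in a two-column TSV (read_id, barcode), as
#     produced by external demultiplexers for 10X-style data.

strip_mate_suffix <- function(ids) sub("/[12]$", "", ids)

#' Read barcoded paired-end FASTQ
#'
#' Parses a read pair's FASTQ files (plain or gzip) and extracts the barcode
#' of every pair. Reads with a missing or placeholder barcode are kept with
#' `barcode = NA` (a discard bin) so that read accounting stays exact.
#'
#' @param r1,r2 Paths to the mate-1 and mate-2 FASTQ files.
#' @param dialect `"stlfr"` (barcode after the final `#` of the read name) or
#'   `"sidecar"` (barcode looked up in a TSV).
#' @param sidecar For `dialect = "sidecar"`: path to a headerless two-column
#'   TSV (read_id, barcode) or a data frame with those columns.
#' @param placeholder Barcode value treated as missing (default `"0_0_0"`).
#' @return A tibble with columns `barcode` (`NA` for the discard bin),
#'   `read_id`, `seq1`, `seq2`, classed `lfr_reads`.
#' @export
read_barcoded_fastq <- function(r1, r2, dialect = c("stlfr", "sidecar"),
                                sidecar = NULL, placeholder = "0_0_0") {
  dialect <- match.arg(dialect)
  for (p in c(r1, r2)) if (!file.exists(p)) stop("FASTQ file not found: ", p)
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq")
  if (length(s1) != length(s2)) {
    stop(sprintf("unpaired FASTQ: %d reads in %s but %d in %s", length(s1), r1, length(s2), r2))
  }
  id1 <- strip_mate_suffix(sub("\\s.*$", "", names(s1)))
  id2 <- strip_mate_suffix(sub("\\s.*$", "", names(s2)))
  bad <- which(id1 != id2)
  if (length(bad) > 0L) {
    stop(sprintf(
      "unpaired records: mate-1 read '%s' does not match mate-2 read '%s' (record %d)",
      id1[bad[1L]], id2[bad[1L]], bad[1L]
    ))
  }
  if (dialect == "stlfr") {
    has_bc <- grepl("#", id1, fixed = TRUE)
    barcode <- ifelse(has_bc, sub(".*#", "", id1), NA_character_)
    read_id <- ifelse(has_bc, sub("#[^#]*$", "", id1), id1)
  } else {
    if (is.null(sidecar)) stop("dialect 'sidecar' requires a sidecar table")
    sc <- if (is.data.frame(sidecar)) {
      tibble::as_tibble(sidecar)
    } else {
      readr::read_tsv(sidecar,
        col_names = c("read_id", "barcode"),
        col_types = readr::cols(.default = readr::col_character())
      )
    }
    read_id <- id1
    barcode <- sc$barcode[match(id1, sc$read_id)]
  }
  barcode[!is.na(barcode) & barcode == placeholder] <- NA_character_
  out <- tibble::tibble(
    barcode = barcode, read_id = read_id,
    seq1 = unname(as.character(s1)), seq2 = unname(as.character(s2))
  )
  n_discard <- sum(is.na(out$barcode))
  if (n_discard > 0L) {
    message(sprintf("%d read pair(s) without a usable barcode routed to the discard bin", n_discard))
  }
  structure(out, class = c("lfr_reads", class(tibble::tibble())))
}

#' Write barcoded paired-end FASTQ
#'
#' Writes a reads tibble back to two FASTQ files in the stLFR name dialect
#' (`read_id#barcode`), with constant qualities. Pairs in the discard bin
#' (`barcode` `NA`) are written with the placeholder barcode.
#'
#' @param reads A tibble with columns `barcode`, `read_id`, `seq1`, `seq2`.
#' @param r1,r2 Output paths (`.gz` suffix enables compression).
#' @param placeholder Barcode written for `NA` barcodes.
#' @return Invisibly, the input `reads`.
#' @export
write_barcoded_fastq <- function(reads, r1, r2, placeholder = "0_0_0") {
  bc <- ifelse(is.na(reads$barcode), placeholder, reads$barcode)
  nm <- paste0(reads$read_id, "#", bc)
  write_one <- function(seqs, nms, mate, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- paste0(nms, "/", mate)
    q <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q, compress = grepl("\\.gz$", path))
  }
  write_one(reads$seq1, nm, 1L, r1)
  write_one(reads$seq2, nm, 2L, r2)
  invisible(reads)
}

#' Drop small barcodes
#'
#' Barcodes with too few read pairs carry too few unique k-mers to relate to
#' any other barcode and are removed before profiling. The threshold is
#' strict: barcodes are kept only when they have *more than* `min_pairs`
#' pairs (the published stLFR filter keeps barcodes with more than 10).
#'
#' @param x A reads tibble (pairs counted per barcode) or a profiles tibble
#'   (its `n_pairs` column is used).
#' @param min_pairs Keep barcodes with `n_pairs > min_pairs` (default 10).
#'   `min_pairs = 0` keeps every barcode with at least one pair.
#' @return `x` restricted to retained barcodes (discard-bin reads are
#'   removed as a side effect when `x` is a reads tibble).
#' @export
filter_small_barcodes <- function(x, min_pairs = 10L) {
  stopifnot(min_pairs >= 0)
  if ("n_pairs" %in% names(x)) {
    return(dplyr::filter(x, .data$n_pairs > min_pairs))
  }
  keep <- x |>
    dplyr::filter(!is.na(.data$barcode)) |>
    dplyr::count(.data$barcode) |>
    dplyr::filter(.data$n > min_pairs)
  dplyr::filter(x, .data$barcode %in% keep$barcode)
}

new_profiles <- function(tbl, k, freq_lo, freq_hi) {
  structure(tbl,
    class = c("lfr_profiles", class(tibble::tibble())),
    k = k, freq_lo = freq_lo, freq_hi = freq_hi
  )
}

#' Build per-barcode unique-k-mer profiles
#'
#' For each barcode, collects the distinct canonical k-mers of its reads
#' (both mates contribute) and intersects them with the dataset-wide unique
#' k-mer set, yielding the barcode's feature set K(b). The unique fraction
#' |K(b)| / (distinct k-mers in the barcode) is the seed-quality statistic
#' used by [select_seed_candidates()].
#'
#' @param reads A reads tibble from [read_barcoded_fastq()] or
#'   [simulate_linked_reads()]; discard-bin reads are ignored.
#' @param unique_kmers An `lfr_unique_kmers` table from
#'   [select_unique_kmers()].
#' @return A tibble with one row per barcode: `barcode`, `n_pairs`,
#'   `n_kmers` (distinct canonical k-mers), `n_unique` (|K(b)|),
#'   `unique_fraction`, and `kmers` (list-column of packed k-mer codes,
#'   sorted). Classed `lfr_profiles` with attribute `k`.
#' @export
build_barcode_profiles <- function(reads, unique_kmers) {
  k <- attr(unique_kmers, "k")
  stopifnot(!is.null(k))
  reads <- dplyr::filter(reads, !is.na(.data$barcode))
  n <- nrow(reads)
  dt <- kmer_window_codes(c(reads$seq1, reads$seq2), k)
  bcs <- reads$barcode
  dt[, barcode := bcs[(read - 1L) %% n + 1L]] # mate 2 of pair i sits at row n + i
  dt <- unique(dt[, .(barcode, code)])
  dt[, u := code %in% unique_kmers$code]
  per <- dt[, .(
    n_kmers = .N,
    kmers = list(sort(code[u]))
  ), by = barcode]
  pairs <- reads |>
    dplyr::count(.data$barcode, name = "n_pairs")
  out <- tibble::as_tibble(per) |>
    dplyr::left_join(pairs, by = "barcode") |>
    dplyr::mutate(
      n_unique = lengths(.data$kmers),
      unique_fraction = ifelse(.data$n_kmers > 0, .data$n_unique / .data$n_kmers, 0)
    ) |>
    dplyr::select("barcode", "n_pairs", "n_kmers", "n_unique", "unique_fraction", "kmers") |>
    dplyr::arrange(.data$barcode)
  new_profiles(out,
    k = k,
    freq_lo = attr(unique_kmers, "freq_lo"), freq_hi = attr(unique_kmers, "freq_hi")
  )
}

#' @export
print.lfr_profiles <- function(x, ...) {
  cat(sprintf(
    "# Barcode profiles: %d barcodes, k = %d, mean |K(b)| = %.1f\n",
    nrow(x), attr(x, "k"), mean(x$n_unique)
  ))
  NextMethod()
}

# Long (barcode, code) data.table over profiles, one row per distinct
# unique k-mer of a barcode. The workhorse layout for adjacency and capture.
profiles_long <- function(profiles) {
  data.table::data.table(
    barcode = rep.int(profiles$barcode, lengths(profiles$kmers)),
    code = unlist(profiles$kmers, use.names = FALSE)
  )
}
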