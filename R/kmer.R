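# Canonical k-mer counting and unique-k-mer selection.
#
# K-mers are represented in two ways: as DNA strings (user-facing) and as
# packed 2-bit numeric codes (internal; A=0, C=1, G=2, T=3, leftmost base
# most significant). For k <= 26 the code fits exactly in a double, and
# numeric order on codes equals lexicographic order on the strings, so
# canonicalization and set operations work identically on either form.

.base_lut <- local({
  lut <- rep(NA_real_, 256L)
  lut[utf8ToInt("A") + 1L] <- 0
  lut[utf8ToInt("C") + 1L] <- 1
  lut[utf8ToInt("G") + 1L] <- 2
  lut[utf8ToInt("T") + 1L] <- 3
  lut
})

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp(c("ACGT", "AAAC"))
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

#' Pack k-mers into 2-bit numeric codes
#'
#' Encodes DNA strings of common length `k` as numeric codes (A=0, C=1, G=2,
#' T=3; leftmost base most significant). Exact for `k <= 26`; numeric order
#' on codes equals lexicographic order on the strings.
#'
#' @param kmers Character vector of equal-length A/C/G/T strings.
#' @return Numeric vector of packed codes.
#' @seealso [decode_kmers()]
#' @examples
#' encode_kmers(c("AAA", "ACG", "TTT"))
#' @export
encode_kmers <- function(kmers) {
  if (length(kmers) == 0L) return(numeric(0))
  k <- unique(nchar(kmers))
  if (length(k) != 1L) stop("all k-mers must have the same length")
  if (k > 26L) stop("k must be <= 26 for exact 2-bit packing in a double")
  b <- .base_lut[as.integer(charToRaw(paste(kmers, collapse = ""))) + 1L]
  if (anyNA(b)) stop("k-mers must contain only A/C/G/T")
  m <- matrix(b, nrow = k)
  as.numeric(4^((k - 1):0) %*% m)
}

#' Unpack 2-bit numeric codes into k-mer strings
#'
#' @param codes Numeric vector of packed codes (see [encode_kmers()]).
#' @param k K-mer length in bases.
#' @return Character vector of DNA strings.
#' @examples
#' decode_kmers(c(0, 6, 63), k = 3)
#' @export
decode_kmers <- function(codes, k) {
  if (length(codes) == 0L) return(character(0))
  bases <- c("A", "C", "G", "T")
  cols <- vector("list", k)
  x <- codes
  for (j in k:1) {
    cols[[j]] <- bases[x %% 4 + 1]
    x <- x %/% 4
  }
  do.call(paste0, cols)
}

#' Canonicalize k-mers
#'
#' Collapses each k-mer onto its canonical strand form: the lexicographic
#' minimum of the k-mer and its reverse complement. Reads sample both strands
#' of a fragment, so strand collapsing is required for any k-mer overlap
#' between barcodes to be detectable. Idempotent.
#'
#' @param kmers Character vector of equal-length A/C/G/T strings.
#' @return Character vector of canonical k-mers.
#' @examples
#' canonicalize(c("ACG", "TTT"))
#' @export
canonicalize <- function(kmers) {
  if (length(kmers) == 0L) return(character(0))
  rc <- revcomp(kmers)
  # numeric comparison on packed codes = lexicographic, locale-independent
  ifelse(encode_kmers(kmers) <= encode_kmers(rc), kmers, rc)
}

# Canonical codes of every N-free length-k window across `reads`.
# Returns a data.table(read = integer index into `reads`, code = numeric).
# Windows containing a non-ACGT base are skipped; their count is kept in
# attr(, "n_skipped").
kmer_window_codes <- function(reads, k) {
  stopifnot(k >= 1, k <= 26)
  lens <- nchar(reads)
  if (length(reads) == 0L || all(lens < k)) {
    out <- data.table::data.table(read = integer(0), code = numeric(0))
    data.table::setattr(out, "n_skipped", 0L)
    return(out)
  }
  b <- .base_lut[as.integer(charToRaw(paste(reads, collapse = ""))) + 1L]
  fw <- as.numeric(stats::filter(b, 4^(0:(k - 1)), sides = 1))
  rc <- as.numeric(stats::filter(3 - b, 4^((k - 1):0), sides = 1))
  # windows end at in-read positions k..len; mask windows spanning two reads
  pos_in_read <- sequence(lens)
  ok <- pos_in_read >= k
  fw <- fw[ok]
  rc <- rc[ok]
  read <- rep.int(seq_along(reads), pmax(lens - k + 1L, 0L))
  valid <- !is.na(fw) # NA propagates from any non-ACGT base in the window
  n_skipped <- sum(!valid)
  out <- data.table::data.table(read = read[valid], code = pmin(fw[valid], rc[valid]))
  data.table::setattr(out, "n_skipped", n_skipped)
  out
}

new_kmer_freq <- function(tbl, k, n_windows, n_skipped) {
  structure(tbl,
    class = c("lfr_kmer_freq", class(tibble::tibble())),
    k = k, n_windows = n_windows, n_skipped = n_skipped
  )
}

#' Count canonical k-mers across reads
#'
#' Counts every N-free length-`k` window over all reads, after collapsing
#' each window onto its canonical strand form. This is the genome-wide
#' k-mer frequency table from which unique k-mers are selected.
#'
#' @param reads Character vector of read sequences (both mates of each pair
#'   should be included so both sample the fragment).
#' @param k K-mer length in bases (default 17).
#' @param decode If `TRUE` (default) include the k-mer strings; set `FALSE`
#'   to keep only packed codes on very large inputs.
#' @return A tibble with columns `kmer` (unless `decode = FALSE`), `code`
#'   (packed 2-bit code) and `count`, ordered by `code`, with attributes
#'   `k`, `n_windows` (total counted windows) and `n_skipped` (windows
#'   dropped for containing non-ACGT bases).
#' @examples
#' count_kmers(c("AAAA", "ACGT"), k = 3)
#' @export
count_kmers <- function(reads, k = 17L, decode = TRUE) {
  dt <- kmer_window_codes(reads, k)
  n_skipped <- attr(dt, "n_skipped")
  cnt <- dt[, .N, by = code]
  data.table::setorder(cnt, code)
  tbl <- tibble::tibble(code = cnt$code, count = cnt$N)
  if (decode) tbl <- tibble::add_column(tbl, kmer = decode_kmers(tbl$code, k), .before = 1L)
  new_kmer_freq(tbl, k = as.integer(k), n_windows = nrow(dt), n_skipped = n_skipped)
}

#' Select unique k-mers by a frequency window
#'
#' A k-mer is "unique" when its genome-wide count lies inside an inclusive
#' frequency window chosen to match single-copy sequence at the dataset's
#' depth: the lower bound excludes sequencing-error k-mers, the upper bound
#' excludes repeats. Published settings for real data are 20--80 (stLFR at
#' 56x) and 20--60 (10X at 50x); the simulator's desk preset uses 2--24
#' (see [preset_params()]).
#'
#' @param freq A k-mer frequency table from [count_kmers()].
#' @param freq_lo,freq_hi Inclusive bounds on the genome-wide count.
#' @return The filtered tibble, classed `lfr_unique_kmers`, with attributes
#'   `k`, `freq_lo`, `freq_hi`.
#' @examples
#' tbl <- count_kmers(c("AAAAAA", "AAAAA"), k = 3)
#' select_unique_kmers(tbl, 2, 10)
#' @export
select_unique_kmers <- function(freq, freq_lo = 20L, freq_hi = 80L) {
  stopifnot(freq_lo >= 1, freq_lo <= freq_hi)
  out <- dplyr::filter(tibble::as_tibble(freq), .data$count >= freq_lo, .data$count <= freq_hi)
  structure(out,
    class = c("lfr_unique_kmers", class(tibble::tibble())),
    k = attr(freq, "k"), freq_lo = freq_lo, freq_hi = freq_hi
  )
}

#' @export
print.lfr_kmer_freq <- function(x, ...) {
  cat(sprintf(
    "# Canonical %d-mer frequency table: %d distinct k-mers over %d windows (%d skipped)\n",
    attr(x, "k"), nrow(x), attr(x, "n_windows"), attr(x, "n_skipped")
  ))
  NextMethod()
}

#' @export
print.lfr_unique_kmers <- function(x, ...) {
  cat(sprintf(
    "# Unique %d-mers: %d k-mers with genome-wide count in [%d, %d]\n",
    attr(x, "k"), nrow(x), attr(x, "freq_lo"), attr(x, "freq_hi")
  ))
  NextMethod()
}
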