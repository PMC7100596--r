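# Linked-read simulator with exact ground truth.
#
# Emulates the structure of co-barcoded libraries: a random genome is
# sheared into long fragments (normal lengths, clamped) drawn to a target
# fragment coverage; fragments are pooled into barcodes (shifted-Poisson
# fragment counts, mean ~1.18 for stLFR-like or ~8.32 for 10X-like
# libraries); each fragment is sampled by short read pairs at a low local
# coverage with uniform substitution errors. All randomness derives from
# one seed, so output is byte-identical across runs.

#' Simulation configuration
#'
#' @param preset `"desk"` (default; 1 Mb genome sized so the full pipeline
#'   runs in minutes), `"stlfr"` (1.18 fragments/barcode) or `"tenx"`
#'   (8.32 fragments/barcode). Any field can be overridden via `...`.
#' @param ... Overrides: `genome_length`, `fragment_length_mean`,
#'   `fragment_length_sd`, `fragment_min_length`, `fragment_coverage`,
#'   `fragments_per_barcode`, `local_coverage`, `read_length`,
#'   `insert_mean`, `insert_sd`, `error_rate`, `chrom`, `n_repeats`,
#'   `repeat_length`, `seed`.
#' @return A named list classed `lfr_sim_config`.
#' @details Defaults: 1 Mb genome; fragments 20 +- 7 kb (clamped at 1 kb),
#'   drawn to 30x fragment coverage; 1.2 fragments per barcode; local
#'   coverage 0.2x (so ~6x global coverage); 100 bp reads, 300 +- 30 bp
#'   inserts; 0.1% substitution errors; seed 42.
#' @export
sim_config <- function(preset = c("desk", "stlfr", "tenx"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    genome_length = 1e6,
    fragment_length_mean = 20000,
    fragment_length_sd = 7000,
    fragment_min_length = 1000,
    fragment_coverage = 30,
    fragments_per_barcode = switch(preset, desk = 1.2, stlfr = 1.18, tenx = 8.32),
    local_coverage = 0.2,
    read_length = 100L,
    insert_mean = 300,
    insert_sd = 30,
    error_rate = 0.001,
    chrom = "sim1",
    n_repeats = 0L,
    repeat_length = 5000,
    seed = 42L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(
    cfg$genome_length >= 10 * cfg$fragment_length_mean,
    cfg$local_coverage > 0, cfg$local_coverage <= 1,
    cfg$fragments_per_barcode >= 1, cfg$error_rate >= 0, cfg$error_rate < 1,
    cfg$fragment_min_length >= 2 * cfg$read_length
  )
  structure(cfg, class = "lfr_sim_config")
}

#' @export
print.lfr_sim_config <- function(x, ...) {
  cat(sprintf(
    "# Linked-read sim config (%s): %.2g bp genome, %.0f kb +- %.0f kb fragments at %gx,\n#   %.2f fragments/barcode, local coverage %gx, %d bp reads, error %g, seed %d\n",
    x$preset, x$genome_length, x$fragment_length_mean / 1e3, x$fragment_length_sd / 1e3,
    x$fragment_coverage, x$fragments_per_barcode, x$local_coverage,
    x$read_length, x$error_rate, x$seed
  ))
  invisible(x)
}

#' Simulate a random genome
#'
#' Uniform-random ACGT sequence; with `n_repeats > 0`, segments of length
#' `repeat_length` are copied to second loci to exercise repeat robustness.
#'
#' @param config An `lfr_sim_config`.
#' @param seed RNG seed (defaults to `config$seed`; stages derive distinct
#'   streams by fixed offsets so they are reproducible run separately or
#'   chained).
#' @return A single character string of length `config$genome_length`.
#' @export
simulate_genome <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- as.integer(config$genome_length)
  g <- stringi::stri_flatten(sample(c("A", "C", "G", "T"), n, replace = TRUE))
  if (config$n_repeats > 0L) {
    L <- as.integer(config$repeat_length)
    for (i in seq_len(config$n_repeats)) {
      src <- sample.int(n - L, 1L)
      dst <- sample.int(n - L, 1L)
      stringi::stri_sub(g, dst, dst + L - 1L) <- stringi::stri_sub(g, src, src + L - 1L)
    }
  }
  g
}

#' Simulate long fragments
#'
#' Fragments get uniform-random starts and normal lengths (clamped at
#' `fragment_min_length`), drawn until the summed length reaches
#' `fragment_coverage` x genome length.
#'
#' @inheritParams simulate_genome
#' @return A tibble `fragment` (id), `start`, `end` (0-based half-open).
#' @export
simulate_fragments <- function(config, seed = config$seed + 1L) {
  set.seed(seed)
  G <- config$genome_length
  target <- config$fragment_coverage * G
  lens <- numeric(0)
  starts <- numeric(0)
  while (sum(lens) < target) {
    n_draw <- max(100L, ceiling((target - sum(lens)) / config$fragment_length_mean * 1.2))
    l <- pmax(
      round(rnorm(n_draw, config$fragment_length_mean, config$fragment_length_sd)),
      config$fragment_min_length
    )
    l <- pmin(l, G)
    s <- floor(runif(n_draw, 0, G - l + 1))
    lens <- c(lens, l)
    starts <- c(starts, s)
  }
  n_keep <- which(cumsum(lens) >= target)[1L]
  lens <- lens[seq_len(n_keep)]
  starts <- starts[seq_len(n_keep)]
  tibble::tibble(
    fragment = seq_len(n_keep),
    start = starts, end = starts + lens
  )
}

#' Pool fragments into barcodes
#'
#' Partitions the fragments into barcodes, each barcode receiving a
#' shifted-Poisson number of fragments, `1 + Poisson(mean - 1)`, so the
#' configured mean is matched while every barcode holds at least one
#' fragment. Every fragment is assigned exactly once.
#'
#' @param fragments Tibble from [simulate_fragments()].
#' @inheritParams simulate_genome
#' @return `fragments` with a `barcode` column appended.
#' @export
assign_barcodes <- function(fragments, config, seed = config$seed + 2L) {
  set.seed(seed)
  n <- nrow(fragments)
  counts <- integer(0)
  while (sum(counts) < n) {
    counts <- c(counts, 1L + rpois(max(64L, n), config$fragments_per_barcode - 1))
  }
  n_bc <- which(cumsum(counts) >= n)[1L]
  counts <- counts[seq_len(n_bc)]
  counts[n_bc] <- counts[n_bc] - (sum(counts) - n) # truncate the last barcode
  bc <- rep.int(sprintf("B%05d", seq_len(n_bc)), counts)
  fragments$barcode <- bc[sample.int(n)] # random fragment-to-barcode pairing
  fragments
}

# Substitution errors: pick error bases binomially over all read bases and
# replace each with a different base.
apply_errors <- function(seqs, error_rate, rl) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  total <- length(seqs) * rl
  n_err <- rbinom(1L, total, error_rate)
  if (n_err == 0L) return(seqs)
  at <- sample.int(total, n_err)
  ri <- (at - 1L) %/% rl + 1L
  pos <- (at - 1L) %% rl + 1L
  bases <- c("A", "C", "G", "T")
  for (j in seq_len(n_err)) {
    old <- stringi::stri_sub(seqs[ri[j]], pos[j], pos[j])
    stringi::stri_sub(seqs[ri[j]], pos[j], pos[j]) <- sample(setdiff(bases, old), 1L)
  }
  seqs
}

#' Simulate a full linked-read dataset
#'
#' Runs all stages (genome, fragments, barcodes, reads) and returns the
#' reads together with the exact truth table. Pairs are FR-oriented with
#' normal insert sizes (clamped to [2 x read length, fragment length]);
#' mate 2 is the reverse complement of its template. The truth table holds
#' one row per (barcode, fragment) that emitted at least one pair, with
#' `n_pairs` exactly equal to the pairs emitted.
#'
#' @param config An `lfr_sim_config` from [sim_config()].
#' @return A list classed `lfr_sim`: `reads` (tibble `barcode`, `read_id`,
#'   `seq1`, `seq2`, `fragment`), `truth` (`lfr_truth` tibble), `fragments`,
#'   `genome` (character), `config`.
#' @examples
#' sim <- simulate_linked_reads(sim_config(genome_length = 2e5, fragment_coverage = 5))
#' dplyr::count(sim$reads, barcode)
#' @export
simulate_linked_reads <- function(config = sim_config()) {
  genome <- simulate_genome(config)
  fragments <- simulate_fragments(config)
  fragments <- assign_barcodes(fragments, config)
  set.seed(config$seed + 3L)
  rl <- config$read_length
  lens <- fragments$end - fragments$start
  n_pairs <- rpois(nrow(fragments), lens * config$local_coverage / (2 * rl))
  fi <- rep.int(seq_len(nrow(fragments)), n_pairs)
  n_tot <- length(fi)
  insert <- pmin(pmax(round(rnorm(n_tot, config$insert_mean, config$insert_sd)), 2L * rl), lens[fi])
  off <- floor(runif(n_tot, 0, lens[fi] - insert + 1))
  p1 <- fragments$start[fi] + off + 1 # 1-based genome position of mate 1
  p2 <- fragments$start[fi] + off + insert - rl + 1
  seq1 <- stringi::stri_sub(genome, p1, length = rl)
  seq2 <- revcomp(stringi::stri_sub(genome, p2, length = rl))
  seq1 <- apply_errors(seq1, config$error_rate, rl)
  seq2 <- apply_errors(seq2, config$error_rate, rl)
  reads <- tibble::tibble(
    barcode = fragments$barcode[fi],
    read_id = sprintf("F%05d_P%07d", fi, seq_len(n_tot)),
    seq1 = seq1, seq2 = seq2,
    fragment = fi
  )
  truth <- fragments |>
    dplyr::mutate(n_pairs = n_pairs) |>
    dplyr::filter(.data$n_pairs > 0L) |>
    dplyr::mutate(chrom = config$chrom) |>
    dplyr::select("barcode", "chrom", "start", "end", "n_pairs")
  structure(
    list(
      reads = structure(reads, class = c("lfr_reads", class(tibble::tibble()))),
      truth = validate_truth(truth, src = "simulated truth"),
      fragments = fragments, genome = genome, config = config
    ),
    class = "lfr_sim"
  )
}

#' @export
print.lfr_sim <- function(x, ...) {
  cat(sprintf(
    "# Simulated linked reads: %d pairs, %d barcodes, %d fragments over %.2g bp\n",
    nrow(x$reads), dplyr::n_distinct(x$reads$barcode), nrow(x$fragments),
    x$config$genome_length
  ))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits `reads_1.fq.gz` / `reads_2.fq.gz` (stLFR name dialect),
#' `truth.tsv`, and a `config.yml` echo of the configuration.
#'
#' @param sim An `lfr_sim` from [simulate_linked_reads()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_linked_reads <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_barcoded_fastq(sim$reads, file.path(dir, "reads_1.fq.gz"), file.path(dir, "reads_2.fq.gz"))
  readr::write_tsv(tibble::as_tibble(sim$truth), file.path(dir, "truth.tsv"))
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(unclass(sim$config), file.path(dir, "config.yml"))
  }
  invisible(dir)
}
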