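#' Simulate paired-end reads from a genome sequence
#'
#' Draws a Poisson number of fragments (mean `coverage * L / (2 * read_len)`)
#' with uniform start positions and Gaussian fragment lengths, and reads both
#' fragment ends: read 1 is the leftmost `read_len` bases on the forward
#' strand, read 2 the reverse complement of the rightmost `read_len` bases
#' (FR orientation).  Sequencing error is a uniform per-base substitution;
#' base qualities are constant Q30.
#'
#' @param genome Character scalar, `reference_genome` or
#'   `derivative_genome`.
#' @param coverage Target fold coverage (> 0).
#' @param read_len Read length in bases; must be < `insert_mean`.
#' @param insert_mean,insert_sd Fragment-length distribution (bases).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed; identical inputs give identical reads.
#' @param sample_name Prefix used in read names.
#'
#' @return Object of class `read_pairs`: list with character vectors `r1`,
#'   `r2` (sequenced orientation), numeric `frag_start` (0-based on the
#'   source genome), `frag_len`, and fields `read_len`, `sample_name`,
#'   `genome_length`.
#' @export
simulate_reads <- function(genome, coverage = 30, read_len = 100,
                           insert_mean = 300, insert_sd = 50,
                           error_rate = 0.005, seed = 1,
                           sample_name = "sample") {
  seq <- if (inherits(genome, c("reference_genome", "derivative_genome")))
    genome$sequence else genome
  L <- nchar(seq)
  if (coverage <= 0) stop("`coverage` must be > 0", call. = FALSE)
  if (read_len >= insert_mean) {
    stop("`read_len` must be smaller than `insert_mean`", call. = FALSE)
  }
  with_seed(seed, {
    n <- stats::rpois(1, coverage * L / (2 * read_len))
    flen <- pmax(read_len + 2, pmin(L, round(stats::rnorm(n, insert_mean, insert_sd))))
    fstart <- floor(stats::runif(n, min = 0, max = L - flen + 1))
    r1 <- substring(seq, fstart + 1, fstart + read_len)
    r2 <- revcomp(substring(seq, fstart + flen - read_len + 1, fstart + flen))
    if (error_rate > 0) {
      r1 <- inject_errors(r1, error_rate)
      r2 <- inject_errors(r2, error_rate)
    }
    structure(list(r1 = r1, r2 = r2, frag_start = fstart, frag_len = flen,
                   read_len = as.integer(read_len), sample_name = sample_name,
                   genome_length = L),
              class = "read_pairs")
  })
}

# Uniform substitution errors, vectorized: reads are edited one error-rank
# round at a time so each round is a single vectorized substr<- call.
inject_errors <- function(reads, rate) {
  rl <- nchar(reads[1])
  nerr <- stats::rbinom(length(reads), rl, rate)
  idx <- which(nerr > 0)
  if (!length(idx)) return(reads)
  bases <- c("A", "C", "G", "T")
  for (round in seq_len(max(nerr))) {
    cur <- idx[nerr[idx] >= round]
    pos <- sample.int(rl, length(cur), replace = TRUE)
    old <- substr(reads[cur], pos, pos)
    # substitute with one of the three other bases, uniformly
    shift <- sample.int(3, length(cur), replace = TRUE)
    new <- bases[(match(old, bases) - 1L + shift) %% 4L + 1L]
    substring(reads[cur], pos, pos) <- new
  }
  reads
}

#' @export
print.read_pairs <- function(x, ...) {
  cat(sprintf("<read_pairs> %s pairs of %d bp (%s)\n",
              format(length(x$r1), big.mark = ","), x$read_len, x$sample_name))
  invisible(x)
}

#' Write paired reads as a pair of FASTQ files
#'
#' @param pairs A `read_pairs` object.
#' @param prefix Output path prefix; files `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written.
#' @param qual_char Constant base-quality character (default `"I"`, Q40
#'   dialect commonly used for simulated data).
#' @return The two file paths, invisibly.
#' @export
write_fastq <- function(pairs, prefix, qual_char = "I") {
  stopifnot(inherits(pairs, "read_pairs"))
  n <- length(pairs$r1)
  ids <- sprintf("@%s:%d", pairs$sample_name, seq_len(n))
  qual <- strrep(qual_char, pairs$read_len)
  p1 <- paste0(prefix, "_1.fastq")
  p2 <- paste0(prefix, "_2.fastq")
  writeLines(paste(ids, pairs$r1, "+", qual, sep = "\n"), p1)
  writeLines(paste(ids, pairs$r2, "+", qual, sep = "\n"), p2)
  invisible(c(p1, p2))
}
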