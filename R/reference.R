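#' Generate a random haploid reference sequence
#'
#' Produces a reproducible random DNA sequence with a target GC content,
#' standing in for a multi-megabase chromosome arm.  Simulated references
#' contain only A/C/G/T (no ambiguity codes), so every downstream alignment
#' and realignment operation is exact.
#'
#' @param length Sequence length in bases (>= 1).
#' @param gc_fraction Target GC proportion in (0, 1).  The default 0.36
#'   approximates the nucleotide composition of the *C. elegans* genome.
#' @param seed Integer seed; identical `(length, gc_fraction, seed)` yield
#'   identical sequences.
#' @param name Sequence name used in FASTA/SAM output.
#'
#' @return An object of class `reference_genome`: a list with elements
#'   `name`, `sequence` (character scalar) and `length`.
#' @examples
#' ref <- make_reference(1e4, gc_fraction = 0.36, seed = 1)
#' ref$length
#' @export
make_reference <- function(length, gc_fraction = 0.36, seed = 1,
                           name = "chrS") {
  check_count(length, "length", min = 1)
  if (!is.numeric(gc_fraction) || gc_fraction <= 0 || gc_fraction >= 1) {
    stop("`gc_fraction` must be strictly between 0 and 1", call. = FALSE)
  }
  seq <- with_seed(seed, {
    p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
           G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  })
  structure(list(name = name, sequence = seq, length = as.integer(length)),
            class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf("<reference_genome> %s: %s bp, GC %.3f\n",
              x$name, format(x$length, big.mark = ","),
              gc_fraction(x$sequence)))
  invisible(x)
}

as_ref_seq <- function(reference) {
  if (inherits(reference, "reference_genome")) reference$sequence
  else if (is.character(reference) && length(reference) == 1L) reference
  else stop("expected a `reference_genome` or a character scalar", call. = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences, or a `reference_genome`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "reference_genome")) {
    seqs <- stats::setNames(seqs$sequence, seqs$name)
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}
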