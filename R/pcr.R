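# In silico PCR: junction-flanking primer pairs must amplify from the
# derivative genome and not from the reference -- the computational analog
# of running junction primers against mutant and wild-type template DNA.

#' Find primer binding sites in a template
#'
#' Reports all sites on both strands with at most `max_mismatch` mismatches
#' outside the 3'-terminal 3 nucleotides, which must match exactly
#' (polymerase extension requires an annealed 3' end).
#'
#' @param primer Primer sequence (A/C/G/T, 18--30 nt).
#' @param template Template sequence (character scalar or
#'   `reference_genome`/`derivative_genome`).
#' @param max_mismatch Mismatches tolerated outside the 3' anchor (<= 3).
#' @return `data.frame` with `start` (0-based), `strand` (`"+"` binds the
#'   forward strand and extends rightward; `"-"` binds the reverse strand
#'   and extends leftward).
#' @export
find_binding_sites <- function(primer, template, max_mismatch = 0) {
  if (!is.character(primer) || nchar(primer) < 18) {
    stop("primer must be at least 18 nt", call. = FALSE)
  }
  if (nchar(primer) > 30) stop("primer longer than 30 nt", call. = FALSE)
  if (grepl("[^ACGT]", primer)) stop("primer must be over A/C/G/T", call. = FALSE)
  if (max_mismatch > 3) stop("`max_mismatch` must be <= 3", call. = FALSE)
  seq <- if (inherits(template, c("reference_genome", "derivative_genome")))
    template$sequence else template
  dna <- Biostrings::DNAString(seq)
  k <- nchar(primer)
  out <- list()
  scan <- function(pat, strand) {
    m <- Biostrings::matchPattern(pat, dna, max.mismatch = max_mismatch)
    for (i in seq_along(m)) {
      st <- IRanges::start(m)[i]
      win <- as.character(Biostrings::subseq(dna, st, st + k - 1L))
      mm <- which(strsplit(win, "")[[1]] != strsplit(pat, "")[[1]])
      # 3' anchor: last 3 primer bases for "+", first 3 window bases for "-"
      anchor_bad <- if (strand == "+") any(mm > k - 3L) else any(mm <= 3L)
      if (!anchor_bad && length(mm) <= max_mismatch) {
        out[[length(out) + 1L]] <<- data.frame(start = st - 1L, strand = strand,
                                               stringsAsFactors = FALSE)
      }
    }
  }
  scan(primer, "+")
  scan(revcomp(primer), "-")
  if (!length(out)) {
    return(data.frame(start = numeric(0), strand = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$strand), , drop = FALSE]
}

#' Predict PCR products for a primer pair
#'
#' Every convergent pairing of a forward-strand site of one primer with a
#' downstream reverse-strand site of the other, spanning at most
#' `max_product` bases, yields a product.  Swapping the two primers gives
#' the same product set.
#'
#' @param forward,reverse Primer sequences.
#' @param template Template sequence (or genome object).
#' @param max_product Maximum product size in bases.
#' @param max_mismatch Binding-site mismatch tolerance.
#' @return `data.frame` of class `pcr_products`: `start`, `end` (0-based
#'   half-open), `size`, `fwd_site`, `rev_site`, `fwd_primer` (which primer
#'   acted as the forward one), sorted by size.
#' @export
predict_products <- function(forward, reverse, template, max_product = 2000,
                             max_mismatch = 0) {
  seq <- if (inherits(template, c("reference_genome", "derivative_genome")))
    template$sequence else template
  sf <- find_binding_sites(forward, seq, max_mismatch)
  sr <- find_binding_sites(reverse, seq, max_mismatch)
  res <- list()
  pair_up <- function(plus, minus, plus_len, minus_len, label) {
    for (i in seq_len(nrow(plus))) {
      for (j in seq_len(nrow(minus))) {
        st <- plus$start[i]
        en <- minus$start[j] + minus_len
        size <- en - st
        if (size >= plus_len + minus_len && size <= max_product) {
          res[[length(res) + 1L]] <<- data.frame(
            start = st, end = en, size = size,
            fwd_site = st, rev_site = minus$start[j], fwd_primer = label,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  pair_up(sf[sf$strand == "+", , drop = FALSE], sr[sr$strand == "-", , drop = FALSE],
          nchar(forward), nchar(reverse), "forward")
  if (forward != reverse) {
    pair_up(sr[sr$strand == "+", , drop = FALSE], sf[sf$strand == "-", , drop = FALSE],
            nchar(reverse), nchar(forward), "reverse")
  }
  out <- if (length(res)) unique(do.call(rbind, res)) else
    data.frame(start = numeric(0), end = numeric(0), size = numeric(0),
               fwd_site = numeric(0), rev_site = numeric(0),
               fwd_primer = character(0))
  out <- out[order(out$size, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pcr_products", "data.frame")
  out
}

gc_of <- function(x) {
  b <- strsplit(x, "")[[1]]
  mean(b %in% c("G", "C"))
}

#' Design a junction-specific primer pair
#'
#' Picks 20-mers from the two derivative-oriented junction flanks such that
#' the pair yields exactly one product of 150--1000 bp from the derivative
#' and none from the reference, with GC content in 40--60% and a unique
#' binding site in the reference (both strands, zero mismatches).
#'
#' @param junction One row of a junction table (`coord_a`, `orient_a`,
#'   `coord_b`, `orient_b`, optionally `insert`/`ins_len_hint`).
#' @param reference `reference_genome` or character scalar.
#' @param derivative `derivative_genome` or character scalar.
#' @param primer_len Primer length (default 20).
#' @param flank Search window on each side of the junction (>= 200).
#' @param product_range Acceptable product-size range on the derivative.
#' @param gc_range Acceptable primer GC fraction range.
#' @param max_product Scan limit for off-target products.
#' @return `data.frame` of class `primer_pair`: `name`, `forward`,
#'   `reverse`, `product_size`.  Errors with "design failed" when no pair
#'   within the search window satisfies all constraints.
#' @export
design_junction_primers <- function(junction, reference, derivative,
                                    primer_len = 20, flank = 200,
                                    product_range = c(150, 1000),
                                    gc_range = c(0.40, 0.60),
                                    max_product = 2000) {
  ref_seq <- as_ref_seq(reference)
  der_seq <- if (inherits(derivative, "derivative_genome")) derivative$sequence
             else derivative
  a_fl <- breakend_flank(ref_seq, junction$coord_a, junction$orient_a,
                         flank, "retained")
  b_fl <- breakend_flank(ref_seq, junction$coord_b, junction$orient_b,
                         flank, "continuation")
  if (nchar(a_fl) < flank || nchar(b_fl) < flank) {
    stop("junction flanks shorter than required", call. = FALSE)
  }
  # candidate 3'-end offsets from the junction, nearest first
  offs <- seq(5, flank - primer_len, by = 9)
  for (ga in offs) {
    fwd <- substr(a_fl, nchar(a_fl) - ga - primer_len + 1L, nchar(a_fl) - ga)
    if (gc_of(fwd) < gc_range[1] || gc_of(fwd) > gc_range[2]) next
    if (nrow(find_binding_sites(fwd, ref_seq, 0)) != 1L) next
    ins <- junction$ins_len_hint %||% junction$insert_len %||% 0L
    if (is.na(ins)) ins <- 0L
    for (gb in offs) {
      size <- ga + gb + 2L * primer_len + ins
      if (size < product_range[1] || size > product_range[2]) next
      rev <- revcomp(substr(b_fl, gb + 1L, gb + primer_len))
      if (gc_of(rev) < gc_range[1] || gc_of(rev) > gc_range[2]) next
      if (nrow(find_binding_sites(rev, ref_seq, 0)) != 1L) next
      pd <- predict_products(fwd, rev, der_seq, max_product)
      ok <- nrow(pd) == 1L && pd$size[1] >= product_range[1] &&
        pd$size[1] <= product_range[2]
      if (!ok) next
      pr <- predict_products(fwd, rev, ref_seq, max_product)
      if (nrow(pr) > 0L) next
      out <- data.frame(name = junction$name %||% "junction",
                        forward = fwd, reverse = rev,
                        product_size = pd$size[1], stringsAsFactors = FALSE)
      class(out) <- c("primer_pair", "data.frame")
      return(out)
    }
  }
  stop("design failed", call. = FALSE)
}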