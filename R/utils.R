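# Internal helpers shared across modules.

#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#' @importFrom methods as
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Reverse complement of plain character vectors (empty strings pass through).
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- character(length(x))
  nz <- nzchar(x)
  if (any(nz)) {
    out[nz] <- as.character(reverseComplement(DNAStringSet(x[nz])))
  }
  out
}

# 0-based half-open substring of a character scalar.
subseq0 <- function(seq, start0, end0) {
  substring(seq, start0 + 1L, end0)
}

gc_fraction <- function(seq) {
  b <- Biostrings::letterFrequency(DNAString(seq), letters = c("GC"))
  as.numeric(b) / nchar(seq)
}

# Stop unless scalar positive integer-ish.
check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    stop(sprintf("`%s` must be a single number >= %s", name, format(min)),
         call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Count mismatches between two equal-length strings.
str_mismatches <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("internal: unequal lengths")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Sequence flanks around an oriented breakend, expressed in derivative
# orientation.  A breakend is (coord, orient) with 0-based coord; orient "+"
# means the fused segment lies on the lower-coordinate side (it *ends* at
# coord), "-" means it lies on the higher-coordinate side (it *starts* at
# coord).
#
# retained : the `len` derivative bases approaching the junction, ending at it.
# continuation : the `len` derivative bases leaving the junction into the
#   partner segment, starting at it.
# preceding : the `len` bases just before `continuation` in the same reading
#   direction (used for microhomology).
breakend_flank <- function(ref_seq, coord, orient,
                           len, what = c("retained", "continuation", "preceding")) {
  what <- match.arg(what)
  n <- nchar(ref_seq)
  if (what == "retained") {
    if (orient == "+") {
      s <- max(0L, coord - len)
      subseq0(ref_seq, s, coord)
    } else {
      e <- min(n, coord + len)
      revcomp(subseq0(ref_seq, coord, e))
    }
  } else if (what == "continuation") {
    if (orient == "-") {
      e <- min(n, coord + len)
      subseq0(ref_seq, coord, e)
    } else {
      s <- max(0L, coord - len)
      revcomp(subseq0(ref_seq, s, coord))
    }
  } else {
    if (orient == "-") {
      s <- max(0L, coord - len)
      subseq0(ref_seq, s, coord)
    } else {
      e <- min(n, coord + len)
      revcomp(subseq0(ref_seq, coord, e))
    }
  }
}
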