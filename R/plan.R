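#' Declarative description of a derivative chromosome
#'
#' A segment plan is an ordered list of oriented reference intervals
#' ("pieces") whose concatenation, with optional junctional insertions
#' interposed, realizes a derivative chromosome.  Intervals are 0-based
#' half-open; pieces may overlap across the list (overlap is what creates
#' copy-number gains).
#'
#' @param pieces `data.frame` with columns `start`, `end` (0-based half-open)
#'   and `strand` (`"+"` or `"-"`).
#' @param insertions List of junctional insertions, each a list with
#'   `after` (piece index; the insertion sits between piece `after` and piece
#'   `after + 1`) and either `seq` (literal DNA) or `template`
#'   (list with `start`, `end`, `strand`: the insertion is copied from the
#'   reference, reverse-complemented when `strand == "-"`).
#' @param engineer Optional list of reference-edit directives applied by
#'   [engineer_reference()] to guarantee designed junction signatures
#'   (e.g. a shared terminal triplet).
#'
#' @return An object of class `segment_plan`.
#' @seealso [default_dpdp667_plan()], [build_derivative()]
#' @export
segment_plan <- function(pieces, insertions = list(), engineer = list()) {
  stopifnot(is.data.frame(pieces), all(c("start", "end", "strand") %in% names(pieces)))
  pieces <- data.frame(start = as.numeric(pieces$start),
                       end = as.numeric(pieces$end),
                       strand = as.character(pieces$strand),
                       stringsAsFactors = FALSE)
  if (any(pieces$end <= pieces$start)) {
    stop("every piece must satisfy start < end", call. = FALSE)
  }
  if (!all(pieces$strand %in% c("+", "-"))) {
    stop("piece strand must be '+' or '-'", call. = FALSE)
  }
  n <- nrow(pieces)
  for (ins in insertions) {
    a <- ins$after
    if (is.null(a) || a < 1 || a > n - 1) {
      stop("insertion `after` must reference an inter-piece position (1..n-1)",
           call. = FALSE)
    }
    if (is.null(ins$seq) && is.null(ins$template)) {
      stop("insertion needs `seq` or `template`", call. = FALSE)
    }
  }
  structure(list(pieces = pieces, insertions = insertions, engineer = engineer),
            class = "segment_plan")
}

#' @export
print.segment_plan <- function(x, ...) {
  cat(sprintf("<segment_plan> %d pieces, %d insertions\n",
              nrow(x$pieces), length(x$insertions)))
  print(x$pieces)
  invisible(x)
}

validate_plan <- function(plan, ref_length) {
  p <- plan$pieces
  if (any(p$start < 0) || any(p$end > ref_length)) {
    stop("plan interval out of reference bounds", call. = FALSE)
  }
  for (ins in plan$insertions) {
    if (!is.null(ins$template)) {
      t <- ins$template
      if (t$start < 0 || t$end > ref_length || t$end <= t$start) {
        stop("templated insertion source interval out of bounds", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Default CGR plan: localized duplications and a triplication
#'
#' Builds the package's default derivative-chromosome plan: a complex
#' rearrangement confined to a sub-3-Mb region, consisting of two large
#' regions of copy-number doubling (about 2 Mb and about 500 kb), one
#' smaller triplicated region, and a pair of inverted copies of a small
#' segment flanking a 17-nt insertion that is templated from sequence a few
#' dozen bases away.  The four resulting novel junctions carry, in genomic
#' order: a short templated insertion, a 3-bp sequence (`AGT`) shared by the
#' ends of both fusion partners, a blunt fusion, and the 17-nt templated
#' insertion between the inverted copies.
#'
#' The derivative is the walk
#' `[0,e1)+  [c,e2)+  [b,f2)+  ins17  [f1, f2-40)-  [f2,L)+`
#' over the reference, where `b < c < e1 < e2 < f1 < f2`.  Coverage
#' accounting gives copy 2 on `[b,c)` (~2 Mb), copy 3 on `[c,e1)` (the
#' triplicated segment), copy 2 on `[e1,e2)` (~500 kb) and copy 2 on most of
#' the small segment `[f1,f2)`, everything else copy 1 (no deletions).
#'
#' @param reference_length Length of the reference the plan must fit into.
#' @param scale Proportion by which all interval coordinates are scaled
#'   (the 17-nt insertion, the 40-bp offset between the inverted copy ends
#'   and the templated-insert source offsets are sequence-level features and
#'   are not scaled).  `scale = 1` spans just under 3 Mb of breakends.
#' @param triplicated Which of the two small participating segments is
#'   triplicated: `"28kb"` (default) or `"9kb"`.  The other becomes the
#'   inverted duplicated pair.
#'
#' @return A `segment_plan` whose `engineer` directives pin down the designed
#'   junction signatures; apply them with [engineer_reference()] before
#'   [build_derivative()].
#' @examples
#' plan <- default_dpdp667_plan(1e5, scale = 0.02)
#' plan$pieces
#' @export
default_dpdp667_plan <- function(reference_length, scale = 1,
                                 triplicated = c("28kb", "9kb")) {
  triplicated <- match.arg(triplicated)
  sizes <- if (triplicated == "28kb") c(trip = 28000, inv = 9000)
           else c(trip = 9000, inv = 28000)
  sc <- function(x) as.integer(round(x * scale))
  b  <- sc(1000000)                 # start of the large doubled region
  cc <- sc(3000000)                 # start of the triplicated segment
  e1 <- cc + sc(sizes[["trip"]])    # end of triplicated / start of 500 kb
  e2 <- e1 + sc(500000)             # end of the 500 kb doubled region
  f1 <- e2 + sc(250000)             # start of the small inverted segment
  f2 <- f1 + sc(sizes[["inv"]])     # end of the small inverted segment
  inv_off <- 40L                    # the two inverted copies end 40 bp apart
  if (f2 - inv_off - f1 < 10L || b < 10L || e1 - cc < 10L) {
    stop("scale too small: plan segments degenerate", call. = FALSE)
  }
  if (f2 + 600 > reference_length) {
    stop("scale too large for reference", call. = FALSE)
  }
  pieces <- data.frame(
    start  = c(0,  cc, b,  f1,            f2),
    end    = c(e1, e2, f2, f2 - inv_off,  reference_length),
    strand = c("+", "+", "+", "-",        "+"),
    stringsAsFactors = FALSE
  )
  insertions <- list(
    # short templated insertion at the triplication junction; the source lies
    # 50 bp downstream of the donor breakend
    list(after = 1L, template = list(start = e1 + 50, end = e1 + 59, strand = "+")),
    # 17-nt insertion between the two inverted segment copies, templated from
    # 25 bp beyond the fold-back breakend
    list(after = 3L, template = list(start = f2 + 25, end = f2 + 42, strand = "+"))
  )
  engineer <- list(
    list(op = "set", pos = e2 - 3, seq = "AGT"),   # shared triplet, partner A
    list(op = "set", pos = b - 3,  seq = "AGT"),   # shared triplet, partner B
    # cap the shared block at exactly 3 bp
    list(op = "differ", pos = b - 4, other = e2 - 4, comp = FALSE),
    # keep the fourth junction blunt (no accidental 1-bp homology on either
    # side of the fusion point)
    list(op = "differ", pos = f2 - 1, other = f1, comp = TRUE),
    list(op = "differ", pos = f1 - 1, other = f2, comp = TRUE),
    # and cap the shared triplet on its far side as well
    list(op = "differ", pos = b, other = e2, comp = FALSE),
    # make both junctional insertions irreducible: neither end base may
    # extend a fusion-partner flank, otherwise the breakpoint representation
    # (and the reported insertion length) becomes ambiguous
    list(op = "differ", pos = e1 + 50, other = e1, comp = FALSE),
    list(op = "differ", pos = e1 + 58, other = cc - 1, comp = FALSE),
    list(op = "differ", pos = f2 + 25, other = f2, comp = FALSE),
    list(op = "differ", pos = f2 + 41, other = f2 - inv_off, comp = TRUE)
  )
  segment_plan(pieces, insertions, engineer)
}

#' Apply a plan's designed reference edits
#'
#' Junction signatures such as a shared terminal triplet are guaranteed by
#' editing a handful of reference bases before the derivative is built.
#' Directives are deterministic: `set` writes literal bases, `differ` forces
#' the base at `pos` to differ from the (optionally complemented) base at
#' `other`.
#'
#' @param reference A `reference_genome` (or character scalar).
#' @param plan A `segment_plan` carrying `engineer` directives.
#' @return The edited `reference_genome`.
#' @export
engineer_reference <- function(reference, plan) {
  seq <- as_ref_seq(reference)
  for (d in plan$engineer %||% list()) {
    if (d$op == "set") {
      substr(seq, d$pos + 1L, d$pos + nchar(d$seq)) <- d$seq
    } else if (d$op == "differ") {
      other <- substr(seq, d$other + 1L, d$other + 1L)
      if (isTRUE(d$comp)) other <- chartr("ACGT", "TGCA", other)
      cur <- substr(seq, d$pos + 1L, d$pos + 1L)
      if (cur == other) {
        repl <- setdiff(c("A", "C", "G", "T"), c(other, cur))[1L]
        substr(seq, d$pos + 1L, d$pos + 1L) <- repl
      }
    } else {
      stop("unknown engineer directive: ", d$op, call. = FALSE)
    }
  }
  if (inherits(reference, "reference_genome")) {
    reference$sequence <- seq
    reference
  } else {
    structure(list(name = "chrS", sequence = seq, length = nchar(seq)),
              class = "reference_genome")
  }
}

resolve_insertion <- function(ins, ref_seq) {
  if (!is.null(ins$seq)) return(toupper(ins$seq))
  t <- ins$template
  s <- subseq0(ref_seq, t$start, t$end)
  if (identical(t$strand, "-")) s <- revcomp(s) else s
}

# Breakend at the junction-facing extremity of a piece.
piece_breakend <- function(piece, end_of_piece) {
  if (end_of_piece) {
    if (piece$strand == "+") list(coord = piece$end, orient = "+")
    else list(coord = piece$start, orient = "-")
  } else {
    if (piece$strand == "+") list(coord = piece$start, orient = "-")
    else list(coord = piece$end, orient = "+")
  }
}

#' Realize a derivative chromosome from a segment plan
#'
#' Concatenates the plan's oriented pieces (with junctional insertions
#' interposed) into the derivative sequence, and derives the truth set:
#' the novel breakpoint junctions (adjacencies absent from the reference),
#' the piecewise-constant integer copy-number profile (per-base piece
#' coverage), and the derivative length.
#'
#' @param reference A `reference_genome` or character scalar.
#' @param plan A `segment_plan`.  Apply [engineer_reference()] first if the
#'   plan carries engineered signatures.
#'
#' @return An object of class `derivative_genome`: list with `sequence`,
#'   `layout` (derivative-to-reference interval map), and `truth`, itself a
#'   list with `junctions` (data.frame: `name`, `coord_a`, `orient_a`,
#'   `coord_b`, `orient_b`, `insert`, `insert_len`, `inverted`),
#'   `copy_profile` (data.frame: `start`, `end`, `copy`) and
#'   `derivative_length`.
#' @examples
#' ref <- make_reference(2000, seed = 3)
#' plan <- segment_plan(data.frame(start = c(0, 500), end = c(1000, 1500),
#'                                 strand = c("+", "+")))
#' d <- build_derivative(ref, plan)
#' d$truth$junctions
#' @export
build_derivative <- function(reference, plan) {
  ref_seq <- as_ref_seq(reference)
  ref_len <- nchar(ref_seq)
  validate_plan(plan, ref_len)
  p <- plan$pieces
  n <- nrow(p)
  ins_after <- rep(list(NULL), n)
  for (ins in plan$insertions) ins_after[[ins$after]] <- ins

  seq_parts <- character(0)
  layout <- list()
  d <- 0
  for (i in seq_len(n)) {
    s <- subseq0(ref_seq, p$start[i], p$end[i])
    if (p$strand[i] == "-") s <- revcomp(s)
    w <- nchar(s)
    layout[[length(layout) + 1L]] <- data.frame(
      d_start = d, d_end = d + w, ref_start = p$start[i], ref_end = p$end[i],
      strand = p$strand[i], type = "piece", piece = i, stringsAsFactors = FALSE)
    seq_parts <- c(seq_parts, s)
    d <- d + w
    if (!is.null(ins_after[[i]])) {
      is_seq <- resolve_insertion(ins_after[[i]], ref_seq)
      wI <- nchar(is_seq)
      layout[[length(layout) + 1L]] <- data.frame(
        d_start = d, d_end = d + wI, ref_start = NA_real_, ref_end = NA_real_,
        strand = "+", type = "insert", piece = NA_integer_,
        stringsAsFactors = FALSE)
      seq_parts <- c(seq_parts, is_seq)
      d <- d + wI
    }
  }
  layout <- do.call(rbind, layout)
  derivative <- paste(seq_parts, collapse = "")

  # truth junctions: adjacencies between consecutive pieces not present in
  # the reference
  jx <- list()
  for (i in seq_len(n - 1L)) {
    a <- piece_breakend(p[i, ], end_of_piece = TRUE)
    b <- piece_breakend(p[i + 1L, ], end_of_piece = FALSE)
    ins <- ins_after[[i]]
    ref_adjacent <- is.null(ins) &&
      ((p$strand[i] == "+" && p$strand[i + 1L] == "+" && p$start[i + 1L] == p$end[i]) ||
       (p$strand[i] == "-" && p$strand[i + 1L] == "-" && p$end[i + 1L] == p$start[i]))
    if (ref_adjacent) next
    insert <- if (is.null(ins)) "" else resolve_insertion(ins, ref_seq)
    if (a$coord > b$coord) { tmp <- a; a <- b; b <- tmp }
    jx[[length(jx) + 1L]] <- data.frame(
      coord_a = a$coord, orient_a = a$orient,
      coord_b = b$coord, orient_b = b$orient,
      insert = insert, insert_len = nchar(insert),
      inverted = a$orient == b$orient, stringsAsFactors = FALSE)
  }
  junctions <- if (length(jx)) do.call(rbind, jx) else
    data.frame(coord_a = numeric(0), orient_a = character(0),
               coord_b = numeric(0), orient_b = character(0),
               insert = character(0), insert_len = integer(0),
               inverted = logical(0), stringsAsFactors = FALSE)
  if (nrow(junctions)) {
    junctions <- junctions[order(junctions$coord_a, junctions$coord_b), , drop = FALSE]
    junctions <- cbind(name = sprintf("jx%d", seq_len(nrow(junctions))), junctions,
                       stringsAsFactors = FALSE)
    rownames(junctions) <- NULL
  } else {
    junctions <- cbind(name = character(0), junctions)
  }

  truth <- list(
    junctions = junctions,
    copy_profile = piece_copy_profile(p, ref_len),
    derivative_length = nchar(derivative)
  )
  structure(list(name = "derivative", sequence = derivative,
                 layout = layout, truth = truth, plan = plan),
            class = "derivative_genome")
}

# Per-base piece coverage as a piecewise-constant profile.
piece_copy_profile <- function(pieces, ref_len) {
  bounds <- sort(unique(c(0, ref_len, pieces$start, pieces$end)))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L]
  copy <- vapply(seq_along(starts), function(i) {
    sum(pieces$start <= starts[i] & pieces$end >= ends[i])
  }, numeric(1))
  prof <- data.frame(start = starts, end = ends, copy = copy)
  # merge adjacent equal states
  keep <- c(TRUE, diff(prof$copy) != 0)
  grp <- cumsum(keep)
  data.frame(start = tapply(prof$start, grp, min),
             end = tapply(prof$end, grp, max),
             copy = tapply(prof$copy, grp, function(x) x[1]),
             row.names = NULL)
}

#' @export
print.derivative_genome <- function(x, ...) {
  cat(sprintf("<derivative_genome> %s bp, %d truth junctions\n",
              format(x$truth$derivative_length, big.mark = ","),
              nrow(x$truth$junctions)))
  invisible(x)
}

#' Build the default CGR scenario end to end
#'
#' Convenience wrapper: generates a reference, applies the default plan's
#' engineered edits, and realizes the derivative.
#'
#' @param length Reference length in bases.
#' @param scale Plan scale, see [default_dpdp667_plan()].
#' @param gc_fraction,seed Passed to [make_reference()].
#' @param triplicated Passed to [default_dpdp667_plan()].
#' @return List with `reference`, `plan`, `derivative`.
#' @export
cgr_scenario <- function(length = 5e6, scale = 1, gc_fraction = 0.36,
                         seed = 1, triplicated = "28kb") {
  ref <- make_reference(length, gc_fraction, seed)
  plan <- default_dpdp667_plan(length, scale, triplicated)
  ref <- engineer_reference(ref, plan)
  list(reference = ref, plan = plan,
       derivative = build_derivative(ref, plan))
}
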