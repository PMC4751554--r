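# Segment-graph reconstruction: integrate copy segments and junctions,
# enumerate derivative-chromosome walks, classify the rearrangement.

#' Build a segment graph from copy segments and junctions
#'
#' The reference is partitioned at every junction breakend; each resulting
#' segment receives an integer copy number, and junctions become novel
#' adjacencies between segment ends.  Copy numbers are transferred from the
#' windowed segmentation by majority overlap; segments smaller than the
#' segmentation's resolution (`refine_below`) are re-estimated from a direct
#' test/control read-count ratio over the exact interval when alignments
#' are supplied -- the segment-level analog of shrinking the counting
#' interval to localize a feature the windowed view cannot resolve.
#' Segments smaller than `min_direct` inherit the overlap copy (interval
#' counts too noisy).  Each copy-state change boundary in the input
#' segmentation is matched to a junction breakend within `tolerance`;
#' unmatched boundaries are recorded as inconsistencies (data, not errors).
#'
#' @param cn_segments `cn_segments` from [call_cn_segments()] (edges ideally
#'   refined with [refine_breakpoint()]).
#' @param junctions `junction_calls` (or truth junction) table.
#' @param tolerance Match distance in bases between a copy-number boundary
#'   and a junction breakend (default 400, twice the finest default
#'   refinement window).
#' @param test,control Optional alignment tables enabling sub-resolution
#'   copy re-estimation.
#' @param refine_below Segments narrower than this get direct re-estimation.
#' @param min_direct Narrowest segment re-estimated directly.
#' @return Object of class `segment_graph`: list with `segments`
#'   (data.frame `id`, `start`, `end`, `copy`), `novel_adjacencies`
#'   (data.frame with endpoint segment ids and sides), `reference_adjacencies`,
#'   `inconsistencies` (unmatched boundaries), and `baseline`.
#' @export
build_segment_graph <- function(cn_segments, junctions, tolerance = 400,
                                test = NULL, control = NULL,
                                refine_below = 10000, min_direct = 500) {
  region <- c(min(cn_segments$start), max(cn_segments$end))
  bks <- sort(unique(c(junctions$coord_a, junctions$coord_b)))
  bks <- bks[bks > region[1] & bks < region[2]]
  cuts <- c(region[1], bks, region[2])
  seg <- data.frame(start = cuts[-length(cuts)], end = cuts[-1])
  seg$id <- sprintf("S%d", seq_len(nrow(seg)))

  # majority-overlap copy transfer
  seg$copy <- vapply(seq_len(nrow(seg)), function(i) {
    ov <- pmin(seg$end[i], cn_segments$end) - pmax(seg$start[i], cn_segments$start)
    cn_segments$state[which.max(ov)]
  }, numeric(1))
  baseline <- attr(cn_segments, "baseline") %||% 1

  if (!is.null(test) && !is.null(control)) {
    test <- as_alignments(test); control <- as_alignments(control)
    drop <- SAM_FLAG["unmapped"] + SAM_FLAG["secondary"] +
      SAM_FLAG["dup"] + SAM_FLAG["supplementary"]
    pt <- test$pos[bitwAnd(test$flag, drop) == 0L] - 1L
    pc <- control$pos[bitwAnd(control$flag, drop) == 0L] - 1L
    nt <- length(pt); nc <- length(pc)
    small <- which(seg$end - seg$start < refine_below &
                     seg$end - seg$start >= min_direct)
    for (i in small) {
      ct <- sum(pt >= seg$start[i] & pt < seg$end[i])
      cc <- sum(pc >= seg$start[i] & pc < seg$end[i])
      if (cc > 0) {
        seg$copy[i] <- max(0, round(((ct / nt) / (cc / nc)) / baseline))
      }
    }
  }

  # junction breakend -> (segment, side)
  endpoint <- function(coord, orient) {
    if (orient == "+") {
      i <- match(coord, seg$end)
      if (is.na(i)) return(NULL)
      list(seg = i, side = "R")
    } else {
      i <- match(coord, seg$start)
      if (is.na(i)) return(NULL)
      list(seg = i, side = "L")
    }
  }
  novel <- list()
  for (k in seq_len(nrow(junctions))) {
    ea <- endpoint(junctions$coord_a[k], junctions$orient_a[k])
    eb <- endpoint(junctions$coord_b[k], junctions$orient_b[k])
    if (is.null(ea) || is.null(eb)) next
    novel[[length(novel) + 1L]] <- data.frame(
      name = junctions$name[k],
      seg_a = ea$seg, side_a = ea$side, seg_b = eb$seg, side_b = eb$side,
      stringsAsFactors = FALSE)
  }
  novel <- if (length(novel)) do.call(rbind, novel) else
    data.frame(name = character(0), seg_a = integer(0), side_a = character(0),
               seg_b = integer(0), side_b = character(0))

  ref_adj <- if (nrow(seg) > 1L) {
    data.frame(seg_a = seq_len(nrow(seg) - 1L), side_a = "R",
               seg_b = 2:nrow(seg), side_b = "L")
  } else data.frame(seg_a = integer(0), side_a = character(0),
                    seg_b = integer(0), side_b = character(0))

  # CN state-change boundaries must be explained by a junction breakend
  cn_bounds <- cn_segments$end[-nrow(cn_segments)]
  cn_bounds <- cn_bounds[diff(cn_segments$state) != 0]
  unmatched <- cn_bounds[vapply(cn_bounds, function(bd) {
    !length(bks) || min(abs(bks - bd)) > tolerance
  }, logical(1))]

  structure(list(segments = seg[, c("id", "start", "end", "copy")],
                 novel_adjacencies = novel,
                 reference_adjacencies = ref_adj,
                 inconsistencies = unmatched,
                 baseline = baseline),
            class = "segment_graph")
}

#' @export
print.segment_graph <- function(x, ...) {
  cat(sprintf("<segment_graph> %d segments, %d novel adjacencies, %d inconsistencies\n",
              nrow(x$segments), nrow(x$novel_adjacencies),
              length(x$inconsistencies)))
  print(x$segments)
  invisible(x)
}

# All adjacencies as endpoint pairs; an endpoint is (segment, side).
graph_adjacencies <- function(graph) {
  a <- graph$reference_adjacencies[, c("seg_a", "side_a", "seg_b", "side_b")]
  a$novel <- rep(FALSE, nrow(a)); a$name <- rep("ref", nrow(a))
  b <- graph$novel_adjacencies[, c("seg_a", "side_a", "seg_b", "side_b")]
  b$novel <- rep(TRUE, nrow(b)); b$name <- graph$novel_adjacencies$name
  rbind(a, b)
}

#' Enumerate candidate derivative-chromosome walks
#'
#' Backtracking enumeration of linear walks over the segment graph in which
#' every segment is traversed exactly its copy-number times
#' (orientation-aware: a `+` traversal enters at the left end and exits at
#' the right, a `-` traversal the reverse) and every novel adjacency is used
#' at least once.  Reference adjacencies may be reused freely; a walk may
#' also traverse a novel adjacency more than once, as repeated copies of a
#' junction region require.  Walks identical to the reverse complement of an
#' earlier walk are not reported twice.  The reference-collinear
#' continuation is explored first, so the collinear walk (when valid) heads
#' the list.
#'
#' @param graph A `segment_graph`.
#' @param max_walks Maximum number of walks returned (>= 1).
#' @param max_states Exploration budget; hitting it sets the `truncated`
#'   attribute.
#' @return List of walks, each a character vector like `c("S1+", "S2+")`.
#'   Attributes: `truncated` (logical), `diagnostic` (character, set when no
#'   walk exists, e.g. copy numbers unbalanced against adjacencies).
#' @export
enumerate_derivatives <- function(graph, max_walks = 1000, max_states = 1e6) {
  if (max_walks < 1) stop("`max_walks` must be >= 1", call. = FALSE)
  seg <- graph$segments
  copies <- as.integer(seg$copy)
  n <- nrow(seg)
  adj <- graph_adjacencies(graph)
  total <- sum(copies)
  walks <- list()
  truncated <- FALSE
  if (total == 0L) {
    attr(walks, "truncated") <- FALSE
    attr(walks, "diagnostic") <- "all segments have copy number zero"
    return(walks)
  }
  # adjacency lookup: from an exit endpoint to candidate (segment, entry side)
  moves_from <- function(si, side) {
    out <- list()
    seen <- character(0)
    add <- function(seg, sd, novel, id) {
      key <- paste(seg, sd, id)
      if (key %in% seen) return()
      seen <<- c(seen, key)
      out[[length(out) + 1L]] <<- list(seg = seg, side = sd,
                                       novel = novel, id = id)
    }
    for (r in seq_len(nrow(adj))) {
      if (adj$seg_a[r] == si && adj$side_a[r] == side) {
        add(adj$seg_b[r], adj$side_b[r], adj$novel[r], r)
      }
      # an adjacency whose two endpoints coincide (a fold-back self-loop)
      # must contribute a single move, not one per matching clause
      if (adj$seg_b[r] == si && adj$side_b[r] == side) {
        add(adj$seg_a[r], adj$side_a[r], adj$novel[r], r)
      }
    }
    out
  }
  # precompute move lists for each endpoint, collinear continuation first
  moves <- list()
  for (si in seq_len(n)) for (side in c("L", "R")) {
    mv <- moves_from(si, side)
    if (length(mv) > 1L) {
      pref <- vapply(mv, function(m) !m$novel, logical(1))
      mv <- c(mv[pref], mv[!pref])
    }
    moves[[paste0(si, side)]] <- mv
  }
  novel_ids <- which(adj$novel)
  states <- 0L

  rec <- function(remaining, cur_seg, cur_orient, used_novel, walk) {
    if (truncated || length(walks) >= max_walks) { truncated <<- TRUE; return() }
    states <<- states + 1L
    if (states > max_states) { truncated <<- TRUE; return() }
    if (all(remaining == 0L)) {
      if (all(novel_ids %in% used_novel)) {
        wfwd <- walk
        wrev <- rev(vapply(strsplit(walk, ""), function(ch) {
          paste0(paste(ch[-length(ch)], collapse = ""),
                 if (ch[length(ch)] == "+") "-" else "+")
        }, character(1)))
        if (paste(wfwd, collapse = " ") <= paste(wrev, collapse = " ")) {
          walks[[length(walks) + 1L]] <<- wfwd
        }
      }
      return()
    }
    exit_side <- if (cur_orient == "+") "R" else "L"
    for (m in moves[[paste0(cur_seg, exit_side)]]) {
      if (remaining[m$seg] == 0L) next
      orient <- if (m$side == "L") "+" else "-"
      remaining[m$seg] <- remaining[m$seg] - 1L
      rec(remaining, m$seg, orient,
          if (m$novel) union(used_novel, m$id) else used_novel,
          c(walk, paste0(seg$id[m$seg], orient)))
      remaining[m$seg] <- remaining[m$seg] + 1L
    }
  }

  # any nonzero segment may start the walk, in either orientation; the
  # collinear start (first segment, forward) is explored first
  starts <- which(copies > 0L)
  for (si in starts) {
    for (orient in c("+", "-")) {
      remaining <- copies
      remaining[si] <- remaining[si] - 1L
      rec(remaining, si, orient, integer(0), paste0(seg$id[si], orient))
    }
  }
  attr(walks, "truncated") <- truncated
  if (!length(walks) && !truncated) {
    attr(walks, "diagnostic") <-
      "no walk realizes the copy numbers with the available adjacencies (unbalanced)"
  }
  walks
}

#' Verify a walk against a graph's copy numbers
#'
#' @param graph A `segment_graph`.
#' @param walk Character vector of oriented segments (e.g. `"S2+"`).
#' @return TRUE when the multiset of traversed segments equals the graph's
#'   copy-number vector.
#' @export
walk_is_balanced <- function(graph, walk) {
  ids <- sub("[+-]$", "", walk)
  tab <- table(factor(ids, levels = graph$segments$id))
  all(as.integer(tab) == as.integer(graph$segments$copy))
}

#' Classify a rearrangement from its graph and junction signatures
#'
#' Deterministic rule table over the evidence:
#' \itemize{
#'   \item at most one junction: `"simple"`;
#'   \item no lost segments, at least one gained segment, and at least half
#'     of the junctions carrying microhomology (>= `mh_min` bases) or a
#'     templated insertion: `"chromoanasynthesis-like"`;
#'   \item lost segments interleaved with retained ones (at least
#'     `min_alternations` state alternations) and a homology fraction below
#'     one half: `"chromothripsis-like"`;
#'   \item anything else: `"unclassified"`.
#' }
#'
#' @param graph A `segment_graph`.
#' @param signatures `data.frame` with one row per novel adjacency (same
#'   order), with columns `microhomology_len`, `templated`.
#' @param mh_min Minimum microhomology length counted as homology evidence.
#' @param feature_frac Junction fraction threshold (default 0.5).
#' @param min_alternations Minimum 0-state alternations for the
#'   chromothripsis call.
#' @return Object of class `cgr_classification`: list with `label` and
#'   `evidence`.
#' @export
classify_cgr <- function(graph, signatures, mh_min = 2, feature_frac = 0.5,
                         min_alternations = 2) {
  nj <- nrow(graph$novel_adjacencies)
  if (nj > 0) {
    if (is.null(signatures) || nrow(signatures) < nj ||
        any(is.na(signatures$microhomology_len)) || any(is.na(signatures$templated))) {
      stop("a junction signature is required for every novel adjacency",
           call. = FALSE)
    }
  }
  st <- graph$segments$copy
  gains_present <- any(st >= 2)
  deletions_present <- any(st == 0)
  zero_flag <- rle(as.integer(st == 0))$values
  alternations <- max(0L, length(zero_flag) - 1L)
  feat <- if (nj > 0) {
    signatures$microhomology_len[seq_len(nj)] >= mh_min |
      signatures$templated[seq_len(nj)]
  } else logical(0)
  mh_fraction <- if (nj > 0) mean(feat) else NA_real_
  templated_count <- if (nj > 0) sum(signatures$templated[seq_len(nj)]) else 0L

  label <- if (nj <= 1) "simple"
  else if (!deletions_present && gains_present && isTRUE(mh_fraction >= feature_frac))
    "chromoanasynthesis-like"
  else if (deletions_present && alternations >= min_alternations &&
           isTRUE(mh_fraction < feature_frac))
    "chromothripsis-like"
  else "unclassified"

  structure(list(
    label = label,
    evidence = list(gains_present = gains_present,
                    deletions_present = deletions_present,
                    oscillating_states = alternations,
                    junction_count = nj,
                    microhomology_fraction = mh_fraction,
                    templated_insertion_count = as.integer(templated_count))),
    class = "cgr_classification")
}

#' @export
print.cgr_classification <- function(x, ...) {
  cat(sprintf("<cgr_classification> %s\n", x$label))
  ev <- x$evidence
  cat(sprintf("  junctions: %d | gains: %s | deletions: %s | alternations: %d\n",
              ev$junction_count, ev$gains_present, ev$deletions_present,
              ev$oscillating_states))
  cat(sprintf("  homology/templated fraction: %s | templated insertions: %d\n",
              format(ev$microhomology_fraction), ev$templated_insertion_count))
  invisible(x)
}
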