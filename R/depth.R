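# Read-depth copy-number estimation: windowed counts, library-rescaled
# test/control ratios, integer state segmentation, and multi-resolution
# breakpoint refinement.

#' Count reads per genomic window
#'
#' Each primary, mapped, non-duplicate alignment with mapping quality at or
#' above `min_mapq` is assigned to exactly one window: the window containing
#' its leftmost aligned base.  Secondary and supplementary records are
#' excluded so split reads are counted once.
#'
#' @param alignments A `cgr_alignments` table or SAM file path.
#' @param window_size Window width in bases (>= 100).
#' @param reference_length Total reference length; defaults to the
#'   alignment table's attribute.
#' @param min_mapq Minimum mapping quality (default 1).
#'
#' @return Object of class `window_counts`: list with `window_size`,
#'   `counts` (integer vector, one per window), `total_aligned` and
#'   `reference_length`.
#' @export
window_counts <- function(alignments, window_size = 10000,
                          reference_length = NULL, min_mapq = 1) {
  if (window_size < 100) {
    stop("`window_size` < 100 unsupported (sub-read-length windows)", call. = FALSE)
  }
  aln <- as_alignments(alignments)
  reference_length <- reference_length %||% attr(aln, "reference_length")
  if (is.null(reference_length)) stop("`reference_length` required", call. = FALSE)
  nwin <- ceiling(reference_length / window_size)
  drop <- SAM_FLAG["unmapped"] + SAM_FLAG["secondary"] +
    SAM_FLAG["dup"] + SAM_FLAG["supplementary"]
  keep <- bitwAnd(aln$flag, drop) == 0L & aln$mapq >= min_mapq
  win <- (aln$pos[keep] - 1L) %/% window_size + 1L
  counts <- tabulate(win, nbins = nwin)
  structure(list(window_size = as.integer(window_size),
                 counts = as.integer(counts),
                 total_aligned = sum(counts),
                 reference_length = reference_length),
            class = "window_counts")
}

#' @export
print.window_counts <- function(x, ...) {
  cat(sprintf("<window_counts> %d windows of %d bp, %s reads\n",
              length(x$counts), x$window_size,
              format(x$total_aligned, big.mark = ",")))
  invisible(x)
}

#' Normalized test/control depth-ratio track
#'
#' Per-window copy-number ratio: test and control counts are rescaled to a
#' common total number of aligned reads per library before division,
#' `r_i = (c_test_i / N_test) / (c_ctrl_i / N_ctrl)`.  Windows with zero
#' control reads are masked (never infinite).
#'
#' @param test,control `window_counts` on the same window grid.
#' @return Object of class `ratio_track`: list with `window_size`, `ratios`
#'   (NA where masked), `masked` (logical), `mask_reason`, plus the two
#'   library totals.
#' @export
depth_ratio <- function(test, control) {
  stopifnot(inherits(test, "window_counts"), inherits(control, "window_counts"))
  if (test$window_size != control$window_size ||
      length(test$counts) != length(control$counts)) {
    stop("test and control window grids differ", call. = FALSE)
  }
  masked <- control$counts == 0L
  ratios <- rep(NA_real_, length(test$counts))
  ratios[!masked] <- (test$counts[!masked] / test$total_aligned) /
    (control$counts[!masked] / control$total_aligned)
  structure(list(window_size = test$window_size, ratios = ratios,
                 masked = masked,
                 mask_reason = ifelse(masked, "control_zero", ""),
                 n_test = test$total_aligned, n_control = control$total_aligned,
                 control_counts = control$counts,
                 reference_length = test$reference_length),
            class = "ratio_track")
}

#' @export
print.ratio_track <- function(x, ...) {
  cat(sprintf("<ratio_track> %d windows of %d bp (%d masked)\n",
              length(x$ratios), x$window_size, sum(x$masked)))
  invisible(x)
}

#' Segment a ratio track into integer copy states
#'
#' Ratios are smoothed with a running median (halfwidth
#' `smoothing_halfwidth` windows), each window gets the nearest-integer
#' copy state, adjacent same-state windows are merged, and segments shorter
#' than `min_segment` windows are absorbed into the flanking segment whose
#' mean ratio is closer.  Masked windows carry no state of their own; a run
#' of unmasked windows continues across them.
#'
#' States are assigned relative to the copy-number lattice rather than by
#' rounding the raw ratio: the lattice unit (the ratio corresponding to one
#' copy) is estimated by a grid search minimizing the distance of the
#' smoothed ratios to an integer lattice, and each window's state is
#' `round(ratio / unit)`.  When the analyzed region is mostly copy-neutral
#' the unit is ~1 and this reduces to plain rounding; unlike plain rounding
#' it remains correct when gained sequence occupies a large fraction of the
#' analyzed region, which depresses all library-rescaled ratios by the mean
#' copy number.  The estimated unit is returned as attribute `baseline`.
#'
#' @param track A `ratio_track`.
#' @param smoothing_halfwidth Running-median halfwidth in windows.
#' @param min_segment Minimum segment length in windows.
#' @return `data.frame` of class `cn_segments`: `start`, `end` (0-based
#'   half-open reference coordinates), `state`, `mean_ratio`, `n_windows`.
#' @export
call_cn_segments <- function(track, smoothing_halfwidth = 2, min_segment = 3) {
  stopifnot(inherits(track, "ratio_track"))
  ok <- which(!track$masked)
  if (!length(ok)) stop("all windows are masked", call. = FALSE)
  r <- track$ratios[ok]
  k <- 2L * as.integer(smoothing_halfwidth) + 1L
  sm <- if (length(r) >= k && k > 1L) stats::runmed(r, k, endrule = "median") else r
  unit <- lattice_unit(sm)
  state <- pmax(0L, as.integer(round(sm / unit)))

  # run-length segments over the unmasked windows
  runs <- rle(state)
  seg <- data.frame(first = cumsum(c(1L, runs$lengths[-length(runs$lengths)])),
                    n = runs$lengths, state = runs$values)
  seg$mean <- vapply(seq_len(nrow(seg)), function(i) {
    mean(r[seg$first[i]:(seg$first[i] + seg$n[i] - 1L)])
  }, numeric(1))

  # absorb short segments into the flank with the closer mean ratio
  repeat {
    short <- which(seg$n < min_segment)
    if (!length(short) || nrow(seg) == 1L) break
    i <- short[which.min(seg$n[short])]
    left <- if (i > 1L) abs(seg$mean[i] - seg$mean[i - 1L]) else Inf
    right <- if (i < nrow(seg)) abs(seg$mean[i] - seg$mean[i + 1L]) else Inf
    into <- if (left <= right) i - 1L else i + 1L
    lo <- min(i, into); hi <- max(i, into)
    seg$n[lo] <- seg$n[lo] + seg$n[hi]
    w <- r[seg$first[lo]:(seg$first[lo] + seg$n[lo] - 1L)]
    seg$mean[lo] <- mean(w)
    seg$state[lo] <- seg$state[into]
    seg <- seg[-hi, , drop = FALSE]
    # re-merge neighbours that now share a state
    j <- 1L
    while (j < nrow(seg)) {
      if (seg$state[j] == seg$state[j + 1L]) {
        seg$n[j] <- seg$n[j] + seg$n[j + 1L]
        seg$mean[j] <- mean(r[seg$first[j]:(seg$first[j] + seg$n[j] - 1L)])
        seg <- seg[-(j + 1L), , drop = FALSE]
      } else j <- j + 1L
    }
  }

  w <- track$window_size
  # segment bounds in reference coordinates, spanning any interior masked
  # windows; outer bounds clipped to the analyzed extent
  first_w <- ok[seg$first]
  last_w <- ok[seg$first + seg$n - 1L]
  out <- data.frame(
    start = (first_w - 1L) * as.numeric(w),
    end = pmin(as.numeric(track$reference_length), last_w * as.numeric(w)),
    state = as.integer(seg$state),
    mean_ratio = seg$mean,
    n_windows = as.integer(seg$n))
  # make the tiling exact: extend the first/last segment over edge windows
  out$start[1] <- 0
  out$end[nrow(out)] <- as.numeric(track$reference_length)
  for (i in seq_len(nrow(out) - 1L)) out$end[i] <- out$start[i + 1L]
  class(out) <- c("cn_segments", "data.frame")
  attr(out, "baseline") <- unit
  out
}

# Copy-lattice unit: the ratio value corresponding to one copy.  Grid search
# around the median ratio for the scale under which the smoothed ratios sit
# closest to an integer lattice (truncated absolute loss, so off-lattice
# windows cannot dominate).  Noise measured in lattice units shrinks as the
# unit grows, so the largest near-optimal unit is preferred automatically;
# exact ties (noise-free tracks) also resolve to the largest unit.
lattice_unit <- function(r) {
  r <- r[is.finite(r)]
  med <- stats::median(r)
  if (!is.finite(med) || med <= 0) return(1)
  grid <- med * seq(0.4, 1.6, by = 0.005)
  score <- vapply(grid, function(a) {
    z <- r / a
    mean(pmin(abs(z - round(z)), 0.25))
  }, numeric(1))
  best <- min(score)
  max(grid[score <= best + 1e-9])
}

# Windowed ratio over an arbitrary interval at an arbitrary scale, used by
# the refinement search.  Counts leftmost-base assignments like
# window_counts() but without the >=100 bp floor (refinement legitimately
# probes below read length).
local_ratio <- function(test, control, start0, end0, w,
                        n_test, n_control, min_mapq = 1) {
  edges <- seq(start0, end0, by = w)
  if (length(edges) < 3L) return(NULL)
  cnt <- function(aln) {
    drop <- SAM_FLAG["unmapped"] + SAM_FLAG["secondary"] +
      SAM_FLAG["dup"] + SAM_FLAG["supplementary"]
    keep <- bitwAnd(aln$flag, drop) == 0L & aln$mapq >= min_mapq &
      aln$pos > start0 & aln$pos <= edges[length(edges)]
    p <- aln$pos[keep] - 1L
    tabulate(findInterval(p, edges), nbins = length(edges) - 1L)
  }
  ct <- cnt(test); cc <- cnt(control)
  ratio <- ifelse(cc > 0, (ct / n_test) / (cc / n_control), NA_real_)
  list(edges = edges, ratio = ratio)
}

#' Refine a copy-state boundary by multi-resolution re-windowing
#'
#' Around an approximate copy-state change, ratios are recomputed in
#' progressively smaller windows; at each scale the boundary is relocated
#' to the largest jump between adjacent windows.  The returned interval has
#' width twice the smallest scheduled window and contains the transition.
#'
#' @param test,control Alignment tables (or SAM paths) for the two samples.
#' @param boundary Approximate boundary (0-based reference coordinate),
#'   typically a [call_cn_segments()] segment edge.
#' @param window_schedule Strictly decreasing window sizes in bases.
#' @param min_jump Minimum adjacent-window ratio jump regarded as a
#'   transition; below this the search stops with an error.
#' @param direction Optional expected sign of the transition (`+1` if the
#'   ratio increases left to right, `-1` if it decreases), known to callers
#'   refining a segmentation edge.  Restricting the sign keeps the search
#'   from locking onto the opposite edge of a segment only a few windows
#'   wide.  `NULL` considers both signs.
#' @param min_mapq Minimum mapping quality for counted reads.
#' @return List with `boundary` (refined point estimate), `interval`
#'   (c(start, end), 0-based) and `jump` (ratio change at the transition).
#' @export
refine_breakpoint <- function(test, control, boundary,
                              window_schedule = c(10000, 1000, 200),
                              min_jump = 0.4, direction = NULL,
                              min_mapq = 1) {
  if (any(diff(window_schedule) >= 0)) {
    stop("`window_schedule` must be strictly decreasing", call. = FALSE)
  }
  test <- as_alignments(test); control <- as_alignments(control)
  n_test <- sum(bitwAnd(test$flag, 2304L) == 0L)
  n_control <- sum(bitwAnd(control$flag, 2304L) == 0L)
  b <- boundary
  prev_w <- NA_real_
  jump <- NA_real_
  m <- 2L   # flank width (windows) for the local step contrast
  for (w in window_schedule) {
    # search range covers the incoming uncertainty (about one window of the
    # previous scale); the flanks extend m windows beyond it.  Keeping the
    # contrast local stops a neighbouring true transition of a
    # few-windows-wide segment from hijacking the relocation.
    search <- if (is.na(prev_w)) 2 * w else 1.2 * prev_w
    half <- search + m * w
    lr <- local_ratio(test, control, max(0, b - half), b + half, w,
                      n_test, n_control, min_mapq)
    if (is.null(lr)) next
    r <- lr$ratio
    n <- length(r)
    if (all(is.na(r)) || n < 2L * m) stop("no transition found", call. = FALSE)
    first_scale <- is.na(prev_w)
    js <- (m + 1L):(n - m + 1L)
    js <- js[abs(lr$edges[js] - b) <= search + w / 2]
    if (!length(js)) {
      if (first_scale) stop("no transition found", call. = FALSE)
      next
    }
    contrast <- vapply(js, function(j) {
      mean(r[j:(j + m - 1L)], na.rm = TRUE) -
        mean(r[(j - m):(j - 1L)], na.rm = TRUE)
    }, numeric(1))
    if (!is.null(direction)) {
      keep <- sign(contrast) == sign(direction)
      js <- js[keep]; contrast <- contrast[keep]
      if (!length(js)) {
        if (first_scale) stop("no transition found", call. = FALSE)
        next
      }
    }
    contrast <- abs(contrast)
    cmax <- max(contrast, na.rm = TRUE)
    # the transition is certified at the coarsest scale, where window counts
    # give high signal-to-noise; finer scales only relocate it
    if (first_scale && (!is.finite(cmax) || cmax < min_jump)) {
      stop("no transition found", call. = FALSE)
    }
    # among near-maximal contrasts, stay closest to the incoming estimate
    cand <- js[contrast >= 0.8 * cmax]
    j <- cand[which.min(abs(lr$edges[cand] - b))]
    jump <- contrast[match(j, js)]
    b <- lr$edges[j]
    prev_w <- w
  }
  wmin <- window_schedule[length(window_schedule)]
  b <- polish_changepoint(test, b, 4 * wmin)
  list(boundary = b, interval = c(b - wmin, b + wmin), jump = unname(jump))
}

# Terminal polish: unbinned maximum-likelihood changepoint for a
# piecewise-constant Poisson rate of test read starts around the windowed
# estimate.  The simulator's control coverage is locally flat, so the test
# sample alone carries the transition; read-start resolution beats any
# window grid.
polish_changepoint <- function(test, b, half) {
  drop <- SAM_FLAG["unmapped"] + SAM_FLAG["secondary"] +
    SAM_FLAG["dup"] + SAM_FLAG["supplementary"]
  keep <- bitwAnd(test$flag, drop) == 0L
  p <- sort(test$pos[keep] - 1L)
  L <- b - half; R <- b + half
  s <- p[p >= L & p < R]
  if (length(s) < 10L) return(b)
  cand <- unique(s)
  n <- length(s)
  lo <- function(x) ifelse(x > 0, x * log(x), 0)
  ll <- vapply(cand, function(tau) {
    n1 <- sum(s < tau); n2 <- n - n1
    w1 <- tau - L; w2 <- R - tau
    if (w1 <= 0 || w2 <= 0) return(-Inf)
    lo(n1) - n1 * log(w1) + lo(n2) - n2 * log(w2)
  }, numeric(1))
  cand[which.max(ll)]
}
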