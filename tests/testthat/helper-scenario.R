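# Shared fixtures, built in code and cached for the session.
#
# The miniature scenario is the full default rearrangement geometry scaled
# by 1/20 (reference 250 kb), so windowed views at 500 bp reproduce the
# window-boundary geometry of 10 kb windows at full scale.  Per-window
# counts in the miniature are noisier than at full scale, so depth tests
# that depend on per-window rounding use higher coverage.

.cache <- new.env(parent = emptyenv())

cache_get <- function(key, make) {
  if (!exists(key, envir = .cache)) assign(key, make(), envir = .cache)
  get(key, envir = .cache)
}

mini_scenario <- function() {
  cache_get("mini_scenario", function() {
    cgr_scenario(length = 250000, scale = 0.05, seed = 7)
  })
}

# test + control truth alignments for the miniature scenario
mini_alignments <- function(coverage = 30, seed = 1) {
  key <- sprintf("mini_aln_%d_%d", coverage, seed)
  cache_get(key, function() {
    sc <- mini_scenario()
    mut <- simulate_reads(sc$derivative, coverage = coverage,
                          error_rate = 0.005, seed = 100 + seed,
                          sample_name = "mut")
    ctl <- simulate_reads(sc$reference, coverage = coverage,
                          error_rate = 0.005, seed = 200 + seed,
                          sample_name = "ctl")
    list(test = emit_truth_alignments(mut, sc$derivative),
         control = emit_truth_alignments(ctl, sc$reference),
         mut_reads = mut, ctl_reads = ctl)
  })
}

mini_junctions <- function(coverage = 30, seed = 1) {
  key <- sprintf("mini_jx_%d_%d", coverage, seed)
  cache_get(key, function() {
    sc <- mini_scenario()
    al <- mini_alignments(coverage, seed)
    cl <- collect_clip_clusters(al$test)
    jx <- call_junctions(cl, sc$reference, min_support = 3,
                         control_clusters = collect_clip_clusters(al$control))
    list(clusters = cl, junctions = jx)
  })
}

# truth breakend coordinates of the miniature scenario, as (coord, side)
mini_truth_breakends <- function() {
  tj <- mini_scenario()$derivative$truth$junctions
  unique(rbind(
    data.frame(coord = tj$coord_a, orient = tj$orient_a),
    data.frame(coord = tj$coord_b, orient = tj$orient_b)))
}

# the full-scale pipeline run used by the acceptance checks (computed once)
acceptance_run <- function() {
  cache_get("acceptance_run", function() {
    run_all(chromo_config(seed = 20150667))
  })
}

# hand-constructed segment graph
make_graph <- function(copies, novel = NULL, width = 100) {
  n <- length(copies)
  seg <- data.frame(id = sprintf("S%d", seq_len(n)),
                    start = (seq_len(n) - 1) * width,
                    end = seq_len(n) * width, copy = copies)
  if (is.null(novel)) {
    novel <- data.frame(name = character(0), seg_a = integer(0),
                        side_a = character(0), seg_b = integer(0),
                        side_b = character(0))
  }
  ref <- if (n > 1) data.frame(seg_a = seq_len(n - 1), side_a = "R",
                               seg_b = 2:n, side_b = "L")
         else data.frame(seg_a = integer(0), side_a = character(0),
                         seg_b = integer(0), side_b = character(0))
  structure(list(segments = seg, novel_adjacencies = novel,
                 reference_adjacencies = ref, inconsistencies = numeric(0),
                 baseline = 1), class = "segment_graph")
}

# Brute-force oracle for walk enumeration: exhaustively generates every
# ordering (with orientations) of the segment multiset and keeps those
# whose consecutive pairs are connected by an available adjacency and that
# use every novel adjacency; reverse-complement duplicates removed.
oracle_walks <- function(graph) {
  seg <- graph$segments
  copies <- as.integer(seg$copy)
  items <- rep(seq_len(nrow(seg)), copies)
  adj <- chromoscout:::graph_adjacencies(graph)
  connects <- function(s1, o1, s2, o2) {
    e1 <- c(s1, if (o1 == "+") "R" else "L")
    e2 <- c(s2, if (o2 == "+") "L" else "R")
    hit <- (adj$seg_a == e1[1] & adj$side_a == e1[2] &
              adj$seg_b == e2[1] & adj$side_b == e2[2]) |
           (adj$seg_b == e1[1] & adj$side_b == e1[2] &
              adj$seg_a == e2[1] & adj$side_a == e2[2])
    which(hit)
  }
  perms <- function(x) {
    if (length(x) <= 1) return(list(x))
    out <- list()
    for (v in unique(x)) {
      rest <- x[-match(v, x)]
      for (p in perms(rest)) out[[length(out) + 1]] <- c(v, p)
    }
    out
  }
  novel_rows <- which(adj$novel)
  found <- character(0)
  for (p in perms(items)) {
    k <- length(p)
    for (mask in 0:(2^k - 1)) {
      orients <- ifelse(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0, "-", "+")
      ok <- TRUE; used <- integer(0)
      for (i in seq_len(k - 1)) {
        hit <- connects(p[i], orients[i], p[i + 1], orients[i + 1])
        if (!length(hit)) { ok <- FALSE; break }
        used <- union(used, hit)
      }
      if (!ok || !all(novel_rows %in% used)) next
      w <- paste0(seg$id[p], orients)
      wrev <- rev(paste0(sub("[+-]$", "", w),
                         ifelse(grepl("\\+$", w), "-", "+")))
      key <- min(paste(w, collapse = " "), paste(wrev, collapse = " "))
      found <- union(found, key)
    }
  }
  sort(found)
}

walk_key <- function(w) {
  wrev <- rev(paste0(sub("[+-]$", "", w),
                     ifelse(grepl("\\+$", w), "-", "+")))
  min(paste(w, collapse = " "), paste(wrev, collapse = " "))
}
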