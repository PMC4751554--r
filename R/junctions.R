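# Split-read breakpoint junction calling: clip clustering, partner
# realignment, consensus, and microhomology / insertion signatures.

#' Collect soft-clip clusters from an alignment table
#'
#' Every primary alignment carrying a soft clip of at least `min_clip` bases
#' contributes to exactly one cluster, keyed by the reference coordinate of
#' the clip boundary and the clipped side.  For a left clip the coordinate
#' is the position of the first aligned base; for a right clip, one past the
#' last aligned base (0-based, so both coincide with the junction breakend).
#' Clustering is exact-coordinate by default; `merge_dist` allows near-miss
#' merging for externally aligned data.
#'
#' @param alignments `cgr_alignments` table or SAM path.
#' @param min_clip Minimum clip length in bases (>= 10).
#' @param merge_dist Maximum coordinate difference merged into one cluster
#'   (default 0: exact).
#' @return `data.frame` of class `clip_clusters`: `coord` (0-based), `side`
#'   (`"left"`/`"right"`), `support`, plus list-columns `clipped` (clipped
#'   substrings), `anchored` (aligned flank adjacent to the clip) and
#'   `qnames`, sorted by coordinate.
#' @export
collect_clip_clusters <- function(alignments, min_clip = 15, merge_dist = 0) {
  if (min_clip < 10) stop("`min_clip` must be >= 10", call. = FALSE)
  aln <- as_alignments(alignments)
  prim <- bitwAnd(aln$flag, SAM_FLAG["secondary"] + SAM_FLAG["supplementary"] +
                    SAM_FLAG["unmapped"] + SAM_FLAG["dup"]) == 0L
  aln <- aln[prim & grepl("S", aln$cigar), , drop = FALSE]
  empty <- data.frame(coord = numeric(0), side = character(0),
                      support = integer(0))
  if (!nrow(aln)) {
    empty$clipped <- list(); empty$anchored <- list(); empty$qnames <- list()
    class(empty) <- c("clip_clusters", "data.frame")
    return(empty)
  }
  lcl <- rcl <- integer(nrow(aln))
  hasL <- grepl("^[0-9]+S", aln$cigar)
  lcl[hasL] <- as.integer(sub("^([0-9]+)S.*", "\\1", aln$cigar[hasL]))
  hasR <- grepl("[0-9]+S$", aln$cigar)
  rcl[hasR] <- as.integer(sub(".*?([0-9]+)S$", "\\1", aln$cigar[hasR]))
  mlen <- vapply(regmatches(aln$cigar, gregexpr("[0-9]+(?=M)", aln$cigar, perl = TRUE)),
                 function(x) sum(as.integer(x)), integer(1))
  len <- nchar(aln$seq)
  recs <- list()
  takeL <- which(lcl >= min_clip)
  if (length(takeL)) {
    recs[[1]] <- data.frame(
      coord = aln$pos[takeL] - 1L, side = "left",
      clip = substr(aln$seq[takeL], 1L, lcl[takeL]),
      anchor = substr(aln$seq[takeL], lcl[takeL] + 1L, lcl[takeL] + mlen[takeL]),
      qname = aln$qname[takeL], stringsAsFactors = FALSE)
  }
  takeR <- which(rcl >= min_clip)
  if (length(takeR)) {
    recs[[length(recs) + 1L]] <- data.frame(
      coord = aln$pos[takeR] - 1L + mlen[takeR], side = "right",
      clip = substr(aln$seq[takeR], len[takeR] - rcl[takeR] + 1L, len[takeR]),
      anchor = substr(aln$seq[takeR], lcl[takeR] + 1L, lcl[takeR] + mlen[takeR]),
      qname = aln$qname[takeR], stringsAsFactors = FALSE)
  }
  if (!length(recs)) {
    empty$clipped <- list(); empty$anchored <- list(); empty$qnames <- list()
    class(empty) <- c("clip_clusters", "data.frame")
    return(empty)
  }
  recs <- do.call(rbind, recs)
  key <- recs$coord
  if (merge_dist > 0) {
    # greedy merge of coordinates within merge_dist, per side
    for (sd in c("left", "right")) {
      ix <- which(recs$side == sd)
      if (length(ix) < 2L) next
      o <- ix[order(recs$coord[ix])]
      grp_anchor <- recs$coord[o[1]]
      for (k in seq_along(o)) {
        if (recs$coord[o[k]] - grp_anchor > merge_dist) grp_anchor <- recs$coord[o[k]]
        key[o[k]] <- grp_anchor
      }
    }
  }
  grp <- paste(key, recs$side)
  ug <- unique(grp)
  out <- data.frame(
    coord = vapply(ug, function(g) stats::median(recs$coord[grp == g]), numeric(1)),
    side = vapply(ug, function(g) recs$side[grp == g][1], character(1)),
    support = vapply(ug, function(g) sum(grp == g), integer(1)),
    stringsAsFactors = FALSE)
  out$clipped <- lapply(ug, function(g) recs$clip[grp == g])
  out$anchored <- lapply(ug, function(g) recs$anchor[grp == g])
  out$qnames <- lapply(ug, function(g) recs$qname[grp == g])
  out <- out[order(out$coord, out$side), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("clip_clusters", "data.frame")
  out
}

# Realign one clipped substring against the reference: exact 12-nt seed at
# offset `off` into the clip (the junction-proximal end), extended over the
# full remaining clip with <= 1 mismatch, both strands.  Returns partner
# breakend candidates (coordinate + orientation) with the unexplained clip
# prefix length (candidate junctional insertion).
realign_clip <- function(clip, ref_dna, seed_len = 12L, max_off = 40L,
                         max_mismatch = 1L) {
  L <- nchar(clip)
  for (off in 0:min(max_off, L - seed_len)) {
    seed <- substr(clip, off + 1L, off + seed_len)
    tail_seq <- substr(clip, off + 1L, L)
    tl <- L - off
    # forward strand: clip continues into increasing coordinates
    hits <- Biostrings::matchPattern(seed, ref_dna)
    for (st in IRanges::start(hits)) {
      if (st + tl - 1L > length(ref_dna)) next
      cand <- as.character(Biostrings::subseq(ref_dna, st, st + tl - 1L))
      if (str_mismatches(cand, tail_seq) <= max_mismatch) {
        return(list(coord = st - 1L, orient = "-", ins_len = off))
      }
    }
    # reverse strand: clip continues into decreasing coordinates
    rcseed <- revcomp(seed)
    hits <- Biostrings::matchPattern(rcseed, ref_dna)
    for (st in IRanges::start(hits)) {
      en <- st + seed_len - 1L
      if (en - tl + 1L < 1L) next
      cand <- revcomp(as.character(Biostrings::subseq(ref_dna, en - tl + 1L, en)))
      if (str_mismatches(cand, tail_seq) <= max_mismatch) {
        return(list(coord = en, orient = "+", ins_len = off))
      }
    }
  }
  NULL
}

#' Call breakpoint junctions from clip clusters
#'
#' For each cluster the clipped substrings are realigned against the
#' reference (12-nt exact seed, full-clip extension with at most one
#' mismatch, both strands).  Clusters whose clipped parts agree on a common
#' partner coordinate and orientation are paired with the reciprocal
#' cluster at that partner; pairs with combined support at or above
#' `min_support` become junctions.  Junctions whose breakends also carry
#' clipped support in the control sample are suppressed.  Unpaired or
#' under-supported clusters are reported in the `orphans` attribute.
#'
#' @param clusters `clip_clusters` from the test sample.
#' @param reference `reference_genome` or character scalar.
#' @param min_support Minimum combined supporting reads (default 3).
#' @param control_clusters Optional `clip_clusters` from the control sample;
#'   any cluster there with support >= 2 at a candidate breakend suppresses
#'   the junction.
#' @param max_realign Realign at most this many clips per cluster when
#'   determining the partner (support is still counted over all reads).
#' @return `data.frame` of class `junction_calls`: `name`, `coord_a`,
#'   `orient_a`, `coord_b`, `orient_b`, `support`, `ins_len_hint`, with the
#'   contributing cluster indices in list-columns `cluster_a`, `cluster_b`.
#'   Attribute `orphans` lists unpaired clusters.
#' @export
call_junctions <- function(clusters, reference, min_support = 3,
                           control_clusters = NULL, max_realign = 30) {
  ref_seq <- as_ref_seq(reference)
  ref_dna <- Biostrings::DNAString(ref_seq)
  n <- nrow(clusters)
  part <- vector("list", n)
  for (i in seq_len(n)) {
    # realign the clip in the junction-outward direction: a right clip reads
    # away from the junction as stored; a left clip abuts the junction with
    # its last base, so its outward reading is the reverse complement
    outward <- if (clusters$side[i] == "left") revcomp(clusters$clipped[[i]])
               else clusters$clipped[[i]]
    if (length(outward) > max_realign) {
      outward <- outward[order(-nchar(outward))[seq_len(max_realign)]]
    }
    votes <- lapply(outward, realign_clip, ref_dna = ref_dna)
    votes <- votes[!vapply(votes, is.null, logical(1))]
    if (!length(votes)) next
    keyv <- vapply(votes, function(v) paste(v$coord, v$orient), character(1))
    top <- names(sort(table(keyv), decreasing = TRUE))[1]
    sel <- votes[keyv == top]
    part[[i]] <- list(coord = sel[[1]]$coord, orient = sel[[1]]$orient,
                      n = length(sel),
                      ins_len = as.integer(stats::median(
                        vapply(sel, `[[`, numeric(1), "ins_len"))))
  }
  # own breakend of each cluster: right clip -> segment retained on the low
  # side ("+"); left clip -> retained on the high side ("-")
  own_orient <- ifelse(clusters$side == "right", "+", "-")
  used <- rep(FALSE, n)
  out <- list(); orphans <- integer(0)
  ctrl_hit <- function(coord, orient) {
    if (is.null(control_clusters) || !nrow(control_clusters)) return(FALSE)
    sd <- ifelse(orient == "+", "right", "left")
    any(control_clusters$side == sd & abs(control_clusters$coord - coord) <= 2 &
          control_clusters$support >= 2)
  }
  for (i in seq_len(n)) {
    if (used[i] || is.null(part[[i]])) next
    p <- part[[i]]
    # reciprocal cluster at the partner breakend
    sd <- ifelse(p$orient == "+", "right", "left")
    j <- which(!used & clusters$side == sd & abs(clusters$coord - p$coord) <= 2)
    j <- j[j != i]
    recip <- NA_integer_
    for (jj in j) {
      q <- part[[jj]]
      if (!is.null(q) && abs(q$coord - clusters$coord[i]) <= 2 &&
          q$orient == own_orient[i]) { recip <- jj; break }
    }
    supp <- clusters$support[i] + if (!is.na(recip)) clusters$support[recip] else 0L
    if (supp < min_support ||
        ctrl_hit(clusters$coord[i], own_orient[i]) ||
        ctrl_hit(p$coord, p$orient)) {
      orphans <- c(orphans, i)
      next
    }
    used[i] <- TRUE
    if (!is.na(recip)) used[recip] <- TRUE
    a <- list(coord = clusters$coord[i], orient = own_orient[i], cl = i)
    b <- list(coord = p$coord, orient = p$orient,
              cl = if (!is.na(recip)) recip else NA_integer_)
    if (a$coord > b$coord) { tmp <- a; a <- b; b <- tmp }
    out[[length(out) + 1L]] <- data.frame(
      coord_a = a$coord, orient_a = a$orient,
      coord_b = b$coord, orient_b = b$orient,
      support = supp, ins_len_hint = p$ins_len,
      cluster_a = I(list(a$cl)), cluster_b = I(list(b$cl)),
      stringsAsFactors = FALSE)
  }
  orphans <- unique(c(orphans, which(!used & !vapply(part, is.null, logical(1)))))
  jx <- if (length(out)) do.call(rbind, out) else
    data.frame(coord_a = numeric(0), orient_a = character(0),
               coord_b = numeric(0), orient_b = character(0),
               support = integer(0), ins_len_hint = integer(0),
               cluster_a = I(list()), cluster_b = I(list()))
  if (nrow(jx)) {
    jx <- jx[order(jx$coord_a, jx$coord_b), , drop = FALSE]
    jx <- cbind(name = sprintf("jx%d", seq_len(nrow(jx))), jx,
                stringsAsFactors = FALSE)
    rownames(jx) <- NULL
  } else jx <- cbind(name = character(0), jx)
  attr(jx, "orphans") <- clusters[orphans, c("coord", "side", "support"),
                                  drop = FALSE]
  class(jx) <- c("junction_calls", "data.frame")
  jx
}

#' Consensus sequence across a junction
#'
#' Supporting reads from both breakend clusters are laid out in a common
#' junction frame (partner-A side entering from the left, junction point at
#' `flank`), and a per-position majority vote is taken.  Reads from the
#' B-side cluster are reverse-complemented into the A frame.  Ties are
#' broken toward the alphabetically first base with a warning; positions
#' where reads disagree in more than 20% of cases raise an error.
#'
#' @param junction One row of a `junction_calls` table.
#' @param clusters The `clip_clusters` the junctions were called from.
#' @param flank Flank length retained on each side of the junction.
#' @param max_disagree Maximum tolerated per-position disagreement fraction.
#' @return Character scalar with attribute `junction_at` giving the 0-based
#'   offset of the junction point (end of the A-side flank).
#' @export
junction_consensus <- function(junction, clusters, flank = 50,
                               max_disagree = 0.2) {
  lay <- list()
  # Common frame: partner-A segment approaches the junction from the left.
  # A SAM record stores anchor and clip in reference-forward orientation;
  # how they map into the A frame depends on which partner the cluster
  # belongs to and on the clipped side:
  #   A cluster, right clip: [anchor][clip]
  #   A cluster, left clip:  rc -> [rc(anchor)][rc(clip)]
  #   B cluster, right clip: rc -> [rc(clip)][rc(anchor)]
  #   B cluster, left clip:  [clip][anchor]
  ins_hint <- junction$ins_len_hint
  if (is.null(ins_hint) || is.na(ins_hint)) ins_hint <- 0L
  add_cluster <- function(ci, role) {
    if (is.na(ci)) return()
    anch <- clusters$anchored[[ci]]; clip <- clusters$clipped[[ci]]
    side <- clusters$side[ci]
    for (k in seq_along(anch)) {
      if (role == "A" && side == "right") {
        l <- anch[k]; r <- clip[k]
      } else if (role == "A" && side == "left") {
        l <- revcomp(anch[k]); r <- revcomp(clip[k])
      } else if (role == "B" && side == "right") {
        l <- revcomp(clip[k]); r <- revcomp(anch[k])
      } else {
        l <- clip[k]; r <- anch[k]
      }
      if (role == "B" && ins_hint > 0L) {
        # a B-side read's clip carries the junctional insertion at the
        # A-frame end of its left portion; it belongs right of the junction.
        # A clip shorter than the insertion cannot be positioned in the
        # frame at all and is dropped.
        if (nchar(l) < ins_hint) next
        r <- paste0(substr(l, nchar(l) - ins_hint + 1L, nchar(l)), r)
        l <- substr(l, 1L, nchar(l) - ins_hint)
      }
      lay[[length(lay) + 1L]] <<- list(left = l, right = r)
    }
  }
  ca <- junction$cluster_a[[1]]; cb <- junction$cluster_b[[1]]
  add_cluster(ca, "A")
  add_cluster(cb, "B")
  if (!length(lay)) stop("junction has no supporting reads", call. = FALSE)
  if (length(lay) == 1L) {
    warning("junction consensus from a single read")
  }
  lmax <- min(flank, max(vapply(lay, function(x) nchar(x$left), integer(1))))
  rmax <- max(vapply(lay, function(x) nchar(x$right), integer(1)))
  width <- lmax + rmax
  mat <- matrix(NA_character_, nrow = length(lay), ncol = width)
  for (k in seq_along(lay)) {
    l <- lay[[k]]$left; r <- lay[[k]]$right
    nl <- min(nchar(l), lmax)
    if (nl > 0) {
      mat[k, (lmax - nl + 1L):lmax] <-
        strsplit(substr(l, nchar(l) - nl + 1L, nchar(l)), "")[[1]]
    }
    nr <- nchar(r)
    mat[k, (lmax + 1L):(lmax + nr)] <- strsplit(r, "")[[1]]
  }
  cons <- character(width); bad <- 0L; tie <- FALSE
  for (j in seq_len(width)) {
    col <- mat[, j]; col <- col[!is.na(col)]
    if (!length(col)) { cons[j] <- ""; next }
    tb <- sort(table(col), decreasing = TRUE)
    if (length(tb) > 1L && tb[1] == tb[2]) {
      cons[j] <- sort(names(tb)[tb == tb[1]])[1]
      tie <- TRUE
    } else cons[j] <- names(tb)[1]
    if (length(col) > 1L && sum(col != cons[j]) / length(col) > max_disagree) {
      bad <- bad + 1L
    }
  }
  if (bad > 0L && bad > 0.2 * width) stop("inconsistent junction", call. = FALSE)
  if (tie) warning("consensus tie broken alphabetically")
  # trim edge columns covered by a single read: with one voter an error
  # cannot be outvoted, so thin ends are unreliable
  cov <- colSums(!is.na(mat))
  solid <- which(cov >= min(2L, max(cov)))
  lo <- min(solid); hi <- max(solid)
  out <- paste(cons[lo:hi], collapse = "")
  attr(out, "junction_at") <- lmax - (lo - 1L)
  out
}

#' Microhomology and insertion signature of a junction
#'
#' Accounts for every consensus base exactly once: bases beyond the A-side
#' flank that match the partner-B continuation belong to B; bases matching
#' neither partner are the junctional insertion; when there is no insertion,
#' the microhomology is the longest block terminating both fusion-partner
#' ends (an identical suffix of the A side and of the sequence immediately
#' preceding partner B).  An insertion is classified as templated when it
#' (or its reverse complement) occurs within `search_radius` of either
#' breakend with at most one mismatch.
#'
#' @param junction One row of a `junction_calls` (or truth junction) table.
#' @param consensus Junction consensus from [junction_consensus()] (or a
#'   derivative subsequence spanning the junction with attribute
#'   `junction_at`).
#' @param reference `reference_genome` or character scalar.
#' @param search_radius Distance around the breakends searched for the
#'   insertion template (default 500 bp).
#' @param max_ins Longest insertion considered.
#' @return `data.frame` of class `junction_signature` with fields
#'   `microhomology_len`, `microhomology_seq`, `insertion_len`,
#'   `insertion_seq`, `templated`, `template_start`, `template_end`,
#'   `template_strand`.
#' @export
junction_signature <- function(junction, consensus, reference,
                               search_radius = 500, max_ins = 60) {
  ref_seq <- as_ref_seq(reference)
  japos <- attr(consensus, "junction_at")
  if (is.null(japos)) stop("consensus lacks a `junction_at` attribute", call. = FALSE)
  cons <- as.character(consensus)
  a <- list(coord = junction$coord_a, orient = junction$orient_a)
  b <- list(coord = junction$coord_b, orient = junction$orient_b)
  # verify the A flank: consensus approaching the junction must match the
  # reference at breakend A (the consensus frame is anchored there)
  a_fl <- breakend_flank(ref_seq, a$coord, a$orient, japos, "retained")
  got <- substr(cons, japos - nchar(a_fl) + 1L, japos)
  if (nchar(got) >= 10 && str_mismatches(substr(a_fl, nchar(a_fl) - nchar(got) + 1L,
                                                nchar(a_fl)), got) > 2) {
    # consensus may be in the B frame instead
    stop("consensus does not contain the expected junction flank", call. = FALSE)
  }
  after <- substr(cons, japos + 1L, nchar(cons))
  probe <- 15L
  b_cont <- breakend_flank(ref_seq, b$coord, b$orient, probe, "continuation")
  ins_len <- NA_integer_
  for (i in 0:max_ins) {
    w <- min(probe, nchar(after) - i)
    if (w < 8L) break
    if (str_mismatches(substr(after, i + 1L, i + w),
                       substr(b_cont, 1L, w)) <= 1L) {
      ins_len <- i
      break
    }
  }
  if (is.na(ins_len)) {
    stop("consensus does not contain the partner-B flank", call. = FALSE)
  }
  ins_seq <- if (ins_len > 0) substr(after, 1L, ins_len) else ""

  mh_len <- 0L; mh_seq <- ""
  if (ins_len == 0L) {
    # Microhomology is the block of bases terminating both fusion-partner
    # ends, which makes the breakpoint position ambiguous.  It can sit on
    # either side of the nominal fusion point, so both shift directions are
    # measured: a left shift (suffix of the A side equals the sequence just
    # before partner B) and a right shift (the same comparison with the
    # roles swapped).  The total ambiguity is their sum; the reported block
    # is taken from the direction where it terminates a partner end.
    suffix_match <- function(x, y) {
      k <- 0L; kmax <- min(nchar(x), nchar(y))
      while (k < kmax &&
             substr(x, nchar(x) - k, nchar(x) - k) ==
             substr(y, nchar(y) - k, nchar(y) - k)) k <- k + 1L
      k
    }
    a_ret <- breakend_flank(ref_seq, a$coord, a$orient, 30L, "retained")
    b_pre <- breakend_flank(ref_seq, b$coord, b$orient, 30L, "preceding")
    L <- suffix_match(a_ret, b_pre)
    b_ret <- breakend_flank(ref_seq, b$coord, b$orient, 30L, "retained")
    a_pre <- breakend_flank(ref_seq, a$coord, a$orient, 30L, "preceding")
    R <- suffix_match(b_ret, a_pre)
    mh_len <- L + R
    mh_seq <- paste0(
      if (L > 0L) substr(a_ret, nchar(a_ret) - L + 1L, nchar(a_ret)) else "",
      if (R > 0L) substr(b_ret, nchar(b_ret) - R + 1L, nchar(b_ret)) else "")
  }

  templ <- FALSE; tstart <- NA_real_; tend <- NA_real_; tstrand <- NA_character_
  if (ins_len >= 5L) {
    for (mm in 0:1) {   # prefer an exact template over a 1-mismatch one
      for (bk in list(a, b)) {
        lo <- max(0, bk$coord - search_radius)
        hi <- min(nchar(ref_seq), bk$coord + search_radius)
        win <- subseq0(ref_seq, lo, hi)
        for (strand in c("+", "-")) {
          pat <- if (strand == "+") ins_seq else revcomp(ins_seq)
          m <- Biostrings::matchPattern(pat, Biostrings::DNAString(win),
                                        max.mismatch = mm)
          if (length(m)) {
            templ <- TRUE
            tstart <- lo + IRanges::start(m)[1] - 1L
            tend <- tstart + ins_len
            tstrand <- strand
            break
          }
        }
        if (templ) break
      }
      if (templ) break
    }
  }
  out <- data.frame(
    microhomology_len = mh_len, microhomology_seq = mh_seq,
    insertion_len = ins_len, insertion_seq = ins_seq,
    templated = templ, template_start = tstart, template_end = tend,
    template_strand = tstrand, stringsAsFactors = FALSE)
  class(out) <- c("junction_signature", "data.frame")
  out
}
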