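# Truth alignments: back-projection of simulated reads onto the reference.
#
# The simulator knows exactly where every read came from, so instead of
# running an aligner the reads are projected through the derivative layout:
# reads wholly inside one plan piece become a single ungapped alignment;
# reads crossing a junction become a soft-clipped primary (the longer mapped
# portion) plus a supplementary record for the clipped portion, with SA tags
# linking the two.  Coordinates in the emitted table are 1-based (SAM).

SAM_FLAG <- c(paired = 1L, proper = 2L, unmapped = 4L, munmapped = 8L,
              reverse = 16L, mreverse = 32L, first = 64L, last = 128L,
              secondary = 256L, dup = 1024L, supplementary = 2048L)

identity_layout <- function(len) {
  data.frame(d_start = 0, d_end = len, ref_start = 0, ref_end = len,
             strand = "+", type = "piece", piece = 1L, stringsAsFactors = FALSE)
}

#' Emit truth alignments for simulated reads
#'
#' Projects simulated read pairs from their source genome (reference or
#' derivative) onto reference coordinates, producing a coordinate-sorted
#' alignment table equivalent to what a perfect aligner would report.
#'
#' @param pairs A `read_pairs` object simulated from `genome`.
#' @param genome The genome the reads were simulated from: a
#'   `derivative_genome` (its `layout` drives the projection) or a
#'   `reference_genome` (identity projection).
#' @param reference_name Reference sequence name for the records.
#' @param min_portion Minimum mapped length (bases) for a supplementary
#'   record; shorter junction overhangs remain as plain soft clips.
#' @param qual_char Constant base-quality character.
#'
#' @return A `data.frame` of class `cgr_alignments` with SAM-like columns
#'   `qname`, `flag`, `rname`, `pos` (1-based), `mapq`, `cigar`, `rnext`,
#'   `pnext`, `tlen`, `seq`, `qual`, `tags`, sorted by `pos`.
#' @export
emit_truth_alignments <- function(pairs, genome, reference_name = "chrS",
                                  min_portion = 15L, qual_char = "I") {
  stopifnot(inherits(pairs, "read_pairs"))
  layout <- if (inherits(genome, "derivative_genome")) genome$layout
            else identity_layout(pairs$genome_length)
  rl <- pairs$read_len
  n <- length(pairs$r1)
  qname <- sprintf("%s:%d", pairs$sample_name, seq_len(n))
  qual <- strrep(qual_char, rl)
  db <- layout$d_start

  mate_tab <- function(mate) {
    if (mate == 1L) {
      s <- pairs$frag_start
      seq_raw <- pairs$r1
    } else {
      s <- pairs$frag_start + pairs$frag_len - rl
      seq_raw <- pairs$r2
    }
    e <- s + rl
    row_s <- findInterval(s, db)
    row_e <- findInterval(e - 1, db)
    simple <- row_s == row_e & layout$type[row_s] == "piece"

    out <- data.frame(qname = qname, flag = 0L, rname = reference_name,
                      pos = NA_integer_, mapq = 60L, cigar = NA_character_,
                      seq = NA_character_, rev = NA, supp_of = NA_integer_,
                      stringsAsFactors = FALSE)
    # vectorized path: read wholly inside one piece
    i <- which(simple)
    if (length(i)) {
      r <- row_s[i]
      plus <- layout$strand[r] == "+"
      pos0 <- ifelse(plus,
                     layout$ref_start[r] + (s[i] - layout$d_start[r]),
                     layout$ref_end[r] - (e[i] - layout$d_start[r]))
      rev <- xor(mate == 2L, !plus)
      sq <- seq_raw[i]
      flipme <- if (mate == 1L) !plus else plus
      if (any(flipme)) sq[flipme] <- revcomp(sq[flipme])
      out$pos[i] <- as.integer(pos0 + 1)
      out$cigar[i] <- sprintf("%dM", rl)
      out$seq[i] <- sq
      out$rev[i] <- rev
    }
    # split path: read crosses a layout boundary
    extra <- list()
    for (j in which(!simple)) {
      recs <- project_split_read(s[j], e[j], seq_raw[j], mate, rl, layout)
      if (is.null(recs)) {
        stop("simulated read not attributable to any plan piece", call. = FALSE)
      }
      out$pos[j] <- recs$pos[1]; out$cigar[j] <- recs$cigar[1]
      out$seq[j] <- recs$seq[1]; out$rev[j] <- recs$rev[1]
      if (nrow(recs) > 1L && recs$mlen[2] >= min_portion) {
        extra[[length(extra) + 1L]] <- data.frame(
          qname = qname[j], flag = 0L, rname = reference_name,
          pos = recs$pos[2], mapq = 60L, cigar = recs$cigar[2],
          seq = recs$seq[2], rev = recs$rev[2], supp_of = j,
          stringsAsFactors = FALSE)
      }
    }
    list(primary = out, supp = extra)
  }

  m1 <- mate_tab(1L)
  m2 <- mate_tab(2L)
  p1 <- m1$primary; p2 <- m2$primary
  base_flag <- function(p, mate_p, firstbit) {
    SAM_FLAG["paired"] + firstbit +
      ifelse(p$rev, SAM_FLAG["reverse"], 0L) +
      ifelse(mate_p$rev, SAM_FLAG["mreverse"], 0L) +
      ifelse(grepl("S", p$cigar) | grepl("S", mate_p$cigar), 0L, SAM_FLAG["proper"])
  }
  p1$flag <- as.integer(base_flag(p1, p2, SAM_FLAG["first"]))
  p2$flag <- as.integer(base_flag(p2, p1, SAM_FLAG["last"]))
  p1$rnext <- "="; p2$rnext <- "="
  p1$pnext <- p2$pos; p2$pnext <- p1$pos
  p1$tlen <- ifelse(p1$pos <= p2$pos, p2$pos + rl - p1$pos, -(p1$pos + rl - p2$pos))
  p2$tlen <- -p1$tlen

  finish_supp <- function(supp_list, prim, mate_prim, firstbit) {
    if (!length(supp_list)) return(NULL)
    sp <- do.call(rbind, supp_list)
    j <- sp$supp_of
    sp$flag <- as.integer(SAM_FLAG["paired"] + firstbit + SAM_FLAG["supplementary"] +
                            ifelse(sp$rev, SAM_FLAG["reverse"], 0L) +
                            ifelse(mate_prim$rev[j], SAM_FLAG["mreverse"], 0L))
    sp$rnext <- "="; sp$pnext <- mate_prim$pos[j]; sp$tlen <- 0L
    sp$tags <- sprintf("SA:Z:%s,%d,%s,%s,60,0;", reference_name,
                       prim$pos[j], ifelse(prim$rev[j], "-", "+"), prim$cigar[j])
    # reciprocal SA on the primary
    prim$tags[j] <<- sprintf("SA:Z:%s,%d,%s,%s,60,0;", reference_name,
                             sp$pos, ifelse(sp$rev, "-", "+"), sp$cigar)
    sp
  }
  p1$tags <- ""; p2$tags <- ""
  prim <- p1; s1 <- finish_supp(m1$supp, prim, p2, SAM_FLAG["first"]); p1 <- prim
  prim <- p2; s2 <- finish_supp(m2$supp, prim, p1, SAM_FLAG["last"]); p2 <- prim

  keep <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
            "rnext", "pnext", "tlen", "seq", "tags")
  aln <- rbind(p1[keep], p2[keep],
               if (!is.null(s1)) s1[keep], if (!is.null(s2)) s2[keep])
  aln$qual <- qual
  aln <- aln[order(aln$pos), c("qname", "flag", "rname", "pos", "mapq", "cigar",
                               "rnext", "pnext", "tlen", "seq", "qual", "tags")]
  rownames(aln) <- NULL
  attr(aln, "reference_name") <- reference_name
  attr(aln, "reference_length") <-
    if (inherits(genome, "derivative_genome")) {
      max(layout$ref_end, na.rm = TRUE)
    } else pairs$genome_length
  class(aln) <- c("cgr_alignments", "data.frame")
  aln
}

# One split read: returns records ordered primary first.
project_split_read <- function(s, e, seq_raw, mate, rl, layout) {
  rows <- which(layout$d_end > s & layout$d_start < e)
  recs <- list()
  for (r in rows) {
    if (layout$type[r] != "piece") next
    ps <- max(s, layout$d_start[r]); pe <- min(e, layout$d_end[r])
    plus <- layout$strand[r] == "+"
    ref0 <- if (plus) layout$ref_start[r] + (ps - layout$d_start[r])
            else layout$ref_end[r] - (pe - layout$d_start[r])
    # read offsets in sequenced orientation
    offs <- if (mate == 1L) c(ps - s, pe - s) else c(e - pe, e - ps)
    rev <- xor(mate == 2L, !plus)
    # offsets in SAM (reference-forward) orientation
    sam_off <- if (!rev) offs else c(rl - offs[2], rl - offs[1])
    lcl <- sam_off[1]; m <- pe - ps; rcl <- rl - sam_off[2]
    cigar <- paste0(if (lcl > 0) sprintf("%dS", lcl), sprintf("%dM", m),
                    if (rcl > 0) sprintf("%dS", rcl))
    sq <- if (rev) revcomp(seq_raw) else seq_raw
    recs[[length(recs) + 1L]] <- data.frame(
      pos = as.integer(ref0 + 1), cigar = cigar, seq = sq, rev = rev,
      mlen = m, stringsAsFactors = FALSE)
  }
  if (!length(recs)) return(NULL)
  recs <- do.call(rbind, recs)
  recs[order(-recs$mlen), , drop = FALSE]
}

#' Write an alignment table as a coordinate-sorted SAM file
#'
#' @param aln A `cgr_alignments` table from [emit_truth_alignments()].
#' @param path Output path.
#' @param reference_name,reference_length Header `@SQ` values; defaults are
#'   taken from the table's attributes.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path,
                      reference_name = attr(aln, "reference_name"),
                      reference_length = attr(aln, "reference_length")) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", reference_name, as.integer(reference_length)),
           "@PG\tID:chromoscout\tPN:chromoscout")
  body <- paste(aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq, aln$cigar,
                aln$rnext, aln$pnext, aln$tlen, aln$seq, aln$qual, sep = "\t")
  tg <- aln$tags
  has <- !is.na(tg) & nzchar(tg)
  body[has] <- paste(body[has], tg[has], sep = "\t")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(body, con)
  invisible(path)
}

#' Read a SAM/BAM file into an alignment table
#'
#' Parsing goes through Rsamtools (htslib): SAM input is converted to BAM
#' and scanned, so anything a standard SAM reader accepts is accepted here.
#'
#' @param path SAM (or BAM) file path.
#' @return A `cgr_alignments` data.frame (see [emit_truth_alignments()]).
#' @export
read_sam <- function(path) {
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) path
         else Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                               indexDestination = FALSE)
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
             "mrnm", "mpos", "isize", "seq", "qual")))[[1]]
  aln <- data.frame(qname = res$qname, flag = res$flag,
                    rname = as.character(res$rname), pos = res$pos,
                    mapq = res$mapq, cigar = res$cigar,
                    rnext = as.character(res$mrnm), pnext = res$mpos,
                    tlen = res$isize, seq = as.character(res$seq),
                    qual = as.character(res$qual), tags = "",
                    stringsAsFactors = FALSE)
  aln <- aln[!is.na(aln$pos), , drop = FALSE]
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  attr(aln, "reference_name") <- names(hdr)[1]
  attr(aln, "reference_length") <- unname(hdr[1])
  class(aln) <- c("cgr_alignments", "data.frame")
  aln
}

as_alignments <- function(x) {
  if (inherits(x, "cgr_alignments")) x
  else if (is.character(x) && length(x) == 1L) read_sam(x)
  else if (is.data.frame(x)) { class(x) <- c("cgr_alignments", "data.frame"); x }
  else stop("expected an alignment table or a SAM file path", call. = FALSE)
}
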