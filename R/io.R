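# Plain-text writers for the standard interchange formats produced by the
# pipeline (BEDPE, BED, bedGraph, VCF breakends, TSV tables).

#' Write junctions as BEDPE
#'
#' Columns: chrom1, start1, end1, chrom2, start2, end2, name, score
#' (supporting reads where available), strand1, strand2, and the junctional
#' insertion sequence as an extra column.
#'
#' @param junctions Junction table (called or truth).
#' @param path Output path.
#' @param chrom Reference sequence name.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(junctions, path, chrom = "chrS") {
  insert <- junctions$insert %||% junctions$insert_seq %||%
    rep(".", nrow(junctions))
  insert[!nzchar(insert)] <- "."
  score <- junctions$support %||% rep(0L, nrow(junctions))
  df <- data.frame(chrom1 = chrom, start1 = junctions$coord_a,
                   end1 = junctions$coord_a + 1, chrom2 = chrom,
                   start2 = junctions$coord_b, end2 = junctions$coord_b + 1,
                   name = junctions$name, score = score,
                   strand1 = junctions$orient_a, strand2 = junctions$orient_b,
                   insert = insert)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write copy segments (or a truth copy profile) as BED
#'
#' The integer copy state goes in the score column.
#'
#' @param segments `data.frame` with `start`, `end` and `state` (or `copy`).
#' @param path Output path.
#' @param chrom Reference sequence name.
#' @return `path`, invisibly.
#' @export
write_bed_segments <- function(segments, path, chrom = "chrS") {
  state <- segments$state %||% segments$copy
  df <- data.frame(chrom = chrom, start = segments$start, end = segments$end,
                   name = sprintf("cn%d", seq_len(nrow(segments))),
                   score = state)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a ratio track as bedGraph
#'
#' Masked windows are omitted.
#'
#' @param track A `ratio_track`.
#' @param path Output path.
#' @param chrom Reference sequence name.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, chrom = "chrS") {
  w <- track$window_size
  n <- length(track$ratios)
  start <- (seq_len(n) - 1L) * w
  end <- pmin(start + w, track$reference_length)
  keep <- !track$masked
  df <- data.frame(chrom = chrom, start = start[keep], end = end[keep],
                   value = round(track$ratios[keep], 4))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=depth_ratio"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# VCF 4.2 breakend bracket notation for one side of a junction.
bnd_alt <- function(ref_base, own_orient, mate_pos1, mate_orient, chrom) {
  m <- sprintf("%s:%d", chrom, mate_pos1)
  if (own_orient == "+") {
    if (mate_orient == "-") paste0(ref_base, "[", m, "[")
    else paste0(ref_base, "]", m, "]")
  } else {
    if (mate_orient == "-") paste0("[", m, "[", ref_base)
    else paste0("]", m, "]", ref_base)
  }
}

#' Write junctions as VCF 4.2 breakend (BND) records
#'
#' Two mated BND records per junction with `MATEID`, plus `HOMLEN`/`HOMSEQ`
#' and `SVINSSEQ` from the signatures and the split-read support in
#' `SUPPORT`.
#'
#' @param junctions Junction table.
#' @param signatures Matching `junction_signature` rows (may be `NULL`).
#' @param reference `reference_genome` or character scalar.
#' @param path Output path.
#' @param chrom Reference sequence name.
#' @param sample Sample label written in the header.
#' @return `path`, invisibly.
#' @export
write_vcf_bnd <- function(junctions, signatures, reference, path,
                          chrom = "chrS", sample = "test") {
  ref_seq <- as_ref_seq(reference)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", chrom, nchar(ref_seq)),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend\">",
           "##INFO=<ID=HOMLEN,Number=1,Type=Integer,Description=\"Microhomology length\">",
           "##INFO=<ID=HOMSEQ,Number=1,Type=String,Description=\"Microhomology sequence\">",
           "##INFO=<ID=SVINSSEQ,Number=1,Type=String,Description=\"Junctional insertion\">",
           "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Split reads\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 sep = "\t"))
  rows <- character(0)
  for (k in seq_len(nrow(junctions))) {
    j <- junctions[k, ]
    # POS is the 1-based coordinate of the last retained base on each side
    pos_a <- if (j$orient_a == "+") j$coord_a else j$coord_a + 1
    pos_b <- if (j$orient_b == "+") j$coord_b else j$coord_b + 1
    base_a <- substr(ref_seq, pos_a, pos_a)
    base_b <- substr(ref_seq, pos_b, pos_b)
    info <- sprintf("SVTYPE=BND;SUPPORT=%d", j$support %||% 0L)
    if (!is.null(signatures) && nrow(signatures) >= k) {
      s <- signatures[k, ]
      if (s$insertion_len > 0) {
        info <- paste0(info, ";SVINSSEQ=", s$insertion_seq)
      } else if (s$microhomology_len > 0) {
        info <- paste0(info, sprintf(";HOMLEN=%d;HOMSEQ=%s",
                                     s$microhomology_len, s$microhomology_seq))
      }
    }
    ida <- paste0(j$name, "_1"); idb <- paste0(j$name, "_2")
    rows <- c(rows,
              paste(chrom, pos_a, ida, base_a,
                    bnd_alt(base_a, j$orient_a, pos_b, j$orient_b, chrom),
                    ".", "PASS", paste0(info, ";MATEID=", idb), sep = "\t"),
              paste(chrom, pos_b, idb, base_b,
                    bnd_alt(base_b, j$orient_b, pos_a, j$orient_a, chrom),
                    ".", "PASS", paste0(info, ";MATEID=", ida), sep = "\t"))
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write a segment graph as TSV files
#'
#' @param graph A `segment_graph`.
#' @param prefix Output path prefix; writes `<prefix>_segments.tsv` and
#'   `<prefix>_adjacencies.tsv`.
#' @return The two paths, invisibly.
#' @export
write_graph_tsv <- function(graph, prefix) {
  p1 <- paste0(prefix, "_segments.tsv")
  p2 <- paste0(prefix, "_adjacencies.tsv")
  utils::write.table(graph$segments, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  adj <- graph_adjacencies(graph)
  adj$seg_a <- graph$segments$id[adj$seg_a]
  adj$seg_b <- graph$segments$id[adj$seg_b]
  utils::write.table(adj, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
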