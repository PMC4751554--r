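# Split-read clustering, junction calling, consensus and signatures.

test_that("clip clusters form at exact coordinates with correct sides", {
  al <- mini_alignments(30, 1)
  expect_error(collect_clip_clusters(al$test, min_clip = 5), "min_clip")
  expect_equal(nrow(collect_clip_clusters(al$control)), 0)

  cl <- collect_clip_clusters(al$test)
  truth <- mini_truth_breakends()
  expect_equal(nrow(cl), 8)   # two clusters per junction
  expect_true(all(cl$support >= 3))
  # clip boundary (coordinate, side) pairs match the truth breakends; a
  # right clip marks a breakend retaining the lower side
  expect_setequal(paste(cl$coord, cl$side),
                  paste(truth$coord,
                        ifelse(truth$orient == "+", "right", "left")))
})

test_that("coordinates differing by one stay separate unless merging is on", {
  al <- mini_alignments(30, 1)
  aln <- al$test[grepl("S", al$test$cigar) &
                   bitwAnd(al$test$flag, 2048L) == 0L, ][1:2, ]
  aln$pos[2] <- aln$pos[1] + 1L
  aln$cigar <- "20S80M"
  cl <- collect_clip_clusters(aln, min_clip = 15)
  expect_equal(nrow(cl), 2)
  cl2 <- collect_clip_clusters(aln, min_clip = 15, merge_dist = 2)
  expect_equal(nrow(cl2), 1)
  expect_equal(cl2$support, 2L)
})

test_that("all four truth junctions are called exactly, none in the control", {
  sc <- mini_scenario()
  mj <- mini_junctions(30, 1)
  jx <- mj$junctions
  tj <- sc$derivative$truth$junctions
  expect_equal(nrow(jx), 4)
  expect_equal(jx$coord_a, tj$coord_a)
  expect_equal(jx$coord_b, tj$coord_b)
  expect_identical(jx$orient_a, tj$orient_a)
  expect_identical(jx$orient_b, tj$orient_b)
  expect_true(all(jx$support >= 3))
  expect_equal(nrow(attr(jx, "orphans")), 0)
  # breakends in canonical order
  expect_true(all(jx$coord_a <= jx$coord_b))

  # control-vs-control: no clips, no junctions
  al <- mini_alignments(30, 1)
  ctl_cl <- collect_clip_clusters(al$control)
  expect_equal(nrow(call_junctions(ctl_cl, sc$reference, 3)), 0)
})

test_that("junction recall holds within +-5 bp across repeated simulations", {
  sc <- mini_scenario()
  truth <- mini_truth_breakends()
  for (s in 1:4) {
    mj <- mini_junctions(30, s)
    jx <- mj$junctions
    expect_equal(nrow(jx), 4)
    called <- sort(c(jx$coord_a, jx$coord_b))
    expect_true(all(abs(called - sort(truth$coord)) <= 5))
  }
})

test_that("min_support filters junctions into orphan diagnostics", {
  sc <- mini_scenario()
  mj <- mini_junctions(30, 1)
  high <- call_junctions(mj$clusters, sc$reference, min_support = 999)
  expect_equal(nrow(high), 0)
  expect_gt(nrow(attr(high, "orphans")), 0)
})

test_that("consensus reconstructs the derivative sequence across junctions", {
  sc <- mini_scenario()
  mj <- mini_junctions(30, 1)
  jx <- mj$junctions
  lay <- sc$derivative$layout
  dseq <- sc$derivative$sequence
  for (k in seq_len(nrow(jx))) {
    cons <- junction_consensus(jx[k, ], mj$clusters, flank = 40)
    ja <- attr(cons, "junction_at")
    expect_gte(ja, 15)
    # the consensus must occur verbatim in the derivative (possibly reverse
    # complemented, depending on the junction frame)
    hit <- grepl(cons, dseq, fixed = TRUE) ||
      grepl(chromoscout:::revcomp(as.character(cons)), dseq, fixed = TRUE)
    expect_true(hit, info = sprintf("junction %s consensus not in derivative",
                                    jx$name[k]))
  }
})

test_that("single-read consensus warns; contradictory reads error", {
  sc <- mini_scenario()
  mj <- mini_junctions(30, 1)
  jx1 <- mj$junctions[1, ]
  cl <- mj$clusters
  one <- cl
  ca <- jx1$cluster_a[[1]]
  one$clipped[[ca]] <- one$clipped[[ca]][1]
  one$anchored[[ca]] <- one$anchored[[ca]][1]
  solo <- jx1; solo$cluster_b <- I(list(NA_integer_))
  expect_warning(junction_consensus(solo, one), "single read")

  bad <- cl
  n_r <- length(bad$clipped[[ca]])
  half <- seq_len(ceiling(n_r / 2))
  bad$clipped[[ca]][half] <- vapply(
    bad$clipped[[ca]][half],
    function(x) paste(rev(strsplit(chartr("ACGT", "GTAC", x), "")[[1]]),
                      collapse = ""), character(1))
  solo2 <- jx1; solo2$cluster_b <- I(list(NA_integer_))
  expect_error(suppressWarnings(junction_consensus(solo2, bad)),
               "inconsistent")
})

test_that("signatures recover the designed homology and insertions", {
  sc <- mini_scenario()
  mj <- mini_junctions(30, 1)
  jx <- mj$junctions
  sig <- do.call(rbind, lapply(seq_len(nrow(jx)), function(k) {
    junction_signature(jx[k, ], junction_consensus(jx[k, ], mj$clusters),
                       sc$reference)
  }))
  tj <- sc$derivative$truth$junctions

  # the shared-triplet junction
  agt <- which(tj$insert_len == 0 & !tj$inverted)
  expect_equal(sig$microhomology_len[agt], 3)
  expect_identical(sig$microhomology_seq[agt], "AGT")

  # the 17-nt insertion between the inverted copies, templated nearby
  inv17 <- which(tj$insert_len == 17)
  expect_equal(sig$insertion_len[inv17], 17)
  expect_true(sig$templated[inv17])
  expect_true(sig$insertion_seq[inv17] %in%
                c(tj$insert[inv17], chromoscout:::revcomp(tj$insert[inv17])))

  # the short templated insertion
  ins9 <- which(tj$insert_len == 9)
  expect_equal(sig$insertion_len[ins9], 9)
  expect_true(sig$templated[ins9])

  # the blunt junction
  blunt <- which(tj$insert_len == 0 & tj$inverted)
  expect_equal(sig$microhomology_len[blunt], 0)
  expect_equal(sig$insertion_len[blunt], 0)
  expect_false(sig$templated[blunt])

  # accounting: microhomology and insertion are mutually exclusive
  expect_true(all(sig$microhomology_len == 0 | sig$insertion_len == 0))
  expect_equal(sig$microhomology_len, nchar(sig$microhomology_seq))
  expect_equal(sig$insertion_len, nchar(sig$insertion_seq))
  # templated implies a source interval matching the insertion length
  tm <- sig$templated
  expect_true(all(sig$template_end[tm] - sig$template_start[tm] ==
                    sig$insertion_len[tm]))
})

test_that("consensus tolerates sequencing errors by majority vote", {
  sc <- mini_scenario()
  # 2% per-base errors, still error-free consensus at this support
  mut <- simulate_reads(sc$derivative, coverage = 30, error_rate = 0.02,
                        seed = 77, sample_name = "m")
  amut <- emit_truth_alignments(mut, sc$derivative)
  cl <- collect_clip_clusters(amut)
  jx <- call_junctions(cl, sc$reference, 3)
  expect_equal(nrow(jx), 4)
  k <- which(jx$coord_b - jx$coord_a > 1000)[1]   # a well-separated junction
  cons <- suppressWarnings(junction_consensus(jx[k, ], cl, flank = 40))
  dseq <- sc$derivative$sequence
  expect_true(grepl(cons, dseq, fixed = TRUE) ||
                grepl(chromoscout:::revcomp(as.character(cons)), dseq,
                      fixed = TRUE))
})
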