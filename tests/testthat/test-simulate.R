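# Paired-end read simulation and truth alignment emission.

test_that("read counts follow the coverage model and seeds reproduce", {
  ref <- make_reference(1e6, seed = 11)
  rp <- simulate_reads(ref, coverage = 30, read_len = 100, seed = 5)
  lambda <- 30 * 1e6 / (2 * 100)
  expect_lt(abs(length(rp$r1) - lambda), 3 * sqrt(lambda))
  expect_error(simulate_reads(ref, read_len = 300, insert_mean = 300), "insert_mean")
  expect_error(simulate_reads(ref, coverage = 0), "coverage")

  rp2 <- simulate_reads(ref, coverage = 30, read_len = 100, seed = 5)
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(rp, f1); write_fastq(rp2, f2)
  expect_identical(readLines(paste0(f1, "_1.fastq")),
                   readLines(paste0(f2, "_1.fastq")))
  expect_identical(readLines(paste0(f1, "_2.fastq")),
                   readLines(paste0(f2, "_2.fastq")))
})

test_that("error-free reads match their source positions exactly", {
  sc <- mini_scenario()
  rp <- simulate_reads(sc$derivative, coverage = 2, error_rate = 0, seed = 9)
  d <- sc$derivative$sequence
  expect_true(all(rp$r1 == substring(d, rp$frag_start + 1,
                                     rp$frag_start + rp$read_len)))
  expect_true(all(rp$r2 == chromoscout:::revcomp(
    substring(d, rp$frag_start + rp$frag_len - rp$read_len + 1,
              rp$frag_start + rp$frag_len))))
})

test_that("substitution errors appear at roughly the configured rate", {
  ref <- make_reference(2e5, seed = 12)
  rp <- simulate_reads(ref, coverage = 10, error_rate = 0.01, seed = 3)
  mm <- sum(vapply(seq_along(rp$r1), function(i) {
    chromoscout:::str_mismatches(
      rp$r1[i], substring(ref$sequence, rp$frag_start[i] + 1,
                          rp$frag_start[i] + 100))
  }, numeric(1)))
  total <- length(rp$r1) * 100
  expect_gt(mm / total, 0.007)
  expect_lt(mm / total, 0.013)
})

test_that("reads inside one piece project to ungapped truth alignments", {
  sc <- mini_scenario()
  al <- mini_alignments(30, 1)
  aln <- al$test
  ref <- sc$reference$sequence
  # every matched block must equal the reference at the reported position
  idx <- sample(seq_len(nrow(aln)), 500)
  for (k in idx) {
    cg <- aln$cigar[k]
    lcl <- if (grepl("^[0-9]+S", cg)) as.integer(sub("S.*", "", cg)) else 0L
    m <- as.integer(sub("M.*", "", sub("^[0-9]+S", "", cg)))
    mseq <- substr(aln$seq[k], lcl + 1, lcl + m)
    rseq <- substr(ref, aln$pos[k], aln$pos[k] + m - 1)
    # simulated errors allow scattered mismatches but no shifts
    expect_lt(chromoscout:::str_mismatches(mseq, rseq) / m, 0.1)
  }
})

test_that("junction-crossing reads split exactly at the breakends", {
  ref <- make_reference(2000, seed = 11)
  plan <- segment_plan(data.frame(start = c(0, 200), end = c(1000, 1200),
                                  strand = c("+", "+")))
  d <- build_derivative(ref, plan)
  # one pair hand-placed so read 1 crosses the junction (at derivative 1000)
  # with a 60/40 split
  pr <- structure(list(
    r1 = chromoscout:::subseq0(d$sequence, 940, 1040),
    r2 = chromoscout:::revcomp(chromoscout:::subseq0(d$sequence, 1150, 1250)),
    frag_start = 940, frag_len = 310, read_len = 100L,
    sample_name = "t", genome_length = nchar(d$sequence)),
    class = "read_pairs")
  aln <- emit_truth_alignments(pr, d)
  expect_true(any(aln$pos == 941 & aln$cigar == "60M40S"))
  supp <- aln[bitwAnd(aln$flag, 2048L) > 0, ]
  expect_equal(nrow(supp), 1)
  expect_equal(supp$pos, 201)           # partner breakend, 1-based
  expect_equal(supp$cigar, "60S40M")
  expect_match(supp$tags, "^SA:Z:")
})

test_that("control-genome reads never carry clips at junction coordinates", {
  al <- mini_alignments(30, 1)
  cl <- collect_clip_clusters(al$control)
  expect_equal(nrow(cl), 0)
})

test_that("emitted SAM is standards-conformant and round-trips", {
  sc <- mini_scenario()
  rp <- simulate_reads(sc$derivative, coverage = 1, error_rate = 0.005, seed = 4)
  aln <- emit_truth_alignments(rp, sc$derivative)
  f <- tempfile(fileext = ".sam")
  write_sam(aln, f)
  back <- read_sam(f)   # parses via htslib; invalid SAM would fail here
  expect_equal(nrow(back), nrow(aln))
  expect_true(all(diff(aln$pos) >= 0))  # coordinate-sorted
  ord <- order(back$qname, back$flag)
  ord0 <- order(aln$qname, aln$flag)
  expect_identical(back$seq[ord], aln$seq[ord0])
  expect_identical(back$cigar[ord], aln$cigar[ord0])
})

test_that("junction-spanning read fraction matches expectation", {
  sc <- mini_scenario()
  al <- mini_alignments(30, 1)
  cl <- collect_clip_clusters(al$test, min_clip = 15)
  # reads spanning a junction with >= min_clip overhang on the shorter side
  # arise from (read_len - 2*min_clip) start positions per junction copy
  n_reads <- 2 * length(al$mut_reads$r1)
  n_junction_sites <- 4   # each novel adjacency is traversed once
  expected <- n_reads * (100 - 2 * 15) * n_junction_sites /
    sc$derivative$truth$derivative_length
  expect_gt(sum(cl$support), 0.6 * expected)
  expect_lt(sum(cl$support), 1.4 * expected)
})
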