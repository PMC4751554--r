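# Windowed depth ratios, copy-state segmentation, boundary refinement.

test_that("window counting assigns each primary read once", {
  sc <- mini_scenario()
  al <- mini_alignments(30, 1)
  expect_error(window_counts(al$control, window_size = 50), "unsupported")
  wc <- window_counts(al$control, 2000)
  expect_equal(length(wc$counts), 125)
  expect_equal(sum(wc$counts), wc$total_aligned)
  # interior windows match the closed-form expectation cov*w/read_len
  interior <- wc$counts[5:120]
  expect_lt(abs(mean(interior) - 30 * 2000 / 100), 0.05 * 600)
  # supplementary records are not counted
  n_supp <- sum(bitwAnd(al$test$flag, 2048L) > 0)
  wt <- window_counts(al$test, 2000)
  expect_gt(n_supp, 0)
  expect_equal(wt$total_aligned + n_supp,
               sum(al$test$mapq >= 1))
})

test_that("empty alignments give all-zero counts", {
  empty <- mini_alignments(30, 1)$control[0, ]
  wc <- window_counts(empty, 1000, reference_length = 10000)
  expect_equal(wc$counts, rep(0L, 10))
})

test_that("depth ratio is exactly 1 for identical libraries and masks zeros", {
  al <- mini_alignments(30, 1)
  wc <- window_counts(al$control, 1000)
  tr <- depth_ratio(wc, wc)
  expect_true(all(tr$ratios[!tr$masked] == 1))
  # force a zero-control window
  wz <- wc
  wz$counts[3] <- 0L
  wz$total_aligned <- sum(wz$counts)
  tr2 <- depth_ratio(wc, wz)
  expect_true(tr2$masked[3])
  expect_true(is.na(tr2$ratios[3]))
  expect_identical(tr2$mask_reason[3], "control_zero")
  expect_false(any(is.infinite(tr2$ratios), na.rm = TRUE))
  wbad <- window_counts(al$control, 2000)
  expect_error(depth_ratio(wc, wbad), "grids")
})

test_that("count-weighted mean of unmasked ratios is 1 (normalization)", {
  al <- mini_alignments(30, 1)
  tr <- depth_ratio(window_counts(al$test, 500),
                    window_counts(al$control, 500))
  ok <- !tr$masked
  wm <- sum((tr$control_counts[ok] / tr$n_control) * tr$ratios[ok])
  expect_equal(wm, 1, tolerance = 1e-9)
})

test_that("raw ratios sit near copy/background in a mostly-neutral genome", {
  # tandem duplication occupying ~7% of the genome: background ratio ~1
  ref <- make_reference(3e5, seed = 21)
  plan <- segment_plan(data.frame(start = c(0, 100000),
                                  end = c(120000, 3e5), strand = "+"))
  d <- build_derivative(ref, plan)
  mut <- simulate_reads(d, coverage = 30, error_rate = 0.005, seed = 31)
  ctl <- simulate_reads(ref, coverage = 30, error_rate = 0.005, seed = 32)
  tr <- depth_ratio(
    window_counts(emit_truth_alignments(mut, d), 2000),
    window_counts(emit_truth_alignments(ctl, ref), 2000))
  dup_win <- 51:59    # interior of the duplicated [100k,120k)
  bg_win <- c(5:45, 70:145)
  expect_gt(median(tr$ratios[dup_win]), 1.8)
  expect_lt(median(tr$ratios[dup_win]), 2.2)
  expect_gt(median(tr$ratios[bg_win]), 0.9)
  expect_lt(median(tr$ratios[bg_win]), 1.1)
})

test_that("segmentation recovers constant, gained and deleted states", {
  al <- mini_alignments(30, 1)
  # constant track
  wc <- window_counts(al$control, 1000)
  tr <- depth_ratio(wc, wc)
  seg <- call_cn_segments(tr)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$state, 1)
  expect_equal(c(seg$start, seg$end), c(0, 250000))
  expect_error(call_cn_segments(depth_ratio(wc, {
    z <- wc; z$counts[] <- 0L; z$total_aligned <- 0L; z
  })), "masked")

  # homozygous deletion: one state-0 segment recovered
  ref <- make_reference(2e5, seed = 22)
  plan <- segment_plan(data.frame(start = c(0, 80000), end = c(50000, 2e5),
                                  strand = "+"))
  d <- build_derivative(ref, plan)
  mut <- simulate_reads(d, coverage = 30, error_rate = 0.005, seed = 33)
  ctl <- simulate_reads(ref, coverage = 30, error_rate = 0.005, seed = 34)
  seg2 <- call_cn_segments(depth_ratio(
    window_counts(emit_truth_alignments(mut, d), 2000),
    window_counts(emit_truth_alignments(ctl, ref), 2000)))
  del <- seg2[seg2$state == 0, ]
  expect_equal(nrow(del), 1)
  expect_equal(del$start, 50000, tolerance = 0.1)
  expect_equal(del$end, 80000, tolerance = 0.1)
})

test_that("default-scenario segmentation recovers the gained territory", {
  # at miniature window counts the ~3-window triplicated segment is at the
  # edge of resolvability, so this asserts the robust structure (gained
  # territory and its bounds); the exact two-doubled-one-tripled view is
  # checked on the full-size run in the acceptance suite
  al <- mini_alignments(100, 1)   # higher depth offsets miniature window noise
  seg <- call_cn_segments(depth_ratio(window_counts(al$test, 500),
                                      window_counts(al$control, 500)))
  gained <- seg[seg$state >= 2, ]
  expect_equal(sum(gained$end - gained$start), 126400, tolerance = 0.03)
  expect_equal(min(gained$start), 50000, tolerance = 0.03)
  expect_equal(max(gained$end), 176400, tolerance = 0.02)
  expect_false(any(seg$state == 0))
  expect_false(any(seg$state > 3))
})

test_that("state recovery does not degrade with more coverage", {
  sc <- mini_scenario()
  prof <- sc$derivative$truth$copy_profile
  truth_state <- function(w, n) {
    mids <- (seq_len(n) - 0.5) * w
    prof$copy[findInterval(mids, prof$start)]
  }
  err_at <- function(coverage, seed) {
    al <- mini_alignments(coverage, seed)
    tr <- depth_ratio(window_counts(al$test, 500),
                      window_counts(al$control, 500))
    seg <- call_cn_segments(tr)
    w <- 500; n <- length(tr$ratios)
    state <- integer(n)
    for (i in seq_len(nrow(seg))) {
      lo <- seg$start[i] %/% w + 1; hi <- ceiling(seg$end[i] / w)
      state[lo:hi] <- seg$state[i]
    }
    mean(state != truth_state(w, n))
  }
  errs <- vapply(1:3, function(s) c(err_at(30, s), err_at(100, s)),
                 numeric(2))
  expect_lte(mean(errs[2, ]), mean(errs[1, ]) + 0.01)
  # >=95% of windows get their truth state at 30x
  expect_gte(1 - mean(errs[1, ]), 0.95)
})

test_that("multi-resolution refinement localizes a gain boundary", {
  # full-size windows on a small genome: the SNR regime of real use
  ref <- make_reference(2e5, seed = 23)
  plan <- segment_plan(data.frame(start = c(0, 60000, 60000),
                                  end = c(140000, 140000, 2e5), strand = "+"))
  d <- build_derivative(ref, plan)
  set.seed(42)
  devs <- vapply(1:6, function(s) {
    mut <- simulate_reads(d, coverage = 30, error_rate = 0.005, seed = 40 + s)
    ctl <- simulate_reads(ref, coverage = 30, error_rate = 0.005, seed = 60 + s)
    amut <- emit_truth_alignments(mut, d)
    actl <- emit_truth_alignments(ctl, ref)
    r <- refine_breakpoint(amut, actl, 60000 + sample(-4000:4000, 1),
                           window_schedule = c(10000, 1000, 200))
    expect_lte(r$interval[2] - r$interval[1], 400)
    expect_gte(60000, r$interval[1] - 200)
    expect_lte(60000, r$interval[2] + 200)
    r$boundary - 60000
  }, numeric(1))
  expect_lte(max(abs(devs)), 400)

  # a boundary inside a constant-state region has no transition
  mut <- simulate_reads(d, coverage = 30, error_rate = 0.005, seed = 47)
  ctl <- simulate_reads(ref, coverage = 30, error_rate = 0.005, seed = 67)
  expect_error(
    refine_breakpoint(emit_truth_alignments(mut, d),
                      emit_truth_alignments(ctl, ref), 185000,
                      window_schedule = c(10000, 1000, 200)),
    "no transition")
  expect_error(
    refine_breakpoint(emit_truth_alignments(mut, d),
                      emit_truth_alignments(ctl, ref), 60000,
                      window_schedule = c(1000, 10000)),
    "decreasing")
})
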