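# Segment graph construction, derivative-walk enumeration, classification.

mini_graph_inputs <- function(coverage = 100, seed = 1) {
  cache_get(sprintf("mini_graph_%d_%d", coverage, seed), function() {
    sc <- mini_scenario()
    al <- mini_alignments(coverage, seed)
    seg <- call_cn_segments(depth_ratio(window_counts(al$test, 500),
                                        window_counts(al$control, 500)))
    mj <- mini_junctions(coverage, seed)
    list(seg = seg, jx = mj$junctions, clusters = mj$clusters, al = al)
  })
}

test_that("segment graph partitions at breakends with correct copies", {
  sc <- mini_scenario()
  gi <- mini_graph_inputs(100, 1)
  g <- build_segment_graph(gi$seg, gi$jx, tolerance = 600,
                           test = gi$al$test, control = gi$al$control,
                           refine_below = 2000, min_direct = 150)
  expect_equal(nrow(g$novel_adjacencies), 4)
  expect_equal(length(g$inconsistencies), 0)
  # segments partition the analyzed region
  expect_equal(g$segments$start[-1], g$segments$end[-nrow(g$segments)])
  expect_equal(min(g$segments$start), 0)
  expect_equal(max(g$segments$end), 250000)
  # copy numbers: 3 duplicated, 1 triplicated, none deleted
  expect_equal(sum(g$segments$copy == 2), 3)
  expect_equal(sum(g$segments$copy == 3), 1)
  expect_equal(sum(g$segments$copy == 0), 0)
  # the sub-window duplicated segment (inverted pair) is recovered by the
  # direct interval re-estimate, invisible to the 500 bp windowed view
  f_seg <- g$segments[g$segments$end - g$segments$start < 1000 &
                        g$segments$copy == 2, ]
  expect_equal(nrow(f_seg), 1)
})

test_that("unexplained copy boundaries surface as inconsistencies", {
  gi <- mini_graph_inputs(100, 1)
  seg <- gi$seg
  # inject a fake state change far from any junction
  fake <- seg[1, ]; fake$start <- 220000; fake$end <- 230000; fake$state <- 2
  pre <- seg[nrow(seg), ]; pre$end <- 220000
  post <- seg[nrow(seg), ]; post$start <- 230000
  seg2 <- rbind(seg[-nrow(seg), ], pre, fake, post)
  attr(seg2, "baseline") <- attr(seg, "baseline")
  g <- build_segment_graph(seg2, gi$jx, tolerance = 600)
  expect_true(220000 %in% g$inconsistencies || 230000 %in% g$inconsistencies)
})

test_that("tandem duplication yields one adjacency explaining both edges", {
  ref <- make_reference(2e5, seed = 24)
  plan <- segment_plan(data.frame(start = c(0, 60000),
                                  end = c(140000, 2e5), strand = "+"))
  d <- build_derivative(ref, plan)
  mut <- simulate_reads(d, coverage = 30, error_rate = 0.005, seed = 51)
  ctl <- simulate_reads(ref, coverage = 30, error_rate = 0.005, seed = 52)
  amut <- emit_truth_alignments(mut, d)
  actl <- emit_truth_alignments(ctl, ref)
  seg <- call_cn_segments(depth_ratio(window_counts(amut, 2000),
                                      window_counts(actl, 2000)))
  jx <- call_junctions(collect_clip_clusters(amut), ref, 3,
                       collect_clip_clusters(actl))
  expect_equal(nrow(jx), 1)
  g <- build_segment_graph(seg, jx, tolerance = 2500)
  expect_equal(nrow(g$novel_adjacencies), 1)
  expect_equal(length(g$inconsistencies), 0)
  # unique walk: A B B C
  w <- enumerate_derivatives(g, max_walks = 100)
  expect_equal(length(w), 1)
  expect_identical(w[[1]], c("S1+", "S2+", "S2+", "S3+"))
})

test_that("enumeration matches the brute-force oracle on small graphs", {
  # tandem duplication
  g1 <- make_graph(c(1, 2, 1),
                   data.frame(name = "j1", seg_a = 2L, side_a = "R",
                              seg_b = 2L, side_b = "L"))
  # inverted duplication (fold-back)
  g2 <- make_graph(c(1, 2, 1),
                   data.frame(name = c("j1", "j2"),
                              seg_a = c(2L, 2L), side_a = c("R", "L"),
                              seg_b = c(2L, 3L), side_b = c("R", "L")))
  # gain next to a pass-through segment
  g3 <- make_graph(c(2, 1, 2),
                   data.frame(name = "j1", seg_a = 3L, side_a = "R",
                              seg_b = 1L, side_b = "L"))
  for (g in list(g1, g2, g3)) {
    mine <- sort(vapply(enumerate_derivatives(g, max_walks = 1000),
                        walk_key, character(1)))
    expect_identical(mine, oracle_walks(g))
  }
})

test_that("every enumerated walk conserves the copy-number vector", {
  gi <- mini_graph_inputs(100, 1)
  g <- build_segment_graph(gi$seg, gi$jx, tolerance = 600,
                           test = gi$al$test, control = gi$al$control,
                           refine_below = 2000, min_direct = 150)
  w <- enumerate_derivatives(g, max_walks = 5000)
  expect_false(attr(w, "truncated"))
  expect_gt(length(w), 0)
  expect_true(all(vapply(w, walk_is_balanced, logical(1), graph = g)))
  # the generator's own derivative order is among the walks
  truth_walk <- c("S1+", "S2+", "S3+", "S3+", "S4+", "S2+", "S3+", "S4+",
                  "S5+", "S6+", "S7+", "S6-", "S8+")
  keys <- vapply(w, walk_key, character(1))
  expect_true(walk_key(truth_walk) %in% keys)
})

test_that("impossible copy numbers return no walks with a diagnostic", {
  g <- make_graph(c(1, 3, 1))   # a triplication with no supporting adjacency
  w <- enumerate_derivatives(g, max_walks = 10)
  expect_equal(length(w), 0)
  expect_match(attr(w, "diagnostic"), "unbalanced")
  expect_error(enumerate_derivatives(g, max_walks = 0), "max_walks")
})

test_that("classification follows the rule table", {
  sigs <- function(mh, tm) data.frame(microhomology_len = mh, templated = tm)

  # single junction -> simple
  g_simple <- make_graph(c(1, 2, 1),
                         data.frame(name = "j1", seg_a = 2L, side_a = "R",
                                    seg_b = 2L, side_b = "L"))
  expect_identical(classify_cgr(g_simple, sigs(0, FALSE))$label, "simple")

  # gains without losses, homology-rich junctions -> chromoanasynthesis-like
  novel4 <- data.frame(name = paste0("j", 1:4),
                       seg_a = c(2L, 3L, 4L, 5L), side_a = "R",
                       seg_b = c(2L, 3L, 4L, 5L), side_b = "L")
  g_gain <- make_graph(c(1, 2, 3, 2, 2, 1), novel4)
  cls <- classify_cgr(g_gain, sigs(c(3, 0, 2, 0), c(FALSE, TRUE, FALSE, FALSE)))
  expect_identical(cls$label, "chromoanasynthesis-like")
  expect_equal(cls$evidence$microhomology_fraction, 0.75)
  expect_false(cls$evidence$deletions_present)

  # interleaved losses with blunt junctions -> chromothripsis-like
  g_shatter <- make_graph(c(1, 0, 1, 0, 1, 0, 1), novel4)
  cls2 <- classify_cgr(g_shatter, sigs(c(0, 0, 1, 0), rep(FALSE, 4)))
  expect_identical(cls2$label, "chromothripsis-like")
  expect_gte(cls2$evidence$oscillating_states, 2)

  # mixed evidence -> unclassified
  g_mixed <- make_graph(c(1, 0, 2, 0, 1), novel4[1:2, ])
  cls3 <- classify_cgr(g_mixed, sigs(c(3, 3), c(TRUE, TRUE)))
  expect_identical(cls3$label, "unclassified")

  # purity: identical evidence, identical label
  expect_identical(classify_cgr(g_gain, sigs(c(3, 0, 2, 0),
                                             c(FALSE, TRUE, FALSE, FALSE)))$label,
                   cls$label)
  # missing signatures error
  expect_error(classify_cgr(g_gain, sigs(c(3, 0), c(FALSE, TRUE))),
               "signature")
})

test_that("default scenario classifies as chromoanasynthesis-like", {
  sc <- mini_scenario()
  gi <- mini_graph_inputs(100, 1)
  g <- build_segment_graph(gi$seg, gi$jx, tolerance = 600,
                           test = gi$al$test, control = gi$al$control,
                           refine_below = 2000, min_direct = 150)
  sig <- do.call(rbind, lapply(seq_len(nrow(gi$jx)), function(k) {
    junction_signature(gi$jx[k, ],
                       suppressWarnings(junction_consensus(gi$jx[k, ], gi$clusters)),
                       sc$reference)
  }))
  cls <- classify_cgr(g, sig)
  expect_identical(cls$label, "chromoanasynthesis-like")
  expect_equal(cls$evidence$junction_count, 4)
  expect_gte(cls$evidence$microhomology_fraction, 0.75)
})
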