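test_that("density score is the percent of segment probes covered by marker windows", {
  probes <- make_probes(c(chr1 = 40))
  w <- make_windows(probes, k = 7)
  seg <- data.frame(sample = c("A", "A", "B"), chrom = "chr1",
                    start_probe = c(5L, 20L, 5L), end_probe = c(14L, 29L, 11L),
                    n_probes = c(10L, 10L, 7L), seg_mean = c(-0.3, 0.2, -0.4),
                    stringsAsFactors = FALSE)
  # A: one 7-probe window fully inside segment 1 -> 70%; nothing in segment 2
  # B: marker window equal to the segment -> 100%
  m <- manual_markers(c("A", "B"), c(6L, 5L), w)
  scored <- density_score(seg, m, probes)
  expect_equal(nrow(scored), 2L)  # markerless segment sieved out
  expect_equal(scored$density_score[scored$sample == "A"], 70)
  expect_equal(scored$density_score[scored$sample == "B"], 100)
})

test_that("density score ignores marker and segment order", {
  probes <- make_probes(c(chr1 = 40))
  w <- make_windows(probes, k = 7)
  seg <- data.frame(sample = "A", chrom = "chr1",
                    start_probe = c(5L, 25L), end_probe = c(14L, 34L),
                    n_probes = c(10L, 10L), seg_mean = c(-0.3, -0.2),
                    stringsAsFactors = FALSE)
  m1 <- manual_markers(c("A", "A"), c(6L, 26L), w)
  m2 <- manual_markers(c("A", "A"), c(26L, 6L), w)
  s1 <- density_score(seg, m1, probes)
  s2 <- density_score(seg[2:1, ], m2, probes)
  expect_equal(s1[order(s1$start_probe), ]$density_score,
               s2[order(s2$start_probe), ]$density_score)
})

test_that("candidate selection applies both strict thresholds and sorts by score", {
  scored <- data.frame(sample = "A", chrom = "chr1",
                       start_probe = c(1L, 10L, 20L, 30L),
                       end_probe = c(5L, 15L, 25L, 35L),
                       n_probes = 5L,
                       seg_mean = c(-0.3, -0.3, 0.05, -0.3),
                       marker_probes = 3L,
                       density_score = c(60, 50, 90, 80))
  out <- select_candidates(scored)
  # 50.0 dropped (not > 50), |0.05| dropped (not > 0.1); sorted descending
  expect_equal(out$density_score, c(80, 60))
  expect_true(all(out$density_score > 50 & abs(out$seg_mean) > 0.1))
})

test_that("marker clustering unions overlapping windows and respects gaps", {
  probes <- make_probes(c(chr1 = 60))
  w <- make_windows(probes, k = 7)
  L <- matrix(-0.2, 2, 60, dimnames = list(c("A", "B"), probes$probe_id))

  m <- manual_markers(c("A", "A"), c(10L, 11L), w)
  seg <- cluster_markers(m, L, probes)
  expect_equal(seg$start_probe, 10L)
  expect_equal(seg$end_probe, 17L)           # union [10, 11+6]
  expect_equal(seg$seg_mean, -0.2)

  m2 <- manual_markers(c("A", "A"), c(10L, 40L), w)
  seg2 <- cluster_markers(m2, L, probes, max_gap_probes = 0L)
  expect_equal(nrow(seg2), 2L)
  seg3 <- cluster_markers(m2, L, probes, max_gap_probes = 30L)
  expect_equal(nrow(seg3), 1L)

  empty <- manual_markers(character(0), integer(0), w)
  expect_equal(nrow(cluster_markers(empty, L, probes)), 0L)
})

test_that("clustered intervals are disjoint per sample and at least k probes long", {
  probes <- make_probes(c(chr1 = 80))
  w <- make_windows(probes, k = 7)
  set.seed(21)
  L <- matrix(rnorm(160), 2, 80, dimnames = list(c("A", "B"), probes$probe_id))
  m <- manual_markers(rep(c("A", "B"), each = 8),
                      c(sample(w$start, 8), sample(w$start, 8)), w)
  seg <- cluster_markers(m, L, probes)
  expect_true(all(seg$n_probes >= 7))
  for (s in unique(seg$sample)) {
    ss <- seg[seg$sample == s, ]
    ss <- ss[order(ss$start_probe), ]
    if (nrow(ss) > 1)
      expect_true(all(ss$start_probe[-1] > ss$end_probe[-nrow(ss)]))
  }
})

test_that("segmenter leaves flat signal whole and honors min_probes", {
  probes <- make_probes(c(chr1 = 50))
  L <- matrix(0.05, 1, 50, dimnames = list("A", probes$probe_id))
  seg <- simple_segment(L, probes)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_probes, 50L)

  probes6 <- make_probes(c(chr1 = 6))
  L6 <- matrix(c(0, 0, 0, 1, 1, 1), 1, 6, dimnames = list("A", probes6$probe_id))
  seg6 <- simple_segment(L6, probes6, min_probes = 10L)
  expect_equal(nrow(seg6), 1L)               # too short to split
})

test_that("segmenter locates a step breakpoint within 2 probes", {
  probes <- make_probes(c(chr1 = 100))
  set.seed(404)
  for (rep in 1:5) {
    x <- c(rnorm(50, 0, 0.05), rnorm(50, -0.5, 0.05))
    L <- matrix(x, 1, 100, dimnames = list("A", probes$probe_id))
    seg <- simple_segment(L, probes)
    expect_equal(nrow(seg), 2L)
    expect_lte(abs(seg$end_probe[1] - 50L), 2L)
  }
})

test_that("segmenter isolates a short interior CNV from a flat background", {
  probes <- make_probes(c(chr1 = 300))
  set.seed(77)
  x <- rnorm(300, 0, 0.1)
  x[141:170] <- x[141:170] - 0.3
  L <- matrix(x, 1, 300, dimnames = list("A", probes$probe_id))
  seg <- simple_segment(L, probes)
  hit <- seg[abs(seg$seg_mean) > 0.2, ]
  expect_equal(nrow(hit), 1L)
  expect_lte(abs(hit$start_probe - 141L), 2L)
  expect_lte(abs(hit$end_probe - 170L), 2L)
})
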