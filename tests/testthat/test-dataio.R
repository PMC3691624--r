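test_that("logratio table is re-sorted to genome order with matching columns", {
  probes <- make_probes(c(chr1 = 2, chr2 = 2))
  vals <- matrix(c(0.1, 0.2, 0.3, 0.4,
                   -0.1, -0.2, -0.3, -0.4), nrow = 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), probes$probe_id))
  set.seed(1)
  path <- write_logratio_fixture(probes, vals, shuffle = TRUE)
  cohort <- read_logratio_table(path)
  expect_equal(cohort$probes$probe_id, probes$probe_id)
  expect_equal(cohort$probes$start, probes$start)
  expect_equal(cohort$values, vals)
})

test_that("missing header column and duplicate probe ids are rejected", {
  probes <- make_probes(c(chr1 = 2))
  vals <- matrix(0, 1, 2, dimnames = list("A", probes$probe_id))
  path <- write_logratio_fixture(probes, vals)
  lines <- readLines(path)
  lines[1] <- sub("chrom", "chr_name", lines[1])
  writeLines(lines, path)
  expect_error(read_logratio_table(path), "chrom")

  probes2 <- probes
  probes2$probe_id <- c("dup", "dup")
  path2 <- write_logratio_fixture(probes2, vals)
  expect_error(read_logratio_table(path2), "duplicate")
})

test_that("empty cells become NA and non-numeric cells are reported", {
  probes <- make_probes(c(chr1 = 2))
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tprobe_id\tA\tB",
               "chr1\t0\t60\tp1\t\t0.5",
               "chr1\t1000\t1060\tp2\t0.1\t0.2"), path)
  cohort <- read_logratio_table(path)
  expect_true(is.na(cohort$values["A", "p1"]))
  expect_equal(cohort$values["B", "p1"], 0.5)

  writeLines(c("chrom\tstart\tend\tprobe_id\tA",
               "chr1\t0\t60\tp1\toops"), path)
  expect_error(read_logratio_table(path), "oops")
})

test_that("SEG records map to probe ranges with recomputed probe counts", {
  probes <- make_probes(c(chr1 = 12))
  # probes 3..7 (1-based) have starts 2000..6000
  seg <- read_segmentation(write_seg_fixture(data.frame(
    ID = "A", chrom = "chr1", loc.start = 2001, loc.end = 6060,
    num.mark = 99, seg.mean = -0.3)), probes)
  expect_equal(seg$start_probe, 3L)
  expect_equal(seg$end_probe, 7L)
  expect_equal(seg$n_probes, 5L)
  expect_equal(seg$seg_mean, -0.3)
})

test_that("zero-probe and unknown-chromosome segments drop with warning; overlaps error", {
  probes <- make_probes(c(chr1 = 10))
  path <- write_seg_fixture(data.frame(
    ID = c("A", "A"), chrom = c("chr9", "chr1"),
    loc.start = c(1, 1), loc.end = c(5000, 5060),
    num.mark = c(1, 5), seg.mean = c(0.2, -0.1)))
  expect_warning(seg <- read_segmentation(path, probes), "dropped")
  expect_equal(nrow(seg), 1L)

  path2 <- write_seg_fixture(data.frame(
    ID = c("A", "A"), chrom = "chr1",
    loc.start = c(1, 3001), loc.end = c(5060, 8060),
    num.mark = c(5, 5), seg.mean = c(0.1, 0.2)))
  expect_error(read_segmentation(path2, probes), "overlapping")
})

test_that("BED parsing follows 0-based half-open convention and skips bad lines", {
  db <- read_interval_db(write_bed_fixture("chr1\t100\t200\tvarA"), "dgv")
  expect_equal(length(db$gr), 1L)
  expect_equal(GenomicRanges::start(db$gr), 101L)  # 1-based internal
  expect_equal(GenomicRanges::end(db$gr), 200L)
  expect_equal(S4Vectors::mcols(db$gr)$record_id, "varA")

  empty <- read_interval_db(write_bed_fixture(character(0)), "isca")
  expect_equal(length(empty$gr), 0L)

  expect_warning(
    db2 <- read_interval_db(write_bed_fixture(c("chr1\t50\t50\tx",
                                                "chr1\t10\t20")), "gad"),
    "skipped")
  expect_equal(length(db2$gr), 1L)
  expect_equal(S4Vectors::mcols(db2$gr)$record_id, "gad_1")
})

test_that("marker BED and scored-segment reports round-trip", {
  probes <- make_probes(c(chr1 = 10))
  w <- make_windows(probes, k = 7)
  out <- tempfile()

  # empty marker set -> header-only file
  empty <- call_markers(matrix(1, nrow(w), 2,
                               dimnames = list(NULL, c("A", "B"))), w)
  write_outputs(empty, NULL, probes, out)
  expect_equal(length(readLines(file.path(out, "markers.bed"))), 1L)

  # one marker on the window of probes 1..7 spans probe 1 start .. probe 7 end
  m <- manual_markers("A", 1L, w)
  write_marker_bed(m, probes, file.path(out, "markers.bed"))
  bed <- read.delim(file.path(out, "markers.bed"))
  expect_equal(bed$start, probes$start[1])
  expect_equal(bed$end, probes$end[7])

  scored <- data.frame(sample = "A", chrom = "chr1", start_probe = 1L,
                       end_probe = 7L, n_probes = 7L, seg_mean = -0.312345,
                       marker_probes = 7L, density_score = 100)
  write_scored_segments(scored, file.path(out, "segments.tsv"))
  back <- read_scored_segments(file.path(out, "segments.tsv"))
  expect_equal(back$seg_mean, scored$seg_mean, tolerance = 1e-6)
  expect_equal(back$start_probe, scored$start_probe)
  expect_equal(back$density_score, scored$density_score)
})

test_that("logratio write/read round-trips values and NA flags", {
  probes <- make_probes(c(chr1 = 3, chr2 = 2))
  set.seed(7)
  vals <- matrix(round(rnorm(10), 6), 2, 5,
                 dimnames = list(c("A", "B"), probes$probe_id))
  vals[1, 3] <- NA
  cohort <- structure(list(probes = probes, values = vals),
                      class = "acgh_cohort")
  back <- read_logratio_table(write_logratio_table(cohort, tempfile()))
  expect_equal(back$values, vals)
  expect_equal(back$probes, probes, ignore_attr = TRUE)
})
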