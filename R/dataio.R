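# Input/output: logratio tables, SEG segmentations, BED interval databases,
# and the pipeline's own marker/segment reports.

probe_index_cols <- c("probe_id", "chrom", "start", "end")

validate_probe_index <- function(probes) {
  stopifnot(is.data.frame(probes), all(probe_index_cols %in% names(probes)))
  if (any(probes$end <= probes$start))
    stop("probe index: every probe must satisfy end > start")
  by_chrom <- split(probes$start, probes$chrom)
  bad <- vapply(by_chrom, function(s) any(diff(s) <= 0), logical(1))
  if (any(bad))
    stop("probe index: starts must be strictly increasing within chromosome(s): ",
         paste(names(by_chrom)[bad], collapse = ", "))
  invisible(probes)
}

#' Read a cohort logratio table
#'
#' Parses a tab-separated table with header columns `chrom`, `start`, `end`,
#' `probe_id` followed by one column per sample. Rows may be in any order;
#' they are re-sorted to genome order (chromosomes in order of first
#' appearance in the file, then by `start`). Probe coordinates are BED-style
#' 0-based half-open base pairs.
#'
#' @param path path to the TSV file.
#' @return An object of class `acgh_cohort`: a list with `probes` (a
#'   `data.frame` with one row per probe, in genome order) and `values`
#'   (numeric matrix, samples in rows, probes in columns; empty cells become
#'   `NA`).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("chrom\tstart\tend\tprobe_id\tS1\tS2",
#'              "chr1\t100\t160\tp1\t0.02\t-0.31",
#'              "chr1\t0\t60\tp0\t-0.01\t0.04"), tf)
#' cohort <- read_logratio_table(tf)
#' cohort$probes$probe_id  # "p0" "p1" after genome-order sort
#' @export
read_logratio_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(probe_index_cols, names(raw))
  if (length(missing_cols))
    stop("logratio table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  sample_ids <- setdiff(names(raw), probe_index_cols)
  if (!length(sample_ids))
    stop("logratio table has no sample columns")
  if (anyDuplicated(raw$probe_id))
    stop("duplicate probe_id in logratio table: ",
         raw$probe_id[duplicated(raw$probe_id)][1])

  probes <- data.frame(probe_id = raw$probe_id,
                       chrom    = raw$chrom,
                       start    = as.integer(raw$start),
                       end      = as.integer(raw$end),
                       stringsAsFactors = FALSE)
  ord <- order(match(probes$chrom, unique(probes$chrom)), probes$start)
  probes <- probes[ord, , drop = FALSE]
  rownames(probes) <- NULL
  validate_probe_index(probes)

  vals <- matrix(NA_real_, nrow = length(sample_ids), ncol = nrow(probes),
                 dimnames = list(sample_ids, probes$probe_id))
  for (s in sample_ids) {
    cell <- raw[[s]][ord]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !(trimws(cell) %in% c("", "NA", "NaN")))
    if (length(bad))
      stop("non-numeric logratio value '", cell[bad[1]], "' at probe ",
           probes$probe_id[bad[1]], ", sample ", s)
    vals[s, ] <- num
  }
  structure(list(probes = probes, values = vals), class = "acgh_cohort")
}

#' Write a cohort logratio table
#'
#' Inverse of [read_logratio_table()]: writes the probe annotation columns
#' followed by one column per sample. `NA` cells become empty fields.
#'
#' @param cohort an `acgh_cohort`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_logratio_table <- function(cohort, path) {
  tab <- cbind(cohort$probes[, probe_index_cols[c(2, 3, 4, 1)]],
               as.data.frame(t(cohort$values)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.acgh_cohort <- function(x, ...) {
  cat("aCGH cohort:", nrow(x$values), "samples x", ncol(x$values), "probes on",
      length(unique(x$probes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Read a SEG-style segmentation file
#'
#' Parses a tab-separated segmentation in the common SEG dialect with header
#' `ID chrom loc.start loc.end num.mark seg.mean` (as written by CBS-style
#' segmenters). Base-pair coordinates are 1-based with inclusive ends. Each
#' segment is mapped to genome-order probe positions: a probe belongs to a
#' segment when its (0-based) start bp lies in `[loc.start - 1, loc.end)`.
#' `num.mark` is recomputed from the mapping.
#'
#' Segments matching zero probes (including segments on chromosomes absent
#' from the probe index) are dropped with a warning; overlapping segments
#' for the same sample are an error.
#'
#' @param path path to the SEG TSV file.
#' @param probes probe index `data.frame` (see [read_logratio_table()]).
#' @return A `cnv_segmentation` data.frame with columns `sample`, `chrom`,
#'   `start_probe`, `end_probe` (1-based, inclusive), `n_probes`,
#'   `seg_mean`.
#' @export
read_segmentation <- function(path, probes) {
  validate_probe_index(probes)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("ID", "chrom", "loc.start", "loc.end", "num.mark", "seg.mean")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols))
    stop("segmentation file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))

  n_dropped <- 0L
  recs <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    hit <- which(probes$chrom == raw$chrom[i] &
                 probes$start >= raw$loc.start[i] - 1 &
                 probes$start <  raw$loc.end[i])
    if (!length(hit)) { n_dropped <- n_dropped + 1L; next }
    recs[[i]] <- data.frame(sample = as.character(raw$ID[i]),
                            chrom = raw$chrom[i],
                            start_probe = min(hit), end_probe = max(hit),
                            n_probes = length(hit),
                            seg_mean = as.numeric(raw$seg.mean[i]),
                            stringsAsFactors = FALSE)
  }
  if (n_dropped)
    warning(n_dropped, " segment(s) matched zero probes and were dropped")
  seg <- do.call(rbind, recs)
  if (is.null(seg))
    seg <- data.frame(sample = character(), chrom = character(),
                      start_probe = integer(), end_probe = integer(),
                      n_probes = integer(), seg_mean = numeric(),
                      stringsAsFactors = FALSE)
  rownames(seg) <- NULL
  check_segmentation_overlap(seg)
  class(seg) <- c("cnv_segmentation", "data.frame")
  seg
}

check_segmentation_overlap <- function(seg) {
  if (!nrow(seg)) return(invisible(seg))
  for (key in split(seq_len(nrow(seg)),
                    paste(seg$sample, seg$chrom, sep = "\r"))) {
    if (length(key) < 2) next
    s <- seg[key, , drop = FALSE]
    s <- s[order(s$start_probe), , drop = FALSE]
    if (any(s$start_probe[-1] <= s$end_probe[-nrow(s)]))
      stop("overlapping segments for sample ", s$sample[1],
           " on ", s$chrom[1])
  }
  invisible(seg)
}

#' Read an interval database track from a BED file
#'
#' Reads a BED3+ file (0-based, half-open) into an interval database that
#' can stand in for ISCA, DGV or GAD content. The fourth column, when
#' present, supplies record ids; otherwise ids are synthesized. Lines with
#' `start >= end` are skipped and counted in a warning. Track/browser/#
#' lines are ignored.
#'
#' @param path path to the BED file.
#' @param name database role, e.g. `"isca"`, `"dgv"`, `"gad"`.
#' @return An `interval_db`: list with `name` and `gr`, a
#'   [GenomicRanges::GRanges] holding the intervals (1-based internally)
#'   with a `record_id` metadata column.
#' @export
read_interval_db <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  chrom <- character(0); start <- integer(0); end <- integer(0); id <- character(0)
  n_skipped <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) f <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(f) < 3) stop("malformed BED line in ", path, ": ", ln)
    s <- as.integer(f[2]); e <- as.integer(f[3])
    if (is.na(s) || is.na(e)) stop("non-integer BED coordinates in ", path, ": ", ln)
    if (s >= e) { n_skipped <- n_skipped + 1L; next }
    chrom <- c(chrom, f[1]); start <- c(start, s); end <- c(end, e)
    id <- c(id, if (length(f) >= 4) f[4] else NA_character_)
  }
  if (n_skipped)
    warning(n_skipped, " BED line(s) with start >= end skipped in ", path)
  if (anyNA(id) && length(id))
    id[is.na(id)] <- paste0(name, "_", which(is.na(id)))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  S4Vectors::mcols(gr)$record_id <- id
  structure(list(name = name, gr = gr), class = "interval_db")
}

#' @export
print.interval_db <- function(x, ...) {
  cat("interval db '", x$name, "': ", length(x$gr), " interval(s)\n", sep = "")
  invisible(x)
}

#' Write marker and scored-segment reports
#'
#' Markers go to a BED-like file (`chrom`, window start bp, window end bp,
#' `sample`, `p`), one line per (sample, window) marker, with a header.
#' Scored segments go to a TSV carrying every column of the scored table.
#'
#' @param markers a `marker_set` (see [detect_markers()]); may be empty.
#' @param scored a scored/annotated segment `data.frame`
#'   (see [density_score()], [annotate_segments()]); may be `NULL`.
#' @param probes probe index.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the paths written (`markers.bed`, `segments.tsv`).
#' @export
write_outputs <- function(markers, scored, probes, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory ", out_dir)
  marker_path <- file.path(out_dir, "markers.bed")
  seg_path <- file.path(out_dir, "segments.tsv")
  write_marker_bed(markers, probes, marker_path)
  if (!is.null(scored)) write_scored_segments(scored, seg_path)
  invisible(c(markers = marker_path, segments = seg_path))
}

#' @rdname write_outputs
#' @param path output file path.
#' @export
write_marker_bed <- function(markers, probes, path) {
  k <- attr(markers, "k")
  if (is.null(k)) k <- 7L
  df <- data.frame(chrom = character(), start = integer(), end = integer(),
                   sample = character(), p = numeric(),
                   stringsAsFactors = FALSE)
  if (nrow(markers)) {
    q <- markers$start_probe
    df <- data.frame(chrom = probes$chrom[q],
                     start = probes$start[q],
                     end   = probes$end[q + k - 1L],
                     sample = markers$sample,
                     p = markers$p, stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_outputs
#' @export
write_scored_segments <- function(scored, path) {
  utils::write.table(as.data.frame(scored), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_outputs
#' @export
read_scored_segments <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  class(df) <- c("scored_segments", "data.frame")
  df
}
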