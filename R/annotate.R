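# Database annotation of candidate segments and the enrichment curve.

seg_to_granges <- function(scored, probes) {
  GenomicRanges::GRanges(
    scored$chrom,
    IRanges::IRanges(probes$start[scored$start_probe] + 1L,
                     probes$end[scored$end_probe]))
}

#' Count database intervals overlapping a segment
#'
#' Counts intervals of an interval database overlapping a bp segment by at
#' least one base, or — when `min_reciprocal > 0` — by at least that
#' fraction of both the segment and the database interval (reciprocal
#' overlap).
#'
#' @param chrom chromosome name.
#' @param start,end segment bp coordinates, BED-style 0-based half-open.
#' @param db an `interval_db` from [read_interval_db()].
#' @param min_reciprocal reciprocal overlap fraction in \[0, 1\]; 0 (the
#'   default) means any 1-bp overlap counts.
#' @return Integer count of overlapping database records.
#' @export
overlap_counts <- function(chrom, start, end, db, min_reciprocal = 0) {
  stopifnot(inherits(db, "interval_db"), end > start)
  seg <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  # a chromosome absent from the db is an ordinary zero-overlap case
  hits <- suppressWarnings(GenomicRanges::findOverlaps(seg, db$gr))
  if (!length(hits)) return(0L)
  if (min_reciprocal > 0) {
    q <- seg[S4Vectors::queryHits(hits)]
    s <- db$gr[S4Vectors::subjectHits(hits)]
    ov <- IRanges::width(GenomicRanges::pintersect(q, s))
    keep <- ov >= min_reciprocal * IRanges::width(q) &
      ov >= min_reciprocal * IRanges::width(s)
    return(sum(keep))
  }
  length(hits)
}

#' Classify a segment from its database overlap counts
#'
#' A segment with a significant DGV presence (`dgv >= dgv_min` benign
#' records) is a common variant regardless of other hits; otherwise any
#' ISCA (pathogenic) or GAD (disease-association) hit makes it a rare
#' candidate; otherwise it is unsupported.
#'
#' @param db_counts named list/vector of counts; names among `isca`,
#'   `dgv`, `gad` (missing names count as 0).
#' @param dgv_min DGV record count defining "significant" (default 3).
#' @return One of `"common_dgv"`, `"rare_candidate"`, `"unsupported"`.
#' @export
classify_segment <- function(db_counts, dgv_min = 3L) {
  cnt <- function(nm) if (!is.null(db_counts[[nm]]) && !is.na(db_counts[[nm]]))
    db_counts[[nm]] else 0L
  if (cnt("dgv") >= dgv_min) return("common_dgv")
  if (cnt("isca") > 0 || cnt("gad") > 0) return("rare_candidate")
  "unsupported"
}

#' Annotate scored segments against interval databases
#'
#' Adds one overlap-count column per database plus a `label` column from
#' [classify_segment()].
#'
#' @param scored a `scored_segments` data.frame.
#' @param probes probe index (for probe-to-bp conversion).
#' @param dbs named list of `interval_db` objects; expected roles are
#'   `isca`, `dgv`, `gad`, but any BED track can be registered under those
#'   names.
#' @param dgv_min see [classify_segment()].
#' @param min_reciprocal see [overlap_counts()].
#' @return An `annotated_segments` data.frame.
#' @export
annotate_segments <- function(scored, probes, dbs, dgv_min = 3L,
                              min_reciprocal = 0) {
  out <- as.data.frame(scored)
  for (nm in names(dbs)) {
    out[[nm]] <- vapply(seq_len(nrow(out)), function(i)
      overlap_counts(out$chrom[i],
                     probes$start[out$start_probe[i]],
                     probes$end[out$end_probe[i]],
                     dbs[[nm]], min_reciprocal = min_reciprocal),
      integer(1))
  }
  out$label <- vapply(seq_len(nrow(out)), function(i)
    classify_segment(as.list(out[i, names(dbs), drop = FALSE]),
                     dgv_min = dgv_min), character(1))
  class(out) <- c("annotated_segments", "scored_segments", "data.frame")
  out
}

#' Enrichment curve of a ranked candidate list
#'
#' Walks down the density-score ranking and records, after each fraction of
#' the list screened, the fraction of all positives recovered. The curve
#' runs from (0, 0) to (1, 1); a random ordering tracks the diagonal in
#' expectation, a perfect ordering reaches 1 at the positive prevalence.
#'
#' @param scores numeric vector (higher = screened earlier).
#' @param positives logical vector aligned with `scores`; at least one
#'   `TRUE` required.
#' @return A data.frame with `fraction_screened` and `fraction_found`.
#' @export
enrichment_curve <- function(scores, positives) {
  stopifnot(length(scores) == length(positives), any(positives))
  ord <- order(-scores)
  n <- length(scores)
  cum <- cumsum(positives[ord])
  data.frame(fraction_screened = (0:n) / n,
             fraction_found = c(0, cum / sum(positives)))
}
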