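# Marker-to-segment mapping, density score, candidate selection,
# marker clustering (segmentation-free mode), and a minimal recursive
# binary segmenter for plumbing.

marker_probe_mask <- function(markers, k, p) {
  # per-sample logical vector of probes covered by >= 1 flagged window
  masks <- list()
  if (!nrow(markers)) return(masks)
  for (i in seq_len(nrow(markers))) {
    s <- markers$sample[i]
    if (is.null(masks[[s]])) masks[[s]] <- logical(p)
    q <- markers$start_probe[i]
    masks[[s]][q:(q + k - 1L)] <- TRUE
  }
  masks
}

#' Score segments by marker coverage density
#'
#' For each segment of a sample, counts the probes covered by the union of
#' that sample's flagged marker windows and converts the count into the
#' density score: the percent of the segment covered by markers. Segments
#' containing no marker probe are sieved out of the result.
#'
#' @param seg a `cnv_segmentation`.
#' @param markers a (typically polymorphism-filtered) `marker_set`.
#' @param probes probe index.
#' @param k marker window size; defaults to the marker set's `k`.
#' @return A `scored_segments` data.frame: the segment columns plus
#'   `marker_probes` and `density_score` (percent in \[0, 100\]).
#' @export
density_score <- function(seg, markers, probes, k = NULL) {
  if (is.null(k)) k <- attr(markers, "k")
  stopifnot(!is.null(k))
  p <- nrow(probes)
  masks <- marker_probe_mask(markers, k, p)
  covered <- integer(nrow(seg))
  for (i in seq_len(nrow(seg))) {
    mask <- masks[[seg$sample[i]]]
    if (is.null(mask)) next
    covered[i] <- sum(mask[seg$start_probe[i]:seg$end_probe[i]])
  }
  out <- as.data.frame(seg)
  out$marker_probes <- covered
  out$density_score <- 100 * covered / out$n_probes
  out <- out[out$marker_probes > 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scored_segments", "data.frame")
  out
}

#' Select candidate rare-CNV segments
#'
#' Keeps segments with density score strictly above `min_score` percent and
#' absolute segment mean strictly above `min_abs_mean`, sorted by
#' descending density score (stable for ties).
#'
#' @param scored a `scored_segments` data.frame.
#' @param min_score density-score cutoff, percent (default 50).
#' @param min_abs_mean cutoff on |segment mean logratio| (default 0.1).
#' @return The selected subset, sorted by descending `density_score`.
#' @export
select_candidates <- function(scored, min_score = 50, min_abs_mean = 0.1) {
  keep <- scored$density_score > min_score & abs(scored$seg_mean) > min_abs_mean
  out <- scored[keep, , drop = FALSE]
  out <- out[order(-out$density_score), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scored_segments", "data.frame")
  out
}

#' Cluster markers into segments (segmentation-free mode)
#'
#' Per sample, takes the union of all flagged windows' probe intervals,
#' merges runs separated by at most `max_gap_probes` unmarked probes
#' (never across a chromosome boundary), and recomputes each interval's
#' mean logratio from `L`. This turns the marker phase itself into a
#' multi-sample segmenter.
#'
#' @param markers a `marker_set`.
#' @param L logratio matrix (samples x probes) or `acgh_cohort`.
#' @param probes probe index.
#' @param max_gap_probes merge gaps of at most this many probes (default 0).
#' @param k marker window size; defaults to the marker set's `k`.
#' @return A `cnv_segmentation` data.frame.
#' @export
cluster_markers <- function(markers, L, probes, max_gap_probes = 0L, k = NULL) {
  if (inherits(L, "acgh_cohort")) L <- L$values
  if (is.null(k)) k <- attr(markers, "k")
  stopifnot(!is.null(k))
  p <- nrow(probes)
  chrom_id <- match(probes$chrom, unique(probes$chrom))
  masks <- marker_probe_mask(markers, k, p)
  recs <- list()
  for (s in names(masks)) {
    mask <- masks[[s]]
    if (max_gap_probes > 0) {
      r <- rle(mask)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in seq_along(r$values)) {
        # a FALSE run is merged only when flanked by TRUE runs on the
        # same chromosome
        if (!r$values[j] && r$lengths[j] <= max_gap_probes &&
            j > 1 && j < length(r$values) &&
            chrom_id[starts[j] - 1L] == chrom_id[ends[j] + 1L])
          mask[starts[j]:ends[j]] <- TRUE
      }
    }
    in_run <- mask
    r <- rle(paste0(as.integer(in_run), "_", chrom_id))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- grepl("^1_", r$values)
    for (j in which(keep)) {
      a <- starts[j]; b <- ends[j]
      recs[[length(recs) + 1L]] <-
        data.frame(sample = s, chrom = probes$chrom[a],
                   start_probe = a, end_probe = b, n_probes = b - a + 1L,
                   seg_mean = mean(L[s, a:b], na.rm = TRUE),
                   stringsAsFactors = FALSE)
    }
  }
  seg <- do.call(rbind, recs)
  if (is.null(seg))
    seg <- data.frame(sample = character(), chrom = character(),
                      start_probe = integer(), end_probe = integer(),
                      n_probes = integer(), seg_mean = numeric(),
                      stringsAsFactors = FALSE)
  seg <- seg[order(seg$sample, seg$start_probe), , drop = FALSE]
  rownames(seg) <- NULL
  class(seg) <- c("cnv_segmentation", "data.frame")
  seg
}

#' Minimal recursive binary segmenter
#'
#' A deliberately small plumbing segmenter for when no external
#' segmentation is supplied. Per sample and chromosome it performs a
#' CBS-style recursive scan: on each interval it finds the sub-segment
#' maximizing the pooled two-sample t statistic between the segment mean
#' and the mean of the rest of the interval (the segment-vs-rest form is
#' what gives power for short interior CNVs, which a plain left/right
#' breakpoint test dilutes away), accepts it when the Bonferroni-adjusted
#' p-value over all candidate segments is below `alpha` and both segment
#' and rest keep at least `min_probes` probes, and recurses into the
#' resulting parts. Segment means are the mean logratios of the final
#' intervals. The scan is quadratic in chromosome probe count; an external
#' SEG file should take precedence for anything beyond plumbing.
#'
#' @param L logratio matrix (samples x probes) or `acgh_cohort`.
#' @param probes probe index.
#' @param min_probes minimum probes in a segment and in its complement
#'   (default 10).
#' @param alpha significance level for accepting a segment (default 0.01).
#' @return A `cnv_segmentation` data.frame covering every probe of every
#'   sample.
#' @export
simple_segment <- function(L, probes, min_probes = 10L, alpha = 0.01) {
  if (inherits(L, "acgh_cohort")) L <- L$values
  stopifnot(is.matrix(L), ncol(L) == nrow(probes))
  samples <- rownames(L)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(L)))
  runs <- rle(probes$chrom)
  chrom_end <- cumsum(runs$lengths)
  chrom_start <- chrom_end - runs$lengths + 1L

  # length-dependent matrices are identical for every interval of the same
  # length (one full chromosome dominates), so cache them
  geom_cache <- new.env(parent = emptyenv())
  interval_geometry <- function(len) {
    key <- as.character(len)
    g <- geom_cache[[key]]
    if (is.null(g)) {
      N1 <- matrix(0:len, len + 1L, len + 1L, byrow = TRUE) - (0:len)
      N2 <- len - N1
      valid <- N1 >= min_probes & N2 >= min_probes
      invN <- suppressWarnings(1 / N1 + 1 / N2)
      g <- list(N1 = N1, N2 = N2, valid = valid, invN = invN,
                n_valid = sum(valid))
      if (length(ls(geom_cache)) > 3) rm(list = ls(geom_cache)[1],
                                         envir = geom_cache)
      geom_cache[[key]] <- g
    }
    g
  }

  # best segment (a, b] (0-based boundaries within the interval) vs rest
  best_segment <- function(xs) {
    len <- length(xs)
    g <- interval_geometry(len)
    if (!g$n_valid) return(NULL)
    rms <- sqrt(mean(xs^2))
    if (max(xs) - min(xs) <= 1e-10 * (rms + 1e-300)) return(NULL) # constant
    cs <- c(0, cumsum(xs)); css <- c(0, cumsum(xs^2))
    SUM <- matrix(cs, len + 1L, len + 1L, byrow = TRUE) - cs
    SS <- matrix(css, len + 1L, len + 1L, byrow = TRUE) - css
    m1 <- SUM / g$N1
    m2 <- (cs[len + 1L] - SUM) / g$N2
    sp2 <- pmax((SS - g$N1 * m1^2) +
                ((css[len + 1L] - SS) - g$N2 * m2^2), 0) / (len - 2)
    tt <- suppressWarnings(abs(m1 - m2) / sqrt(sp2 * g$invN))
    # pooled variance at rounding-error scale means piecewise-constant data:
    # split when the means genuinely differ, never on cancellation noise
    deg <- g$valid & !is.na(sp2) & sp2 <= 1e-12 * rms^2
    tt[deg] <- ifelse(abs(m1 - m2)[deg] > 1e-6 * rms, Inf, 0)
    tt[!g$valid | is.na(tt)] <- -Inf
    best <- arrayInd(which.max(tt), dim(tt))
    pval <- 2 * stats::pt(-tt[best], df = len - 2)
    pval <- min(1, pval * g$n_valid)  # Bonferroni over candidate segments
    if (is.na(pval) || pval >= alpha) return(NULL)
    c(a = best[1] - 1L, b = best[2] - 1L)  # segment covers positions a+1 .. b
  }

  boundaries <- function(x, lo, hi, acc) {
    len <- hi - lo + 1L
    if (len < 2L * min_probes) return(c(acc, lo))
    seg <- best_segment(x[lo:hi])
    if (is.null(seg)) return(c(acc, lo))
    a <- seg[["a"]]; b <- seg[["b"]]
    if (a > 0) acc <- boundaries(x, lo, lo + a - 1L, acc)
    acc <- boundaries(x, lo + a, lo + b - 1L, acc)
    if (b < len) acc <- boundaries(x, lo + b, hi, acc)
    acc
  }

  recs <- list()
  for (si in seq_along(samples)) {
    x <- L[si, ]
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    for (ci in seq_along(runs$values)) {
      starts <- sort(unique(boundaries(x, chrom_start[ci], chrom_end[ci],
                                       integer(0))))
      ends <- c(starts[-1] - 1L, chrom_end[ci])
      for (j in seq_along(starts)) {
        a <- starts[j]; bnd <- ends[j]
        recs[[length(recs) + 1L]] <-
          data.frame(sample = samples[si], chrom = runs$values[ci],
                     start_probe = a, end_probe = bnd,
                     n_probes = bnd - a + 1L,
                     seg_mean = mean(L[si, a:bnd], na.rm = TRUE),
                     stringsAsFactors = FALSE)
      }
    }
  }
  seg <- do.call(rbind, recs)
  rownames(seg) <- NULL
  class(seg) <- c("cnv_segmentation", "data.frame")
  seg
}
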