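# Cohort polymorphic profile and marker filtering.
#
# The outlier statistic also fires inside highly polymorphic regions, where
# the cohort background itself diverges from the null. The segmentation is
# mapped back onto probes (each probe inherits its segment's mean
# logratio), probes where more than 1% of samples carry a clearly non-noisy
# signal (|mean| > 0.07 in log10 units, i.e. 0.24 in log2) are flagged, and
# windows of k consecutive flagged probes define the polymorphic windows
# whose markers are discarded.

#' Map a segmentation onto per-probe signal values
#'
#' For every sample and probe, the value of the segment mean of the segment
#' containing that probe; probes covered by no segment carry 0 (they are
#' noise by construction and never count toward polymorphism).
#'
#' @param seg a `cnv_segmentation`.
#' @param probes probe index.
#' @param samples character vector of sample ids defining the row order;
#'   defaults to the samples present in `seg`.
#' @return Numeric matrix, samples x probes.
#' @export
segmentation_to_probe_signal <- function(seg, probes, samples = NULL) {
  if (is.null(samples)) samples <- unique(seg$sample)
  p <- nrow(probes)
  sig <- matrix(0, length(samples), p,
                dimnames = list(samples, probes$probe_id))
  for (i in seq_len(nrow(seg))) {
    s <- seg$sample[i]
    if (!s %in% samples) next
    sig[s, seg$start_probe[i]:seg$end_probe[i]] <- seg$seg_mean[i]
  }
  sig
}

#' Build the cohort polymorphic profile
#'
#' Marks probe q as polymorphic (1) when strictly more than
#' `floor(frequency * n)` samples have `|signal| > signal_threshold` there —
#' for a 366-sample cohort at the defaults this is the "more than 3 samples
#' above 0.07" rule. Both comparisons are strict.
#'
#' @param probe_signal samples x probes matrix from
#'   [segmentation_to_probe_signal()].
#' @param signal_threshold non-noise threshold on |segment mean|, log10
#'   units (default 0.07, equivalent to 0.24 in log2).
#' @param frequency cohort frequency defining "polymorphic" (default 0.01).
#' @return A `polymorphic_profile`: integer 0/1 vector of length p with
#'   attributes `signal_threshold` and `count_threshold`.
#' @export
build_polymorphic_profile <- function(probe_signal, signal_threshold = 0.07,
                                      frequency = 0.01) {
  stopifnot(is.matrix(probe_signal), nrow(probe_signal) >= 1)
  n <- nrow(probe_signal)
  count_threshold <- max(1L, as.integer(floor(frequency * n)))
  counts <- colSums(abs(probe_signal) > signal_threshold)
  profile <- as.integer(counts > count_threshold)
  structure(profile, signal_threshold = signal_threshold,
            count_threshold = count_threshold,
            class = "polymorphic_profile")
}

#' Windows lying wholly inside polymorphic regions
#'
#' Finds every genome-order window start position q such that all k probes
#' q..q+k-1 are flagged polymorphic and lie on one chromosome.
#'
#' @param profile a `polymorphic_profile` (or plain 0/1 vector).
#' @param probes probe index (supplies chromosome boundaries).
#' @param k window size; must match the marker window size.
#' @return Integer vector of window start positions.
#' @export
polymorphic_windows <- function(profile, probes, k = 7L) {
  k <- as.integer(k)
  p <- length(profile)
  stopifnot(p == nrow(probes), k >= 2)
  w <- make_windows(probes, k = k, step = 1L)
  if (!nrow(w)) return(integer(0))
  cum <- c(0L, cumsum(as.integer(profile)))
  runsum <- cum[w$start + k] - cum[w$start]
  w$start[runsum == k]
}

#' Remove markers falling in polymorphic windows
#'
#' `mode = "intersect"` (default) drops markers whose window start position
#' is itself a polymorphic window — the literal intersection of the two
#' window sets. `mode = "overlap"` drops markers whose window shares at
#' least one probe with any polymorphic window.
#'
#' @param markers a `marker_set`.
#' @param poly_windows integer vector from [polymorphic_windows()].
#' @param mode exclusion semantics, `"intersect"` or `"overlap"`.
#' @param k window size; defaults to the marker set's own `k`.
#' @return The filtered `marker_set` (a subset of the input; idempotent).
#' @export
filter_markers <- function(markers, poly_windows,
                           mode = c("intersect", "overlap"), k = NULL) {
  mode <- match.arg(mode)
  if (is.null(k)) k <- attr(markers, "k")
  stopifnot(!is.null(k))
  if (!nrow(markers) || !length(poly_windows)) return(markers)
  if (mode == "intersect") {
    drop <- markers$start_probe %in% poly_windows
  } else {
    pw <- sort(unique(poly_windows))
    drop <- vapply(markers$start_probe,
                   function(q) any(abs(q - pw) < k), logical(1))
  }
  out <- markers[!drop, , drop = FALSE]
  rownames(out) <- NULL
  new_marker_set(out, k = k, p_threshold = attr(markers, "p_threshold"),
                 n_windows = attr(markers, "n_windows"),
                 n_samples = attr(markers, "n_samples"))
}
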