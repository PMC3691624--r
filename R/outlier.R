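# Windowed mean-distance outlier statistic, Beta null fit, marker calling.
#
# For a window Q of k consecutive probes and pseudo-rank matrix R, the
# statistic for sample s is the mean L_d distance from its k-mer to every
# sample's k-mer (the zero self-term stays inside the mean):
#
#   mu_d(s) = (1/|S|) * sum_{j in S} ( sum_{l in Q} |R[l,s] - R[l,j]|^d )^(1/d)
#
# Samples whose local rank profile sits far from the rest of the cohort —
# the rare-CNV carriers — have large mu. Within each window the cohort's
# own mu values define the null: they are min-max rescaled to (0,1) and a
# Beta(alpha, beta) is fitted by the method of moments; (sample, window)
# pairs with upper-tail p-value below 1% become rare-CNV markers.

#' Build sliding probe windows
#'
#' Enumerates all windows of `k` consecutive genome-order probes, advancing
#' by `step`, never crossing a chromosome boundary. Chromosomes with fewer
#' than `k` probes contribute no windows.
#'
#' @param probes probe index `data.frame` in genome order.
#' @param k window size in probes (default 7).
#' @param step window stride in probes (default 1, fully sliding).
#' @return A `window_spec` data.frame with columns `chrom` and `start`
#'   (1-based genome-order probe position of the window's first probe;
#'   the window covers probes `start .. start + k - 1`), with attributes
#'   `k` and `step`.
#' @export
make_windows <- function(probes, k = 7L, step = 1L) {
  k <- as.integer(k); step <- as.integer(step)
  if (is.na(k) || k < 2) stop("window size k must be an integer >= 2")
  if (is.na(step) || step < 1) stop("step must be an integer >= 1")
  validate_probe_index(probes)
  runs <- rle(probes$chrom)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- vector("list", length(runs$values))
  for (i in seq_along(runs$values)) {
    if (runs$lengths[i] < k) next
    q <- seq.int(starts[i], ends[i] - k + 1L, by = step)
    out[[i]] <- data.frame(chrom = runs$values[i], start = q,
                           stringsAsFactors = FALSE)
  }
  w <- do.call(rbind, out)
  if (is.null(w))
    w <- data.frame(chrom = character(), start = integer(),
                    stringsAsFactors = FALSE)
  rownames(w) <- NULL
  attr(w, "k") <- k
  attr(w, "step") <- step
  class(w) <- c("window_spec", "data.frame")
  w
}

#' Mean L_d distance statistic for one window
#'
#' Computes, for every sample, the mean L_d distance between its pseudo-rank
#' vector over the window's probes and every sample's vector (including the
#' zero distance to itself; the divisor is the number of samples entering
#' the window). Samples with any missing cell inside the window are
#' excluded: their statistic is `NA` and they are not counted in anyone's
#' mean.
#'
#' @param R pseudo-rank matrix (samples x probes).
#' @param window integer vector of probe positions (columns of `R`) forming
#'   the window.
#' @param d distance order; 1 (Manhattan, the default), any finite p > 0,
#'   or `Inf` for the maximum metric.
#' @return Numeric vector, one value per sample (`NA` for excluded ones).
#' @examples
#' R <- cbind(c(0.25, 0.5, 0.75))
#' mu_statistic(R, 1)  # 0.25, 1/6, 0.25
#' @export
mu_statistic <- function(R, window, d = 1) {
  stopifnot(is.matrix(R))
  if (nrow(R) < 2) stop("mu_statistic needs at least 2 samples")
  Rw <- R[, window, drop = FALSE]
  incl <- rowSums(is.na(Rw)) == 0L
  mu <- rep(NA_real_, nrow(R))
  names(mu) <- rownames(R)
  m <- sum(incl)
  if (m == 0) {
    warning("window has no fully observed sample; skipped")
    return(mu)
  }
  if (m < 2) return(mu)
  Ri <- Rw[incl, , drop = FALSE]
  method <- if (is.infinite(d)) "maximum" else if (d == 1) "manhattan" else "minkowski"
  D <- as.matrix(stats::dist(Ri, method = method, p = d))
  mu[incl] <- rowSums(D) / m
  mu
}

#' Mu statistic for every window (vectorized driver)
#'
#' Computes [mu_statistic()] for every window of a [make_windows()] spec.
#' For the default Manhattan distance on a fully observed matrix the L1
#' distance separates over probes, so per-probe absolute-difference sums
#' are computed once in O(n log n) per probe and windows are formed by
#' cumulative sums — orders of magnitude faster than per-window pairwise
#' distances. Other settings fall back to the per-window computation.
#'
#' @inheritParams mu_statistic
#' @param windows a `window_spec`.
#' @return Numeric matrix, windows x samples.
#' @export
mu_matrix <- function(R, windows, d = 1) {
  k <- attr(windows, "k")
  nw <- nrow(windows)
  M <- matrix(NA_real_, nw, nrow(R),
              dimnames = list(NULL, rownames(R)))
  if (!nw) return(M)
  if (d == 1 && !anyNA(R)) {
    n <- nrow(R)
    # A[s, q] = sum_j |R[s,q] - R[j,q]| via the sorted prefix-sum identity
    A <- matrix(0, n, ncol(R))
    for (q in seq_len(ncol(R))) {
      v <- R[, q]
      o <- order(v)
      vs <- v[o]
      cs <- cumsum(vs)
      i <- seq_len(n)
      S <- (2 * i - n) * vs + cs[n] - 2 * cs
      A[o, q] <- S
    }
    Ccum <- cbind(0, t(apply(A, 1, cumsum)))  # n x (p+1) running sums
    hi <- windows$start + k          # column hi in the 0-padded cumsum
    lo <- windows$start              # column just before the window
    M[] <- (t(Ccum[, hi, drop = FALSE]) - t(Ccum[, lo, drop = FALSE])) / n
  } else {
    for (w in seq_len(nw)) {
      q <- windows$start[w]
      M[w, ] <- suppressWarnings(mu_statistic(R, q:(q + k - 1L), d = d))
    }
  }
  M
}

#' Large-cohort closed form of the k = 1 statistic
#'
#' For a single probe (k = 1) and Manhattan distance, the outlier statistic
#' of a sample at pseudo-rank `z` converges, as the cohort grows, to a
#' parabola with minimum at z = 1/2: the sum of squared distances from z to
#' the two extreme ranks 0 and 1,
#' \deqn{z^2 + (1-z)^2.}
#' This is the corner-distance scale: the mean pairwise distance
#' \eqn{\int_0^1 |t-z|\,dt} equals half of it, so the empirical statistic
#' satisfies \eqn{2\,\mu^1(z) \to z^2 + (1-z)^2}. See the methods vignette
#' for the role of this limit in validating the statistic.
#'
#' @param z pseudo-rank value(s) in \[0, 1\].
#' @return `z^2 + (1 - z)^2`.
#' @export
mu_closed_form_k1 <- function(z) {
  if (any(z < 0 | z > 1)) stop("z must lie in [0, 1]")
  z^2 + (1 - z)^2
}

#' Monte-Carlo draws of mu under the independence null
#'
#' Simulates the null distribution of the statistic when all `k` window
#' columns are pseudo-ranks of independent identically distributed data:
#' each replicate draws an n x k matrix of iid uniforms, rank-transforms
#' each column, and records the statistic of one sample. For d = 1 the
#' statistic is a sum of independent per-column contributions, which is the
#' analytic route to the null; this sampler is its simulation counterpart
#' and the package's independent oracle for the limit results.
#'
#' @param k window size.
#' @param n cohort size.
#' @param reps number of Monte-Carlo replicates.
#' @param d distance order (default 1).
#' @param seed optional integer; when given, draws are reproducible and the
#'   caller's RNG state is untouched.
#' @return Numeric vector of `reps` draws of mu.
#' @export
simulate_independence_null <- function(k, n, reps, d = 1, seed = NULL) {
  stopifnot(k >= 1, n >= 2, reps >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  out <- numeric(reps)
  for (r in seq_len(reps)) {
    X <- matrix(stats::runif(n * k), n, k)
    R <- apply(X, 2, rank) / (n + 1)
    if (k == 1) R <- matrix(R, ncol = 1)
    A <- abs(R - matrix(R[1, ], n, k, byrow = TRUE))
    dists <- if (is.infinite(d)) apply(A, 1, max) else rowSums(A^d)^(1 / d)
    out[r] <- mean(dists)
  }
  out
}

#' Fit the window null as a shifted Beta distribution
#'
#' Rescales the window's mu values to (0, 1) over the observed range
#' `[lo, hi]` (by default `lo = min(mu)`, `hi = max(mu)`, the interval the
#' null is shifted to) and fits Beta(alpha, beta) by the method of moments.
#' The rescaled minimum and maximum land exactly on 0 and 1 where the Beta
#' likelihood degenerates, so boundary values are nudged inward by
#' epsilon = 1/(2m) before moment matching (m = number of observed values).
#'
#' A degenerate window (`hi == lo`, fewer than 8 observed values, or
#' moments incompatible with a Beta) yields `ok = FALSE`; downstream,
#' such windows emit no markers.
#'
#' @param mu numeric vector of mu values for one window (`NA` allowed).
#' @param lo,hi optional known support bounds; default to the observed
#'   minimum and maximum.
#' @return A `beta_null_fit` list: `alpha`, `beta`, `lo`, `hi`, `ok`,
#'   `method = "moments"`.
#' @export
fit_null_beta <- function(mu, lo = NULL, hi = NULL) {
  x <- mu[is.finite(mu)]
  no_fit <- function(lo = NA_real_, hi = NA_real_)
    structure(list(alpha = NA_real_, beta = NA_real_, lo = lo, hi = hi,
                   ok = FALSE, method = "moments"),
              class = "beta_null_fit")
  if (length(x) < 8) return(no_fit())
  if (is.null(lo)) lo <- min(x)
  if (is.null(hi)) hi <- max(x)
  if (!(hi > lo)) return(no_fit(lo, hi))
  z <- (x - lo) / (hi - lo)
  eps <- 1 / (2 * length(z))
  z <- pmin(pmax(z, eps), 1 - eps)
  m <- mean(z); v <- stats::var(z)
  if (!is.finite(v) || v <= 0) return(no_fit(lo, hi))
  common <- m * (1 - m) / v - 1
  if (common <= 0) return(no_fit(lo, hi))
  structure(list(alpha = m * common, beta = (1 - m) * common,
                 lo = lo, hi = hi, ok = TRUE, method = "moments"),
            class = "beta_null_fit")
}

#' @export
print.beta_null_fit <- function(x, ...) {
  if (x$ok)
    cat(sprintf("Beta null fit: alpha=%.3f beta=%.3f on [%.4f, %.4f]\n",
                x$alpha, x$beta, x$lo, x$hi))
  else cat("Beta null fit: degenerate (no fit)\n")
  invisible(x)
}

#' Upper-tail p-values against a fitted window null
#'
#' Rare-CNV carriers have large mean distance to the rest of the cohort, so
#' only the upper tail is tested: `p = 1 - BetaCDF((mu - lo)/(hi - lo))`,
#' with the rescaled argument clipped to \[0, 1\]. A sample at the window
#' minimum gets p = 1, at the maximum p = 0. A degenerate fit returns
#' p = 1 everywhere; `NA` statistics give `NA` p-values.
#'
#' @param mu numeric vector of mu values.
#' @param fit a `beta_null_fit`.
#' @return Numeric vector of p-values in \[0, 1\].
#' @export
marker_pvalues <- function(mu, fit) {
  stopifnot(inherits(fit, "beta_null_fit"))
  p <- rep(NA_real_, length(mu))
  obs <- is.finite(mu)
  if (!fit$ok) { p[obs] <- 1; return(p) }
  z <- pmin(pmax((mu[obs] - fit$lo) / (fit$hi - fit$lo), 0), 1)
  p[obs] <- pmin(pmax(1 - stats::pbeta(z, fit$alpha, fit$beta), 0), 1)
  p
}

#' Call markers from per-window p-values
#'
#' Keeps every (sample, window) pair with `p < threshold`, strictly — the
#' 1% tail definition of a rare-CNV marker. `NA` p-values never qualify.
#'
#' @param pmat numeric matrix of p-values, windows x samples.
#' @param windows the `window_spec` the rows of `pmat` refer to.
#' @param threshold strict p-value cutoff in (0, 1); default 0.01.
#' @return A `marker_set` data.frame: `sample`, `window` (row index into
#'   `windows`), `chrom`, `start_probe`, `p`; attributes `k`,
#'   `p_threshold`, `n_windows`, `n_samples`.
#' @export
call_markers <- function(pmat, windows, threshold = 0.01) {
  stopifnot(is.matrix(pmat), nrow(pmat) == nrow(windows),
            threshold > 0, threshold < 1)
  hit <- which(!is.na(pmat) & pmat < threshold, arr.ind = TRUE)
  samples <- colnames(pmat)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(pmat)))
  m <- data.frame(sample = samples[hit[, 2]],
                  window = as.integer(hit[, 1]),
                  chrom = windows$chrom[hit[, 1]],
                  start_probe = windows$start[hit[, 1]],
                  p = pmat[hit],
                  stringsAsFactors = FALSE)
  m <- m[order(m$window, m$sample), , drop = FALSE]
  rownames(m) <- NULL
  new_marker_set(m, k = attr(windows, "k"), p_threshold = threshold,
                 n_windows = nrow(windows), n_samples = ncol(pmat))
}

new_marker_set <- function(df, k, p_threshold, n_windows = NA_integer_,
                           n_samples = NA_integer_) {
  attr(df, "k") <- k
  attr(df, "p_threshold") <- p_threshold
  attr(df, "n_windows") <- n_windows
  attr(df, "n_samples") <- n_samples
  class(df) <- c("marker_set", "data.frame")
  df
}

#' Detect rare-CNV markers in a pseudo-rank matrix
#'
#' Full marker-calling driver: computes the mu statistic for every window,
#' fits the window-wise Beta null, converts to upper-tail p-values and
#' applies the strict threshold.
#'
#' @inheritParams mu_matrix
#' @param p_threshold strict marker p-value cutoff (default 0.01).
#' @return A `marker_set` (see [call_markers()]); the full p-value matrix
#'   is attached as attribute `pvalues`.
#' @export
detect_markers <- function(R, windows, d = 1, p_threshold = 0.01) {
  M <- mu_matrix(R, windows, d = d)
  P <- matrix(NA_real_, nrow(M), ncol(M), dimnames = dimnames(M))
  for (w in seq_len(nrow(M))) {
    fit <- fit_null_beta(M[w, ])
    P[w, ] <- marker_pvalues(M[w, ], fit)
  }
  m <- call_markers(P, windows, threshold = p_threshold)
  attr(m, "pvalues") <- P
  m
}

#' @export
print.marker_set <- function(x, ...) {
  cat("marker set:", nrow(x), "markers (k =", attr(x, "k"),
      ", p <", attr(x, "p_threshold"), ")\n")
  invisible(x)
}
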