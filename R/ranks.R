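# Column-wise pseudo-rank transform of the cohort logratio matrix.

#' Pseudo-rank transform of a logratio matrix
#'
#' Replaces each logratio by its rank among the samples at the same probe,
#' divided by (number of observed samples + 1), so every non-missing value
#' lies strictly in (0, 1). Working on ranks makes the downstream outlier
#' statistic invariant to any strictly increasing per-probe transformation —
#' in particular to the genome-correlated "wave" artifact and to per-probe
#' experimenter bias, which shift all samples at a probe together.
#'
#' Ties receive midranks, which conserves the column rank sum (a fully
#' observed column always sums to n/2). Missing cells are excluded from the
#' ranking and stay missing; the denominator uses the column's observed
#' count, keeping observed marginals uniform. Columns with fewer than two
#' observed values carry no ordering information and are set entirely to
#' `NA` with a warning.
#'
#' @param L numeric matrix (samples x probes) or an `acgh_cohort`.
#' @return Numeric matrix of pseudo-ranks, same shape and dimnames as the
#'   input values, with attribute `tie_policy = "midrank"`.
#' @examples
#' pseudo_rank(cbind(p1 = c(0.1, -0.3, 0.5)))  # 0.5, 0.25, 0.75
#' @export
pseudo_rank <- function(L) {
  if (inherits(L, "acgh_cohort")) L <- L$values
  stopifnot(is.matrix(L), is.numeric(L))
  if (nrow(L) < 2) stop("pseudo_rank needs at least 2 samples")
  R <- matrix(NA_real_, nrow(L), ncol(L), dimnames = dimnames(L))
  n_degenerate <- 0L
  for (q in seq_len(ncol(L))) {
    x <- L[, q]
    obs <- !is.na(x)
    m <- sum(obs)
    if (m < 2) { if (m > 0) n_degenerate <- n_degenerate + 1L; next }
    R[obs, q] <- rank(x[obs], ties.method = "average") / (m + 1)
  }
  if (n_degenerate)
    warning(n_degenerate,
            " column(s) with < 2 observed values set entirely to NA")
  attr(R, "tie_policy") <- "midrank"
  R
}
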