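test_that("windows cover each chromosome with p - k + 1 sliding positions", {
  w <- make_windows(make_probes(c(chr1 = 10)), k = 7)
  expect_equal(w$start, 1:4)

  expect_equal(nrow(make_windows(make_probes(c(chr1 = 6)), k = 7)), 0L)

  w2 <- make_windows(make_probes(c(chr1 = 8, chr2 = 8)), k = 7)
  expect_equal(nrow(w2), 4L)
  expect_equal(w2$chrom, c("chr1", "chr1", "chr2", "chr2"))
  expect_equal(w2$start, c(1L, 2L, 9L, 10L))  # none spans the boundary

  expect_error(make_windows(make_probes(c(chr1 = 10)), k = 1), ">= 2")
})

test_that("mu matches hand computations on tiny cohorts", {
  expect_equal(as.vector(mu_statistic(cbind(c(1, 2) / 3), 1)),
               c(1 / 6, 1 / 6))
  expect_equal(as.vector(mu_statistic(cbind(c(0.25, 0.5, 0.75)), 1)),
               c(0.25, 1 / 6, 0.25))
})

test_that("vectorized mu equals the naive double-loop oracle", {
  set.seed(31)
  for (rep in 1:20) {
    Rw <- matrix(runif(20 * 7), 20, 7)
    probes <- make_probes(c(chr1 = 7))
    w <- make_windows(probes, k = 7)
    expect_lt(max(abs(mu_matrix(Rw, w)[1, ] - mu_naive(Rw))), 1e-10)
    expect_lt(max(abs(mu_statistic(Rw, 1:7) - mu_naive(Rw))), 1e-10)
  }
  # and for a non-default distance order
  Rw <- matrix(runif(10 * 7), 10, 7)
  expect_lt(max(abs(mu_statistic(Rw, 1:7, d = 2) - mu_naive(Rw, d = 2))),
            1e-10)
})

test_that("fast sliding path agrees with per-window computation", {
  set.seed(17)
  R <- pseudo_rank(matrix(rnorm(30 * 40), 30, 40))
  probes <- make_probes(c(chr1 = 25, chr2 = 15))
  w <- make_windows(probes, k = 7)
  M_fast <- mu_matrix(R, w)
  for (i in seq_len(nrow(w)))
    expect_equal(M_fast[i, ],
                 mu_statistic(R, w$start[i]:(w$start[i] + 6L)),
                 ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("mu is bounded by [0, k] for d = 1 and zero iff rows identical", {
  set.seed(5)
  Rw <- matrix(runif(15 * 7), 15, 7)
  mu <- mu_statistic(Rw, 1:7)
  expect_true(all(mu >= 0 & mu <= 7))
  same <- matrix(rep(runif(7), each = 4), 4, 7)
  expect_equal(as.vector(mu_statistic(same, 1:7)), rep(0, 4))
})

test_that("samples with missing cells in a window are excluded from mu", {
  set.seed(8)
  Rw <- matrix(runif(10 * 3), 10, 3)
  Rw[4, 2] <- NA
  mu <- mu_statistic(Rw, 1:3)
  expect_true(is.na(mu[4]))
  expect_equal(mu[-4], mu_naive(Rw[-4, , drop = FALSE]),
               ignore_attr = TRUE)
})

test_that("closed form equals z^2 + (1-z)^2 and rejects out-of-range input", {
  expect_equal(mu_closed_form_k1(0.5), 0.5)
  expect_equal(mu_closed_form_k1(0), 1)
  expect_equal(mu_closed_form_k1(1), 1)
  expect_equal(mu_closed_form_k1(0.25), 0.625)
  expect_error(mu_closed_form_k1(1.2), "0, 1")
})

test_that("twice the empirical k=1 mu converges to the corner-distance parabola", {
  n <- 2000
  R <- cbind((1:n) / (n + 1))   # pseudo-ranks of any distinct data
  mu <- mu_statistic(R, 1)
  z <- seq(0.1, 0.9, by = 0.1)
  idx <- round(z * (n + 1))
  expect_lt(max(abs(2 * mu[idx] - mu_closed_form_k1(R[idx, 1]))), 0.01)
})

test_that("independence-null sampler is seeded-reproducible with correct support", {
  a <- simulate_independence_null(1, 500, 50, seed = 42)
  b <- simulate_independence_null(1, 500, 50, seed = 42)
  expect_identical(a, b)
  # k=1: mu in [1/4, 1/2] up to finite-n effects, i.e. 2*mu in [0.5, 1]
  x <- 2 * simulate_independence_null(1, 1000, 300, seed = 9)
  expect_true(all(x >= 0.5 - 0.01 & x <= 1))
})

test_that("Beta moment fit recovers known parameters given the true support", {
  set.seed(123)
  x <- 3 + 2 * rbeta(1e4, 2, 5)
  fit <- fit_null_beta(x, lo = 3, hi = 5)
  expect_true(fit$ok)
  expect_lt(abs(fit$alpha - 2), 0.2)
  expect_lt(abs(fit$beta - 5), 0.5)
})

test_that("symmetric samples yield alpha approximately beta", {
  set.seed(11)
  fit <- fit_null_beta(rbeta(1e4, 3, 3))
  expect_lt(abs(fit$alpha - fit$beta), 0.3)
})

test_that("degenerate windows produce no fit and hence no markers", {
  fit <- fit_null_beta(rep(2.5, 20))
  expect_false(fit$ok)
  p <- marker_pvalues(c(2.5, 2.5, 2.5), fit)
  expect_equal(p, rep(1, 3))
  expect_false(fit_null_beta(c(1, 2, 3))$ok)  # below the n >= 8 floor
})

test_that("p-values hit the boundary cases and the uniform special case", {
  set.seed(2)
  mu <- runif(50, 1, 3)
  fit <- fit_null_beta(mu)
  p <- marker_pvalues(mu, fit)
  expect_equal(p[which.min(mu)], 1)
  expect_equal(p[which.max(mu)], 0)
  expect_true(all(p >= 0 & p <= 1))

  unif <- structure(list(alpha = 1, beta = 1, lo = 0, hi = 1, ok = TRUE,
                         method = "moments"), class = "beta_null_fit")
  expect_equal(marker_pvalues(0.9, unif), 0.1)
})

test_that("marker calling applies a strict threshold", {
  w <- make_windows(make_probes(c(chr1 = 8)), k = 7)  # 2 windows
  pmat <- matrix(c(0.005, 0.5, 0.01), nrow(w), 3, byrow = TRUE,
                 dimnames = list(NULL, c("A", "B", "C")))
  m <- call_markers(pmat, w)
  expect_equal(unique(m$sample), "A")  # 0.01 is NOT < 0.01
  expect_equal(nrow(m), nrow(w))

  m_none <- call_markers(matrix(1, nrow(w), 3), w)
  expect_equal(nrow(m_none), 0L)
})
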