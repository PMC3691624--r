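# Synthetic aCGH cohort generator with planted ground truth, and
# evaluation of calls against it.
#
# The generator emulates the structure the method assumes in real
# exon-targeted cohorts: log10-scale logratio noise, a genome-correlated
# sinusoidal wave shared in pattern across samples (with per-sample phase
# jitter), per-batch offsets on a subset of probes (experimenter bias),
# globally disrupted probes with inflated variance, rare CNVs planted in
# <= 1% of samples, and polymorphic CNVs in > 1% of samples.

#' Simulation configuration
#'
#' Builds and validates a configuration for [simulate_cohort()]. Defaults
#' describe the package's reference study condition: a 100-sample,
#' 1000-probe cohort on two chromosomes with noise sd 0.1 (log10 units), a
#' mild wave, two batches, one rare single-carrier 30-probe deletion of
#' amplitude -0.3 and one 5%-carrier polymorphic deletion of the same
#' shape.
#'
#' @param n_samples cohort size.
#' @param n_probes total probe count, split evenly over `n_chrom`.
#' @param n_chrom number of chromosomes.
#' @param noise_sd per-probe Gaussian noise sd, log10 units.
#' @param wave list: `amplitude` (log10 units), `period_probes`,
#'   `per_sample_phase_sd` (radians), `shared_fraction` in \[0, 1\]
#'   (1 = identical wave in every sample).
#' @param batches list: `count`, `disrupted_probe_fraction` (probes per
#'   batch receiving a batch offset), `offset_sd`.
#' @param rare_cnvs list of lists `n_carriers` (at most 1% of the cohort;
#'   a single carrier is always allowed), `length_probes`, `amplitude`.
#' @param poly_cnvs list of lists `carrier_fraction` (> 1%),
#'   `length_probes`, `amplitude`.
#' @param disrupted_probes fraction of probes with 3x inflated noise sd.
#' @param seed integer seed; a fixed seed gives byte-identical cohorts.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 100L, n_probes = 1000L, n_chrom = 2L,
                       noise_sd = 0.1,
                       wave = list(amplitude = 0.05, period_probes = 120,
                                   per_sample_phase_sd = 0.5,
                                   shared_fraction = 0.8),
                       batches = list(count = 2L,
                                      disrupted_probe_fraction = 0.01,
                                      offset_sd = 0.05),
                       rare_cnvs = list(list(n_carriers = 1L,
                                             length_probes = 30L,
                                             amplitude = -0.3)),
                       poly_cnvs = list(list(carrier_fraction = 0.05,
                                             length_probes = 30L,
                                             amplitude = -0.3)),
                       disrupted_probes = 0.01,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_probes = as.integer(n_probes), n_chrom = as.integer(n_chrom),
              noise_sd = noise_sd, wave = wave, batches = batches,
              rare_cnvs = rare_cnvs, poly_cnvs = poly_cnvs,
              disrupted_probes = disrupted_probes, seed = as.integer(seed))
  stopifnot(cfg$n_samples >= 2, cfg$n_probes >= cfg$n_chrom, cfg$n_chrom >= 1,
            cfg$noise_sd > 0,
            wave$shared_fraction >= 0, wave$shared_fraction <= 1,
            disrupted_probes >= 0, disrupted_probes <= 1,
            batches$disrupted_probe_fraction >= 0,
            batches$disrupted_probe_fraction <= 1)
  max_rare <- max(1L, floor(0.01 * cfg$n_samples))
  for (cnv in cfg$rare_cnvs) {
    stopifnot(cnv$length_probes >= 1)
    if (cnv$n_carriers > max_rare)
      stop("rare CNV with ", cnv$n_carriers,
           " carriers exceeds 1% of the cohort (max ", max_rare, ")")
  }
  for (cnv in cfg$poly_cnvs) {
    stopifnot(cnv$length_probes >= 1)
    if (cnv$carrier_fraction <= 0.01)
      stop("polymorphic CNV carrier_fraction must exceed 0.01")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a synthetic aCGH cohort with ground truth
#'
#' Builds a probe index (`n_chrom` chromosomes of 60-bp probes spaced
#' 1 kb), then a logratio matrix as the sum of Gaussian noise (inflated 3x
#' on disrupted probes), a sinusoidal wave with per-sample phase jitter
#' scaled by `1 - shared_fraction`, per-batch offsets on a random probe
#' subset, and the planted CNV amplitudes on carrier-by-range blocks.
#' Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return An `acgh_cohort` with an extra `truth` element: a data.frame of
#'   (sample, chrom, start_probe, end_probe, type `rare`/`polymorphic`,
#'   amplitude) records, one per carrier.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples; p <- config$n_probes
  per <- diff(round(seq(0, p, length.out = config$n_chrom + 1)))
  probes <- do.call(rbind, lapply(seq_len(config$n_chrom), function(ci) {
    m <- per[ci]
    data.frame(probe_id = sprintf("chr%d_p%05d", ci, seq_len(m)),
               chrom = paste0("chr", ci),
               start = (seq_len(m) - 1L) * 1000L,
               end = (seq_len(m) - 1L) * 1000L + 60L,
               stringsAsFactors = FALSE)
  }))
  rownames(probes) <- NULL
  samples <- sprintf("S%03d", seq_len(n))

  probe_sd <- rep(config$noise_sd, p)
  n_disr <- round(config$disrupted_probes * p)
  if (n_disr > 0) probe_sd[sample.int(p, n_disr)] <- 3 * config$noise_sd
  L <- matrix(stats::rnorm(n * p, sd = rep(probe_sd, each = n)), n, p,
              dimnames = list(samples, probes$probe_id))

  wv <- config$wave
  if (wv$amplitude != 0) {
    theta <- 2 * pi * seq_len(p) / wv$period_probes
    phase <- (1 - wv$shared_fraction) *
      stats::rnorm(n, sd = wv$per_sample_phase_sd)
    L <- L + wv$amplitude * sin(outer(phase, theta, `+`))
  }

  bt <- config$batches
  if (bt$count > 1 && bt$disrupted_probe_fraction > 0) {
    batch_of <- rep(seq_len(bt$count), length.out = n)
    n_bp <- round(bt$disrupted_probe_fraction * p)
    for (b in seq_len(bt$count)) {
      if (n_bp == 0) next
      qs <- sample.int(p, n_bp)
      L[batch_of == b, qs] <- L[batch_of == b, qs, drop = FALSE] +
        rep(stats::rnorm(n_bp, sd = bt$offset_sd), each = sum(batch_of == b))
    }
  }

  # CNV placement in disjoint probe blocks, never crossing chromosomes
  chrom_id <- match(probes$chrom, unique(probes$chrom))
  occupied <- logical(p)
  place <- function(len) {
    for (try in 1:1000) {
      a <- sample.int(p - len + 1L, 1L)
      b <- a + len - 1L
      if (chrom_id[a] == chrom_id[b] && !any(occupied[a:b])) {
        occupied[a:b] <<- TRUE
        return(c(a, b))
      }
    }
    stop("could not place a CNV of length ", len,
         "; reduce CNV count/length or enlarge the probe set")
  }
  truth <- list()
  plant <- function(carriers, len, amp, type) {
    rng <- place(len)
    L[carriers, rng[1]:rng[2]] <<- L[carriers, rng[1]:rng[2], drop = FALSE] + amp
    for (s in carriers)
      truth[[length(truth) + 1L]] <<-
        data.frame(sample = s, chrom = probes$chrom[rng[1]],
                   start_probe = rng[1], end_probe = rng[2],
                   type = type, amplitude = amp, stringsAsFactors = FALSE)
  }
  for (cnv in config$rare_cnvs)
    plant(samples[sample.int(n, cnv$n_carriers)], cnv$length_probes,
          cnv$amplitude, "rare")
  for (cnv in config$poly_cnvs)
    plant(samples[sample.int(n, max(1L, round(cnv$carrier_fraction * n)))],
          cnv$length_probes, cnv$amplitude, "polymorphic")

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sample = character(), chrom = character(),
               start_probe = integer(), end_probe = integer(),
               type = character(), amplitude = numeric(),
               stringsAsFactors = FALSE)
  structure(list(probes = probes, values = L, truth = truth,
                 config = config),
            class = "acgh_cohort")
}

#' Evaluate candidate calls against planted truth
#'
#' A planted rare CNV counts as detected when some candidate segment of the
#' same sample covers at least `min_overlap` of its probes. A candidate is
#' a false positive when it overlaps no rare truth record of its sample.
#' Specificity is computed over non-carrier trials: for every rare truth
#' region and every sample not carrying it, the trial is a false alarm if
#' that sample has a candidate covering >= `min_overlap` of the region.
#'
#' @param candidates a `scored_segments`/`annotated_segments` data.frame
#'   (needs `sample`, `chrom`, `start_probe`, `end_probe`).
#' @param truth truth table from [simulate_cohort()].
#' @param samples character vector of all cohort sample ids (for the
#'   non-carrier trials); defaults to samples seen in truth + candidates.
#' @param min_overlap minimum fraction of the truth CNV covered (default
#'   0.5).
#' @return One-row data.frame: `n_rare`, `n_detected`, `sensitivity`,
#'   `n_candidates`, `false_positives`, `n_trials`, `false_alarms`,
#'   `specificity`.
#' @export
evaluate_calls <- function(candidates, truth, samples = NULL,
                           min_overlap = 0.5) {
  if (is.null(samples))
    samples <- unique(c(truth$sample, candidates$sample))
  rare <- truth[truth$type == "rare", , drop = FALSE]
  ov_frac <- function(s, chrom, a, b) {
    cand <- candidates[candidates$sample == s & candidates$chrom == chrom, ,
                       drop = FALSE]
    if (!nrow(cand)) return(0)
    ov <- pmax(0, pmin(cand$end_probe, b) - pmax(cand$start_probe, a) + 1L)
    max(ov) / (b - a + 1L)
  }
  detected <- logical(nrow(rare))
  for (i in seq_len(nrow(rare)))
    detected[i] <- ov_frac(rare$sample[i], rare$chrom[i],
                           rare$start_probe[i], rare$end_probe[i]) >= min_overlap
  fp <- 0L
  for (i in seq_len(nrow(candidates))) {
    tr <- rare[rare$sample == candidates$sample[i] &
               rare$chrom == candidates$chrom[i], , drop = FALSE]
    ov <- if (nrow(tr)) pmax(0, pmin(tr$end_probe, candidates$end_probe[i]) -
                               pmax(tr$start_probe, candidates$start_probe[i]) + 1L)
          else 0L
    if (!any(ov > 0)) fp <- fp + 1L
  }
  regions <- unique(rare[, c("chrom", "start_probe", "end_probe")])
  trials <- 0L; alarms <- 0L
  for (i in seq_len(nrow(regions))) {
    carriers <- rare$sample[rare$chrom == regions$chrom[i] &
                            rare$start_probe == regions$start_probe[i]]
    for (s in setdiff(samples, carriers)) {
      trials <- trials + 1L
      if (ov_frac(s, regions$chrom[i], regions$start_probe[i],
                  regions$end_probe[i]) >= min_overlap)
        alarms <- alarms + 1L
    }
  }
  data.frame(n_rare = nrow(rare), n_detected = sum(detected),
             sensitivity = if (nrow(rare)) mean(detected) else NA_real_,
             n_candidates = nrow(candidates), false_positives = fp,
             n_trials = trials, false_alarms = alarms,
             specificity = if (trials) 1 - alarms / trials else NA_real_)
}
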