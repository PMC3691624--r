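# Shared fixture builders: everything is generated in code at test time.

make_probes <- function(n_per_chrom, spacing = 1000L, width = 60L) {
  # n_per_chrom: named integer vector, e.g. c(chr1 = 10, chr2 = 8)
  do.call(rbind, lapply(names(n_per_chrom), function(ch) {
    m <- n_per_chrom[[ch]]
    data.frame(probe_id = sprintf("%s_p%03d", ch, seq_len(m)),
               chrom = ch,
               start = (seq_len(m) - 1L) * spacing,
               end = (seq_len(m) - 1L) * spacing + width,
               stringsAsFactors = FALSE)
  }))
}

write_logratio_fixture <- function(probes, values, path = tempfile(fileext = ".tsv"),
                                   shuffle = FALSE) {
  tab <- cbind(probes[, c("chrom", "start", "end", "probe_id")],
               as.data.frame(t(values)))
  if (shuffle) tab <- tab[sample(nrow(tab)), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

write_seg_fixture <- function(df, path = tempfile(fileext = ".seg")) {
  # df: data.frame with ID, chrom, loc.start, loc.end, num.mark, seg.mean
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_bed_fixture <- function(lines, path = tempfile(fileext = ".bed")) {
  writeLines(lines, path)
  path
}

# naive O(n^2 k) double-loop oracle for the mu statistic
mu_naive <- function(Rw, d = 1) {
  n <- nrow(Rw)
  sapply(seq_len(n), function(s) {
    mean(sapply(seq_len(n), function(j) {
      a <- abs(Rw[s, ] - Rw[j, ])
      if (is.infinite(d)) max(a) else sum(a^d)^(1 / d)
    }))
  })
}

# marker set built by hand for filter/score tests
manual_markers <- function(sample, start_probe, windows, k = attr(windows, "k"),
                           p = 0.001) {
  df <- data.frame(sample = sample,
                   window = match(start_probe, windows$start),
                   chrom = windows$chrom[match(start_probe, windows$start)],
                   start_probe = start_probe,
                   p = rep(p, length.out = length(sample)),
                   stringsAsFactors = FALSE)
  rareCGH:::new_marker_set(df, k = k, p_threshold = 0.01,
                           n_windows = nrow(windows), n_samples = NA_integer_)
}

# study-condition config for the controlled recovery experiment: pure noise
# plus the planted rare and polymorphic CNVs (no wave/batch artifacts)
recovery_config <- function(seed, n_probes = 600L) {
  sim_config(n_samples = 100L, n_probes = n_probes, noise_sd = 0.1,
             wave = list(amplitude = 0, period_probes = 120,
                         per_sample_phase_sd = 0.5, shared_fraction = 0.8),
             batches = list(count = 1L, disrupted_probe_fraction = 0,
                            offset_sd = 0),
             rare_cnvs = list(list(n_carriers = 1L, length_probes = 30L,
                                   amplitude = -0.3)),
             poly_cnvs = list(list(carrier_fraction = 0.05,
                                   length_probes = 30L, amplitude = -0.3)),
             disrupted_probes = 0, seed = seed)
}

# iid-normal null cohort (no structure at all)
null_cohort <- function(n, p, seed, n_chrom = 2L) {
  set.seed(seed)
  probes <- make_probes(stats::setNames(rep(p %/% n_chrom, n_chrom),
                                        paste0("chr", seq_len(n_chrom))))
  L <- matrix(rnorm(n * nrow(probes)), n, nrow(probes),
              dimnames = list(sprintf("S%03d", seq_len(n)), probes$probe_id))
  list(probes = probes, L = L)
}
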