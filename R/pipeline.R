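# End-to-end orchestration: segmentation -> rank transform -> markers ->
# polymorphism filtering -> density scoring -> candidate selection ->
# annotation, with a run manifest.

#' Pipeline parameters
#'
#' Collects every tunable of the three-phase pipeline with its default.
#' Unknown keys are rejected.
#'
#' @param k marker window size in probes (default 7).
#' @param d distance order of the mu statistic (default 1, Manhattan).
#' @param p_threshold strict marker p-value cutoff (default 0.01).
#' @param step window stride (default 1).
#' @param signal_threshold polymorphic-profile |segment mean| threshold,
#'   log10 units (default 0.07).
#' @param frequency polymorphic cohort frequency (default 0.01).
#' @param filter_mode marker exclusion semantics, `"intersect"` or
#'   `"overlap"`.
#' @param min_score candidate density-score cutoff, percent (default 50).
#' @param min_abs_mean candidate |segment mean| cutoff (default 0.1).
#' @param dgv_min DGV count defining a common variant (default 3).
#' @param min_reciprocal reciprocal overlap fraction for db hits
#'   (default 0).
#' @param segmenter `"external"` (SEG file required), `"simple"`
#'   (built-in recursive segmenter) or `"cluster"` (segmentation-free
#'   marker clustering).
#' @param min_probes,alpha built-in segmenter controls.
#' @param max_gap_probes marker-clustering gap merge (default 0).
#' @return A `pipeline_params` list.
#' @export
pipeline_params <- function(k = 7L, d = 1, p_threshold = 0.01, step = 1L,
                            signal_threshold = 0.07, frequency = 0.01,
                            filter_mode = c("intersect", "overlap"),
                            min_score = 50, min_abs_mean = 0.1,
                            dgv_min = 3L, min_reciprocal = 0,
                            segmenter = c("external", "simple", "cluster"),
                            min_probes = 10L, alpha = 0.01,
                            max_gap_probes = 0L) {
  p <- list(k = as.integer(k), d = d, p_threshold = p_threshold,
            step = as.integer(step), signal_threshold = signal_threshold,
            frequency = frequency, filter_mode = match.arg(filter_mode),
            min_score = min_score, min_abs_mean = min_abs_mean,
            dgv_min = as.integer(dgv_min), min_reciprocal = min_reciprocal,
            segmenter = match.arg(segmenter),
            min_probes = as.integer(min_probes), alpha = alpha,
            max_gap_probes = as.integer(max_gap_probes))
  class(p) <- "pipeline_params"
  p
}

#' Run the rare-CNV pipeline on in-memory objects
#'
#' Executes the full method: pseudo-rank transform, sliding windows, mu
#' statistic with window-wise Beta null, marker calling, polymorphic
#' profile and marker filtering, segment density scoring, candidate
#' selection and (when databases are given) annotation. Each stage failure
#' is re-raised with the stage named.
#'
#' @param cohort an `acgh_cohort` (from [read_logratio_table()] or
#'   [simulate_cohort()]).
#' @param seg optional external `cnv_segmentation`; required when
#'   `params$segmenter == "external"`.
#' @param dbs named list of `interval_db` objects (may be empty).
#' @param params a [pipeline_params()] list.
#' @return A `rare_cnv_result` list: `windows`, `markers`,
#'   `markers_filtered`, `segmentation`, `profile`, `poly_windows`,
#'   `scored`, `candidates`, `annotated` (or `NULL`), `manifest`, `params`.
#' @export
rare_cnv_pipeline <- function(cohort, seg = NULL, dbs = list(),
                              params = pipeline_params()) {
  stopifnot(inherits(cohort, "acgh_cohort"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  probes <- cohort$probes
  samples <- rownames(cohort$values)

  R <- stage("pseudo_rank", pseudo_rank(cohort$values))
  windows <- stage("make_windows",
                   make_windows(probes, k = params$k, step = params$step))
  markers <- stage("detect_markers",
                   detect_markers(R, windows, d = params$d,
                                  p_threshold = params$p_threshold))

  if (params$segmenter == "external") {
    if (is.null(seg))
      stop("segmenter = 'external' but no segmentation was supplied")
  } else if (params$segmenter == "simple") {
    seg <- stage("simple_segment",
                 simple_segment(cohort$values, probes,
                                min_probes = params$min_probes,
                                alpha = params$alpha))
  } else {
    seg <- stage("cluster_markers",
                 cluster_markers(markers, cohort$values, probes,
                                 max_gap_probes = params$max_gap_probes))
  }

  signal <- stage("probe_signal",
                  segmentation_to_probe_signal(seg, probes, samples))
  profile <- stage("polymorphic_profile",
                   build_polymorphic_profile(
                     signal, signal_threshold = params$signal_threshold,
                     frequency = params$frequency))
  poly_w <- stage("polymorphic_windows",
                  polymorphic_windows(profile, probes, k = params$k))
  filtered <- stage("filter_markers",
                    filter_markers(markers, poly_w,
                                   mode = params$filter_mode))
  scored <- stage("density_score",
                  density_score(seg, filtered, probes, k = params$k))
  candidates <- stage("select_candidates",
                      select_candidates(scored,
                                        min_score = params$min_score,
                                        min_abs_mean = params$min_abs_mean))
  annotated <- NULL
  if (length(dbs))
    annotated <- stage("annotate",
                       annotate_segments(candidates, probes, dbs,
                                         dgv_min = params$dgv_min,
                                         min_reciprocal = params$min_reciprocal))

  manifest <- list(
    package_version = as.character(utils::packageVersion("rareCGH")),
    n_samples = nrow(cohort$values), n_probes = ncol(cohort$values),
    n_windows = nrow(windows), n_markers = nrow(markers),
    n_markers_filtered = nrow(filtered),
    n_polymorphic_windows = length(poly_w),
    n_segments = nrow(seg), n_scored = nrow(scored),
    n_candidates = nrow(candidates))
  manifest <- c(manifest, stats::setNames(
    lapply(unclass(params), function(x) x), paste0("param_", names(params))))

  structure(list(windows = windows, markers = markers,
                 markers_filtered = filtered, segmentation = seg,
                 profile = profile, poly_windows = poly_w, scored = scored,
                 candidates = candidates, annotated = annotated,
                 manifest = manifest, params = params),
            class = "rare_cnv_result")
}

#' @export
print.rare_cnv_result <- function(x, ...) {
  m <- x$manifest
  cat("rare-CNV pipeline result\n",
      "  windows: ", m$n_windows, "  markers: ", m$n_markers,
      " (", m$n_markers_filtered, " after polymorphism filter)\n",
      "  segments: ", m$n_segments, "  scored: ", m$n_scored,
      "  candidates: ", m$n_candidates, "\n", sep = "")
  invisible(x)
}

#' Run the pipeline on files
#'
#' File-based front end: reads the logratio table, optional SEG
#' segmentation and optional BED databases, runs [rare_cnv_pipeline()],
#' and writes the marker BED, the candidate segment report and a
#' plain-text key-value run manifest into `out_dir`.
#'
#' @param logratio_path logratio TSV path.
#' @param seg_path optional SEG file path (required for
#'   `segmenter = "external"`); a missing file is an error naming it.
#' @param db_paths named list of BED paths (names become database roles).
#' @param out_dir output directory.
#' @param params a [pipeline_params()] list.
#' @return The `rare_cnv_result`, invisibly; side effect: `markers.bed`,
#'   `segments.tsv`, `manifest.txt` in `out_dir`.
#' @export
run_pipeline <- function(logratio_path, seg_path = NULL, db_paths = list(),
                         out_dir, params = pipeline_params()) {
  cohort <- read_logratio_table(logratio_path)
  seg <- NULL
  if (!is.null(seg_path)) {
    if (!file.exists(seg_path))
      stop("segmentation file not found: ", seg_path)
    seg <- read_segmentation(seg_path, cohort$probes)
  }
  dbs <- list()
  for (nm in names(db_paths))
    dbs[[nm]] <- read_interval_db(db_paths[[nm]], nm)
  res <- rare_cnv_pipeline(cohort, seg = seg, dbs = dbs, params = params)
  report <- if (!is.null(res$annotated)) res$annotated else res$candidates
  write_outputs(res$markers_filtered, report, cohort$probes, out_dir)
  man <- res$manifest
  writeLines(paste0(names(man), "\t",
                    vapply(man, function(v) paste(format(v), collapse = ","),
                           character(1))),
             file.path(out_dir, "manifest.txt"))
  invisible(res)
}

#' Convert a log2 aberration threshold to the log10 scale
#'
#' The conventional conservative aberration threshold of 0.24 on log2
#' ratios corresponds to 0.24 * log10(2) = 0.07 (to two decimals) on the
#' log10 scale used throughout this package — the default
#' `signal_threshold` of the polymorphic profile.
#'
#' @param log2_threshold threshold on the log2 scale (default 0.24).
#' @return The equivalent threshold on the log10 scale.
#' @examples
#' round(log2_to_log10_threshold(0.24), 2)  # 0.07
#' @export
log2_to_log10_threshold <- function(log2_threshold = 0.24) {
  log2_threshold * log10(2)
}
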