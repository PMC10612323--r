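#' @title Per-feature metric summaries
#'
#' @description Collapses per-peak values into one metric row per mass
#' feature: peak-list summary statistics, design-of-experiments fractions,
#' pooled-QC coefficients of variation, across-file medians of the raw-data
#' metrics, and the isotope transforms. Missing inputs are silently dropped
#' from every summary; a summary over zero non-missing inputs is itself
#' missing.
#'
#' @name feature-summary
NULL

#' Canonical metric column order
#'
#' The fixed order of the per-feature metric columns; correlation pruning
#' keeps the earlier column of a redundant pair in this order.
#' @export
METRIC_COLUMNS <- c(
  "mean_rt", "sd_rt", "mean_pw", "sd_pw", "mean_mz", "sd_ppm",
  "mean_log_area", "sd_log_area", "mean_log_sn",
  "mean_f", "mean_scale", "mean_lmin",
  "n_peaks_frac", "frac_found", "frac_samples_found", "frac_stans_found",
  "cv_pooled", "cv_pooled_robust",
  "med_shape_r", "med_snr_log", "med_missed_prop",
  "iso_shape_t", "iso_area_t")

## Quality direction per metric, used by impute_design_metrics(): "higher"
## means larger values indicate better features (missing is penalized low),
## "lower" the reverse, "auto" has no quality direction (fill away from the
## bulk). iso_*_t are log10(1 - r): lower is better.
.METRIC_DIRECTION <- c(
  mean_rt = "auto", sd_rt = "lower", mean_pw = "auto", sd_pw = "lower",
  mean_mz = "auto", sd_ppm = "lower",
  mean_log_area = "auto", sd_log_area = "lower", mean_log_sn = "higher",
  mean_f = "auto", mean_scale = "auto", mean_lmin = "auto",
  n_peaks_frac = "higher", frac_found = "higher",
  frac_samples_found = "higher", frac_stans_found = "higher",
  cv_pooled = "lower", cv_pooled_robust = "lower",
  med_shape_r = "higher", med_snr_log = "higher", med_missed_prop = "lower",
  iso_shape_t = "lower", iso_area_t = "lower")

.safe_stat <- function(x, fun) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  fun(x)
}

.safe_mean <- function(x) .safe_stat(x, mean)
.safe_median <- function(x) .safe_stat(x, stats::median)
.safe_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)  # sample sd of one value is undefined
  stats::sd(x)
}

#' Summarize one mass feature into its metric row
#'
#' @param feature A `mass_feature`.
#' @param peak_metrics Per-peak raw-data metric rows for this feature (the
#'   [score_peaks()] rows with matching `feature_id`); may be `NULL`.
#' @param iso_metrics One [score_isotopes()] row for this feature, or `NULL`.
#' @param manifest Manifest `data.frame` ([read_manifest()]).
#' @param n_files Total number of files in the run (defaults to
#'   `nrow(manifest)`).
#' @return One-row `data.frame`: `feature_id` plus [METRIC_COLUMNS].
#'
#' @details Notable rules: `sd_ppm` is the standard deviation of each peak's
#' m/z divided by the feature's median m/z times 1e6; area summaries use
#' `log10` of each area and then the mean/sd; XCMS `sn` values below zero
#' are discarded and zeros replaced by ones before `log10`; the "found"
#' fractions count only non-gap-filled peaks, deduplicated per file, while
#' `n_peaks_frac` and the area summaries include filled peaks; pooled CVs
#' use peak areas from pooled runs (`sd/mean`, and `MAD/median` without the
#' 1.4826 consistency constant); the raw-data metrics are across-file
#' medians with SNR log10-transformed first.
#' @export
summarize_feature <- function(feature, peak_metrics = NULL,
                              iso_metrics = NULL, manifest,
                              n_files = nrow(manifest)) {
  pk <- feature$peaks
  stopifnot(nrow(pk) >= 1L, n_files >= 1L)
  ppm <- pk$mz / feature$mzmed * 1e6
  log_area <- log10(pk$into)

  sn <- pk$sn[!is.na(pk$sn) & pk$sn >= 0]
  sn[sn == 0] <- 1
  mean_log_sn <- if (length(sn)) mean(log10(sn)) else NA_real_

  found_files <- unique(pk$sample_id[!pk$filled])
  type_of <- stats::setNames(manifest$run_type, manifest$sample_id)
  frac_in_type <- function(type) {
    denom <- sum(manifest$run_type == type)
    if (denom == 0L) return(NA_real_)
    sum(type_of[found_files] == type) / denom
  }
  pooled_areas <- pk$into[type_of[pk$sample_id] == "pooled" & !is.na(pk$into)]
  cv_pooled <- if (length(pooled_areas) >= 2L && mean(pooled_areas) != 0) {
    stats::sd(pooled_areas) / mean(pooled_areas)
  } else NA_real_
  cv_robust <- if (length(pooled_areas) >= 2L &&
                   stats::median(pooled_areas) != 0) {
    stats::mad(pooled_areas, constant = 1) / stats::median(pooled_areas)
  } else NA_real_

  if (is.null(peak_metrics) || nrow(peak_metrics) == 0L) {
    peak_metrics <- data.frame(shape_r = NA_real_, snr = NA_real_,
                               missed_prop = NA_real_)
  }
  iso_shape_t <- iso_area_t <- NA_real_
  if (!is.null(iso_metrics) && nrow(iso_metrics) == 1L) {
    iso_shape_t <- iso_metrics$iso_shape_t
    iso_area_t <- iso_metrics$iso_area_t
  }

  data.frame(
    feature_id = feature$feature_id,
    mean_rt = .safe_mean(pk$rt), sd_rt = .safe_sd(pk$rt),
    mean_pw = .safe_mean(pk$rtmax - pk$rtmin),
    sd_pw = .safe_sd(pk$rtmax - pk$rtmin),
    mean_mz = .safe_mean(pk$mz), sd_ppm = .safe_sd(ppm),
    mean_log_area = .safe_mean(log_area), sd_log_area = .safe_sd(log_area),
    mean_log_sn = mean_log_sn,
    mean_f = .safe_mean(pk$f), mean_scale = .safe_mean(pk$scale),
    mean_lmin = .safe_mean(pk$lmin),
    n_peaks_frac = min(length(unique(pk$sample_id)) / n_files, 1),
    frac_found = length(found_files) / n_files,
    frac_samples_found = frac_in_type("sample"),
    frac_stans_found = frac_in_type("standard"),
    cv_pooled = cv_pooled, cv_pooled_robust = cv_robust,
    med_shape_r = .safe_median(peak_metrics$shape_r),
    med_snr_log = .safe_median(log10(peak_metrics$snr)),
    med_missed_prop = .safe_median(peak_metrics$missed_prop),
    iso_shape_t = iso_shape_t, iso_area_t = iso_area_t)
}

#' Summarize every feature into the metric table
#'
#' @param features `mass_feature_list`.
#' @param peak_metrics [score_peaks()] output (or `NULL` to skip raw-data
#'   metrics).
#' @param iso_metrics [score_isotopes()] output (or `NULL`).
#' @param manifest Manifest `data.frame`.
#' @param n_files Total file count (defaults to `nrow(manifest)`).
#' @return Metric `data.frame`, one row per feature.
#' @export
summarize_features <- function(features, peak_metrics = NULL,
                               iso_metrics = NULL, manifest,
                               n_files = nrow(manifest)) {
  rows <- lapply(features, function(ft) {
    pm <- if (is.null(peak_metrics)) NULL else
      peak_metrics[peak_metrics$feature_id == ft$feature_id, , drop = FALSE]
    im <- if (is.null(iso_metrics)) NULL else
      iso_metrics[iso_metrics$feature_id == ft$feature_id, , drop = FALSE]
    summarize_feature(ft, pm, im, manifest, n_files)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Manual labels of a feature list
#'
#' @param features `mass_feature_list`.
#' @return Named character vector of labels keyed by feature_id.
#' @export
feature_labels <- function(features) {
  vapply(features, `[[`, character(1), "label")
}

.fill_value <- function(x, direction) {
  obs <- x[!is.na(x)]
  span <- diff(range(obs))
  if (span == 0) span <- max(abs(obs), 1)
  switch(direction,
    higher = min(obs) - span,
    lower  = max(obs) + span,
    auto = {
      med <- stats::median(obs)
      if ((max(obs) - med) >= (med - min(obs))) max(obs) + span
      else min(obs) - span
    })
}

#' Impute missing metric values one span beyond the worst observation
#'
#' Missing metric values (a feature with no pooled peaks, no isotope signal,
#' no standards run, ...) are themselves evidence of a poor feature, so each
#' missing cell is filled an order of magnitude of the column's span beyond
#' the column's worst observed value, per a fixed quality-direction
#' registry. Direction-free metrics fill beyond whichever extreme is
#' farther from the median. Non-missing cells are untouched.
#'
#' @param metrics Metric `data.frame` from [summarize_features()].
#' @param columns Columns to impute (default: all metric columns present).
#' @return Imputed `data.frame`.
#' @export
impute_design_metrics <- function(metrics,
                                  columns = intersect(METRIC_COLUMNS,
                                                      names(metrics))) {
  out <- metrics
  for (col in columns) {
    x <- out[[col]]
    if (!anyNA(x)) next
    if (all(is.na(x))) {
      stop("cannot impute column '", col, "': all values are missing")
    }
    dir <- .METRIC_DIRECTION[[col]]
    if (is.null(dir)) dir <- "auto"
    x[is.na(x)] <- .fill_value(x, dir)
    out[[col]] <- x
  }
  out
}

#' Drop redundant highly-correlated metric columns
#'
#' Greedy scan in column order: whenever a later column's absolute Pearson
#' correlation with an already-kept column exceeds the threshold, the later
#' column is removed, keeping the column order deterministic.
#'
#' @param metrics Complete (imputed) metric `data.frame`.
#' @param threshold Absolute Pearson correlation above which a pair is
#'   redundant (default 0.9).
#' @param columns Columns to consider (default: metric columns present).
#' @return List with `metrics` (pruned table) and `removed` (character
#'   vector of dropped column names).
#' @export
prune_correlated <- function(metrics, threshold = 0.9,
                             columns = intersect(METRIC_COLUMNS,
                                                 names(metrics))) {
  if (anyNA(metrics[, columns])) {
    stop("prune_correlated requires a complete table; run ",
         "impute_design_metrics() first")
  }
  kept <- character(0)
  removed <- character(0)
  for (col in columns) {
    redundant <- FALSE
    for (prev in kept) {
      r <- suppressWarnings(stats::cor(metrics[[prev]], metrics[[col]]))
      if (!is.na(r) && abs(r) > threshold) {
        redundant <- TRUE
        break
      }
    }
    if (redundant) removed <- c(removed, col) else kept <- c(kept, col)
  }
  list(metrics = metrics[, setdiff(names(metrics), removed), drop = FALSE],
       removed = removed)
}
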