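#' @title End-to-end scoring pipeline
#'
#' @description Convenience wrapper chaining the per-module steps: group the
#' peak table into features, apply the feature-level RT filter, score EICs
#' and isotopes against the raw scans, summarize per feature, and
#' optionally impute.
#'
#' @name pipeline
NULL

#' Compute the per-feature metric table from raw scans and a peak table
#'
#' @param scans_by_file Named list of scan-point data frames keyed by
#'   sample_id.
#' @param features `mass_feature_list` (e.g. from [read_peak_table()] or
#'   [peak_table_to_features()]).
#' @param manifest Manifest `data.frame`.
#' @param rt_filter Length-2 numeric RT bounds in seconds, or `NULL` to
#'   skip filtering. Default keeps 30 s to 20 min.
#' @param impute Impute missing metric cells ([impute_design_metrics()])?
#' @return List with `metrics` (the metric `data.frame`), `features` (the
#'   post-filter feature list), `peak_metrics` and `iso_metrics`.
#' @export
compute_metric_table <- function(scans_by_file, features, manifest,
                                 rt_filter = c(30, 1200), impute = TRUE) {
  if (!is.null(rt_filter)) {
    features <- filter_features_by_rt(features, rt_filter[1], rt_filter[2])
  }
  peak_metrics <- score_peaks(scans_by_file, features)
  iso_metrics <- score_isotopes(scans_by_file, features)
  metrics <- summarize_features(features, peak_metrics, iso_metrics,
                                manifest)
  if (impute) metrics <- impute_design_metrics(metrics)
  list(metrics = metrics, features = features,
       peak_metrics = peak_metrics, iso_metrics = iso_metrics)
}
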