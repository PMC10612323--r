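#' @title Peak table, manifest and label I/O
#'
#' @description Readers for the XCMS-style per-file peak table, the sample
#' manifest and manual label files, plus the feature-level retention-time
#' filter and a lossless metric-table serialization.
#'
#' @name msdata-io
NULL

.PEAK_COLS <- c("feature_id", "sample_id", "mz", "mzmin", "mzmax",
                "rt", "rtmin", "rtmax", "into", "maxo", "sn",
                "f", "scale", "lmin", "filled")
.RUN_TYPES <- c("sample", "pooled", "standard", "blank")
.LABELS <- c("Good", "Bad", "Ambiguous", "StansOnly", "Unlabeled")

#' Construct a mass feature
#'
#' A mass feature groups the per-file peaks that share a feature identity.
#' `mzmed`/`rtmed` are the medians of the member peaks' `mz`/`rt`.
#'
#' @param feature_id Feature identifier.
#' @param peaks `data.frame` of member peaks (columns as in the peak-table
#'   dialect, minus `feature_id`).
#' @param label One of `"Good"`, `"Bad"`, `"Ambiguous"`, `"StansOnly"`,
#'   `"Unlabeled"`.
#' @return An object of class `mass_feature`.
#' @export
mass_feature <- function(feature_id, peaks, label = "Unlabeled") {
  stopifnot(nrow(peaks) >= 1L)
  label <- match.arg(label, .LABELS)
  structure(
    list(feature_id = as.character(feature_id),
         mzmed = stats::median(peaks$mz),
         rtmed = stats::median(peaks$rt),
         peaks = peaks,
         label = label),
    class = "mass_feature")
}

#' @export
print.mass_feature <- function(x, ...) {
  cat(sprintf("<mass_feature %s> m/z %.4f @ %.1f s, %d peaks, label %s\n",
              x$feature_id, x$mzmed, x$rtmed, nrow(x$peaks), x$label))
  invisible(x)
}

#' Read a sample manifest
#'
#' The manifest maps each file/run to its run type. Extra `key=value`
#' fields are kept as a free-form metadata string.
#'
#' @param path CSV with header `sample_id,run_type` and optional trailing
#'   `key=value` columns.
#' @return `data.frame` with columns `sample_id`, `run_type`, `metadata`.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty manifest: ", path)
  header <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header[1:2]), c("sample_id", "run_type"))) {
    stop("manifest must start with columns sample_id,run_type")
  }
  rows <- lapply(lines[-1], function(l) {
    f <- trimws(strsplit(l, ",", fixed = TRUE)[[1]])
    data.frame(sample_id = f[[1]], run_type = f[[2]],
               metadata = paste(f[-(1:2)], collapse = ";"))
  })
  man <- do.call(rbind, rows)
  if (!all(man$run_type %in% .RUN_TYPES)) {
    bad <- setdiff(unique(man$run_type), .RUN_TYPES)
    stop("unknown run_type value(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(man$sample_id)) {
    stop("duplicated sample_id in manifest: ",
         paste(unique(man$sample_id[duplicated(man$sample_id)]),
               collapse = ", "))
  }
  man
}

#' Read manual feature labels
#'
#' @param path CSV with header `feature_id,label`; labels are `Good`, `Bad`,
#'   `Ambiguous` or `StansOnly` (the literal "Stans only" is accepted too).
#' @return Named character vector of labels keyed by feature_id.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("feature_id", "label") %in% names(df))) {
    stop("label file must have columns feature_id,label")
  }
  lab <- gsub("^Stans ?only$", "StansOnly", df$label, ignore.case = TRUE)
  bad <- setdiff(unique(lab), .LABELS)
  if (length(bad)) stop("unknown label value(s): ", paste(bad, collapse = ", "))
  stats::setNames(lab, df$feature_id)
}

#' Read an XCMS-style peak table into mass features
#'
#' Rows are grouped by `feature_id`; each group becomes a [mass_feature()]
#' whose `mzmed`/`rtmed` are medians of member peaks. Empty numeric cells
#' become `NA` (never zero).
#'
#' @param path CSV with header exactly
#'   `feature_id,sample_id,mz,mzmin,mzmax,rt,rtmin,rtmax,into,maxo,sn,f,scale,lmin,filled`.
#' @param manifest Manifest `data.frame` from [read_manifest()]; every
#'   `sample_id` in the table must appear in it.
#' @param labels Optional named label vector from [read_labels()].
#' @param rt_units `"sec"` (default) or `"min"`; minute-valued rt columns
#'   are converted to seconds on ingest.
#' @return Named list of `mass_feature` objects (class `mass_feature_list`).
#' @export
read_peak_table <- function(path, manifest, labels = NULL,
                            rt_units = c("sec", "min")) {
  rt_units <- match.arg(rt_units)
  df <- utils::read.csv(path, colClasses = c(
    feature_id = "character", sample_id = "character"))
  missing_cols <- setdiff(.PEAK_COLS, names(df))
  if (length(missing_cols)) {
    stop("peak table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[, .PEAK_COLS]
  df$filled <- as.logical(df$filled)
  df$filled[is.na(df$filled)] <- FALSE
  if (rt_units == "min") {
    for (col in c("rt", "rtmin", "rtmax")) df[[col]] <- df[[col]] * 60
  }
  unknown <- setdiff(unique(df$sample_id), manifest$sample_id)
  if (length(unknown)) {
    stop("peak table references sample_id(s) absent from the manifest: ",
         paste(unknown, collapse = ", "))
  }
  peak_table_to_features(df, labels)
}

#' Group a peak-table data frame into mass features
#'
#' @param df Peak table `data.frame` with the standard columns.
#' @param labels Optional named label vector.
#' @return Named `mass_feature_list`.
#' @export
peak_table_to_features <- function(df, labels = NULL) {
  ids <- unique(df$feature_id)
  feats <- lapply(ids, function(id) {
    peaks <- df[df$feature_id == id, setdiff(names(df), "feature_id"),
                drop = FALSE]
    rownames(peaks) <- NULL
    lab <- if (!is.null(labels) && id %in% names(labels)) {
      labels[[id]]
    } else "Unlabeled"
    mass_feature(id, peaks, lab)
  })
  names(feats) <- ids
  structure(feats, class = "mass_feature_list")
}

#' @export
print.mass_feature_list <- function(x, ...) {
  labs <- vapply(x, `[[`, character(1), "label")
  cat(sprintf("<mass_feature_list> %d features (%s)\n", length(x),
              paste(names(table(labs)), table(labs),
                    sep = ":", collapse = ", ")))
  invisible(x)
}

#' Filter features by median retention time
#'
#' Features eluting during the initial or final solvent washes are removed;
#' the defaults keep features with `rtmed` between 30 s and 20 min.
#'
#' @param features `mass_feature_list`.
#' @param min_rt,max_rt Retention-time bounds in seconds (closed interval).
#' @return Filtered `mass_feature_list`; the number removed is reported via
#'   `message()`.
#' @export
filter_features_by_rt <- function(features, min_rt = 30, max_rt = 1200) {
  stopifnot(min_rt < max_rt)
  rtmed <- vapply(features, `[[`, numeric(1), "rtmed")
  keep <- rtmed >= min_rt & rtmed <= max_rt
  message(sum(!keep), " feature(s) removed by RT filter [",
          min_rt, ", ", max_rt, "] s")
  structure(features[keep], class = "mass_feature_list")
}

#' Write a metric table losslessly
#'
#' Numeric cells are serialized with 17 significant digits so finite values
#' survive a write/read round trip bit-exactly; missing values are written
#' as `NA`.
#'
#' @param metrics Metric `data.frame` (feature ids in column `feature_id`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(metrics, path) {
  out <- metrics
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- "NA"
      out[[col]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a metric table written by [write_metric_table()]
#'
#' @param path CSV path.
#' @return Metric `data.frame` with `feature_id` character and all other
#'   columns numeric.
#' @export
read_metric_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  for (col in setdiff(names(df), "feature_id")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}
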