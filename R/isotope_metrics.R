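#' @title 13C isotope verification metrics
#'
#' @description A real analyte's M+1 (13C) companion trace co-elutes with
#' the monoisotopic (12C) trace and keeps a fixed abundance ratio across
#' files. Two metrics capture this: the per-file Pearson correlation between
#' the paired 12C and 13C intensity traces (summarized as the median across
#' files) and the Pearson correlation between 13C and 12C trapezoidal peak
#' areas across files. Because both cluster near 1 for true isotopes, the
#' model uses the `log10(1 - x)` transform of each.
#'
#' @name isotope-metrics
NULL

.C13_DELTA <- 1.003355
.ISO_PPM <- 4
.MIN_ISO_FILES <- 3L

#' m/z window of the M+1 isotope trace
#'
#' The monoisotopic mass is shifted by +1.003355 Th and the +/- 4 ppm
#' tolerance is applied to the shifted mass (closed interval).
#'
#' @param mz Monoisotopic m/z (Th).
#' @return Numeric `c(lo, hi)`.
#' @export
isotope_mz_window <- function(mz) {
  shifted <- mz + .C13_DELTA
  shifted * c(1 - .ISO_PPM * 1e-6, 1 + .ISO_PPM * 1e-6)
}

#' Trapezoidal area under an intensity trace
#'
#' @param rt Retention times (seconds), strictly increasing.
#' @param intensity Intensities at `rt`.
#' @return Trapezoidal Riemann sum, or `NA` for traces with fewer than two
#'   points (zero-width integral carries no information).
#' @export
trapezoid_area <- function(rt, intensity) {
  if (length(rt) < 2L) return(NA_real_)
  sum(diff(rt) * (utils::head(intensity, -1) + utils::tail(intensity, -1)) / 2)
}

## One file's isotope evidence for one peak: pair the 12C and 13C EICs by
## exact shared scan time; NA unless >= 5 shared points exist.
.isotope_one_file <- function(scans, peak) {
  eic12 <- extract_eic(scans, peak)
  win <- isotope_mz_window(peak$mz)
  iso_box <- list(mzmin = win[1], mzmax = win[2],
                  rtmin = peak$rtmin, rtmax = peak$rtmax)
  eic13 <- extract_eic(scans, iso_box)
  shared <- intersect(eic12$points$rt, eic13$points$rt)
  out <- list(r = NA_real_, area12 = NA_real_, area13 = NA_real_,
              n_shared = length(shared))
  if (length(shared) < .MIN_EIC_POINTS) return(out)
  shared <- sort(shared)
  i12 <- eic12$points$intensity[match(shared, eic12$points$rt)]
  i13 <- eic13$points$intensity[match(shared, eic13$points$rt)]
  if (stats::sd(i12) > 0 && stats::sd(i13) > 0) {
    out$r <- stats::cor(i12, i13)
  }
  out$area12 <- trapezoid_area(eic12$points$rt, eic12$points$intensity)
  out$area13 <- trapezoid_area(eic13$points$rt, eic13$points$intensity)
  out
}

#' Per-file isotope evidence for one feature
#'
#' For each member peak (one per file) the 12C EIC is extracted from the
#' peak's bounding box and the 13C EIC from the same RT bounds at the
#' shifted m/z window; traces are paired by exact shared scan time.
#'
#' @param scans_by_file Named list of scan-point data frames.
#' @param feature A `mass_feature`.
#' @return `data.frame` with one row per peak: `sample_id`, `r` (Pearson
#'   correlation of the paired traces, `NA` unless >= 5 shared points),
#'   `area12`, `area13` (trapezoidal areas), `n_shared`.
#' @export
isotope_evidence <- function(scans_by_file, feature) {
  pk <- feature$peaks
  rows <- lapply(seq_len(nrow(pk)), function(i) {
    sid <- pk$sample_id[i]
    res <- .isotope_one_file(scans_by_file[[sid]], pk[i, ])
    data.frame(sample_id = sid, r = res$r, area12 = res$area12,
               area13 = res$area13, n_shared = res$n_shared)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median isotope shape similarity of a feature
#'
#' @param scans_by_file Named list of scan-point data frames.
#' @param feature A `mass_feature`.
#' @return List with `per_file` (the [isotope_evidence()] table) and
#'   `median_r` (median of per-file correlations ignoring missing; `NA`
#'   when no file qualifies).
#' @export
isotope_shape_similarity <- function(scans_by_file, feature) {
  ev <- isotope_evidence(scans_by_file, feature)
  med <- if (all(is.na(ev$r))) NA_real_ else stats::median(ev$r, na.rm = TRUE)
  list(per_file = ev, median_r = med)
}

#' Isotope area correlation across files
#'
#' A true isotope keeps a fixed 13C/12C abundance ratio, so its 13C areas
#' are linear in the 12C areas across files.
#'
#' @param per_file_areas `data.frame` with columns `area12`, `area13` (one
#'   row per file; rows with a missing area are dropped).
#' @return Pearson correlation, or `NA` with fewer than 3 complete files
#'   (two points always correlate at +/- 1) or degenerate (constant) areas.
#' @export
isotope_area_correlation <- function(per_file_areas) {
  ok <- stats::complete.cases(per_file_areas[, c("area12", "area13")])
  a <- per_file_areas[ok, , drop = FALSE]
  if (nrow(a) < .MIN_ISO_FILES) return(NA_real_)
  if (stats::sd(a$area12) == 0 || stats::sd(a$area13) == 0) return(NA_real_)
  stats::cor(a$area12, a$area13)
}

#' log10(1 - x) transform for near-one correlation metrics
#'
#' Isotope correlations pile up just under 1; `log10(1 - x)` spreads them
#' into an approximately normal scale. `x` is clamped to `1 - 1e-12` first
#' so an exact 1 stays finite (maps to -12).
#'
#' @param x Correlation-scale values (<= 1, possibly `NA`).
#' @return Transformed values; `NA` propagates.
#' @export
log_one_minus <- function(x) {
  if (any(x > 1, na.rm = TRUE)) {
    stop("log_one_minus: value(s) > 1 are not valid correlations")
  }
  out <- log10(1 - x)
  clamped <- !is.na(x) & (1 - x) < 1e-12
  out[clamped] <- -12
  out
}

#' Isotope metrics for every feature
#'
#' @param scans_by_file Named list of scan-point data frames.
#' @param features `mass_feature_list`.
#' @return `data.frame` with one row per feature: `feature_id`,
#'   `iso_shape_med`, `iso_area_cor`, and their [log_one_minus()] transforms
#'   `iso_shape_t`, `iso_area_t`.
#' @export
score_isotopes <- function(scans_by_file, features) {
  rows <- lapply(features, function(ft) {
    shape <- isotope_shape_similarity(scans_by_file, ft)
    area_cor <- isotope_area_correlation(shape$per_file)
    data.frame(feature_id = ft$feature_id,
               iso_shape_med = shape$median_r,
               iso_area_cor = area_cor,
               iso_shape_t = log_one_minus(shape$median_r),
               iso_area_t = log_one_minus(area_cor))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
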