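#' @title Raw-data peak quality metrics
#'
#' @description Extracted-ion-chromatogram (EIC) metrics computed inside each
#' peak's m/z-by-RT bounding box: similarity of the intensity profile to an
#' idealized bell curve (a beta-distribution pdf with alpha in
#' {2.5, 3, 4, 5} and beta fixed at 5, spanning symmetric to right-skewed
#' shapes), a signal-to-noise ratio estimated from the residuals of that
#' fit, and the proportion of acquired scans with no signal at the peak's
#' m/z.
#'
#' @name eic-metrics
NULL

.BETA_ALPHAS <- c(2.5, 3, 4, 5)
.BETA_BETA <- 5
.MIN_EIC_POINTS <- 5L
.SNR_CAP <- 1e6

#' Build an EIC from one file's scan points and a peak bounding box
#'
#' Keeps the points with `mzmin <= mz <= mzmax` and `rtmin <= rt <= rtmax`
#' (closed intervals). Multiple centroids falling inside the m/z window at
#' one scan are summed into a single point at that retention time. The EIC
#' also records `scan_times`: every retention time the file acquired inside
#' the RT bounds, at any mass, which defines the denominator of
#' [missed_scan_proportion()].
#'
#' @param scans One file's scan-point `data.frame` (see [read_scans()]).
#' @param peak A list or one-row `data.frame` with `mzmin`, `mzmax`,
#'   `rtmin`, `rtmax`.
#' @return An object of class `eic`: `points` (`data.frame` of `rt`,
#'   `intensity`, sorted by `rt`, one row per scan) and `scan_times`.
#'   An empty EIC is valid.
#' @export
extract_eic <- function(scans, peak) {
  stopifnot(peak$mzmin <= peak$mzmax, peak$rtmin <= peak$rtmax)
  in_rt <- scans$rt >= peak$rtmin & scans$rt <= peak$rtmax
  st <- sort(unique(scans$rt[in_rt]))
  hit <- in_rt & scans$mz >= peak$mzmin & scans$mz <= peak$mzmax
  if (!any(hit)) {
    pts <- data.frame(rt = numeric(0), intensity = numeric(0))
  } else {
    agg <- rowsum(scans$intensity[hit], group = scans$rt[hit])
    pts <- data.frame(rt = as.numeric(rownames(agg)),
                      intensity = as.numeric(agg[, 1]))
    pts <- pts[order(pts$rt), , drop = FALSE]
    rownames(pts) <- NULL
  }
  structure(list(points = pts, scan_times = st), class = "eic")
}

#' @export
print.eic <- function(x, ...) {
  cat(sprintf("<eic> %d points over %d scan times\n",
              nrow(x$points), length(x$scan_times)))
  invisible(x)
}

#' Linearly scale values into [0, 1]
#'
#' Subtracts the minimum and divides by the maximum of the shifted values,
#' so the minimum maps to 0 and the maximum to 1.
#'
#' @param values Numeric vector.
#' @return Scaled vector, or a vector of `NA` when the input is degenerate
#'   (fewer than 2 values, all values equal, or any non-finite value) --
#'   a flat trace carries no shape information.
#' @export
unit_scale <- function(values) {
  if (length(values) < 2L || !all(is.finite(values)) ||
      max(values) == min(values)) {
    return(rep(NA_real_, length(values)))
  }
  shifted <- values - min(values)
  shifted / max(shifted)
}

## Shared worker: one pass computing r, best alpha and snr for an EIC.
.shape_fit <- function(eic) {
  miss <- list(r = NA_real_, alpha = NA_real_, snr = NA_real_,
               n_points = nrow(eic$points))
  pts <- eic$points
  if (nrow(pts) < .MIN_EIC_POINTS) return(miss)
  u <- unit_scale(pts$rt)
  y <- pts$intensity
  if (anyNA(u) || max(y) == min(y)) return(miss)
  r_by_alpha <- vapply(.BETA_ALPHAS, function(a) {
    stats::cor(stats::dbeta(u, a, .BETA_BETA), y)
  }, numeric(1))
  if (all(is.na(r_by_alpha))) return(miss)
  best <- which.max(r_by_alpha)
  pdf_best <- stats::dbeta(u, .BETA_ALPHAS[best], .BETA_BETA)
  scaled_pdf <- unit_scale(pdf_best)
  resid <- unit_scale(y) - scaled_pdf
  sd_resid <- stats::sd(resid)
  snr <- if (is.na(sd_resid)) {
    NA_real_
  } else if (sd_resid == 0) {
    .SNR_CAP
  } else {
    ## noise = sd(scaled residuals) * max height; snr = max height / noise
    min(1 / sd_resid, .SNR_CAP)
  }
  list(r = r_by_alpha[best], alpha = .BETA_ALPHAS[best], snr = snr,
       n_points = nrow(pts))
}

#' Best beta-shape correlation of an EIC
#'
#' Scales the EIC's retention times onto [0, 1], evaluates the beta pdf at
#' those positions for alpha in {2.5, 3, 4, 5} (beta = 5), and returns the
#' highest Pearson correlation between pdf and raw intensities together with
#' the alpha that achieved it. Fewer than 5 points, or a constant trace,
#' yields missing.
#'
#' @param eic An [extract_eic()] result.
#' @return List with `r` (in [-1, 1] or `NA`) and `alpha` (`NA` iff `r` is).
#' @export
best_beta_correlation <- function(eic) {
  fit <- .shape_fit(eic)
  list(r = fit$r, alpha = fit$alpha)
}

#' Within-peak signal-to-noise ratio
#'
#' Both the intensities and the best-fitting beta pdf are scaled to [0, 1];
#' their difference is the fit residual. The noise level is the standard
#' deviation of the residuals times the maximum peak height, and the SNR is
#' the maximum height divided by that noise -- numerically `1 / sd(residuals)`
#' in scaled space, so peak height cancels. Zero-residual (perfect) peaks
#' return the cap `1e6`.
#'
#' @param eic An [extract_eic()] result.
#' @return SNR (> 0) or `NA` when the shape fit is missing.
#' @export
within_peak_snr <- function(eic) {
  .shape_fit(eic)$snr
}

#' Proportion of missed scans inside a peak
#'
#' Fraction of the file's acquisition times between the peak's RT bounds at
#' which no centroid fell inside the peak's m/z window.
#'
#' @param eic An [extract_eic()] result.
#' @return Fraction in [0, 1], or `NA` when the file acquired no scans in
#'   the RT window.
#' @export
missed_scan_proportion <- function(eic) {
  n_scans <- length(eic$scan_times)
  if (n_scans == 0L) return(NA_real_)
  present <- sum(eic$scan_times %in% eic$points$rt)
  1 - present / n_scans
}

#' Score every peak of every feature against its raw EIC
#'
#' Runs [extract_eic()], [best_beta_correlation()], [within_peak_snr()] and
#' [missed_scan_proportion()] for each member peak of each feature.
#'
#' @param scans_by_file Named list of scan-point data frames, keyed by
#'   `sample_id`.
#' @param features `mass_feature_list`.
#' @return `data.frame` with one row per peak: `feature_id`, `sample_id`,
#'   `shape_r`, `shape_alpha`, `snr`, `missed_prop`, `n_points`.
#' @export
score_peaks <- function(scans_by_file, features) {
  rows <- lapply(features, function(ft) {
    pk <- ft$peaks
    per_peak <- lapply(seq_len(nrow(pk)), function(i) {
      sid <- pk$sample_id[i]
      if (!sid %in% names(scans_by_file)) {
        stop("no raw scans available for sample_id '", sid, "'")
      }
      eic <- extract_eic(scans_by_file[[sid]], pk[i, ])
      fit <- .shape_fit(eic)
      data.frame(feature_id = ft$feature_id, sample_id = sid,
                 shape_r = fit$r, shape_alpha = fit$alpha, snr = fit$snr,
                 missed_prop = missed_scan_proportion(eic),
                 n_points = fit$n_points)
    })
    do.call(rbind, per_peak)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
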