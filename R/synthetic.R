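#' @title Synthetic multi-file chromatogram bundles
#'
#' @description Generates labeled synthetic LC-MS datasets -- per-file
#' centroided scans, an XCMS-style peak table, a sample manifest, and
#' Good/Bad labels -- so the whole scoring and classification pipeline can
#' be exercised without real data. Good features are beta-shaped elution
#' profiles shared across files with multiplicative height variation,
#' additive Gaussian noise and a fixed-ratio 13C companion trace; Bad
#' features are either uncorrelated noise points or the trailing tail of a
#' Good feature's profile (the pseudo-replication artifact seen in real
#' peak lists).
#'
#' @name synthetic-data
NULL

#' Simulation configuration
#'
#' Defaults describe a small HILIC-like batch: 9 files (6 samples, 2 pooled
#' QC, 1 standard mix), 20-80 s wide peaks on a 2 s scan grid over a
#' 60-1140 s gradient and a 60-900 Th scan range, 5% additive noise, 30%
#' Good features, and an M+1 companion at 1.1% of the monoisotopic trace.
#'
#' @param n_features Number of mass features.
#' @param n_files Number of files/runs.
#' @param frac_good Fraction of features that are Good (count is rounded).
#' @param noise_sd Additive Gaussian noise sd as a fraction of peak height.
#' @param tail_artifact_frac Fraction of Bad features that are peak-tail
#'   artifacts (the rest are uncorrelated noise).
#' @param iso_ratio 13C/12C abundance ratio of the companion trace.
#' @param rt_range Feature elution window, seconds.
#' @param mz_range Feature m/z window, Thomson.
#' @param scan_interval Scan spacing, seconds.
#' @param seed Integer seed; generation is deterministic given the config.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_features = 200, n_files = 9, frac_good = 0.3,
                       noise_sd = 0.05, tail_artifact_frac = 0.3,
                       iso_ratio = 0.011, rt_range = c(60, 1140),
                       mz_range = c(60, 900), scan_interval = 2, seed = 1) {
  cfg <- list(n_features = n_features, n_files = n_files,
              frac_good = frac_good, noise_sd = noise_sd,
              tail_artifact_frac = tail_artifact_frac,
              iso_ratio = iso_ratio, rt_range = rt_range,
              mz_range = mz_range, scan_interval = scan_interval,
              seed = seed)
  if (n_features < 1 || n_files < 1) {
    stop("need at least one feature and one file")
  }
  stopifnot(frac_good >= 0, frac_good <= 1,
            tail_artifact_frac >= 0, tail_artifact_frac <= 1,
            noise_sd >= 0, iso_ratio >= 0, scan_interval > 0,
            rt_range[1] < rt_range[2], mz_range[1] < mz_range[2])
  structure(cfg, class = "sim_config")
}

.sim_manifest <- function(n_files) {
  types <- rep("sample", n_files)
  if (n_files >= 5) types[n_files] <- "standard"
  n_pooled <- if (n_files >= 4) 2L else if (n_files >= 2) 1L else 0L
  if (n_pooled > 0) {
    types[seq(n_files - (n_files >= 5) - n_pooled + 1,
              length.out = n_pooled)] <- "pooled"
  }
  data.frame(sample_id = sprintf("file%02d", seq_len(n_files)),
             run_type = types, metadata = "")
}

#' Generate a synthetic feature bundle
#'
#' @param config A [sim_config()].
#' @return List of class `sim_bundle` with `scans_by_file` (named list of
#'   scan-point data frames), `peak_table` (XCMS-style `data.frame`),
#'   `manifest`, `labels` (named vector), and `truth` (`data.frame` of the
#'   generating parameters and artifact type per feature).
#' @export
generate_feature_set <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  manifest <- .sim_manifest(config$n_files)
  grid <- seq(config$rt_range[1] - 40, config$rt_range[2] + 40,
              by = config$scan_interval)

  n_good <- round(config$frac_good * config$n_features)
  n_bad <- config$n_features - n_good
  n_tail <- if (n_good >= 1) round(config$tail_artifact_frac * n_bad) else 0L
  kinds <- c(rep("good", n_good), rep("tail", n_tail),
             rep("noise", n_bad - n_tail))
  ids <- sprintf("FT%04d", seq_len(config$n_features))

  scans <- lapply(seq_len(config$n_files), function(i) list())
  names(scans) <- manifest$sample_id
  peak_rows <- list()
  truth_rows <- list()

  ## persistent background trace so every file has a full scan grid at some
  ## mass (defines the missed-scan denominator), like a solvent/calibrant ion
  for (sid in manifest$sample_id) {
    scans[[sid]][[1]] <- data.frame(
      rt = grid, mz = 445.120025 * (1 + stats::rnorm(length(grid), 0, 2e-7)),
      intensity = 1e5 * exp(stats::rnorm(length(grid), 0, 0.05)))
  }

  good_params <- list()
  for (j in seq_len(config$n_features)) {
    kind <- kinds[j]
    if (kind == "tail") next  # filled in after parents exist
    mz <- stats::runif(1, config$mz_range[1], config$mz_range[2])
    width <- stats::runif(1, 20, 80)
    center <- stats::runif(1, config$rt_range[1] + width,
                           config$rt_range[2] - width)
    rtmin <- center - width / 2
    rtmax <- center + width / 2
    box_rt <- grid[grid >= rtmin & grid <= rtmax]
    mz_lo <- mz * (1 - 2.5e-6)
    mz_hi <- mz * (1 + 2.5e-6)
    alpha <- sample(.BETA_ALPHAS, 1)
    base_height <- 10^stats::runif(1, 5.5, 7.5)
    apex_rt <- NA_real_

    for (i in seq_len(config$n_files)) {
      sid <- manifest$sample_id[i]
      if (kind == "good") {
        detected <- stats::runif(1) < 0.9
        filled <- !detected && stats::runif(1) < 0.5
        height <- base_height * exp(stats::rnorm(1, 0, 0.4))
        u <- unit_scale(box_rt)
        shape <- stats::dbeta(u, alpha, .BETA_BETA)
        shape <- shape / max(shape)
        clean <- height * shape
        y12 <- pmax(clean + stats::rnorm(length(u), 0,
                                         config$noise_sd * height), 0)
        y13 <- pmax(config$iso_ratio * clean +
                      stats::rnorm(length(u), 0,
                                   config$noise_sd * height *
                                     config$iso_ratio), 0)
        pt_mz <- mz * (1 + pmin(pmax(stats::rnorm(length(u), 0, 5e-7),
                                     -2e-6), 2e-6))
        scans[[sid]][[length(scans[[sid]]) + 1L]] <- data.frame(
          rt = c(box_rt, box_rt),
          mz = c(pt_mz, pt_mz + .C13_DELTA),
          intensity = c(y12, y13))
        if (!detected && !filled) next
        apex_rt <- box_rt[which.max(y12)]
        peak_rows[[length(peak_rows) + 1L]] <- data.frame(
          feature_id = ids[j], sample_id = sid,
          mz = mean(pt_mz), mzmin = mz_lo, mzmax = mz_hi,
          rt = apex_rt, rtmin = rtmin, rtmax = rtmax,
          into = trapezoid_area(box_rt, y12), maxo = max(y12),
          sn = 10^stats::runif(1, 0.5, 2),
          f = stats::rpois(1, 50), scale = width / 4 + stats::rnorm(1),
          lmin = stats::rpois(1, 20), filled = filled)
      } else {  # uncorrelated noise feature
        detected <- stats::runif(1) < 0.6
        if (!detected) next
        present <- stats::runif(length(box_rt)) < 0.6
        if (sum(present) < 3L) present[sample(length(box_rt), 3L)] <- TRUE
        t_obs <- box_rt[present]
        height <- 10^stats::runif(1, 4.5, 6)
        y <- stats::runif(length(t_obs), 0.05 * height, height)
        pt_mz <- mz * (1 + pmin(pmax(stats::rnorm(length(t_obs), 0, 5e-7),
                                     -2e-6), 2e-6))
        scans[[sid]][[length(scans[[sid]]) + 1L]] <- data.frame(
          rt = t_obs, mz = pt_mz, intensity = y)
        peak_rows[[length(peak_rows) + 1L]] <- data.frame(
          feature_id = ids[j], sample_id = sid,
          mz = mean(pt_mz), mzmin = mz_lo, mzmax = mz_hi,
          rt = t_obs[which.max(y)], rtmin = rtmin, rtmax = rtmax,
          into = max(trapezoid_area(t_obs, y), 0, na.rm = TRUE),
          maxo = max(y),
          sn = if (stats::runif(1) < 0.1) NA_real_
               else stats::runif(1, -2, 5),
          f = stats::rpois(1, 50), scale = width / 4 + stats::rnorm(1),
          lmin = stats::rpois(1, 20), filled = FALSE)
      }
    }
    if (kind == "good") {
      good_params[[ids[j]]] <- list(mz_lo = mz_lo, mz_hi = mz_hi,
                                    rtmin = rtmin, rtmax = rtmax,
                                    alpha = alpha)
    }
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      feature_id = ids[j],
      label = if (kind == "good") "Good" else "Bad",
      artifact = if (kind == "good") "none" else "random-noise",
      parent_id = NA_character_, mz = mz, rt_center = center,
      width = width, alpha = if (kind == "good") alpha else NA_real_,
      height = if (kind == "good") base_height else NA_real_)
  }

  ## tail artifacts: a bounding box over the trailing 30% of a parent Good
  ## feature's profile mass (from the 0.7 quantile of its beta shape to the
  ## peak end); no new scan points, the parent's trace is re-integrated, so
  ## the artifact retains the parent's biological signal
  good_ids <- names(good_params)
  for (j in which(kinds == "tail")) {
    parent <- good_ids[sample(length(good_ids), 1)]
    gp <- good_params[[parent]]
    t_lo <- gp$rtmin +
      stats::qbeta(0.7, gp$alpha, .BETA_BETA) * (gp$rtmax - gp$rtmin)
    box <- list(mzmin = gp$mz_lo, mzmax = gp$mz_hi,
                rtmin = t_lo, rtmax = gp$rtmax)
    for (i in seq_len(config$n_files)) {
      sid <- manifest$sample_id[i]
      file_scans <- do.call(rbind, scans[[sid]])
      eic <- extract_eic(file_scans, box)
      if (nrow(eic$points) < 3L) next
      peak_rows[[length(peak_rows) + 1L]] <- data.frame(
        feature_id = ids[j], sample_id = sid,
        mz = gp$mz_lo / (1 - 2.5e-6), mzmin = gp$mz_lo, mzmax = gp$mz_hi,
        rt = eic$points$rt[which.max(eic$points$intensity)],
        rtmin = t_lo, rtmax = gp$rtmax,
        into = trapezoid_area(eic$points$rt, eic$points$intensity),
        maxo = max(eic$points$intensity),
        sn = stats::runif(1, 0, 4),
        f = stats::rpois(1, 50),
        scale = (gp$rtmax - t_lo) / 4 + stats::rnorm(1),
        lmin = stats::rpois(1, 20), filled = FALSE)
    }
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      feature_id = ids[j], label = "Bad", artifact = "peak-tail",
      parent_id = parent, mz = gp$mz_lo / (1 - 2.5e-6),
      rt_center = (t_lo + gp$rtmax) / 2, width = gp$rtmax - t_lo,
      alpha = NA_real_, height = NA_real_)
  }

  scans_by_file <- lapply(scans, function(pieces) {
    df <- do.call(rbind, pieces)
    df <- df[order(df$rt, df$mz), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  peak_table <- do.call(rbind, peak_rows)
  rownames(peak_table) <- NULL
  truth <- do.call(rbind, truth_rows)
  truth <- truth[match(ids[ids %in% truth$feature_id], truth$feature_id), ]
  rownames(truth) <- NULL
  labels <- stats::setNames(truth$label, truth$feature_id)

  structure(list(scans_by_file = scans_by_file, peak_table = peak_table,
                 manifest = manifest, labels = labels, truth = truth,
                 config = config),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("<sim_bundle> %d features x %d files (%d Good / %d Bad)\n",
              x$config$n_features, x$config$n_files,
              sum(x$labels == "Good"), sum(x$labels == "Bad")))
  invisible(x)
}

#' Write a synthetic bundle to disk
#'
#' Writes one centroided mzML per file plus `peaks.csv`, `manifest.csv` and
#' `labels.csv` in the dialects consumed by [read_peak_table()],
#' [read_manifest()] and [read_labels()]. Numeric peak-table columns are
#' serialized at full precision so re-reading reproduces the in-memory
#' objects.
#'
#' @param bundle A [generate_feature_set()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mzml_paths <- character(0)
  for (sid in names(bundle$scans_by_file)) {
    p <- file.path(dir, paste0(sid, ".mzML"))
    write_mzml(bundle$scans_by_file[[sid]], p)
    mzml_paths[sid] <- p
  }
  pk <- bundle$peak_table
  for (col in names(pk)) {
    if (is.numeric(pk[[col]]) && !is.logical(pk[[col]])) {
      v <- sprintf("%.17g", pk[[col]])
      v[is.na(pk[[col]])] <- "NA"
      pk[[col]] <- v
    }
  }
  peaks_path <- file.path(dir, "peaks.csv")
  utils::write.csv(pk, peaks_path, row.names = FALSE, quote = FALSE,
                   na = "NA")
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(bundle$manifest[, c("sample_id", "run_type")],
                   manifest_path, row.names = FALSE, quote = FALSE)
  labels_path <- file.path(dir, "labels.csv")
  utils::write.csv(data.frame(feature_id = names(bundle$labels),
                              label = unname(bundle$labels)),
                   labels_path, row.names = FALSE, quote = FALSE)
  invisible(list(mzml = mzml_paths, peaks = peaks_path,
                 manifest = manifest_path, labels = labels_path))
}

#' Read a bundle directory written by [write_bundle()]
#'
#' @param dir Bundle directory.
#' @return List with `scans_by_file`, `features` (a `mass_feature_list`),
#'   `peak_table`, `manifest`, `labels`.
#' @export
read_bundle <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  labels <- read_labels(file.path(dir, "labels.csv"))
  features <- read_peak_table(file.path(dir, "peaks.csv"), manifest, labels)
  scans_by_file <- lapply(manifest$sample_id, function(sid) {
    read_scans(file.path(dir, paste0(sid, ".mzML")))
  })
  names(scans_by_file) <- manifest$sample_id
  peak_table <- utils::read.csv(file.path(dir, "peaks.csv"), colClasses = c(
    feature_id = "character", sample_id = "character"))
  list(scans_by_file = scans_by_file, features = features,
       peak_table = peak_table, manifest = manifest, labels = labels)
}
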