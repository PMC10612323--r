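#' @title Logistic peak-quality models
#'
#' @description Fits multiple logistic regression models of the likelihood
#' that a mass feature would be manually labeled "Good", on three metric
#' subsets: the two raw-data metrics alone (`two_param`), the peak-list
#' metrics available without raw data (`xcms_only`), or every surviving
#' metric (`full`). Ambiguous and standards-only features are dropped from
#' fitting. Predictors are standardized by training mean/sd and the
#' standardization is stored with the model so coefficients are comparable
#' across training sets.
#'
#' @name classifier
NULL

.SPEC_COLUMNS <- list(
  two_param = c("med_shape_r", "med_snr_log"),
  xcms_only = c("mean_mz", "sd_ppm", "mean_rt", "sd_rt", "mean_pw", "sd_pw",
                "mean_log_area", "sd_log_area", "mean_lmin", "mean_f",
                "mean_scale", "n_peaks_frac", "frac_samples_found",
                "frac_stans_found"))

#' Define a model specification
#'
#' @param name `"two_param"`, `"xcms_only"` or `"full"`.
#' @param columns Metric columns; required for `"full"` (the columns
#'   surviving [prune_correlated()]), fixed for the other two.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name = c("two_param", "xcms_only", "full"),
                       columns = NULL) {
  name <- match.arg(name)
  if (name %in% names(.SPEC_COLUMNS)) {
    columns <- .SPEC_COLUMNS[[name]]
  } else if (is.null(columns) || length(columns) == 0L) {
    stop("the 'full' model needs the surviving metric columns ",
         "(pass prune_correlated()$metrics column names)")
  }
  structure(list(name = name, columns = columns), class = "model_spec")
}

.align_labels <- function(metrics, labels) {
  if (!is.null(names(labels))) {
    labels <- labels[metrics$feature_id]
    labels[is.na(labels)] <- "Unlabeled"
  } else {
    stopifnot(length(labels) == nrow(metrics))
  }
  unname(labels)
}

#' Fit a logistic peak-quality model
#'
#' Maximum-likelihood logistic regression of Good (1) vs Bad (0) on the
#' spec's standardized metric columns. Features labeled Ambiguous,
#' StansOnly or Unlabeled are dropped before fitting. Complete separation
#' is detected and warned about; the (capped) fit is still returned.
#'
#' @param metrics Metric `data.frame` with a `feature_id` column.
#' @param labels Named label vector (keyed by feature_id) or a vector
#'   aligned with `metrics` rows.
#' @param spec A [model_spec()].
#' @param training_id Identifier recorded with the model.
#' @return Object of class `fitted_model`: coefficients, standard errors,
#'   z statistics, p-values, standardization centers/scales, training n.
#' @export
fit_logistic <- function(metrics, labels, spec, training_id = "training") {
  stopifnot(inherits(spec, "model_spec"))
  missing_cols <- setdiff(spec$columns, names(metrics))
  if (length(missing_cols)) {
    stop("metric table is missing model column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  labels <- .align_labels(metrics, labels)
  keep <- labels %in% c("Good", "Bad")
  y <- as.integer(labels[keep] == "Good")
  if (length(unique(y)) < 2L) {
    stop("need at least one Good and one Bad labeled feature to fit")
  }
  X <- as.matrix(metrics[keep, spec$columns, drop = FALSE])
  if (anyNA(X)) {
    stop("missing values in predictor columns; run impute_design_metrics() ",
         "before fitting")
  }
  centers <- colMeans(X)
  scales <- apply(X, 2, stats::sd)
  scales[scales == 0] <- 1
  Z <- scale(X, center = centers, scale = scales)
  dat <- data.frame(.y = y, Z, check.names = FALSE)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separation) {
    warning("possible complete separation in logistic fit '", training_id,
            "'; coefficients are at the iteration cap and standard errors ",
            "are unreliable", call. = FALSE)
  }
  ct <- summary(fit)$coefficients
  structure(
    list(spec = spec,
         coefficients = ct[, "Estimate"],
         se = ct[, "Std. Error"],
         z = ct[, "z value"],
         p = ct[, "Pr(>|z|)"],
         centers = centers, scales = scales,
         n = length(y), training_id = training_id,
         separation = separation),
    class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("<fitted_model %s> trained on '%s' (n = %d)%s\n",
              x$spec$name, x$training_id, x$n,
              if (x$separation) " [separation warning]" else ""))
  print(round(cbind(estimate = x$coefficients, se = x$se, z = x$z, p = x$p),
              4))
  invisible(x)
}

#' Predict the likelihood that each feature is Good
#'
#' Applies the training standardization to the metric columns and returns
#' the inverse logit of the linear predictor.
#'
#' @param model A [fit_logistic()] result.
#' @param metrics Metric `data.frame` containing the model's columns.
#' @return Numeric vector of likelihoods in (0, 1), named by feature_id
#'   when available.
#' @export
predict_likelihood <- function(model, metrics) {
  stopifnot(inherits(model, "fitted_model"))
  cols <- model$spec$columns
  missing_cols <- setdiff(cols, names(metrics))
  if (length(missing_cols)) {
    stop("metric table is missing model column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  X <- as.matrix(metrics[, cols, drop = FALSE])
  if (anyNA(X)) stop("missing values in predictor columns")
  Z <- scale(X, center = model$centers, scale = model$scales)
  eta <- drop(model$coefficients[1] + Z %*% model$coefficients[-1])
  p <- stats::plogis(eta)
  if ("feature_id" %in% names(metrics)) names(p) <- metrics$feature_id
  p
}

#' Confusion counts, FDR and GFF at a likelihood threshold
#'
#' A feature is predicted Good iff its likelihood is greater than or equal
#' to the threshold. Only Good/Bad-labeled features enter the counts;
#' Ambiguous, StansOnly and Unlabeled features are excluded entirely.
#'
#' @param likelihoods Predicted likelihoods.
#' @param labels Label vector aligned with `likelihoods` (or named by
#'   feature_id, matched against `names(likelihoods)`).
#' @param threshold Likelihood threshold in (0, 1); 0.5 for internal
#'   evaluation, 0.9 for application to novel data.
#' @return Object of class `confusion_summary`: `tp`, `fp`, `tn`, `fn`,
#'   `fdr` (percent, `NA` if no positive predictions), `gff` (percent,
#'   `NA` if no actual positives), `threshold`.
#' @export
confusion_summary <- function(likelihoods, labels, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  if (!is.null(names(labels)) && !is.null(names(likelihoods))) {
    labels <- labels[names(likelihoods)]
    labels[is.na(labels)] <- "Unlabeled"
  }
  stopifnot(length(labels) == length(likelihoods))
  keep <- labels %in% c("Good", "Bad")
  lab <- labels[keep]
  pred_good <- likelihoods[keep] >= threshold
  tp <- sum(pred_good & lab == "Good")
  fp <- sum(pred_good & lab == "Bad")
  tn <- sum(!pred_good & lab == "Bad")
  fn <- sum(!pred_good & lab == "Good")
  fdr <- if (tp + fp == 0) NA_real_ else 100 * fp / (fp + tp)
  gff <- if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 fdr = fdr, gff = gff, threshold = threshold),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf(paste0("<confusion_summary> threshold %.2f: TP %d, FP %d, ",
                     "TN %d, FN %d | FDR %.2f%%, GFF %.2f%%\n"),
              x$threshold, x$tp, x$fp, x$tn, x$fn, x$fdr, x$gff))
  invisible(x)
}

#' Agreement between two models' predictions
#'
#' Pearson correlation compares raw likelihoods; Spearman compares the
#' rank ordering (which is what matters when labeling "down" a ranked
#' feature list).
#'
#' @param likelihoods_a,likelihoods_b Paired prediction vectors (length
#'   >= 3).
#' @return List with `pearson_r` and `spearman_rho` (`NA` for a constant
#'   vector).
#' @export
agreement_stats <- function(likelihoods_a, likelihoods_b) {
  stopifnot(length(likelihoods_a) == length(likelihoods_b),
            length(likelihoods_a) >= 3L)
  safe_cor <- function(method) {
    if (stats::sd(likelihoods_a) == 0 || stats::sd(likelihoods_b) == 0) {
      return(NA_real_)
    }
    stats::cor(likelihoods_a, likelihoods_b, method = method)
  }
  list(pearson_r = safe_cor("pearson"), spearman_rho = safe_cor("spearman"))
}

.derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 1009) %% 2147483629)
}

#' Coefficient stability under smaller training sets
#'
#' Subsamples the labeled features without replacement at each training
#' fraction, refits the model, and reports the per-replicate coefficient
#' estimates alongside the full-data fit and its 1- and 2-SE bands.
#'
#' @param metrics Metric `data.frame`.
#' @param labels Label vector (named or aligned).
#' @param spec A [model_spec()].
#' @param fractions Training fractions in (0, 1].
#' @param reps Replicates per fraction (default 10).
#' @param seed Integer seed; per-replicate seeds are derived
#'   deterministically from it.
#' @return List with `estimates` (`data.frame`: `fraction`, `rep`, `term`,
#'   `estimate`; skipped replicates appear as `NA`) and `full` (the
#'   full-data `fitted_model`).
#' @export
training_fraction_stability <- function(metrics, labels, spec,
                                        fractions = c(0.25, 0.5, 0.75, 1),
                                        reps = 10, seed = 1) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  labels <- .align_labels(metrics, labels)
  keep <- which(labels %in% c("Good", "Bad"))
  full <- fit_logistic(metrics[keep, , drop = FALSE], labels[keep], spec,
                       training_id = "full")
  out <- list()
  k <- 0L
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    n_take <- ceiling(f * length(keep))
    for (r in seq_len(reps)) {
      k <- k + 1L
      set.seed(.derive_seed(seed, fi * 1000L + r))
      idx <- sort(sample(keep, n_take))
      sub_lab <- labels[idx]
      est <- if (length(unique(sub_lab)) < 2L) {
        message("fraction ", f, " rep ", r,
                ": subsample lost a class, skipped")
        rep(NA_real_, length(full$coefficients))
      } else {
        suppressWarnings(
          fit_logistic(metrics[idx, , drop = FALSE], sub_lab, spec,
                       training_id = sprintf("frac%.2f_rep%d", f, r))
        )$coefficients
      }
      out[[k]] <- data.frame(fraction = f, rep = r,
                             term = names(full$coefficients),
                             estimate = unname(est))
    }
  }
  list(estimates = do.call(rbind, out), full = full)
}

#' Serialize a fitted model to a plain-text JSON file
#'
#' @param model A `fitted_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- list(name = model$spec$name, columns = model$spec$columns,
              coefficients = as.list(model$coefficients),
              se = as.list(model$se),
              centers = as.list(model$centers),
              scales = as.list(model$scales),
              n = model$n, training_id = model$training_id,
              separation = model$separation)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted model written by [write_model()]
#'
#' @param path JSON path.
#' @return A `fitted_model` (z/p slots are `NA`; they are training-time
#'   diagnostics).
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- model_spec(obj$name, columns = obj$columns)
  structure(
    list(spec = spec,
         coefficients = unlist(obj$coefficients),
         se = unlist(obj$se),
         z = rep(NA_real_, length(obj$coefficients)),
         p = rep(NA_real_, length(obj$coefficients)),
         centers = unlist(obj$centers), scales = unlist(obj$scales),
         n = obj$n, training_id = obj$training_id,
         separation = isTRUE(obj$separation)),
    class = "fitted_model")
}
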