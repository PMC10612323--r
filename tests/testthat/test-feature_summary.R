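mk_feature <- function(peaks, id = "FT1") mass_feature(id, peaks)

base_peaks <- function(n = 2, sample_id = c("s1", "s2")[seq_len(n)]) {
  data.frame(sample_id = sample_id,
             mz = rep(100.0002, n), mzmin = 99.999, mzmax = 100.001,
             rt = 300 + seq_len(n), rtmin = 290, rtmax = 310,
             into = rep(1e6, n), maxo = 1e5, sn = 10,
             f = 1, scale = 2, lmin = 3, filled = FALSE)
}

test_that("stated summary rules: log areas, ppm sd, sn handling", {
  man <- tiny_manifest()
  pk <- base_peaks(2)
  pk$into <- c(1e6, 1e8)
  mv <- summarize_feature(mk_feature(pk), manifest = man)
  expect_equal(mv$mean_log_area, 7.0)

  pk2 <- base_peaks(2)
  pk2$mz <- c(100.0000, 100.0004)
  mv2 <- summarize_feature(mk_feature(pk2), manifest = man)
  ppm <- pk2$mz / median(pk2$mz) * 1e6
  expect_equal(mv2$sd_ppm, sd(ppm))
  expect_equal(mv2$sd_ppm, 2.828, tolerance = 1e-3)

  pk3 <- base_peaks(3, sample_id = c("s1", "s2", "s1"))
  pk3$sn <- c(-1, 0, 10)
  mv3 <- summarize_feature(mk_feature(pk3), manifest = man)
  expect_equal(mv3$mean_log_sn, 0.5)  # {-1 dropped, 0 -> 1} -> logs {0, 1}
})

test_that("sd fields of a single-peak feature are missing, not zero", {
  mv <- summarize_feature(mk_feature(base_peaks(1)),
                          manifest = tiny_manifest())
  expect_true(is.na(mv$sd_rt))
  expect_true(is.na(mv$sd_pw))
  expect_true(is.na(mv$sd_ppm))
  expect_true(is.na(mv$sd_log_area))
})

test_that("summarize_feature is permutation-invariant to peak order", {
  set.seed(41)
  pk <- base_peaks(6, sample_id = rep(c("s1", "s2"), 3))
  pk$rt <- 300 + rnorm(6)
  pk$into <- 10^runif(6, 5, 7)
  pk$sn <- c(-2, 0, 3, 10, NA, 7)
  man <- tiny_manifest()
  a <- summarize_feature(mk_feature(pk), manifest = man)
  b <- summarize_feature(mk_feature(pk[sample(6), ]), manifest = man)
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("fractions deduplicate per file and respect run types", {
  man <- data.frame(sample_id = c("s1", "s2", "p1", "st1"),
                    run_type = c("sample", "sample", "pooled", "standard"),
                    metadata = "")
  pk <- base_peaks(5, sample_id = c("s1", "s1", "s2", "p1", "st1"))
  pk$filled <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  mv <- summarize_feature(mk_feature(pk), manifest = man)
  expect_equal(mv$n_peaks_frac, 4 / 4)  # 4 distinct files
  expect_equal(mv$frac_found, 3 / 4)    # s2 only gap-filled
  expect_equal(mv$frac_samples_found, 1 / 2)
  expect_equal(mv$frac_stans_found, 1 / 1)
  expect_lte(mv$n_peaks_frac, 1)
})

test_that("pooled CVs use areas of pooled runs; absent pools are missing", {
  man <- data.frame(sample_id = c("s1", "p1", "p2", "p3"),
                    run_type = c("sample", "pooled", "pooled", "pooled"),
                    metadata = "")
  pk <- base_peaks(4, sample_id = c("s1", "p1", "p2", "p3"))
  pk$into <- c(99, 100, 200, 400)
  mv <- summarize_feature(mk_feature(pk), manifest = man)
  pooled <- c(100, 200, 400)
  expect_equal(mv$cv_pooled, sd(pooled) / mean(pooled))
  expect_equal(mv$cv_pooled_robust,
               median(abs(pooled - median(pooled))) / median(pooled))
  mv2 <- summarize_feature(mk_feature(base_peaks(2)),
                           manifest = tiny_manifest())
  # single pooled area: sample sd undefined
  expect_true(is.na(mv2$cv_pooled))
})

test_that("raw-data metric medians log-transform snr and drop missing", {
  pm <- data.frame(feature_id = "FT1",
                   shape_r = c(0.9, 0.8, NA),
                   snr = c(10, 1000, NA),
                   missed_prop = c(0, 0.5, NA))
  mv <- summarize_feature(mk_feature(base_peaks(2)), peak_metrics = pm,
                          manifest = tiny_manifest())
  expect_equal(mv$med_shape_r, 0.85)
  expect_equal(mv$med_snr_log, 2)  # median of log10({10, 1000}) = {1, 3}
  expect_equal(mv$med_missed_prop, 0.25)
  # SNR cap maps to 6 on the log scale
  pm$snr <- c(1e6, 1e6, 1e6)
  mv2 <- summarize_feature(mk_feature(base_peaks(2)), peak_metrics = pm,
                           manifest = tiny_manifest())
  expect_equal(mv2$med_snr_log, 6)
})

test_that("impute_design_metrics fills one span beyond the worst value", {
  m <- data.frame(feature_id = c("a", "b", "c", "d"),
                  med_shape_r = c(0.1, 0.5, 1.0, NA),     # larger better
                  med_missed_prop = c(0.0, 0.2, 0.4, NA), # smaller better
                  cv_pooled = c(1, 2, 3, 3))              # no missing
  out <- impute_design_metrics(m)
  expect_equal(out$med_shape_r[4], 0.1 - 0.9)   # -0.8, one span below min
  expect_equal(out$med_missed_prop[4], 0.4 + 0.4)
  expect_identical(out$cv_pooled, m$cv_pooled)  # identity when complete
  expect_identical(out$med_shape_r[1:3], m$med_shape_r[1:3])
  expect_error(
    impute_design_metrics(data.frame(feature_id = "a",
                                     med_shape_r = NA_real_)),
    "med_shape_r")
})

test_that("imputation leaves non-missing cells bit-identical", {
  set.seed(43)
  m <- data.frame(feature_id = sprintf("f%02d", 1:30))
  for (col in intersect(METRIC_COLUMNS, METRIC_COLUMNS)[1:10]) {
    v <- rnorm(30)
    v[sample(30, 4)] <- NA
    m[[col]] <- v
  }
  out <- impute_design_metrics(m)
  for (col in names(m)[-1]) {
    ok <- !is.na(m[[col]])
    expect_identical(out[[col]][ok], m[[col]][ok])
    expect_false(anyNA(out[[col]]))
  }
})

test_that("prune_correlated drops the later redundant column", {
  set.seed(44)
  m <- data.frame(feature_id = sprintf("f%02d", 1:50))
  m$mean_rt <- rnorm(50)
  m$sd_rt <- rnorm(50)
  m$mean_pw <- m$mean_rt  # exact duplicate, later in canonical order
  res <- prune_correlated(m)
  expect_identical(res$removed, "mean_pw")
  expect_false("mean_pw" %in% names(res$metrics))

  # orthogonal columns are untouched
  m2 <- data.frame(feature_id = sprintf("f%02d", 1:50),
                   mean_rt = rnorm(50), sd_rt = rnorm(50))
  res2 <- prune_correlated(m2)
  expect_length(res2$removed, 0L)

  # constructed r = 0.95 pair among random columns, checked against a
  # brute-force all-pairs correlation scan
  cols <- METRIC_COLUMNS[1:10]
  m3 <- data.frame(feature_id = sprintf("f%02d", 1:200))
  for (col in cols) m3[[col]] <- rnorm(200)
  rho <- 0.95
  m3[[cols[7]]] <- rho * scale(m3[[cols[3]]])[, 1] +
    sqrt(1 - rho^2) * rnorm(200)
  cm <- abs(cor(as.matrix(m3[, cols])))
  diag(cm) <- 0
  over <- which(cm > 0.9, arr.ind = TRUE)
  expect_true(all(rownames(over) %in% cols[c(3, 7)]))  # only that pair
  res3 <- prune_correlated(m3)
  expect_identical(res3$removed, cols[7])
})

test_that("pruning requires a complete table", {
  m <- data.frame(feature_id = "a", mean_rt = NA_real_, sd_rt = 1)
  expect_error(prune_correlated(m), "complete")
})
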