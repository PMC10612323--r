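# Shared fixtures and independent plain-formula oracles. The oracles
# deliberately avoid the package's code paths (no unit_scale, no cor) so
# they can stand as independent checks.

make_eic <- function(rt, intensity, scan_times = sort(unique(rt))) {
  structure(list(points = data.frame(rt = rt, intensity = intensity),
                 scan_times = scan_times),
            class = "eic")
}

# Pearson's r from the raw sum formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

oracle_scale01 <- function(v) {
  s <- v - min(v)
  s / max(s)
}

# Recompute all four per-alpha correlations and the residual-based SNR
# directly from the formulas.
oracle_shape_metrics <- function(rt, intensity, alphas = c(2.5, 3, 4, 5),
                                 beta = 5) {
  u <- oracle_scale01(rt)
  r_all <- sapply(alphas, function(a) {
    oracle_pearson(dbeta(u, a, beta), intensity)
  })
  best <- which.max(r_all)
  resid <- oracle_scale01(intensity) -
    oracle_scale01(dbeta(u, alphas[best], beta))
  s <- sqrt(sum((resid - mean(resid))^2) / (length(resid) - 1))
  list(r = max(r_all), alpha = alphas[best],
       snr = if (s == 0) 1e6 else 1 / s)
}

oracle_trapezoid <- function(x, y) {
  a <- 0
  for (i in seq_len(length(x) - 1)) {
    a <- a + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  }
  a
}

# A small deterministic beta-shaped EIC with optional additive noise.
beta_peak_eic <- function(n = 20, alpha = 4, noise_sd = 0, height = 1e6,
                          rt0 = 100, width = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rt <- seq(rt0, rt0 + width, length.out = n)
  u <- (rt - min(rt)) / (max(rt) - min(rt))
  y <- height * dbeta(u, alpha, 5) / max(dbeta(u, alpha, 5))
  if (noise_sd > 0) y <- pmax(y + rnorm(n, 0, noise_sd * height), 0)
  make_eic(rt, y)
}

# Minimal 4-row peak table data.frame for io tests.
tiny_peak_table <- function() {
  data.frame(
    feature_id = c("FT1", "FT1", "FT2", "FT2"),
    sample_id = c("s1", "s2", "s1", "s2"),
    mz = c(100.0000, 100.0004, 200.1, 200.3),
    mzmin = c(99.999, 99.999, 200.0, 200.0),
    mzmax = c(100.001, 100.001, 200.4, 200.4),
    rt = c(300, 302, 600, 604),
    rtmin = c(290, 292, 590, 594),
    rtmax = c(310, 312, 610, 614),
    into = c(1e6, 1e8, 2e5, 3e5),
    maxo = c(1e5, 1e7, 2e4, 3e4),
    sn = c(10, NA, -1, 0),
    f = c(1, 2, 3, 4), scale = c(5, 5, 6, 6), lmin = c(10, 11, 12, 13),
    filled = c(FALSE, FALSE, FALSE, TRUE))
}

tiny_manifest <- function() {
  data.frame(sample_id = c("s1", "s2"),
             run_type = c("sample", "pooled"),
             metadata = "")
}

write_tiny_bundle_csvs <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(tiny_peak_table(), file.path(dir, "peaks.csv"),
            row.names = FALSE, quote = FALSE, na = "")
  writeLines(c("sample_id,run_type", "s1,sample", "s2,pooled"),
             file.path(dir, "manifest.csv"))
  writeLines(c("feature_id,label", "FT1,Good", "FT2,Bad"),
             file.path(dir, "labels.csv"))
  dir
}

# Small cached default-ish bundle shared by synthetic/pipeline tests
# (computed once per test run; 60 features keeps the suite fast).
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_feature_set(
        sim_config(n_features = 60, n_files = 9, seed = 42))
    }
    cache
  }
})
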