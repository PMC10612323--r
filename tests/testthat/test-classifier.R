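# Synthetic metric table drawn from a known logistic generative model on
# the standardized scale: P(Good) = plogis(b0 + b1 * z1 [+ b2 * z2]).
logistic_table <- function(n, b0 = 0, b1 = 3, b2 = 0, seed = 1) {
  set.seed(seed)
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(b0 + b1 * z1 + b2 * z2))
  list(metrics = data.frame(feature_id = sprintf("f%05d", seq_len(n)),
                            med_shape_r = z1, med_snr_log = z2),
       labels = ifelse(y == 1, "Good", "Bad"))
}

test_that("fit_logistic recovers a known slope within 2 SE", {
  sim <- logistic_table(2000, b1 = 3, seed = 101)
  fit <- fit_logistic(sim$metrics, sim$labels, model_spec("two_param"))
  est <- fit$coefficients["med_shape_r"]
  se <- fit$se["med_shape_r"]
  # truth on the standardized scale is 3 * sd(z1)
  truth <- 3 * sd(sim$metrics$med_shape_r)
  expect_lt(abs(est - truth), 2 * se)
  expect_length(fit$coefficients, 3L)
  expect_length(fit$se, 3L)
  expect_true(all(is.finite(fit$p)))
})

test_that("label handling: single class errors, Ambiguous/StansOnly drop", {
  sim <- logistic_table(100, seed = 102)
  expect_error(fit_logistic(sim$metrics, rep("Good", 100),
                            model_spec("two_param")), "at least one")
  labs <- sim$labels
  labs[1:20] <- "Ambiguous"
  labs[21:30] <- "StansOnly"
  fit <- fit_logistic(sim$metrics, labs, model_spec("two_param"))
  expect_equal(fit$n, sum(labs %in% c("Good", "Bad")))
})

test_that("missing predictor values and columns are hard errors", {
  sim <- logistic_table(50, seed = 103)
  m <- sim$metrics
  m$med_shape_r[3] <- NA
  expect_error(fit_logistic(m, sim$labels, model_spec("two_param")),
               "impute")
  expect_error(fit_logistic(sim$metrics[, 1:2], sim$labels,
                            model_spec("two_param")), "med_snr_log")
})

test_that("predict_likelihood is the inverse logit of the dot product", {
  sim <- logistic_table(500, b1 = 2, b2 = -1, seed = 104)
  fit <- fit_logistic(sim$metrics, sim$labels, model_spec("two_param"))
  lik <- predict_likelihood(fit, sim$metrics)
  # plain-formula oracle
  Z <- scale(as.matrix(sim$metrics[, c("med_shape_r", "med_snr_log")]),
             center = fit$centers, scale = fit$scales)
  eta <- fit$coefficients[1] + Z %*% fit$coefficients[-1]
  expect_equal(unname(lik), unname(1 / (1 + exp(-eta[, 1]))),
               tolerance = 1e-12)
  # standardized x = 0 with intercept 0 gives 0.5; monotone in x
  toy <- fit
  toy$coefficients <- c("(Intercept)" = 0, med_shape_r = 1, med_snr_log = 0)
  toy$centers <- c(med_shape_r = 0, med_snr_log = 0)
  toy$scales <- c(med_shape_r = 1, med_snr_log = 1)
  grid <- data.frame(med_shape_r = c(-5, 0, 5, 50), med_snr_log = 0)
  p <- predict_likelihood(toy, grid)
  expect_equal(p[2], 0.5)
  expect_true(all(diff(p) > 0))
  expect_error(predict_likelihood(fit, grid[, 1, drop = FALSE]),
               "med_snr_log")
})

test_that("confusion_summary reproduces the in-paper FDR arithmetic", {
  # 192 features above 0.9: 151 Good, 3 Bad, 21 Ambiguous, 17 StansOnly
  lik <- c(rep(0.95, 192), rep(0.1, 100))
  lab <- c(rep("Good", 151), rep("Bad", 3), rep("Ambiguous", 21),
           rep("StansOnly", 17), rep("Bad", 100))
  cs <- confusion_summary(lik, lab, threshold = 0.9)
  expect_equal(cs$tp, 151)
  expect_equal(cs$fp, 3)
  expect_equal(cs$fdr, 100 * 3 / 154)
  expect_equal(cs$fdr, 1.95, tolerance = 0.01)

  # 400 flagged: 348 Good, 17 Bad, 35 Ambiguous
  lik2 <- rep(0.95, 400)
  lab2 <- c(rep("Good", 348), rep("Bad", 17), rep("Ambiguous", 35))
  cs2 <- confusion_summary(lik2, lab2, threshold = 0.9)
  expect_equal(cs2$fdr, 100 * 17 / 365)
  expect_equal(cs2$fdr, 4.66, tolerance = 0.01)

  # degenerate branches
  cs3 <- confusion_summary(c(0.99, 0.99, 0.99, 0.2), rep("Good", 4), 0.5)
  expect_equal(cs3$fdr, 0)
  expect_equal(cs3$gff, 75)
  cs4 <- confusion_summary(c(0.1, 0.1), c("Bad", "Bad"), 0.5)
  expect_true(is.na(cs4$fdr))
  expect_true(is.na(cs4$gff))
})

test_that("counts are monotone in the threshold and bounded in [0, 100]", {
  sim <- logistic_table(400, b1 = 1.5, seed = 105)
  fit <- fit_logistic(sim$metrics, sim$labels, model_spec("two_param"))
  lik <- predict_likelihood(fit, sim$metrics)
  prev <- NULL
  for (th in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    cs <- confusion_summary(lik, sim$labels, th)
    expect_gte(cs$fdr, 0); expect_lte(cs$fdr, 100)
    expect_gte(cs$gff, 0); expect_lte(cs$gff, 100)
    if (!is.null(prev)) {
      expect_lte(cs$fp, prev$fp)
      expect_lte(cs$tp, prev$tp)
    }
    prev <- cs
  }
})

test_that("training-table predictions at 0.5 reproduce the fit's own
           classifications", {
  sim <- logistic_table(300, b1 = 2, seed = 106)
  fit <- fit_logistic(sim$metrics, sim$labels, model_spec("two_param"))
  lik <- predict_likelihood(fit, sim$metrics)
  cs <- confusion_summary(lik, sim$labels, 0.5)
  expect_equal(cs$tp + cs$fp + cs$tn + cs$fn, 300)
  expect_equal(cs$tp + cs$fp, sum(lik >= 0.5))
})

test_that("agreement_stats matches plain-formula Pearson and Spearman", {
  x <- c(0.1, 0.4, 0.8, 0.9, 0.3)
  expect_equal(agreement_stats(x, x), list(pearson_r = 1, spearman_rho = 1))
  expect_equal(agreement_stats(x, -x)$spearman_rho, -1)
  expect_true(is.na(agreement_stats(x, rep(0.5, 5))$pearson_r))
  # two models trained on disjoint halves, compared on a common test set
  sim <- logistic_table(1200, b1 = 2.5, b2 = 1, seed = 107)
  test_idx <- 1:200
  a_idx <- 201:700
  b_idx <- 701:1200
  fit_a <- fit_logistic(sim$metrics[a_idx, ], sim$labels[a_idx],
                        model_spec("two_param"), training_id = "A")
  fit_b <- fit_logistic(sim$metrics[b_idx, ], sim$labels[b_idx],
                        model_spec("two_param"), training_id = "B")
  pa <- predict_likelihood(fit_a, sim$metrics[test_idx, ])
  pb <- predict_likelihood(fit_b, sim$metrics[test_idx, ])
  got <- agreement_stats(pa, pb)
  expect_equal(got$pearson_r, oracle_pearson(pa, pb), tolerance = 1e-12)
  expect_equal(got$spearman_rho, oracle_pearson(rank(pa), rank(pb)),
               tolerance = 1e-12)
  expect_gt(got$pearson_r, 0.9)  # same generative model, both should agree
})

test_that("training_fraction_stability: fraction 1 is exact, seeds are
           deterministic, half-data estimates stay near the full fit", {
  sim <- logistic_table(2000, b1 = 2, b2 = -1, seed = 108)
  spec <- model_spec("two_param")
  st <- training_fraction_stability(sim$metrics, sim$labels, spec,
                                    fractions = c(0.5, 1), reps = 10,
                                    seed = 9)
  full <- st$full
  at1 <- st$estimates[st$estimates$fraction == 1, ]
  for (term in names(full$coefficients)) {
    expect_identical(unique(at1$estimate[at1$term == term]),
                     unname(full$coefficients[term]))
  }
  st2 <- training_fraction_stability(sim$metrics, sim$labels, spec,
                                     fractions = c(0.5, 1), reps = 10,
                                     seed = 9)
  expect_identical(st$estimates, st2$estimates)

  at_half <- st$estimates[st$estimates$fraction == 0.5 &
                            st$estimates$term != "(Intercept)", ]
  within <- mapply(function(term, est) {
    abs(est - full$coefficients[term]) <= 2 * full$se[term]
  }, at_half$term, at_half$estimate)
  expect_gte(mean(within), 0.8)
})
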