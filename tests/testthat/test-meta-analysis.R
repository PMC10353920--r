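make_rate_db <- function(values, ns = NA, variances = NA) {
  make_db(data.frame(study_id = sprintf("s%d", seq_along(values)),
                     vital_rate = "sa", value = values, n = ns,
                     variance = variances))
}

test_that("method selection uses the conjunctive thin-evidence rule", {
  db25 <- make_rate_db(runif(25, 0.7, 0.95),
                       ns = c(rep(50, 22), rep(NA, 3)))  # 12% lacking n
  expect_equal(choose_method(db25), "meta")
  db10 <- make_rate_db(runif(10, 0.7, 0.95),
                       ns = c(rep(50, 5), rep(NA, 5)))   # 50% lacking n
  expect_equal(choose_method(db10), "simple")
  db10b <- make_rate_db(runif(10, 0.7, 0.95), ns = rep(50, 10))
  expect_equal(choose_method(db10b), "meta")  # only one condition holds
  expect_error(choose_method(db10[0, ]), "no estimates")
})

test_that("simple mean returns the arithmetic mean and k-1 sample variance", {
  res <- simple_mean(c(0.2, 0.4, 0.6))
  expect_equal(res$mean, 0.4)
  expect_equal(res$variance, 0.04)
  expect_equal(res$method, "simple")
  one <- simple_mean(0.75)
  expect_equal(one$mean, 0.75)
  expect_equal(one$variance, 0)
  expect_error(simple_mean(numeric(0)), "no estimates")
})

test_that("random-effects meta reproduces the hand-worked two-study example", {
  res <- random_effects_meta(deltas = c(0.8, 0.9),
                             variances = c(0.01, 0.01), ns = c(10, 40))
  # hand arithmetic: s2 = 0.01; v = {0.001, 0.00025};
  # T2 = 0.005 - 0.000625 = 0.004375; W = {186.0465, 216.2162}
  expect_equal(res$s2_pooled, 0.01)
  expect_equal(res$T2, 0.004375)
  expect_equal(res$weights, c(1 / 0.005375, 1 / 0.004625))
  expect_equal(res$mean, 0.85375, tolerance = 1e-5)
  expect_equal(res$variance, 0.0024859, tolerance = 1e-4)
  expect_identical(res$variance, 1 / sum(res$weights))
})

test_that("identical studies truncate T2 at zero", {
  res <- random_effects_meta(c(0.5, 0.5), c(0.02, 0.02), c(5, 5))
  expect_equal(res$T2, 0)
  expect_equal(res$mean, 0.5)
  expect_equal(res$variance, 0.002)
})

test_that("equal error variances reduce the meta mean to the simple mean", {
  res <- random_effects_meta(c(0.2, 0.4, 0.6), rep(0.03, 3), rep(10, 3))
  expect_equal(res$mean, 0.4)
  expect_equal(res$T2, 0.04 - 0.003)
  expect_true(all(abs(res$weights - res$weights[1]) < 1e-12))
})

test_that("meta preconditions are enforced", {
  expect_error(random_effects_meta(0.5, 0.01, 10), "at least two")
  expect_error(random_effects_meta(c(0.5, 0.6), c(0.01, 0.01), c(10, NA)),
               "sample size")
  expect_error(random_effects_meta(c(0.5, 0.6), c(NA, NA), c(10, 10)),
               "variance")
})

test_that("estimator agrees with an independent Hedges-type implementation", {
  set.seed(31)
  for (rep in 1:5) {
    k <- sample(5:15, 1)
    ns <- sample(20:200, k, replace = TRUE)
    deltas <- rnorm(k, 0.7, 0.08)
    variances <- runif(k, 0.01, 0.08)
    res <- random_effects_meta(deltas, variances, ns)
    vi <- mean(variances) / ns
    fit <- metafor::rma(yi = deltas, vi = vi, method = "HE")
    expect_equal(res$T2, fit$tau2, tolerance = 1e-8)
    expect_equal(res$mean, as.numeric(fit$beta), tolerance = 1e-8)
    expect_equal(res$variance, fit$se^2, tolerance = 1e-8)
  }
})

test_that("meta-variance never exceeds any single study's error variance plus T2", {
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(3:20, 1)
    res <- random_effects_meta(runif(k, 0.3, 0.9),
                               runif(k, 0.001, 0.05),
                               sample(10:300, k, replace = TRUE))
    expect_lte(res$variance, min(1 / res$weights) + 1e-12)
    expect_true(res$mean >= 0.3 && res$mean <= 0.9)
  }
})

test_that("the synthesis is scale-equivariant", {
  deltas <- c(0.3, 0.5, 0.7)
  variances <- c(0.01, 0.02, 0.015)
  ns <- c(20, 40, 80)
  base <- random_effects_meta(deltas, variances, ns)
  c_ <- 3.7
  scaled <- random_effects_meta(c_ * deltas, c_^2 * variances, ns)
  expect_equal(scaled$mean, c_ * base$mean)
  expect_equal(scaled$variance, c_^2 * base$variance)
})

test_that("T2 estimator and meta mean are calibrated under the generating model", {
  # delta_i ~ N(theta, T2_true + sigma2 / n_i), k = 30, n_i = 20
  theta <- 0.7; T2_true <- 0.01; sigma2 <- 0.05; k <- 30; n <- 20
  set.seed(2024)
  T2_hat <- numeric(1000)
  means <- numeric(1000)
  for (r in 1:1000) {
    deltas <- rnorm(k, theta, sqrt(T2_true + sigma2 / n))
    # studies report population-level variances s_i^2 around sigma^2, so the
    # pooled error variances v_i = mean(s_i^2) / n target sigma^2 / n
    s2_i <- sigma2 * rchisq(k, n - 1) / (n - 1)
    res <- random_effects_meta(deltas, s2_i, rep(n, k))
    T2_hat[r] <- res$T2
    means[r] <- res$mean
  }
  expect_lt(abs(mean(T2_hat) - T2_true), 0.1 * T2_true)
  expect_lt(abs(mean(means) - theta), 0.005)
})

test_that("sub-meta-analysis collapses replicates and passes singletons through", {
  reps <- make_db(data.frame(study_id = "s1", vital_rate = "CS",
                             value = c(4.0, 4.2, 4.4),
                             replicate_year = c("2001", "2002", "2003")))
  out <- sub_meta_analysis(reps)
  expect_equal(nrow(out), 1)
  expect_equal(out$value, 4.2)  # simple-mean path without sample sizes
  expect_equal(out$provenance, "sub_meta")

  withn <- make_db(data.frame(study_id = "s1", vital_rate = "sa",
                              value = c(0.6, 0.6), n = c(30, 30),
                              variance = c(0.01, 0.01)))
  out2 <- sub_meta_analysis(withn)
  expect_equal(out2$value, 0.6)
  expect_equal(out2$n, 60)

  single <- make_db(data.frame(study_id = "s1", vital_rate = "sa",
                               value = 0.9))
  expect_equal(sub_meta_analysis(single)$value, 0.9)
  expect_equal(sub_meta_analysis(single)$provenance, "original")
})

test_that("sensitivity comparison detects overlap and separation", {
  same <- make_db(data.frame(study_id = sprintf("s%d", 1:6),
                             vital_rate = "sa", value = rep(0.8, 6),
                             n = 50, variance = 0.01,
                             verified = c(FALSE, rep(TRUE, 5))))
  res <- sensitivity_compare(same, "unverified")
  expect_equal(res$with$mean, res$without$mean)
  expect_true(res$overlapping)

  outlier <- make_db(data.frame(study_id = sprintf("s%d", 1:8),
                                vital_rate = "CS",
                                value = c(rep(4, 7), 40),
                                n = 400, variance = 0.04,
                                midpoint = c(rep(FALSE, 7), TRUE)))
  res2 <- sensitivity_compare(outlier, "midpoint")
  expect_false(res2$overlapping)
  expect_equal(res2$n_flagged, 1)

  unflagged <- make_db(data.frame(study_id = c("a", "b"), vital_rate = "sa",
                                  value = c(0.8, 0.85), n = 50,
                                  variance = 0.01))
  expect_warning(res3 <- sensitivity_compare(unflagged, "unverified"),
                 "nothing to exclude")
  expect_identical(res3$with$mean, res3$without$mean)
})
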