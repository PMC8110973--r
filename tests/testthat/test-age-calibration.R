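test_that("an exact linear relation is fitted identically at every tau", {
  x <- 1:8
  y <- 2 + 3 * x
  fit <- fit_quantile_regression(x, y)
  for (k in seq_along(fit$taus)) {
    expect_equal(unname(fit$coefficients[k, ]), c(2, 3))
  }
  expect_equal(ppe(fit), 0)
})

test_that("the fit minimises the check loss at least as well as optim", {
  set.seed(7)
  for (tau in c(0.25, 0.5, 0.9)) {
    x <- runif(40); y <- 5 - 2 * x + rnorm(40, 0, 0.3)
    fit <- fit_quantile_regression(x, y, taus = tau)
    mine <- pampachron:::check_loss(
      y - fit$coefficients[1, 1] - fit$coefficients[1, 2] * x, tau)
    ref <- Inf
    for (start in list(c(5, -2), c(0, 0), c(4, -1)))
      ref <- min(ref, stats::optim(start, function(b)
        pampachron:::check_loss(y - b[1] - b[2] * x, tau))$value)
    expect_lte(mine, ref + 1e-6)
  }
})

test_that("the median-line slope is recovered under symmetric noise", {
  set.seed(7)
  x <- runif(200, 0, 1)
  y <- 9 - 6 * x + rnorm(200, 0, 0.4)
  fit <- fit_quantile_regression(x, y, taus = 0.5)
  # asymptotic se of the median-regression slope ~ sqrt(pi/2)*sigma/(sd(x)*sqrt(n))
  se <- sqrt(pi / 2) * 0.4 / (stats::sd(x) * sqrt(200))
  expect_lt(abs(fit$coefficients[1, 2] - (-6)), 3 * se)
})

test_that("outer quantile lines bracket the median line on the data range", {
  set.seed(15)
  x <- runif(60, 0, 2)
  y <- 8 - 3 * x + rnorm(60, 0, 0.5)
  fit <- fit_quantile_regression(x, y)
  for (xv in range(x)) {
    lo <- predict(fit, xv, tau = 0.05)
    md <- predict(fit, xv, tau = 0.5)
    hi <- predict(fit, xv, tau = 0.95)
    expect_lte(lo, md + 1e-9)
    expect_lte(md, hi + 1e-9)
  }
})

test_that("degenerate calibrations are refused", {
  expect_error(fit_quantile_regression(1:2, 1:2), ">= 3")
  expect_error(fit_quantile_regression(rep(1, 5), 1:5), "constant")
  expect_error(fit_quantile_regression(1:5, 1:5, taus = 1.2), "taus")
})

test_that("PPE follows the predicted-denominator convention", {
  fit <- fit_quantile_regression(1:5, 1:5) # the identity line
  expect_equal(ppe(fit, x = 9, y = 10), 100 * 1 / 9)
  # symmetric +/-10% relative errors average to 10%
  expect_equal(ppe(fit, x = c(10, 10), y = c(11, 9)), 10)
  expect_equal(ppe(fit, x = c(10, 10), y = c(11, 9),
                   denominator = "observed"),
               100 * mean(c(1 / 11, 1 / 9)))
  expect_error(ppe(fit, x = -3, y = 1), "non-positive")
})

test_that("PPE is invariant under joint rescaling of ages", {
  set.seed(3)
  x <- runif(12); y <- 4 + 2 * x + rnorm(12, 0, 0.2)
  f1 <- fit_quantile_regression(x, y, taus = 0.5)
  f2 <- fit_quantile_regression(x, y * 10, taus = 0.5)
  expect_equal(ppe(f1), ppe(f2), tolerance = 1e-8)
})

test_that("age estimation medians across the passing equations", {
  mk <- function(b0, b1) {
    x <- seq(0, 1, length.out = 5)
    fit_quantile_regression(x, b0 + b1 * x, predictor = paste0("p", b0))
  }
  models <- list(mk(5, 0), mk(6, 0), mk(7, 0)) # flat lines predicting 5,6,7
  targets <- stats::setNames(0.5, "MHlike")
  est <- estimate_ages(models, targets)
  expect_equal(est$age, 6)
  expect_equal(est$n_equations, 3L)
  single <- estimate_ages(models[1], targets)
  expect_equal(single$age, 5)
  expect_equal(single$age_max, 5)
})

test_that("estimation fails loudly when no equation beats the threshold", {
  set.seed(9)
  x <- runif(8); y <- 5 + 5 * rnorm(8)^2
  bad <- fit_quantile_regression(x, abs(y), predictor = "noisy")
  expect_error(estimate_ages(list(bad), stats::setNames(0.4, "f")),
               "no calibration equation.*best")
})

test_that("larger scores never get younger maxima under positive slopes", {
  set.seed(4)
  x <- seq(0, 1, length.out = 10)
  y <- 2 + 6 * x + rnorm(10, 0, 0.1)
  fit <- fit_quantile_regression(x, y)
  targets <- stats::setNames(c(0.2, 0.5, 0.9), c("a", "b", "c"))
  est <- estimate_ages(list(fit), targets)
  est <- est[order(targets[est$fauna]), ]
  expect_true(all(diff(est$age_max) >= -1e-9))
})

test_that("estimated ages approach truth as sampling noise vanishes", {
  maes <- vapply(c(0.9, 0.99999), function(r) {
    sim <- simulate_succession(succession_spec(seed = 5, r = r,
                                               n_taxa = 120))
    m <- drop_singletons(sim$matrix)
    ords <- list(ca = ordinate_ca(m, ages = sim$true_ages))
    fit <- ml_aeo(m, nboot = 0, seed = 1, ages = sim$true_ages)
    known <- sim$true_ages
    undated <- names(known)[seq(2, 10, 3)]
    ages <- known; ages[undated] <- NA
    cand <- candidate_equations(ords, fit, ages)
    est <- estimate_ages(cand$models, cand$targets, threshold = 100)
    mean(abs(est$age - known[est$fauna]))
  }, 0)
  expect_lt(maes[2], 0.5)
  expect_lte(maes[2], maes[1] + 0.1)
})

test_that("geography correlations report rho, percent explained and p", {
  meta <- fauna_metadata(data.frame(
    fauna = paste0("F", 1:6), latitude = c(-38, -37, -36, -35, -34, -33),
    longitude = c(-60, -61, -62, -63, -64, -65)))
  scores <- matrix(rank(meta$longitude), 6, 1,
                   dimnames = list(meta$fauna, "axis1"))
  gc <- geography_correlation(scores, meta)
  lon <- gc[gc$coordinate == "longitude", ]
  expect_equal(lon$rho, 1)
  expect_equal(lon$pct_explained, 100)
  rev_scores <- -scores
  gc2 <- geography_correlation(rev_scores, meta)
  expect_equal(gc2[gc2$coordinate == "longitude", "rho"], -1)
})

test_that("constant coordinates are flagged rather than correlated", {
  meta <- fauna_metadata(data.frame(
    fauna = paste0("F", 1:5), latitude = rep(-38, 5),
    longitude = c(-60, -61, -62, -63, -64)))
  scores <- matrix(1:5, 5, 1, dimnames = list(meta$fauna, "axis1"))
  gc <- geography_correlation(scores, meta)
  lat <- gc[gc$coordinate == "latitude", ]
  expect_true(is.na(lat$rho))
  expect_equal(lat$note, "constant")
})

test_that("independent scores give null-like geography correlations", {
  set.seed(3)
  meta <- fauna_metadata(data.frame(
    fauna = paste0("F", 1:19), latitude = runif(19, -40, -25),
    longitude = runif(19, -70, -55)))
  ps <- replicate(40, {
    sc <- matrix(rnorm(19), 19, 1, dimnames = list(meta$fauna, "axis1"))
    geography_correlation(sc, meta)$p_value[1]
  })
  expect_gt(mean(ps < 0.05), -1e-9) # sanity: computable
  expect_lt(mean(ps < 0.05), 0.25)  # near the nominal 5% false-positive rate
})
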