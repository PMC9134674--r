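test_that("concordance statistic handles separation, ties and random fixtures", {
  expect_equal(c_statistic(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0),
                           n_boot = 20)$estimate, 1)
  expect_equal(c_statistic(rep(0.4, 6), c(1, 0, 1, 0, 0, 1),
                           n_boot = 20)$estimate, 0.5)
  expect_error(c_statistic(runif(5), rep(1, 5)), "degenerate outcome")

  set.seed(11)
  for (rep in 1:5) {
    n <- sample(20:50, 1)
    pred <- round(runif(n), 2)              # ties likely
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(c_statistic(pred, y, n_boot = 10)$estimate,
                 cstat_bruteforce(pred, y))
  }
})

test_that("concordance is rank-based: monotone-transform invariant, reversal flips it", {
  set.seed(5)
  pred <- runif(60); y <- rbinom(60, 1, pred)
  c1 <- c_statistic(pred, y, n_boot = 10)$estimate
  expect_equal(c_statistic(qlogis(pred), y, n_boot = 10)$estimate, c1)
  expect_equal(c_statistic(pred^3, y, n_boot = 10)$estimate, c1)
  expect_equal(c_statistic(1 - pred, y, n_boot = 10)$estimate, 1 - c1)
})

test_that("bootstrap CI is seeded-reproducible, covers the estimate, and DeLong agrees", {
  set.seed(9)
  pred <- runif(150); y <- rbinom(150, 1, pred)
  a <- c_statistic(pred, y, n_boot = 400, seed = 42)
  b <- c_statistic(pred, y, n_boot = 400, seed = 42)
  expect_identical(a, b)
  expect_true(a$ci[1] <= a$estimate && a$estimate <= a$ci[2])
  d <- c_statistic(pred, y, ci_method = "delong")
  expect_equal(d$estimate, a$estimate)
  expect_true(d$ci[1] <= d$estimate && d$estimate <= d$ci[2])
  # Asymptotically equivalent intervals: endpoints close at this n.
  expect_equal(d$ci, a$ci, tolerance = 0.05)
  if (requireNamespace("pROC", quietly = TRUE)) {
    auc <- as.numeric(pROC::auc(pROC::roc(y, pred, quiet = TRUE,
                                          direction = "<")))
    expect_equal(a$estimate, auc)
  }
})

test_that("Brier score matches closed forms and a hand-summed fixture", {
  expect_equal(brier_score(c(0, 1, 1, 0), c(0, 1, 1, 0)), 0)
  expect_equal(brier_score(rep(0.5, 7), c(1, 0, 1, 0, 1, 0, 1)), 0.25)
  expect_equal(brier_score(c(0.2, 0.7, 0.9), c(0, 1, 1)),
               (0.2^2 + 0.3^2 + 0.1^2) / 3)
  expect_error(brier_score(numeric(0), numeric(0)), "empty")
})

test_that("Nagelkerke R2 hits degenerate values and a hand-evaluated fixture", {
  set.seed(2)
  y <- rbinom(40, 1, 0.3)
  expect_equal(nagelkerke_r2(rep(mean(y), 40), y), 0)
  # Near-perfect predictions approach 1.
  expect_gt(nagelkerke_r2(ifelse(y == 1, 0.999, 0.001), y), 0.97)

  # 20-patient fixture against direct evaluation of both log-likelihoods.
  set.seed(31)
  p <- runif(20, 0.05, 0.95); yy <- rbinom(20, 1, p)
  l1 <- sum(yy * log(p) + (1 - yy) * log(1 - p))
  pb <- mean(yy)
  l0 <- sum(yy * log(pb) + (1 - yy) * log(1 - pb))
  expected <- (1 - exp(2 * (l0 - l1) / 20)) / (1 - exp(2 * l0 / 20))
  expect_equal(nagelkerke_r2(p, yy), expected)
})

test_that("calibration refit recovers truth, known distortions, and a grid oracle", {
  set.seed(77)
  p <- runif(5000, 0.02, 0.95)
  y <- rbinom(5000, 1, p)
  cal <- calibration_slope_intercept(p, y)
  expect_equal(unname(cal["slope"]), 1, tolerance = 0.15)
  expect_equal(unname(cal["intercept"]), 0, tolerance = 0.15)

  # Halving the odds of every prediction must be recovered as an
  # intercept of log(2) with slope still 1.
  p_half <- plogis(qlogis(p) - log(2))
  cal2 <- calibration_slope_intercept(p_half, y)
  expect_equal(unname(cal2["intercept"]), log(2), tolerance = 0.15)
  expect_equal(unname(cal2["slope"]), 1, tolerance = 0.15)

  # Doubling the logit must halve the recovered slope.
  p_double <- plogis(2 * qlogis(p))
  cal3 <- calibration_slope_intercept(p_double, y)
  expect_equal(unname(cal3["slope"]), 0.5, tolerance = 0.1)

  # Tiny fixture against a brute-force Bernoulli-likelihood grid maximiser.
  p8 <- c(0.1, 0.3, 0.4, 0.45, 0.55, 0.6, 0.7, 0.9)
  y8 <- c(0, 0, 1, 0, 1, 0, 1, 1)
  lp <- qlogis(p8)
  ll <- function(a, b) sum(y8 * (a + b * lp) - log(1 + exp(a + b * lp)))
  ab <- expand.grid(a = seq(-2, 2, 0.005), b = seq(-1, 4, 0.005))
  vals <- mapply(ll, ab$a, ab$b)
  best <- ab[which.max(vals), ]
  cal8 <- calibration_slope_intercept(p8, y8)
  expect_equal(unname(cal8["slope"]), best$b, tolerance = 0.01)
  a_grid <- seq(-2, 2, 0.0005)
  ll_off <- vapply(a_grid, function(a)
    sum(y8 * (a + lp) - log(1 + exp(a + lp))), numeric(1))
  expect_equal(unname(cal8["intercept"]), a_grid[which.max(ll_off)],
               tolerance = 0.001)
})

test_that("group calibration table matches independent per-band summaries", {
  co <- exact_table_cohort()
  pts <- fivea_points(co)
  g <- risk_group(pts$total)
  pred <- predict(reference_model(), pts$total)
  gt <- group_calibration(pred, co$outcome, g)
  expect_equal(gt$n, c(483L, 334L, 193L, 129L))
  expect_equal(gt$deaths, c(60L, 59L, 63L, 89L))
  expect_equal(gt$observed_rate, gt$deaths / gt$n)
  expect_equal(gt$mean_predicted,
               as.numeric(tapply(pred, g, mean)[as.character(gt$group)]))

  # Single-patient band and an empty band survive.
  g2 <- factor(c("a", "b", "b"), levels = c("a", "b", "c"))
  gt2 <- group_calibration(c(0.9, 0.2, 0.3), c(1, 0, 0), g2)
  expect_equal(gt2$observed_rate[1], 1)
  expect_equal(gt2$n, c(1L, 2L, 0L))
  expect_true(is.na(gt2$observed_rate[3]))
})

test_that("calibration smoother matches loess and degenerate shapes", {
  set.seed(42)
  x <- round(runif(80, 0.05, 0.9), 2)
  y <- rbinom(80, 1, x)
  cv <- smoothed_calibration_curve(x, y, 0.75)
  lo <- loess(y ~ x, span = 0.75, degree = 1, family = "gaussian",
              control = loess.control(surface = "direct"))
  expect_equal(cv$smoothed_observed,
               unname(predict(lo, newdata = data.frame(x = cv$predicted))),
               tolerance = 1e-6)

  # Constant outcome gives a flat curve at zero.
  cv0 <- smoothed_calibration_curve(seq(0.1, 0.9, length.out = 20),
                                    rep(0, 20))
  expect_true(all(abs(cv0$smoothed_observed) < 1e-12))

  # Perfectly calibrated grouped data sits on the identity diagonal.
  xg <- rep(seq(0.1, 0.9, by = 0.1), each = 200)
  set.seed(8)
  yg <- rbinom(length(xg), 1, xg)
  cvg <- smoothed_calibration_curve(xg, yg, 0.3)
  expect_lt(max(abs(cvg$smoothed_observed - cvg$predicted)), 0.06)

  expect_error(smoothed_calibration_curve(rep(c(0.2, 0.8), 10), rbinom(20, 1, 0.5)),
               "distinct")
})
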