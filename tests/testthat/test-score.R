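test_that("component points follow the published rules on worked examples", {
  # Registry-typical patient: two age points and one acidemia point.
  p <- patient(age = 79, sbp = 117, ph = 7.29, albumin = 3.54)
  s <- fivea_points(p)
  expect_equal(unlist(s[1, ]),
               c(age_pts = 2, adl_pts = 0, arrest_pts = 0, acidemia_pts = 1,
                 albumin_pts = 0, total = 3))

  # Every rule's zero branch.
  s0 <- fivea_points(patient(age = 18, sbp = 120, ph = 7.40, albumin = 4.0))
  expect_true(all(s0 == 0))

  # Every rule's maximal branch sums to the 9-point ceiling.
  s9 <- fivea_points(patient(age = 85, adl_disturbance = TRUE,
                             cardiac_arrest = TRUE, sbp = 0, ph = 7.10,
                             albumin = 2.5))
  expect_equal(unlist(s9[1, ]),
               c(age_pts = 3, adl_pts = 1, arrest_pts = 2, acidemia_pts = 2,
                 albumin_pts = 1, total = 9))
})

test_that("boundary values assign the inclusive-branch points", {
  bnd <- function(...) fivea_points(patient(...))
  expect_equal(bnd(age = 59)$age_pts, 0L)
  expect_equal(bnd(age = 60)$age_pts, 1L)
  expect_equal(bnd(age = 69)$age_pts, 1L)
  expect_equal(bnd(age = 70)$age_pts, 2L)
  expect_equal(bnd(age = 79)$age_pts, 2L)
  expect_equal(bnd(age = 80)$age_pts, 3L)
  expect_equal(bnd(sbp = 60)$arrest_pts, 2L)
  expect_equal(bnd(sbp = 61)$arrest_pts, 0L)
  expect_equal(bnd(ph = 7.20)$acidemia_pts, 1L)
  expect_equal(bnd(ph = 7.19)$acidemia_pts, 2L)
  expect_equal(bnd(ph = 7.35)$acidemia_pts, 1L)
  expect_equal(bnd(ph = 7.36)$acidemia_pts, 0L)
  expect_equal(bnd(albumin = 3.0)$albumin_pts, 1L)
  expect_equal(bnd(albumin = 3.01)$albumin_pts, 0L)
  # Cardiac arrest dominates regardless of pressure.
  expect_equal(bnd(cardiac_arrest = TRUE, sbp = 150)$arrest_pts, 2L)
})

test_that("brute-force enumeration attains exactly the scores 0..9", {
  totals <- fivea_points(component_grid())$total
  expect_setequal(unique(totals), 0:9)
  expect_equal(max(totals), 9L)
})

test_that("risk bands are 0-3 / 4 / 5 / 6-9 and monotone in the score", {
  g <- risk_group(0:9)
  expect_equal(as.character(g),
               c(rep("low", 4), "mild", "moderate", rep("high", 4)))
  expect_true(all(diff(as.integer(g)) >= 0))
  expect_error(risk_group(10), "0..9")
  expect_error(risk_group(-1), "0..9")
})

test_that("auxiliary fields never influence the score", {
  base <- patient(age = 72, ph = 7.25, albumin = 2.9)
  alt <- base
  alt$sex <- "female"; alt$body_temp <- 22.5; alt$calcium <- 7.2
  expect_identical(fivea_points(base), fivea_points(alt))
})

test_that("missing or implausible predictors are rejected with the field named", {
  expect_error(fivea_points(patient(ph = NA)), "unresolved predictor 'ph'")
  expect_error(fivea_points(patient(albumin = NA)),
               "unresolved predictor 'albumin'")
  expect_error(fivea_points(patient(age = 12)), "implausible age")
  expect_error(fivea_points(patient(ph = 8.4)), "implausible ph")
  # Missing SBP is tolerated only under cardiac arrest (arrest dominates).
  expect_equal(fivea_points(patient(cardiac_arrest = TRUE, sbp = NA))$arrest_pts, 2L)
  expect_error(fivea_points(patient(sbp = NA)), "unresolved predictor 'sbp'")
})

test_that("logistic probability map matches closed-form evaluation and monotonicity", {
  expect_equal(predict(probability_model(0, 0), 3), 0.5)
  expect_equal(predict(probability_model(-2, 0.5), 4), 0.5)
  m <- probability_model(-3, 0.6)
  p <- predict(m, 0:9)
  x <- -3 + 0.6 * (0:9)
  expect_equal(p, exp(x) / (1 + exp(x)))
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
  # Lookup table overrides the linear form.
  tab <- seq(0.05, 0.95, length.out = 10)
  expect_equal(predict(probability_model(per_score = tab), c(0, 9)),
               c(0.05, 0.95))
  expect_error(predict(m, 10), "0..9")
})
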