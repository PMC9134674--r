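# 5A scoring rules: component points, total score, risk bands.

# Plausibility bounds used by input validation throughout the package.
.plausible <- list(
  age     = c(18, Inf),
  sbp     = c(0, Inf),
  ph      = c(6.5, 7.9),
  albumin = c(1.0, 6.0),
  calcium = c(4, 14)
)

.check_range <- function(x, field) {
  b <- .plausible[[field]]
  bad <- which(!is.na(x) & (x < b[1] | x > b[2]))
  if (length(bad))
    stop(sprintf("implausible %s value(s) (outside [%g, %g]) at row(s) %s",
                 field, b[1], b[2], paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  invisible(x)
}

.require_resolved <- function(x, field) {
  bad <- which(is.na(x))
  if (length(bad))
    stop(sprintf("unresolved predictor '%s': missing at row(s) %s; resolve missing data before scoring",
                 field, paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  invisible(x)
}

#' Compute 5A component points and total score
#'
#' Applies the published point rules to each patient: age (60-69 -> 1,
#' 70-79 -> 2, >= 80 -> 3), disturbance of activities of daily living (1),
#' cardiac arrest or systolic blood pressure <= 60 mmHg (2), acidemia
#' (pH in \[7.20, 7.35\] -> 1, pH < 7.20 -> 2), and low serum albumin
#' (<= 3.0 g/dL -> 1). The total ranges 0-9.
#'
#' Missing score predictors are a hard error: resolution of missingness
#' (albumin estimation, imputation, worst-case scenarios) is the job of
#' [estimate_albumin()] and [iterative_impute()], upstream of scoring.
#' The only exception is the albumin worst-case sensitivity scenarios,
#' which assign the albumin point directly for patients whose albumin is
#' unmeasured.
#'
#' @param data data.frame with columns `age`, `adl_disturbance` (logical),
#'   `cardiac_arrest` (logical), `sbp` (mmHg; may be `NA` only when
#'   `cardiac_arrest` is `TRUE`), `ph`, and `albumin` (g/dL). Auxiliary
#'   columns (sex, body_temp, calcium, outcome) are ignored.
#' @param albumin_scenario `"measured"` (default) scores the albumin column
#'   and errors on missing values; `"worst_case_high"` / `"worst_case_low"`
#'   assign 1 / 0 albumin points to patients with missing albumin (measured
#'   values are still scored), bounding the score distribution for
#'   sensitivity analysis.
#' @return data.frame with integer columns `age_pts`, `adl_pts`,
#'   `arrest_pts`, `acidemia_pts`, `albumin_pts`, `total`.
#' @examples
#' pt <- data.frame(age = 79, adl_disturbance = FALSE, cardiac_arrest = FALSE,
#'                  sbp = 117, ph = 7.29, albumin = 3.54)
#' fivea_points(pt)  # total 3: two age points, one acidemia point
#' @export
fivea_points <- function(data,
                         albumin_scenario = c("measured", "worst_case_high",
                                              "worst_case_low")) {
  albumin_scenario <- match.arg(albumin_scenario)
  need <- c("age", "adl_disturbance", "cardiac_arrest", "sbp", "ph", "albumin")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "), call. = FALSE)

  age <- data$age; adl <- data$adl_disturbance
  arrest <- data$cardiac_arrest; sbp <- data$sbp
  ph <- data$ph; alb <- data$albumin

  .require_resolved(age, "age")
  .require_resolved(adl, "adl_disturbance")
  .require_resolved(arrest, "cardiac_arrest")
  # SBP only needs resolving for non-arrest patients (arrest dominates).
  if (any(is.na(sbp) & !arrest))
    stop("unresolved predictor 'sbp': missing at row(s) ",
         paste(utils::head(which(is.na(sbp) & !arrest), 5), collapse = ", "),
         "; resolve missing data before scoring", call. = FALSE)
  .require_resolved(ph, "ph")
  if (albumin_scenario == "measured") .require_resolved(alb, "albumin")

  .check_range(age, "age"); .check_range(sbp, "sbp")
  .check_range(ph, "ph"); .check_range(alb, "albumin")

  age_pts <- ifelse(age >= 80, 3L, ifelse(age >= 70, 2L, ifelse(age >= 60, 1L, 0L)))
  adl_pts <- ifelse(adl, 1L, 0L)
  arrest_pts <- ifelse(arrest | (!is.na(sbp) & sbp <= 60), 2L, 0L)
  acidemia_pts <- ifelse(ph < 7.20, 2L, ifelse(ph <= 7.35, 1L, 0L))
  albumin_pts <- ifelse(!is.na(alb) & alb <= 3.0, 1L,
                        ifelse(!is.na(alb), 0L, NA_integer_))
  if (albumin_scenario == "worst_case_high")
    albumin_pts[is.na(albumin_pts)] <- 1L
  if (albumin_scenario == "worst_case_low")
    albumin_pts[is.na(albumin_pts)] <- 0L

  out <- data.frame(age_pts = age_pts, adl_pts = adl_pts,
                    arrest_pts = arrest_pts, acidemia_pts = acidemia_pts,
                    albumin_pts = albumin_pts)
  out$total <- as.integer(rowSums(out))
  out
}

#' Map total 5A scores to risk groups
#'
#' Band boundaries are 0-3 (low), 4 (mild), 5 (moderate), 6-9 (high),
#' all inclusive.
#'
#' @param total integer vector of total scores in 0..9.
#' @return ordered factor with levels `low < mild < moderate < high`.
#' @examples
#' risk_group(c(0, 3, 4, 5, 6, 9))
#' @export
risk_group <- function(total) {
  if (any(is.na(total)) || any(total < 0 | total > 9) ||
      any(total != as.integer(total)))
    stop("total score must be an integer in 0..9", call. = FALSE)
  cut(total, breaks = c(-0.5, 3.5, 4.5, 5.5, 9.5),
      labels = c("low", "mild", "moderate", "high"), ordered_result = TRUE)
}

#' Logistic score-to-probability model
#'
#' The mapping from total score to predicted in-hospital mortality is a
#' logistic model in the score, `plogis(intercept + slope_per_point * total)`,
#' or an explicit per-score lookup table. Coefficients are configuration:
#' the published coefficient set lives in the source study's supplement,
#' so [reference_model()] provides a documented stand-in and any user-supplied
#' coefficients can be used instead.
#'
#' @param intercept log-odds at score 0.
#' @param slope_per_point log-odds increment per score point.
#' @param per_score optional numeric vector of 10 probabilities (scores 0..9)
#'   overriding the linear form; all strictly in (0, 1).
#' @return object of class `fivea_prob_model`.
#' @examples
#' m <- probability_model(intercept = -3, slope_per_point = 0.6)
#' predict(m, total = 0:9)
#' @export
probability_model <- function(intercept = NULL, slope_per_point = NULL,
                              per_score = NULL) {
  if (!is.null(per_score)) {
    stopifnot(length(per_score) == 10, all(per_score > 0 & per_score < 1))
    m <- list(per_score = as.numeric(per_score))
  } else {
    stopifnot(is.numeric(intercept), is.numeric(slope_per_point),
              length(intercept) == 1, length(slope_per_point) == 1,
              is.finite(intercept), is.finite(slope_per_point))
    m <- list(intercept = as.numeric(intercept),
              slope_per_point = as.numeric(slope_per_point))
  }
  class(m) <- "fivea_prob_model"
  m
}

#' @rdname probability_model
#' @param object,x a `fivea_prob_model`.
#' @param total integer scores in 0..9 for which probabilities are wanted.
#' @param ... unused.
#' @export
predict.fivea_prob_model <- function(object, total, ...) {
  if (any(is.na(total)) || any(total < 0 | total > 9))
    stop("total score must be in 0..9", call. = FALSE)
  if (!is.null(object$per_score)) return(object$per_score[total + 1L])
  stats::plogis(object$intercept + object$slope_per_point * total)
}

#' @rdname probability_model
#' @export
print.fivea_prob_model <- function(x, ...) {
  if (!is.null(x$per_score)) {
    cat("5A score probability model (per-score lookup)\n")
    print(round(stats::setNames(x$per_score, 0:9), 4))
  } else {
    cat(sprintf("5A score probability model: logit(p) = %.4f + %.4f * score\n",
                x$intercept, x$slope_per_point))
  }
  invisible(x)
}

#' Reference probability model fitted to the published contingency table
#'
#' Fits a logistic regression of in-hospital mortality on the total score
#' using the exact-table synthetic cohort ([exact_table_cohort()]), whose
#' risk-group sizes and deaths reproduce the published validation table.
#' This is a documented stand-in for the original derivation-study
#' coefficients (which are not reproduced here) and should be replaced by
#' them via [probability_model()] when available.
#'
#' @return a `fivea_prob_model`.
#' @export
reference_model <- function() {
  co <- exact_table_cohort()
  total <- fivea_points(co)$total
  fit <- stats::glm(co$outcome ~ total, family = stats::binomial())
  probability_model(intercept = unname(stats::coef(fit)[1]),
                    slope_per_point = unname(stats::coef(fit)[2]))
}
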