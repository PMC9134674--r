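# External validation of the score model: one call computes discrimination,
# calibration, accuracy and clinical utility, returned as a classed object.

#' Externally validate the 5A score model on a cohort
#'
#' The workhorse of the package. Scores every patient, maps scores to
#' predicted in-hospital mortality through `model`, and computes the full
#' validation battery: concordance statistic with confidence interval,
#' Brier score, Nagelkerke R-squared, calibration slope and intercept,
#' the per-risk-group predicted/observed table, the locally weighted
#' calibration curve, and the decision-curve table against age-only,
#' body-temperature-only, treat-all and treat-none strategies.
#'
#' The cohort must already be complete in the score predictors (run
#' [estimate_albumin()] / [iterative_impute()] first, or use
#' [run_validation()] which orchestrates the whole pipeline) and satisfy
#' the inclusion rule: adults with body temperature at or below 35 degrees C.
#'
#' @param data cohort data.frame with complete score predictors, `body_temp`
#'   and 0/1 `outcome`.
#' @param model a [probability_model()]; defaults to [reference_model()].
#' @param albumin_scenario passed to [fivea_points()] for worst-case
#'   sensitivity runs.
#' @param ci_method,n_boot,seed concordance-interval settings, see
#'   [c_statistic()].
#' @param smoother_fraction span of the calibration smoother.
#' @param thresholds decision-curve threshold grid.
#' @return object of class `fivea_validation`; see [print.fivea_validation()].
#' @examples
#' co <- exact_table_cohort()
#' fit <- validate_5a(co, n_boot = 200, seed = 7)
#' fit$group_table
#' @export
validate_5a <- function(data, model = reference_model(),
                        albumin_scenario = "measured",
                        ci_method = "bootstrap", n_boot = 2000, seed = 1,
                        smoother_fraction = 0.75,
                        thresholds = seq(0.01, 0.60, by = 0.01)) {
  if (!nrow(data)) stop("empty cohort", call. = FALSE)
  if (any(is.na(data$body_temp)) || any(data$body_temp > 35))
    stop("cohort violates the inclusion rule (body temperature <= 35)",
         call. = FALSE)
  y <- data$outcome
  if (any(is.na(y)) || !all(y %in% c(0, 1)))
    stop("outcomes must be complete 0/1", call. = FALSE)

  pts <- fivea_points(data, albumin_scenario = albumin_scenario)
  grp <- risk_group(pts$total)
  pred <- predict(model, pts$total)

  cs <- c_statistic(pred, y, ci_method = ci_method, n_boot = n_boot,
                    seed = seed)
  cal <- calibration_slope_intercept(pred, y)
  out <- list(
    n = nrow(data),
    deaths = sum(y),
    prevalence = mean(y),
    scores = pts,
    groups = grp,
    predicted = pred,
    outcome = y,
    model = model,
    c_statistic = cs$estimate,
    c_ci = cs$ci,
    ci_method = cs$ci_method,
    brier = brier_score(pred, y),
    nagelkerke_r2 = nagelkerke_r2(pred, y),
    calibration_intercept = unname(cal["intercept"]),
    calibration_slope = unname(cal["slope"]),
    calibration_converged = attr(cal, "converged"),
    group_table = group_calibration(pred, y, grp),
    curve = smoothed_calibration_curve(pred, y, smoother_fraction),
    dca = decision_curve(data, model, thresholds,
                         albumin_scenario = albumin_scenario),
    seed = seed,
    call = match.call()
  )
  class(out) <- "fivea_validation"
  out
}

#' @rdname validate_5a
#' @param x,object a `fivea_validation`.
#' @param ... unused.
#' @export
print.fivea_validation <- function(x, ...) {
  cat("External validation of the 5A score model\n")
  cat(sprintf("  Patients: %d  In-hospital deaths: %d (%.1f%%)\n",
              x$n, x$deaths, 100 * x$prevalence))
  cat(sprintf("  C-statistic: %.3f [%.3f-%.3f] (%s)\n",
              x$c_statistic, x$c_ci[1], x$c_ci[2], x$ci_method))
  cat(sprintf("  Brier score: %.3f   Nagelkerke R2: %.3f\n",
              x$brier, x$nagelkerke_r2))
  cat(sprintf("  Calibration intercept: %.3f   slope: %.3f\n",
              x$calibration_intercept, x$calibration_slope))
  cat("\nRisk-group calibration:\n")
  gt <- x$group_table
  gt$observed <- sprintf("%.1f%% (%d/%d)", 100 * gt$observed_rate,
                         gt$deaths, gt$n)
  gt$predicted <- sprintf("%.1f%% (%.1f-%.1f)", 100 * gt$mean_predicted,
                          100 * gt$predicted_ci_low, 100 * gt$predicted_ci_high)
  print(gt[, c("group", "observed", "predicted")], row.names = FALSE)
  invisible(x)
}

#' @rdname validate_5a
#' @export
summary.fivea_validation <- function(object, ...) {
  print(object)
  cat("\nScore distribution:\n")
  print(table(score = object$scores$total))
  invisible(object)
}

#' @rdname validate_5a
#' @export
coef.fivea_validation <- function(object, ...) {
  c(calibration_intercept = object$calibration_intercept,
    calibration_slope = object$calibration_slope)
}

#' @rdname validate_5a
#' @param which `"calibration"` draws the smoothed curve with per-group
#'   predicted vs observed bars alongside; `"dca"` draws the decision curves.
#' @export
plot.fivea_validation <- function(x, which = c("calibration", "dca"), ...) {
  which <- match.arg(which)
  if (which == "dca") return(plot(x$dca, ...))
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  plot(x$curve$predicted, x$curve$smoothed_observed, type = "b", pch = 16,
       xlim = c(0, 1), ylim = c(0, 1),
       xlab = "Predicted probability", ylab = "Observed probability", ...)
  graphics::abline(0, 1, lty = 2)
  gt <- x$group_table
  bp <- rbind(predicted = gt$mean_predicted, observed = gt$observed_rate)
  graphics::barplot(bp, beside = TRUE, names.arg = as.character(gt$group),
                    ylim = c(0, 1), legend.text = TRUE,
                    ylab = "In-hospital mortality")
  invisible(x)
}

#' Run the full validation pipeline from a cohort file
#'
#' Orchestrates the analysis end to end: read the cohort CSV, apply the
#' inclusion filter (age >= 18, body temperature recorded and <= 35),
#' resolve missing albumin (linear estimate from total calcium, or a
#' worst-case scenario), impute any remaining missing score predictors with
#' [iterative_impute()], score, validate and run the decision-curve
#' analysis. Artifacts (JSON report, group table, calibration curve and
#' decision-curve CSVs, run log with seeds and participant-flow counts) are
#' written under `output_dir`.
#'
#' @param input path to a cohort CSV in the documented schema.
#' @param model a [probability_model()].
#' @param albumin list: `estimator` (an [albumin_estimator()]) and
#'   `scenario` (`"linear_estimate"`, `"worst_case_high"`,
#'   `"worst_case_low"`).
#' @param n_boot,seed,thresholds,smoother_fraction as in [validate_5a()].
#' @param output_dir directory for artifacts; created if needed. `NULL`
#'   writes nothing.
#' @return list with `fit` (the [validate_5a()] object), `flow`
#'   (participant counts at each filter stage), and `imputation_log`.
#' @export
run_validation <- function(input, model = reference_model(),
                           albumin = list(estimator = albumin_estimator(),
                                          scenario = "linear_estimate"),
                           n_boot = 2000, seed = 1,
                           thresholds = seq(0.01, 0.60, by = 0.01),
                           smoother_fraction = 0.75, output_dir = NULL) {
  rd <- read_cohort(input)
  co <- rd$cohort
  flow <- c(registered = nrow(co))
  keep <- !is.na(co$age) & co$age >= 18 &
    !is.na(co$body_temp) & co$body_temp <= 35 & !is.na(co$outcome)
  co <- co[keep, , drop = FALSE]
  rownames(co) <- NULL
  flow["excluded"] <- flow["registered"] - nrow(co)
  flow["analyzed"] <- nrow(co)
  if (!nrow(co)) stop("empty cohort after inclusion filter", call. = FALSE)

  scenario <- albumin$scenario %||% "linear_estimate"
  alb_scenario_score <- "measured"
  if (scenario == "linear_estimate") {
    fix <- is.na(co$albumin) & !is.na(co$calcium)
    if (any(fix))
      co$albumin[fix] <- estimate_albumin(co$calcium[fix], albumin$estimator)
  } else {
    alb_scenario_score <- switch(scenario,
                                 worst_case_high = "worst_case_high",
                                 worst_case_low = "worst_case_low",
                                 stop("unknown albumin scenario: ", scenario,
                                      call. = FALSE))
  }

  pred_cols <- c("age", "adl_disturbance", "cardiac_arrest", "sbp", "ph",
                 "albumin", "calcium", "body_temp")
  imp_cols <- if (alb_scenario_score == "measured") pred_cols else
    setdiff(pred_cols, c("albumin", "calcium"))
  imp_log <- list(fields = character(0), iterations = 0L)
  sub <- co[, imp_cols, drop = FALSE]
  # SBP of arrest patients is 0 by convention, not missing.
  sub$sbp[is.na(sub$sbp) & co$cardiac_arrest %in% TRUE] <- 0
  if (anyNA(sub)) {
    fields <- names(sub)[colSums(is.na(sub)) > 0]
    imp <- iterative_impute(sub, seed = seed)
    co[, imp_cols] <- imp$data
    imp_log <- list(fields = fields, iterations = imp$iterations,
                    convergence = imp$convergence)
  } else {
    co[, imp_cols] <- sub
  }

  fit <- validate_5a(co, model = model, albumin_scenario = alb_scenario_score,
                     n_boot = n_boot, seed = seed,
                     smoother_fraction = smoother_fraction,
                     thresholds = thresholds)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    report <- list(
      n = fit$n, deaths = fit$deaths, prevalence = fit$prevalence,
      c_statistic = fit$c_statistic, c_ci = fit$c_ci,
      brier = fit$brier, nagelkerke_r2 = fit$nagelkerke_r2,
      calibration_intercept = fit$calibration_intercept,
      calibration_slope = fit$calibration_slope,
      seed = seed, flow = as.list(flow),
      albumin_scenario = scenario,
      imputation = imp_log
    )
    jsonlite::write_json(report, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(fit$group_table, file.path(output_dir, "group_table.csv"),
                     row.names = FALSE)
    utils::write.csv(fit$curve, file.path(output_dir, "calibration_curve.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(fit$dca), file.path(output_dir, "dca.csv"),
                     row.names = FALSE)
    writeLines(c(sprintf("seed: %d", seed),
                 sprintf("registered: %d", flow["registered"]),
                 sprintf("excluded: %d", flow["excluded"]),
                 sprintf("analyzed: %d", flow["analyzed"]),
                 sprintf("albumin_scenario: %s", scenario),
                 sprintf("imputed_fields: %s",
                         paste(imp_log$fields, collapse = ", "))),
               file.path(output_dir, "run_log.txt"))
  }
  list(fit = fit, flow = flow, imputation_log = imp_log)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
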