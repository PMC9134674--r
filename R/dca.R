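# Decision-curve analysis: net benefit across threshold probabilities.

#' Net benefit at a single threshold probability
#'
#' Patients are classified positive when `pred >= p_t` (ties treat).
#' Net benefit is TP/n - (FP/n) * p_t / (1 - p_t): true positives gained per
#' patient minus false positives penalised at the odds of the threshold.
#'
#' @inheritParams c_statistic
#' @param p_t threshold probability, strictly in (0, 1).
#' @return numeric net benefit; at most the cohort prevalence.
#' @examples
#' net_benefit(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
#'             c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0), p_t = 0.2)  # 0.4
#' @export
net_benefit <- function(pred, y, p_t) {
  .check_pred_y(pred, y)
  if (!is.numeric(p_t) || length(p_t) != 1 || p_t <= 0 || p_t >= 1)
    stop("threshold probability must lie strictly in (0, 1)", call. = FALSE)
  pos <- pred >= p_t
  n <- length(y)
  tp <- sum(pos & y == 1)
  fp <- sum(pos & y == 0)
  tp / n - (fp / n) * p_t / (1 - p_t)
}

#' Decision-curve table for the score model and comparator strategies
#'
#' Computes one net-benefit series per strategy over a threshold grid:
#' the 5A score model, univariable logistic refits of the outcome on age and
#' on body temperature (each giving that comparator its best-calibrated
#' probability scale within the evaluation cohort), treat-all, and
#' treat-none. A comparator whose covariate is constant in the cohort is
#' skipped with a warning.
#'
#' @param data cohort data.frame with complete score predictors, `body_temp`
#'   and 0/1 `outcome`.
#' @param model a [probability_model()] mapping the total score to mortality
#'   probability.
#' @param thresholds threshold-probability grid; default 0.01-0.60 by 0.01.
#' @param albumin_scenario passed to [fivea_points()] (worst-case
#'   sensitivity runs).
#' @return data.frame of class `fivea_dca` with columns `threshold`,
#'   `strategy`, `net_benefit`.
#' @export
decision_curve <- function(data, model,
                           thresholds = seq(0.01, 0.60, by = 0.01),
                           albumin_scenario = "measured") {
  stopifnot(all(thresholds > 0), all(thresholds < 1))
  y <- data$outcome
  if (any(is.na(y)) || !all(y %in% c(0, 1)))
    stop("cohort outcomes must be complete 0/1", call. = FALSE)
  total <- fivea_points(data, albumin_scenario = albumin_scenario)$total
  preds <- list(model = predict(model, total),
                treat_all = rep(1, length(y)),
                treat_none = rep(0, length(y)))
  for (cmp in c(age_only = "age", bt_only = "body_temp")) {
    nm <- names(which(c(age_only = "age", bt_only = "body_temp") == cmp))
    x <- data[[cmp]]
    if (is.null(x) || any(is.na(x)) || stats::sd(x) == 0) {
      warning(sprintf("comparator '%s' degenerate or missing; strategy skipped", cmp))
      next
    }
    fit <- stats::glm(y ~ x, family = stats::binomial())
    preds[[nm]] <- unname(stats::fitted(fit))
  }
  out <- do.call(rbind, lapply(names(preds), function(s) {
    data.frame(threshold = thresholds, strategy = s,
               net_benefit = vapply(thresholds, function(pt)
                 net_benefit(preds[[s]], y, pt), numeric(1)))
  }))
  rownames(out) <- NULL
  class(out) <- c("fivea_dca", "data.frame")
  attr(out, "prevalence") <- mean(y)
  out
}

#' @rdname decision_curve
#' @param x a `fivea_dca` table.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.fivea_dca <- function(x, ...) {
  wide <- stats::reshape(as.data.frame(x), idvar = "threshold",
                         timevar = "strategy", direction = "wide")
  m <- as.matrix(wide[-1])
  graphics::matplot(wide$threshold, m, type = "l", lty = 1,
                    col = seq_len(ncol(m)),
                    xlab = "Threshold probability", ylab = "Net benefit",
                    ylim = c(min(-0.02, min(m)), attr(x, "prevalence") * 1.1), ...)
  graphics::legend("topright", legend = sub("^net_benefit\\.", "", colnames(m)),
                   col = seq_len(ncol(m)), lty = 1, bty = "n")
  invisible(x)
}
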