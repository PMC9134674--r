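# Discrimination, calibration and overall-accuracy indices.

.clamp_prob <- function(p, eps = 1e-12) {
  if (any(p <= 0 | p >= 1))
    warning("probabilities at 0 or 1 clamped for log-likelihood finiteness")
  pmin(pmax(p, eps), 1 - eps)
}

.check_pred_y <- function(pred, y) {
  if (length(pred) != length(y)) stop("pred and y lengths differ", call. = FALSE)
  if (length(y) == 0) stop("empty input", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("outcomes must be 0/1", call. = FALSE)
  invisible(NULL)
}

.cstat_point <- function(pred, y) {
  # Midrank (Mann-Whitney) form: ties between a death and a survivor count 1/2.
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(pred)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Concordance statistic with confidence interval
#'
#' Probability that a randomly chosen death received a higher predicted
#' probability than a randomly chosen survivor, ties counting one half:
#' (concordant + 0.5 tied) / (all death-survivor pairs). The confidence
#' interval is a seeded percentile bootstrap over patients (default), or the
#' DeLong asymptotic normal interval.
#'
#' @param pred numeric predictions (any monotone score works; the statistic
#'   is rank-based).
#' @param y binary outcomes (1 = died in hospital).
#' @param ci_method `"bootstrap"` (percentile over patient resamples) or
#'   `"delong"`.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level.
#' @return list with `estimate`, `ci` (length-2), `ci_method`.
#' @examples
#' c_statistic(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), n_boot = 50, seed = 1)
#' @export
c_statistic <- function(pred, y, ci_method = c("bootstrap", "delong"),
                        n_boot = 2000, seed = 1, conf = 0.95) {
  ci_method <- match.arg(ci_method)
  .check_pred_y(pred, y)
  if (length(y) < 2 || length(unique(y)) < 2)
    stop("degenerate outcome: need at least one death and one survivor",
         call. = FALSE)
  est <- .cstat_point(pred, y)
  a <- (1 - conf) / 2
  if (ci_method == "bootstrap") {
    n <- length(y)
    old <- .Random.seed_save()
    set.seed(seed)
    stats <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[i])) < 2) return(NA_real_)
      .cstat_point(pred[i], y[i])
    }, numeric(1))
    .Random.seed_restore(old)
    ci <- unname(stats::quantile(stats, c(a, 1 - a), na.rm = TRUE))
  } else {
    # DeLong structural-component variance.
    cases <- pred[y == 1]; ctrls <- pred[y == 0]
    m <- length(cases); n0 <- length(ctrls)
    psi <- function(x, yv) (x > yv) + 0.5 * (x == yv)
    v10 <- vapply(cases, function(x) mean(psi(x, ctrls)), numeric(1))
    v01 <- vapply(ctrls, function(x) mean(psi(cases, x)), numeric(1))
    se <- sqrt(stats::var(v10) / m + stats::var(v01) / n0)
    z <- stats::qnorm(1 - a)
    ci <- c(max(0, est - z * se), min(1, est + z * se))
  }
  list(estimate = est, ci = ci, ci_method = ci_method)
}

# Save/restore .Random.seed so metric CIs do not perturb caller RNG streams.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and binary outcome.
#'
#' @inheritParams c_statistic
#' @return numeric in \[0, 1\].
#' @examples
#' brier_score(rep(0.5, 4), c(0, 1, 0, 1))  # 0.25
#' @export
brier_score <- function(pred, y) {
  .check_pred_y(pred, y)
  mean((pred - y)^2)
}

#' Nagelkerke R-squared for externally supplied predictions
#'
#' Cox-Snell R2 = 1 - exp(2 (l0 - l1) / n) rescaled by its maximum
#' 1 - exp(2 l0 / n), where l1 is the Bernoulli log-likelihood under the
#' supplied predictions and l0 the log-likelihood under the constant
#' prevalence prediction. Probabilities are clamped away from 0/1 first.
#'
#' @inheritParams c_statistic
#' @return numeric, 0 when predictions equal the prevalence, approaching 1
#'   for near-perfect predictions.
#' @export
nagelkerke_r2 <- function(pred, y) {
  .check_pred_y(pred, y)
  if (length(unique(y)) < 2)
    stop("degenerate outcome: need both classes", call. = FALSE)
  p <- .clamp_prob(pred)
  n <- length(y)
  ll <- function(p) sum(y * log(p) + (1 - y) * log(1 - p))
  l1 <- ll(p)
  l0 <- ll(rep(mean(y), n))
  r2_cs <- 1 - exp(2 * (l0 - l1) / n)
  r2_cs / (1 - exp(2 * l0 / n))
}

#' Calibration slope and intercept
#'
#' Slope: coefficient of logit(pred) in a maximum-likelihood logistic
#' refit of the outcomes on the logit of the predictions. Intercept:
#' calibration-in-the-large, the intercept of a logistic fit with
#' logit(pred) entered as a fixed offset. A perfectly calibrated model has
#' slope 1 and intercept 0.
#'
#' @inheritParams c_statistic
#' @return named numeric `c(intercept, slope)` with attribute `converged`.
#' @export
calibration_slope_intercept <- function(pred, y) {
  .check_pred_y(pred, y)
  if (length(unique(y)) < 2)
    stop("degenerate outcome: need both classes", call. = FALSE)
  lp <- stats::qlogis(.clamp_prob(pred))
  f_slope <- stats::glm(y ~ lp, family = stats::binomial())
  f_int <- stats::glm(y ~ 1 + offset(lp), family = stats::binomial())
  conv <- f_slope$converged && f_int$converged &&
    all(abs(stats::coef(f_slope)) < 20)
  if (!conv)
    warning("calibration refit did not converge (possible separation); ",
            "estimates unreliable")
  out <- c(intercept = unname(stats::coef(f_int)[1]),
           slope = unname(stats::coef(f_slope)["lp"]))
  attr(out, "converged") <- conv
  out
}

#' Risk-group calibration table
#'
#' Per risk band: patients, deaths, observed mortality, mean predicted
#' probability and a normal-approximation 95 percent confidence interval of
#' that mean. Empty bands are kept as n = 0 rows with `NA` rates.
#'
#' @inheritParams c_statistic
#' @param groups factor of risk bands aligned with `pred`/`y` (all factor
#'   levels are reported, including empty ones).
#' @param conf confidence level for the mean-predicted interval.
#' @return data.frame with one row per band.
#' @export
group_calibration <- function(pred, y, groups, conf = 0.95) {
  .check_pred_y(pred, y)
  groups <- as.factor(groups)
  if (length(groups) != length(y)) stop("groups length differs", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  rows <- lapply(levels(groups), function(g) {
    i <- which(groups == g)
    n <- length(i)
    if (n == 0)
      return(data.frame(group = g, n = 0L, deaths = 0L, observed_rate = NA_real_,
                        mean_predicted = NA_real_, predicted_ci_low = NA_real_,
                        predicted_ci_high = NA_real_))
    d <- sum(y[i]); mp <- mean(pred[i])
    se <- if (n > 1) stats::sd(pred[i]) / sqrt(n) else 0
    data.frame(group = g, n = n, deaths = as.integer(d),
               observed_rate = d / n, mean_predicted = mp,
               predicted_ci_low = mp - z * se, predicted_ci_high = mp + z * se)
  })
  out <- do.call(rbind, rows)
  out$group <- factor(out$group, levels = levels(groups), ordered = is.ordered(groups))
  out
}

#' Locally weighted calibration curve
#'
#' Tricube-weighted local linear regression of the observed outcomes on the
#' predicted probabilities, evaluated at each distinct predicted value (one
#' point per attained score when predictions come from a score model).
#'
#' @inheritParams c_statistic
#' @param smoother_fraction nearest-neighbour span in (0, 1\]; default 0.75.
#' @return data.frame with `predicted` (distinct values, ascending) and
#'   `smoothed_observed`.
#' @export
smoothed_calibration_curve <- function(pred, y, smoother_fraction = 0.75) {
  .check_pred_y(pred, y)
  if (length(y) < 10) stop("need at least 10 observations", call. = FALSE)
  x0 <- sort(unique(pred))
  if (length(x0) < 3)
    stop("need at least 3 distinct predicted values", call. = FALSE)
  stopifnot(smoother_fraction > 0, smoother_fraction <= 1)
  n <- length(pred)
  q <- min(n, ceiling(smoother_fraction * n))
  sm <- vapply(x0, function(z) {
    d <- abs(pred - z)
    dq <- sort(d, partial = q)[q]
    if (dq <= 0) dq <- .Machine$double.eps
    w <- (1 - pmin(d / dq, 1)^3)^3
    keep <- w > 0
    xc <- pred[keep] - z
    ww <- w[keep]; yy <- y[keep]
    if (sum(ww * xc^2) < 1e-14 * max(1, sum(ww))) {
      sum(ww * yy) / sum(ww)          # degenerate local design: weighted mean
    } else {
      X <- cbind(1, xc)
      b <- solve(crossprod(X * sqrt(ww)), crossprod(X, ww * yy))
      b[1]
    }
  }, numeric(1))
  data.frame(predicted = x0, smoothed_observed = sm)
}
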