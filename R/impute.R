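# Missing-data resolution: albumin estimation from total calcium,
# worst-case sensitivity scenarios, and chained random-forest imputation.

#' Albumin estimator configuration
#'
#' Serum albumin is linearly correlated with total calcium, so unmeasured
#' albumin can be estimated as `intercept + slope * calcium`, clipped to the
#' plausible range 1.0-6.0 g/dL. The default slope, 1.25 g/dL per mg/dL, is
#' the inverse of the classic 0.8 mg/dL-per-g/dL dependence of total calcium
#' on albumin from the calcium-correction literature; the default intercept
#' anchors a typical total calcium of 9.4 mg/dL to an estimated albumin of
#' 3.54 g/dL. Both are configuration and sensitivity analyses should sweep
#' alternative equations.
#'
#' @param intercept g/dL.
#' @param slope g/dL per mg/dL of total calcium.
#' @return object of class `fivea_albumin_estimator`.
#' @export
albumin_estimator <- function(intercept = -8.21, slope = 1.25) {
  stopifnot(is.numeric(intercept), is.numeric(slope),
            length(intercept) == 1, length(slope) == 1)
  structure(list(intercept = intercept, slope = slope),
            class = "fivea_albumin_estimator")
}

#' Estimate serum albumin from total calcium
#'
#' @param calcium total calcium in mg/dL (no missing values allowed; a
#'   patient without calcium cannot use the linear estimate and must fall
#'   back to a worst-case scenario in [fivea_points()]).
#' @param estimator an [albumin_estimator()].
#' @return estimated albumin in g/dL, clipped to \[1.0, 6.0\].
#' @examples
#' estimate_albumin(9.4)
#' @export
estimate_albumin <- function(calcium, estimator = albumin_estimator()) {
  stopifnot(inherits(estimator, "fivea_albumin_estimator"))
  if (any(is.na(calcium)))
    stop("unresolvable albumin: calcium missing at row(s) ",
         paste(utils::head(which(is.na(calcium)), 5), collapse = ", "),
         "; use a worst-case albumin scenario for these patients",
         call. = FALSE)
  .check_range(calcium, "calcium")
  pmin(pmax(estimator$intercept + estimator$slope * calcium, 1.0), 6.0)
}

#' Chained random-forest imputation of missing predictors
#'
#' Nonparametric iterative imputation in the missForest style: each
#' incomplete column is initialised with its mean (numeric) or mode
#' (categorical/logical), then repeatedly re-predicted from all other
#' columns with a random forest, cycling columns in order of increasing
#' missingness until the normalised change in imputed values stops
#' decreasing or `max_iter` is reached. Observed cells are never altered.
#'
#' @param data data.frame of predictors (numeric, logical or factor columns).
#' @param seed integer seed; the procedure is fully reproducible given it.
#' @param max_iter maximum sweeps over the incomplete columns.
#' @param ntree trees per forest.
#' @return list with `data` (completed data.frame), `iterations`, and
#'   `convergence` (per-iteration normalised change in imputed values).
#' @export
iterative_impute <- function(data, seed = 1, max_iter = 10, ntree = 100) {
  stopifnot(is.data.frame(data))
  na_count <- vapply(data, function(x) sum(is.na(x)), integer(1))
  if (any(na_count == nrow(data)))
    stop("column(s) entirely missing: ",
         paste(names(data)[na_count == nrow(data)], collapse = ", "),
         call. = FALSE)
  if (all(na_count == 0))
    return(list(data = data, iterations = 0L, convergence = numeric(0)))

  out <- data
  logical_cols <- names(data)[vapply(data, is.logical, logical(1))]
  for (cl in logical_cols) out[[cl]] <- factor(out[[cl]], levels = c("FALSE", "TRUE"))
  char_cols <- names(out)[vapply(out, is.character, logical(1))]
  for (cl in char_cols) out[[cl]] <- factor(out[[cl]])

  mask <- is.na(data)
  # Mean/mode initialisation.
  for (cl in names(out)[na_count > 0]) {
    if (is.numeric(out[[cl]])) {
      out[[cl]][mask[, cl]] <- mean(out[[cl]], na.rm = TRUE)
    } else {
      tab <- table(out[[cl]])
      out[[cl]][mask[, cl]] <- names(tab)[which.max(tab)]
    }
  }

  order_cols <- names(sort(na_count[na_count > 0]))
  old_seed <- .Random.seed_save()
  set.seed(seed)
  prev <- out
  delta <- numeric(0)
  it <- 0L
  repeat {
    it <- it + 1L
    for (cl in order_cols) {
      obs <- !mask[, cl]
      # Near-constant responses are legitimate here; silence the forest's
      # "five or fewer unique values" regression warning.
      fit <- withCallingHandlers(
        randomForest::randomForest(
          x = out[obs, setdiff(names(out), cl), drop = FALSE],
          y = out[obs, cl], ntree = ntree),
        warning = function(w) {
          if (grepl("five or fewer unique values", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      pr <- stats::predict(fit, out[mask[, cl], setdiff(names(out), cl), drop = FALSE])
      out[mask[, cl], cl] <- pr
    }
    # Normalised change in imputed numeric values (categorical: disagreement).
    num <- 0; den <- 0
    for (cl in order_cols) {
      a <- out[mask[, cl], cl]; b <- prev[mask[, cl], cl]
      if (is.numeric(a)) {
        num <- num + sum((a - b)^2); den <- den + sum(a^2)
      } else {
        num <- num + sum(a != b); den <- den + length(a)
      }
    }
    delta <- c(delta, if (den > 0) num / den else 0)
    if (it >= max_iter || (it > 1 && delta[it] >= delta[it - 1])) {
      if (it > 1 && delta[it] >= delta[it - 1]) out <- prev  # keep the better sweep
      break
    }
    prev <- out
  }
  .Random.seed_restore(old_seed)

  for (cl in logical_cols) out[[cl]] <- out[[cl]] == "TRUE"
  for (cl in char_cols) out[[cl]] <- as.character(out[[cl]])
  list(data = out, iterations = it, convergence = delta)
}
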