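# Synthetic cohorts: marginal-matched simulation, the exact published
# contingency table, missingness injection, and cohort CSV input/output.

# Two-piece (split) normal draw matched exactly to (Q1, median, Q3), then
# clamped to [lower, upper]. Clamping only moves mass beyond the matched
# quartiles, so median and IQR are preserved.
.rsplitnorm <- function(n, q1, med, q3, lower = -Inf, upper = Inf) {
  if (!(q1 < med && med < q3))
    stop("infeasible marginal target: need Q1 < median < Q3", call. = FALSE)
  z <- stats::rnorm(n)
  k <- stats::qnorm(0.75)
  x <- med + ifelse(z > 0, (q3 - med) / k, (med - q1) / k) * z
  pmin(pmax(x, lower), upper)
}

#' Simulation parameters for a synthetic hypothermia cohort
#'
#' Defaults reproduce the marginal structure of the national registry cohort
#' used for the external validation: age median 79 (IQR 68-87), 54.9% male,
#' 22% with disturbed activities of daily living, 8.9% cardiac arrest on
#' arrival, systolic blood pressure 117 (87-144) mmHg, pH 7.29 (7.18-7.35),
#' estimated albumin 3.54 (3.23-3.77) g/dL, and body temperature 30.9
#' (28.2-33.4) degrees C truncated at the 35-degree inclusion boundary.
#' Continuous marginals are `(q1, median, q3)` triples matched by a split
#' normal. Covariates are drawn independently (the registry's joint
#' distribution is unpublished); total calcium is derived from albumin by
#' inverting the default [albumin_estimator()] plus noise so the
#' albumin-calcium correlation the estimation step relies on is present.
#'
#' @param n cohort size.
#' @param age,sbp,ph,albumin,body_temp numeric `(q1, median, q3)` triples.
#' @param male_frac,adl_frac,arrest_frac marginal fractions in \[0, 1\].
#' @param outcome_model a [probability_model()] used as the ground-truth
#'   mortality mechanism: outcome ~ Bernoulli(p(total score)).
#' @return list of class `fivea_sim_params`.
#' @export
cohort_params <- function(n = 1139,
                          age = c(68, 79, 87),
                          male_frac = 0.549,
                          adl_frac = 0.22,
                          arrest_frac = 0.089,
                          sbp = c(87, 117, 144),
                          ph = c(7.18, 7.29, 7.35),
                          albumin = c(3.23, 3.54, 3.77),
                          body_temp = c(28.2, 30.9, 33.4),
                          outcome_model = reference_model()) {
  fr <- c(male_frac, adl_frac, arrest_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  for (q in list(age, sbp, ph, albumin, body_temp))
    if (length(q) != 3 || !(q[1] < q[2] && q[2] < q[3]))
      stop("infeasible marginal target: quartile triple must be increasing",
           call. = FALSE)
  structure(list(n = n, age = age, male_frac = male_frac, adl_frac = adl_frac,
                 arrest_frac = arrest_frac, sbp = sbp, ph = ph,
                 albumin = albumin, body_temp = body_temp,
                 outcome_model = outcome_model),
            class = "fivea_sim_params")
}

#' Generate a synthetic cohort
#'
#' Draws `n` patient records from the marginal targets in `params` and
#' simulates in-hospital mortality from the ground-truth probability model
#' applied to each patient's true 5A score. Reproducible given `seed`.
#'
#' @param params a [cohort_params()] object.
#' @param seed integer seed.
#' @return data.frame in the cohort schema: `age`, `sex`, `adl_disturbance`,
#'   `cardiac_arrest`, `sbp`, `ph`, `albumin`, `calcium`, `body_temp`,
#'   `outcome`.
#' @export
generate_cohort <- function(params = cohort_params(), seed = 1) {
  stopifnot(inherits(params, "fivea_sim_params"))
  old <- .Random.seed_save()
  set.seed(seed)
  n <- params$n
  est <- albumin_estimator()
  co <- data.frame(
    age = round(.rsplitnorm(n, params$age[1], params$age[2], params$age[3],
                            lower = 18, upper = 105)),
    sex = ifelse(stats::runif(n) < params$male_frac, "male", "female"),
    adl_disturbance = stats::runif(n) < params$adl_frac,
    cardiac_arrest = stats::runif(n) < params$arrest_frac,
    sbp = round(.rsplitnorm(n, params$sbp[1], params$sbp[2], params$sbp[3],
                            lower = 0, upper = 260)),
    ph = round(.rsplitnorm(n, params$ph[1], params$ph[2], params$ph[3],
                           lower = 6.51, upper = 7.89), 2),
    albumin = round(.rsplitnorm(n, params$albumin[1], params$albumin[2],
                                params$albumin[3], lower = 1, upper = 6), 2),
    body_temp = round(.rsplitnorm(n, params$body_temp[1], params$body_temp[2],
                                  params$body_temp[3], lower = 15, upper = 35), 1)
  )
  co$sbp[co$cardiac_arrest] <- 0  # convention: SBP recorded as 0 in arrest
  co$calcium <- round(pmin(pmax(
    (co$albumin - est$intercept) / est$slope + stats::rnorm(n, 0, 0.15),
    4), 14), 1)
  total <- fivea_points(co)$total
  p <- predict(params$outcome_model, total)
  co$outcome <- as.integer(stats::runif(n) < p)
  .Random.seed_restore(old)
  co[, .cohort_cols]
}

# Largest-remainder apportionment of `total` into shares proportional to w.
.apportion <- function(total, w) {
  raw <- total * w / sum(w)
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Covariate template guaranteed to score exactly `s` points: greedy
# decomposition age(0-3) -> acidemia(0-2) -> arrest(0/2) -> ADL(0/1) ->
# albumin(0/1).
.score_template <- function(s) {
  age_p <- min(s, 3); r <- s - age_p
  acid_p <- min(r, 2); r <- r - acid_p
  arr_p <- if (r >= 2) 2 else 0; r <- r - arr_p
  adl_p <- if (r >= 1) 1 else 0; r <- r - adl_p
  alb_p <- r
  if (alb_p > 1) stop("assembly error: no covariate template for score ", s,
                      call. = FALSE)
  data.frame(
    age = c(45, 65, 75, 85)[age_p + 1],
    adl_disturbance = adl_p == 1,
    cardiac_arrest = arr_p == 2,
    sbp = if (arr_p == 2) 0 else 117,
    ph = c(7.45, 7.30, 7.10)[acid_p + 1],
    albumin = if (alb_p == 1) 2.8 else 3.6
  )
}

#' Deterministic cohort reproducing the published risk-group outcome table
#'
#' Assembles exactly 1139 patients whose component scores place 483, 334,
#' 193 and 129 of them in the low (0-3), mild (4), moderate (5) and high
#' (6-9) risk bands, with exactly 60, 59, 63 and 89 in-hospital deaths per
#' band (271 overall, 23.8%). Within each band, patients are spread
#' uniformly over the band's score values and deaths over score cells by
#' largest-remainder apportionment; covariates per score come from fixed
#' templates that round-trip through [fivea_points()] to exactly their
#' target score. Fully deterministic.
#'
#' @param band_n patients per band (low, mild, moderate, high).
#' @param band_deaths deaths per band.
#' @return cohort data.frame (same schema as [generate_cohort()]).
#' @export
exact_table_cohort <- function(band_n = c(483L, 334L, 193L, 129L),
                               band_deaths = c(60L, 59L, 63L, 89L)) {
  stopifnot(length(band_n) == 4, length(band_deaths) == 4,
            all(band_deaths <= band_n))
  band_scores <- list(0:3, 4L, 5L, 6:9)
  est <- albumin_estimator()
  blocks <- vector("list", 0)
  for (b in seq_len(4)) {
    sc <- band_scores[[b]]
    n_per <- .apportion(band_n[b], rep(1, length(sc)))
    d_per <- .apportion(band_deaths[b], n_per)
    for (j in seq_along(sc)) {
      if (n_per[j] == 0) next
      tpl <- .score_template(sc[j])
      if (fivea_points(tpl)$total != sc[j])
        stop("assembly error: template for score ", sc[j],
             " does not round-trip", call. = FALSE)
      blk <- tpl[rep(1, n_per[j]), , drop = FALSE]
      blk$outcome <- as.integer(seq_len(n_per[j]) <= d_per[j])
      blocks[[length(blocks) + 1]] <- blk
    }
  }
  co <- do.call(rbind, blocks)
  rownames(co) <- NULL
  co$sex <- ifelse(seq_len(nrow(co)) %% 2 == 1, "male", "female")
  co$body_temp <- 30.9
  co$calcium <- round((co$albumin - est$intercept) / est$slope, 1)
  co[, c("age", "sex", "adl_disturbance", "cardiac_arrest", "sbp", "ph",
         "albumin", "calcium", "body_temp", "outcome")]
}

#' Blank cells at random to emulate registry missingness
#'
#' @param cohort cohort data.frame.
#' @param rates named numeric vector of per-field missingness rates in
#'   \[0, 1); names must be cohort columns. Rate 1 on any score predictor is
#'   rejected (it could never be resolved).
#' @param seed integer seed.
#' @return list with `cohort` (holes as `NA`) and `mask` (logical
#'   data.frame, `TRUE` where blanked).
#' @export
inject_missingness <- function(cohort, rates, seed = 1) {
  stopifnot(is.data.frame(cohort), length(rates) > 0, !is.null(names(rates)))
  if (!all(names(rates) %in% names(cohort)))
    stop("unknown field(s): ",
         paste(setdiff(names(rates), names(cohort)), collapse = ", "),
         call. = FALSE)
  if (any(rates < 0 | rates >= 1))
    stop("missingness rates must lie in [0, 1)", call. = FALSE)
  mask <- as.data.frame(matrix(FALSE, nrow(cohort), ncol(cohort),
                               dimnames = list(NULL, names(cohort))))
  old <- .Random.seed_save()
  set.seed(seed)
  for (f in names(rates)) {
    hit <- stats::runif(nrow(cohort)) < rates[[f]]
    mask[[f]] <- hit
    cohort[[f]][hit] <- NA
  }
  .Random.seed_restore(old)
  list(cohort = cohort, mask = mask)
}

.cohort_cols <- c("age", "sex", "adl_disturbance", "cardiac_arrest", "sbp",
                  "ph", "albumin", "calcium", "body_temp", "outcome")

#' Read a cohort CSV
#'
#' One row per patient, fixed header (`age, sex, adl_disturbance,
#' cardiac_arrest, sbp, ph, albumin, calcium, body_temp, outcome`), empty
#' cells for missing values. Unknown categorical levels in `sex` are kept
#' as `"Unknown"` rather than imputed.
#'
#' @param path CSV file path.
#' @return list with `cohort` (typed data.frame) and `mask` (logical
#'   data.frame flagging the empty cells).
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("", "NA"))
  miss <- setdiff(.cohort_cols, names(raw))
  if (length(miss))
    stop("cohort file missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  raw <- raw[, .cohort_cols]
  as_num <- function(x, cl) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at data line(s) %s",
                   cl, paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    v
  }
  as_lgl <- function(x, cl) {
    v <- rep(NA, length(x))
    v[tolower(x) %in% c("true", "1", "yes")] <- TRUE
    v[tolower(x) %in% c("false", "0", "no")] <- FALSE
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad))
      stop(sprintf("non-logical value in column '%s' at data line(s) %s",
                   cl, paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    v
  }
  co <- data.frame(
    age = as_num(raw$age, "age"),
    sex = ifelse(is.na(raw$sex) |
                   !tolower(raw$sex) %in% c("male", "female"),
                 "Unknown", tolower(raw$sex)),
    adl_disturbance = as_lgl(raw$adl_disturbance, "adl_disturbance"),
    cardiac_arrest = as_lgl(raw$cardiac_arrest, "cardiac_arrest"),
    sbp = as_num(raw$sbp, "sbp"),
    ph = as_num(raw$ph, "ph"),
    albumin = as_num(raw$albumin, "albumin"),
    calcium = as_num(raw$calcium, "calcium"),
    body_temp = as_num(raw$body_temp, "body_temp"),
    outcome = as_num(raw$outcome, "outcome")
  )
  mask <- as.data.frame(is.na(raw))
  list(cohort = co, mask = mask)
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: missing values become empty cells.
#'
#' @param cohort cohort data.frame.
#' @param path output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort[, .cohort_cols], path, row.names = FALSE, na = "")
  invisible(path)
}
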