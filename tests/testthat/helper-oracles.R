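# Shared fixtures and independent oracles used across test files.

# Exhaustive O(n^2) pair-counting concordance oracle, independent of the
# rank-based implementation.
cstat_bruteforce <- function(pred, y) {
  cases <- pred[y == 1]
  ctrls <- pred[y == 0]
  num <- 0
  for (a in cases) for (b in ctrls)
    num <- num + (a > b) + 0.5 * (a == b)
  num / (length(cases) * length(ctrls))
}

# Covariate grid covering every branch of every component rule.
component_grid <- function() {
  expand.grid(
    age = c(45, 65, 75, 85),
    adl_disturbance = c(FALSE, TRUE),
    cardiac_arrest = c(FALSE, TRUE),
    sbp = c(50, 117),
    ph = c(7.45, 7.30, 7.10),
    albumin = c(3.6, 2.8),
    KEEP.OUT.ATTRS = FALSE
  )
}

# One-row patient record with overridable fields.
patient <- function(age = 50, adl_disturbance = FALSE, cardiac_arrest = FALSE,
                    sbp = 120, ph = 7.40, albumin = 4.0, sex = "male",
                    body_temp = 30, calcium = 9.4, outcome = 0) {
  data.frame(age = age, adl_disturbance = adl_disturbance,
             cardiac_arrest = cardiac_arrest, sbp = sbp, ph = ph,
             albumin = albumin, sex = sex, body_temp = body_temp,
             calcium = calcium, outcome = outcome)
}
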