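# Independent closed-form oracles used to check the fitting and
# transform code paths.

# Simple-regression normal equations, no lm().
ols_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - (intercept + slope * x)
  list(intercept = intercept, slope = slope, n = n,
       residual_sd = sqrt(sum(resid^2) / (n - 2)),
       r_squared = 1 - sum(resid^2) / sum((y - mean(y))^2))
}

# Direct evaluation of the Hill-form dissociation relation.
hill_po2_oracle <- function(s, p50 = 29.11, n = 0.3704) {
  p50 * (s / (100 - s))^n
}

# One fully observed study row for constructing small scenario inputs.
study_row <- function(reference = "synthetic", altitude_m = 5000,
                      hr_ratio = 0.9, sa_max_pct = 75, hb_ratio = 1.2,
                      days = NA_character_) {
  tibble::tibble(reference = reference, altitude_m = altitude_m,
                 hr_ratio = hr_ratio, sa_max_pct = sa_max_pct,
                 hb_ratio = hb_ratio, days = days)
}
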