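#' Configuration for the synthetic study-table generator
#'
#' The generator emulates the structure of the literature table: one row
#' per (study, altitude) pair with altitudes uniform over a range,
#' arterial saturation linear in altitude with Gaussian noise, heart-rate
#' ratio linear in altitude with Gaussian noise, hemoglobin ratio uniform
#' over a range, and optional cells dropped independently at random.
#'
#' Defaults: the saturation trend is the canonical altitude relation
#' (107.6, -0.0066) with noise sd 5%; the heart-rate trend and its noise
#' sd (1.1124, -4.808e-05, 0.048) are the least-squares fit of the
#' bundled table's heart-rate column on altitude and its residual sd.
#'
#' @param n_studies Number of rows to generate (>= 1).
#' @param altitude_range_m Length-2 numeric, min and max altitude in
#'   meters, within (0, 12000).
#' @param sa_intercept_pct,sa_slope_pct_per_m True saturation trend.
#' @param sa_noise_sd_pct Gaussian noise sd on saturation, percent.
#' @param hr_intercept,hr_slope_per_m True heart-rate-ratio trend.
#' @param hr_noise_sd Gaussian noise sd on the heart-rate ratio.
#' @param hb_ratio_range Length-2 numeric, hemoglobin-ratio range.
#' @param missing_prob Either a single probability applied to each
#'   optional cell (`hr_ratio`, `sa_max_pct`, `hb_ratio`) or a named
#'   vector with those three names; each in [0, 1).
#' @param seed Integer seed; all draws derive from it.
#' @return A validated list of class `"generator_config"`.
#' @export
generator_config <- function(n_studies = 29,
                             altitude_range_m = c(3000, 9000),
                             sa_intercept_pct = 107.6,
                             sa_slope_pct_per_m = -0.0066,
                             sa_noise_sd_pct = 5,
                             hr_intercept = 1.1124,
                             hr_slope_per_m = -4.808e-05,
                             hr_noise_sd = 0.048,
                             hb_ratio_range = c(1.0, 1.5),
                             missing_prob = 0,
                             seed = 1L) {
  if (length(missing_prob) == 1 && is.null(names(missing_prob))) {
    missing_prob <- c(hr_ratio = missing_prob, sa_max_pct = missing_prob,
                      hb_ratio = missing_prob)
  }
  cfg <- list(
    n_studies = as.integer(n_studies),
    altitude_range_m = as.numeric(altitude_range_m),
    sa_intercept_pct = as.numeric(sa_intercept_pct),
    sa_slope_pct_per_m = as.numeric(sa_slope_pct_per_m),
    sa_noise_sd_pct = as.numeric(sa_noise_sd_pct),
    hr_intercept = as.numeric(hr_intercept),
    hr_slope_per_m = as.numeric(hr_slope_per_m),
    hr_noise_sd = as.numeric(hr_noise_sd),
    hb_ratio_range = as.numeric(hb_ratio_range),
    missing_prob = missing_prob,
    seed = as.integer(seed)
  )
  bad <- character(0)
  if (is.na(cfg$n_studies) || cfg$n_studies < 1) {
    bad <- c(bad, "n_studies must be >= 1")
  }
  if (length(cfg$altitude_range_m) != 2 ||
      cfg$altitude_range_m[1] > cfg$altitude_range_m[2] ||
      cfg$altitude_range_m[1] <= 0 || cfg$altitude_range_m[2] >= 12000) {
    bad <- c(bad, "altitude_range_m must be an increasing pair within (0, 12000)")
  }
  if (cfg$sa_noise_sd_pct < 0 || cfg$hr_noise_sd < 0) {
    bad <- c(bad, "noise sds must be >= 0")
  }
  if (length(cfg$hb_ratio_range) != 2 ||
      cfg$hb_ratio_range[1] > cfg$hb_ratio_range[2]) {
    bad <- c(bad, "hb_ratio_range must be an increasing pair")
  }
  if (!setequal(names(cfg$missing_prob),
                c("hr_ratio", "sa_max_pct", "hb_ratio")) ||
      any(cfg$missing_prob < 0 | cfg$missing_prob >= 1)) {
    bad <- c(bad, "missing_prob must be in [0, 1) for hr_ratio, sa_max_pct, hb_ratio")
  }
  if (is.na(cfg$seed)) bad <- c(bad, "seed must be an integer")
  if (length(bad) > 0) {
    stop("invalid generator config:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  }
  class(cfg) <- "generator_config"
  cfg
}

#' Generate a synthetic study table with known ground truth
#'
#' Draws a literature-like table from a [generator_config()]. Saturation
#' values are clipped to (30, 100) and heart-rate ratios to (0.5, 1.1) so
#' every generated row satisfies the study-table range invariants;
#' clipping events are counted and exposed through the `n_clipped`
#' attribute rather than resampled. The draw order is fixed (altitudes,
#' then saturation noise, then heart-rate noise, then hemoglobin ratios,
#' then the three missingness masks) so output is bit-reproducible from
#' the seed alone.
#'
#' @param config A `"generator_config"` object.
#' @return A study-table tibble in the same dialect as [load_table1()],
#'   with attributes `config` and `n_clipped` (named count of clipped sa
#'   and hr cells).
#' @examples
#' tbl <- generate_studies(generator_config(n_studies = 10, seed = 42))
#' @export
generate_studies <- function(config = generator_config()) {
  if (!inherits(config, "generator_config")) {
    config <- do.call(generator_config, config)
  }
  n <- config$n_studies
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(config$seed)
  alt <- stats::runif(n, config$altitude_range_m[1], config$altitude_range_m[2])
  sa <- config$sa_intercept_pct + config$sa_slope_pct_per_m * alt +
    stats::rnorm(n, 0, config$sa_noise_sd_pct)
  hr <- config$hr_intercept + config$hr_slope_per_m * alt +
    stats::rnorm(n, 0, config$hr_noise_sd)
  hb <- stats::runif(n, config$hb_ratio_range[1], config$hb_ratio_range[2])
  eps <- 1e-6
  n_clipped <- c(sa = sum(sa <= 30 | sa >= 100),
                 hr = sum(hr <= 0.5 | hr >= 1.1))
  sa <- pmin(pmax(sa, 30 + eps), 100 - eps)
  hr <- pmin(pmax(hr, 0.5 + eps), 1.1 - eps)
  drop <- function(x, p) {
    x[stats::runif(length(x)) < p] <- NA_real_
    x
  }
  hr <- drop(hr, config$missing_prob[["hr_ratio"]])
  sa <- drop(sa, config$missing_prob[["sa_max_pct"]])
  hb <- drop(hb, config$missing_prob[["hb_ratio"]])
  out <- tibble::tibble(
    reference = sprintf("synthetic study %02d", seq_len(n)),
    altitude_m = alt,
    hr_ratio = hr,
    sa_max_pct = sa,
    hb_ratio = hb,
    days = NA_character_
  )
  attr(out, "config") <- config
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Synthetic table mimicking the bundled literature table
#'
#' Convenience preset: 29 rows spanning 3090-8848 m with the bundled
#' table's missingness frequencies (heart-rate ratio always present,
#' saturation missing in 12/29 of cells, hemoglobin ratio in 11/29) and
#' its fitted trends and noise levels (saturation residual sd ~6.1%).
#'
#' @param seed Integer seed.
#' @return A study-table tibble (see [generate_studies()]).
#' @export
make_table1_like <- function(seed = 1L) {
  generate_studies(generator_config(
    n_studies = 29,
    altitude_range_m = c(3090, 8848),
    sa_noise_sd_pct = 6.1,
    missing_prob = c(hr_ratio = 0, sa_max_pct = 12 / 29, hb_ratio = 11 / 29),
    seed = seed
  ))
}
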