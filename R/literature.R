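#' Load the bundled literature study table
#'
#' Reads the literature-extracted table of maximal-exercise measurements
#' at altitude that feeds the model: one row per (study, altitude) pair,
#' with the maximal-heart-rate ratio hypoxia/normoxia, arterial O2
#' saturation at maximal exercise, hemoglobin-concentration ratio, and
#' days spent at altitude. Multi-altitude expeditions (Sutton;
#' West/Winslow; Richalet/Robach) appear as separate rows because each
#' altitude is an independent model input. Missing cells are `NA`, never
#' 0. The `days` column is free text (values like "60-90") and is never
#' used in computation.
#'
#' @param path Path to a CSV in the same dialect; defaults to the bundled
#'   table.
#' @return A tibble with columns `reference`, `altitude_m`, `hr_ratio`,
#'   `sa_max_pct`, `hb_ratio`, `days`.
#' @examples
#' tbl <- load_table1()
#' nrow(tbl)   # 29 study-altitude rows
#' @export
load_table1 <- function(path = system.file("extdata", "table1.csv",
                                           package = "myoxalt")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("study table not found: ", path, call. = FALSE)
  }
  spec <- readr::cols(
    reference = readr::col_character(),
    altitude_m = readr::col_double(),
    hr_ratio = readr::col_double(),
    sa_max_pct = readr::col_double(),
    hb_ratio = readr::col_double(),
    days = readr::col_character()
  )
  # parse problems are re-raised below as a fatal error naming the line,
  # so readr's advisory warnings are silenced here
  tbl <- suppressWarnings(
    readr::read_csv(path, col_types = spec, na = "", progress = FALSE)
  )
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0) {
    stop("malformed study table ", path, ": parse failure at line(s) ",
         paste(unique(prob$row + 1L), collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(names(spec$cols), names(tbl))
  if (length(missing_cols) > 0) {
    stop("malformed study table ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tbl
}

#' Write a study table in the bundled CSV dialect
#'
#' Missing cells are written as empty fields so that writing and
#' re-loading is the identity.
#'
#' @param records A study-table tibble (see [load_table1()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_studies <- function(records, path) {
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' Validate a study table
#'
#' Checks the physiological range invariants row by row: altitude in
#' [3000, 9000] m, heart-rate ratio in (0.5, 1.1), arterial saturation in
#' (30, 100)%, hemoglobin ratio in [1.0, 1.6]. Missing values pass (the
#' ranges only constrain cells that are present). All violations are
#' reported together, each naming its row.
#'
#' @param records A study-table tibble.
#' @return `records`, invisibly, if valid; otherwise an error listing
#'   every violating row.
#' @export
validate_studies <- function(records) {
  required <- c("reference", "altitude_m", "hr_ratio", "sa_max_pct", "hb_ratio")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("study table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- character(0)
  flag <- function(ok, what) {
    viol <- which(!ok & !is.na(ok))
    if (length(viol) > 0) {
      bad <<- c(bad, sprintf("row %d (%s): %s", viol,
                             records$reference[viol], what))
    }
  }
  flag(records$altitude_m >= 3000 & records$altitude_m <= 9000,
       "altitude_m outside [3000, 9000]")
  flag(is.na(records$hr_ratio) |
         (records$hr_ratio > 0.5 & records$hr_ratio < 1.1),
       "hr_ratio outside (0.5, 1.1)")
  flag(is.na(records$sa_max_pct) |
         (records$sa_max_pct > 30 & records$sa_max_pct < 100),
       "sa_max_pct outside (30, 100)")
  flag(is.na(records$hb_ratio) |
         (records$hb_ratio >= 1.0 & records$hb_ratio <= 1.6),
       "hb_ratio outside [1.0, 1.6]")
  if (length(bad) > 0) {
    stop("invalid study table:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(records)
}

#' Per-column summary of a study table
#'
#' @param records A study-table tibble.
#' @return A tibble with one row per numeric column: `column`,
#'   `n_present`, `min`, `max`.
#' @examples
#' summarize_studies(load_table1())
#' @export
summarize_studies <- function(records) {
  cols <- c("altitude_m", "hr_ratio", "sa_max_pct", "hb_ratio")
  purrr::map_dfr(cols, function(cl) {
    x <- if (cl %in% names(records)) records[[cl]] else numeric(0)
    x <- x[!is.na(x)]
    tibble::tibble(
      column = cl,
      n_present = length(x),
      min = if (length(x) > 0) min(x) else NA_real_,
      max = if (length(x) > 0) max(x) else NA_real_
    )
  })
}

#' Fit a linear altitude trend to a study-table column
#'
#' Ordinary least squares of the selected column on altitude, using every
#' row where the column is present; duplicate altitudes are kept as
#' independent points. This is the refitting stage behind the
#' arterial-saturation-versus-altitude relation: note that refitting the
#' bundled table's saturation column gives intercept ~111.1 and slope
#' ~-0.0070, not the canonical constants (107.6, -0.0066) used downstream
#' by default -- the refit is a diagnostic, the canonical constants are
#' what the model reproduces.
#'
#' @param records A study-table tibble.
#' @param field Column to regress on altitude (tidy-eval), e.g.
#'   `sa_max_pct` or `hr_ratio`.
#' @return An object of class `"altitude_trend"` wrapping the [stats::lm]
#'   fit; use [tidy()] / [glance()] to extract coefficients and
#'   diagnostics.
#' @examples
#' fit <- fit_altitude_trend(load_table1(), sa_max_pct)
#' glance(fit)
#' @export
fit_altitude_trend <- function(records, field) {
  field <- rlang::ensym(field)
  fname <- rlang::as_string(field)
  if (!fname %in% names(records)) {
    stop("column not found: ", fname, call. = FALSE)
  }
  d <- dplyr::filter(records, !is.na(!!field), !is.na(.data$altitude_m))
  if (nrow(d) < 3) {
    stop("insufficient data: need at least 3 rows with both altitude_m and ",
         fname, " present, got ", nrow(d), call. = FALSE)
  }
  fit <- stats::lm(stats::reformulate("altitude_m", response = fname), data = d)
  structure(list(fit = fit, field = fname, n_points = nrow(d)),
            class = "altitude_trend")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an altitude-trend fit
#'
#' @param x An `"altitude_trend"` object.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy altitude_trend
#' @export
tidy.altitude_trend <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std.error = cf[, "Std. Error"],
    statistic = cf[, "t value"],
    p.value = cf[, "Pr(>|t|)"]
  )
}

#' One-row diagnostics for an altitude-trend fit
#'
#' @param x An `"altitude_trend"` object.
#' @param ... Unused.
#' @return A one-row tibble: `field`, `intercept`, `slope`, `n_points`,
#'   `residual_sd`, `r_squared`.
#' @method glance altitude_trend
#' @export
glance.altitude_trend <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    field = x$field,
    intercept = unname(stats::coef(x$fit)[1]),
    slope = unname(stats::coef(x$fit)["altitude_m"]),
    n_points = x$n_points,
    residual_sd = s$sigma,
    r_squared = s$r.squared
  )
}

#' @export
print.altitude_trend <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Linear trend of %s vs altitude (n = %d)\n", g$field, g$n_points))
  cat(sprintf("  %s = %.4f %+.3e * altitude_m   (r^2 = %.3f, residual sd = %.3f)\n",
              g$field, g$intercept, g$slope, g$r_squared, g$residual_sd))
  invisible(x)
}
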