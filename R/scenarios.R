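#' Per-study venous oxygenation under two heart-rate hypotheses
#'
#' For every study row with heart-rate ratio, arterial saturation and
#' hemoglobin ratio all present, computes myocardial venous O2 saturation
#' and partial pressure under (1) the heart rate actually observed at
#' altitude and (2) a fixed sea-level maximal heart rate (`hr_ratio = 1`,
#' i.e. no chronotropic blunting). Venous pressure is obtained from
#' saturation through the dissociation transform and left `NA` whenever
#' the saturation is outside its domain (Sv <= 0 or >= 100): a negative
#' saturation has no physical pressure.
#'
#' Rows with any of the three inputs missing are excluded; they are
#' reported in the `excluded` attribute (reference, altitude, reason) and
#' via a message.
#'
#' @param records A study-table tibble (see [load_table1()]).
#' @param params Model parameters, see [model_parameters()].
#' @param quiet Suppress the exclusion message.
#' @return A tibble with one row per usable study row: `reference`,
#'   `altitude_m`, `hr_ratio`, `sa_max_pct`, `hb_ratio`,
#'   `sv_actual_hr_pct`, `pv_actual_hr_mmHg`, `sv_fixed_hr_pct`,
#'   `pv_fixed_hr_mmHg`, `feasible_fixed_hr` (Sv > 0),
#'   `above_floor_fixed_hr` (Sv >= the viability floor). Excluded rows in
#'   attribute `excluded`.
#' @examples
#' rows <- run_scenarios(load_table1(), quiet = TRUE)
#' rows[rows$altitude_m >= 8840, c("reference", "sv_fixed_hr_pct")]
#' @export
run_scenarios <- function(records, params = model_parameters(),
                          quiet = FALSE) {
  needed <- c("hr_ratio", "sa_max_pct", "hb_ratio")
  usable <- stats::complete.cases(records[needed])
  excluded <- records[!usable, , drop = FALSE]
  if (nrow(excluded) > 0) {
    reason <- apply(is.na(excluded[needed]), 1L, function(m) {
      paste("missing", paste(needed[m], collapse = ", "))
    })
    excluded <- tibble::tibble(
      reference = excluded$reference,
      altitude_m = excluded$altitude_m,
      reason = reason
    )
    if (!quiet) {
      message(nrow(excluded), " row(s) excluded from scenarios (",
              "incomplete hr_ratio/sa_max_pct/hb_ratio)")
    }
  } else {
    excluded <- tibble::tibble(reference = character(0),
                               altitude_m = numeric(0),
                               reason = character(0))
  }
  d <- records[usable, , drop = FALSE]
  if (nrow(d) == 0) {
    stop("no usable rows: every record lacks hr_ratio, sa_max_pct or hb_ratio",
         call. = FALSE)
  }
  pv_of <- function(sv) {
    ifelse(sv > 0 & sv < 100,
           so2_to_po2(pmin(pmax(sv, 0), 99.999), params), NA_real_)
  }
  sv1 <- as.numeric(venous_saturation(d$sa_max_pct, d$hr_ratio, d$hb_ratio,
                                      params = params))
  sv2 <- as.numeric(venous_saturation(d$sa_max_pct, 1, d$hb_ratio,
                                      params = params))
  out <- tibble::tibble(
    reference = d$reference,
    altitude_m = d$altitude_m,
    hr_ratio = d$hr_ratio,
    sa_max_pct = d$sa_max_pct,
    hb_ratio = d$hb_ratio,
    sv_actual_hr_pct = sv1,
    pv_actual_hr_mmHg = pv_of(sv1),
    sv_fixed_hr_pct = sv2,
    pv_fixed_hr_mmHg = pv_of(sv2),
    feasible_fixed_hr = sv2 > 0,
    above_floor_fixed_hr = sv2 >= params$sv_min_pct
  )
  out <- dplyr::arrange(out, .data$altitude_m)
  attr(out, "excluded") <- excluded
  out
}

#' Maximal tolerable altitude across a grid of coronary-reserve increases
#'
#' Sweeps [max_altitude()] over a grid of assumed percent increases in
#' coronary reserve, producing the curve of maximal altitude compatible
#' with the venous-saturation floor when maximal heart rate does not
#' decrease with altitude. Altitudes are returned at full precision;
#' set `round_to_100m = TRUE` for the reporting convention of rounding to
#' the nearest 100 m.
#'
#' @param delta_q_grid Numeric vector of percent increases in coronary
#'   reserve, each > -100, sorted increasing.
#' @param round_to_100m Round reported altitudes to the nearest 100 m.
#' @inheritParams run_scenarios
#' @return A tibble with columns `delta_q_pct` and `max_altitude_m`.
#' @examples
#' reserve_sweep(c(0, 20, 44.5))
#' @export
reserve_sweep <- function(delta_q_grid, params = model_parameters(),
                          round_to_100m = FALSE) {
  if (length(delta_q_grid) == 0) {
    return(tibble::tibble(delta_q_pct = numeric(0),
                          max_altitude_m = numeric(0)))
  }
  if (is.unsorted(delta_q_grid)) {
    stop("delta_q_grid must be sorted increasing", call. = FALSE)
  }
  alt <- max_altitude(delta_q_grid, params)
  if (round_to_100m) alt <- round(alt / 100) * 100
  tibble::tibble(delta_q_pct = as.numeric(delta_q_grid),
                 max_altitude_m = alt)
}

#' Lowest altitudes at which the fixed-heart-rate scenario fails
#'
#' Scans scenario rows (study-level data, not the regression line) for
#' the lowest altitude at which venous saturation under a fixed sea-level
#' heart rate drops below the viability floor, and the lowest at which it
#' becomes negative.
#'
#' @param rows A scenario tibble from [run_scenarios()].
#' @inheritParams run_scenarios
#' @return A tibble with one row per threshold: `threshold` ("below
#'   floor", "negative"), `cutoff_pct`, `first_altitude_m` (NA if no row
#'   violates), `reference`, `n_violating`.
#' @examples
#' threshold_crossings(run_scenarios(load_table1(), quiet = TRUE))
#' @export
threshold_crossings <- function(rows, params = model_parameters()) {
  if (nrow(rows) < 1) stop("need at least one scenario row", call. = FALSE)
  one <- function(label, cutoff, viol) {
    idx <- which(viol)
    if (length(idx) == 0) {
      return(tibble::tibble(threshold = label, cutoff_pct = cutoff,
                            first_altitude_m = NA_real_,
                            reference = NA_character_, n_violating = 0L))
    }
    first <- idx[which.min(rows$altitude_m[idx])]
    tibble::tibble(threshold = label, cutoff_pct = cutoff,
                   first_altitude_m = rows$altitude_m[first],
                   reference = rows$reference[first],
                   n_violating = length(idx))
  }
  dplyr::bind_rows(
    one("below floor", params$sv_min_pct,
        rows$sv_fixed_hr_pct < params$sv_min_pct),
    one("negative", 0, rows$sv_fixed_hr_pct < 0)
  )
}
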