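#' Oxyhemoglobin dissociation transforms
#'
#' Hill-form relation between O2 saturation and partial pressure,
#' `PO2 = P50 * (S / (100 - S))^n`, with constants fixed for myocardial
#' venous blood at pH 7.32 (P50 = 29.11 mmHg, n = 0.3704 by default).
#' `po2_to_so2()` is the exact algebraic inverse,
#' `S = 100 r / (1 + r)` with `r = (P / P50)^(1/n)`.
#'
#' The transform is singular at S = 100 (infinite pressure), so full
#' saturation is outside the domain; S = 0 maps to 0 mmHg.
#'
#' @param so2_pct O2 saturation in percent; each value must lie in
#'   `[0, 100)`.
#' @param po2_mmHg O2 partial pressure in mmHg; must be non-negative.
#' @param params Model parameters, see [model_parameters()].
#' @return A numeric vector of pressures (mmHg) or saturations (percent).
#' @examples
#' so2_to_po2(50)          # returns the P50 constant, 29.11
#' po2_to_so2(so2_to_po2(30))
#' @export
so2_to_po2 <- function(so2_pct, params = model_parameters()) {
  if (any(is.na(so2_pct))) stop("so2_pct must not contain NA", call. = FALSE)
  if (any(so2_pct < 0 | so2_pct >= 100)) {
    stop("so2_pct must lie in [0, 100): saturation at or above 100% has no finite pressure",
         call. = FALSE)
  }
  params$p50_mmHg * (so2_pct / (100 - so2_pct))^params$hill_exponent
}

#' @rdname so2_to_po2
#' @export
po2_to_so2 <- function(po2_mmHg, params = model_parameters()) {
  if (any(is.na(po2_mmHg))) stop("po2_mmHg must not contain NA", call. = FALSE)
  if (any(po2_mmHg < 0)) stop("po2_mmHg must be non-negative", call. = FALSE)
  r <- (po2_mmHg / params$p50_mmHg)^(1 / params$hill_exponent)
  100 * r / (1 + r)
}

#' Arterial O2 saturation at maximal exercise as a function of altitude
#'
#' Evaluates the linear altitude relation
#' `Sa = intercept + slope * altitude` fitted to literature data. Values
#' above 100% (which the line produces below about 1150 m) are capped at
#' 100 and flagged rather than silently truncated: the `clipped`
#' attribute marks the affected elements.
#'
#' @param altitude_m Altitude(s) in meters, non-negative.
#' @inheritParams so2_to_po2
#' @return Numeric vector of saturations in percent, capped at 100, with
#'   a logical attribute `clipped` of the same length.
#' @examples
#' samh_at_altitude(8848)
#' attr(samh_at_altitude(0), "clipped")
#' @export
samh_at_altitude <- function(altitude_m, params = model_parameters()) {
  if (any(altitude_m < 0)) stop("altitude_m must be non-negative", call. = FALSE)
  sa <- params$samh_intercept_pct + params$samh_slope_pct_per_m * altitude_m
  clipped <- sa > 100
  sa[clipped] <- 100
  structure(sa, clipped = clipped)
}

#' Myocardial venous O2 saturation from the Fick balance
#'
#' Solves the maximal-exercise Fick balance for venous saturation:
#' `Sv = Sa - av_diff * hr_ratio / (hb_ratio * q_ratio * a_ratio)`,
#' where `av_diff` is the normoxic arterio-venous saturation difference
#' (68% by default). With all ratios at 1 and arterial saturation at its
#' normoxic anchor this returns the normoxic venous anchor exactly.
#'
#' Negative results are physiologically impossible and mean the imposed
#' heart rate cannot be sustained at that arterial saturation; they are
#' returned as-is (never clamped) and flagged through the `feasible`
#' attribute.
#'
#' @param sa_pct Arterial O2 saturation, percent, in `[0, 100]`.
#' @param hr_ratio Maximal heart-rate ratio hypoxia/normoxia.
#' @param hb_ratio Hemoglobin-concentration ratio hypoxia/normoxia.
#' @param q_ratio Myocardial blood-flow (coronary reserve) ratio;
#'   defaults to the value in `params`.
#' @param a_ratio Composite mechanical-power ratio; defaults to the value
#'   in `params`.
#' @inheritParams so2_to_po2
#' @return Numeric vector of venous saturations in percent (possibly
#'   negative) with a logical attribute `feasible` (`Sv > 0`).
#' @examples
#' venous_saturation(98, 1, 1)                 # normoxic anchor: 30
#' venous_saturation(49, 0.70, 1.26)           # Sutton 8840 m row
#' @export
venous_saturation <- function(sa_pct, hr_ratio, hb_ratio,
                              q_ratio = params$q_ratio,
                              a_ratio = params$a_ratio,
                              params = model_parameters()) {
  if (any(sa_pct < 0 | sa_pct > 100)) {
    stop("sa_pct must lie in [0, 100]", call. = FALSE)
  }
  if (any(c(hr_ratio, hb_ratio, q_ratio, a_ratio) <= 0)) {
    stop("hr_ratio, hb_ratio, q_ratio and a_ratio must all be positive",
         call. = FALSE)
  }
  sv <- sa_pct - params$av_diff_normoxia_pct * hr_ratio /
    (hb_ratio * q_ratio * a_ratio)
  structure(sv, feasible = sv > 0)
}

#' Maximal altitude compatible with myocardial oxygenation
#'
#' Under the no-heart-rate-regulation hypothesis (`hr_ratio = 1`), finds
#' the altitude at which venous saturation falls exactly to the viability
#' floor: it solves
#' `Sa(alt) = sv_min + av_diff / (hb_ratio_ref * (1 + delta_q_pct/100))`
#' for altitude, where `delta_q_pct` is the assumed percent increase in
#' coronary reserve over its sea-level maximum. The curve is strictly
#' increasing in `delta_q_pct`.
#'
#' `use_printed_constants = TRUE` selects the closed-form variant
#' `maxAlt = 14788 - 8445 / (1 + delta_q_pct/100)`, whose rounded second
#' constant corresponds to a reference hemoglobin ratio of about 1.22 and
#' yields slightly higher altitudes; the default parameterisation
#' (hb_ratio_ref = 1.2) is the one consistent with the headline results
#' (6200 m with no extra reserve, 7600 m with +20%, +44.5% for 8848 m).
#'
#' @param delta_q_pct Percent increase(s) in coronary reserve; must be
#'   greater than -100.
#' @param use_printed_constants Use the rounded closed-form constants
#'   (14788, 8445) instead of deriving the curve from `params`.
#' @inheritParams so2_to_po2
#' @return Numeric vector of altitudes in meters (full precision; round
#'   to the nearest 100 m for reporting).
#' @examples
#' max_altitude(0)     # ~6202 m
#' max_altitude(20)    # ~7633 m
#' @export
max_altitude <- function(delta_q_pct, params = model_parameters(),
                         use_printed_constants = FALSE) {
  if (any(delta_q_pct <= -100)) {
    stop("delta_q_pct must be greater than -100", call. = FALSE)
  }
  if (use_printed_constants) {
    return(14788 - 8445 / (1 + delta_q_pct / 100))
  }
  sa_required <- params$sv_min_pct + params$av_diff_normoxia_pct /
    (params$hb_ratio_ref * (1 + delta_q_pct / 100))
  if (any(sa_required > params$samh_intercept_pct)) {
    stop("required arterial saturation exceeds the sea-level intercept: ",
         "no feasible altitude >= 0 for this parameter set", call. = FALSE)
  }
  (sa_required - params$samh_intercept_pct) / params$samh_slope_pct_per_m
}

#' Coronary reserve increase required to tolerate a target altitude
#'
#' Exact algebraic inverse of [max_altitude()]: the percent increase in
#' coronary reserve that places the venous-saturation floor exactly at
#' `target_altitude_m` under the no-heart-rate-regulation hypothesis.
#' Altitudes already tolerable with no extra reserve return 0, flagged
#' through the `no_reserve_needed` attribute.
#'
#' @param target_altitude_m Target altitude(s) in meters.
#' @inheritParams so2_to_po2
#' @return Numeric vector of percent increases in coronary reserve, with
#'   a logical attribute `no_reserve_needed`.
#' @examples
#' required_reserve(8848)   # ~44.5 (%)
#' @export
required_reserve <- function(target_altitude_m, params = model_parameters()) {
  sa <- params$samh_intercept_pct +
    params$samh_slope_pct_per_m * target_altitude_m
  if (any(sa <= params$sv_min_pct)) {
    stop("target altitude puts arterial saturation at or below the venous ",
         "floor: no finite coronary reserve suffices", call. = FALSE)
  }
  delta <- 100 * (params$av_diff_normoxia_pct /
                    (params$hb_ratio_ref * (sa - params$sv_min_pct)) - 1)
  none_needed <- delta <= 0
  delta[none_needed] <- 0
  structure(delta, no_reserve_needed = none_needed)
}
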