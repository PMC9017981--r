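#' Model parameters for the myocardial oxygen balance
#'
#' Bundles every constant of the model: the normoxic saturation anchors,
#' the arterio-venous saturation difference at maximal exercise in
#' normoxia, the minimal viable myocardial venous saturation, the
#' coefficients of the arterial-saturation-versus-altitude regression,
#' the Hill-form dissociation-curve constants, and the three
#' hypoxia/normoxia ratios (coronary flow, composite mechanical-power
#' term, reference hemoglobin) that close the Fick balance.
#'
#' Saturations are in percent (0-100), pressures in mmHg, altitudes in
#' meters. `venous_pH` is informational only: the dissociation constants
#' already correspond to a venous pH of 7.32 and carry no pH term.
#'
#' @param sa_normoxia_pct Arterial O2 saturation at maximal exercise in
#'   normoxia (`Samn`), percent.
#' @param sv_normoxia_pct Myocardial venous O2 saturation at maximal
#'   exercise in normoxia (`Svmn`), percent.
#' @param av_diff_normoxia_pct Normoxic arterio-venous saturation
#'   difference `Samn - Svmn`, percent. Must equal the difference of the
#'   two anchors above.
#' @param sv_min_pct Minimal venous saturation compatible with adequate
#'   myocardial oxygenation, percent.
#' @param samh_intercept_pct,samh_slope_pct_per_m Coefficients of the
#'   linear arterial-saturation-versus-altitude relation (percent and
#'   percent per meter; the slope is negative).
#' @param p50_mmHg O2 partial pressure at half saturation, mmHg.
#' @param hill_exponent Exponent of the Hill-form dissociation curve,
#'   dimensionless in (0, 1).
#' @param venous_pH Venous pH annotation (not used in computation).
#' @param q_ratio Myocardial blood flow ratio hypoxia/normoxia at maximal
#'   exercise (coronary reserve actually mobilised), dimensionless.
#' @param a_ratio Composite ratio of energetic equivalent, stroke volume
#'   and summed ejection pressures between hypoxia and normoxia,
#'   dimensionless; assumed 1.
#' @param hb_ratio_ref Reference hemoglobin-concentration ratio
#'   hypoxia/normoxia used by the altitude-limit calculations.
#'
#' @return An object of class `"myox_params"` (a named list).
#' @examples
#' p <- model_parameters()
#' p$av_diff_normoxia_pct
#' @export
model_parameters <- function(sa_normoxia_pct = 98,
                             sv_normoxia_pct = 30,
                             av_diff_normoxia_pct = sa_normoxia_pct - sv_normoxia_pct,
                             sv_min_pct = 10,
                             samh_intercept_pct = 107.6,
                             samh_slope_pct_per_m = -0.0066,
                             p50_mmHg = 29.11,
                             hill_exponent = 0.3704,
                             venous_pH = 7.32,
                             q_ratio = 1,
                             a_ratio = 1,
                             hb_ratio_ref = 1.2) {
  p <- list(
    sa_normoxia_pct = as.numeric(sa_normoxia_pct),
    sv_normoxia_pct = as.numeric(sv_normoxia_pct),
    av_diff_normoxia_pct = as.numeric(av_diff_normoxia_pct),
    sv_min_pct = as.numeric(sv_min_pct),
    samh_intercept_pct = as.numeric(samh_intercept_pct),
    samh_slope_pct_per_m = as.numeric(samh_slope_pct_per_m),
    p50_mmHg = as.numeric(p50_mmHg),
    hill_exponent = as.numeric(hill_exponent),
    venous_pH = as.numeric(venous_pH),
    q_ratio = as.numeric(q_ratio),
    a_ratio = as.numeric(a_ratio),
    hb_ratio_ref = as.numeric(hb_ratio_ref)
  )
  class(p) <- "myox_params"
  validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Collects every violated constraint and reports them all at once.
#'
#' @param params A `"myox_params"` object or a named list of the same
#'   fields.
#' @return `params`, invisibly, if valid; otherwise an error listing all
#'   violations.
#' @export
validate_parameters <- function(params) {
  bad <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) bad <<- c(bad, msg)
  with(params, {
    chk(abs(av_diff_normoxia_pct - (sa_normoxia_pct - sv_normoxia_pct)) < 1e-9,
        "av_diff_normoxia_pct must equal sa_normoxia_pct - sv_normoxia_pct")
    chk(samh_slope_pct_per_m < 0, "samh_slope_pct_per_m must be negative")
    chk(p50_mmHg > 0, "p50_mmHg must be positive")
    chk(hill_exponent > 0 && hill_exponent < 1, "hill_exponent must be in (0, 1)")
    chk(q_ratio > 0 && a_ratio > 0 && hb_ratio_ref > 0, "all ratios must be positive")
    chk(sv_min_pct >= 0 && sv_min_pct < sa_normoxia_pct,
        "sv_min_pct must be in [0, sa_normoxia_pct)")
  })
  if (length(bad) > 0) {
    stop("invalid model parameters:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(params)
}

#' Read and write parameter configuration files
#'
#' Parameters round-trip through a flat key-value YAML file. Keys absent
#' from the file keep their defaults, so a config file may override just
#' one constant.
#'
#' @param path Path to a YAML file.
#' @return `read_parameters()` returns a validated `"myox_params"`
#'   object; `write_parameters()` returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(model_parameters))
  known <- setdiff(known, "av_diff_normoxia_pct")
  extra <- setdiff(names(vals), c(known, "av_diff_normoxia_pct"))
  if (length(extra) > 0) {
    stop("unknown parameter key(s) in ", path, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  do.call(model_parameters, vals)
}

#' @rdname read_parameters
#' @param params A `"myox_params"` object.
#' @export
write_parameters <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @export
print.myox_params <- function(x, ...) {
  cat("Myocardial oxygen-balance model parameters\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}
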