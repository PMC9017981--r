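#' Run the full pipeline and write a report bundle
#'
#' Loads (or accepts) a study table, fits the altitude trends, runs both
#' heart-rate scenarios, scans the threshold crossings, sweeps the
#' coronary-reserve curve, and writes everything to `out_dir`:
#' `scenarios.csv`, `reserve_curve.csv`, `report.json` (parameters,
#' trend fits, headline quantities, scenario table, crossings, curve) and
#' `manifest.json`. The manifest carries the run metadata (command,
#' parameter snapshot, input hash, output list, package version,
#' timestamp); every data file is byte-stable across reruns because the
#' timestamp lives only in the manifest.
#'
#' @param records A study-table tibble; defaults to the bundled table.
#' @param params Model parameters.
#' @param out_dir Output directory, created if needed.
#' @param delta_q_grid Grid for the reserve sweep, percent.
#' @param command Label recorded in the manifest.
#' @param input_path Path recorded (and hashed) in the manifest, if the
#'   table came from a file.
#' @return Invisibly, a list with the report (as an R list) and the
#'   manifest.
#' @export
run_report <- function(records = load_table1(),
                       params = model_parameters(),
                       out_dir = ".",
                       delta_q_grid = seq(0, 100, by = 5),
                       command = "report",
                       input_path = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  validate_studies(records)
  rows <- run_scenarios(records, params, quiet = TRUE)
  crossings <- threshold_crossings(rows, params)
  curve <- reserve_sweep(delta_q_grid, params)
  fits <- list(
    sa_max_pct = glance(fit_altitude_trend(records, sa_max_pct)),
    hr_ratio = glance(fit_altitude_trend(records, hr_ratio))
  )
  headline <- list(
    max_altitude_m_no_extra_reserve = as.numeric(max_altitude(0, params)),
    max_altitude_m_20pct_reserve = as.numeric(max_altitude(20, params)),
    required_reserve_pct_everest = as.numeric(required_reserve(8848, params)),
    p50_mmHg = as.numeric(so2_to_po2(50, params))
  )
  report <- list(
    parameters = unclass(params),
    trend_fits = lapply(fits, as.list),
    headline = headline,
    scenarios = rows,
    threshold_crossings = crossings,
    reserve_curve = curve
  )
  scen_path <- file.path(out_dir, "scenarios.csv")
  curve_path <- file.path(out_dir, "reserve_curve.csv")
  report_path <- file.path(out_dir, "report.json")
  readr::write_csv(rows, scen_path, na = "")
  readr::write_csv(curve, curve_path, na = "")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(
    command = command,
    parameters = unclass(params),
    input = if (is.null(input_path)) "in-memory table" else input_path,
    input_md5 = if (!is.null(input_path) && file.exists(input_path)) {
      unname(tools::md5sum(input_path))
    } else NA_character_,
    outputs = c(scen_path, curve_path, report_path),
    package_version = as.character(utils::packageVersion("myoxalt")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(report = report, manifest = manifest))
}

cli_usage <- function() {
  paste(
    "usage: myoxalt <subcommand> [options]",
    "",
    "subcommands:",
    "  data       load, validate and summarize the bundled study table",
    "             options: --input <csv> --validate",
    "  fit        linear altitude trends of saturation and heart-rate ratio",
    "             options: --input <csv>",
    "  scenarios  per-study venous oxygenation under both HR hypotheses",
    "             options: --input <csv> --out <csv> --config <yaml>",
    "  sweep      maximal-altitude curve vs coronary-reserve increase",
    "             options: --from <pct> --to <pct> --step <pct> --out <csv>",
    "             --round --config <yaml>",
    "  simulate   synthetic study table with known ground truth",
    "             options: --n <rows> --seed <int> --missing <prob> --out <csv>",
    "  report     full pipeline -> CSVs + JSON report + manifest",
    "             options: --input <csv> --out-dir <dir> --config <yaml>",
    sep = "\n"
  )
}

cli_opt <- function(args, flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 0) return(default)
  if (i[1] == length(args)) stop("flag ", flag, " needs a value", call. = FALSE)
  args[i[1] + 1]
}

cli_has <- function(args, flag) flag %in% args

cli_table <- function(args) {
  path <- cli_opt(args, "--input")
  if (is.null(path)) load_table1() else load_table1(path)
}

cli_params <- function(args) {
  cfg <- cli_opt(args, "--config")
  if (is.null(cfg)) model_parameters() else read_parameters(cfg)
}

#' Command-line entry point
#'
#' Thin dispatcher over the package's functions, exposed so the shipped
#' `inst/cli/myoxalt` script (and tests) can drive the pipeline with
#' string arguments. Subcommands: `data`, `fit`, `scenarios`, `sweep`,
#' `simulate`, `report`. Diagnostics go to standard error; data tables go
#' to standard output or to files.
#'
#' @param argv Character vector of arguments (excluding the program name).
#' @return Integer exit status, 0 on success (invisibly).
#' @examples
#' cli_main(c("sweep", "--from", "0", "--to", "50", "--step", "10"))
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(argv) == 0 || argv[1] %in% c("-h", "--help", "help")) {
      cat(cli_usage(), "\n")
      return(invisible(if (length(argv) == 0) 2L else 0L))
    }
    cmd <- argv[1]
    args <- argv[-1]
    known_flags <- c("--input", "--out", "--out-dir", "--config", "--from",
                     "--to", "--step", "--n", "--seed", "--missing",
                     "--validate", "--round")
    flagged <- grepl("^--", args)
    unknown <- setdiff(args[flagged], known_flags)
    if (length(unknown) > 0) {
      stop("unknown flag(s): ", paste(unknown, collapse = ", "), "\n",
           cli_usage(), call. = FALSE)
    }
    switch(
      cmd,
      data = {
        tbl <- cli_table(args)
        validate_studies(tbl)
        if (cli_has(args, "--validate")) {
          message("study table valid: ", nrow(tbl), " rows")
        }
        readr::write_csv(summarize_studies(tbl), stdout(), na = "")
      },
      fit = {
        tbl <- cli_table(args)
        g <- dplyr::bind_rows(
          glance(fit_altitude_trend(tbl, sa_max_pct)),
          glance(fit_altitude_trend(tbl, hr_ratio))
        )
        readr::write_csv(g, stdout(), na = "")
      },
      scenarios = {
        tbl <- cli_table(args)
        rows <- run_scenarios(tbl, cli_params(args))
        out <- cli_opt(args, "--out")
        if (is.null(out)) readr::write_csv(rows, stdout(), na = "")
        else readr::write_csv(rows, out, na = "")
      },
      sweep = {
        from <- as.numeric(cli_opt(args, "--from", "0"))
        to <- as.numeric(cli_opt(args, "--to", "100"))
        step <- as.numeric(cli_opt(args, "--step", "5"))
        curve <- reserve_sweep(seq(from, to, by = step), cli_params(args),
                               round_to_100m = cli_has(args, "--round"))
        out <- cli_opt(args, "--out")
        if (is.null(out)) readr::write_csv(curve, stdout(), na = "")
        else readr::write_csv(curve, out, na = "")
      },
      simulate = {
        cfg <- generator_config(
          n_studies = as.integer(cli_opt(args, "--n", "29")),
          missing_prob = as.numeric(cli_opt(args, "--missing", "0")),
          seed = as.integer(cli_opt(args, "--seed", "1"))
        )
        tbl <- generate_studies(cfg)
        out <- cli_opt(args, "--out")
        if (is.null(out)) readr::write_csv(tbl, stdout(), na = "")
        else write_studies(tbl, out)
      },
      report = {
        input <- cli_opt(args, "--input")
        tbl <- if (is.null(input)) load_table1() else load_table1(input)
        run_report(tbl, cli_params(args),
                   out_dir = cli_opt(args, "--out-dir", "."),
                   command = paste(c("report", args), collapse = " "),
                   input_path = if (is.null(input)) {
                     system.file("extdata", "table1.csv", package = "myoxalt")
                   } else input)
        message("report written to ", cli_opt(args, "--out-dir", "."))
      },
      stop("unknown subcommand: ", cmd, "\n", cli_usage(), call. = FALSE)
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
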