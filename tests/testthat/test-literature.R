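test_that("bundled study table loads with the expected rows and cells", {
  tbl <- load_table1()
  expect_equal(nrow(tbl), 29)
  expect_named(tbl, c("reference", "altitude_m", "hr_ratio", "sa_max_pct",
                      "hb_ratio", "days"))

  sutton <- dplyr::filter(tbl, grepl("Sutton", reference), altitude_m == 8840)
  expect_equal(nrow(sutton), 1)
  expect_equal(sutton$hr_ratio, 0.70)
  expect_equal(sutton$sa_max_pct, 49)
  expect_equal(sutton$hb_ratio, 1.26)

  moore <- dplyr::filter(tbl, grepl("Moore", reference))
  expect_equal(moore$altitude_m, 4350)
  expect_equal(moore$sa_max_pct, 82)
  expect_equal(moore$hb_ratio, 1.23)

  # missing cells are NA, never 0
  expect_true(anyNA(tbl$sa_max_pct))
  expect_false(any(tbl$sa_max_pct == 0, na.rm = TRUE))
  expect_false(any(tbl$hb_ratio == 0, na.rm = TRUE))

  # multi-altitude expeditions expanded one row per altitude
  expect_equal(sum(grepl("Sutton", tbl$reference)), 3)
  expect_equal(sum(grepl("Winslow", tbl$reference)), 3)

  expect_invisible(validate_studies(tbl))
})

test_that("loading is idempotent and write/reload is the identity", {
  tbl <- load_table1()
  expect_identical(tbl, load_table1())
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_studies(tbl, tmp)
  expect_equal(as.data.frame(load_table1(tmp)), as.data.frame(tbl))
})

test_that("malformed or absent study tables fail loudly", {
  expect_error(load_table1("no-such-file.csv"), "not found")

  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("reference,altitude_m,hr_ratio,sa_max_pct,hb_ratio,days",
               "ok,4000,0.9,80,1.2,10",
               "broken,4000,0.9,80,1.2,10,EXTRA,FIELDS"), tmp)
  expect_error(load_table1(tmp), "line")

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("reference,altitude_m", "x,4000"), tmp2)
  expect_error(load_table1(tmp2), "missing column")
})

test_that("range validation names every violating row", {
  bad <- dplyr::bind_rows(
    study_row("too low", altitude_m = 2500),
    study_row("bad hr", hr_ratio = 1.3),
    study_row("fine")
  )
  err <- expect_error(validate_studies(bad), "invalid study table")
  expect_match(conditionMessage(err), "row 1 \\(too low\\)")
  expect_match(conditionMessage(err), "row 2 \\(bad hr\\)")
  expect_no_match(conditionMessage(err), "fine")

  # missing values are not range violations
  ok <- study_row("has gaps", hr_ratio = NA, sa_max_pct = NA, hb_ratio = NA)
  expect_invisible(validate_studies(ok))
})

test_that("altitude trend fit matches the normal-equations oracle", {
  tbl <- load_table1()
  for (field in c("sa_max_pct", "hr_ratio")) {
    fit <- fit_altitude_trend(tbl, !!rlang::sym(field))
    g <- glance(fit)
    o <- ols_oracle(tbl$altitude_m, tbl[[field]])
    expect_equal(g$intercept, o$intercept, tolerance = 1e-9)
    expect_equal(g$slope, o$slope, tolerance = 1e-9)
    expect_equal(g$n_points, o$n)
    expect_equal(g$residual_sd, o$residual_sd, tolerance = 1e-9)
    expect_equal(g$r_squared, o$r_squared, tolerance = 1e-9)
    expect_gte(g$r_squared, 0)
    expect_lte(g$r_squared, 1)
  }
})

test_that("refitting the saturation column gives ~(111.1, -0.0070), not the canonical constants", {
  g <- glance(fit_altitude_trend(load_table1(), sa_max_pct))
  expect_equal(g$n_points, 17)
  expect_equal(g$intercept, 111.1274, tolerance = 1e-4)
  expect_equal(g$slope, -0.0070206, tolerance = 1e-4)
  # the canonical downstream defaults are deliberately not the refit
  p <- model_parameters()
  expect_gt(abs(g$intercept - p$samh_intercept_pct), 1)
  expect_gt(abs(g$slope - p$samh_slope_pct_per_m), 1e-4)
})

test_that("noiseless linear input is recovered exactly", {
  alt <- seq(3000, 9000, length.out = 12)
  d <- study_row(sprintf("s%02d", 1:12), altitude_m = alt,
                 sa_max_pct = 100 - 0.005 * alt)
  g <- suppressWarnings(glance(fit_altitude_trend(d, sa_max_pct)))
  expect_equal(g$slope, -0.005, tolerance = 1e-12)
  expect_equal(g$intercept, 100, tolerance = 1e-9)
  expect_equal(g$r_squared, 1, tolerance = 1e-12)
})

test_that("missing values are excluded, not imputed, and too few rows error", {
  alt <- c(3000, 4000, 5000, 6000, 7000)
  y <- 95 - 0.004 * alt + c(0.3, -0.2, 0.1, 0, -0.1)
  with_na <- study_row(sprintf("s%d", 1:7),
                       altitude_m = c(alt, 8000, 8500),
                       sa_max_pct = c(y, NA, NA))
  without <- with_na[1:5, ]
  g1 <- glance(fit_altitude_trend(with_na, sa_max_pct))
  g2 <- glance(fit_altitude_trend(without, sa_max_pct))
  expect_equal(g1$slope, g2$slope, tolerance = 1e-12)
  expect_equal(g1$intercept, g2$intercept, tolerance = 1e-12)
  expect_equal(g1$n_points, 5)

  expect_error(fit_altitude_trend(with_na[1:2, ], sa_max_pct),
               "insufficient data")
  expect_error(fit_altitude_trend(with_na, nonexistent), "column not found")
})

test_that("duplicate altitudes are kept as independent points", {
  d <- study_row(sprintf("s%d", 1:4),
                 altitude_m = c(4300, 4300, 6000, 8000),
                 sa_max_pct = c(80, 78, 65, 50))
  g <- glance(fit_altitude_trend(d, sa_max_pct))
  o <- ols_oracle(d$altitude_m, d$sa_max_pct)
  expect_equal(g$n_points, 4)
  expect_equal(g$slope, o$slope, tolerance = 1e-12)
})

test_that("summaries count present cells and report ranges", {
  s <- summarize_studies(load_table1())
  expect_equal(s$n_present[s$column == "sa_max_pct"], 17)
  expect_equal(s$n_present[s$column == "altitude_m"], 29)
  expect_equal(s$n_present[s$column == "hr_ratio"], 29)
  expect_equal(s$n_present[s$column == "hb_ratio"], 18)
  expect_equal(s$min[s$column == "altitude_m"], 3090)
  expect_equal(s$max[s$column == "altitude_m"], 8848)

  empty <- summarize_studies(load_table1()[0, ])
  expect_true(all(empty$n_present == 0))
  expect_true(all(is.na(empty$min)))

  one <- summarize_studies(study_row())
  expect_equal(one$min, one$max)
})

test_that("tidy() exposes coefficient-level statistics", {
  td <- tidy(fit_altitude_trend(load_table1(), sa_max_pct))
  expect_equal(nrow(td), 2)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_true(all(td$std.error > 0))
})
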