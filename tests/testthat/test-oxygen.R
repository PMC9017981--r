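test_that("dissociation transform returns P50 at half saturation and 0 at 0", {
  expect_equal(so2_to_po2(50), 29.11)
  expect_equal(so2_to_po2(0), 0)
  # frozen against direct high-precision evaluation of the Hill form
  expect_equal(so2_to_po2(30), 21.268830, tolerance = 1e-6)
  expect_equal(so2_to_po2(30), hill_po2_oracle(30), tolerance = 1e-12)
})

test_that("dissociation transform enforces its domain", {
  expect_error(so2_to_po2(100), "\\[0, 100\\)")
  expect_error(so2_to_po2(-1), "\\[0, 100\\)")
  expect_error(po2_to_so2(-0.1), "non-negative")
  expect_error(so2_to_po2(NA_real_), "NA")
})

test_that("saturation-pressure round trip is exact across the open interval", {
  s <- c(1e-6, 0.5, seq(1, 99, by = 0.5), 99.9, 100 - 1e-9)
  expect_equal(po2_to_so2(so2_to_po2(s)), s, tolerance = 1e-9)
  expect_equal(po2_to_so2(29.11), 50)
  expect_equal(po2_to_so2(0), 0)
  expect_equal(po2_to_so2(21.268830), 30, tolerance = 1e-5)
})

test_that("dissociation transform is strictly increasing", {
  s <- seq(0, 99.5, by = 0.5)
  expect_true(all(diff(so2_to_po2(s)) > 0))
  p <- seq(0, 120, by = 1)
  expect_true(all(diff(po2_to_so2(p)) > 0))
})

test_that("arterial saturation follows the altitude line and flags clipping", {
  expect_equal(as.numeric(samh_at_altitude(8848)), 49.2032)
  expect_equal(as.numeric(samh_at_altitude(6100)), 67.34)
  at0 <- samh_at_altitude(0)
  expect_equal(as.numeric(at0), 100)
  expect_true(attr(at0, "clipped"))
  mixed <- samh_at_altitude(c(0, 5000))
  expect_equal(attr(mixed, "clipped"), c(TRUE, FALSE))
  expect_error(samh_at_altitude(-10), "non-negative")
})

test_that("venous saturation reproduces the normoxic anchor and study rows", {
  p <- model_parameters()
  expect_equal(as.numeric(venous_saturation(98, 1, 1)), p$sv_normoxia_pct)
  # Sutton 8840 m row under both heart-rate hypotheses
  expect_equal(as.numeric(venous_saturation(49, 0.70, 1.26)),
               49 - 68 * 0.70 / 1.26, tolerance = 1e-12)
  expect_equal(as.numeric(venous_saturation(49, 0.70, 1.26)), 11.2222,
               tolerance = 1e-4)
  fixed <- venous_saturation(49, 1.0, 1.26)
  expect_equal(as.numeric(fixed), -4.9683, tolerance = 1e-4)
  expect_false(attr(fixed, "feasible"))
  expect_true(attr(venous_saturation(49, 0.70, 1.26), "feasible"))
})

test_that("venous saturation is monotone in each ratio and guards its domain", {
  sv_at <- function(...) as.numeric(venous_saturation(...))
  hr <- seq(0.6, 1.1, by = 0.1)
  expect_true(all(diff(sapply(hr, function(h) sv_at(70, h, 1.2))) < 0))
  hb <- seq(1.0, 1.5, by = 0.1)
  expect_true(all(diff(sapply(hb, function(h) sv_at(70, 0.9, h))) > 0))
  qq <- seq(0.8, 1.4, by = 0.1)
  expect_true(all(diff(sapply(qq, function(q) sv_at(70, 0.9, 1.2, q_ratio = q))) > 0))
  aa <- seq(0.8, 1.4, by = 0.1)
  expect_true(all(diff(sapply(aa, function(a) sv_at(70, 0.9, 1.2, a_ratio = a))) > 0))

  expect_error(venous_saturation(101, 1, 1), "\\[0, 100\\]")
  expect_error(venous_saturation(70, 0, 1), "positive")
  expect_error(venous_saturation(70, 1, -1), "positive")
})

test_that("maximal altitude matches the closed-form inversion and both constant sets", {
  expect_equal(max_altitude(0), 6202.0202, tolerance = 1e-4)
  expect_equal(max_altitude(20), 7632.9966, tolerance = 1e-4)
  # rounded reporting convention reproduces the headline altitudes
  expect_equal(round(max_altitude(c(0, 20)) / 100) * 100, c(6200, 7600))
  # the printed rounded constants give a slightly different curve
  expect_equal(max_altitude(0, use_printed_constants = TRUE), 6343)
  expect_no_error(max_altitude(-20))
  expect_error(max_altitude(-100), "greater than -100")
  # near-total loss of reserve pushes the required saturation above the
  # sea-level intercept: no feasible altitude
  expect_error(max_altitude(-99.99), "no feasible altitude")
  # a parameter set whose required saturation exceeds the intercept
  p_bad <- model_parameters(hb_ratio_ref = 0.5)
  expect_error(max_altitude(0, p_bad), "no feasible altitude")
})

test_that("required reserve reaches the Everest headline and floors at zero", {
  rr <- required_reserve(8848)
  expect_equal(round(as.numeric(rr), 1), 44.5)
  expect_false(attr(rr, "no_reserve_needed"))
  low <- required_reserve(4000)
  expect_equal(as.numeric(low), 0)
  expect_true(attr(low, "no_reserve_needed"))
  expect_error(required_reserve(16000), "no finite coronary reserve")
})

test_that("max_altitude and required_reserve are mutual inverses", {
  x <- seq(0, 100, by = 2.5)
  expect_equal(as.numeric(required_reserve(max_altitude(x))), x,
               tolerance = 1e-9)
  alt <- seq(max_altitude(0), 9500, by = 100)
  expect_equal(max_altitude(as.numeric(required_reserve(alt))), alt,
               tolerance = 1e-6)
  # strictly increasing curve
  expect_true(all(diff(max_altitude(x)) > 0))
})

test_that("maximal altitude is invariant to joint rescaling of the supply terms", {
  withr::local_seed(7)
  for (i in 1:20) {
    scale <- runif(1, 0.6, 1.6)
    hb0 <- runif(1, 1.0, 1.4)
    dq <- runif(1, 0, 80)
    base <- model_parameters(sv_normoxia_pct = 30, hb_ratio_ref = hb0)
    # multiply av_diff and hb_ratio_ref by the same factor: the balance
    # av_diff / (hb_ref * (1 + dq/100)) is unchanged
    scaled <- model_parameters(
      sv_normoxia_pct = base$sa_normoxia_pct -
        scale * base$av_diff_normoxia_pct,
      hb_ratio_ref = scale * hb0
    )
    expect_equal(max_altitude(dq, scaled), max_altitude(dq, base),
                 tolerance = 1e-9)
  }
})
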