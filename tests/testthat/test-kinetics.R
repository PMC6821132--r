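test_that("forward model reproduces known death-window scenarios", {
  # roundtrip of the fitted RGC clearance time: P1 count, pyknotic
  # fraction and 2.47 h visibility land on the P11 count
  expect_equal(predict_final_count(S = 200000, D = 0.005375,
                                   V = 2.47, n = 10),
               117000, tolerance = 1e-3)
  # zero death rate is the identity
  expect_identical(predict_final_count(26987, 0, 2.47, 9), 26987)
  # low apoptotic fraction with a plausible clearance time barely dents
  # the population (hand-stepped oracle: nine multiplications by 1 - d)
  d <- 0.000583 * 24 / 2.47
  oracle <- 26987
  for (i in 1:9) oracle <- oracle * (1 - d)
  expect_equal(predict_final_count(26987, 0.000583, 2.47, 9), oracle,
               tolerance = 1e-12)
  expect_equal(oracle, 25642, tolerance = 1e-4)
})

test_that("forward model rejects invalid regimes", {
  expect_error(predict_final_count(-5, 0.01, 2, 5), "positive")
  expect_error(predict_final_count(100, 0.01, -2, 5), "positive")
  expect_error(predict_final_count(100, 0.5, 1, 5), "valid regime")
  expect_error(predict_final_count(100, 1.0, 24, 5), "\\[0, 1\\)")
})

test_that("clearance-time inversion matches the printed fits", {
  # retinal ganglion cell validation fit
  expect_equal(round(solve_clearance_time(200000, 117000, 0.005375, 10), 2),
               2.47)
  # engulfment-sufficiency fit, in minutes
  expect_equal(
    round(60 * solve_clearance_time(26987, 6513, 0.00556, 9), 1),
    54.8
  )
  # microglia-free cannibalism scenario (direct formula oracle)
  oracle <- 24 * 0.0168 / (1 - (14247 / 30063)^(1 / 8))
  expect_equal(solve_clearance_time(30063, 14247, 0.0168, 8), oracle,
               tolerance = 1e-12)
  expect_equal(oracle, 4.52, tolerance = 2e-3)
  # the apoptosis-only permutation needs implausibly fast clearance
  v_apo <- solve_clearance_time(26987, 6513, 0.000583, 9)
  expect_equal(60 * v_apo, 5.7, tolerance = 0.02)
})

test_that("clearance-time inversion rejects degenerate inputs", {
  expect_error(solve_clearance_time(100, 100, 0.01, 5), "no decline")
  expect_error(solve_clearance_time(100, 120, 0.01, 5), "exceeds")
  expect_error(solve_clearance_time(100, 0, 0.01, 5), "positive")
  expect_error(solve_clearance_time(100, 50, 0, 5), "undefined")
})

test_that("tabular wrappers add clearance and decline columns", {
  out <- tibble::tibble(
    s = c(200000, 26987), n_t = c(117000, 6513),
    d = c(0.005375, 0.00556), n = c(10, 9)
  ) |> solve_clearance()
  expect_s3_class(out, "tbl_df")
  expect_equal(round(out$v_hours[1], 2), 2.47)
  expect_equal(round(out$v_minutes[2], 1), 54.8)
  expect_error(solve_clearance(tibble::tibble(s = 1)), "missing required")

  pred <- tibble::tibble(s = 26987, d = 0, v = 2.47, n = 9) |>
    predict_decline()
  expect_equal(pred$n_t, 26987)
})

test_that("loss projection steps the model day by day", {
  proj <- loss_projection(S = 26987, D = 0.0003, V = 2.47, n = 9)
  expect_s3_class(proj, "loss_projection")
  expect_equal(nrow(proj), 10)
  # day-stepping oracle
  d <- 0.0003 * 24 / 2.47
  counts <- 26987 * (1 - d)^(0:9)
  expect_equal(proj$count, counts, tolerance = 1e-12)
  expect_equal(proj$loss[-1], -diff(counts), tolerance = 1e-12)
  expect_equal(attr(proj, "mean_daily_loss"), (counts[1] - counts[10]) / 9)
  expect_equal(attr(proj, "mean_daily_loss"), 77.8, tolerance = 1e-3)
  expect_equal(counts[1] - counts[10], 700, tolerance = 1e-3)

  # degenerate cases: no death, one-day window
  expect_true(all(loss_projection(1000, 0, 2, 5)$loss[-1] == 0))
  one <- loss_projection(1000, 0.01, 24, 1)
  expect_equal(one$loss[2], 1000 * 0.01)
})

test_that("cumulative loss is the linearised mean-daily extrapolation", {
  proj <- loss_projection(26987, 0.0003, 2.47, 9)
  expect_equal(cumulative_loss(proj, 6),
               attr(proj, "mean_daily_loss") * 6)
  expect_equal(cumulative_loss(proj, 6), 466.5, tolerance = 1e-3)
  # the geometric alternative sums the model's own first-k losses
  expect_equal(cumulative_loss(proj, 6, method = "geometric"),
               26987 - predict_final_count(26987, 0.0003, 2.47, 6))
  # upper-bound dying fraction (hand-stepped then x6 oracle)
  proj_hi <- loss_projection(26987, 0.0006, 2.47, 9)
  expect_equal(cumulative_loss(proj_hi, 6), 922, tolerance = 1e-3)
  expect_equal(cumulative_loss(loss_projection(100, 0, 2, 5), 6), 0)
  expect_error(cumulative_loss(proj, 0), "positive")
})

test_that("visible-fraction estimate uses a two-sided t interval", {
  est <- estimate_visible_fraction(c(0, 0.001, 0.0005, 0.0009))
  # textbook t-interval oracle for n = 4: s^2 = 6.2e-7 / 3, half-width
  # t_{0.975,3} * s / 2 ~ 7.234e-4
  expect_equal(est$mean, 0.0006)
  half <- stats::qt(0.975, df = 3) * sqrt(6.2e-7 / 3) / 2
  expect_equal(half, 7.234e-4, tolerance = 1e-4)
  expect_equal(est$ci_low, 0.0006 - half, tolerance = 1e-12)
  expect_equal(est$ci_high, 0.0006 + half, tolerance = 1e-12)
  # identical samples collapse the interval
  same <- estimate_visible_fraction(rep(0.0003, 5))
  expect_equal(same$ci_low, 0.0003)
  expect_equal(same$ci_high, 0.0003)
  # vanishing confidence collapses to the mean
  tiny <- estimate_visible_fraction(c(0.1, 0.2, 0.3), confidence = 1e-12)
  expect_equal(tiny$ci_low, tiny$mean, tolerance = 1e-6)
  expect_error(estimate_visible_fraction(0.5), "at least 2")
  expect_error(estimate_visible_fraction(c(0.5, 1.2)), "\\[0, 1\\)")
})

test_that("corpse-density band propagates the dying-fraction interval", {
  est <- visible_fraction_estimate(mean = 0.0003, ci_low = 0.0002,
                                   ci_high = 0.0006)
  band <- corpse_density_band(S = 26987, V = 2.47, n = 9, estimate = est,
                              k = 6, area = 10)
  expect_equal(band$bound, c("low", "mid", "high"))
  expect_equal(band$density, c(31.2, 46.7, 92.2), tolerance = 1e-3)
  expect_true(all(diff(band$density) >= 0))
  # degenerate interval gives a zero-width band
  flat <- visible_fraction_estimate(0.0003, 0.0003, 0.0003)
  bf <- corpse_density_band(26987, 2.47, 9, flat, 6, 10)
  expect_equal(diff(range(bf$density)), 0)
  # density scales inversely with area
  half <- corpse_density_band(26987, 2.47, 9, est, 6, 20)
  expect_equal(half$density, band$density / 2)
  expect_error(visible_fraction_estimate(0.1, 0.2, 0.3), "ci_low <= mean")
})

test_that("tidiers summarise kinetic objects", {
  proj <- loss_projection(26987, 0.0003, 2.47, 9)
  g <- glance(proj)
  expect_equal(g$total_loss, proj$count[1] - proj$count[10])
  expect_equal(g$per_day_loss, 0.0003 * 24 / 2.47)
  td <- tidy(estimate_visible_fraction(c(0.1, 0.2)))
  expect_named(td, c("label", "n_samples", "mean", "ci_low", "ci_high",
                     "confidence"))
})
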