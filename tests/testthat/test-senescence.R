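# Decline splines, averaged profiles, crossing dates and senescence
# parameters.

test_that("the decline spline reproduces exactly linear data", {
  days <- seq(200, 300, 10)
  sizes <- 30 - 0.1 * (days - 200)
  sp <- fit_decline_spline(days, sizes)
  expect_equal(sp$fun(days), sizes, tolerance = 1e-6)
})

test_that("heavy smoothing approaches the least-squares line", {
  set.seed(9)
  days <- seq(200, 300, 5)
  sizes <- 20 * (1 + exp(0.1 * (days - 250)))^(-1) + rnorm(length(days), 0, 0.2)
  sp <- fit_decline_spline(days, sizes, spar = 1.5)
  line <- predict(lm(sizes ~ days), data.frame(days = days))
  expect_lt(max(abs(sp$fun(days) - line)), 0.05 * diff(range(sizes)))
})

test_that("with under four points the spline falls back to interpolation", {
  expect_warning(sp <- fit_decline_spline(c(200, 220, 240), c(10, 6, 2)),
                 "linear interpolation")
  expect_equal(sp$fun(210), 8)
  expect_error(fit_decline_spline(200, 10), "insufficient-data")
})

test_that("zero-noise daily decline spline matches the true fractions at the crossings", {
  tr <- make_truth(theta = 1.5)
  tj <- true_join_day(tr)
  days <- seq(ceiling(tj), 360, 1)
  sp <- fit_decline_spline(days, true_size(tr, days))
  for (q in c(0.95, 0.5, 0.25, 0.05)) {
    tq <- true_crossing(tr, q)
    expect_equal(sp$fun(tq) / tr$K_true, q, tolerance = 0.01)
  }
})

test_that("a single individual's profile equals its own normalized spline", {
  days <- seq(200, 300, 10)
  sizes <- 30 - 0.1 * (days - 200)
  sp <- fit_decline_spline(days, sizes)
  prof <- average_profile(list(sp))
  expect_equal(prof$mean_fraction,
               sp$fun(prof$grid_days) / max(sp$fun(prof$grid_days)),
               tolerance = 1e-9)
})

test_that("averaging is invariant to individual size scale", {
  days <- seq(200, 300, 10)
  shape <- (1 + exp(0.08 * (days - 250)))^(-1)
  p1 <- average_profile(list(fit_decline_spline(days, 10 * shape),
                             fit_decline_spline(days, 20 * shape)))
  p2 <- average_profile(list(fit_decline_spline(days, 10 * shape)))
  expect_equal(p1$mean_fraction, p2$mean_fraction, tolerance = 1e-9)
})

test_that("two linear declines average to the midpoint crossing", {
  d1 <- seq(200, 280, 10)
  d2 <- seq(220, 300, 10)
  sp1 <- fit_decline_spline(d1, 10 * (280 - d1) / 80)
  sp2 <- fit_decline_spline(d2, 20 * (300 - d2) / 80)
  prof <- average_profile(list(sp1, sp2))
  expect_equal(crossing_date(prof, 0.5, "first"), 250, tolerance = 0.2)
})

test_that("crossing dates of a linear profile match the closed form", {
  prof <- linear_profile(200, 300)
  expect_equal(crossing_date(prof, 0.50, "first"), 250, tolerance = 0.1)
  expect_equal(crossing_date(prof, 0.95, "last"), 205, tolerance = 0.1)
  expect_equal(crossing_date(prof, 0.05, "first"), 295, tolerance = 0.1)
})

test_that("non-monotone dips are honoured by first/last crossing modes", {
  # dip to 0.4, recovery to 0.8, then final decline; brute-force scan oracle
  grid <- 200:320
  f <- c(seq(1, 0.4, length.out = 31), seq(0.4, 0.8, length.out = 31)[-1],
         seq(0.8, 0, length.out = 61)[-1])
  prof <- senescence_profile(grid, f)
  first50 <- crossing_date(prof, 0.5, "first")
  last95 <- crossing_date(prof, 0.95, "last")
  scan_first <- grid[min(which(f <= 0.5))]
  expect_lt(abs(first50 - scan_first), 2)
  expect_lt(first50, 230)          # inside the dip
  expect_lt(last95, 210)           # before the dip
  # recovery never regains 95%, so "last" stays on the first limb
  expect_true(all(f[grid > 230 & grid < 260] < 0.95))
})

test_that("profiles that never fall to 25% are flagged as overwintering", {
  grid <- 200:300
  prof <- senescence_profile(grid, 1 - 0.5 * (grid - 200) / 100)
  expect_true(is.na(crossing_date(prof, 0.25, "first")))
  expect_true(prof$overwinters)
  p <- extract_senescence_params(prof)
  expect_true(is.na(p$season_end))
  expect_true(p$overwinters)
})

test_that("linear decline yields pace 1/90 and shape 0", {
  p <- extract_senescence_params(linear_profile(200, 300))
  expect_equal(p$sen_date, 250, tolerance = 0.1)
  expect_equal(p$sen_pace, 1 / 90, tolerance = 0.002 / 90 * 90)
  expect_equal(p$c_days, 45, tolerance = 0.2)
  expect_equal(p$d_days, 45, tolerance = 0.2)
  expect_equal(p$sen_shape, 0, tolerance = 0.01)
  expect_equal(p$season_end, 275, tolerance = 0.1)
})

test_that("a symmetric Richards decline reproduces its closed-form crossings", {
  grid <- 150:350
  prof <- senescence_profile(grid, (1 + exp(0.1 * (grid - 250)))^(-1))
  p <- extract_senescence_params(prof)
  expect_equal(prof$crossings[["0.95"]], 220.6, tolerance = 0.1)
  expect_equal(prof$crossings[["0.05"]], 279.4, tolerance = 0.1)
  expect_equal(p$sen_pace, 1 / 58.89, tolerance = 0.003)
  expect_equal(p$sen_shape, 0, tolerance = 0.01)
})

test_that("time shifts move dates and leave pace and shape unchanged", {
  p0 <- extract_senescence_params(linear_profile(200, 300))
  p10 <- extract_senescence_params(linear_profile(210, 310))
  expect_equal(p10$sen_date, p0$sen_date + 10, tolerance = 0.1)
  expect_equal(p10$season_end, p0$season_end + 10, tolerance = 0.1)
  expect_equal(p10$sen_pace, p0$sen_pace, tolerance = 1e-9)
  expect_equal(p10$sen_shape, p0$sen_shape, tolerance = 1e-9)
})

test_that("senescence parameters are invariant to a global size rescaling", {
  set.seed(12)
  days <- seq(180, 350, 14)
  sizes <- 15 * (1 + exp(0.09 * (days - 255)))^(-1.4) *
    exp(rnorm(length(days), 0, 0.03))
  p1 <- extract_senescence_params(
    average_profile(list(fit_decline_spline(days, sizes))))
  p2 <- extract_senescence_params(
    average_profile(list(fit_decline_spline(days, 7.3 * sizes))))
  expect_equal(p1[, c("sen_date", "sen_pace", "sen_shape", "season_end")],
               p2[, c("sen_date", "sen_pace", "sen_shape", "season_end")],
               tolerance = 1e-9)
})

test_that("recovered shape sign tracks the decline asymmetry theta", {
  for (theta in c(0.3, 1, 3)) {
    tr <- make_truth(theta = theta)
    tj <- true_join_day(tr)
    # observe far enough for the 5% crossing (days continue past Dec 31)
    days <- seq(ceiling(tj), ceiling(true_crossing(tr, 0.02)), 1)
    prof <- average_profile(list(fit_decline_spline(days,
                                                    true_size(tr, days))))
    p <- extract_senescence_params(prof)
    true_shape <- log((true_crossing(tr, 0.05) - true_crossing(tr, 0.5)) /
                        (true_crossing(tr, 0.5) - true_crossing(tr, 0.95)))
    if (abs(true_shape) > 1e-6)
      expect_identical(sign(p$sen_shape), sign(true_shape))
    else expect_lt(abs(p$sen_shape), 0.05)
  }
})

test_that("the flipped shape convention negates the log-ratio", {
  tr <- make_truth(theta = 3)
  days <- seq(ceiling(true_join_day(tr)), 365, 1)
  prof <- average_profile(list(fit_decline_spline(days,
                                                  true_size(tr, days))))
  expect_equal(extract_senescence_params(prof, flip_shape = TRUE)$sen_shape,
               -extract_senescence_params(prof)$sen_shape,
               tolerance = 1e-12)
})
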