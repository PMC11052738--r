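test_that("noiseless mono-exponential data are recovered exactly", {
  # hand-constructed exact curve: A0 = 1, T_eff = 1 h
  tac <- time_activity_curve("S", "r", c(1, 2, 4), c(0.5, 0.25, 0.0625))
  fit <- fit_monoexponential(tac)
  expect_equal(fit$amplitude_A0, 1, tolerance = 1e-6)
  expect_equal(fit$half_life_eff_h, 1, tolerance = 1e-6)
  expect_equal(fit$lambda_eff_per_h * fit$half_life_eff_h, log(2))

  # randomized noiseless curves, both weightings, 6 significant figures
  set.seed(42)
  for (i in 1:10) {
    A0 <- runif(1, 0.001, 0.5); Tf <- runif(1, 0.3, 5)
    cu <- monoexp_curve(A0, Tf)
    for (w in c("uniform", "relative")) {
      f <- fit_monoexponential(cu, weighting = w)
      expect_equal(f$amplitude_A0, A0, tolerance = 1e-6)
      expect_equal(f$half_life_eff_h, Tf, tolerance = 1e-6)
    }
  }
})

test_that("two-point curves are solved in closed form", {
  # mean kidney uptakes 1.3 %ID at 1 h, 0.44 %ID at 4 h
  tac <- time_activity_curve("S", "kidneys", c(1, 4), c(0.013, 0.0044))
  fit <- fit_monoexponential(tac)
  t_oracle <- 3 * log(2) / log(0.013 / 0.0044)  # closed two-point solution
  expect_equal(fit$half_life_eff_h, t_oracle)
  expect_equal(t_oracle, 1.92, tolerance = 0.005)
  expect_identical(fit$method, "closed-form")
})

test_that("fit matches a brute-force grid-search oracle on noisy data", {
  A0 <- 0.02; Tf <- 2.6; times <- c(0.5, 1, 2, 4)
  set.seed(11)
  scale <- 1e5  # expected counts at A0
  frac <- rpois(length(times), A0 * exp(-log(2) / Tf * times) * scale) / scale
  tac <- time_activity_curve("S", "r", times, frac)
  fit <- fit_monoexponential(tac)

  # independent oracle: dense grid over (A0, T_eff), same objective
  a_grid <- seq(0.5 * A0, 1.5 * A0, length.out = 201)
  t_grid <- seq(1, 5, length.out = 401)
  ss <- outer(a_grid, t_grid, Vectorize(function(a, tt)
    sum((frac - a * exp(-log(2) / tt * times))^2)))
  best <- arrayInd(which.min(ss), dim(ss))
  expect_lte(sum((frac - fit$amplitude_A0 *
                    exp(-fit$lambda_eff_per_h * times))^2),
             min(ss) + 1e-15)
  expect_equal(fit$half_life_eff_h, t_grid[best[2]],
               tolerance = 2 * diff(t_grid[1:2]) / t_grid[best[2]])
})

test_that("degenerate and non-positive inputs are handled", {
  expect_error(fit_monoexponential(
    time_activity_curve("S", "r", 1, 0.5)), "2 samples")
  expect_error(time_activity_curve("S", "r", c(1, 1), c(0.5, 0.4)),
               "duplicate")
  # a zero sample still fits through the positive-sample initialisation
  tac <- time_activity_curve("S", "r", c(0.5, 1, 2, 4),
                             c(0.4, 0.2, 0.05, 0))
  fit <- fit_monoexponential(tac)
  expect_gt(fit$amplitude_A0, 0)
  expect_gt(fit$half_life_eff_h, 0)
  # fewer than 2 positive samples falls back to the grid initialisation
  start <- mirddose:::.monoexp_start(c(0.5, 1, 2, 4), c(0.3, 0, 0, 0))
  expect_gt(start$A0, 0)
  expect_gt(start$lambda, 0)
})

test_that("rescaling a curve rescales A0 and leaves T_eff unchanged", {
  set.seed(7)
  cu <- monoexp_curve(0.05, 1.8)
  noisy <- time_activity_curve("S", "r", cu$time_h,
                               cu$fraction_id * (1 + rnorm(4, 0, 0.03)))
  f1 <- fit_monoexponential(noisy)
  scaled <- time_activity_curve("S", "r", noisy$time_h,
                                noisy$fraction_id * 0.25)
  f2 <- fit_monoexponential(scaled)
  expect_equal(f2$amplitude_A0, 0.25 * f1$amplitude_A0, tolerance = 1e-6)
  expect_equal(f2$half_life_eff_h, f1$half_life_eff_h, tolerance = 1e-6)
})

test_that("TIAC equals the analytic and quadrature integrals", {
  # A0 = 1, T_eff = ln2 -> TIAC exactly 1 h
  f <- fit_monoexponential(monoexp_curve(1, log(2), times = c(0.1, 0.5, 1)))
  expect_equal(tiac_from_fit(f), 1, tolerance = 1e-6)

  # quadrature oracle on randomized fits, 0.1%
  set.seed(3)
  for (i in 1:10) {
    f <- fit_monoexponential(monoexp_curve(runif(1, 0.01, 1),
                                           runif(1, 0.5, 5)))
    q <- integrate(function(t) f$amplitude_A0 * exp(-f$lambda_eff_per_h * t),
                   0, 50 * f$half_life_eff_h, rel.tol = 1e-9)$value
    expect_equal(tiac_from_fit(f), q, tolerance = 1e-3)
  }
})

test_that("TIAC is strictly increasing in A0 and T_eff", {
  base <- tiac_from_fit(fit_monoexponential(monoexp_curve(0.02, 2.6)))
  up_a <- tiac_from_fit(fit_monoexponential(monoexp_curve(0.03, 2.6)))
  up_t <- tiac_from_fit(fit_monoexponential(monoexp_curve(0.02, 3.1)))
  expect_gt(up_a, base)
  expect_gt(up_t, base)
})

test_that("back-extrapolation follows the closed form", {
  expect_equal(back_extrapolate(0.5, 1, 1), 1)
  expect_equal(back_extrapolate(0.013, 1, 2.6), 0.013 * 2^(1 / 2.6))
  expect_equal(back_extrapolate(0.013, 1, 2.6), 0.01697, tolerance = 1e-3)
  expect_equal(back_extrapolate(0.2, 0, 3.3), 0.2)  # identity at t = 0
  expect_error(back_extrapolate(0.1, 1, -2), "positive")
})

test_that("biological half-life decomposes the effective half-life", {
  cst <- decay_constants()
  expect_equal(biological_half_life(2, cst),
               1 / (1 / 2 - 1 / cst$t_phys_h))
  expect_equal(biological_half_life(2, cst), 3.00, tolerance = 0.002)
  expect_equal(biological_half_life(cst$t_phys_h / 2, cst), cst$t_phys_h)
  # monotone increasing towards the physical half-life
  ts <- seq(1, cst$t_phys_h - 0.1, length.out = 20)
  expect_true(all(diff(sapply(ts, biological_half_life, cst)) > 0))
  expect_error(biological_half_life(cst$t_phys_h, cst), "biological")
})

test_that("TAC CSV round trip preserves curves", {
  f <- tempfile(fileext = ".csv")
  df <- rbind(
    data.frame(subject_id = "P1", region_id = "kidneys",
               time_h = c(1, 2, 4), fraction_id = c(0.013, 0.009, 0.0044)),
    data.frame(subject_id = "P1", region_id = "liver",
               time_h = c(1, 2, 4), fraction_id = c(0.02, 0.015, 0.008)))
  write.csv(df, f, row.names = FALSE)
  curves <- read_tac_csv(f)
  expect_length(curves, 2)
  expect_s3_class(curves[["P1|kidneys"]], "time_activity_curve")
  expect_equal(curves[["P1|kidneys"]]$fraction_id, c(0.013, 0.009, 0.0044))
  unlink(f)
})
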