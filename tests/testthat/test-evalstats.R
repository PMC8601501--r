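test_that("days after planting honors the calendar, including leap years", {
  expect_equal(days_after_planting("2014-09-25", "2015-02-22"), 150)
  expect_equal(days_after_planting("2015-09-24", "2016-04-22"), 211)
  expect_equal(days_after_planting("2016-09-27", "2016-09-27"), 0)
  expect_error(days_after_planting("2015-01-01", "2014-12-31"), "precedes")
})

test_that("perfect agreement yields zero errors and d = 1", {
  st <- fit_statistics(c(150, 149, 140), c(150, 149, 140))
  expect_equal(st$RMSE, 0)
  expect_equal(st$nRMSE, 0)
  expect_equal(st$ME, 0)
  expect_equal(st$d, 1)
  # identical constant series: degenerate denominator, d defined as 1
  expect_equal(fit_statistics(c(5, 5), c(5, 5))$d, 1)
})

test_that("reference calibration statistics reproduce from observed days", {
  seasons <- canola_seasons()
  cal <- seasons[seasons$role == "calibration", ]
  obs <- days_after_planting(cal$sowing_date, cal$anthesis_date)
  expect_equal(obs, c(150, 149))
  st <- fit_statistics(obs, obs + c(3, 2))
  expect_equal(round(st$RMSE, 2), 2.55)
  expect_equal(round(st$nRMSE, 2), 1.71)
  expect_equal(st$ME, 2.5)
  expect_equal(round(st$rME, 2), 1.67)

  norm <- normalize_fit_stats(1109.87, -1075, c(13293, 9757))
  expect_equal(round(norm$nRMSE, 2), 9.63)
  expect_equal(round(norm$rME, 2), -9.33)
})

test_that("integer error reconstruction inverts printed RMSE/ME pairs", {
  expect_equal(reconstruct_errors(2.55, 2.50, 2), c(2L, 3L))
  expect_equal(reconstruct_errors(3.16, 3.00, 2), c(2L, 4L))
  expect_equal(reconstruct_errors(2.08, 1.67, 3), c(0L, 2L, 3L))
  expect_equal(reconstruct_errors(2.16, 2.00, 3), c(1L, 2L, 3L))
  expect_null(reconstruct_errors(1.00, 5.00, 2))  # inconsistent pair
})

test_that("RMSE dominates |ME| and d is shift invariant", {
  set.seed(3)
  for (i in 1:25) {
    o <- rnorm(sample(2:8, 1), 100, 20)
    s <- o + rnorm(length(o), 0, 10)
    st <- fit_statistics(o, s)
    expect_gte(st$RMSE, abs(st$ME) - 1e-12)
    st2 <- fit_statistics(o + 37.5, s + 37.5)
    expect_equal(st2$d, st$d, tolerance = 1e-12)
  }
  expect_warning(fit_statistics(c(-1, 1), c(0, 0)), "zero")
  expect_error(fit_statistics(1:3, 1:2), "differ")
})

test_that("calibration objective is zero at truth and recovers EM-FL", {
  w1 <- wuhan_weather(seed = 11, days = 200)
  w2 <- wuhan_weather(seed = 12, days = 200)
  model <- make_season_model(list(w1, w2))
  truth <- canola_defaults()
  truth[["EM-FL"]] <- 34
  obs <- generate_observations(truth, list(w1, w2), seed = 1)
  seasons <- data.frame(adap = obs$adap, mdap = obs$mdap,
                        yield = obs$yield, biomass = obs$biomass)
  expect_equal(calibration_objective(truth, seasons, model), 0,
               tolerance = 1e-12)
  grid <- seq(24, 44, by = 2)
  res <- calibrate_grid(seasons, model, "EM-FL", grid, truth)
  expect_lte(abs(res$best - 34), 2)   # within one grid step
  # loss increases away from the recovered optimum over the bracketing grid
  lo <- res$losses$loss
  i0 <- which.min(lo)
  expect_true(all(diff(lo[i0:length(lo)]) >= -1e-9))
  expect_true(all(diff(rev(lo[1:i0])) >= -1e-9))
  bad_model <- function(p) stop("sim crashed")
  expect_warning(l <- calibration_objective(truth, seasons, bad_model),
                 "failure")
  expect_identical(l, Inf)
})

test_that("evaluation table mirrors the season-record layout", {
  seasons <- canola_seasons()
  sim <- data.frame(
    adap = days_after_planting(seasons$sowing_date, seasons$anthesis_date),
    mdap = days_after_planting(seasons$sowing_date, seasons$maturity_date),
    hwam = seasons$yield_kg_ha, cwam = seasons$biomass_kg_ha)
  tab <- evaluation_table(seasons, sim)
  expect_equal(nrow(tab), 8)   # 4 attributes x 2 periods
  expect_true(all(tab$RMSE == 0))
  expect_true(all(tab$d == 1))
  expect_equal(tab$N[tab$period == "evaluation"], rep(3, 4))
})
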