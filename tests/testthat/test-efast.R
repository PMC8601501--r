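test_that("design obeys the spectral frequency rules", {
  d <- efast_design(unit_pars(3), M = 4, Ns = 65, seed = 1)
  expect_equal(d$omega_max, 8)
  expect_equal(unname(d$freq[1, 1]), 8L)
  expect_true(all(d$freq[1, -1] == 1L))  # floor(8/8) = 1 admissible frequency

  d35 <- efast_design(canola_parameters(), M = 4, Ns = 129, seed = 1)
  expect_equal(d35$omega_max, 16)
  expect_equal(d35$total_runs, 4515)
  expect_true(all(d35$freq[2, -2] <= d35$omega_max %/% (2 * 4)))
  # Ns >= 2*M*omega_max + 1 by construction
  expect_true(d35$Ns >= 2 * 4 * d35$omega_max + 1)

  expect_error(efast_design(unit_pars(3), Ns = 64), "odd")
  expect_error(efast_design(unit_pars(1), Ns = 65), "at least 2")
  expect_error(efast_design(unit_pars(3), M = 4, Ns = 7), "too small")
})

test_that("search-curve sampling matches the arcsine transform and bounds", {
  pars <- param_table(data.frame(name = c("SLLL", "other"),
                                 lower = c(0.055, 10), upper = c(0.123, 20)))
  d <- efast_design(pars, Ns = 65, seed = 2)
  s <- efast_sample(d)
  expect_true(all(s$X[, "SLLL"] >= 0.055 & s$X[, "SLLL"] <= 0.123))
  expect_true(all(s$X[, "other"] >= 10 & s$X[, "other"] <= 20))

  # independent recomputation of one block from the declared transform
  sgrid <- -pi + 2 * pi * seq_len(65) / 65
  for (j in 1:2) {
    g <- 0.5 + asin(sin(d$freq[1, j] * sgrid + d$phases[1, j])) / pi
    expect_equal(unname(s$X[1:65, j]),
                 pars$lower[j] + (pars$upper[j] - pars$lower[j]) * g)
  }
  # the driving factor traverses its full range within its own block
  drv <- s$X[s$block$driver == "SLLL", "SLLL"]
  expect_lt(min(drv), 0.056)
  expect_gt(max(drv), 0.122)
})

test_that("sampled marginals are uniform and sampling is deterministic", {
  d <- efast_design(unit_pars(3), Ns = 1025, seed = 5)
  s <- efast_sample(d)
  x_drv <- s$X[s$block$driver == "x1", "x1"]
  x_cmp <- s$X[s$block$driver == "x1", "x2"]
  expect_lt(suppressWarnings(ks.test(x_drv, punif))$statistic, 0.05)
  expect_lt(suppressWarnings(ks.test(x_cmp, punif))$statistic, 0.05)

  s2 <- efast_sample(efast_design(unit_pars(3), Ns = 1025, seed = 5))
  expect_identical(s$X, s2$X)   # bit-identical under the same seed
  s3 <- efast_sample(efast_design(unit_pars(3), Ns = 1025, seed = 6))
  expect_false(identical(s$X, s3$X))
})

test_that("indices recover analytic first-order variance shares", {
  fit <- efast(linear_fn(c(1, 2)), unit_pars(2), Ns = 1025, seed = 1)
  expect_equal(fit$indices$Si, c(0.2, 0.8), tolerance = 0.03 / 0.8)
  expect_equal(fit$indices$STi, fit$indices$Si, tolerance = 0.05)
  # additive model: first-order shares sum to one
  fit4 <- efast(linear_fn(c(1, 2, 3, 4)), unit_pars(4), Ns = 1025, seed = 2)
  expect_gt(sum(fit4$indices$Si), 0.95)
  expect_lt(sum(fit4$indices$Si), 1.05)
})

test_that("indices match the Ishigami closed form", {
  tru <- ishigami_true()
  fit <- efast(ishigami_fn(), ishigami_pars, Ns = 1025, Nr = 2, seed = 1)
  si <- fit$indices$Si; sti <- fit$indices$STi
  expect_equal(si[1], tru$S1, tolerance = 0.05 / tru$S1)
  expect_equal(si[2], tru$S2, tolerance = 0.05 / tru$S2)
  expect_lt(abs(si[3] - 0), 0.05)
  expect_lt(abs(sti[3] - tru$ST3), 0.05)
})

test_that("degenerate constant output is flagged, not silently zeroed", {
  d <- efast_design(unit_pars(2), Ns = 65, seed = 1)
  fit <- efast_indices(d, rep(3.7, d$total_runs))
  expect_true(length(fit$degenerate) > 0)
  expect_true(all(is.na(fit$indices$Si)))
})

test_that("indices are affine invariant in the output", {
  d <- efast_design(unit_pars(3), Ns = 257, seed = 3)
  s <- efast_sample(d)
  y <- s$X[, 1] + 2 * s$X[, 2] * s$X[, 3]
  f1 <- efast_indices(d, y)
  f2 <- efast_indices(d, -4.2 * y + 17)
  expect_equal(f1$indices$Si, f2$indices$Si, tolerance = 1e-12)
  expect_equal(f1$indices$STi, f2$indices$STi, tolerance = 1e-12)
})

test_that("total-order never falls materially below first-order", {
  d <- efast_design(unit_pars(3), Ns = 513, seed = 4)
  s <- efast_sample(d)
  cases <- list(
    s$X[, 1] + 2 * s$X[, 2] + 3 * s$X[, 3],
    s$X[, 1] * s$X[, 2] + s$X[, 3]^2,
    sin(2 * pi * s$X[, 1]) + s$X[, 2] * s$X[, 3])
  for (y in cases) {
    f <- efast_indices(d, y)
    expect_true(all(f$indices$STi >= f$indices$Si - 0.02))
  }
})

test_that("failed model rows invalidate their whole block", {
  d <- efast_design(unit_pars(2), Ns = 65, seed = 1)
  s <- efast_sample(d)
  y <- s$X[, 1] + s$X[, 2]
  y[3] <- NA   # one bad run in block 1
  fit <- efast_indices(d, y)
  expect_length(fit$incomplete, 1)
  expect_true(is.na(fit$indices$Si[1]))
  expect_false(is.na(fit$indices$Si[2]))
  expect_error(efast_indices(d, y[-1]), "rows")

  flaky <- function(x) if (x[["x1"]] < 0.1) stop("boom") else c(y = x[["x1"]])
  fit2 <- efast(flaky, unit_pars(2), Ns = 65, seed = 1)
  expect_true(length(fit2$incomplete) > 0)
  expect_error(efast(flaky, unit_pars(2), Ns = 65, seed = 1,
                     on_failure = "error"), "failed")
})

test_that("artifacts round-trip through delimited text", {
  td <- withr::local_tempdir()
  fit <- efast(linear_fn(c(1, 2)), unit_pars(2), Ns = 65, seed = 1,
               artifact_dir = td)
  expect_true(file.exists(file.path(td, "sample_matrix.csv")))
  sm <- read.csv(file.path(td, "sample_matrix.csv"))
  expect_equal(nrow(sm), fit$design$total_runs)
  idx <- read.csv(file.path(td, "sensitivity_indices.csv"))
  expect_equal(idx$Si, fit$indices$Si, tolerance = 1e-12)
})
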