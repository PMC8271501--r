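test_that("environmental factors respect their configured bounds and are finite", {
  for (preset in c("dataset1", "dataset2", "dataset3")) {
    spec <- climate_preset(preset)
    env <- simulate_environment(spec, 365, seed = 7)
    expect_true(all(is.finite(env)))
    for (f in colnames(env)) {
      expect_gte(min(env[, f]), spec[[f]]$min)
      expect_lte(max(env[, f]), spec[[f]]$max)
    }
  }
  # temperature of the first preset stays inside its recorded extremes
  spec1 <- climate_preset("dataset1")
  env1 <- simulate_environment(spec1, 365, seed = 99)
  expect_true(all(env1[, "temperature"] >= 4.73 & env1[, "temperature"] <= 23.73))
})

test_that("noiseless limit reduces to the closed-form seasonal sinusoid", {
  fs <- factor_spec(min = -100, max = 100, mean = 10, sd = 1,
                    amplitude = 5, phi = 0, noise_sd = 0, peak_day = 181)
  spec <- climate_preset("dataset1")
  spec$temperature <- fs
  env <- simulate_environment(spec, 50, seed = 1)
  d <- 0:49
  expect_equal(env[, "temperature"], 10 + 5 * cos(2 * pi * (d - 181) / 365),
               tolerance = 1e-12)
})

test_that("simulation is deterministic under a seed and varies across seeds", {
  spec <- climate_preset("dataset1")
  expect_identical(simulate_environment(spec, 100, seed = 3),
                   simulate_environment(spec, 100, seed = 3))
  expect_false(identical(simulate_environment(spec, 100, seed = 3),
                         simulate_environment(spec, 100, seed = 4)))
  gs1 <- simulate_greenhouse(n_days = 365, seed = 11)
  gs2 <- simulate_greenhouse(n_days = 365, seed = 11)
  expect_identical(as.data.frame(gs1), as.data.frame(gs2))
  gs3 <- simulate_greenhouse(n_days = 365, seed = 12)
  expect_false(identical(gs1$yield, gs3$yield))
  expect_identical(names(gs3), names(gs1))
})

test_that("accumulated yield is non-decreasing, zero before onset, flat after saturation", {
  spec <- yield_spec(onset_day = 60, saturation_day = 330)
  for (seed in 1:20) {
    gs <- simulate_greenhouse(growth = spec, n_days = 365, seed = seed)
    y <- gs$yield
    expect_true(all(diff(y) >= 0))
    expect_true(all(y[1:60] == 0))  # days 0..59 precede onset
    expect_true(all(diff(y[332:365]) == 0))
    expect_true(all(is.finite(y)))
  }
})

test_that("null growth and the noiseless closed form of total yield", {
  climate <- simulate_environment(climate_preset("dataset1"), 365, seed = 5)
  null_spec <- yield_spec(base = 0, beta = c(radiation = 0), noise_sd = 0)
  expect_true(all(simulate_yield(climate, null_spec, seed = 1) == 0))

  const_spec <- yield_spec(onset_day = 60, saturation_day = 330, base = 8,
                           beta = c(radiation = 0), noise_sd = 0)
  y <- simulate_yield(climate, const_spec, seed = 1)
  expect_equal(y[365], 8 * (330 - 60), tolerance = 1e-9)
  # small-noise Monte Carlo mean converges to the same closed form
  finals <- vapply(1:30, function(s) {
    sp <- yield_spec(onset_day = 60, saturation_day = 330, base = 8,
                     beta = c(radiation = 0), noise_sd = 0.01)
    simulate_yield(climate, sp, seed = s)[365]
  }, numeric(1))
  expect_equal(mean(finals), 8 * (330 - 60), tolerance = 1e-3)
})

test_that("with no season and no autocorrelation sample moments match the spec", {
  fs <- factor_spec(min = -1000, max = 3000, mean = 700, sd = 150,
                    amplitude = 0, phi = 0, noise_sd = 150)
  spec <- climate_preset("dataset1")
  spec$co2 <- fs
  env <- simulate_environment(spec, 10000, seed = 21)
  x <- env[, "co2"]
  se_mean <- 150 / sqrt(10000)
  expect_lt(abs(mean(x) - 700), 3 * se_mean)
  se_sd <- 150 / sqrt(2 * (10000 - 1))
  expect_lt(abs(sd(x) - 150), 3 * se_sd)
})

test_that("preset envelopes: low-CO2 greenhouse stays lowest, sample mean near target", {
  means <- vapply(c("dataset1", "dataset2", "dataset3"), function(p) {
    env <- simulate_environment(climate_preset(p), 365, seed = 31)
    mean(env[, "co2"])
  }, numeric(1))
  expect_identical(names(which.min(means)), "dataset2")

  # dataset2 CO2: AR(1)-adjusted standard error of a 365-day mean
  spec <- climate_preset("dataset2")$co2
  phi <- spec$phi
  se <- spec$sd * sqrt((1 + phi) / (1 - phi)) / sqrt(365)
  expect_lt(abs(means[["dataset2"]] - 624.19), 3 * se)
})

test_that("a simulated year matches the pipeline CSV schema", {
  gs <- simulate_greenhouse(n_days = 365, seed = 2)
  expect_s3_class(gs, "greenhouse_series")
  expect_identical(dim(as.data.frame(gs)), c(365L, 7L))
  expect_identical(names(gs), c("day", greenhouse_factors()))
  path <- withr::local_tempfile(fileext = ".csv")
  write_greenhouse_csv(gs, path)
  expect_identical(readLines(path, n = 1L),
                   "day,yield,co2,temperature,humidity_deficit,relative_humidity,radiation")
})

test_that("specification validation rejects impossible settings", {
  expect_error(factor_spec(5, 5, 5, 1), "min < max")
  expect_error(factor_spec(0, 10, 20, 1), "inside")
  expect_error(factor_spec(0, 10, 5, 1, phi = 1), "phi")
  expect_error(yield_spec(onset_day = 100, saturation_day = 50), "precede")
  expect_error(yield_spec(beta = c(moonlight = 1)), "unknown beta")
  expect_error(simulate_yield(matrix(1, 3, 1), yield_spec(), 1), "driver")
})
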