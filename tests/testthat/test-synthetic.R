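# Benchmark generators and the reference-vs-surrogate experiment.

test_that("Lorenz equilibria behave as fixed points of the integrator", {
  # the origin is an exact equilibrium
  x0 <- simulate_lorenz(n = 50, burn_in = 0, init = c(0, 0, 0))
  expect_true(all(abs(x0) < 1e-8))
  # the nontrivial fixed point (sqrt(b(c-1)), sqrt(b(c-1)), c-1) = sqrt(72)...
  fp <- c(sqrt(72), sqrt(72), 27)
  xfp <- simulate_lorenz(n = 30, burn_in = 0, init = fp)
  expect_true(all(abs(xfp - sqrt(72)) < 1e-3))   # unstable: short horizon only
})

test_that("Lorenz sampling converges in tolerance and stays bounded", {
  init <- c(3.1, -1.2, 22.4)
  xa <- simulate_lorenz(n = 1000, burn_in = 0, init = init, tol = 1e-10)
  xb <- simulate_lorenz(n = 1000, burn_in = 0, init = init, tol = 5e-11)
  # chaotic divergence caps the honest comparison horizon: ~8 Lyapunov times
  expect_lt(max(abs(xa[1:30] - xb[1:30])), 1e-6)
  expect_true(all(abs(xa) < 25))
})

test_that("noiseless Lorenz x std is near its long-run value already at 2e4 samples", {
  x <- simulate_lorenz(n = 20000, seed = 4)
  expect_equal(sd(x), 7.9252822, tolerance = 0.02)
})

test_that("observational noise scales with the pinned attractor std", {
  x <- simulate_lorenz(n = 20000, eta = 10, seed = 6)   # noise-dominated
  expect_equal(sd(x), sqrt(1 + 10^2) * 7.9252822, tolerance = 0.05)
  expect_error(simulate_lorenz(n = 100, eta = -1), "eta")
})

test_that("ARFIMA weights match their closed forms", {
  expect_identical(arfima_coefficients(0, 10), numeric(10))
  for (rho in c(0.1, 0.5, 0.9)) {
    co <- arfima_coefficients(rho, 5)
    expect_equal(co[1], rho)
    expect_equal(co[2], rho * (1 - rho) / 2)
  }
  expect_equal(arfima_coefficients(0.5, 2), c(0.5, 0.125))
  expect_error(arfima_coefficients(1), "rho")
  expect_error(arfima_coefficients(-0.2), "rho")
})

test_that("ARFIMA interpolates from white noise to long memory", {
  x0 <- simulate_arfima(n = 10006, rho = 0, seed = 1)
  expect_equal(sd(x0), 1, tolerance = 0.05)
  expect_equal(mean(x0), 0, tolerance = 0.05)
  lag1 <- function(rho) {
    mean(vapply(1:10, function(s) {
      x <- simulate_arfima(n = 2000, rho = rho, seed = 100 * s)
      stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]
    }, numeric(1)))
  }
  r <- vapply(c(0.1, 0.5, 0.9), lag1, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("white-noise normalized PE sits within 3 Harris sigma of unity", {
  x <- simulate_arfima(n = 10006, rho = 0, seed = 19)
  for (m in 4:6) {
    e <- permutation_entropy(ordinal_distribution(detrend_endpoints(x), m))
    band <- 3 * sigma_harris(m, length(x)) / log(factorial(m))
    expect_lt(abs(e$h_normalized - 1), band)
  }
})

test_that("reference spread over white-noise realizations tracks the Harris floor", {
  ref <- reference_pe_std("arfima", m = 4, l = 30, seed = 1, rho = 0, n = 10006)
  harris <- sigma_harris(4, 10006)
  expect_gt(ref$sd, harris / 2)
  expect_lt(ref$sd, harris * 2)
})

test_that("realization seeds must be distinct", {
  expect_error(
    reference_pe_std("arfima", m = 3, l = 3, seeds = c(7L, 7L, 8L), rho = 0,
                     n = 256),
    "distinct")
})

test_that("reference and surrogate PE means coincide for ARFIMA", {
  for (rho in c(0.3, 0.7)) {
    r <- ratio_experiment("arfima", m = 4, l = 20, seed = 11, rho = rho,
                          n = 10006)
    combined <- sqrt(r$s_reference^2 + r$s_surrogate^2)
    expect_lt(abs(r$mean_reference - r$mean_surrogate), 2 * combined)
    expect_gt(r$ratio, 0)
  }
})

test_that("noise-dominated Lorenz brings the spread ratio near unity", {
  # at eta = 10 the signal is buried: surrogate and reference spreads agree
  # up to the Monte-Carlo error of the two sample stds (~18% each at l = 30)
  r <- ratio_experiment("lorenz", m = 4, l = 30, seed = 21, eta = 10,
                        n = 2006)
  expect_gt(r$ratio, 0.4)
  expect_lt(r$ratio, 1.6)
})

test_that("ratio sweep returns one tidy row per grid cell", {
  df <- ratio_sweep("arfima", values = c(0.9), m = c(3, 4), l = 10, seed = 3,
                    n = 512)
  expect_identical(nrow(df), 2L)
  expect_named(df, c("system", "parameter", "m", "mean_X", "mean_Y",
                     "s_X", "s_Y", "ratio"))
  expect_true(all(df$s_X > 0 & df$s_Y > 0))
  expect_equal(df$ratio, df$s_Y / df$s_X)
})

test_that("sweep configurations load from YAML key-value files", {
  cfg_file <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("system: arfima", "values: [0.5, 0.9]", "m: [4]",
               "l: 10", "seed: 2"), cfg_file)
  cfg <- read_sweep_config(cfg_file)
  expect_identical(cfg$system, "arfima")
  expect_equal(cfg$values, c(0.5, 0.9))
  expect_identical(cfg$l, 10L)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("system: arfima", bad)
  expect_error(read_sweep_config(bad), "missing keys")
})
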