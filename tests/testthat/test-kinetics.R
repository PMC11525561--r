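test_that("standard curves recover exact and noisy slopes", {
  conc <- c(0, 6.4, 9.6, 14.4, 21.6, 32.5, 50.6)
  sc <- fit_standard_curve(conc, 40 * conc + 5)
  expect_equal(sc$slope, 40)
  expect_equal(sc$intercept, 5)
  expect_false(sc$negative_slope)
  # normal-equation oracle on noisy data
  set.seed(51)
  sig <- 37 * conc + 12 + rnorm(7, sd = 3)
  sc2 <- fit_standard_curve(conc, sig)
  slope_ne <- sum((conc - mean(conc)) * (sig - mean(sig))) /
    sum((conc - mean(conc))^2)
  expect_lt(abs(sc2$slope - slope_ne), 1e-10)
  expect_warning(fit_standard_curve(conc, -2 * conc + 100), "non-positive")
  expect_error(fit_standard_curve(rep(1, 5), 1:5), "zero variance")
})

test_that("signal-to-rate arithmetic is exact and linear in net signal", {
  plate <- data.frame(condition_label = "LCAT", replicate_id = "rep1",
                      substrate_conc = c(10, 10, 10),
                      signal = c(450, 50, 30),
                      background_signal = 50, time_h = 1)
  curve <- fit_standard_curve(c(0, 10, 20), 40 * c(0, 10, 20))
  r <- signal_to_rate(plate, curve)
  expect_equal(r$rate, c(10, 0, 0))          # (450-50)/40/1; bg; clipped
  expect_equal(r$rate_clipped, c(FALSE, FALSE, TRUE))
  # doubling net signal doubles the rate exactly
  plate2 <- plate; plate2$signal <- 50 + 2 * (plate$signal - 50)
  expect_equal(signal_to_rate(plate2, curve)$rate[1], 20)
  plate$background_signal <- NA
  expect_error(signal_to_rate(plate, curve), "LCAT")
})

test_that("a zero-noise synthetic plate inverts through the full chain", {
  a <- gen_mm_assay(noise_sd_fraction = 0, seed = 3)
  curve <- fit_standard_curve(a$standard_curve$conc, a$standard_curve$signal)
  r <- signal_to_rate(a$plate, curve)
  v_true <- with(a$truth, vmax * r$substrate_conc / (km + r$substrate_conc))
  expect_lt(max(abs(r$rate - v_true)), 1e-9)
})

test_that("Michaelis-Menten recovers noiseless parameters at the plate design", {
  S <- c(6.4, 9.6, 14.4, 21.6, 32.5, 50.6)
  fit <- fit_michaelis_menten(S, 8.66 * S / (11.59 + S))
  expect_lt(abs(fit$vmax - 8.66) / 8.66, 1e-6)
  expect_lt(abs(fit$km - 11.59) / 11.59, 1e-6)
})

test_that("a saturated (flat) rate profile drives Km to the boundary", {
  S <- c(5, 10, 20, 40, 80)
  expect_warning(fit_michaelis_menten(S, rep(7, 5)), "boundary")
})

test_that("the fit matches a grid-search + polish oracle on noisy data", {
  set.seed(52)
  S <- rep(c(6.4, 9.6, 14.4, 21.6, 32.5, 50.6), 3)
  v <- pmax(0, 8.66 * S / (11.59 + S) + rnorm(length(S), sd = 0.17))
  fit <- fit_michaelis_menten(S, v)
  sse <- function(p) sum((v - p[1] * S / (p[2] + S))^2)
  grid <- expand.grid(vmax = seq(5, 14, by = 0.25), km = seq(2, 40, by = 0.5))
  best <- grid[which.min(apply(grid, 1, sse)), ]
  pol <- optim(c(best$vmax, best$km), sse,
               control = list(reltol = 1e-14, maxit = 5000))
  expect_lt(abs(fit$vmax - pol$par[1]) / pol$par[1], 1e-4)
  expect_lt(abs(fit$km - pol$par[2]) / pol$par[2], 1e-4)
})

test_that("MM fits are scale-equivariant in the rate axis", {
  set.seed(53)
  S <- c(6.4, 9.6, 14.4, 21.6, 32.5, 50.6)
  v <- 8.66 * S / (11.59 + S) + rnorm(6, sd = 0.1)
  f1 <- fit_michaelis_menten(S, v)
  f2 <- fit_michaelis_menten(S, 3 * v)
  expect_lt(abs(f2$vmax - 3 * f1$vmax) / (3 * f1$vmax), 1e-9)
  expect_lt(abs(f2$km - f1$km) / f1$km, 1e-9)
})

test_that("parameter recovery stays within the stated error bands under noise", {
  errs <- t(vapply(1:200, function(seed) {
    a <- gen_mm_assay(noise_sd_fraction = 0.02, n_replicates = 3, seed = seed)
    curve <- fit_standard_curve(a$standard_curve$conc, a$standard_curve$signal)
    r <- signal_to_rate(a$plate, curve)
    fit <- fit_michaelis_menten(r$substrate_conc, r$rate)
    c(abs(fit$vmax - 8.66) / 8.66, abs(fit$km - 11.59) / 11.59)
  }, numeric(2)))
  expect_lt(median(errs[, 1]), 0.05)
  expect_lt(median(errs[, 2]), 0.15)
})

test_that("catalytic efficiency follows kcat/Km and cancels enzyme units in ratios", {
  f <- fit_michaelis_menten(c(5, 10, 20, 40), 10 * c(5, 10, 20, 40) / (5 + c(5, 10, 20, 40)))
  f <- catalytic_efficiency(f, 0.1)
  expect_equal(f$kcat, f$vmax / 0.1)
  expect_equal(f$efficiency, f$kcat / f$km)
  expect_lt(abs(f$kcat - 100) / 100, 1e-6)     # vmax 10, E 0.1
  expect_lt(abs(f$efficiency - 20) / 20, 1e-6) # km 5
  # efficiency ratio between conditions is independent of E
  g <- fit_michaelis_menten(c(5, 10, 20, 40), 14 * c(5, 10, 20, 40) / (9 + c(5, 10, 20, 40)))
  r1 <- catalytic_efficiency(g, 0.1)$efficiency / catalytic_efficiency(f, 0.1)$efficiency
  r2 <- catalytic_efficiency(g, 7)$efficiency / catalytic_efficiency(f, 7)$efficiency
  expect_equal(r1, r2)
  # direct-formula oracle on random parameter sets
  set.seed(54)
  for (i in 1:20) {
    vm <- runif(1, 1, 20); km <- runif(1, 1, 60); E <- runif(1, 0.01, 1)
    ff <- f; ff$vmax <- vm; ff$km <- km
    expect_equal(catalytic_efficiency(ff, E)$efficiency, vm / E / km)
  }
  expect_error(catalytic_efficiency(f, 0), "> 0")
})

test_that("percent change reproduces the quoted round-ten percentages", {
  expect_equal(percent_change(15.70, 6.76, round_to = NULL), 132.2, tolerance = 1e-3)
  expect_equal(percent_change(15.70, 6.76), 130)
  expect_equal(percent_change(11.68, 6.76), 70)
  expect_equal(percent_change(14.78, 8.66, round_to = NULL), 70.7, tolerance = 1e-2)
  expect_equal(percent_change(14.78, 8.66), 70)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(3, 6), -50)
  expect_error(percent_change(5, 0), "> 0")
})

test_that("4PL fitting recovers noiseless curves at the five-dose design", {
  concs <- c(0.001, 0.01, 0.1, 1, 10)
  dr <- gen_dose_response(ec50 = 0.1, top = 250, bottom = 100, hill = 1,
                          concs = concs, noise_sd = 0)
  fit <- fit_dose_response(dr$responses$conc, dr$responses$response)
  expect_lt(abs(fit$ec50 - 0.1) / 0.1, 1e-5)
  expect_lt(abs(fit$top - 250) / 250, 1e-5)
  expect_lt(abs(fit$bottom - 100) / 100, 1e-5)
  expect_lt(abs(fit$hill - 1), 1e-5)
  expect_false(fit$no_effect)
})

test_that("a flat response is flagged as no effect", {
  concs <- rep(c(0.001, 0.01, 0.1, 1, 10), 3)
  fit <- fit_dose_response(concs, rep(100, 15))
  expect_true(fit$no_effect)
})

test_that("4PL matches a log-grid-search oracle on noisy data", {
  set.seed(55)
  concs <- rep(c(0.001, 0.01, 0.1, 1, 10), 3)
  mu <- 100 + 150 / (1 + 10^((log10(0.08) - log10(concs)) * 1.2))
  y <- mu + rnorm(length(concs), sd = 5)
  fit <- fit_dose_response(concs, y)
  lc <- log10(concs)
  sse <- function(p) # p = (bottom, top, lec50, hill)
    sum((y - (p[1] + (p[2] - p[1]) / (1 + 10^((p[3] - lc) * p[4]))))^2)
  grid <- expand.grid(bottom = seq(80, 120, 5), top = seq(200, 300, 5),
                      lec50 = seq(-2, 0, 0.1), hill = seq(0.5, 2, 0.1))
  best <- as.numeric(grid[which.min(apply(grid, 1, sse)), ])
  pol <- optim(best, sse, control = list(reltol = 1e-15, maxit = 20000))
  pol <- optim(pol$par, sse, control = list(reltol = 1e-15, maxit = 20000))
  expect_lt(abs(fit$ec50 - 10^pol$par[3]) / 10^pol$par[3], 1e-3)
  expect_lt(abs(fit$hill - pol$par[4]) / abs(pol$par[4]), 1e-3)
})

test_that("EC50 recovery stays within 1.5x under 10% response noise", {
  ok <- vapply(1:200, function(seed) {
    # 10% noise on the percent-of-control scale: SD 10 percentage points.
    # Responses are normalized so the zero-dose level is 100% by
    # construction, so the bottom is anchored at the control level.
    dr <- gen_dose_response(ec50 = 0.1, top = 250, bottom = 100, hill = 1,
                            noise_sd = 10, seed = seed)
    fit <- tryCatch(suppressWarnings(
      fit_dose_response(dr$responses$conc, dr$responses$response,
                        fix_bottom = 100)),
      error = function(e) NULL)
    !is.null(fit) && !is.na(fit$ec50) &&
      fit$ec50 > 0.1 / 1.5 && fit$ec50 < 0.1 * 1.5
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("zero-dose wells inform the bottom and fix_bottom pins it", {
  concs <- c(0, 0.001, 0.01, 0.1, 1, 10)
  mu <- 100 + 150 / (1 + 10^((log10(0.1) - log10(pmax(concs, 1e-9))) * 1))
  mu[concs == 0] <- 100
  fit <- fit_dose_response(concs, mu)
  expect_lt(abs(fit$bottom - 100), 1e-4)
  fitf <- fit_dose_response(concs, mu, fix_bottom = 100)
  expect_equal(fitf$bottom, 100)
  expect_true(fitf$bottom_fixed)
  expect_lt(abs(fitf$ec50 - 0.1) / 0.1, 1e-5)
})
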