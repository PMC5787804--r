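noiseless_points <- function(r = c(1e2, 1e3, 1e4, 1e5)) {
  data.frame(velocity = seq_along(r), mean_loading_rate = r,
             sd_loading_rate = 0,
             f_star = c(39.4987, 58.4459, 77.3931, 96.3403)[seq_along(r)],
             f_star_se = 0)
}

test_that("noiseless Bell-Evans data round-trip to the generating parameters", {
  fit <- fit_bell_evans(noiseless_points(), ctx298)
  expect_equal(fit$x_beta, 0.500, tolerance = 1e-3)
  expect_equal(fit$k_off, 0.100, tolerance = 1e-3)
  expect_equal(fit$slope, ctx298$kBT / 0.5, tolerance = 1e-4)
  # the derived-parameter identities hold
  expect_equal(fit$x_beta, ctx298$kBT / fit$slope)
  expect_equal(fit$k_off, (1 / fit$slope) * exp(-fit$intercept / fit$slope))
  expect_true(fit$x_beta_ci[1] <= fit$x_beta & fit$x_beta <= fit$x_beta_ci[2])
  expect_true(fit$k_off_ci[1] <= fit$k_off & fit$k_off <= fit$k_off_ci[2])
})

test_that("two points give the exact interpolating line", {
  pts <- noiseless_points(c(1e2, 1e4))[, ]
  pts$f_star <- c(39.4987, 77.3931)
  fit <- fit_bell_evans(pts, ctx298)
  resid <- pts$f_star - (fit$intercept + fit$slope * log(pts$mean_loading_rate))
  expect_equal(resid, c(0, 0), tolerance = 1e-9)
})

test_that("rescaling every loading rate shifts the intercept, not the slope", {
  p1 <- noiseless_points()
  p2 <- p1; p2$mean_loading_rate <- p2$mean_loading_rate * 10
  f1 <- fit_bell_evans(p1, ctx298); f2 <- fit_bell_evans(p2, ctx298)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-9)
  expect_equal(f1$x_beta, f2$x_beta, tolerance = 1e-9)
  expect_equal(f2$intercept, f1$intercept - f1$slope * log(10),
               tolerance = 1e-6)
})

test_that("model violations and degenerate inputs are rejected", {
  pts <- noiseless_points()
  pts$f_star <- rev(pts$f_star)          # forces fall with loading rate
  expect_error(fit_bell_evans(pts, ctx298), class = "dfspec_numeric_error")
  expect_error(fit_bell_evans(noiseless_points()[1, ], ctx298),
               class = "dfspec_input_error")
  same <- noiseless_points(); same$mean_loading_rate <- 5000
  expect_error(fit_bell_evans(same, ctx298), class = "dfspec_input_error")
})

test_that("effective-variance weighting uses the loading-rate spread", {
  set.seed(51)
  r <- c(425, 1390, 4010, 11260, 30800, 90760)
  pts <- data.frame(velocity = 1:6, mean_loading_rate = r,
                    sd_loading_rate = 0.45 * r,
                    f_star = fstar_closed_form(r) + rnorm(6, 0, 1),
                    f_star_se = 1)
  fit <- fit_bell_evans(pts, ctx298)
  expect_true(fit$weighted)
  expect_true(is.finite(fit$reduced_chisq))
  expect_equal(fit$x_beta, 0.5, tolerance = 0.15)
  # k_off is the noisier parameter: wider relative CI than x_beta
  rel_xb <- diff(fit$x_beta_ci) / fit$x_beta
  rel_koff <- diff(log(fit$k_off_ci))
  expect_gt(rel_koff, rel_xb)
})

test_that("confidence band has regression geometry and honest degrees of freedom", {
  fit <- fit_bell_evans(noiseless_points(), ctx298)
  band <- confidence_band(fit)
  expect_equal(band$upper - band$lower, rep(0, nrow(band)), tolerance = 1e-9)
  set.seed(52)
  pts <- noiseless_points()
  pts$f_star <- pts$f_star + rnorm(4, 0, 1.5)
  pts$f_star_se <- 1.5
  fitn <- fit_bell_evans(pts, ctx298)
  bandn <- confidence_band(fitn)
  width <- bandn$upper - bandn$lower
  xbar <- sum(log(pts$mean_loading_rate)) / 4
  i_center <- which.min(abs(bandn$lnr - xbar))
  expect_gt(width[1], width[i_center])
  expect_gt(width[nrow(bandn)], width[i_center])
  two <- fit_bell_evans(noiseless_points(c(1e2, 1e4)), ctx298)
  expect_error(confidence_band(two), class = "dfspec_input_error")
})

test_that("an eventless experiment fails with a clean input error", {
  cfg <- simulation_config(velocities = c(500, 3000), curves_per_velocity = 10,
                           p_bind = 0, p_nonspecific = 0, seed = 61)
  expect_error(run_dfs_experiment(cfg), class = "dfspec_input_error")
})

test_that("more events per velocity tighten the k_off confidence interval", {
  base <- function(n, seed) simulation_config(
    velocities = c(150, 600, 2200, 8000), curves_per_velocity = n,
    p_bind = 1, p_nonspecific = 0, seed = seed)
  width <- function(n, seed)
    diff(log(run_dfs_experiment(base(n, seed))$fit$k_off_ci))
  # residual scatter at few points is noisy, so compare across seeds
  seeds <- c(71, 72, 73)
  w_big <- vapply(seeds, function(s) width(200, s), numeric(1))
  w_small <- vapply(seeds, function(s) width(40, s), numeric(1))
  expect_lt(mean(w_big), mean(w_small))
})
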