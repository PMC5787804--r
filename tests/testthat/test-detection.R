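test_that("baseline estimation recovers offset, tilt and noise scale", {
  piezo <- seq(-3, 30, by = 0.1)
  set.seed(11)
  flat <- structure(list(curve_id = "b", piezo = piezo,
                         trace_force = numeric(length(piezo)),
                         retrace_force = rnorm(length(piezo), 0, 5),
                         velocity = 1000, k_c = 30, sample_step = 0.1,
                         temperature = 298, ground_truth = NULL),
                    class = "force_curve")
  bl <- estimate_baseline(flat)
  expect_gt(bl$sigma, 4); expect_lt(bl$sigma, 6)
  # noiseless tilted baseline recovered exactly
  tilted <- flat
  tilted$retrace_force <- 2 + 0.1 * piezo
  bl2 <- estimate_baseline(tilted)
  expect_equal(bl2$offset, 2, tolerance = 1e-6)
  expect_equal(bl2$tilt, 0.1, tolerance = 1e-6)
  expect_equal(bl2$sigma, 0)
  # all-zero trace
  zero <- flat; zero$retrace_force <- numeric(length(piezo))
  expect_equal(unlist(estimate_baseline(zero)),
               c(offset = 0, tilt = 0, sigma = 0))
  expect_error(estimate_baseline(rnorm(10), piezo = 1:10),
               class = "dfspec_input_error")
})

test_that("Hooke's law conversion is linear in deflection and stiffness", {
  expect_equal(deflection_to_force(1, 30), 30)   # 0.03 N/m cantilever
  expect_equal(deflection_to_force(0, 30), 0)
  dz <- c(0.3, 1.2, 2.5)
  expect_equal(deflection_to_force(2 * dz, 30), 2 * deflection_to_force(dz, 30))
  expect_error(deflection_to_force(1, 0), class = "dfspec_domain_error")
})

test_that("a noiseless bound curve yields exactly one exact accepted event", {
  cv <- make_noiseless_bound_curve(rupture_force = 50)
  ev <- detect_events(cv)
  expect_identical(nrow(ev), 1L)
  expect_true(ev$accepted)
  truth <- attr(cv, "true_rupture_force")
  expect_lt(abs(ev$rupture_force_pN - truth), 0.5)
  expect_lt(abs(ev$rupture_separation_nm - attr(cv, "true_rupture_separation")),
            0.4)
  # loading stiffness invariants on the emitted event
  expect_lte(ev$k_eff_pN_nm, min(ev$k_peg_pN_nm, 30) + 1e-9)
  expect_equal(ev$loading_rate_pN_s, ev$k_eff_pN_nm * cv$velocity)
})

test_that("the detector is invariant under baseline translation", {
  cv0 <- make_noiseless_bound_curve(rupture_force = 60, offset = 0)
  cv1 <- make_noiseless_bound_curve(rupture_force = 60, offset = 25)
  ev0 <- detect_events(cv0); ev1 <- detect_events(cv1)
  expect_equal(ev0$rupture_force_pN, ev1$rupture_force_pN, tolerance = 1e-9)
  expect_equal(ev0$rupture_separation_nm, ev1$rupture_separation_nm,
               tolerance = 1e-9)
})

test_that("contact-zone adhesion is found but rejected as nonspecific", {
  step <- 0.2
  d_pos <- seq(step, 30, by = step)
  retrace <- numeric(length(d_pos))
  ramp <- d_pos > 1 & d_pos <= 3          # abrupt spike ending at 3 nm
  retrace[ramp] <- -30 * (d_pos[ramp] - 1)
  piezo <- c(-rev(seq_len(17)) * step, 0, d_pos)
  contact <- pmax(-piezo, 0) * 30
  cv <- structure(list(curve_id = "spike", piezo = piezo,
                       trace_force = contact,
                       retrace_force = c(contact[1:18], retrace),
                       velocity = 1000, k_c = 30, sample_step = step,
                       temperature = 298, ground_truth = NULL),
                  class = "force_curve")
  ev <- detect_events(cv)
  expect_gte(nrow(ev), 1L)
  expect_false(any(ev$accepted))
})

test_that("pure-noise curves yield essentially no accepted events", {
  cfg <- simulation_config(velocities = 2900, curves_per_velocity = 100,
                           p_bind = 0, p_nonspecific = 0, seed = 13)
  ens <- simulate_ensemble(cfg)
  ev <- analyze_curves(ens)
  expect_lte(sum(ev$accepted), 1L)
})

test_that("event invariants hold across a noisy ensemble", {
  cfg <- simulation_config(velocities = c(380, 8000), curves_per_velocity = 60,
                           p_bind = 0.5, seed = 19)
  ens <- simulate_ensemble(cfg)
  ev <- analyze_curves(ens)
  ok <- is.finite(ev$k_peg_pN_nm)
  expect_true(all(ev$k_eff_pN_nm[ok] <= pmin(ev$k_peg_pN_nm[ok], 30) + 1e-9))
  expect_equal(ev$loading_rate_pN_s[ok],
               ev$k_eff_pN_nm[ok] * ev$velocity_nm_s[ok])
  acc <- ev[ev$accepted, ]
  expect_true(all(acc$rupture_separation_nm >= 5 &
                    acc$rupture_separation_nm <= 15))
  expect_true(all(acc$rupture_force_pN > 0))
})

test_that("effective spring constant is the harmonic combination", {
  expect_equal(effective_spring_constant(3, 30), 30 / 11, tolerance = 1e-9)
  expect_equal(effective_spring_constant(7, 7), 3.5)
  expect_equal(effective_spring_constant(1e12, 30), 30, tolerance = 1e-6)
  k <- c(2, 10, 80)
  expect_true(all(effective_spring_constant(k, 30) <= pmin(k, 30)))
  expect_error(effective_spring_constant(-1, 30), class = "dfspec_domain_error")
})

test_that("loading rate is stiffness times velocity", {
  expect_equal(loading_rate(2.5, 2000), 5000)   # the ~5000 pN/s regime
  expect_equal(loading_rate(2.5, 4000), 2 * loading_rate(2.5, 2000))
  expect_error(loading_rate(2.5, 0), class = "dfspec_domain_error")
})
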