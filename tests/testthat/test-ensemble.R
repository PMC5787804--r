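fake_curves <- function(n, velocity = 2000) {
  lapply(seq_len(n), function(i)
    structure(list(curve_id = sprintf("c%04d", i), velocity = velocity),
              class = "force_curve"))
}

fake_events <- function(ids, velocity = 2000, force = 60, accepted = TRUE) {
  data.frame(curve_id = ids, velocity_nm_s = velocity,
             rupture_force_pN = force, rupture_separation_nm = 9,
             k_peg_pN_nm = 20, k_eff_pN_nm = 12,
             loading_rate_pN_s = 12 * velocity, baseline_sigma_pN = 5,
             accepted = accepted)
}

test_that("binding probability is the fraction of curves with an event", {
  curves <- fake_curves(1000)
  ev <- fake_events(sprintf("c%04d", 1:130))
  bp <- binding_probability(curves, ev)
  expect_equal(bp$probability, 0.130)
  expect_equal(bp$se, sqrt(0.13 * 0.87 / 1000), tolerance = 1e-9)
  # duplicate events on one curve do not double count
  ev2 <- rbind(ev, ev[1, ])
  expect_equal(binding_probability(curves, ev2)$probability, 0.130)
  expect_equal(binding_probability(curves, ev[0, ])$probability, 0)
  expect_error(binding_probability(list(), ev), class = "dfspec_input_error")
  expect_error(binding_probability(curves, fake_events("zzz")),
               class = "dfspec_input_error")
})

test_that("specific event selection keeps the farthest accepted rupture", {
  ev <- rbind(fake_events("c1", force = 40), fake_events("c1", force = 70))
  ev$rupture_separation_nm <- c(6, 11)
  ev2 <- rbind(ev, fake_events("c2", accepted = FALSE))
  sel <- specific_events(ev2)
  expect_identical(nrow(sel), 1L)
  expect_equal(sel$rupture_force_pN, 70)
})

test_that("the empirical pdf is a mean of unit-area Gaussian kernels", {
  pdf <- construct_pdf(60, sigma = 5)
  expect_equal(pdf$force[which.max(pdf$density)], 60, tolerance = 0.11)
  # equal to the single kernel up to the tiny tail renormalisation
  expect_lt(max(abs(pdf$density - dnorm(pdf$force, 60, 5))), 1e-4)
  # unit trapezoidal area for arbitrary mixtures
  set.seed(4)
  for (i in 1:3) {
    p <- construct_pdf(runif(50, 20, 110), sigma = runif(50, 2, 8))
    area <- sum(diff(p$force) * (head(p$density, -1) + tail(p$density, -1)) / 2)
    expect_equal(area, 1, tolerance = 1e-6)
    expect_true(all(p$density >= 0))
  }
  expect_error(construct_pdf(numeric(0)), class = "dfspec_input_error")
  expect_error(construct_pdf(60, sigma = 0), class = "dfspec_input_error")
})

test_that("Gaussian fit extracts the most probable force from the pdf", {
  mp <- fit_most_probable_force(construct_pdf(60, sigma = 5))
  expect_equal(mp$f_star, 60, tolerance = 1e-4)
  expect_true(mp$converged)
  # bimodal: the heavier mode wins
  pdf_bi <- construct_pdf(c(30, 90, 90), sigma = 5)
  expect_equal(fit_most_probable_force(pdf_bi)$f_star, 90, tolerance = 1)
  # mode of sampled Bell ruptures matches the closed form (oracle)
  set.seed(8)
  f <- sample_rupture_force(5000, bell01, ctx298, u = runif(500))
  pdf_s <- construct_pdf(f, sigma = 5)
  expect_lt(abs(pdf_s$force[which.max(pdf_s$density)] -
                  fstar_closed_form(5000)), 3)
})

test_that("velocity summaries assemble consistent ensemble statistics", {
  curves <- fake_curves(40)
  # no events: probability zero, no F*
  s0 <- summarize_group(curves, fake_events("c0001")[0, ], velocity = 2000)
  expect_equal(s0$binding_probability, 0)
  expect_true(is.na(s0$f_star))
  # deterministic on fixed inputs
  ev <- fake_events(sprintf("c%04d", 1:12),
                    force = seq(50, 72, length.out = 12))
  s1 <- summarize_group(curves, ev, velocity = 2000)
  s2 <- summarize_group(curves, ev, velocity = 2000)
  expect_identical(s1[names(s1) != "pdf"], s2[names(s2) != "pdf"])
  expect_equal(s1$binding_probability, 12 / 40)
  expect_equal(s1$mean_loading_rate, 12 * 2000)
  expect_equal(s1$sd_loading_rate, 0)
  expect_error(summarize_group(curves, ev, velocity = 999),
               class = "dfspec_input_error")
})

test_that("mean loading rates increase with pulling velocity", {
  cfg <- simulation_config(velocities = c(380, 2900, 8000),
                           curves_per_velocity = 120, p_bind = 0.5,
                           p_nonspecific = 0, seed = 37)
  ens <- simulate_ensemble(cfg)
  ev <- analyze_curves(ens)
  summ <- summarize_velocities(ens, ev)
  lr <- vapply(summ, function(s) s$mean_loading_rate, numeric(1))
  expect_true(all(diff(lr) > 0))
})

test_that("two-sample comparison reproduces Student's t and the star labels", {
  expect_identical(compare_samples(c(1, 2, 3), c(1, 2, 3)),
                   list(statistic = 0, p_value = 1,
                        significance_label = "n.s."))
  # dual route: cross-check statistic and p against stats::t.test,
  # and the label against the published mapping
  star <- function(p) if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "n.s."
  set.seed(15)
  for (delta in c(0, 3, 6, 12)) {
    a <- rnorm(20, 60, 10); b <- rnorm(20, 60 + delta, 10)
    res <- compare_samples(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(res$p_value, ref$p.value)
    expect_equal(res$statistic, unname(ref$statistic))
    expect_identical(res$significance_label, star(ref$p.value))
  }
  # well-powered separation is three-star significant
  set.seed(16)
  res <- compare_samples(rnorm(200, 60, 10), rnorm(200, 75, 10))
  expect_identical(res$significance_label, "***")
  expect_lt(res$p_value, 1e-10)
  expect_error(compare_samples(1, c(1, 2)), class = "dfspec_input_error")
  expect_error(compare_samples(c(2, 2), c(3, 3)),
               class = "dfspec_input_error")
})
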