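baseline <- observer_params()

test_that("parameter validation enforces the documented bounds", {
  expect_s3_class(baseline, "observer_params")
  expect_error(observer_params(c_stim = 0), class = "dotlattice_parameter_error")
  expect_error(observer_params(kappa_sens_l1 = -2),
               class = "dotlattice_parameter_error")
  expect_error(observer_params(w_stim_l1 = 1.2),
               class = "dotlattice_parameter_error")
  expect_warning(observer_params(kappa_sens_l2 = 25),
                 "sensory precision")
  p2 <- update_params(baseline, c_stim = 7, w_perc_l1 = 0)
  expect_equal(p2$c_stim, 7)
  expect_equal(p2$w_perc_l1, 0)
  expect_equal(p2$kappa_stim_l1, baseline$kappa_stim_l1)
})

test_that("first-lattice likelihood weights follow AR^c_stim", {
  # AR = 1: equal peaks
  lik <- l1_likelihood(baseline, 1)
  expect_equal(density_at_test(lik, 0), density_at_test(lik, 90),
               tolerance = 1e-12)
  # AR = 1.3^-1, c_stim = 5: response probability equals the analytic
  # mixture weight 1 / (1 + 1.3^-5) because peak overlap is negligible
  w <- 1 / (1 + 1.3^-5)
  post <- l1_posterior(baseline, 1 / 1.3)
  p <- l1_response_probs(post)
  expect_equal(p$prob[p$r1 == 0], w, tolerance = 1e-6)
  # and symmetrically for AR = 1.3
  post_hi <- l1_posterior(baseline, 1.3)
  p_hi <- l1_response_probs(post_hi)
  expect_equal(p_hi$prob[p_hi$r1 == 90], w, tolerance = 1e-6)
  expect_error(l1_likelihood(baseline, -1), class = "dotlattice_condition_error")
})

test_that("uniform prior makes the posterior proportional to the likelihood", {
  lik <- l1_likelihood(baseline, 1 / 1.2, phi = 30)
  post <- l1_posterior(baseline, 1 / 1.2, phi = 30)
  expect_equal(post$density, lik$density, tolerance = 1e-12)
  expect_equal(sum(post$density) * pi / 180, 1, tolerance = 1e-9)
})

test_that("natural prior pulls the first-lattice posterior toward cardinals", {
  p <- observer_params(prior_kind = "natural")
  post <- l1_posterior(p, 1, phi = 0)
  expect_gt(density_at_test(post, 0), density_at_test(post, 45))
})

test_that("response probabilities are a symmetric null at AR = 1", {
  post <- l1_posterior(baseline, 1)
  p <- l1_response_probs(post)
  expect_equal(sum(p$prob), 1)
  expect_equal(p$prob[p$r1 == 0], 0.5, tolerance = 1e-10)
})

test_that("proximity: p(0 | L1) strictly decreases across the AR levels", {
  p0 <- vapply(default_aspect_ratios(), function(a) {
    pt <- predict_trial(baseline, a)
    pt$prob[pt$lattice == "L1" & pt$response == 0]
  }, numeric(1))
  expect_true(all(diff(p0) < 0))
})

test_that("stimulus frequency and perceptual prior are the documented mixtures", {
  prior <- make_prior("uniform")
  post <- l1_posterior(baseline, 1 / 1.3)
  sf <- stimulus_frequency(prior, post, 0)
  expect_equal(sf$density, prior$density, tolerance = 1e-12)
  sf1 <- stimulus_frequency(prior, post, 1)
  expect_equal(sf1$density, post$density, tolerance = 1e-12)
  sf6 <- stimulus_frequency(prior, post, 0.6)
  expect_equal(sf6$density, 0.4 * prior$density + 0.6 * post$density,
               tolerance = 1e-9)
  expect_error(stimulus_frequency(prior, post, 1.2),
               class = "dotlattice_parameter_error")

  pp0 <- perceptual_prior(prior, 40, 10, 0)
  expect_equal(pp0$density, prior$density, tolerance = 1e-12)
  pp1 <- perceptual_prior(prior, 40, 10, 1)
  expect_equal(pp1$density, vm_pdf(prior$theta_deg, 40, 10), tolerance = 1e-9)
  pp <- perceptual_prior(prior, 40, 10, 0.5)
  expect_gt(density_at_test(pp, 40), density_at_test(pp, 130))
  expect_error(perceptual_prior(prior, 40, 10, -0.1),
               class = "dotlattice_parameter_error")
})

test_that("second lattice shows hysteresis and adaptation at baseline", {
  ars <- default_aspect_ratios()
  p0 <- sapply(c(0, 90), function(r1) {
    vapply(ars, function(a) l2_predict(baseline, a, r1 = r1)$prob[1],
           numeric(1))
  })
  # hysteresis: conditioning on a 0-degree percept raises p(0 | L2) everywhere
  expect_true(all(p0[, 1] > p0[, 2]))
  # adaptation: p(0 | L2) increases with the AR for both conditioning percepts
  expect_true(all(diff(p0[, 1]) > 0))
  expect_true(all(diff(p0[, 2]) > 0))
  # probabilities form a proper distribution
  pred <- l2_predict(baseline, 1 / 1.1, r1 = 90)
  expect_equal(sum(pred$prob), 1, tolerance = 1e-12)
  expect_error(l2_predict(baseline, 1 / 1.1, r1 = NULL),
               class = "dotlattice_condition_error")
})

test_that("model variants ablate exactly one effect each", {
  sp <- observer_params(variant = "stimulus_prior", w_perc_l1 = 0)
  a <- l2_predict(sp, 1 / 1.3, r1 = 0)
  b <- l2_predict(sp, 1 / 1.3, r1 = 90)
  expect_lt(max(abs(a$prob - b$prob)), 1e-12)

  ne <- observer_params(variant = "no_efficient_coding")
  p0 <- vapply(default_aspect_ratios(),
               function(ar) l2_predict(ne, ar, r1 = 0)$prob[1], numeric(1))
  expect_lt(diff(range(p0)), 1e-10)
  hyst <- l2_predict(ne, 1, r1 = 0)$prob[1] - l2_predict(ne, 1, r1 = 90)$prob[1]
  expect_gt(hyst, 0)
})

test_that("uniform-prior predictions are rotation invariant", {
  probs <- sapply(seq(0, 170, by = 10), function(phi) {
    pt <- predict_trial(baseline, 1 / 1.2, phi = phi)
    pt$prob
  })
  expect_lt(max(apply(probs, 1, function(r) diff(range(r)))), 1e-9)
})

test_that("off-grid orientations are snapped with a warning", {
  expect_warning(predict_trial(baseline, 1, phi = 10.4), "snapped")
})

test_that("intermediate densities are exposed and normalized", {
  pred <- l2_predict(baseline, 1 / 1.3, r1 = 0, intermediates = TRUE)
  dens <- attr(pred, "densities")
  expect_named(dens, c("prior_l1", "posterior_l1", "stimulus_frequency",
                       "likelihood_l2", "prior_l2", "posterior_l2"))
  for (d in dens) {
    expect_equal(sum(d$density) * pi / 180, 1, tolerance = 1e-9)
  }
})
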