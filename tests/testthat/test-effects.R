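# Build a response table directly from known logistic models; the fits must
# recover the generating coefficients.
make_l1_table <- function(beta0, beta1, n, ars = default_aspect_ratios()) {
  x <- log(ars) - mean(log(ars))
  p <- plogis(beta0 + beta1 * x)
  k <- rbinom(length(ars), n, p)
  tibble::tibble(
    aspect_ratio = rep(ars, each = 2), phi = 0,
    r1 = rep(c(0, 90), length(ars)), r2 = 0,
    count = as.vector(rbind(k, n - k)), n = n, mode = "sampled"
  )
}

make_l2_table <- function(beta0, beta_ar, beta_r1, n,
                          ars = default_aspect_ratios()) {
  grid <- expand.grid(aspect_ratio = ars, r1 = c(0, 90))
  x <- log(grid$aspect_ratio) - mean(log(ars))
  r1c <- ifelse(grid$r1 == 0, 0.5, -0.5)
  p <- plogis(beta0 + beta_ar * x + beta_r1 * r1c)
  k <- rbinom(nrow(grid), n, p)
  tibble::tibble(
    aspect_ratio = rep(grid$aspect_ratio, each = 2), phi = 0,
    r1 = rep(grid$r1, each = 2), r2 = rep(c(0, 60), nrow(grid)),
    count = as.vector(rbind(k, n - k)), n = n, mode = "sampled"
  )
}

test_that("L1 fit recovers a known proximity slope", {
  withr::with_seed(101, {
    tab <- make_l1_table(beta0 = 0.2, beta1 = -2, n = 1e5)
    fit <- fit_l1_effect(tab)
    expect_false(fit$separated)
    expect_lt(abs(fit$estimate - (-2)), 3 * fit$se)
    # null model: flat in AR
    null_tab <- make_l1_table(beta0 = 0.2, beta1 = 0, n = 1e5)
    null_fit <- fit_l1_effect(null_tab)
    expect_lt(abs(null_fit$estimate), 3 * null_fit$se)
  })
})

test_that("L2 fit recovers known adaptation and hysteresis coefficients", {
  withr::with_seed(202, {
    tab <- make_l2_table(beta0 = 1, beta_ar = 2.5, beta_r1 = 1.8, n = 1e5)
    fit <- fit_l2_effects(tab)
    expect_false(any(fit$separated))
    est <- setNames(fit$estimate, fit$effect)
    se <- setNames(fit$se, fit$effect)
    expect_lt(abs(est["adaptation"] - 2.5), 3 * se["adaptation"])
    expect_lt(abs(est["hysteresis"] - 1.8), 3 * se["hysteresis"])
  })
})

test_that("fit bias shrinks as the sample grows", {
  errs <- withr::with_seed(303, {
    vapply(c(1e3, 1e5), function(n) {
      mean(vapply(1:5, function(i) {
        abs(fit_l1_effect(make_l1_table(0, -2, n))$estimate - (-2))
      }, numeric(1)))
    }, numeric(1))
  })
  expect_lt(errs[2], errs[1])
})

test_that("fits on baseline expected-mode tables have the published signs", {
  tab <- predict_experiment(experiment_design(n_per_condition = 100),
                            observer_params())
  expect_lt(fit_l1_effect(tab)$estimate, 0)
  f2 <- fit_l2_effects(tab)
  expect_gt(f2$estimate[f2$effect == "adaptation"], 0)
  expect_gt(f2$estimate[f2$effect == "hysteresis"], 0)
})

test_that("ablated observers fit to null effects", {
  sp <- observer_params(variant = "stimulus_prior", w_perc_l1 = 0)
  design <- experiment_design(n_per_condition = 1e4, seed = 21)
  tab <- sample_experiment(design, sp)
  fit <- fit_l2_effects(tab)
  hyst <- fit[fit$effect == "hysteresis", ]
  expect_lt(abs(hyst$estimate), 3 * hyst$se)
})

test_that("degenerate inputs raise informative errors", {
  tab <- predict_experiment(experiment_design(), observer_params())
  one_ar <- tab[abs(tab$aspect_ratio - 1) < 1e-9, ]
  expect_error(fit_l1_effect(one_ar), class = "dotlattice_input_error")
  no_r1 <- tab[tab$r1 == 0, ]
  expect_error(fit_l2_effects(no_r1), class = "dotlattice_input_error")
})

test_that("separation triggers the ridge fallback and is flagged", {
  ars <- default_aspect_ratios()
  tab <- tibble::tibble(
    aspect_ratio = rep(ars, each = 2), phi = 0,
    r1 = rep(c(0, 90), length(ars)), r2 = 0,
    count = as.vector(rbind(ifelse(ars < 1, 50, 0), ifelse(ars < 1, 0, 50))),
    n = 50, mode = "sampled"
  )
  fit <- fit_l1_effect(tab)
  expect_true(fit$separated)
  expect_true(is.finite(fit$estimate))
  expect_lt(fit$estimate, 0)
})

test_that("correlation report behaves on trivial inputs", {
  base <- tibble::tibble(
    id = 1:30,
    proximity = rnorm(30), proximity_se = 0.1,
    adaptation = rnorm(30), adaptation_se = 0.1,
    hysteresis = rnorm(30), hysteresis_se = 0.1,
    separated = FALSE
  )
  # identical vectors correlate at exactly 1
  same <- base
  same$adaptation <- same$hysteresis
  co <- correlate_effects(same, n_boot = 200, seed = 1)
  r <- tidy(co)
  expect_equal(r$r[r$effect_1 == "hysteresis" & r$effect_2 == "adaptation"], 1)
  # independent vectors stay near zero at this n
  co2 <- withr::with_seed(77, {
    shuffled <- base
    correlate_effects(shuffled, n_boot = 200, seed = 2)
  })
  expect_lt(max(abs(tidy(co2)$r)), 0.5)
  # CI contains the point estimate
  t2 <- tidy(co2)
  expect_true(all(t2$ci_lower <= t2$r & t2$r <= t2$ci_upper))
  # degenerate input
  flat <- base
  flat$proximity <- 1
  expect_error(correlate_effects(flat), class = "dotlattice_input_error")
  expect_error(correlate_effects(base[1:2, ]), class = "dotlattice_input_error")
})

test_that("tidiers return the documented shapes", {
  pop <- baseline_population_effects()
  est <- pop$effects
  long <- tidy(est)
  expect_named(long, c("id", "effect", "estimate", "se"))
  expect_equal(nrow(long), 3 * nrow(est))
  g <- glance(est)
  expect_equal(g$n_individuals, 75)
  co <- correlate_effects(est, n_boot = 100, seed = 3)
  expect_named(tidy(co), c("effect_1", "effect_2", "r", "ci_lower", "ci_upper"))
  expect_equal(glance(co)$n_boot, 100)
})
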