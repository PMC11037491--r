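# Binomial GLM with logit link on (possibly fractional) counts, with a small
# ridge-penalized IRLS fallback when the ML fit separates. Expected-frequency
# tables carry non-integer counts; point estimates are the same as for the
# rescaled proportions, so the integer warning from stats::glm is suppressed.
fit_binomial <- function(k, n, X, ridge_lambda = 1e-4) {
  keep <- n > 0
  k <- k[keep]; n <- n[keep]; X <- X[keep, , drop = FALSE]
  fit <- suppressWarnings(
    stats::glm.fit(X, k / n, weights = n, family = stats::binomial())
  )
  beta <- fit$coefficients
  se <- tryCatch(
    sqrt(diag(chol2inv(chol(crossprod(X * sqrt(fit$weights), X))))),
    error = function(e) rep(NA_real_, ncol(X))
  )
  separated <- !fit$converged || any(!is.finite(beta)) || any(abs(beta) > 30) ||
    any(!is.finite(se)) || any(se > 1e3)
  if (separated) {
    rf <- ridge_logistic(k, n, X, ridge_lambda)
    beta <- rf$beta
    se <- rf$se
  }
  list(beta = unname(beta), se = unname(se), separated = separated)
}

# Plain IRLS for ridge-penalized binomial regression (penalty lambda * I,
# intercept included in the penalty; lambda is tiny so this only tames
# separation).
ridge_logistic <- function(k, n, X, lambda = 1e-4, max_iter = 100) {
  beta <- numeric(ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- n * mu * (1 - mu)
    z <- eta + (k - n * mu) / pmax(w, 1e-12)
    H <- crossprod(X * sqrt(w), X) + diag(lambda, ncol(X))
    beta_new <- drop(solve(H, crossprod(X * w, z)))
    if (max(abs(beta_new - beta)) < 1e-10) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- n * mu * (1 - mu)
  H <- crossprod(X * sqrt(w), X) + diag(lambda, ncol(X))
  list(beta = beta, se = sqrt(diag(solve(H))))
}

l1_counts <- function(table) {
  table |>
    dplyr::group_by(.data$aspect_ratio, .data$phi) |>
    dplyr::summarize(k = sum(.data$count[.data$r1 == 0]),
                     n = sum(.data$count), .groups = "drop")
}

l2_counts <- function(table) {
  table |>
    dplyr::group_by(.data$aspect_ratio, .data$phi, .data$r1) |>
    dplyr::summarize(k = sum(.data$count[.data$r2 == 0]),
                     n = sum(.data$count), .groups = "drop")
}

#' Direct proximity effect from a response table
#'
#' Fits a binomial regression with logit link of the first-lattice 0-degree
#' response on centered log aspect ratio, by maximum likelihood on the cell
#' counts. The slope is the proximity effect: the logit change in
#' p(0 | L1) per unit log-AR, expected negative (larger AR means the dots are
#' relatively closer along the competing axis).
#'
#' @param table A response table from [predict_experiment()] or
#'   [sample_experiment()].
#' @return A one-row tibble: `effect = "proximity"`, `estimate`, `se`,
#'   `separated`.
#' @export
fit_l1_effect <- function(table) {
  d <- l1_counts(table)
  if (length(unique(d$aspect_ratio)) < 2) {
    abort("At least two aspect-ratio levels are needed.",
          class = "dotlattice_input_error")
  }
  x <- log(d$aspect_ratio) - mean(log(unique(d$aspect_ratio)))
  f <- fit_binomial(d$k, d$n, cbind(1, x))
  tibble(effect = "proximity", estimate = f$beta[2], se = f$se[2],
         separated = f$separated)
}

#' Adaptation and hysteresis effects from a response table
#'
#' Fits a binomial regression with logit link of the second-lattice 0-degree
#' response on centered log aspect ratio and a first-lattice percept contrast
#' (+0.5 for r1 = 0, -0.5 for r1 = 90). The log-AR coefficient is the
#' adaptation (repulsive) effect, expected positive; the percept-contrast
#' coefficient is the hysteresis (attractive) effect, also expected positive
#' and read as a full 0-vs-90 logit difference.
#'
#' @inheritParams fit_l1_effect
#' @return A two-row tibble with `effect` in `("adaptation", "hysteresis")`,
#'   `estimate`, `se`, `separated`.
#' @export
fit_l2_effects <- function(table) {
  d <- l2_counts(table)
  d <- d[d$n > 0, ]
  if (length(unique(d$r1)) < 2) {
    abort("Both first-lattice percepts (r1 = 0 and 90) must be present.",
          class = "dotlattice_input_error")
  }
  x <- log(d$aspect_ratio) - mean(log(unique(d$aspect_ratio)))
  r1c <- ifelse(d$r1 == 0, 0.5, -0.5)
  f <- fit_binomial(d$k, d$n, cbind(1, x, r1c))
  tibble(effect = c("adaptation", "hysteresis"),
         estimate = f$beta[2:3], se = f$se[2:3], separated = f$separated)
}

#' Per-individual effect estimates
#'
#' Applies [fit_l1_effect()] and [fit_l2_effects()] to each individual's
#' response table (tables distinguished by an `id` column, as produced by
#' [simulate_population()]).
#'
#' @param tables A response-table tibble with an `id` column.
#' @return A tibble of class `effect_estimates` with one row per individual:
#'   `id`, `proximity`, `proximity_se`, `adaptation`, `adaptation_se`,
#'   `hysteresis`, `hysteresis_se`, `separated`.
#' @export
estimate_effects <- function(tables) {
  if (!"id" %in% names(tables)) {
    tables$id <- 1L
  }
  out <- tables |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(function(tab, key) {
      e <- dplyr::bind_rows(fit_l1_effect(tab), fit_l2_effects(tab))
      tibble(proximity = e$estimate[e$effect == "proximity"],
             proximity_se = e$se[e$effect == "proximity"],
             adaptation = e$estimate[e$effect == "adaptation"],
             adaptation_se = e$se[e$effect == "adaptation"],
             hysteresis = e$estimate[e$effect == "hysteresis"],
             hysteresis_se = e$se[e$effect == "hysteresis"],
             separated = any(e$separated))
    }) |>
    dplyr::ungroup()
  structure(out, class = c("effect_estimates", class(out)))
}

#' Cross-individual correlations between context effects
#'
#' Pearson correlations between the per-individual proximity, adaptation and
#' hysteresis estimates, with nonparametric bootstrap confidence intervals
#' (resampling individuals with replacement). The headline quantity is the
#' hysteresis-adaptation correlation: a simulated population with positively
#' correlated temporal-integration weights reproduces the empirically
#' observed positive correlation between individuals' attractive and
#' repulsive effects.
#'
#' @param estimates An [estimate_effects()] tibble (>= 3 individuals).
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @param conf_level Confidence level of the percentile interval.
#' @return An object of class `effect_correlations`; see [tidy()] and
#'   [glance()] methods.
#' @export
correlate_effects <- function(estimates, n_boot = 2000, seed = 1,
                              conf_level = 0.95) {
  eff <- as.data.frame(estimates[c("hysteresis", "adaptation", "proximity")])
  if (nrow(eff) < 3) {
    abort("At least 3 individuals are needed.", class = "dotlattice_input_error")
  }
  if (any(vapply(eff, stats::sd, numeric(1)) < 1e-12)) {
    abort("An effect vector has zero variance; correlations are undefined.",
          class = "dotlattice_input_error")
  }
  pairs <- list(c("hysteresis", "adaptation"),
                c("adaptation", "proximity"),
                c("hysteresis", "proximity"))
  point <- vapply(pairs, function(p) cor(eff[[p[1]]], eff[[p[2]]]), numeric(1))
  old <- .Random.seed_safe()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, length(pairs))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(eff), replace = TRUE)
    boot[b, ] <- vapply(pairs, function(p) {
      suppressWarnings(cor(eff[[p[1]]][idx], eff[[p[2]]][idx]))
    }, numeric(1))
  }
  alpha <- (1 - conf_level) / 2
  ci <- apply(boot, 2, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  structure(
    list(correlations = tibble(
           effect_1 = vapply(pairs, `[`, character(1), 1),
           effect_2 = vapply(pairs, `[`, character(1), 2),
           r = point, ci_lower = ci[1, ], ci_upper = ci[2, ]),
         n_individuals = nrow(eff), n_boot = n_boot, seed = seed,
         conf_level = conf_level),
    class = "effect_correlations"
  )
}

#' @export
print.effect_correlations <- function(x, ...) {
  cat(sprintf("<effect_correlations> %d individuals, %d bootstrap resamples (%.0f%% CI)\n",
              x$n_individuals, x$n_boot, 100 * x$conf_level))
  print(x$correlations)
  invisible(x)
}

#' Tidy an effect-correlation report
#'
#' @param x An `effect_correlations` object.
#' @param ... Unused.
#' @return A tibble with one row per effect pair: `effect_1`, `effect_2`,
#'   `r`, `ci_lower`, `ci_upper`.
#' @method tidy effect_correlations
#' @export
tidy.effect_correlations <- function(x, ...) {
  x$correlations
}

#' @rdname tidy.effect_correlations
#' @return For `glance()`: a one-row tibble with `n_individuals`, `n_boot`,
#'   `conf_level`.
#' @method glance effect_correlations
#' @export
glance.effect_correlations <- function(x, ...) {
  tibble(n_individuals = x$n_individuals, n_boot = x$n_boot,
         conf_level = x$conf_level)
}

#' Tidy per-individual effect estimates
#'
#' @param x An `effect_estimates` tibble.
#' @param ... Unused.
#' @return A long tibble with columns `id`, `effect`, `estimate`, `se`.
#' @method tidy effect_estimates
#' @export
tidy.effect_estimates <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(
      cols = c("proximity", "adaptation", "hysteresis"),
      names_to = "effect", values_to = "estimate"
    ) |>
    dplyr::mutate(se = dplyr::case_when(
      .data$effect == "proximity" ~ .data$proximity_se,
      .data$effect == "adaptation" ~ .data$adaptation_se,
      TRUE ~ .data$hysteresis_se
    )) |>
    dplyr::select("id", "effect", "estimate", "se")
}

#' @rdname tidy.effect_estimates
#' @return For `glance()`: one row with `n_individuals` and the share of
#'   individuals whose three effects have the baseline signs.
#' @method glance effect_estimates
#' @export
glance.effect_estimates <- function(x, ...) {
  tibble(
    n_individuals = nrow(x),
    prop_proximity_negative = mean(x$proximity < 0),
    prop_adaptation_positive = mean(x$adaptation > 0),
    prop_hysteresis_positive = mean(x$hysteresis > 0),
    n_separated = sum(x$separated)
  )
}
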