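#' Observer parameter set
#'
#' Collects the free parameters of the efficient Bayesian observer together
#' with the long-term prior choice and the model variant. The default values
#' are the baseline set that reproduces the average behavioral pattern:
#' `c_stim = 5`, `kappa_stim_l1 = 20`, `kappa_sens_l1 = 20`,
#' `kappa_stim_l2 = 20`, `kappa_sens_l2 = 18`, `kappa_perc_l1 = 10`,
#' `w_stim_l1 = 0.60`, `w_perc_l1 = 0.50`.
#'
#' @param c_stim Sensitivity of the likelihood-peak weighting to the lattice
#'   aspect ratio (the mixture weight ratio is `AR^c_stim`). Must be `> 0`.
#' @param kappa_stim_l1,kappa_stim_l2 Stimulus (external) noise concentrations
#'   for the first (rectangular) and second (hexagonal) lattice.
#' @param kappa_sens_l1,kappa_sens_l2 Sensory (internal) noise concentrations.
#'   The second lattice is presented more briefly, so `kappa_sens_l2` is
#'   expected to be below `kappa_sens_l1`; a warning is emitted otherwise.
#' @param kappa_perc_l1 Concentration of the von Mises bump the previous
#'   *percept* contributes to the perceptual prior for the second lattice.
#' @param w_stim_l1 Weight in [0, 1] of the first-lattice posterior in the
#'   stimulus-frequency distribution that re-derives the sensory mapping for
#'   the second lattice.
#' @param w_perc_l1 Weight in [0, 1] of the previous-percept bump in the
#'   perceptual prior for the second lattice.
#' @param prior_kind Long-term prior for the first lattice: `"uniform"` or
#'   `"natural"`.
#' @param variant Model variant: `"hierarchical"` (full model),
#'   `"stimulus_prior"` (second-lattice posterior uses the stimulus-frequency
#'   distribution instead of the perceptual prior; no hysteresis), or
#'   `"no_efficient_coding"` (identity sensory mapping throughout; no
#'   adaptation).
#' @param grid_step Orientation grid spacing in degrees (default 1; must
#'   divide 180).
#' @return An object of class `observer_params`.
#' @examples
#' observer_params()                       # baseline
#' observer_params(variant = "stimulus_prior", w_perc_l1 = 0)
#' @export
observer_params <- function(c_stim = 5,
                            kappa_stim_l1 = 20, kappa_sens_l1 = 20,
                            kappa_stim_l2 = 20, kappa_sens_l2 = 18,
                            kappa_perc_l1 = 10,
                            w_stim_l1 = 0.60, w_perc_l1 = 0.50,
                            prior_kind = c("uniform", "natural"),
                            variant = c("hierarchical", "stimulus_prior",
                                        "no_efficient_coding"),
                            grid_step = 1) {
  prior_kind <- match.arg(prior_kind)
  variant <- match.arg(variant)
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
      abort(sprintf("`%s` must be a single number.", nm),
            class = "dotlattice_parameter_error")
    }
    x
  }
  for (nm in c("kappa_stim_l1", "kappa_sens_l1", "kappa_stim_l2",
               "kappa_sens_l2", "kappa_perc_l1")) {
    if (num1(get(nm), nm) < 0) {
      abort(sprintf("`%s` must be >= 0.", nm), class = "dotlattice_parameter_error")
    }
  }
  if (num1(c_stim, "c_stim") <= 0) {
    abort("`c_stim` must be > 0.", class = "dotlattice_parameter_error")
  }
  for (nm in c("w_stim_l1", "w_perc_l1")) {
    w <- num1(get(nm), nm)
    if (w < 0 || w > 1) {
      abort(sprintf("`%s` must lie in [0, 1].", nm),
            class = "dotlattice_parameter_error")
    }
  }
  grid_points(grid_step) # validates
  if (kappa_sens_l2 > kappa_sens_l1) {
    warn("kappa_sens_l2 > kappa_sens_l1: the second lattice is usually encoded with *less* sensory precision.")
  }
  structure(
    list(c_stim = c_stim,
         kappa_stim_l1 = kappa_stim_l1, kappa_sens_l1 = kappa_sens_l1,
         kappa_stim_l2 = kappa_stim_l2, kappa_sens_l2 = kappa_sens_l2,
         kappa_perc_l1 = kappa_perc_l1,
         w_stim_l1 = w_stim_l1, w_perc_l1 = w_perc_l1,
         prior_kind = prior_kind, variant = variant, grid_step = grid_step),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  cat("<observer_params>", x$variant, "variant,", x$prior_kind, "prior\n")
  cat(sprintf("  c_stim = %g, kappa stim/sens L1 = %g/%g, L2 = %g/%g, kappa_perc_l1 = %g\n",
              x$c_stim, x$kappa_stim_l1, x$kappa_sens_l1,
              x$kappa_stim_l2, x$kappa_sens_l2, x$kappa_perc_l1))
  cat(sprintf("  w_stim_l1 = %g, w_perc_l1 = %g, grid step = %g deg\n",
              x$w_stim_l1, x$w_perc_l1, x$grid_step))
  invisible(x)
}

#' Update a subset of observer parameters
#'
#' @param params An `observer_params` object.
#' @param ... Named parameter values to replace.
#' @return A new `observer_params` object.
#' @export
update_params <- function(params, ...) {
  new <- modifyList(unclass(params), list(...))
  do.call(observer_params, new)
}

l1_mapping <- function(params, prior) {
  if (params$variant == "no_efficient_coding") {
    identity_mapping(params$grid_step)
  } else {
    cumulative_mapping(prior)
  }
}

check_condition <- function(aspect_ratio, phi, step) {
  if (!is.numeric(aspect_ratio) || aspect_ratio <= 0) {
    abort("`aspect_ratio` must be > 0.", class = "dotlattice_condition_error")
  }
  phi_snapped <- (round((phi %% 180) / step) * step) %% 180
  off <- abs(phi_snapped - (phi %% 180))
  if (min(off, 180 - off) > 1e-9) {
    warn(sprintf("phi = %g is not on the %g-degree grid; snapped to %g.",
                 phi, step, phi_snapped))
  }
  phi_snapped
}

#' First-lattice likelihood
#'
#' Double-peaked likelihood for a rectangular lattice: a weighted mixture of
#' the single-measurement likelihoods for the expected sensory measurements of
#' the relative 0 and 90 degree orientations. The weight ratio is
#' `w_AR = AR^c_stim`; the 0-degree component gets weight `1 / (1 + w_AR)`,
#' so aspect ratios below 1 (dots closer along the 0-degree axis) favor the
#' 0-degree percept.
#'
#' @param params An [observer_params()] object.
#' @param aspect_ratio Lattice aspect ratio `|a| / |b| > 0`.
#' @param phi Absolute lattice orientation in degrees (on the grid).
#' @param mapping Stimulus-to-sensory mapping for the first lattice; computed
#'   from the long-term prior when omitted.
#' @return A normalized density tibble (`theta_deg`, `density`).
#' @export
l1_likelihood <- function(params, aspect_ratio, phi = 0, mapping = NULL) {
  prior <- make_prior(params$prior_kind, params$grid_step)
  mapping <- mapping %||% l1_mapping(params, prior)
  phi <- check_condition(aspect_ratio, phi, params$grid_step)
  w_ar <- aspect_ratio^params$c_stim
  ms <- mapping_at(mapping, c(phi, phi + 90))
  mixture_likelihood(ms, c(1, w_ar) / (1 + w_ar), mapping,
                     params$kappa_stim_l1, params$kappa_sens_l1)
}

#' First-lattice posterior
#'
#' Pointwise product of the long-term prior and the first-lattice likelihood,
#' renormalized. With a uniform prior the posterior equals the normalized
#' likelihood.
#'
#' @inheritParams l1_likelihood
#' @param prior Prior density tibble; defaults to `make_prior(params$prior_kind)`.
#' @return A normalized density tibble.
#' @export
l1_posterior <- function(params, aspect_ratio, phi = 0, prior = NULL,
                         mapping = NULL) {
  prior <- prior %||% make_prior(params$prior_kind, params$grid_step)
  lik <- l1_likelihood(params, aspect_ratio, phi, mapping)
  check_same_grid(prior, lik)
  normalize_density(tibble(theta_deg = prior$theta_deg,
                           density = prior$density * lik$density))
}

#' First-lattice response probabilities
#'
#' Reads the posterior density at the two dominant relative orientations and
#' converts them to percept probabilities:
#' `p(0) = post(phi) / (post(phi) + post(phi + 90))`.
#'
#' @param posterior Normalized posterior density tibble.
#' @param phi Absolute lattice orientation in degrees.
#' @return A tibble with columns `r1` (0, 90) and `prob` summing to 1.
#' @export
l1_response_probs <- function(posterior, phi = 0) {
  assert_normalized(posterior, "posterior")
  d <- density_at(posterior, c(phi, phi + 90))
  tibble(r1 = c(0, 90), prob = d / sum(d))
}

#' Stimulus-frequency distribution for the second lattice
#'
#' Weighted mixture of the long-term prior (weight `1 - w`) and the
#' first-lattice posterior (weight `w`), representing the short-term update of
#' the frequency-of-occurrence distribution by the previous stimulus evidence.
#' It determines the sensory mapping — and only the mapping — for the second
#' lattice in the hierarchical model.
#'
#' @param prior,posterior Normalized density tibbles on the same grid.
#' @param w Mixture weight of the posterior, in [0, 1].
#' @return A normalized density tibble.
#' @export
stimulus_frequency <- function(prior, posterior, w) {
  if (!is.numeric(w) || length(w) != 1 || w < 0 || w > 1) {
    abort("`w` must lie in [0, 1].", class = "dotlattice_parameter_error")
  }
  check_same_grid(prior, posterior)
  assert_normalized(prior, "prior")
  assert_normalized(posterior, "posterior")
  normalize_density(tibble(theta_deg = prior$theta_deg,
                           density = (1 - w) * prior$density + w * posterior$density))
}

#' Perceptual prior for the second lattice
#'
#' Weighted mixture of the long-term prior (weight `1 - w`) and a
#' single-peaked axial von Mises bump at the orientation actually *perceived*
#' in the first lattice (weight `w`, concentration `kappa`). This is the prior
#' combined with the second-lattice likelihood in the hierarchical model and
#' is the source of the attractive (hysteresis) effect.
#'
#' @param prior Normalized long-term prior density tibble.
#' @param r1_abs Absolute perceived first-lattice orientation in degrees.
#' @param kappa Concentration of the percept bump (`kappa_perc_l1`).
#' @param w Mixture weight of the percept bump, in [0, 1].
#' @return A normalized density tibble.
#' @export
perceptual_prior <- function(prior, r1_abs, kappa, w) {
  if (!is.numeric(w) || length(w) != 1 || w < 0 || w > 1) {
    abort("`w` must lie in [0, 1].", class = "dotlattice_parameter_error")
  }
  assert_normalized(prior, "prior")
  bump <- vm_pdf(prior$theta_deg, r1_abs, kappa)
  normalize_density(tibble(theta_deg = prior$theta_deg,
                           density = (1 - w) * prior$density + w * bump))
}

# Shared second-lattice machinery: everything that does not depend on which
# orientation was perceived in the first lattice.
l2_context <- function(params, aspect_ratio, phi) {
  prior <- make_prior(params$prior_kind, params$grid_step)
  map1 <- l1_mapping(params, prior)
  phi <- check_condition(aspect_ratio, phi, params$grid_step)
  post1 <- l1_posterior(params, aspect_ratio, phi, prior, map1)
  p_r1 <- l1_response_probs(post1, phi)
  stimfreq <- stimulus_frequency(prior, post1, params$w_stim_l1)
  map2 <- if (params$variant == "no_efficient_coding") {
    identity_mapping(params$grid_step)
  } else {
    cumulative_mapping(stimfreq)
  }
  ms <- mapping_at(map2, phi + c(0, 60, 120))
  lik2 <- mixture_likelihood(ms, rep(1 / 3, 3), map2,
                             params$kappa_stim_l2, params$kappa_sens_l2)
  list(prior = prior, phi = phi, posterior1 = post1, p_r1 = p_r1,
       stimulus_frequency = stimfreq, mapping2 = map2, likelihood2 = lik2)
}

l2_from_context <- function(ctx, params, r1) {
  prior2 <- if (params$variant == "stimulus_prior") {
    ctx$stimulus_frequency
  } else {
    if (is.null(r1) || is.na(r1)) {
      abort("`r1` (perceived first-lattice orientation, 0 or 90) is required.",
            class = "dotlattice_condition_error")
    }
    perceptual_prior(ctx$prior, ctx$phi + r1,
                     params$kappa_perc_l1, params$w_perc_l1)
  }
  post2 <- normalize_density(tibble(theta_deg = prior2$theta_deg,
                                    density = prior2$density * ctx$likelihood2$density))
  d <- density_at(post2, ctx$phi + c(0, 60, 120))
  list(prior2 = prior2, posterior2 = post2,
       probs = tibble(r2 = c(0, 60, 120), prob = d / sum(d)))
}

#' Second-lattice prediction for one percept history
#'
#' Predicts the probabilities of perceiving the relative 0, 60 or 120 degree
#' orientation in the hexagonal second lattice, given the first-lattice aspect
#' ratio and (except in the stimulus-prior variant) the orientation perceived
#' in the first lattice. The likelihood is an equal-weight mixture of the
#' three single-measurement likelihoods under the mapping derived from the
#' stimulus-frequency distribution; the prior is the perceptual prior
#' (hierarchical and no-efficient-coding variants) or the stimulus-frequency
#' distribution itself (stimulus-prior variant).
#'
#' @inheritParams l1_likelihood
#' @param r1 Perceived first-lattice orientation relative to `phi`: 0 or 90.
#'   Ignored by the `stimulus_prior` variant.
#' @param intermediates If `TRUE`, attach the intermediate densities (priors,
#'   likelihood, posteriors) as an attribute `"densities"`.
#' @return A tibble with columns `r2` (0, 60, 120) and `prob` summing to 1.
#' @export
l2_predict <- function(params, aspect_ratio, phi = 0, r1 = NULL,
                       intermediates = FALSE) {
  ctx <- l2_context(params, aspect_ratio, phi)
  res <- l2_from_context(ctx, params, r1)
  out <- res$probs
  if (intermediates) {
    attr(out, "densities") <- list(
      prior_l1 = ctx$prior, posterior_l1 = ctx$posterior1,
      stimulus_frequency = ctx$stimulus_frequency,
      likelihood_l2 = ctx$likelihood2,
      prior_l2 = res$prior2, posterior_l2 = res$posterior2)
  }
  out
}

#' Full trial-level prediction
#'
#' Runs both stages of the observer for one trial condition and returns the
#' first-lattice percept probabilities together with the second-lattice
#' percept probabilities conditional on each possible first-lattice percept.
#'
#' @inheritParams l1_likelihood
#' @return A tidy tibble with columns `aspect_ratio`, `phi`, `lattice`
#'   (`"L1"`/`"L2"`), `r1` (conditioning percept; `NA` for L1 rows),
#'   `response` (relative orientation) and `prob`. Probabilities sum to 1
#'   within each (lattice, r1) block.
#' @examples
#' predict_trial(observer_params(), aspect_ratio = 1 / 1.3)
#' @export
predict_trial <- function(params, aspect_ratio, phi = 0) {
  ctx <- l2_context(params, aspect_ratio, phi)
  l1 <- tibble(lattice = "L1", r1 = NA_real_,
               response = ctx$p_r1$r1, prob = ctx$p_r1$prob)
  l2 <- purrr::map_dfr(c(0, 90), function(r1) {
    probs <- l2_from_context(ctx, params, r1)$probs
    tibble(lattice = "L2", r1 = r1, response = probs$r2, prob = probs$prob)
  })
  dplyr::bind_rows(l1, l2) |>
    dplyr::mutate(aspect_ratio = aspect_ratio, phi = ctx$phi, .before = 1)
}
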