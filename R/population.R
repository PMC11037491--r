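#' Default population covariance matrix
#'
#' Covariance of the raw individual parameters (`c_stim`, raw `w_stim_l1`,
#' raw `w_perc_l1`) on the 0-10 scale: variances 25, 9 and 9, with a single
#' positive covariance of 8.95 between the two raw weights (correlation
#' ~0.994) and none with `c_stim`. The positively correlated weights are what
#' lets the simulated population reproduce the positive correlation between
#' individuals' attractive and repulsive context effects.
#'
#' @return A symmetric 3x3 matrix.
#' @export
default_population_covariance <- function() {
  m <- diag(c(25, 9, 9))
  m[2, 3] <- m[3, 2] <- 8.95
  dimnames(m) <- rep(list(c("c_stim", "w_stim_l1", "w_perc_l1")), 2)
  m
}

#' Population specification
#'
#' Describes a population of simulated observers whose `c_stim`, `w_stim_l1`
#' and `w_perc_l1` are drawn from a truncated multivariate normal. Raw draws
#' live on a 0-10 scale; the two weights are afterwards divided by
#' `weight_rescale` to land in [0, 1]. Defaults: 75 individuals, means
#' (5, 6.5, 5), lower bounds 0 for all three parameters, upper bounds 10 for
#' the weights (none for `c_stim`), rescale divisor 10.
#'
#' @param n_individuals Number of observers to draw.
#' @param means Length-3 means of (`c_stim`, raw `w_stim_l1`, raw
#'   `w_perc_l1`).
#' @param covariance Symmetric positive-definite 3x3 covariance matrix.
#' @param lower,upper Length-3 truncation bounds on the raw scale.
#' @param weight_rescale Divisor mapping raw weights to [0, 1].
#' @param seed RNG seed for [draw_individuals()].
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(n_individuals = 75,
                            means = c(5, 6.5, 5),
                            covariance = default_population_covariance(),
                            lower = c(0, 0, 0),
                            upper = c(Inf, 10, 10),
                            weight_rescale = 10,
                            seed = NULL) {
  if (length(means) != 3 || length(lower) != 3 || length(upper) != 3) {
    abort("`means`, `lower` and `upper` must have length 3.",
          class = "dotlattice_parameter_error")
  }
  covariance <- as.matrix(covariance)
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (!isTRUE(all.equal(covariance, t(covariance), check.attributes = FALSE)) ||
      any(ev < -1e-8 * max(1, abs(ev)))) {
    abort("`covariance` must be symmetric positive semi-definite.",
          class = "dotlattice_parameter_error")
  }
  structure(list(n_individuals = n_individuals, means = means,
                 covariance = covariance, lower = lower, upper = upper,
                 weight_rescale = weight_rescale, seed = seed),
            class = "population_spec")
}

#' Draw individual observer parameters
#'
#' Samples `n_individuals` parameter triples from the truncated multivariate
#' normal of a [population_spec()] by rejection from the unconstrained
#' multivariate normal, then rescales the two weights by
#' `1 / weight_rescale`. An error is raised if the acceptance rate falls
#' below 1e-4, which indicates inconsistent bounds or covariance.
#'
#' @param spec A [population_spec()].
#' @param seed RNG seed; defaults to the seed in the spec. Required.
#' @return A tibble with columns `id`, `c_stim`, `w_stim_l1`, `w_perc_l1`
#'   (weights already rescaled to [0, 1]).
#' @export
draw_individuals <- function(spec, seed = spec$seed) {
  if (is.null(seed)) {
    abort("A seed is required to draw individuals.",
          class = "dotlattice_config_error")
  }
  old <- .Random.seed_safe()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  n <- spec$n_individuals
  accepted <- matrix(numeric(0), ncol = 3)
  proposed <- 0
  zero_var <- all(abs(spec$covariance) < 1e-12)
  while (nrow(accepted) < n) {
    batch <- max(1000, 4 * n)
    draws <- if (zero_var) {
      matrix(spec$means, nrow = batch, ncol = 3, byrow = TRUE)
    } else {
      MASS::mvrnorm(batch, mu = spec$means, Sigma = spec$covariance)
    }
    keep <- apply(draws, 1, function(x) all(x >= spec$lower & x <= spec$upper))
    accepted <- rbind(accepted, draws[keep, , drop = FALSE])
    proposed <- proposed + batch
    if (proposed >= 1e6 && nrow(accepted) / proposed < 1e-4) {
      abort("Truncated-normal acceptance rate below 1e-4; check the bounds and covariance.",
            class = "dotlattice_parameter_error")
    }
  }
  accepted <- accepted[seq_len(n), , drop = FALSE]
  tibble(id = seq_len(n),
         c_stim = accepted[, 1],
         w_stim_l1 = accepted[, 2] / spec$weight_rescale,
         w_perc_l1 = accepted[, 3] / spec$weight_rescale)
}

#' Simulate an experiment for every individual
#'
#' Runs [predict_experiment()] (expected mode) or [sample_experiment()]
#' (sampled mode) once per individual, substituting each individual's
#' `c_stim`, `w_stim_l1` and `w_perc_l1` into the shared observer parameters.
#'
#' @param individuals Tibble from [draw_individuals()].
#' @param design An [experiment_design()].
#' @param params Shared [observer_params()]; the three individual parameters
#'   are overridden per observer.
#' @param mode `"expected"` (deterministic) or `"sampled"`.
#' @param seed Base seed for sampled mode; individual `i` uses `seed + i`.
#' @return A response-table tibble with an `id` column.
#' @export
simulate_population <- function(individuals, design,
                                params = observer_params(),
                                mode = c("expected", "sampled"),
                                seed = attr(design, "seed")) {
  mode <- match.arg(mode)
  purrr::pmap_dfr(
    individuals[c("id", "c_stim", "w_stim_l1", "w_perc_l1")],
    function(id, c_stim, w_stim_l1, w_perc_l1) {
      p <- update_params(params, c_stim = c_stim,
                         w_stim_l1 = w_stim_l1, w_perc_l1 = w_perc_l1)
      tab <- if (mode == "expected") {
        predict_experiment(design, p)
      } else {
        if (is.null(seed)) {
          abort("A seed is required for sampled population simulation.",
                class = "dotlattice_config_error")
        }
        sample_experiment(design, p, seed = seed + id)
      }
      dplyr::mutate(tab, id = id, .before = 1)
    })
}
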