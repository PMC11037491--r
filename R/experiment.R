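#' Default aspect-ratio levels
#'
#' The seven aspect ratios used throughout:
#' `1.3^-1, 1.2^-1, 1.1^-1, 1, 1.1, 1.2, 1.3`, symmetric on the log scale.
#'
#' @return Numeric vector of length 7.
#' @export
default_aspect_ratios <- function() {
  c(1 / 1.3, 1 / 1.2, 1 / 1.1, 1, 1.1, 1.2, 1.3)
}

#' Experiment design
#'
#' Enumerates the design cells of a two-lattice experiment: every combination
#' of first-lattice aspect ratio and absolute lattice orientation, with a
#' fixed number of trials per cell. With the uniform long-term prior the model
#' is rotation invariant, so a single representative orientation (`phi = 0`)
#' suffices; with the natural prior pass `orientations = 0:179` to average
#' over the full orientation sweep.
#'
#' @param aspect_ratios Aspect-ratio levels; default [default_aspect_ratios()].
#' @param orientations Absolute lattice orientations in degrees; default 0.
#' @param n_per_condition Trials per (aspect ratio x orientation) cell
#'   (default 100).
#' @param seed Optional RNG seed used by [sample_experiment()].
#' @return A tibble with one row per design cell (columns `aspect_ratio`,
#'   `phi`, `n`), of class `experiment_design`, carrying the seed as an
#'   attribute.
#' @export
experiment_design <- function(aspect_ratios = default_aspect_ratios(),
                              orientations = 0, n_per_condition = 100,
                              seed = NULL) {
  if (any(aspect_ratios <= 0)) {
    abort("Aspect ratios must be > 0.", class = "dotlattice_condition_error")
  }
  if (n_per_condition < 1) {
    abort("`n_per_condition` must be >= 1.", class = "dotlattice_condition_error")
  }
  cells <- tidyr::expand_grid(aspect_ratio = aspect_ratios, phi = orientations)
  cells$n <- n_per_condition
  structure(cells, seed = seed, class = c("experiment_design", class(cells)))
}

# Joint (r1, r2) probabilities for every design cell; the workhorse behind
# both the expected-frequency and the sampled mode. Caches per unique
# (aspect_ratio, phi) so repeated orientations cost nothing extra.
joint_cell_probs <- function(design, params) {
  cells <- dplyr::distinct(as_tibble(design)[c("aspect_ratio", "phi")])
  purrr::pmap_dfr(cells, function(aspect_ratio, phi) {
    ctx <- l2_context(params, aspect_ratio, phi)
    purrr::map_dfr(c(0, 90), function(r1) {
      p1 <- ctx$p_r1$prob[ctx$p_r1$r1 == r1]
      probs <- l2_from_context(ctx, params, r1)$probs
      tibble(aspect_ratio = aspect_ratio, phi = phi, r1 = r1,
             r2 = probs$r2, prob_r1 = p1, prob_r2_given_r1 = probs$prob)
    })
  })
}

#' Expected response frequencies for an experiment
#'
#' Runs the observer deterministically over every design cell and returns the
#' expected joint frequency of each (first-lattice percept, second-lattice
#' percept) pair: `n * p(r1) * p(r2 | r1)`.
#'
#' @param design An [experiment_design()] tibble.
#' @param params An [observer_params()] object.
#' @return A response-table tibble with columns `aspect_ratio`, `phi`, `r1`,
#'   `r2`, `prob_r1`, `prob_r2_given_r1`, `n`, `count` and `mode`
#'   (`"expected"`). Counts within each cell sum to `n`.
#' @examples
#' predict_experiment(experiment_design(n_per_condition = 10), observer_params())
#' @export
predict_experiment <- function(design, params) {
  joint <- joint_cell_probs(design, params)
  out <- as_tibble(design) |>
    dplyr::inner_join(joint, by = c("aspect_ratio", "phi"),
                      relationship = "many-to-many") |>
    dplyr::mutate(count = .data$n * .data$prob_r1 * .data$prob_r2_given_r1,
                  mode = "expected")
  out
}

#' Sampled responses for an experiment
#'
#' Stochastic counterpart of [predict_experiment()]: draws one multinomial
#' sample of size `n` per design cell over the six (r1, r2) outcomes. A seed
#' is required so that simulated data sets are reproducible.
#'
#' @inheritParams predict_experiment
#' @param seed RNG seed; defaults to the seed stored in the design. An error
#'   is raised if neither is given.
#' @return A response-table tibble shaped like [predict_experiment()] output,
#'   with integer `count` and `mode = "sampled"`.
#' @export
sample_experiment <- function(design, params, seed = attr(design, "seed")) {
  if (is.null(seed)) {
    abort("A seed is required for sampled experiments (set it in the design or pass `seed`).",
          class = "dotlattice_config_error")
  }
  expected <- predict_experiment(design, params)
  old <- .Random.seed_safe()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  out <- expected |>
    dplyr::group_by(.data$aspect_ratio, .data$phi) |>
    dplyr::mutate(count = as.numeric(
      rmultinom(1, .data$n[1], .data$prob_r1 * .data$prob_r2_given_r1))) |>
    dplyr::ungroup() |>
    dplyr::mutate(mode = "sampled")
  out
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Logit summaries of a response table
#'
#' Collapses a response table to the curves usually plotted: the per-aspect-
#' ratio logit probability of perceiving the relative 0-degree orientation in
#' the first lattice, and in the second lattice conditional on each
#' first-lattice percept, averaged over absolute orientations. Expected-mode
#' tables use the exact `logit(p)`; sampled tables use the empirical logit
#' `log((k + 0.5) / (n - k + 0.5))`.
#'
#' @param table A response table from [predict_experiment()] or
#'   [sample_experiment()].
#' @return A tibble with columns `lattice` (`"L1"`/`"L2"`), `aspect_ratio`,
#'   `r1` (`NA` for L1 rows) and `logit`, of class `logit_summary`.
#' @export
summarize_logit <- function(table) {
  if (nrow(table) == 0) {
    abort("Empty response table.", class = "dotlattice_condition_error")
  }
  sampled <- table$mode[1] == "sampled"
  cell_logit <- function(k, n) {
    if (sampled) empirical_logit(k, n) else logit(k / n)
  }
  l1 <- table |>
    dplyr::group_by(.data$aspect_ratio, .data$phi) |>
    dplyr::summarize(k = sum(.data$count[.data$r1 == 0]),
                     n = sum(.data$count), .groups = "drop")
  l2 <- table |>
    dplyr::group_by(.data$aspect_ratio, .data$phi, .data$r1) |>
    dplyr::summarize(k = sum(.data$count[.data$r2 == 0]),
                     n = sum(.data$count), .groups = "drop")
  empty <- sum(l2$n == 0)
  if (empty > 0) {
    warn(sprintf("Dropping %d empty (aspect_ratio, phi, r1) cells.", empty))
    l2 <- l2[l2$n > 0, ]
  }
  out <- dplyr::bind_rows(
    l1 |>
      dplyr::mutate(lattice = "L1", r1 = NA_real_,
                    cell = cell_logit(.data$k, .data$n)),
    l2 |>
      dplyr::mutate(lattice = "L2", cell = cell_logit(.data$k, .data$n))
  ) |>
    dplyr::group_by(.data$lattice, .data$aspect_ratio, .data$r1) |>
    dplyr::summarize(logit = mean(.data$cell), .groups = "drop") |>
    dplyr::arrange(.data$lattice, .data$r1, .data$aspect_ratio)
  structure(out, class = c("logit_summary", class(out)))
}

#' Summary effect sizes of an observer
#'
#' Convenience summaries of the three context effects, computed directly from
#' deterministic trial probabilities (no regression): `proximity` is the
#' change in logit p(0 | L1) from the smallest to the largest aspect ratio
#' (negative at baseline); `adaptation` is the same change for logit
#' p(0 | L2), averaged over the conditioning first-lattice percept (positive
#' at baseline); `hysteresis` is the mean over aspect ratios of
#' logit p(0 | L2, r1 = 0) - logit p(0 | L2, r1 = 90) (positive at baseline).
#'
#' @param params An [observer_params()] object.
#' @param aspect_ratios Aspect-ratio levels (default the seven standard ones).
#' @param orientations Absolute orientations to average over (default 0).
#' @return A one-row tibble with columns `proximity`, `adaptation`,
#'   `hysteresis`.
#' @export
effect_sizes <- function(params, aspect_ratios = default_aspect_ratios(),
                         orientations = 0) {
  design <- experiment_design(aspect_ratios, orientations, n_per_condition = 1)
  s <- summarize_logit(predict_experiment(design, params))
  ar_lo <- min(aspect_ratios)
  ar_hi <- max(aspect_ratios)
  l1 <- s[s$lattice == "L1", ]
  l2 <- s[s$lattice == "L2", ]
  prox <- l1$logit[l1$aspect_ratio == ar_hi] - l1$logit[l1$aspect_ratio == ar_lo]
  l2_mean <- l2 |>
    dplyr::group_by(.data$aspect_ratio) |>
    dplyr::summarize(logit = mean(.data$logit), .groups = "drop")
  adapt <- l2_mean$logit[l2_mean$aspect_ratio == ar_hi] -
    l2_mean$logit[l2_mean$aspect_ratio == ar_lo]
  wide <- tidyr::pivot_wider(l2, names_from = "r1", values_from = "logit",
                             names_prefix = "r1_")
  hyst <- mean(wide$r1_0 - wide$r1_90)
  tibble(proximity = prox, adaptation = adapt, hysteresis = hyst)
}
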