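#' Semicircular (axial) von Mises density
#'
#' Density of a von Mises distribution adapted to axial data with period 180
#' degrees by angle doubling: the concentration acts on twice the orientation
#' difference, so the density is `exp(kappa * cos(2 * d)) / (pi * I0(kappa))`
#' with `d` the orientation difference in radians. The density is expressed
#' per radian and integrates to 1 over one 180-degree period. `kappa = 0`
#' gives the uniform density `1 / pi`.
#'
#' @param theta Orientation(s) in degrees (any real; period 180).
#' @param mu Mean orientation in degrees.
#' @param kappa Concentration, a single number `>= 0`. Large values give a
#'   narrow peak at `mu`.
#' @return Density values per radian, same length as `theta`.
#' @examples
#' vm_pdf(0, 0, 0)        # uniform: 1 / pi
#' vm_pdf(90, 0, 20)      # far tail of a concentrated axial density
#' @export
vm_pdf <- function(theta, mu = 0, kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1 || is.na(kappa) || kappa < 0) {
    abort("`kappa` must be a single nonnegative number.",
          class = "dotlattice_parameter_error")
  }
  d2 <- (theta - mu) * (pi / 90) # doubled angle in radians
  # exponentially-scaled Bessel keeps this stable for large kappa
  exp(kappa * (cos(d2) - 1)) / (pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Long-term orientation priors on a grid
#'
#' Tabulates one of the two long-term priors on a uniform orientation grid:
#' `"uniform"` (constant `1 / pi` per radian, the within-experiment stimulus
#' distribution where every absolute lattice orientation is equally likely) or
#' `"natural"` (proportional to `2 - |sin(2 * theta)|`, peaking at the cardinal
#' orientations 0 and 90 degrees as orientations do in natural scenes).
#'
#' @param kind `"uniform"` or `"natural"`.
#' @param step Grid spacing in degrees; must divide 180. Default 1.
#' @return A tibble with columns `theta_deg` and `density` (per radian),
#'   normalized so that its Riemann sum over the half-circle is 1.
#' @examples
#' make_prior("natural")
#' @export
make_prior <- function(kind = c("uniform", "natural"), step = 1) {
  kind <- match.arg(kind)
  theta <- grid_points(step)
  values <- switch(kind,
    uniform = rep(1 / pi, length(theta)),
    natural = 2 - abs(sin(2 * theta * DEG))
  )
  normalize_density(tibble(theta_deg = theta, density = values))
}

#' Efficient-coding stimulus-to-sensory mapping
#'
#' Builds the monotone mapping from stimulus orientation to sensory coordinate
#' induced by a frequency-of-occurrence distribution: the cumulative
#' distribution of the frequency density, rescaled to sweep [0, 180) degrees.
#' Orientations that occur more often get a steeper mapping and hence finer
#' sensory resolution; this is the efficient-encoding step of the observer.
#' The cumulative sum is left-sided so that the first grid point maps to 0,
#' and a uniform density yields the identity mapping.
#'
#' @param freq A normalized density tibble (`theta_deg`, `density`), e.g. from
#'   [make_prior()] or [stimulus_frequency()].
#' @return A tibble with columns `theta_deg` and `sensory_deg`.
#' @examples
#' cumulative_mapping(make_prior("uniform"))  # identity
#' @export
cumulative_mapping <- function(freq) {
  assert_normalized(freq, "frequency distribution")
  step <- grid_step_of(freq)
  mass <- freq$density * step * DEG
  sensory <- 180 * cumsum(c(0, mass[-length(mass)]))
  tibble(theta_deg = freq$theta_deg, sensory_deg = sensory)
}

#' Identity stimulus-to-sensory mapping
#'
#' The mapping induced by a uniform frequency distribution; used by the
#' no-efficient-coding model variant.
#'
#' @param step Grid spacing in degrees.
#' @return A mapping tibble as from [cumulative_mapping()].
#' @export
identity_mapping <- function(step = 1) {
  theta <- grid_points(step)
  tibble(theta_deg = theta, sensory_deg = theta)
}

# Evaluate a mapping at arbitrary orientations (degrees, mod 180) by linear
# interpolation; the mapping wraps to 180 at the end of the period.
mapping_at <- function(mapping, theta) {
  step <- mapping$theta_deg[2] - mapping$theta_deg[1]
  g <- nrow(mapping)
  x <- (theta %% 180) / step
  i <- pmin(floor(x), g - 1)
  frac <- x - i
  f <- c(mapping$sensory_deg, 180)
  f[i + 1] * (1 - frac) + f[i + 2] * frac
}

#' Likelihood of a single sensory measurement over stimulus orientations
#'
#' Computes `p(m | theta)` on the grid for one sensory measurement `m`. A
#' stimulus orientation `theta` is first jittered by external stimulus noise
#' (axial von Mises, symmetric in stimulus space, concentration `kappa_stim`),
#' mapped to sensory space through the efficient-coding mapping, and read out
#' with internal sensory noise (axial von Mises, symmetric in *sensory* space,
#' concentration `kappa_sens`). The likelihood is the quadrature
#' `sum_j vm(m - F(theta_j); kappa_sens) * vm(theta_j - theta; kappa_stim) * dtheta`.
#'
#' With the identity mapping this is a symmetric function of `theta - m`; with
#' a non-uniform mapping the unequal sensory resolution makes it asymmetric in
#' stimulus space, biasing estimates away from frequent orientations
#' (likelihood repulsion).
#'
#' @param m Sensory coordinate of the measurement, degrees in [0, 180).
#' @param mapping Mapping tibble from [cumulative_mapping()].
#' @param kappa_stim,kappa_sens Nonnegative concentrations of the stimulus and
#'   sensory noise.
#' @param normalize If `TRUE` (default) the returned function of `theta` is
#'   renormalized to unit mass so it can be treated as a density for plotting
#'   and mixing; response probabilities are invariant to this scale.
#' @return A density tibble (`theta_deg`, `density`).
#' @export
measurement_likelihood <- function(m, mapping, kappa_stim, kappa_sens,
                                   normalize = TRUE) {
  if (any(m < 0) || any(m >= 180)) {
    abort("`m` must lie in [0, 180) degrees.", class = "dotlattice_parameter_error")
  }
  theta <- mapping$theta_deg
  step <- theta[2] - theta[1]
  if (step <= 0) {
    abort("Mapping grid has zero resolution.", class = "dotlattice_config_error")
  }
  sens <- vm_pdf(m, mapping$sensory_deg, kappa_sens)
  lag <- outer(theta, theta, "-") # lag[j, i] = theta_j - theta_i
  values <- as.vector(sens %*% vm_pdf(lag, 0, kappa_stim)) * step * DEG
  out <- tibble(theta_deg = theta, density = values)
  if (normalize) normalize_density(out) else out
}

# Mixture likelihood for several measurements with given weights. The raw
# convolution values are mixed directly (no per-component renormalization):
# under a non-uniform mapping the component at a frequent orientation is
# narrow in stimulus space and the stimulus-noise convolution flattens its
# peak, which is exactly the likelihood-repulsion mechanism. Only the final
# mixture is normalized, which leaves response probabilities untouched.
mixture_likelihood <- function(ms, weights, mapping, kappa_stim, kappa_sens) {
  theta <- mapping$theta_deg
  step <- theta[2] - theta[1]
  sens <- vapply(ms, function(m) vm_pdf(m, mapping$sensory_deg, kappa_sens),
                 numeric(length(theta)))
  lag <- outer(theta, theta, "-")
  comps <- crossprod(sens, vm_pdf(lag, 0, kappa_stim)) * step * DEG
  values <- as.vector(weights %*% comps)
  normalize_density(tibble(theta_deg = theta, density = values))
}

#' Write a density to CSV
#'
#' @param density A density tibble (`theta_deg`, `density`).
#' @param path Output file path.
#' @return The input, invisibly.
#' @export
write_density_csv <- function(density, path) {
  readr::write_csv(density, path)
  invisible(density)
}
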