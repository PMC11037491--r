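# Independent oracles used by the tests. These deliberately avoid the package
# internals: the von Mises sampler is Best & Fisher (1979) rejection, the
# mapping interpolation and the truncated-normal reference are coded from
# scratch here.

# von Mises sampler on [-pi, pi), concentration kappa (Best-Fisher rejection).
rvonmises_oracle <- function(n, kappa) {
  if (kappa < 1e-8) {
    return(stats::runif(n, -pi, pi))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- n - length(out)
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, sign(u3[keep] - 0.5) * acos(pmin(pmax(f[keep], -1), 1)))
  }
  out[seq_len(n)]
}

# Axial noise in degrees on (-90, 90]: half the angle of a full-circle draw.
raxial_oracle <- function(n, kappa) {
  rvonmises_oracle(n, kappa) * 90 / pi
}

# Linear interpolation of a cumulative mapping, wrapping to 180.
mapping_lookup_oracle <- function(mapping, theta) {
  x <- c(mapping$theta_deg, 180)
  y <- c(mapping$sensory_deg, 180)
  stats::approx(x, y, xout = theta %% 180, rule = 2)$y
}

# Monte-Carlo estimate of p(m | theta): simulate the generative measurement
# chain (stimulus noise in stimulus space, mapping, sensory noise in sensory
# space) and bin the simulated measurements around the observed one.
mc_measurement_likelihood <- function(m, theta, mapping, kappa_stim,
                                      kappa_sens, n_samples = 1e6,
                                      bin_deg = 1) {
  vapply(theta, function(th) {
    th_jit <- (th + raxial_oracle(n_samples, kappa_stim)) %% 180
    sens <- mapping_lookup_oracle(mapping, th_jit)
    m_sim <- (sens + raxial_oracle(n_samples, kappa_sens)) %% 180
    d <- abs(((m_sim - m + 90) %% 180) - 90)
    mean(d < bin_deg / 2) / (bin_deg * pi / 180)
  }, numeric(1))
}

# Hand-rolled truncated-MVN rejection sampler (Cholesky, no MASS).
rtruncmvn_oracle <- function(n, mu, sigma, lower, upper) {
  L <- chol(sigma)
  out <- matrix(numeric(0), ncol = length(mu))
  while (nrow(out) < n) {
    z <- matrix(stats::rnorm(3 * n * length(mu)), ncol = length(mu))
    draws <- sweep(z %*% L, 2, mu, "+")
    keep <- apply(draws, 1, function(x) all(x >= lower & x <= upper))
    out <- rbind(out, draws[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# Rescale a tabulated density to a unit-sum discrete distribution, the common
# scale on which implementation and Monte-Carlo oracle are compared.
as_prob <- function(values) values / sum(values)

# Nearest-grid-point density lookup (1-degree grids in tests).
density_at_test <- function(density, theta) {
  density$density[match(round(theta) %% 180, density$theta_deg)]
}

# The default-population run is shared by several expensive tests; compute it
# once per test session.
.cache <- new.env(parent = emptyenv())

baseline_population_effects <- function(seed = 20240418 %% 100000) {
  key <- paste0("pop_", seed)
  if (is.null(.cache[[key]])) {
    spec <- population_spec(seed = seed)
    individuals <- draw_individuals(spec)
    design <- experiment_design(n_per_condition = 100)
    tables <- suppressWarnings(
      simulate_population(individuals, design, observer_params(),
                          mode = "expected")
    )
    .cache[[key]] <- list(individuals = individuals,
                          tables = tables,
                          effects = estimate_effects(tables))
  }
  .cache[[key]]
}
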