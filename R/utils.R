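# Shared small helpers. Orientations live on the half-circle [0, 180) degrees;
# densities are tabulated per radian, so a normalized density satisfies
# sum(density) * step * pi / 180 == 1.

DEG <- pi / 180

logit <- function(p) log(p) - log1p(-p)

#' Empirical logit of a count
#'
#' `log((k + 0.5) / (n - k + 0.5))`, the usual continuity-corrected logit of a
#' binomial proportion, finite even at k = 0 or k = n.
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @return Numeric vector of empirical logits.
#' @export
empirical_logit <- function(k, n) {
  log(k + 0.5) - log(n - k + 0.5)
}

grid_points <- function(step = 1) {
  if (!is.numeric(step) || length(step) != 1 || step <= 0 || abs(180 / step - round(180 / step)) > 1e-9) {
    abort("`step` must be a positive divisor of 180 degrees.", class = "dotlattice_config_error")
  }
  seq(0, 180 - step, by = step)
}

grid_step_of <- function(density) {
  theta <- density$theta_deg
  if (length(theta) < 2) {
    abort("Orientation grid needs at least two points.", class = "dotlattice_config_error")
  }
  step <- theta[2] - theta[1]
  if (max(abs(diff(theta) - step)) > 1e-9 || abs(theta[1]) > 1e-9 ||
      abs(180 / step - round(180 / step)) > 1e-9) {
    abort("Orientation grid must be uniform on [0, 180) starting at 0.",
          class = "dotlattice_config_error")
  }
  step
}

density_mass <- function(density) {
  sum(density$density) * grid_step_of(density) * DEG
}

normalize_density <- function(density) {
  density$density <- density$density / (sum(density$density) * grid_step_of(density) * DEG)
  density
}

assert_normalized <- function(density, what = "density", tol = 1e-6) {
  if (abs(density_mass(density) - 1) > tol) {
    abort(sprintf("%s is not normalized (mass = %.6g).", what, density_mass(density)),
          class = "dotlattice_density_error")
  }
  invisible(density)
}

# Nearest-grid-point density lookup at an orientation in degrees (mod 180).
density_at <- function(density, theta) {
  step <- grid_step_of(density)
  idx <- (round((theta %% 180) / step) %% (180 / step)) + 1
  density$density[idx]
}

check_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b) || max(abs(a$theta_deg - b$theta_deg)) > 1e-9) {
    abort("Inputs are tabulated on different orientation grids.",
          class = "dotlattice_shape_error")
  }
  invisible(TRUE)
}
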