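# Fixture builders shared across the test files. All fixtures are built in
# code; closed forms are stated next to each builder so the tests can assert
# against them independently of the analysis path.

# Exponential isotherm A(pi) = A0 * exp(-pi / k): constant modulus Cs^-1 = k.
exp_isotherm <- function(A0 = 60, k = 50, pi_max = 45, step = 0.25, ...) {
  p <- seq(0, pi_max, by = step)
  isotherm(area = A0 * exp(-p / k), pressure = p, ...)
}

# Linear isotherm pi = m * (A0 - A) for A <= A0, pi = 0 above, sampled on a
# uniform area grid. Its steepest-segment zero-pressure extrapolation is A0
# and its modulus is m * A.
linear_isotherm <- function(A0 = 80, m = 2, A_min = 40, A_max = 120, step = 0.5, ...) {
  a <- seq(A_max, A_min, by = -step)
  isotherm(area = a, pressure = pmax(0, m * (A0 - a)), ...)
}

# Kinked isotherm: steep linear rise to (A_C, pi_C), then a shallow
# post-collapse rise, on a uniform area grid.
kinked_isotherm <- function(A_L = 150, A_C = 44, pi_C = 54, post_slope = 0.05,
                            step = 0.5, A_max = 170, A_min = 30, ...) {
  a <- seq(A_max, A_min, by = -step)
  m <- pi_C / (A_L - A_C)
  p <- ifelse(a >= A_L, 0,
              ifelse(a >= A_C, m * (A_L - a), pi_C + post_slope * (A_C - a)))
  isotherm(area = a, pressure = p, ...)
}

# Components for mixture tests: two exponential films on a shared pressure
# grid (so ideal mixing cancels exactly under linear interpolation).
mixture_components <- function(pi_max = 45, step = 0.25) {
  list(
    list(fraction = 0.6, isotherm = exp_isotherm(A0 = 70, k = 60, pi_max = pi_max, step = step)),
    list(fraction = 0.4, isotherm = exp_isotherm(A0 = 40, k = 45, pi_max = pi_max, step = step))
  )
}

expect_rel_equal <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol * abs(expected)),
              label = sprintf("max rel err %.3g vs tol %.3g",
                              max(abs(object - expected) / abs(expected)), tol))
}
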