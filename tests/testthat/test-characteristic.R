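test_that("liftoff area is found where pressure first exceeds baseline + threshold", {
  iso <- kinked_isotherm(A_L = 150, A_C = 44, pi_C = 54, step = 0.5)
  expect_lt(abs(liftoff_area(iso, threshold = 0.5) - 150), 2 * 0.5 + 1e-9)
  expect_error(liftoff_area(isotherm(area = seq(100, 50, by = -1),
                                     pressure = rep(0, 51))),
               "never exceeds")
})

test_that("liftoff survives baseline noise (sigma = 0.05 mN/m, 100 seeds)", {
  step <- 0.5
  a <- seq(170, 100, by = -step)
  p_clean <- pmax(0, 1.0 * (150 - a))
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    iso <- isotherm(area = a, pressure = p_clean + rnorm(length(a), sd = 0.05))
    abs(liftoff_area(iso, threshold = 0.5) - 150)
  }, numeric(1))
  expect_true(all(errs <= 2 * step + 1e-9))
})

test_that("limiting area extrapolates the steepest segment to zero pressure", {
  # a straight line extrapolates to its own zero crossing
  expect_equal(as.numeric(limiting_area(linear_isotherm(A0 = 80, m = 2))), 80,
               tolerance = 1e-8)
  # two-slope isotherm whose steep segment lies on pi = 5 * (60 - A)
  a <- seq(100, 40, by = -0.5)
  p <- ifelse(a >= 70, pmax(0, 0.5 * (80 - a)), 5 * (70 - a) + 0.5 * (80 - 70))
  iso <- isotherm(area = a, pressure = p)
  # steep branch: pi = 5 - 5*(a - 70) + ... ; its zero crossing:
  # pi(a) = 5*(70 - a) + 5 -> 0 at a = 71
  expect_equal(as.numeric(limiting_area(iso)), 71, tolerance = 1e-6)
  expect_error(limiting_area(exp_isotherm(), window = 2), "at least 3")
  expect_error(limiting_area(linear_isotherm(step = 8), window = 15),
               "fewer samples")
})

test_that("limiting area is invariant under uniform pressure rescaling", {
  a <- seq(100, 40, by = -0.5)
  base <- pmax(0, 3 * (75 - a))
  for (scale in c(0.5, 2, 10)) {
    iso <- isotherm(area = a, pressure = base * scale)
    expect_equal(as.numeric(limiting_area(iso)), 75, tolerance = 1e-6)
  }
})

test_that("collapse point sits at the slope-drop kink", {
  iso <- kinked_isotherm(A_L = 150, A_C = 44, pi_C = 54, step = 0.5)
  cp <- collapse_point(iso)
  expect_false(isTRUE(attr(cp, "no_distinct_collapse")))
  expect_lt(abs(cp[["A_C"]] - 44), 0.5 + 1e-9)
  expect_lt(abs(cp[["pi_C"]] - 54), 54 / (150 - 44) * 0.5 + 1e-9)
})

test_that("collapse detection degrades gracefully", {
  # smooth exponential truncated at 45 mN/m: no kink, final point flagged
  iso <- exp_isotherm(A0 = 60, k = 12, pi_max = 45)
  cp <- collapse_point(iso)
  expect_true(isTRUE(attr(cp, "no_distinct_collapse")))
  expect_equal(cp[["pi_C"]], 45)
  expect_equal(cp[["A_C"]], min(iso$area))
  # truncated below 30 mN/m: detection error
  expect_error(collapse_point(exp_isotherm(A0 = 60, k = 50, pi_max = 20)),
               "never exceeds 30")
})

test_that("additivity rule is the fraction-weighted sum and validates input", {
  expect_equal(round(ideal_limiting_area(c(0.9, 0.1), c(61.87, 32.99)), 2), 58.98)
  expect_equal(round(ideal_limiting_area(c(0.7, 0.3), c(61.87, 32.99)), 2), 53.21)
  expect_equal(round(ideal_limiting_area(c(0.5, 0.5), c(61.87, 32.99)), 2), 47.43)
  expect_identical(ideal_limiting_area(c(1, 0), c(61.87, 999)), 61.87)
  # three-component form is expressible too
  expect_equal(ideal_limiting_area(c(0.2, 0.3, 0.5), c(50, 60, 70)), 63)
  expect_error(ideal_limiting_area(c(0.6, 0.5), c(50, 60)), "sum to 1")
  expect_error(ideal_limiting_area(c(0.5, 0.5), c(-1, 60)), "positive")
})

test_that("ideal limiting area is linear in fractions and bounded by components", {
  areas <- c(61.87, 32.99)
  for (x in seq(0, 1, by = 0.1)) {
    v <- ideal_limiting_area(c(1 - x, x), areas)
    expect_equal(v, (1 - x) * areas[1] + x * areas[2])
    expect_gte(v, min(areas)); expect_lte(v, max(areas))
  }
})

test_that("additivity deviation is experimental minus ideal", {
  ideal_07 <- ideal_limiting_area(c(0.3, 0.7), c(61.87, 32.99))
  expect_equal(round(additivity_deviation(40.79, ideal_07), 2), -0.86)
  expect_equal(additivity_deviation(50, 50), 0)
})

test_that("generator round trip recovers all characteristic parameters (noise-free)", {
  # prescribed: collapse at pi_C = 54 with a steep condensed branch; the
  # generator's ground-truth area function pins A_L, A_inf, A_C
  profile <- modulus_profile(c(0, 2, 6, 10, 14, 25, 40, 50),
                             c(8, 20, 35, 18, 40, 90, 140, 150))
  step <- 0.25
  iso <- isotherm_from_modulus(profile, reference_area = 95,
                               pressure_grid = seq(0, 55, by = step),
                               collapse = list(pressure = 54, modulus = 3))
  gt <- attr(iso, "ground_truth")
  grid_area_step <- max(abs(diff(iso$area)))

  # collapse: prescribed kink
  cp <- collapse_point(iso)
  expect_lt(abs(cp[["pi_C"]] - 54), 2 * step + 1e-9)
  expect_lt(abs(cp[["A_C"]] - gt$area_fun(54)), 2 * grid_area_step + 1e-9)

  # liftoff: prepend a gaseous plateau (zero pressure at large areas, as a
  # real record would show) so the baseline is flat; detection must land at
  # the prescribed area where pi passes the 0.5 mN/m threshold
  full <- isotherm(area = c(seq(95 + 48, 95 + 1, by = -1), iso$area),
                   pressure = c(rep(0, 48), iso$pressure))
  expect_lt(abs(liftoff_area(full) - gt$area_fun(0.5)), 2 * grid_area_step + 1e-9)

  # limiting area: steepest pre-collapse window extrapolated to pi = 0;
  # oracle computed from the ground-truth area function at the same window
  al <- limiting_area(iso)
  slope_true <- function(p) -profile$fun(p) / gt$area_fun(p)  # dpi/dA at p
  # the steepest stretch is just below collapse (highest modulus, small A)
  p_star <- 53.9
  a_star <- gt$area_fun(p_star)
  oracle <- a_star - p_star / slope_true(p_star)  # line through (a*, p*) at true slope
  expect_lt(abs(as.numeric(al) - oracle), 2)
})
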