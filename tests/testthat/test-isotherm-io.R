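test_that("composition validates fractions", {
  x <- composition(c(DPPC = 0.72, DPPG = 0.18, AmB = 0.10))
  expect_s3_class(x, "composition")
  expect_equal(sum(x), 1)
  expect_error(composition(c(a = 0.5, b = 0.6)), "sum to 1")
  expect_error(composition(c(a = -0.1, b = 1.1)), "\\[0, 1\\]")
  expect_error(composition(c(0.5, 0.5)), "named")
})

test_that("isotherm constructor canonicalizes order and rejects bad input", {
  p <- seq(0, 20, length.out = 30)
  a <- 90 - 2 * p
  iso_comp <- isotherm(area = a, pressure = p)                 # compression order after sort
  iso_exp <- isotherm(area = rev(a), pressure = rev(p))        # expansion order input
  expect_identical(iso_comp$area, iso_exp$area)
  expect_identical(iso_comp$pressure, iso_exp$pressure)
  expect_true(all(diff(iso_comp$area) < 0))

  # duplicate areas averaged
  iso_dup <- isotherm(area = c(a, a[5]), pressure = c(p, p[5] + 1))
  expect_equal(length(iso_dup$area), 30)
  expect_equal(iso_dup$pressure[5], p[5] + 0.5)

  expect_error(isotherm(area = a[1:5], pressure = p[1:5]), "at least 10")
  expect_error(isotherm(area = c(-1, a[-1]), pressure = p), "positive")
  expect_error(isotherm(area = a, pressure = c(-1, p[-1])), "noise floor")
  expect_error(isotherm(area = a, pressure = p[-1]), "equal length")
})

test_that("isotherm CSV read -> write -> read round-trips bit-identically", {
  dir <- withr::local_tempdir()
  iso <- exp_isotherm(composition = composition(c(DPPC = 0.8, DPPG = 0.2)),
                      label = "roundtrip")
  f1 <- file.path(dir, "iso1.csv"); m1 <- file.path(dir, "iso1.json")
  write_isotherm(iso, f1, metadata = m1)
  back <- read_isotherm(f1, metadata = m1)
  expect_equal(back$area, iso$area)
  expect_equal(back$pressure, iso$pressure)
  expect_equal(unclass(back$composition), unclass(iso$composition))
  expect_identical(back$label, "roundtrip")

  f2 <- file.path(dir, "iso2.csv")
  write_isotherm(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("reader flags missing and non-numeric columns with the offending row", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.csv")
  writeLines(c("area_A2,pressure_mN_m", "100,0.0", "95,NA", "90,1.0"), bad)
  expect_error(read_isotherm(bad), "row 2")
  writeLines(c("area,press", "100,0.0"), bad)
  expect_error(read_isotherm(bad), "missing column")
})

test_that("sidecar metadata populates composition and temperature, with defaults", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "iso.csv")
  write_isotherm(exp_isotherm(), f)
  y <- file.path(dir, "meta.yaml")
  writeLines(c("components:", "  DPPC: 0.5", "  AmB: 0.5",
               "temperature_K: 298.15", "label: mix"), y)
  iso <- read_isotherm(f, metadata = y)
  expect_equal(unclass(iso$composition), c(DPPC = 0.5, AmB = 0.5))
  expect_equal(iso$temperature, 298.15)
  # no sidecar: the 35 C default
  expect_equal(read_isotherm(f)$temperature, 308.15)
})

test_that("area_at_pressure is the identity on a strictly monotone record", {
  iso <- exp_isotherm(A0 = 60, k = 50)
  expect_equal(area_at_pressure(iso, iso$pressure), iso$area)
  # closed form at an off-grid point via linear interpolation of a smooth curve
  expect_equal(area_at_pressure(iso, 25), 60 * exp(-0.5), tolerance = 1e-4)
})

test_that("area_at_pressure monotonizes plateaus and clamps below the record", {
  # non-monotone pressure: dip in the middle of a rise
  a <- seq(100, 50, by = -1)
  p <- seq(0, 25, length.out = length(a))
  p[20:25] <- p[19]  # flat stretch
  p[30] <- p[29] - 0.3  # noise dip
  iso <- isotherm(area = a, pressure = p)
  got <- area_at_pressure(iso, seq(0, 24, by = 0.5))
  expect_true(all(diff(got) <= 1e-12))

  # clamp: queries below the record's first pressure return the floor area
  iso2 <- isotherm(area = seq(90, 60, by = -1), pressure = seq(5, 20, length.out = 31))
  expect_equal(area_at_pressure(iso2, c(0, 1, 5)), c(90, 90, 90))
  # explicit floor at a liftoff threshold
  expect_equal(area_at_pressure(iso2, 0, floor_pressure = 6),
               area_at_pressure(iso2, 6))

  # above the recorded maximum: range error
  expect_error(area_at_pressure(iso2, 200), "above maximum recorded")
})

test_that("area_at_pressure is monotone non-increasing for noisy records", {
  for (s in 1:20) {
    iso <- isotherm_from_modulus(modulus_profile(c(0, 10, 30), c(15, 40, 90)),
                                 reference_area = 80,
                                 pressure_grid = seq(0, 35, by = 0.25),
                                 noise_sd = 0.2, seed = s)
    grid <- seq(0, 30, by = 0.5)
    expect_true(all(diff(area_at_pressure(iso, grid)) <= 1e-12))
  }
})

test_that("relaxation trace IO round-trips with sidecar", {
  dir <- withr::local_tempdir()
  tr <- simulate_relaxation(C = 0.7, a = 0.25, tau = 500, pi0 = 15,
                            t_max = 2000, n_points = 50)
  f <- file.path(dir, "trace.csv"); m <- file.path(dir, "trace.json")
  write_relaxation_trace(tr, f, metadata = m)
  back <- read_relaxation_trace(f, metadata = m)
  expect_equal(back$time, tr$time)
  expect_equal(back$pressure, tr$pressure)
  expect_equal(back$initial_pressure, 15)
  expect_error(relaxation_trace(time = c(0, 1, 1, 2:8), pressure = rep(1, 10)),
               "strictly increasing")
  expect_error(relaxation_trace(time = 0:9, pressure = rep(1, 10),
                                initial_pressure = 0), "positive")
})
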