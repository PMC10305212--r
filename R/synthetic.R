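#' Piecewise elasticity profile
#'
#' A prescribed compressional modulus Cs^-1 as a function of surface
#' pressure, given as knots with monotone (Fritsch-Carlson) interpolation
#' between them. Inverting `Cs^-1 = -A dpi/dA` turns such a profile into a
#' synthetic isotherm with exactly known elasticity everywhere, which is
#' what makes generator/analyzer round trips possible.
#'
#' @param pressure knot pressures (mN/m), strictly ascending.
#' @param modulus knot modulus values (mN/m), all > 0.
#' @return An object of class `"modulus_profile"`: list with the knots and
#'   `fun`, a vectorized function pi -> Cs^-1 (constant beyond the outer
#'   knots).
#' @export
modulus_profile <- function(pressure, modulus) {
  pressure <- as.numeric(pressure); modulus <- as.numeric(modulus)
  if (length(pressure) != length(modulus) || length(pressure) < 1) {
    stop("pressure and modulus knots must have equal positive length", call. = FALSE)
  }
  if (is.unsorted(pressure, strictly = TRUE)) {
    stop("knot pressures must be strictly ascending", call. = FALSE)
  }
  if (any(modulus <= 0)) stop("modulus values must be positive", call. = FALSE)
  fun <- if (length(pressure) == 1L) {
    function(p) rep(modulus, length(p))
  } else {
    sf <- stats::splinefun(pressure, modulus, method = "monoH.FC")
    lo <- pressure[1]; hi <- pressure[length(pressure)]
    function(p) sf(pmin(pmax(p, lo), hi))
  }
  structure(list(pressure = pressure, modulus = modulus, fun = fun),
            class = "modulus_profile")
}

#' Generate a synthetic isotherm from a prescribed elasticity profile
#'
#' Inverts the modulus definition: with Cs^-1(pi) prescribed, the area obeys
#' `A(pi) = A_ref * exp(-integral_0^pi dp / Cs^-1(p))`, evaluated by
#' cumulative trapezoidal quadrature on a fine grid. An optional collapse
#' switches the film to a small post-collapse modulus above `pi_C`, so the
#' record shows the near-plateau (fast area loss at almost constant
#' pressure) that collapse detection looks for. Gaussian pressure noise, if
#' requested, is reproducible via `seed`.
#'
#' @param profile a [modulus_profile()] (or a single positive number for a
#'   constant modulus).
#' @param reference_area area at pi = 0, Angstrom^2/molecule (> 0).
#' @param pressure_grid ascending pressures from 0 (mN/m) at which to sample.
#' @param collapse optional `list(pressure = pi_C, modulus = )` giving the
#'   collapse pressure and the (small) post-collapse modulus in mN/m.
#' @param noise_sd Gaussian pressure noise s.d. (mN/m, >= 0).
#' @param seed integer seed used when `noise_sd > 0`.
#' @param composition,temperature,label passed to [isotherm()].
#' @param refine quadrature refinement: integration substeps per grid
#'   interval.
#' @return An [isotherm()] with attribute `ground_truth`: list with the
#'   profile, `area_fun` (pi -> noise-free area) and the collapse settings.
#' @export
isotherm_from_modulus <- function(profile, reference_area = 60,
                                  pressure_grid = seq(0, 50, by = 0.25),
                                  collapse = NULL, noise_sd = 0, seed = 1L,
                                  composition = monofilm::composition(c(film = 1)),
                                  temperature = DEFAULT_TEMPERATURE_K,
                                  label = "synthetic", refine = 8L) {
  if (is.numeric(profile) && length(profile) == 1L) {
    profile <- modulus_profile(0, profile)
  }
  stopifnot(inherits(profile, "modulus_profile"), reference_area > 0, noise_sd >= 0)
  pressure_grid <- as.numeric(pressure_grid)
  if (pressure_grid[1] != 0 || is.unsorted(pressure_grid, strictly = TRUE)) {
    stop("pressure_grid must ascend strictly from 0", call. = FALSE)
  }
  cs <- function(p) {
    m <- profile$fun(p)
    if (!is.null(collapse)) {
      stopifnot(is.numeric(collapse$pressure), collapse$pressure > 0,
                is.numeric(collapse$modulus), collapse$modulus > 0)
      m[p > collapse$pressure] <- collapse$modulus
    }
    if (any(m <= 0)) stop("modulus profile must be positive everywhere", call. = FALSE)
    m
  }
  # fine grid: every sample pressure plus `refine` substeps per interval,
  # plus the collapse pressure itself so the kink is integrated exactly
  fine <- sort(unique(c(
    unlist(lapply(seq_len(length(pressure_grid) - 1L), function(i) {
      seq(pressure_grid[i], pressure_grid[i + 1L], length.out = refine + 1L)
    })),
    if (!is.null(collapse)) collapse$pressure
  )))
  integ <- pracma::cumtrapz(fine, 1 / cs(fine))[, 1]
  area_fine <- reference_area * exp(-integ)
  area_fun <- stats::approxfun(fine, area_fine, rule = 2)
  area <- area_fun(pressure_grid)
  pressure <- pressure_grid
  if (noise_sd > 0) {
    old <- globalenv()$.Random.seed
    set.seed(as.integer(seed))
    pressure <- pressure + stats::rnorm(length(pressure), sd = noise_sd)
    pressure <- pmax(pressure, -0.5)
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  }
  iso <- isotherm(area = area, pressure = pressure, composition = composition,
                  temperature = temperature, label = label)
  attr(iso, "ground_truth") <- list(profile = profile, area_fun = area_fun,
                                    collapse = collapse,
                                    reference_area = reference_area)
  iso
}

#' Build a mixture isotherm with a prescribed non-ideality
#'
#' Constructs the isotherm of a hypothetical mixed film whose area at every
#' surface pressure is the ideal (mole-fraction-weighted) combination of the
#' component areas plus a prescribed deviation `delta(pi)` in
#' Angstrom^2/molecule. The exact excess Gibbs energy of such a film is
#' `integral_0^pi delta dp`, so the thermodynamic analysis has a closed-form
#' ground truth; it is attached (in J/mol, as a function of pi) in attribute
#' `ground_truth_GE`.
#'
#' @param components list of `list(fraction = , isotherm = )`, fractions
#'   summing to 1, isotherms sharing a common pressure range.
#' @param delta function pi -> deviation in Angstrom^2/molecule (vectorized);
#'   default: no deviation (ideal mixing).
#' @param pressure_grid pressures (mN/m) at which to sample the mixture;
#'   default: a 201-point uniform grid over the common range.
#' @param composition,temperature,label passed to [isotherm()]; composition
#'   defaults to the fraction-weighted combination of component compositions.
#' @return An [isotherm()] with attribute `ground_truth_GE` (function pi ->
#'   J/mol) and `delta` (the deviation function).
#' @export
mixture_with_deviation <- function(components, delta = function(p) rep(0, length(p)),
                                   pressure_grid = NULL,
                                   composition = NULL,
                                   temperature = DEFAULT_TEMPERATURE_K,
                                   label = "synthetic mixture") {
  fr <- check_components(components)
  lo <- max(vapply(components, function(cm) compression_envelope(cm$isotherm)$pressure[1], numeric(1)))
  hi <- min(vapply(components, function(cm) max(cm$isotherm$pressure), numeric(1)))
  if (hi <= lo) stop("components share no common pressure range", call. = FALSE)
  if (is.null(pressure_grid)) pressure_grid <- seq(lo, hi, length.out = 201L)
  if (any(pressure_grid < lo - 1e-9) || any(pressure_grid > hi + 1e-9)) {
    stop(sprintf("pressure_grid outside the common range [%.3f, %.3f] mN/m", lo, hi),
         call. = FALSE)
  }
  a_ideal <- 0
  for (k in seq_along(components)) {
    a_ideal <- a_ideal + fr[k] * area_at_pressure(components[[k]]$isotherm, pressure_grid)
  }
  area <- a_ideal + delta(pressure_grid)
  if (any(area <= 0)) {
    stop("deviation drives the mixture area nonpositive", call. = FALSE)
  }
  if (is.null(composition)) {
    acc <- list()
    for (k in seq_along(components)) {
      cc <- unclass(components[[k]]$isotherm$composition)
      for (nm in names(cc)) acc[[nm]] <- (if (is.null(acc[[nm]])) 0 else acc[[nm]]) + fr[k] * cc[[nm]]
    }
    composition <- monofilm::composition(unlist(acc))
  }
  iso <- isotherm(area = area, pressure = pressure_grid, composition = composition,
                  temperature = temperature, label = label)
  truth <- function(p) {
    vapply(p, function(pp) {
      g <- seq(0, pp, length.out = 2001L)
      pracma::trapz(g, delta(g)) * A2_MNM_TO_J_MOL
    }, numeric(1))
  }
  attr(iso, "ground_truth_GE") <- truth
  attr(iso, "delta") <- delta
  iso
}

#' Simulate a constant-area relaxation trace
#'
#' Generates `pi(t) = pi0 * (C + a * exp(-t / tau))` on a uniform time grid,
#' with optional Gaussian pressure noise (mN/m scale; a noise s.d. of
#' `s * pi0` corresponds to s.d. `s` on the normalized pi/pi0 scale).
#' Reproducible via `seed`.
#'
#' @param C normalized equilibrium pressure (dimensionless).
#' @param a decay amplitude (dimensionless).
#' @param tau relaxation lifetime, s (> 0).
#' @param pi0 initial surface pressure, mN/m (> 0).
#' @param t_max trace length, s.
#' @param n_points number of samples (>= 10).
#' @param noise_sd Gaussian pressure noise s.d., mN/m (>= 0).
#' @param seed integer seed used when `noise_sd > 0`.
#' @param composition,temperature,label passed to [relaxation_trace()].
#' @return A [relaxation_trace()] with attribute `ground_truth` = list(C, a,
#'   tau).
#' @export
simulate_relaxation <- function(C, a, tau, pi0, t_max = 4 * tau, n_points = 300L,
                                noise_sd = 0, seed = 1L,
                                composition = monofilm::composition(c(film = 1)),
                                temperature = DEFAULT_TEMPERATURE_K,
                                label = "synthetic relaxation") {
  stopifnot(is.numeric(C), is.numeric(a), tau > 0, pi0 > 0, t_max > 0,
            noise_sd >= 0)
  n_points <- as.integer(n_points)
  if (n_points < 10L) stop("n_points must be at least 10", call. = FALSE)
  t <- seq(0, t_max, length.out = n_points)
  p <- pi0 * (C + a * exp(-t / tau))
  if (noise_sd > 0) {
    old <- globalenv()$.Random.seed
    set.seed(as.integer(seed))
    p <- p + stats::rnorm(n_points, sd = noise_sd)
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  }
  tr <- relaxation_trace(time = t, pressure = p, initial_pressure = pi0,
                         composition = composition, temperature = temperature,
                         label = label)
  attr(tr, "ground_truth") <- list(C = C, a = a, tau = tau)
  tr
}

#' Default synthetic scenario bundle
#'
#' Two qualitative film archetypes for exercising the full pipeline without
#' experimental data: a phospholipid-like film (limiting area near 62
#' Angstrom^2, transition dip near 10 mN/m, collapse near 54 mN/m) and a
#' macrolide-drug-like film (limiting area near 33 Angstrom^2, pronounced
#' plateau dip near 15 mN/m, collapse near 42 mN/m). These are synthetic
#' fixtures shaped after typical published characteristics, not replicas of
#' any measured curve.
#'
#' @param noise_sd Gaussian pressure noise s.d. (mN/m) applied to both.
#' @param seed integer seed.
#' @return Named list of two [isotherm_from_modulus()] outputs:
#'   `lipid_like`, `drug_like`.
#' @export
default_scenarios <- function(noise_sd = 0, seed = 1L) {
  lipid_profile <- modulus_profile(
    pressure = c(0, 2, 6, 10, 14, 25, 40, 50),
    modulus = c(8, 20, 35, 18, 40, 90, 140, 150)
  )
  drug_profile <- modulus_profile(
    pressure = c(0, 3, 8, 15, 22, 32, 40),
    modulus = c(6, 18, 30, 7, 35, 60, 70)
  )
  list(
    lipid_like = isotherm_from_modulus(
      lipid_profile, reference_area = 95,
      pressure_grid = seq(0, 55, by = 0.25),
      collapse = list(pressure = 54, modulus = 3),
      noise_sd = noise_sd, seed = seed,
      composition = composition(c(DPPC = 0.8, DPPG = 0.2)),
      label = "lipid-like synthetic"),
    drug_like = isotherm_from_modulus(
      drug_profile, reference_area = 120,
      pressure_grid = seq(0, 43, by = 0.25),
      collapse = list(pressure = 42, modulus = 3),
      noise_sd = noise_sd, seed = seed + 1L,
      composition = composition(c(AmB = 1)),
      label = "drug-like synthetic")
  )
}
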