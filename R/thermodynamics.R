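# Unit bridge: 1 Angstrom^2 * 1 mN/m per molecule = 1e-23 J per molecule;
# times Avogadro's number this is 6.02214076 J/mol.
A2_MNM_TO_J_MOL <- 6.02214076
R_GAS <- 8.314  # J/(mol K)

# Surface pressures (mN/m) at which mixing thermodynamics are tabulated.
DEFAULT_PRESSURE_GRID <- c(1, 5, 10, 15, 20, 25, 30, 35, 40)

check_components <- function(components) {
  stopifnot(is.list(components), length(components) >= 1)
  fr <- vapply(components, function(cm) as.numeric(cm$fraction), numeric(1))
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    stop("component fractions must be nonnegative and sum to 1", call. = FALSE)
  }
  for (cm in components) stopifnot(inherits(cm$isotherm, "isotherm"))
  fr
}

#' Excess area of a mixed monolayer at given surface pressures
#'
#' The difference between the mixed film's mean molecular area and the
#' mole-fraction-weighted sum of the pure-component areas at the same
#' surface pressure: `A_mix(pi) - sum(x_i A_i(pi))`. Zero everywhere for
#' ideal mixing; its pressure integral is the excess Gibbs energy.
#'
#' @param mixture the mixed film's [isotherm()].
#' @param components list of components, each a
#'   `list(fraction = , isotherm = )`; fractions sum to 1.
#' @param pi numeric vector of surface pressures (mN/m) covered by every
#'   isotherm.
#' @return numeric vector of excess areas (Angstrom^2/molecule).
#' @export
excess_area <- function(mixture, components, pi) {
  stopifnot(inherits(mixture, "isotherm"))
  fr <- check_components(components)
  a_mix <- area_at_pressure(mixture, pi)
  a_ideal <- 0
  for (k in seq_along(components)) {
    a_ideal <- a_ideal + fr[k] * area_at_pressure(components[[k]]$isotherm, pi)
  }
  a_mix - a_ideal
}

#' Excess Gibbs energy of mixing at one surface pressure
#'
#' Integrates the excess area from 0 to `pi_target` over a uniform pressure
#' grid (trapezoidal rule) and converts the result from
#' Angstrom^2 mN/m per molecule to J/mol. A negative value signals net
#' attraction between the film components, a positive one net repulsion.
#'
#' Pressures requested beyond any isotherm's recorded maximum (e.g. past a
#' component's collapse) raise a range error rather than extrapolating.
#' Below the lowest recorded pressure of an isotherm, areas are clamped by
#' [area_at_pressure()]; the integral contribution of that clamped
#' subinterval is returned in attribute `clamp_contribution` (J/mol) so its
#' effect on the total is auditable.
#'
#' @inheritParams excess_area
#' @param pi_target upper integration limit (mN/m).
#' @param n_grid number of integration nodes (>= 50, default 200).
#' @return Excess Gibbs energy G_E in J/mol, with attributes `raw`
#'   (Angstrom^2 mN/m per molecule) and `clamp_contribution` (J/mol).
#' @export
excess_gibbs <- function(mixture, components, pi_target, n_grid = 200L) {
  stopifnot(length(pi_target) == 1, pi_target >= 0)
  n_grid <- as.integer(n_grid)
  if (n_grid < 50L) stop("n_grid must be at least 50", call. = FALSE)
  if (pi_target == 0) {
    return(structure(0, raw = 0, clamp_contribution = 0))
  }
  grid <- seq(0, pi_target, length.out = n_grid)
  dev <- excess_area(mixture, components, grid)
  raw <- pracma::trapz(grid, dev)
  # part of the integral where at least one curve was below its record
  floors <- vapply(c(list(list(isotherm = mixture)), components),
                   function(cm) compression_envelope(cm$isotherm)$pressure[1],
                   numeric(1))
  clamp_to <- max(floors)
  clamp_raw <- if (clamp_to > 0) {
    sub <- grid <= clamp_to
    if (sum(sub) >= 2) pracma::trapz(grid[sub], dev[sub]) else 0
  } else 0
  structure(raw * A2_MNM_TO_J_MOL, raw = raw,
            clamp_contribution = clamp_raw * A2_MNM_TO_J_MOL)
}

#' Gibbs energy of mixing
#'
#' Adds the ideal entropic term to the excess Gibbs energy:
#' `G_E + R T sum(x_i log x_i)`. Zero fractions contribute zero
#' (the x log x -> 0 limit). Negative values indicate a stable mixed film.
#'
#' @param G_E excess Gibbs energy, J/mol.
#' @param composition a [composition()] (or named fraction vector).
#' @param temperature kelvin (> 0).
#' @return Gibbs energy of mixing in J/mol.
#' @export
mixing_gibbs <- function(G_E, composition, temperature = DEFAULT_TEMPERATURE_K) {
  if (!inherits(composition, "composition")) composition <- monofilm::composition(composition)
  stopifnot(is.numeric(temperature), temperature > 0)
  x <- unclass(composition)
  xlogx <- ifelse(x > 0, x * log(x), 0)
  as.numeric(G_E) + R_GAS * temperature * sum(xlogx)
}

#' Mixing thermodynamics profile over a pressure grid
#'
#' Tabulates the excess Gibbs energy and Gibbs energy of mixing of a mixed
#' monolayer at a series of surface pressures (default: 1, 5, 10, ..., 40
#' mN/m, the grid at which mixed-film thermodynamics are conventionally
#' reported).
#'
#' @inheritParams excess_gibbs
#' @param pressures surface pressures (mN/m) at which to evaluate.
#' @param temperature kelvin; defaults to the mixture isotherm's.
#' @return data frame of class `"mixing_thermo"` with columns `pressure`,
#'   `G_E_raw` (Angstrom^2 mN/m per molecule), `G_E` (J/mol), `DmixG`
#'   (J/mol), `clamp_contribution` (J/mol); attributes `composition` and
#'   `temperature`.
#' @export
thermo_profile <- function(mixture, components,
                           pressures = DEFAULT_PRESSURE_GRID,
                           n_grid = 200L, temperature = NULL) {
  stopifnot(inherits(mixture, "isotherm"))
  check_components(components)
  if (is.null(temperature)) temperature <- mixture$temperature
  ge <- lapply(pressures, function(p) excess_gibbs(mixture, components, p, n_grid = n_grid))
  G_E <- vapply(ge, as.numeric, numeric(1))
  out <- data.frame(
    pressure = as.numeric(pressures),
    G_E_raw = vapply(ge, function(g) attr(g, "raw"), numeric(1)),
    G_E = G_E,
    DmixG = vapply(G_E, mixing_gibbs, numeric(1),
                   composition = mixture$composition, temperature = temperature),
    clamp_contribution = vapply(ge, function(g) attr(g, "clamp_contribution"), numeric(1))
  )
  structure(out, class = c("mixing_thermo", "data.frame"),
            composition = mixture$composition, temperature = temperature)
}
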