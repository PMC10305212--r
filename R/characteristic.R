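#' Liftoff area of a compression isotherm
#'
#' The liftoff area A_L is the mean molecular area at which the surface
#' pressure first rises detectably above the gaseous-phase baseline during
#' compression. The baseline is the median pressure over the largest-area
#' decile of the record; the detection threshold defaults to 0.5 mN/m above
#' it (five times a typical 0.1 mN/m Wilhelmy-plate accuracy).
#'
#' @param iso an [isotherm()].
#' @param threshold detection threshold above baseline, mN/m (> 0).
#' @return A_L in Angstrom^2/molecule.
#' @export
liftoff_area <- function(iso, threshold = 0.5) {
  stopifnot(inherits(iso, "isotherm"), threshold > 0)
  n <- length(iso$area)
  n_base <- max(2L, ceiling(n / 10))
  baseline <- stats::median(iso$pressure[seq_len(n_base)])
  hit <- which(iso$pressure > baseline + threshold)
  if (!length(hit)) {
    stop(sprintf("surface pressure never exceeds baseline (%.3f) + threshold (%.3f) mN/m",
                 baseline, threshold), call. = FALSE)
  }
  iso$area[hit[1]]
}

# Local least-squares slope of pressure vs area over each window of `window`
# consecutive samples; returns one slope per window start index.
window_slopes <- function(area, pressure, window) {
  n <- length(area) - window + 1L
  vapply(seq_len(n), function(i) {
    idx <- i:(i + window - 1L)
    a <- area[idx] - mean(area[idx])
    sum(a * (pressure[idx] - mean(pressure[idx]))) / sum(a * a)
  }, numeric(1))
}

#' Limiting area by steepest-slope extrapolation
#'
#' The limiting area A_inf approximates the mean molecular cross-section of
#' the film-forming molecules. It is obtained by finding the steepest stretch
#' of the condensed-phase rise (the window of consecutive samples with the
#' largest |dpi/dA| by local linear fit, below any detected collapse) and
#' extrapolating that line to zero surface pressure.
#'
#' @param iso an [isotherm()].
#' @param window number of consecutive samples in the local fit (>= 3).
#' @return A_inf in Angstrom^2/molecule, with attributes `window` (the value
#'   used) and `slope` (the fitted dpi/dA, mN/m per Angstrom^2).
#' @export
limiting_area <- function(iso, window = 5L) {
  stopifnot(inherits(iso, "isotherm"))
  window <- as.integer(window)
  if (window < 3L) stop("window must be at least 3 samples", call. = FALSE)
  area <- iso$area; pressure <- iso$pressure
  # restrict to the pre-collapse branch when a distinct collapse exists
  cp <- tryCatch(collapse_point(iso), error = function(e) NULL)
  if (!is.null(cp) && !isTRUE(attr(cp, "no_distinct_collapse"))) {
    keep <- area >= cp[["A_C"]] - 1e-12
    if (sum(keep) >= window) { area <- area[keep]; pressure <- pressure[keep] }
  }
  if (length(area) < window) {
    stop("fewer samples than the fitting window", call. = FALSE)
  }
  slopes <- window_slopes(area, pressure, window)
  i <- which.max(abs(slopes))
  idx <- i:(i + window - 1L)
  fit <- stats::lm(pressure[idx] ~ area[idx])
  b <- unname(stats::coef(fit))
  if (b[2] >= 0) stop("steepest segment is not compressive (dpi/dA >= 0)", call. = FALSE)
  structure(-b[1] / b[2], window = window, slope = b[2])
}

#' Collapse point of an isotherm
#'
#' Locates the high-pressure inflection where the two-dimensional film starts
#' buckling into three dimensions: scanning the region above 30 mN/m, the
#' collapse is placed at the junction between adjacent fitting windows with
#' the largest drop in local slope |dpi/dA|, provided the drop exceeds
#' `drop_ratio`. If no slope drop is that pronounced the final recorded point
#' is returned with attribute `no_distinct_collapse = TRUE`.
#'
#' @param iso an [isotherm()] reaching beyond 30 mN/m.
#' @param window samples per local slope fit (>= 3).
#' @param drop_ratio minimum relative slope drop (default 0.5, i.e. 50 percent).
#' @return Named numeric `c(pi_C = , A_C = )` (mN/m, Angstrom^2/molecule).
#' @export
collapse_point <- function(iso, window = 5L, drop_ratio = 0.5) {
  stopifnot(inherits(iso, "isotherm"))
  window <- as.integer(window)
  if (window < 3L) stop("window must be at least 3 samples", call. = FALSE)
  if (max(iso$pressure) <= 30) {
    stop("isotherm never exceeds 30 mN/m: collapse not reachable", call. = FALSE)
  }
  hi <- which(iso$pressure > 30)
  first <- max(1L, hi[1] - window)  # include a pre-30 run-up for the first window
  area <- iso$area[first:length(iso$area)]
  pressure <- iso$pressure[first:length(iso$pressure)]
  n <- length(area)
  last_point <- structure(c(pi_C = pressure[n], A_C = area[n]),
                          no_distinct_collapse = TRUE)
  if (n < 2L * window) return(last_point)
  slopes <- abs(window_slopes(area, pressure, window))
  # junction j: window ending at j vs window starting at j+1
  best_j <- 0L; best_drop <- -Inf
  for (j in window:(n - window)) {
    s_before <- slopes[j - window + 1L]
    s_after <- slopes[j + 1L]
    if (s_before <= 0) next
    drop <- 1 - s_after / s_before
    if (drop > best_drop) { best_drop <- drop; best_j <- j }
  }
  if (best_j == 0L || best_drop < drop_ratio) return(last_point)
  c(pi_C = pressure[best_j], A_C = area[best_j])
}

#' Extract all characteristic isotherm parameters
#'
#' Convenience wrapper returning the liftoff area A_L, limiting area A_inf,
#' and collapse point (pi_C, A_C) of one isotherm as a one-row data frame,
#' the shape of a characteristic-parameter table.
#'
#' @inheritParams liftoff_area
#' @inheritParams limiting_area
#' @param collapse_drop_ratio passed to [collapse_point()].
#' @return data frame with columns `label`, `A_L`, `A_inf`, `pi_C`, `A_C`,
#'   `distinct_collapse`.
#' @export
characteristic_params <- function(iso, threshold = 0.5, window = 5L,
                                  collapse_drop_ratio = 0.5) {
  cp <- collapse_point(iso, window = window, drop_ratio = collapse_drop_ratio)
  data.frame(
    label = iso$label,
    A_L = liftoff_area(iso, threshold = threshold),
    A_inf = as.numeric(limiting_area(iso, window = window)),
    pi_C = unname(cp[["pi_C"]]),
    A_C = unname(cp[["A_C"]]),
    distinct_collapse = !isTRUE(attr(cp, "no_distinct_collapse"))
  )
}

#' Ideal limiting area of a mixed film (additivity rule)
#'
#' For an ideally mixed film the limiting area is the mole-fraction-weighted
#' sum of the component limiting areas, `sum(x_i * A_inf_i)`. Any number of
#' components is accepted; the common two-group use treats a fixed lipid
#' mixture as one pseudo-component and the added drug as the other.
#'
#' @param fractions molar fractions, summing to 1 within `1e-9`.
#' @param areas component limiting areas (Angstrom^2/molecule), positive,
#'   same length as `fractions`.
#' @return The ideal A_inf in Angstrom^2/molecule.
#' @examples
#' # lipid film 61.87 A^2 mixed with a drug of 32.99 A^2 at x_drug = 0.1
#' ideal_limiting_area(c(0.9, 0.1), c(61.87, 32.99))
#' @export
ideal_limiting_area <- function(fractions, areas) {
  fractions <- as.numeric(fractions); areas <- as.numeric(areas)
  if (length(fractions) != length(areas)) {
    stop("fractions and areas must have equal length", call. = FALSE)
  }
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop("molar fractions must be nonnegative and sum to 1", call. = FALSE)
  }
  if (any(areas <= 0)) stop("limiting areas must be positive", call. = FALSE)
  sum(fractions * areas)
}

#' Deviation of the measured limiting area from the additivity rule
#'
#' Returns `experimental - ideal`: positive when the real mixed film packs
#' looser than ideal mixing predicts (net repulsion or component expulsion),
#' negative when it packs tighter (condensation).
#'
#' @param experimental measured A_inf (Angstrom^2/molecule, > 0).
#' @param ideal additivity-rule A_inf (Angstrom^2/molecule, > 0).
#' @return The signed deviation in Angstrom^2/molecule.
#' @export
additivity_deviation <- function(experimental, ideal) {
  stopifnot(is.numeric(experimental), is.numeric(ideal),
            experimental > 0, ideal > 0)
  experimental - ideal
}
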