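#' Molar composition of a monolayer
#'
#' A named vector of molar fractions describing which amphiphiles form the
#' spread film (e.g. DPPC, DPPG, AmB). Fractions must lie in \[0, 1\] and sum
#' to 1 within `1e-9`.
#'
#' @param fractions named numeric vector of molar fractions.
#' @return An object of class `"composition"` (a named numeric vector).
#' @examples
#' composition(c(DPPC = 0.72, DPPG = 0.18, AmB = 0.10))
#' @export
composition <- function(fractions) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    stop("composition fractions must be a named numeric vector", call. = FALSE)
  }
  fractions <- vapply(fractions, as.numeric, numeric(1))
  if (any(!is.finite(fractions)) || any(fractions < 0) || any(fractions > 1)) {
    stop("molar fractions must be finite and in [0, 1]", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop(sprintf("molar fractions must sum to 1 (got %.12f)", sum(fractions)),
         call. = FALSE)
  }
  structure(fractions, class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat("<composition> ",
      paste(sprintf("%s = %g", names(x), unclass(x)), collapse = ", "), "\n")
  invisible(x)
}

# Lab temperature used throughout when none is supplied (35.0 C subphase).
DEFAULT_TEMPERATURE_K <- 308.15

#' Surface pressure--area compression isotherm
#'
#' Container for one pi-A compression isotherm of a Langmuir monolayer:
#' mean molecular area (Angstrom^2/molecule) against surface pressure (mN/m)
#' at fixed composition and temperature. Samples are stored in compression
#' order (area strictly decreasing); input rows in expansion order are
#' re-sorted, and duplicate areas are collapsed by averaging their pressures.
#'
#' Validation enforces: strictly positive areas, finite pressures no lower
#' than a -0.5 mN/m sensor-noise floor, and at least 10 samples.
#'
#' @param area numeric, mean molecular area in Angstrom^2/molecule.
#' @param pressure numeric, surface pressure in mN/m, same length as `area`.
#' @param composition a [composition()] object (defaults to a single
#'   unnamed component).
#' @param temperature subphase temperature in kelvin (default 308.15 K).
#' @param label free-text label carried through outputs.
#' @return An object of class `"isotherm"`: a list with elements `area`,
#'   `pressure`, `composition`, `temperature`, `label`.
#' @seealso [read_isotherm()], [area_at_pressure()]
#' @export
isotherm <- function(area, pressure,
                     composition = monofilm::composition(c(film = 1)),
                     temperature = DEFAULT_TEMPERATURE_K,
                     label = "") {
  area <- as.numeric(area)
  pressure <- as.numeric(pressure)
  if (length(area) != length(pressure)) {
    stop("area and pressure must have equal length", call. = FALSE)
  }
  if (anyNA(area) || anyNA(pressure) || any(!is.finite(area)) || any(!is.finite(pressure))) {
    bad <- which(!is.finite(area) | !is.finite(pressure))[1]
    stop(sprintf("non-numeric or non-finite isotherm value at row %d", bad),
         call. = FALSE)
  }
  if (length(area) < 10) {
    stop("an isotherm needs at least 10 samples", call. = FALSE)
  }
  if (any(area <= 0)) {
    stop("mean molecular areas must be strictly positive", call. = FALSE)
  }
  if (any(pressure < -0.5)) {
    stop("surface pressures below the -0.5 mN/m noise floor", call. = FALSE)
  }
  # canonical compression order: area strictly decreasing
  ord <- order(area, decreasing = TRUE)
  area <- area[ord]; pressure <- pressure[ord]
  if (anyDuplicated(area)) {
    pressure <- as.numeric(tapply(pressure, factor(area, levels = unique(area)), mean))
    area <- unique(area)
    if (length(area) < 10) {
      stop("fewer than 10 distinct areas after collapsing duplicates", call. = FALSE)
    }
  }
  if (!inherits(composition, "composition")) composition <- monofilm::composition(composition)
  stopifnot(is.numeric(temperature), temperature > 0)
  structure(
    list(area = area, pressure = pressure, composition = composition,
         temperature = as.numeric(temperature), label = as.character(label)),
    class = "isotherm"
  )
}

#' @export
print.isotherm <- function(x, ...) {
  cat(sprintf("<isotherm> %s: %d samples, A %.2f..%.2f A^2, pi %.2f..%.2f mN/m, T = %.2f K\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$area), min(x$area), max(x$area),
              min(x$pressure), max(x$pressure), x$temperature))
  invisible(x)
}

#' @export
as.data.frame.isotherm <- function(x, ...) {
  data.frame(area_A2 = x$area, pressure_mN_m = x$pressure)
}

#' Constant-area surface pressure relaxation trace
#'
#' After compressing a monolayer to an initial surface pressure `pi0` the
#' barriers are held fixed and the pressure decays towards equilibrium as the
#' film reorganises. This container holds that pi-t record.
#'
#' @param time seconds, strictly increasing from 0, at least 10 samples.
#' @param pressure surface pressure in mN/m, same length as `time`.
#' @param initial_pressure pi0 in mN/m (> 0); defaults to the first pressure.
#' @inheritParams isotherm
#' @return An object of class `"relaxation_trace"`.
#' @seealso [fit_relaxation()], [simulate_relaxation()]
#' @export
relaxation_trace <- function(time, pressure, initial_pressure = pressure[1],
                             composition = monofilm::composition(c(film = 1)),
                             temperature = DEFAULT_TEMPERATURE_K,
                             label = "") {
  time <- as.numeric(time); pressure <- as.numeric(pressure)
  if (length(time) != length(pressure)) {
    stop("time and pressure must have equal length", call. = FALSE)
  }
  if (anyNA(time) || anyNA(pressure)) stop("NA in relaxation trace", call. = FALSE)
  if (length(time) < 10) stop("a relaxation trace needs at least 10 samples", call. = FALSE)
  if (time[1] < 0 || any(diff(time) <= 0)) {
    stop("time must be strictly increasing and start at t >= 0", call. = FALSE)
  }
  initial_pressure <- as.numeric(initial_pressure)
  if (!is.finite(initial_pressure) || initial_pressure <= 0) {
    stop("initial pressure pi0 must be positive", call. = FALSE)
  }
  if (!inherits(composition, "composition")) composition <- monofilm::composition(composition)
  structure(
    list(time = time, pressure = pressure, initial_pressure = initial_pressure,
         composition = composition, temperature = as.numeric(temperature),
         label = as.character(label)),
    class = "relaxation_trace"
  )
}

#' @export
print.relaxation_trace <- function(x, ...) {
  cat(sprintf("<relaxation_trace> %s: %d samples, t 0..%.0f s, pi0 = %.2f mN/m\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$time), max(x$time), x$initial_pressure))
  invisible(x)
}

read_sidecar <- function(path) {
  if (is.null(path) || length(path) == 0 || is.na(path)) return(list())
  if (!file.exists(path)) stop(sprintf("sidecar file not found: %s", path), call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

sidecar_composition <- function(meta) {
  if (!is.null(meta$components)) {
    composition(unlist(meta$components))
  } else {
    composition(c(film = 1))
  }
}

read_numeric_table <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s) %s", path, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  for (col in required) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v)) {
      stop(sprintf("%s: non-numeric value in column '%s' at data row %d",
                   path, col, which(is.na(v))[1]), call. = FALSE)
    }
    tab[[col]] <- v
  }
  tab
}

#' Read a compression isotherm from CSV
#'
#' Reads a comma-separated table with columns `area_A2` (Angstrom^2/molecule)
#' and `pressure_mN_m` (mN/m); column names are configurable. An optional
#' YAML/JSON sidecar supplies `components` (name -> molar fraction),
#' `temperature_K`, and `label`; without one the film is treated as a single
#' component at 308.15 K.
#'
#' @param path CSV file path.
#' @param metadata optional sidecar path (YAML or JSON).
#' @param area_col,pressure_col column names in the CSV.
#' @return A validated [isotherm()].
#' @export
read_isotherm <- function(path, metadata = NULL,
                          area_col = "area_A2", pressure_col = "pressure_mN_m") {
  tab <- read_numeric_table(path, c(area_col, pressure_col))
  meta <- read_sidecar(metadata)
  isotherm(
    area = tab[[area_col]], pressure = tab[[pressure_col]],
    composition = sidecar_composition(meta),
    temperature = if (!is.null(meta$temperature_K)) meta$temperature_K else DEFAULT_TEMPERATURE_K,
    label = if (!is.null(meta$label)) meta$label else sub("\\.csv$", "", basename(path))
  )
}

#' Write an isotherm to the canonical CSV dialect
#'
#' Comma-separated, dot decimal, UTF-8, header row `area_A2,pressure_mN_m`,
#' rows in compression order. Reading the file back reproduces the isotherm.
#'
#' @param iso an [isotherm()].
#' @param path output CSV path.
#' @param metadata optional path for a JSON sidecar recording composition,
#'   temperature, and label.
#' @return `path`, invisibly.
#' @export
write_isotherm <- function(iso, path, metadata = NULL) {
  stopifnot(inherits(iso, "isotherm"))
  utils::write.csv(as.data.frame(iso), path, row.names = FALSE, quote = FALSE)
  if (!is.null(metadata)) {
    jsonlite::write_json(
      list(components = as.list(unclass(iso$composition)),
           temperature_K = iso$temperature, label = iso$label),
      metadata, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a constant-area relaxation trace from CSV
#'
#' Expects columns `time_s` and `pressure_mN_m`; the sidecar may add
#' `initial_pressure` (mN/m), `components`, `temperature_K`, `label`.
#'
#' @inheritParams read_isotherm
#' @return A validated [relaxation_trace()].
#' @export
read_relaxation_trace <- function(path, metadata = NULL) {
  tab <- read_numeric_table(path, c("time_s", "pressure_mN_m"))
  meta <- read_sidecar(metadata)
  relaxation_trace(
    time = tab$time_s, pressure = tab$pressure_mN_m,
    initial_pressure = if (!is.null(meta$initial_pressure)) meta$initial_pressure else tab$pressure_mN_m[1],
    composition = sidecar_composition(meta),
    temperature = if (!is.null(meta$temperature_K)) meta$temperature_K else DEFAULT_TEMPERATURE_K,
    label = if (!is.null(meta$label)) meta$label else sub("\\.csv$", "", basename(path))
  )
}

#' Write a relaxation trace to CSV
#'
#' @param trace a [relaxation_trace()].
#' @param path output CSV path.
#' @param metadata optional JSON sidecar path (records `initial_pressure`,
#'   composition, temperature, label).
#' @return `path`, invisibly.
#' @export
write_relaxation_trace <- function(trace, path, metadata = NULL) {
  stopifnot(inherits(trace, "relaxation_trace"))
  utils::write.csv(data.frame(time_s = trace$time, pressure_mN_m = trace$pressure),
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(metadata)) {
    jsonlite::write_json(
      list(initial_pressure = trace$initial_pressure,
           components = as.list(unclass(trace$composition)),
           temperature_K = trace$temperature, label = trace$label),
      metadata, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# Monotone upper envelope of the compression branch: pressures clamped to the
# 0 noise floor, running maximum along compression, keeping the first sample
# (largest area) at which each new pressure maximum is reached. Returns a
# strictly increasing pi grid with its (decreasing) areas.
compression_envelope <- function(iso) {
  p <- pmax(iso$pressure, 0)
  cm <- cummax(p)
  keep <- c(TRUE, diff(cm) > 0)
  list(pressure = cm[keep], area = iso$area[keep])
}

#' Invert an isotherm: area as a function of surface pressure
#'
#' Evaluates the mean molecular area at requested surface pressures by
#' piecewise-linear interpolation of the compression branch. Because measured
#' isotherms can be locally non-monotone (plateaus, sensor noise), the
#' monotone upper envelope of pi along compression is taken before inversion,
#' so the result is always monotone non-increasing in pressure.
#'
#' Grid points below `floor_pressure` (by default the lowest pressure of the
#' monotonized branch, i.e. the start of the record) are clamped: they return
#' the area at `floor_pressure`. Grid points above the maximum recorded
#' pressure raise an error rather than extrapolate.
#'
#' @param iso an [isotherm()].
#' @param grid numeric vector of surface pressures (mN/m).
#' @param floor_pressure clamp pressure in mN/m; queries below it return the
#'   area at this pressure. Pass e.g. a liftoff threshold to make the
#'   below-liftoff clamp explicit.
#' @return numeric vector of areas (Angstrom^2/molecule), one per grid point.
#' @export
area_at_pressure <- function(iso, grid, floor_pressure = NULL) {
  stopifnot(inherits(iso, "isotherm"))
  grid <- as.numeric(grid)
  env <- compression_envelope(iso)
  if (length(env$pressure) < 2) {
    stop("isotherm pressure never rises: cannot invert", call. = FALSE)
  }
  pmax_rec <- env$pressure[length(env$pressure)]
  if (any(grid > pmax_rec + 1e-9)) {
    stop(sprintf("requested pressure %.3f mN/m above maximum recorded %.3f mN/m",
                 max(grid), pmax_rec), call. = FALSE)
  }
  floor_pressure <- if (is.null(floor_pressure)) env$pressure[1] else as.numeric(floor_pressure)
  q <- pmax(grid, floor_pressure)
  q <- pmin(q, pmax_rec)  # guard fp round-off at the top end
  stats::approx(env$pressure, env$area, xout = q, rule = 2, ties = "ordered")$y
}
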