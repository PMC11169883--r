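#' Parallel-plate sensor geometry
#'
#' Describes the detection cell of a parallel-plate capacitive grain sensor.
#' The default plate area corresponds to the 150 mm x 100 mm brass detection
#' plates of the reference sensor design. Plate spacing and pore ratio are
#' not fixed by that design and default to nominal values; both should be
#' calibrated for a real instrument.
#'
#' @param plate_area Relative plate area S in m^2 (> 0).
#' @param plate_spacing Plate spacing d in m (> 0).
#' @param pore_ratio Fraction e of the filled detection volume occupied by
#'   inter-grain air, dimensionless in `[0, 1)`.
#' @return An object of class `sensor_geometry`.
#' @examples
#' geom <- sensor_geometry()
#' geom$plate_area
#' @export
sensor_geometry <- function(plate_area = 0.15 * 0.10,
                            plate_spacing = 0.10,
                            pore_ratio = 0.40) {
  check_scalar(plate_area, "plate_area", lower = 0, open_lower = TRUE)
  check_scalar(plate_spacing, "plate_spacing", lower = 0, open_lower = TRUE)
  check_scalar(pore_ratio, "pore_ratio", lower = 0, upper = 1, open_upper = TRUE)
  structure(
    list(plate_area = plate_area, plate_spacing = plate_spacing,
         pore_ratio = pore_ratio),
    class = "sensor_geometry"
  )
}

#' Dielectric and density constants of the sensed materials
#'
#' Relative permittivities and densities of the three phases between the
#' plates (dry grain, water, air) plus the vacuum permittivity. Defaults are
#' the room-temperature values for foxtail millet.
#'
#' @param eps0 Vacuum permittivity in F/m.
#' @param eps_cereal Relative permittivity of dry grain (dimensionless).
#' @param eps_water Relative permittivity of water.
#' @param eps_air Relative permittivity of air.
#' @param rho_cereal Dry grain density in kg/m^3.
#' @param rho_water Water density in kg/m^3.
#' @return An object of class `material_constants`.
#' @details The moisture sensitivity of the sensor rests on
#'   `eps_water > eps_cereal > eps_air`; the constructor enforces this
#'   ordering.
#' @examples
#' material_constants()
#' @export
material_constants <- function(eps0 = 8.854187818e-12,
                               eps_cereal = 3,
                               eps_water = 81,
                               eps_air = 1.00053,
                               rho_cereal = 600,
                               rho_water = 1000) {
  for (nm in c("eps0", "eps_cereal", "eps_water", "eps_air",
               "rho_cereal", "rho_water")) {
    check_scalar(get(nm), nm, lower = 0, open_lower = TRUE)
  }
  if (!(eps_water > eps_cereal && eps_cereal > eps_air && eps_air >= 1)) {
    stop("material constants must satisfy eps_water > eps_cereal > eps_air >= 1",
         call. = FALSE)
  }
  structure(
    list(eps0 = eps0, eps_cereal = eps_cereal, eps_water = eps_water,
         eps_air = eps_air, rho_cereal = rho_cereal, rho_water = rho_water),
    class = "material_constants"
  )
}

#' Structural constants of the capacitive cell
#'
#' Collapses geometry and material constants into the four structural
#' constants (A, B, D, F) of the closed-form capacitance-moisture relation
#' `C = A / (W/(1-W) + B) + D + F`, where W is the wet-basis moisture
#' fraction. They are:
#' \itemize{
#'   \item `A = S*eps0*rho_water*(1-e)*(eps_cereal - eps_water) / (d*rho_cereal)`
#'     (farads; negative whenever water is the high-permittivity phase),
#'   \item `B = rho_water / rho_cereal` (dimensionless),
#'   \item `D = S*eps0*(1-e)*eps_water / d` (farads),
#'   \item `F = S*eps0*e*eps_air / d` (farads; named `F_const` to avoid the
#'     base `F` alias).
#' }
#'
#' @param geometry A [sensor_geometry()] object.
#' @param materials A [material_constants()] object.
#' @return An object of class `structural_constants` with fields `A`, `B`,
#'   `D`, `F_const` and the attainable capacitance limits `c_dry` (moisture
#'   0) and `c_wet` (moisture -> 1).
#' @examples
#' sc <- structural_constants(sensor_geometry(), material_constants())
#' sc$B  # rho_water / rho_cereal
#' @export
structural_constants <- function(geometry = sensor_geometry(),
                                 materials = material_constants()) {
  stopifnot(inherits(geometry, "sensor_geometry"),
            inherits(materials, "material_constants"))
  S <- geometry$plate_area
  d <- geometry$plate_spacing
  e <- geometry$pore_ratio
  k <- S * materials$eps0 / d
  A <- k * materials$rho_water * (1 - e) *
    (materials$eps_cereal - materials$eps_water) / materials$rho_cereal
  B <- materials$rho_water / materials$rho_cereal
  D <- k * (1 - e) * materials$eps_water
  F_const <- k * e * materials$eps_air
  sc <- structure(
    list(A = A, B = B, D = D, F_const = F_const,
         c_dry = A / B + D + F_const,  # two-phase grain + air limit
         c_wet = D + F_const),         # two-phase water + air limit
    class = "structural_constants"
  )
  sc
}

#' Capacitance of the cell at a given moisture content
#'
#' Evaluates the closed-form dielectric mixing model
#' `C = A / (W/(1-W) + B) + D + F`. Because water has a much larger
#' permittivity than dry grain, the curve is strictly increasing in moisture
#' over `[0, 1)`, from the dry-grain limit `A/B + D + F` to the all-water
#' limit `D + F`.
#'
#' @param w Wet-basis moisture content as a fraction in `[0, 1)` (vectorised).
#' @param sc A [structural_constants()] object.
#' @return Capacitance in farads, same length as `w`.
#' @examples
#' sc <- structural_constants()
#' capacitance_from_moisture(c(0, 0.15, 0.25), sc)
#' @seealso [moisture_from_capacitance()] for the exact inverse.
#' @export
capacitance_from_moisture <- function(w, sc = structural_constants()) {
  stopifnot(inherits(sc, "structural_constants"))
  if (!is.numeric(w) || any(!is.finite(w)) || any(w < 0) || any(w >= 1)) {
    stop("moisture fraction `w` must lie in [0, 1)", call. = FALSE)
  }
  sc$A / (w / (1 - w) + sc$B) + sc$D + sc$F_const
}

#' Attainable capacitance interval of a cell
#'
#' @param sc A [structural_constants()] object.
#' @return Length-2 numeric `c(dry, wet)`: the closed lower endpoint at
#'   moisture 0 and the open upper endpoint approached as moisture -> 1.
#' @export
capacitance_range <- function(sc = structural_constants()) {
  stopifnot(inherits(sc, "structural_constants"))
  c(dry = sc$c_dry, wet = sc$c_wet)
}

#' Moisture content from a measured capacitance (exact model inverse)
#'
#' Analytic inverse of [capacitance_from_moisture()]: with
#' `G = A/(C - D - F) - B`, the moisture fraction is `w = G / (1 + G)`.
#'
#' @param capacitance Capacitance in farads (vectorised). Must lie in the
#'   attainable interval `[c_dry, c_wet)` of the cell.
#' @param sc A [structural_constants()] object.
#' @return Moisture fraction in `[0, 1)`.
#' @examples
#' sc <- structural_constants()
#' moisture_from_capacitance(capacitance_from_moisture(0.15, sc), sc)
#' @export
moisture_from_capacitance <- function(capacitance, sc = structural_constants()) {
  stopifnot(inherits(sc, "structural_constants"))
  rng <- capacitance_range(sc)
  if (!is.numeric(capacitance) || any(!is.finite(capacitance)) ||
      any(capacitance < rng[["dry"]]) || any(capacitance >= rng[["wet"]])) {
    stop(sprintf(
      "capacitance outside the attainable interval [%.6g, %.6g) F of this cell",
      rng[["dry"]], rng[["wet"]]), call. = FALSE)
  }
  g <- sc$A / (capacitance - sc$D - sc$F_const) - sc$B
  g / (1 + g)
}

#' Empirical linear capacitance calibration
#'
#' The fitted straight-line relation between moisture content (in percent,
#' wet basis) and differenced sensor capacitance (sensor units, treated as
#' pF): `C = 0.30744 * W + 17.28085`. Valid only at 22 degrees C and volume
#' duty cycle 1/3, the conditions under which it was fitted. Note the sensor
#' scale of this calibration is never mixed with the farad scale of
#' [capacitance_from_moisture()].
#'
#' @param w_percent Moisture content in percent, in `[0, 100]` (vectorised).
#' @return Capacitance in sensor units (pF).
#' @examples
#' linear_calibration(c(0, 10, 14.42))
#' @export
linear_calibration <- function(w_percent) {
  if (!is.numeric(w_percent) || any(!is.finite(w_percent)) ||
      any(w_percent < 0) || any(w_percent > 100)) {
    stop("`w_percent` must lie in [0, 100]", call. = FALSE)
  }
  0.30744 * w_percent + 17.28085
}

#' @export
print.structural_constants <- function(x, ...) {
  cat("Structural constants of capacitive cell\n")
  cat(sprintf("  A = %.6g F   B = %.6g   D = %.6g F   F = %.6g F\n",
              x$A, x$B, x$D, x$F_const))
  cat(sprintf("  attainable capacitance: [%.6g, %.6g) F\n", x$c_dry, x$c_wet))
  invisible(x)
}

# shared scalar validator: errors name the offending field
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lower) x > lower else x >= lower) &&
    (if (open_upper) x < upper else x <= upper)
  if (!ok) {
    stop(sprintf("invalid `%s`: must be a finite scalar in %s%s, %s%s",
                 name, if (open_lower) "(" else "[", format(lower),
                 format(upper), if (open_upper) ")" else "]"),
         call. = FALSE)
  }
  invisible(TRUE)
}
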