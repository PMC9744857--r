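# Core electro-acoustic relations shared by every other module.
# Strict SI internally: Pa, V, m, s, kg m^-3. Unit conversions (MPa, mV, us,
# W cm^-2) happen only in the report layer.

#' Hydrophone calibration
#'
#' A needle hydrophone links acoustic pressure to voltage through a single
#' sensitivity constant `M` (volts per pascal): `p(t) = V(t) / M`. The
#' default, 70 nV/Pa, is the nominal sensitivity of the ONDA HNA-0400
#' hydrophone used to calibrate the 1.1 MHz therapeutic transducer the
#' models emulate.
#'
#' @param sensitivity Sensitivity `M` in volts per pascal. Must be a single
#'   positive finite number.
#' @return An object of class `hydrophone_calibration`.
#' @examples
#' cal <- hydrophone_calibration()
#' voltage_to_pressure(17.5e-3, cal) # 0.25 MPa
#' @export
hydrophone_calibration <- function(sensitivity = 70e-9) {
  if (!is.numeric(sensitivity) || length(sensitivity) != 1L ||
      !is.finite(sensitivity) || sensitivity <= 0) {
    stop("`sensitivity` must be a single positive finite number (V/Pa)",
         call. = FALSE)
  }
  structure(list(sensitivity = as.numeric(sensitivity)),
            class = "hydrophone_calibration")
}

#' @export
print.hydrophone_calibration <- function(x, ...) {
  cat(sprintf("<hydrophone_calibration> M = %g V/Pa (%.3g nV/Pa)\n",
              x$sensitivity, x$sensitivity * 1e9))
  invisible(x)
}

#' Acoustic medium
#'
#' A homogeneous tissue medium characterised by its density and longitudinal
#' speed of sound; the two determine the characteristic acoustic impedance
#' `Z = rho * c` (rayl).
#'
#' @param density Density in kg/m^3 (positive, finite).
#' @param speed Speed of sound in m/s (positive, finite).
#' @return An object of class `acoustic_medium`.
#' @examples
#' nerve <- acoustic_medium(density = 1075, speed = 1630)
#' acoustic_impedance(nerve)
#' @export
acoustic_medium <- function(density, speed) {
  for (nm in c("density", "speed")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single positive finite number", nm),
           call. = FALSE)
    }
  }
  structure(list(density = as.numeric(density), speed = as.numeric(speed)),
            class = "acoustic_medium")
}

#' @export
print.acoustic_medium <- function(x, ...) {
  cat(sprintf("<acoustic_medium> rho = %g kg/m^3, c = %g m/s, Z = %.4g rayl\n",
              x$density, x$speed, x$density * x$speed))
  invisible(x)
}

check_finite <- function(x, what) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite numeric (got %s)", what,
                 paste(utils::head(format(x), 3L), collapse = ", ")),
         call. = FALSE)
  }
  as.numeric(x)
}

#' Convert hydrophone voltage to acoustic pressure
#'
#' Applies `p = V / M`. Linear, vectorised, exact inverse of
#' [pressure_to_voltage()].
#'
#' @param voltage Voltage in volts (finite numeric vector).
#' @param cal A [hydrophone_calibration()].
#' @return Pressure in pascals.
#' @export
voltage_to_pressure <- function(voltage, cal = hydrophone_calibration()) {
  stopifnot(inherits(cal, "hydrophone_calibration"))
  check_finite(voltage, "voltage") / cal$sensitivity
}

#' Convert acoustic pressure to hydrophone voltage
#'
#' Applies `V = M * p`, the rearranged calibration relation used to set the
#' source amplitude from a target acoustic pressure (0.25 MPa -> 17.5 mV and
#' 0.83 MPa -> 58.1 mV at the default sensitivity).
#'
#' @param pressure Pressure in pascals (finite numeric vector).
#' @inheritParams voltage_to_pressure
#' @return Voltage in volts.
#' @export
pressure_to_voltage <- function(pressure, cal = hydrophone_calibration()) {
  stopifnot(inherits(cal, "hydrophone_calibration"))
  check_finite(pressure, "pressure") * cal$sensitivity
}

#' Characteristic acoustic impedance
#'
#' `Z = rho * c`, in rayl (kg m^-2 s^-1). Impedance mismatch between
#' adjacent media drives partial reflection at interfaces.
#'
#' @param medium An [acoustic_medium()].
#' @return Impedance in rayl.
#' @export
acoustic_impedance <- function(medium) {
  stopifnot(inherits(medium, "acoustic_medium"))
  medium$density * medium$speed
}

#' One-way propagation delay through a tissue layer
#'
#' `t = d / c`. Delays along a path are additive, so a terminal's arrival
#' time is the sum over the segments on its root path.
#'
#' @param distance Layer thickness/length in metres (`>= 0`).
#' @param speed Speed of sound in m/s (`> 0`).
#' @return Delay in seconds.
#' @export
propagation_delay <- function(distance, speed) {
  distance <- check_finite(distance, "distance")
  speed <- check_finite(speed, "speed")
  if (any(distance < 0)) stop("`distance` must be >= 0", call. = FALSE)
  if (any(speed <= 0)) stop("`speed` must be > 0", call. = FALSE)
  distance / speed
}

#' Spatial-peak temporal-average intensity
#'
#' Plane-wave intensity `I = p^2 / (2 rho c)`, evaluated with the local
#' tissue's impedance and reported in W/cm^2 (the SI W/m^2 value divided by
#' 1e4). This is the quantity compared against the 0.1 W/cm^2
#' action-potential threshold, the 3 W/cm^2 FDA therapeutic ceiling and the
#' 35 W/cm^2 thermal-burn bound. No duty-cycle factor is applied: the pulse
#' amplitude enters directly.
#'
#' @param pressure Peak acoustic pressure in pascals.
#' @param medium An [acoustic_medium()] giving the local rho and c.
#' @return Intensity in W/cm^2 (quadratic in `pressure`).
#' @examples
#' skin <- acoustic_medium(1109, 1513)
#' intensity_spta(0.25e6, skin) # ~1.86 W/cm^2
#' @export
intensity_spta <- function(pressure, medium) {
  stopifnot(inherits(medium, "acoustic_medium"))
  pressure <- check_finite(pressure, "pressure")
  pressure^2 / (2 * medium$density * medium$speed) / 1e4
}

#' Attenuation of a terminal signal relative to the incident signal
#'
#' `20 * log10(v_terminal / v_incident)` in decibels: negative for loss,
#' positive for gain (constructive interference can push a terminal voltage
#' above the incident one, as in the site-focused splenic model).
#'
#' @param v_terminal Terminal voltage amplitude (volts, `> 0`).
#' @param v_incident Incident voltage amplitude (volts, `> 0`).
#' @return Attenuation in dB.
#' @examples
#' attenuation_db(12.84e-3, 17.5e-3) # -2.69 dB
#' @export
attenuation_db <- function(v_terminal, v_incident) {
  v_terminal <- check_finite(v_terminal, "v_terminal")
  v_incident <- check_finite(v_incident, "v_incident")
  if (any(v_terminal <= 0) || any(v_incident <= 0)) {
    stop("voltage amplitudes must be > 0 (log undefined otherwise)",
         call. = FALSE)
  }
  20 * log10(v_terminal / v_incident)
}

#' Round half away from zero
#'
#' Report-layer rounding convention: printed dosimetry tables round half
#' away from zero (2.675 -> 2.68, -2.675 -> -2.68), unlike base `round()`'s
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}
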