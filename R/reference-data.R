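# Published reference cells shipped with the package.

#' Reported dosimetry cells from the original PSpice study
#'
#' The summary-table cells reported by the original PSpice
#' transmission-line study of cervical and site-focused splenic ultrasonic
#' vagus nerve stimulation, at source pressures 0.25 and 0.83 MPa: one row
#' per measurement (incident value plus each terminal) with propagation
#' time (us), delivered voltage (mV), mechanical pressure (MPa), I_SPTA
#' (W/cm^2) and attenuation (dB) as printed (two decimals).
#'
#' These are reference inputs for cross-checking the core relations — e.g.
#' recomputing the attenuation column from the voltage column — not outputs
#' of this package.
#'
#' @return A data.frame with columns `study_pressure_mpa`, `model`,
#'   `tissue`, `terminal`, `propagation_time_us`, `voltage_mv`,
#'   `pressure_mpa`, `intensity_w_cm2`, `attenuation_db`.
#' @export
reported_study_values <- function() {
  utils::read.csv(sonoline_example("reported_study_values.csv"),
                  stringsAsFactors = FALSE)
}
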