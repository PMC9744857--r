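# End-to-end dosimetry: first-peak measurements -> per-terminal records
# (voltage, mechanical pressure, I_SPTA, attenuation, safety flags), plus
# the study driver that runs a whole model at a given source pressure.

#' Acoustic intensity safety thresholds
#'
#' Three I_SPTA thresholds frame the therapeutic window: the minimum
#' intensity for ultrasound-induced intramembrane cavitation to trigger an
#' action potential (0.1 W/cm^2), the FDA ceiling for therapeutic
#' ultrasound (3 W/cm^2), and the thermal-burn bound reported for pulsed
#' splenic stimulation (35 W/cm^2).
#'
#' @param action_potential_min Excitation threshold, W/cm^2.
#' @param fda_max FDA therapeutic limit, W/cm^2.
#' @param thermal_burn_max Thermal-burn bound, W/cm^2.
#' @return An object of class `safety_thresholds`.
#' @export
safety_thresholds <- function(action_potential_min = 0.1, fda_max = 3,
                              thermal_burn_max = 35) {
  v <- c(action_potential_min, fda_max, thermal_burn_max)
  if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
    stop("thresholds must be positive finite numbers", call. = FALSE)
  }
  if (!(action_potential_min < fda_max && fda_max < thermal_burn_max)) {
    stop("thresholds must satisfy action_potential_min < fda_max < thermal_burn_max",
         call. = FALSE)
  }
  structure(list(action_potential_min = action_potential_min,
                 fda_max = fda_max, thermal_burn_max = thermal_burn_max),
            class = "safety_thresholds")
}

#' Classify an intensity against the safety thresholds
#'
#' @param intensity I_SPTA in W/cm^2 (numeric vector, `>= 0`).
#' @param thresholds A [safety_thresholds()].
#' @return A data.frame of logicals: `excites_action_potential`
#'   (`intensity >= action_potential_min`), `exceeds_fda`
#'   (`> fda_max`) and `exceeds_thermal` (`> thermal_burn_max`).
#' @examples
#' classify_safety(c(0.05, 2.19, 21.43))
#' @export
classify_safety <- function(intensity, thresholds = safety_thresholds()) {
  stopifnot(inherits(thresholds, "safety_thresholds"))
  intensity <- check_finite(intensity, "intensity")
  if (any(intensity < 0)) stop("`intensity` must be >= 0", call. = FALSE)
  data.frame(
    excites_action_potential = intensity >= thresholds$action_potential_min,
    exceeds_fda = intensity > thresholds$fda_max,
    exceeds_thermal = intensity > thresholds$thermal_burn_max)
}

#' Dosimetry record for one terminal measurement
#'
#' Chains the core relations on a first-peak measurement: voltage ->
#' mechanical pressure (`p = V/M`), pressure -> I_SPTA using the terminal
#' tissue's own rho and c (the intensity as if the transducer sat directly
#' on that tissue), and voltage -> attenuation in dB relative to the
#' incident voltage. All values are kept at full precision; rounding is a
#' formatting concern (see [format()] / [write_report()]).
#'
#' @param peak A [first_peak()] measurement (must have `detected = TRUE`).
#' @param incident_voltage Incident source voltage `v(T1:A+)` in volts.
#' @param terminal_tissue The [tissue_segment()] feeding the terminal.
#' @param cal A [hydrophone_calibration()].
#' @param thresholds A [safety_thresholds()].
#' @param tissue_name Report name for the row (defaults to the segment
#'   name).
#' @param attenuation_mode `"full"` computes dB from full-precision
#'   voltages; `"rounded_first"` rounds both voltages to 0.01 mV before the
#'   ratio, the convention needed to match two-decimal published cells.
#' @return A one-row data.frame (class `dosimetry_report`) with columns
#'   `tissue`, `terminal`, `propagation_time_us`, `voltage_mv`,
#'   `pressure_mpa`, `intensity_w_cm2`, `attenuation_db` and the three
#'   safety flags.
#' @export
terminal_dosimetry <- function(peak, incident_voltage, terminal_tissue,
                               cal = hydrophone_calibration(),
                               thresholds = safety_thresholds(),
                               tissue_name = terminal_tissue$name,
                               attenuation_mode = c("full", "rounded_first")) {
  stopifnot(inherits(peak, "peak_measurement"),
            inherits(terminal_tissue, "tissue_segment"))
  attenuation_mode <- match.arg(attenuation_mode)
  if (!isTRUE(peak$detected)) {
    stop("no arrival was detected at ", peak$label,
         "; cannot build a dosimetry record", call. = FALSE)
  }
  v <- abs(peak$amplitude)
  p <- voltage_to_pressure(v, cal)
  intensity <- intensity_spta(p, terminal_tissue$medium)
  att <- if (attenuation_mode == "rounded_first") {
    attenuation_db(round_half_away(v * 1e3) , round_half_away(incident_voltage * 1e3))
  } else {
    attenuation_db(v, incident_voltage)
  }
  flags <- classify_safety(intensity, thresholds)
  out <- data.frame(
    tissue = tissue_name, terminal = peak$label,
    propagation_time_us = peak$arrival_time * 1e6,
    voltage_mv = v * 1e3, pressure_mpa = p / 1e6,
    intensity_w_cm2 = intensity, attenuation_db = att,
    stringsAsFactors = FALSE)
  out <- cbind(out, flags)
  class(out) <- c("dosimetry_report", class(out))
  out
}

incident_record <- function(amplitude, first_segment, cal, thresholds) {
  p <- voltage_to_pressure(amplitude, cal)
  intensity <- intensity_spta(p, first_segment$medium)
  flags <- classify_safety(intensity, thresholds)
  out <- data.frame(
    tissue = "Initial value at epidermis surface", terminal = "T1:A+",
    propagation_time_us = 0, voltage_mv = amplitude * 1e3,
    pressure_mpa = p / 1e6, intensity_w_cm2 = intensity,
    attenuation_db = 0, stringsAsFactors = FALSE)
  cbind(out, flags)
}

#' Run a full stimulation study
#'
#' Pipeline driver reproducing the published study design: choose a model
#' (branched cervical or linear site-focused), set the source amplitude
#' from the target acoustic pressure through the hydrophone calibration,
#' run the transient simulation, measure the first peak at every labelled
#' terminal and assemble the dosimetry table — one incident row
#' (`v(T1:A+)`, time 0, attenuation 0) plus one row per terminal.
#'
#' @param pressure_mpa Source acoustic pressure in MPa (e.g. 0.25 or 0.83).
#' @param model `"cervical"`, `"site_focused"`, or `"custom"` (supply
#'   `network`).
#' @param table Tissue table (see [load_tissue_table()]); defaults to the
#'   shipped synthetic table.
#' @param config A [sim_config()]; defaults to 800 us (cervical) or 100 us
#'   (site-focused) at a 10 ns step.
#' @param network A `txline_network`, required for `model = "custom"`.
#' @param cal A [hydrophone_calibration()].
#' @param thresholds A [safety_thresholds()].
#' @param source Optional [source_pulse()] template; its amplitude is
#'   replaced by the calibrated value.
#' @param noise_floor_rel Peak-detection floor as a fraction of the source
#'   amplitude (default 1e-6).
#' @param attenuation_mode Passed to [terminal_dosimetry()].
#' @return A `dosimetry_report` data.frame; attributes `parameters` (list
#'   of run settings) and `traces` (the simulated A-scans).
#' @examples
#' \donttest{
#' tab <- load_tissue_table(sonoline_example("tissue_properties_synthetic.csv"))
#' rep <- run_study(0.25, "site_focused", tab,
#'                  config = sim_config(100e-6, time_step = 5e-8))
#' rep
#' }
#' @export
run_study <- function(pressure_mpa,
                      model = c("cervical", "site_focused", "custom"),
                      table = NULL, config = NULL, network = NULL,
                      cal = hydrophone_calibration(),
                      thresholds = safety_thresholds(),
                      source = NULL, noise_floor_rel = 1e-6,
                      attenuation_mode = c("full", "rounded_first")) {
  model <- match.arg(model)
  attenuation_mode <- match.arg(attenuation_mode)
  if (!is.numeric(pressure_mpa) || length(pressure_mpa) != 1L ||
      !is.finite(pressure_mpa) || pressure_mpa <= 0) {
    stop("`pressure_mpa` must be a single positive number", call. = FALSE)
  }
  if (model == "custom") {
    if (is.null(network)) stop("`network` is required for model = \"custom\"",
                               call. = FALSE)
  } else {
    if (is.null(table)) {
      table <- load_tissue_table(
        sonoline_example("tissue_properties_synthetic.csv"))
    }
    network <- switch(model,
                      cervical = cervical_vagus_model(table),
                      site_focused = site_focused_model(table))
  }
  if (is.null(config)) {
    config <- sim_config(if (model == "site_focused") 100e-6 else 800e-6)
  }
  amplitude <- pressure_to_voltage(pressure_mpa * 1e6, cal)
  source <- if (is.null(source)) {
    source_pulse(amplitude)
  } else {
    stopifnot(inherits(source, "source_pulse"))
    source_pulse(amplitude, period = source$period, width = source$width,
                 shape = source$shape, frequency = source$frequency)
  }
  traces <- simulate_network(network, source, config)

  first_seg <- network_segment(network, match(network$source,
                                              network$segments$from))
  rows <- list(incident_record(amplitude, first_seg, cal, thresholds))
  # first-peak window: a single pulse, so arrivals are measured before the
  # second emission can contaminate them
  window <- min(config$duration, source$period)
  for (i in seq_len(nrow(network$terminals))) {
    term <- network$terminals[i, ]
    tr <- traces[[term$label]]
    keep <- tr$times <= window
    tr_w <- ascan_trace(tr$node, tr$times[keep], tr$voltages[keep],
                        label = tr$label)
    pk <- first_peak(tr_w, noise_floor = noise_floor_rel * amplitude)
    if (!pk$detected) {
      stop("no arrival detected at terminal ", term$label,
           " within ", window * 1e6, " us", call. = FALSE)
    }
    seg_i <- match(term$node, network$segments$to)
    tissue_name <- if (!is.null(network$anatomy) &&
                       term$node %in% names(network$anatomy)) {
      unname(network$anatomy[term$node])
    } else term$tissue
    rows[[length(rows) + 1L]] <- terminal_dosimetry(
      pk, amplitude, network_segment(network, seg_i), cal, thresholds,
      tissue_name = tissue_name, attenuation_mode = attenuation_mode)
  }
  report <- do.call(rbind, lapply(rows, as.data.frame))
  class(report) <- c("dosimetry_report", class(report))
  attr(report, "parameters") <- list(
    pressure_mpa = pressure_mpa, model = model,
    amplitude_v = amplitude, sensitivity = cal$sensitivity,
    duration = config$duration, time_step = config$time_step,
    pulse_width = source$width, pulse_period = source$period,
    pulse_shape = source$shape, noise_floor_rel = noise_floor_rel,
    attenuation_mode = attenuation_mode)
  attr(report, "traces") <- traces
  report
}

#' @export
print.dosimetry_report <- function(x, digits = 2L, ...) {
  y <- as.data.frame(x)
  num <- c("propagation_time_us", "voltage_mv", "pressure_mpa",
           "intensity_w_cm2", "attenuation_db")
  y[num] <- lapply(y[num], round_half_away, digits = digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

report_columns <- c("tissue", "terminal", "propagation_time_us",
                    "voltage_mv", "pressure_mpa", "intensity_w_cm2",
                    "attenuation_db", "excites_action_potential",
                    "exceeds_fda", "exceeds_thermal")

#' Write a dosimetry report to CSV
#'
#' Columns mirror the published summary-table order (tissue, terminal,
#' propagation time, voltage, mechanical pressure, intensity, attenuation)
#' followed by the three safety flags. Values are written at full precision
#' so [read_report()] round-trips losslessly; use `digits` to emit a
#' rounded presentation copy instead.
#'
#' @param report A `dosimetry_report`.
#' @param path Output CSV path.
#' @param digits Optional decimal places for numeric columns (default
#'   `NULL`: full precision).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, digits = NULL) {
  stopifnot(is.data.frame(report))
  missing_cols <- setdiff(report_columns, names(report))
  if (length(missing_cols)) {
    stop("report lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- as.data.frame(report)[report_columns]
  if (!is.null(digits)) {
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], round_half_away, digits = digits)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a dosimetry report written by write_report
#'
#' @param path CSV path.
#' @return A `dosimetry_report` data.frame.
#' @export
read_report <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(report_columns, names(x))
  if (length(missing_cols)) {
    stop("file lacks report column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  class(x) <- c("dosimetry_report", class(x))
  x
}
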