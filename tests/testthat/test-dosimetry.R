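synthetic_table <- function() {
  load_tissue_table(sonoline_example("tissue_properties_synthetic.csv"))
}

test_that("safety thresholds validate and classify intensities correctly", {
  th <- safety_thresholds()
  expect_equal(th$action_potential_min, 0.1)
  expect_equal(th$fda_max, 3)
  expect_equal(th$thermal_burn_max, 35)
  expect_error(safety_thresholds(fda_max = 40), "action_potential_min")

  f <- classify_safety(c(0, 0.05, 0.1, 2.19, 3.0, 21.43, 36), th)
  expect_equal(f$excites_action_potential,
               c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(f$exceeds_fda,
               c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(f$exceeds_thermal,
               c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("terminal dosimetry chains calibration, intensity and attenuation on a peak", {
  # an A-scan whose first peak is the LRLN delivered voltage
  v <- numeric(400); v[301:310] <- 12.84e-3
  tr <- ascan_trace("lrln", (seq_along(v) - 1) * 1e-7, v, label = "T7:B+")
  pk <- first_peak(tr, noise_floor = 1e-6)
  nerve <- tissue_segment("lrln_terminal", acoustic_medium(1075, 1630), 0.1)

  rec <- terminal_dosimetry(pk, 17.5e-3, nerve)
  expect_equal(round_half_away(rec$pressure_mpa), 0.18)
  expect_equal(round_half_away(rec$attenuation_db), -2.69)
  expect_equal(round_half_away(rec$intensity_w_cm2), 0.96)
  expect_true(rec$excites_action_potential)
  expect_false(rec$exceeds_fda)

  # equal amplitude -> 0 dB regardless of tissue
  v2 <- numeric(100); v2[51:60] <- 17.5e-3
  pk2 <- first_peak(ascan_trace("x", (1:100 - 1) * 1e-7, v2), 1e-6)
  rec2 <- terminal_dosimetry(pk2, 17.5e-3, nerve)
  expect_equal(rec2$attenuation_db, 0)
  expect_equal(round_half_away(rec2$pressure_mpa), 0.25)

  # a no-arrival measurement cannot be turned into a record
  none <- first_peak(ascan_trace("y", (1:10 - 1) * 1e-7, numeric(10)), 0)
  expect_error(terminal_dosimetry(none, 17.5e-3, nerve), "no arrival")
})

test_that("run_study emits the expected report structure for both models", {
  tab <- synthetic_table()
  cfg <- sim_config(800e-6, time_step = 5e-8)
  cerv <- run_study(0.25, "cervical", tab, config = cfg)
  expect_equal(nrow(cerv), 6L)           # incident row + 5 terminals
  expect_equal(cerv$terminal[1], "T1:A+")
  expect_setequal(cerv$terminal[-1],
                  c("T7:B+", "T9:B+", "T16:B+", "T18:B+", "T14:B+"))
  expect_equal(cerv$attenuation_db[1], 0)
  expect_equal(cerv$voltage_mv[1], 17.5)
  expect_equal(round_half_away(cerv$intensity_w_cm2[1]), 1.86)

  sf <- run_study(0.25, "site_focused", tab,
                  config = sim_config(100e-6, time_step = 5e-8))
  expect_equal(nrow(sf), 2L)
  expect_equal(sf$terminal, c("T1:A+", "T8:B+"))

  # fewer excited terminals under site-focused stimulation
  expect_lt(sum(sf$terminal != "T1:A+"), sum(cerv$terminal != "T1:A+"))

  # attenuation column is consistent with the voltage column via the dB rule
  for (rep in list(cerv, sf)) {
    recomputed <- attenuation_db(rep$voltage_mv[-1], rep$voltage_mv[1])
    expect_lt(max(abs(recomputed - rep$attenuation_db[-1])), 0.005)
  }
})

test_that("attenuation columns agree across source pressures; times agree within one step", {
  tab <- synthetic_table()
  cfg <- sim_config(800e-6, time_step = 5e-8)
  lo <- run_study(0.25, "cervical", tab, config = cfg)
  hi <- run_study(0.83, "cervical", tab, config = cfg)
  expect_equal(hi$attenuation_db, lo$attenuation_db, tolerance = 1e-9)
  expect_lt(max(abs(hi$propagation_time_us - lo$propagation_time_us)),
            cfg$time_step * 1e6 + 1e-9)
  # voltages scale with the source: 58.1/17.5 exactly
  expect_equal(hi$voltage_mv / lo$voltage_mv, rep(58.1 / 17.5, 6),
               tolerance = 1e-9)
})

test_that("reports round-trip through CSV losslessly", {
  tab <- synthetic_table()
  rep <- run_study(0.25, "site_focused", tab,
                   config = sim_config(100e-6, time_step = 5e-8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, path)
  back <- read_report(path)
  expect_equal(as.data.frame(back), as.data.frame(rep)[names(back)],
               tolerance = 1e-12, ignore_attr = TRUE)

  # empty report -> header-only file
  empty <- rep[0, ]
  write_report(empty, path)
  expect_equal(nrow(read_report(path)), 0L)
  expect_equal(names(read_report(path)),
               c("tissue", "terminal", "propagation_time_us", "voltage_mv",
                 "pressure_mpa", "intensity_w_cm2", "attenuation_db",
                 "excites_action_potential", "exceeds_fda",
                 "exceeds_thermal"))
})

test_that("the rounded-first attenuation convention reproduces two-decimal table arithmetic", {
  # with printed (two-decimal mV) voltages the two conventions coincide
  v <- numeric(100); v[51:60] <- 12.84e-3
  pk <- first_peak(ascan_trace("x", (1:100 - 1) * 1e-7, v), 1e-6)
  nerve <- tissue_segment("n", acoustic_medium(1075, 1630), 0.1)
  full <- terminal_dosimetry(pk, 17.5e-3, nerve, attenuation_mode = "full")
  rf <- terminal_dosimetry(pk, 17.5e-3, nerve,
                           attenuation_mode = "rounded_first")
  expect_equal(round_half_away(full$attenuation_db),
               round_half_away(rf$attenuation_db))
})
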