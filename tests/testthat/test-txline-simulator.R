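test_that("junction scattering matches closed forms and conserves power", {
  # matched: no reflection, full transmission
  m <- junction_scatter(1, 2e6, 2e6)
  expect_equal(m$reflected, 0)
  expect_equal(m$node_voltage, 1)

  # single mismatch 1.5 -> 3.0: Gamma = 1/3, node voltage 4/3
  s <- junction_scatter(1, 1.5, 3.0)
  expect_equal(s$gamma, 1 / 3)
  expect_equal(s$node_voltage, 4 / 3)

  # symmetric Y: two downstream lines of the trunk impedance
  y <- junction_scatter(1, 2e6, c(2e6, 2e6))
  expect_equal(y$gamma, -1 / 3)
  expect_equal(y$node_voltage, 2 / 3)

  # power conservation Gamma^2 + (1+Gamma)^2 z_in/Z_load = 1 over random junctions
  set.seed(42)
  for (i in 1:200) {
    z_in <- stats::runif(1, 0.5e6, 3e6)
    k <- sample(0:4, 1)
    down <- if (k > 0) stats::runif(k, 0.5e6, 3e6)
    shunt <- if (k == 0 || stats::runif(1) < 0.5) stats::runif(1, 0.5e6, 3e6)
    r <- junction_scatter(1, z_in, down, shunt)
    z_load <- 1 / sum(1 / c(down, shunt))
    residual <- r$gamma^2 + (1 + r$gamma)^2 * z_in / z_load - 1
    expect_lt(abs(residual), 1e-12)
  }

  expect_error(junction_scatter(1, 1e6, numeric(0)), "open end")
})

test_that("a matched uniform chain delivers a delayed copy with zero echoes", {
  net <- chain_network(rep(1000, 3), rep(1500, 3), c(0.015, 0.009, 0.012))
  src <- source_pulse(1, width = 2e-6)
  cfg <- sim_config(60e-6, time_step = 1e-7)
  traces <- simulate_network(net, src, cfg)
  out <- traces[["T3:B+"]]

  dt <- cfg$time_step
  lag <- sum(round(net$segments$delay / dt))
  expected <- c(numeric(lag),
                source_waveform(src, out$times)[1:(length(out$times) - lag)])
  expect_lt(max(abs(out$voltages - expected)), 1e-12)

  # analytic arrival time within one time step of sum(d/c)
  pk <- first_peak(out, noise_floor = 1e-6)
  expect_lt(abs(pk$arrival_time - path_delay(net, "n3")), dt)
  expect_equal(pk$amplitude, 1)
})

test_that("a two-segment impedance step transmits (1 + Gamma) of the incident amplitude", {
  # Z1 = 1.5e6, Z2 = 3.0e6 -> terminal amplitude 4/3 of the source
  net <- chain_network(c(1500, 3000), c(1000, 1000), c(0.005, 0.004))
  src <- source_pulse(1, width = 1e-6)
  traces <- simulate_network(net, src, sim_config(30e-6, time_step = 1e-7))
  pk <- first_peak(traces[["T2:B+"]], noise_floor = 1e-6)
  expect_equal(pk$amplitude, 4 / 3)
})

test_that("a symmetric N-branch junction transmits 2/(N+1) into each branch", {
  for (n in 2:4) {
    net <- star_network(n)
    traces <- simulate_network(net, source_pulse(1, width = 1e-6),
                               sim_config(30e-6, time_step = 1e-7))
    for (i in seq_len(n)) {
      pk <- first_peak(traces[[sprintf("T%d:B+", i + 1L)]],
                       noise_floor = 1e-6)
      expect_equal(pk$amplitude, 2 / (n + 1))
    }
  }
})

test_that("simulate agrees with the analytic multipath oracle on random short cascades", {
  set.seed(101)
  dt <- 1e-7
  src <- source_pulse(1, width = 1e-6)
  for (rep in 1:25) {
    n <- sample(2:4, 1)
    pr <- random_chain_properties(n)
    for (reflects in c(TRUE, FALSE)) {
      net <- chain_network(pr$densities, pr$speeds, pr$lengths)
      traces <- simulate_network(net, src, sim_config(40e-6, time_step = dt),
                                 source_reflects = reflects)
      sim <- traces[[sprintf("T%d:B+", n)]]
      oracle <- analytic_cascade_response(
        chain_segments(pr$densities, pr$speeds, pr$lengths), src,
        t_max = 40e-6, time_step = dt, source_reflects = reflects)
      expect_lt(max(abs(sim$voltages - oracle$voltages)), 1e-9)
    }
  }
})

test_that("the oracle rejects branched input and kills echoes at a matched end", {
  seg <- chain_segments(c(1000, 1000), c(1500, 1500), c(0.006, 0.0045))
  src <- source_pulse(1, width = 1e-6)
  tr <- analytic_cascade_response(seg, src, 30e-6, time_step = 1e-7)
  expect_equal(nrow(echo_train(tr, noise_floor = 1e-6,
                               min_separation = 2e-6)), 1L)
  expect_error(analytic_cascade_response(as.list(1:5), src, 1e-5),
               "<= 4 segments")
})

test_that("traces scale linearly with source amplitude and dB is amplitude-invariant", {
  pr <- random_chain_properties(3)
  net <- chain_network(pr$densities, pr$speeds, pr$lengths)
  cfg <- sim_config(40e-6, time_step = 1e-7)
  t1 <- simulate_network(net, source_pulse(1, width = 1e-6), cfg)
  k <- 3.32
  t2 <- simulate_network(net, source_pulse(k, width = 1e-6), cfg)
  v1 <- t1[["T3:B+"]]$voltages
  v2 <- t2[["T3:B+"]]$voltages
  expect_lt(max(abs(v2 - k * v1)), 1e-12 * k)

  a1 <- first_peak(t1[["T3:B+"]], 1e-9)$amplitude
  a2 <- first_peak(t2[["T3:B+"]], 1e-9)$amplitude
  expect_equal(attenuation_db(abs(a2), k), attenuation_db(abs(a1), 1),
               tolerance = 1e-12)
})

test_that("configuration guards reject unresolvable delays and runaway sample counts", {
  net <- chain_network(c(1000, 1000), c(1500, 1500), c(0.0000001, 0.005))
  expect_error(
    simulate_network(net, source_pulse(1), sim_config(1e-5, time_step = 1e-8)),
    "time step")
  expect_error(sim_config(1, time_step = 1e-9), "cap")
  expect_error(source_pulse(1, period = 1e-6, width = 2e-6), "width")
})
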