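test_that("tissue tables load from CSV and invalid tables are rejected by row", {
  path <- write_toy_table_csv()
  tab <- load_tissue_table(path)
  expect_s3_class(tab, "tissue_table")
  expect_equal(nrow(tab), 4L)

  bad <- toy_table()
  bad$density_kg_m3[2] <- 0
  expect_error(load_tissue_table(write_toy_table_csv(bad)), "layer_b")

  dup <- toy_table()
  dup$name[3] <- "layer_a"
  expect_error(load_tissue_table(write_toy_table_csv(dup)), "duplicated")

  nocol <- toy_table()[, -2]
  expect_error(load_tissue_table(write_toy_table_csv(nocol)),
               "density_kg_m3")
  expect_error(load_tissue_table(tempfile()), "not found")
})

test_that("tissue segments derive impedance and delay consistently", {
  seg <- tissue_segment("water", acoustic_medium(1000, 1500), 0.015)
  expect_equal(segment_impedance(seg), 1.5e6)
  expect_equal(segment_delay(seg), 10e-6)
  expect_error(tissue_segment("x", acoustic_medium(1000, 1500), 0), "positive")
})

test_that("build_network assembles chains and trees with matched terminations", {
  tab <- toy_table()
  lin <- build_network(tab, topology_spec(
    data.frame(tissue = c("layer_a", "layer_b"),
               from = c("src", "n1"), to = c("n1", "n2")), "src"))
  expect_equal(nrow(lin$terminals), 1L)
  expect_equal(lin$terminals$load_resistance,
               lin$segments$impedance[2])

  y <- build_network(tab, topology_spec(
    data.frame(tissue = c("layer_a", "layer_b", "layer_c"),
               from = c("src", "fork", "fork"),
               to = c("fork", "leaf1", "leaf2")), "src"))
  expect_equal(nrow(y$terminals), 2L)
  # every terminal load matches its upstream segment impedance exactly
  up <- match(y$terminals$node, y$segments$to)
  expect_identical(y$terminals$load_resistance / y$segments$impedance[up],
                   rep(1, 2))

  expect_error(build_network(tab, topology_spec(
    data.frame(tissue = "nonesuch", from = "src", to = "n1"), "src")),
    "nonesuch")
  expect_error(build_network(tab, topology_spec(
    data.frame(tissue = c("layer_a", "layer_b"),
               from = c("src", "n1"), to = c("n1", "src")), "src")),
    "incoming")
  expect_error(build_network(tab, topology_spec(
    data.frame(tissue = c("layer_a", "layer_b"),
               from = c("src", "other_root"), to = c("n1", "n2")), "src")),
    "root")
  # cycle off the main trunk
  expect_error(build_network(tab, topology_spec(
    data.frame(tissue = c("layer_a", "layer_b", "layer_c"),
               from = c("src", "c1", "c2"), to = c("n1", "c2", "c1")),
    "src")), "cycle|incoming|unreachable")
})

test_that("cervical model has the five labelled terminals and a three-way esophageal split", {
  tab <- load_tissue_table(sonoline_example("tissue_properties_synthetic.csv"))
  cv <- cervical_vagus_model(tab)
  expect_equal(nrow(cv$segments), 18L)
  expect_equal(nrow(cv$terminals), 5L)
  expect_setequal(cv$terminals$label,
                  c("T7:B+", "T9:B+", "T16:B+", "T18:B+", "T14:B+"))
  # esophageal junction splits three ways
  outdeg <- table(cv$segments$from)
  expect_equal(unname(outdeg[["esoph_jct"]]), 3L)
  # terminal labels tie to the expected anatomy
  expect_equal(cv$terminals$label[cv$terminals$tissue == "splenic_nerve"],
               "T14:B+")

  short <- tab[tab$name != "celiac_plexus", ]
  expect_error(cervical_vagus_model(short), "celiac_plexus")
})

test_that("site-focused model is a linear 8-segment chain ending at T8:B+", {
  tab <- load_tissue_table(sonoline_example("tissue_properties_synthetic.csv"))
  sf <- site_focused_model(tab)
  expect_equal(nrow(sf$segments), 8L)
  expect_equal(sf$terminals$label, "T8:B+")
  expect_true(all(table(sf$segments$from) == 1L))  # strictly linear
  # path delay equals the analytic sum of d/c over the chain
  expect_equal(path_delay(sf, sf$terminals$node),
               sum(sf$segments$length / sf$segments$speed))
})

test_that("topology YAML files load and build", {
  tab <- load_tissue_table(sonoline_example("tissue_properties_synthetic.csv"))
  topo <- load_topology(sonoline_example("example_topology.yaml"))
  net <- build_network(tab, topo)
  expect_equal(nrow(net$terminals), 2L)
  expect_setequal(net$terminals$label, c("T5:B+", "T6:B+"))
  expect_equal(unname(net$anatomy["cardiac"]), "Cardiac Plexus")
})

test_that("SPICE netlist export has the right cards and round-trips the model graph", {
  net <- chain_network(c(1000, 1200), c(1500, 1600), c(0.015, 0.012))
  src <- source_pulse(17.5e-3)
  txt <- export_spice_netlist(net, src, config = sim_config(100e-6))
  lines <- strsplit(txt, "\n")[[1]]
  expect_length(grep("^T", lines), 2L)
  expect_length(grep("^V", lines), 1L)
  expect_length(grep("^R", lines), 1L)
  expect_length(grep("^\\.TRAN", lines), 1L)

  parsed <- parse_spice_netlist(txt)
  # resistor equals the last segment's impedance (matched-terminal rule)
  expect_equal(parsed$terminals$load_resistance, net$segments$impedance[2])
  expect_equal(parsed$segments$tissue, net$segments$tissue)
  expect_equal(parsed$segments$from, net$segments$from)
  expect_equal(parsed$segments$to, net$segments$to)
  expect_equal(parsed$segments$impedance, net$segments$impedance)
  expect_equal(parsed$segments$delay, net$segments$delay)
  expect_equal(parsed$source$node, net$source)
  expect_equal(parsed$source$amplitude, src$amplitude)
  expect_equal(parsed$source$period, src$period)
})
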