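# Programmatic fixtures: toy tissue tables and small networks built in code.

toy_table <- function() {
  as_tissue_table(data.frame(
    name = c("layer_a", "layer_b", "layer_c", "layer_d"),
    density_kg_m3 = c(1000, 1200, 900, 1100),
    speed_m_s = c(1500, 1600, 1400, 1550),
    length_m = c(0.015, 0.012, 0.010, 0.008),
    stringsAsFactors = FALSE))
}

write_toy_table_csv <- function(df = toy_table()) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  path
}

# strictly linear chain network from per-segment acoustic properties
chain_network <- function(densities, speeds, lengths,
                          names = sprintf("seg%d", seq_along(densities))) {
  tab <- as_tissue_table(data.frame(
    name = names, density_kg_m3 = densities, speed_m_s = speeds,
    length_m = lengths, stringsAsFactors = FALSE))
  n <- length(names)
  nodes <- c("src", sprintf("n%d", seq_len(n)))
  edges <- data.frame(tissue = names, from = nodes[-(n + 1L)],
                      to = nodes[-1L], stringsAsFactors = FALSE)
  build_network(tab, topology_spec(edges, "src"))
}

chain_segments <- function(densities, speeds, lengths) {
  lapply(seq_along(densities), function(i) {
    tissue_segment(sprintf("seg%d", i),
                   acoustic_medium(densities[i], speeds[i]), lengths[i])
  })
}

# one trunk feeding n_branches identical-impedance branches
star_network <- function(n_branches, density = 1000, speed = 1500,
                         trunk_length = 0.006, branch_length = 0.0045) {
  names <- c("trunk", sprintf("branch%d", seq_len(n_branches)))
  tab <- as_tissue_table(data.frame(
    name = names, density_kg_m3 = density, speed_m_s = speed,
    length_m = c(trunk_length, rep(branch_length, n_branches)),
    stringsAsFactors = FALSE))
  edges <- data.frame(
    tissue = names,
    from = c("src", rep("fork", n_branches)),
    to = c("fork", sprintf("leaf%d", seq_len(n_branches))),
    stringsAsFactors = FALSE)
  build_network(tab, topology_spec(edges, "src"))
}

random_chain_properties <- function(n) {
  list(densities = stats::runif(n, 800, 2000),
       speeds = stats::runif(n, 1300, 1900),
       lengths = stats::runif(n, 0.003, 0.012))
}
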