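# SPICE netlist export: one ideal lossless transmission-line card per tissue
# segment, a pulsed voltage source, matched terminal resistors, common
# ground node 0. Lets the model be cross-checked in any SPICE engine.

#' Export a network as a SPICE netlist
#'
#' Emits `.cir` text with a `T` card per segment (`Z0` = characteristic
#' impedance in rayl-equivalent ohms, `TD` = one-way delay), a `V` card for
#' the pulsed source and an `R` card per matched terminal. All negative
#' rails are tied to ground node `0`. Inline `; tissue=` / `; label=`
#' comments preserve names so [parse_spice_netlist()] can reconstruct the
#' model graph.
#'
#' @param network A [build_network()] result.
#' @param source A [source_pulse()] driving the root node.
#' @param config Optional [sim_config()]; adds a matching `.TRAN` card.
#' @return A character scalar of netlist text.
#' @export
export_spice_netlist <- function(network, source, config = NULL) {
  stopifnot(inherits(network, "txline_network"),
            inherits(source, "source_pulse"))
  seg <- network$segments
  rise <- if (!is.null(config)) config$time_step else 1e-8
  lines <- c(
    "* sonoline electro-acoustic transmission-line network",
    sprintf("V1 %s 0 PULSE(0 %.15g 0 %.15g %.15g %.15g %.15g)",
            network$source, source$amplitude, rise, rise,
            source$width, source$period))
  lines <- c(lines, sprintf(
    "T%d %s 0 %s 0 Z0=%.15g TD=%.15g ; tissue=%s",
    seq_len(nrow(seg)), seg$from, seg$to, seg$impedance, seg$delay,
    seg$tissue))
  term <- network$terminals
  lines <- c(lines, sprintf(
    "R%d %s 0 %.15g ; label=%s",
    seq_len(nrow(term)), term$node, term$load_resistance, term$label))
  if (!is.null(config)) {
    lines <- c(lines, sprintf(".TRAN %.15g %.15g", config$time_step,
                              config$duration))
  }
  paste(c(lines, ".END", ""), collapse = "\n")
}

#' Parse a netlist emitted by export_spice_netlist
#'
#' Inverse of [export_spice_netlist()] for the card subset it emits;
#' used to verify that the exported text reproduces the model graph.
#'
#' @param text Netlist text (character scalar or vector of lines).
#' @return A list with `segments` (tissue, from, to, impedance, delay),
#'   `terminals` (node, label, load_resistance) and `source` (node,
#'   amplitude, width, period).
#' @export
parse_spice_netlist <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "*") &
                   !startsWith(lines, ".")]
  tag <- function(line, key) {
    m <- regmatches(line, regexec(paste0(key, "=([^ ;]+)"), line))[[1]]
    if (length(m) < 2L) NA_character_ else m[2]
  }
  seg <- NULL; term <- NULL; src <- NULL
  for (line in lines) {
    fields <- strsplit(sub(";.*$", "", line), "[[:space:]]+")[[1]]
    kind <- toupper(substr(fields[1], 1, 1))
    if (kind == "T") {
      seg <- rbind(seg, data.frame(
        tissue = tag(line, "tissue"), from = fields[2], to = fields[4],
        impedance = as.numeric(tag(line, "Z0")),
        delay = as.numeric(tag(line, "TD")), stringsAsFactors = FALSE))
    } else if (kind == "R") {
      term <- rbind(term, data.frame(
        node = fields[2], label = tag(line, "label"),
        load_resistance = as.numeric(fields[4]), stringsAsFactors = FALSE))
    } else if (kind == "V") {
      pulse <- regmatches(line, regexec(
        "PULSE\\(([^)]*)\\)", line))[[1]][2]
      p <- as.numeric(strsplit(trimws(pulse), "[[:space:]]+")[[1]])
      src <- list(node = fields[2], amplitude = p[2], width = p[6],
                  period = p[7])
    } else {
      stop("unsupported netlist card: ", line, call. = FALSE)
    }
  }
  list(segments = seg, terminals = term, source = src)
}
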