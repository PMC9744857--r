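# Tissue property tables, tissue segments and branched network assembly.

#' A single tissue segment
#'
#' One layer (or nerve span) of the propagation path: an acoustic medium plus
#' a length. Characteristic impedance (`Z = rho c`) and one-way delay
#' (`tau = d / c`) are always derived from the stored fields, never cached,
#' so they cannot fall out of sync.
#'
#' @param name Segment identifier (single non-empty string).
#' @param medium An [acoustic_medium()].
#' @param length Segment length in metres (`> 0`).
#' @return An object of class `tissue_segment` with accessors
#'   [segment_impedance()] and [segment_delay()].
#' @export
tissue_segment <- function(name, medium, length) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a single non-empty string", call. = FALSE)
  }
  stopifnot(inherits(medium, "acoustic_medium"))
  if (!is.numeric(length) || length(length) != 1L || !is.finite(length) ||
      length <= 0) {
    stop("`length` must be a single positive finite number (metres)",
         call. = FALSE)
  }
  structure(list(name = name, medium = medium, length = as.numeric(length)),
            class = "tissue_segment")
}

#' @rdname tissue_segment
#' @param segment A `tissue_segment`.
#' @export
segment_impedance <- function(segment) {
  stopifnot(inherits(segment, "tissue_segment"))
  acoustic_impedance(segment$medium)
}

#' @rdname tissue_segment
#' @export
segment_delay <- function(segment) {
  stopifnot(inherits(segment, "tissue_segment"))
  propagation_delay(segment$length, segment$medium$speed)
}

#' @export
print.tissue_segment <- function(x, ...) {
  cat(sprintf("<tissue_segment> %s: d = %g m, Z = %.4g rayl, tau = %.4g us\n",
              x$name, x$length, segment_impedance(x), segment_delay(x) * 1e6))
  invisible(x)
}

tissue_table_columns <- c("name", "density_kg_m3", "speed_m_s", "length_m")

#' Load a tissue property table
#'
#' Reads a delimited file with header columns `name,density_kg_m3,speed_m_s,
#' length_m` (an optional `reference` column carries provenance notes).
#' Row names must be unique and all numeric fields strictly positive; any
#' violation is rejected with a diagnostic naming the offending row.
#'
#' The package ships `tissue_properties_synthetic.csv` under `extdata`: a
#' fully populated synthetic table whose nerve and epidermis impedances are
#' pinned by published pressure/intensity pairs and whose remaining values
#' are literature-typical. Replace it with your own measurements for
#' quantitative work.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` of class `tissue_table`.
#' @examples
#' tab <- load_tissue_table(sonoline_example("tissue_properties_synthetic.csv"))
#' head(tab)
#' @export
load_tissue_table <- function(path) {
  if (!file.exists(path)) stop("tissue table not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_tissue_table(raw)
}

#' Validate a data frame as a tissue table
#'
#' @param x A data.frame with the tissue table columns.
#' @return `x`, validated, with class `tissue_table` prepended.
#' @export
as_tissue_table <- function(x) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(tissue_table_columns, names(x))
  if (length(missing_cols)) {
    stop("tissue table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$name <- as.character(x$name)
  dup <- unique(x$name[duplicated(x$name)])
  if (length(dup)) {
    stop("duplicated tissue name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("density_kg_m3", "speed_m_s", "length_m")) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad)) {
      stop(sprintf("tissue table column `%s` must be positive numeric; bad row(s): %s",
                   col, paste(x$name[bad], collapse = ", ")), call. = FALSE)
    }
    x[[col]] <- v
  }
  if (!inherits(x, "tissue_table")) class(x) <- c("tissue_table", class(x))
  x
}

#' Path to a file shipped with the package
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a vector of file names).
#' @export
sonoline_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "sonoline")))
  }
  path <- system.file("extdata", file, package = "sonoline")
  if (!nzchar(path)) stop("no shipped file named ", file, call. = FALSE)
  path
}

table_segment <- function(table, tissue) {
  i <- match(tissue, table$name)
  if (is.na(i)) stop("tissue not in table: ", tissue, call. = FALSE)
  tissue_segment(tissue,
                 acoustic_medium(table$density_kg_m3[i], table$speed_m_s[i]),
                 table$length_m[i])
}

#' Describe a network topology
#'
#' A topology specification is the structural half of a model: which tissue
#' fills each span, how spans connect, where the source sits and which leaf
#' nodes are measurement terminals. Tissue properties stay in the
#' [load_tissue_table()] file; the topology only names them.
#'
#' @param edges `data.frame` with columns `tissue`, `from`, `to`: one row per
#'   segment, oriented away from the source.
#' @param source Name of the root node where the pulsed source is applied.
#' @param terminals Named character vector mapping leaf node name ->
#'   measurement label (e.g. `c(lrln = "T7:B+")`). Defaults to labelling each
#'   leaf after its upstream segment index as `T<i>:B+`.
#' @param anatomy Optional named character vector mapping leaf node ->
#'   anatomical name used in reports.
#' @return An object of class `topology_spec`.
#' @export
topology_spec <- function(edges, source, terminals = NULL, anatomy = NULL) {
  stopifnot(is.data.frame(edges))
  need <- c("tissue", "from", "to")
  if (!all(need %in% names(edges))) {
    stop("`edges` needs columns tissue, from, to", call. = FALSE)
  }
  edges <- data.frame(lapply(edges[need], as.character),
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, source = as.character(source),
                 terminals = terminals, anatomy = anatomy),
            class = "topology_spec")
}

#' Read a topology specification from a YAML file
#'
#' File dialect: a mapping with keys `source` (node name), `segments` (list
#' of `{tissue, from, to}` mappings, oriented away from the source) and
#' optional `terminals` (mapping leaf node -> label) and `anatomy` (mapping
#' leaf node -> anatomical name).
#'
#' @param path YAML file path.
#' @return A [topology_spec()].
#' @export
load_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y$source) || is.null(y$segments)) {
    stop("topology file needs `source` and `segments` keys", call. = FALSE)
  }
  edges <- do.call(rbind, lapply(y$segments, function(s) {
    if (is.null(s$tissue) || is.null(s$from) || is.null(s$to)) {
      stop("each segment needs tissue, from, to", call. = FALSE)
    }
    data.frame(tissue = s$tissue, from = s$from, to = s$to,
               stringsAsFactors = FALSE)
  }))
  topology_spec(edges, y$source,
                terminals = if (!is.null(y$terminals)) unlist(y$terminals),
                anatomy = if (!is.null(y$anatomy)) unlist(y$anatomy))
}

#' Assemble a transmission-line network model
#'
#' Joins a tissue property table with a topology into a validated rooted
#' tree. Each edge becomes a [tissue_segment()]; every leaf automatically
#' receives a matched resistive termination equal to the characteristic
#' impedance of its upstream segment, so terminals absorb incident waves
#' without reflection. All inter-element connections share a common ground
#' (the 1-D analogy's return rail).
#'
#' Validation rejects: segments naming tissues absent from the table,
#' multiple roots or in-degree > 1, cycles, and disconnected nodes.
#'
#' @param table A [load_tissue_table()] result (or data.frame passing
#'   [as_tissue_table()]).
#' @param topology A [topology_spec()].
#' @return An object of class `txline_network` with components
#'   `segments` (data.frame: tissue, from, to, density, speed, length,
#'   impedance, delay), `nodes`, `source`, `terminals` (data.frame: node,
#'   label, tissue, load_resistance), `anatomy`.
#' @export
build_network <- function(table, topology) {
  table <- as_tissue_table(as.data.frame(table))
  stopifnot(inherits(topology, "topology_spec"))
  edges <- topology$edges
  if (nrow(edges) == 0L) stop("topology has no segments", call. = FALSE)

  unknown <- setdiff(edges$tissue, table$name)
  if (length(unknown)) {
    stop("topology references tissue(s) absent from table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  nodes <- unique(c(topology$source, edges$from, edges$to))
  src <- topology$source
  if (!src %in% c(edges$from)) {
    stop("source node `", src, "` has no outgoing segment", call. = FALSE)
  }
  indeg <- table(factor(edges$to, levels = nodes))
  if (indeg[[src]] > 0L) {
    stop("source node must have no incoming segment", call. = FALSE)
  }
  multi <- names(indeg)[indeg > 1L]
  if (length(multi)) {
    stop("node(s) with more than one incoming segment (not a tree): ",
         paste(multi, collapse = ", "), call. = FALSE)
  }
  roots <- setdiff(nodes, edges$to)
  if (!identical(sort(roots), sort(src))) {
    stop("multiple root nodes found: ", paste(roots, collapse = ", "),
         call. = FALSE)
  }
  # connectivity from the source; with unique parents this also excludes cycles
  reached <- src
  repeat {
    nxt <- edges$to[edges$from %in% reached & !(edges$to %in% reached)]
    if (!length(nxt)) break
    reached <- c(reached, unique(nxt))
  }
  stray <- setdiff(nodes, reached)
  if (length(stray)) {
    stop("node(s) unreachable from source (cycle or disconnection): ",
         paste(stray, collapse = ", "), call. = FALSE)
  }

  i <- match(edges$tissue, table$name)
  seg <- data.frame(
    tissue = edges$tissue, from = edges$from, to = edges$to,
    density = table$density_kg_m3[i], speed = table$speed_m_s[i],
    length = table$length_m[i], stringsAsFactors = FALSE)
  seg$impedance <- seg$density * seg$speed
  seg$delay <- seg$length / seg$speed

  leaves <- setdiff(nodes, edges$from)
  upstream <- match(leaves, seg$to)
  labels <- topology$terminals
  if (is.null(labels)) {
    labels <- stats::setNames(sprintf("T%d:B+", upstream), leaves)
  } else {
    labels <- unlist(labels)
    miss <- setdiff(leaves, names(labels))
    if (length(miss)) {
      stop("terminal label missing for leaf node(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    extra <- setdiff(names(labels), leaves)
    if (length(extra)) {
      stop("terminal label given for non-leaf node(s): ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    labels <- labels[leaves]
  }
  terminals <- data.frame(
    node = leaves, label = unname(labels), tissue = seg$tissue[upstream],
    load_resistance = seg$impedance[upstream], stringsAsFactors = FALSE)

  anatomy <- topology$anatomy
  structure(list(segments = seg, nodes = nodes, source = src,
                 terminals = terminals,
                 anatomy = if (!is.null(anatomy)) unlist(anatomy)),
            class = "txline_network")
}

#' @export
print.txline_network <- function(x, ...) {
  cat(sprintf("<txline_network> %d segments, %d nodes, %d terminal(s)\n",
              nrow(x$segments), length(x$nodes), nrow(x$terminals)))
  cat("  terminals:",
      paste(sprintf("%s (%s)", x$terminals$label, x$terminals$tissue),
            collapse = ", "), "\n")
  invisible(x)
}

#' Extract one segment of a network as a tissue_segment
#'
#' @param network A [build_network()] result.
#' @param index Segment row index.
#' @return A [tissue_segment()].
#' @export
network_segment <- function(network, index) {
  stopifnot(inherits(network, "txline_network"))
  s <- network$segments[index, ]
  tissue_segment(s$tissue, acoustic_medium(s$density, s$speed), s$length)
}

#' Sum of segment delays from the source to a node
#'
#' Additivity of `t = d/c` along the unique root path: the analytic arrival
#' time of the primary pulse, independent of impedances.
#'
#' @param network A [build_network()] result.
#' @param node Node name (e.g. a terminal's `node`).
#' @return Delay in seconds.
#' @export
path_delay <- function(network, node) {
  stopifnot(inherits(network, "txline_network"))
  seg <- network$segments
  total <- 0
  while (node != network$source) {
    i <- match(node, seg$to)
    if (is.na(i)) stop("node not in network: ", node, call. = FALSE)
    total <- total + seg$delay[i]
    node <- seg$from[i]
  }
  total
}
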