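# Built-in anatomical models: cervical vagus stimulation (branched) and
# site-focused splenic stimulation (linear). Segment numbering T1..T18 /
# T1..T8 follows the measurement labels of the original circuit layouts so
# report rows are directly comparable; intermediate node names are synthetic.

cervical_tissues <- c(
  "epidermis", "dermis", "subcutaneous_tissue",          # T1-T3 skin stack
  "cervical_vagus_trunk",                                # T4
  "lrln_descending", "lrln_loop", "lrln_terminal",       # T5-T7 recurrent laryngeal path
  "thoracic_vagus_trunk",                                # T8
  "cardiac_branch",                                      # T9
  "anterior_vagal_trunk", "esophageal_plexus",           # T10-T11
  "celiac_branch", "celiac_plexus", "splenic_nerve",     # T12-T14
  "hepatic_branch", "hepatic_plexus",                    # T15-T16
  "gastric_branch", "gastric_plexus")                    # T17-T18

site_focused_tissues <- c(
  "epidermis", "dermis", "subcutaneous_tissue",
  "intercostal_muscle", "diaphragm", "spleen_capsule", "spleen",
  "splenic_nerve")

#' Cervical vagus nerve stimulation model
#'
#' The branched model of trans-cutaneous stimulation at the neck: the pulse
#' crosses the three skin layers (epidermis, dermis, subcutaneous tissue),
#' runs down the cervical vagus trunk, splits at the left recurrent
#' laryngeal nerve (LRLN), continues to the thoracic cardiac branch, and at
#' the esophageal plexus splits three ways into the hepatic, anterior
#' gastric and celiac/splenic pathways. Five leaf terminals are measured:
#'
#' * LRLN — `T7:B+`
#' * cardiac plexus — `T9:B+`
#' * hepatic plexus — `T16:B+`
#' * gastric plexus — `T18:B+`
#' * splenic nerve — `T14:B+`
#'
#' @param table A tissue table providing all 18 cervical tissue rows
#'   (see [load_tissue_table()]).
#' @return A `txline_network` with 5 terminals.
#' @export
cervical_vagus_model <- function(table) {
  table <- as_tissue_table(as.data.frame(table))
  missing_rows <- setdiff(cervical_tissues, table$name)
  if (length(missing_rows)) {
    stop("tissue table lacks row(s) required by the cervical model: ",
         paste(missing_rows, collapse = ", "), call. = FALSE)
  }
  e <- function(tissue, from, to) data.frame(tissue = tissue, from = from,
                                             to = to, stringsAsFactors = FALSE)
  edges <- rbind(
    e("epidermis",            "src",   "n1"),
    e("dermis",               "n1",    "n2"),
    e("subcutaneous_tissue",  "n2",    "n3"),
    e("cervical_vagus_trunk", "n3",    "lrln_jct"),
    e("lrln_descending",      "lrln_jct", "n5"),
    e("lrln_loop",            "n5",    "n6"),
    e("lrln_terminal",        "n6",    "lrln"),
    e("thoracic_vagus_trunk", "lrln_jct", "cardiac_jct"),
    e("cardiac_branch",       "cardiac_jct", "cardiac"),
    e("anterior_vagal_trunk", "cardiac_jct", "n10"),
    e("esophageal_plexus",    "n10",   "esoph_jct"),
    e("celiac_branch",        "esoph_jct", "n12"),
    e("celiac_plexus",        "n12",   "n13"),
    e("splenic_nerve",        "n13",   "splenic"),
    e("hepatic_branch",       "esoph_jct", "n15"),
    e("hepatic_plexus",       "n15",   "hepatic"),
    e("gastric_branch",       "esoph_jct", "n17"),
    e("gastric_plexus",       "n17",   "gastric"))
  build_network(table, topology_spec(
    edges, source = "src",
    terminals = c(lrln = "T7:B+", cardiac = "T9:B+", hepatic = "T16:B+",
                  gastric = "T18:B+", splenic = "T14:B+"),
    anatomy = c(lrln = "Left Recurrent Laryngeal Nerve",
                cardiac = "Cardiac Plexus", hepatic = "Hepatic Plexus",
                gastric = "Gastric Plexus", splenic = "Splenic Nerve")))
}

#' Site-focused splenic stimulation model
#'
#' The linear model of stimulation directly over the spleen: skin stack,
#' intercostal muscle, diaphragm, spleen capsule, spleen, splenic nerve —
#' eight segments in series, a single measured terminal `T8:B+`, and no
#' efferent branch for the wave to bifurcate into.
#'
#' @inheritParams cervical_vagus_model
#' @return A `txline_network` with 1 terminal.
#' @export
site_focused_model <- function(table) {
  table <- as_tissue_table(as.data.frame(table))
  missing_rows <- setdiff(site_focused_tissues, table$name)
  if (length(missing_rows)) {
    stop("tissue table lacks row(s) required by the site-focused model: ",
         paste(missing_rows, collapse = ", "), call. = FALSE)
  }
  n <- length(site_focused_tissues)
  nodes <- c("src", paste0("n", seq_len(n - 1L)), "splenic")
  edges <- data.frame(tissue = site_focused_tissues,
                      from = nodes[-length(nodes)], to = nodes[-1L],
                      stringsAsFactors = FALSE)
  build_network(table, topology_spec(
    edges, source = "src", terminals = c(splenic = "T8:B+"),
    anatomy = c(splenic = "Splenic Nerve")))
}
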