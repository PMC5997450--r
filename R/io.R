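# Readers and writers: delimited annotation tables and the bipartite
# connectome graph (GraphML).
#
# Table schema (tab-separated, one directory per specimen):
#   cells.tsv        cell_id, cell_class (haircell|terminal), polarity,
#                    ap_position, sibling_id, age_class, age_source, mature,
#                    enters_neuromast, flag_bouton, flag_cistern
#   traces.tsv       cell_id, section_index, vertex, x, y
#   ribbons.tsv      ribbon_id, haircell_id, terminal_id, apposition_area
#                    (one row per apposed terminal; terminal_id empty for a
#                    ribbon with no apposition recorded yet)
#   associations.tsv haircell_id, terminal_id   (perisynaptic pairs)
#   contacts.tsv     cell_a, cell_b, area       (optional: measured or
#                    generated contact areas, for table-level workflows
#                    without traces)
# Derived fields (terminal kind, polarity preference, ribbon assignment
# weights) are not serialized: they are recomputed by the annotation stage.

required_cols <- list(
  cells = c("cell_id", "cell_class", "polarity", "ap_position", "sibling_id",
            "age_class", "age_source", "mature", "enters_neuromast",
            "flag_bouton", "flag_cistern"),
  traces = c("cell_id", "section_index", "vertex", "x", "y"),
  ribbons = c("ribbon_id", "haircell_id", "terminal_id", "apposition_area"),
  associations = c("haircell_id", "terminal_id"),
  contacts = c("cell_a", "cell_b", "area"))

read_tsv_checked <- function(path, table) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          na.strings = c("NA", ""))
  missing <- setdiff(required_cols[[table]], names(df))
  if (length(missing)) {
    stop(sprintf("table '%s' (%s): missing column(s) %s", table, path,
                 paste(missing, collapse = ", ")))
  }
  df
}

#' Load a connectome from annotation tables
#'
#' Reads the documented TSV schema (cells, traces, ribbons, perisynaptic
#' associations, optional contacts) from a directory, validates referential
#' integrity, and assembles an unannotated [neuromast_connectome()].
#' Derived fields (terminal kind, polarity preference, ribbon assignment
#' weights) are left unset until the annotation and geometry stages run.
#'
#' @param dir Directory containing `cells.tsv`, `traces.tsv`,
#'   `ribbons.tsv`, `associations.tsv`, and optionally `contacts.tsv`.
#' @param specimen_id Specimen label; defaults to the directory name.
#' @param genotype Specimen genotype.
#' @return A [neuromast_connectome()].
#' @export
load_annotation_tables <- function(dir, specimen_id = basename(dir),
                                   genotype = "wild-type") {
  need <- c("cells", "traces", "ribbons", "associations")
  paths <- file.path(dir, paste0(need, ".tsv"))
  ok <- file.exists(paths)
  if (!all(ok)) {
    stop(sprintf("missing table file(s): %s",
                 paste(paths[!ok], collapse = ", ")))
  }
  cells <- read_tsv_checked(paths[1L], "cells")
  traces <- read_tsv_checked(paths[2L], "traces")
  ribbons_raw <- read_tsv_checked(paths[3L], "ribbons")
  assoc <- read_tsv_checked(paths[4L], "associations")
  contacts <- NULL
  cpath <- file.path(dir, "contacts.tsv")
  if (file.exists(cpath)) contacts <- read_tsv_checked(cpath, "contacts")

  bad_class <- !cells$cell_class %in% c("haircell", "terminal")
  if (any(bad_class)) {
    stop(sprintf("cells.tsv row %d: unknown cell_class '%s'",
                 which(bad_class)[1L], cells$cell_class[bad_class][1L]))
  }
  hc_raw <- cells[cells$cell_class == "haircell", , drop = FALSE]
  tm_raw <- cells[cells$cell_class == "terminal", , drop = FALSE]
  haircells <- data.frame(cell_id = as.character(hc_raw$cell_id),
                          polarity = as.character(hc_raw$polarity),
                          ap_position = as.character(hc_raw$ap_position),
                          sibling_id = as.character(hc_raw$sibling_id),
                          age_class = as.character(hc_raw$age_class),
                          age_source = as.character(hc_raw$age_source),
                          mature = as.logical(hc_raw$mature),
                          stringsAsFactors = FALSE)
  terminals <- data.frame(terminal_id = as.character(tm_raw$cell_id),
                          kind = "unclassified",
                          enters_neuromast = as.logical(tm_raw$enters_neuromast),
                          flag_bouton = as.logical(tm_raw$flag_bouton),
                          flag_cistern = as.logical(tm_raw$flag_cistern),
                          polarity_preference = "unassigned",
                          stringsAsFactors = FALSE)

  # referential integrity with row-level error messages
  bad <- !ribbons_raw$haircell_id %in% haircells$cell_id
  if (any(bad)) {
    stop(sprintf("ribbons.tsv: ribbon '%s' references unknown hair cell '%s'",
                 ribbons_raw$ribbon_id[bad][1L],
                 ribbons_raw$haircell_id[bad][1L]))
  }
  has_term <- !is.na(ribbons_raw$terminal_id)
  bad <- has_term & !ribbons_raw$terminal_id %in% terminals$terminal_id
  if (any(bad)) {
    stop(sprintf("ribbons.tsv: ribbon '%s' references unknown terminal '%s'",
                 ribbons_raw$ribbon_id[bad][1L],
                 ribbons_raw$terminal_id[bad][1L]))
  }
  bad <- !assoc$haircell_id %in% haircells$cell_id |
    !assoc$terminal_id %in% terminals$terminal_id
  if (any(bad)) {
    stop(sprintf("associations.tsv row %d: unknown id ('%s', '%s')",
                 which(bad)[1L], assoc$haircell_id[bad][1L],
                 assoc$terminal_id[bad][1L]))
  }
  if (!is.null(contacts)) {
    ids <- c(haircells$cell_id, terminals$terminal_id)
    bad <- !contacts$cell_a %in% ids | !contacts$cell_b %in% ids
    if (any(bad)) {
      stop(sprintf("contacts.tsv row %d: unknown id ('%s', '%s')",
                   which(bad)[1L], contacts$cell_a[bad][1L],
                   contacts$cell_b[bad][1L]))
    }
  }

  ribbons <- unique(data.frame(ribbon_id = as.character(ribbons_raw$ribbon_id),
                               haircell_id = as.character(ribbons_raw$haircell_id),
                               stringsAsFactors = FALSE))
  appo <- ribbons_raw[has_term, , drop = FALSE]
  appositions <- data.frame(ribbon_id = as.character(appo$ribbon_id),
                            terminal_id = as.character(appo$terminal_id),
                            area = as.numeric(appo$apposition_area),
                            stringsAsFactors = FALSE)

  if (nrow(traces)) {
    traces <- data.frame(cell_id = as.character(traces$cell_id),
                         section_index = as.integer(traces$section_index),
                         vertex = as.integer(traces$vertex),
                         x = as.numeric(traces$x), y = as.numeric(traces$y),
                         stringsAsFactors = FALSE)
    key <- paste(traces$cell_id, traces$section_index)
    for (k in unique(key)) {
      sel <- key == k
      poly <- cbind(traces$x[sel], traces$y[sel])[order(traces$vertex[sel]), ,
                                                  drop = FALSE]
      if (nrow(poly) < 3L || !polygon_is_simple(poly)) {
        stop(sprintf("traces.tsv: trace '%s' is not a simple polygon with >= 3 vertices", k))
      }
    }
  }

  conn <- neuromast_connectome(specimen_id = specimen_id, genotype = genotype,
                               haircells = haircells, terminals = terminals,
                               ribbons = ribbons, appositions = appositions,
                               traces = traces, contacts = contacts,
                               perisynaptic = data.frame(
                                 haircell_id = as.character(assoc$haircell_id),
                                 terminal_id = as.character(assoc$terminal_id),
                                 stringsAsFactors = FALSE))
  conn
}

#' Write a connectome back to annotation tables
#'
#' Serializes the connectome to the same TSV schema
#' [load_annotation_tables()] reads, so generator output and loaded data
#' round-trip identically.
#'
#' @param conn A [neuromast_connectome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_connectome_tables <- function(conn, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hc <- conn$haircells
  tm <- conn$terminals
  cells <- rbind(
    data.frame(cell_id = hc$cell_id, cell_class = "haircell",
               polarity = hc$polarity, ap_position = hc$ap_position,
               sibling_id = hc$sibling_id, age_class = hc$age_class,
               age_source = hc$age_source, mature = hc$mature,
               enters_neuromast = NA, flag_bouton = NA, flag_cistern = NA,
               stringsAsFactors = FALSE),
    data.frame(cell_id = tm$terminal_id, cell_class = "terminal",
               polarity = NA, ap_position = NA, sibling_id = NA,
               age_class = NA, age_source = NA, mature = NA,
               enters_neuromast = tm$enters_neuromast,
               flag_bouton = tm$flag_bouton, flag_cistern = tm$flag_cistern,
               stringsAsFactors = FALSE))
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  }
  wt(cells, "cells")
  wt(conn$traces, "traces")
  ap <- conn$appositions
  rib <- merge(conn$ribbons, ap, by = "ribbon_id", all.x = TRUE,
               sort = FALSE)
  ribbons <- data.frame(ribbon_id = rib$ribbon_id,
                        haircell_id = rib$haircell_id,
                        terminal_id = rib$terminal_id,
                        apposition_area = rib$area, stringsAsFactors = FALSE)
  ribbons <- ribbons[order(ribbons$ribbon_id, ribbons$terminal_id), ,
                     drop = FALSE]
  wt(ribbons, "ribbons")
  wt(conn$perisynaptic, "associations")
  if (!is.null(conn$contacts)) wt(conn$contacts, "contacts")
  invisible(dir)
}

#' Export the wiring diagram as a bipartite graph
#'
#' Writes a GraphML bipartite graph with hair cells and terminals as the
#' two vertex classes and one edge per association, typed
#' ribbon / contact / perisynaptic.  Ribbon edges carry the summed synapse
#' weight, contact edges the contact area in nm^2.
#'
#' @param conn An annotated [neuromast_connectome()].
#' @param path Output file path (`.graphml`).
#' @return The igraph object, invisibly.
#' @export
write_connectome_graph <- function(conn, path) {
  if (!is_annotated(conn)) {
    stop("connectome is not annotated; run annotate_connectome() first")
  }
  g <- connectome_graph(conn)
  igraph::write_graph(g, path, format = "graphml")
  invisible(g)
}

#' Build the bipartite association graph of a connectome
#'
#' @inheritParams write_connectome_graph
#' @return An igraph graph with vertex attributes `type` (FALSE = hair
#'   cell, TRUE = terminal), `kind`, `polarity`, and edge attributes
#'   `assoc` and `weight`.
#' @export
connectome_graph <- function(conn) {
  hc <- conn$haircells; tm <- conn$terminals
  verts <- data.frame(
    name = c(hc$cell_id, tm$terminal_id),
    type = c(rep(FALSE, nrow(hc)), rep(TRUE, nrow(tm))),
    kind = c(rep("haircell", nrow(hc)), tm$kind),
    polarity = c(hc$polarity, tm$polarity_preference),
    stringsAsFactors = FALSE)
  edges <- list()
  rt <- conn$assignments
  if (nrow(rt)) {
    cells <- conn$ribbons$haircell_id[match(rt$ribbon_id,
                                            conn$ribbons$ribbon_id)]
    agg <- stats::aggregate(weight ~ cell + term,
                            data = data.frame(cell = cells,
                                              term = rt$terminal_id,
                                              weight = rt$weight),
                            FUN = sum)
    edges$ribbon <- data.frame(from = agg$cell, to = agg$term,
                               assoc = "ribbon", weight = agg$weight,
                               stringsAsFactors = FALSE)
  }
  ct <- contact_table(conn)
  if (nrow(ct)) {
    edges$contact <- data.frame(from = ct$haircell_id, to = ct$terminal_id,
                                assoc = "contact", weight = ct$area,
                                stringsAsFactors = FALSE)
  }
  ps <- conn$perisynaptic
  if (nrow(ps)) {
    edges$peri <- data.frame(from = ps$haircell_id, to = ps$terminal_id,
                             assoc = "perisynaptic", weight = 1,
                             stringsAsFactors = FALSE)
  }
  edf <- if (length(edges)) do.call(rbind, edges) else
    empty_df(c(from = "character", to = "character", assoc = "character",
               weight = "numeric"))
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = verts)
}
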