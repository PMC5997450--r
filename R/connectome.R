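# Domain model for a single neuromast specimen: hair cells, axonal
# terminals, ribbon synapses, membrane contacts, perisynaptic associations.
# All geometry is in nanometres; sections are 0-based indices whose z
# position is section_index * section_thickness (30 nm by default).

#' Construct a neuromast connectome
#'
#' The container every pipeline stage consumes.  All component tables are
#' plain data frames; derived columns (`kind`, `polarity_preference`,
#' ribbon assignments, membrane contacts) may be left unset until the
#' annotation and geometry stages run.
#'
#' @param specimen_id Specimen label, e.g. `"WT1"`.
#' @param genotype One of `"wild-type"`, `"trilobite"`,
#'   `"notch-overexpression"`.
#' @param haircells Data frame with columns `cell_id`, `polarity`
#'   (rostrad-sensitive / caudad-sensitive / undetermined), `ap_position`
#'   (anterior / posterior / unresolved, the cell's position relative to its
#'   sibling after rearrangement), `sibling_id` (`NA` if unpaired),
#'   `age_class` (0-5h / 5-15h / >15h / unknown), `age_source`
#'   (preimaged / classified), `mature` (logical: has a hair bundle).
#' @param terminals Data frame with columns `terminal_id`, `kind`
#'   (afferent / efferent / unclassified), `enters_neuromast` (logical:
#'   branched from the lateral-line nerve and crossed the basal lamina;
#'   annotator-supplied), `flag_bouton`, `flag_cistern` (logical structural
#'   flags: vesicle-filled bouton, postsynaptic cistern),
#'   `polarity_preference` (rostrad / caudad / unassigned; derived).
#' @param ribbons Data frame `ribbon_id`, `haircell_id`: one row per
#'   presynaptic active zone.
#' @param appositions Data frame `ribbon_id`, `terminal_id`, `area`:
#'   annotator-supplied apposition areas (nm^2) of each terminal opposite a
#'   ribbon; the input to partner assignment.
#' @param assignments Data frame `ribbon_id`, `terminal_id`, `weight`:
#'   derived ribbon-partner weights (1, or 0.5/0.5 for equally apposed
#'   pairs).  Empty until [assign_ribbon_partners()] runs.
#' @param traces Data frame `cell_id`, `section_index`, `vertex`, `x`, `y`:
#'   closed membrane contours, vertices ordered along the ring (the closing
#'   edge back to vertex 1 is implicit), coordinates in nm.
#' @param contacts Data frame `cell_a`, `cell_b`, `area` (nm^2), or `NULL`
#'   before the geometry stage (or a contacts table) has supplied them.
#' @param contact_sections Data frame `cell_a`, `cell_b`, `section_index`,
#'   `length` (nm): per-section contact lengths, when computed from traces.
#' @param perisynaptic Data frame `haircell_id`, `terminal_id`: membership
#'   of a terminal in the hair cell's perisynaptic compartment
#'   (annotator- or generator-supplied; not derivable from the traces of
#'   hair cells and terminals alone).
#' @return An object of class `neuromast_connectome`.
#' @seealso [validate_connectome()], [load_annotation_tables()],
#'   [annotate_connectome()]
#' @export
neuromast_connectome <- function(specimen_id,
                                 genotype = "wild-type",
                                 haircells = NULL,
                                 terminals = NULL,
                                 ribbons = NULL,
                                 appositions = NULL,
                                 assignments = NULL,
                                 traces = NULL,
                                 contacts = NULL,
                                 contact_sections = NULL,
                                 perisynaptic = NULL) {
  stopifnot(is.character(specimen_id), length(specimen_id) == 1L)
  genotype <- match.arg(genotype, GENOTYPE_LEVELS)
  conn <- structure(list(
    specimen_id = specimen_id,
    genotype = genotype,
    haircells = haircells %||% empty_haircells(),
    terminals = terminals %||% empty_terminals(),
    ribbons = ribbons %||% empty_df(c(ribbon_id = "character",
                                      haircell_id = "character")),
    appositions = appositions %||% empty_df(c(ribbon_id = "character",
                                              terminal_id = "character",
                                              area = "numeric")),
    assignments = assignments %||% empty_df(c(ribbon_id = "character",
                                              terminal_id = "character",
                                              weight = "numeric")),
    traces = traces %||% empty_df(c(cell_id = "character",
                                    section_index = "integer",
                                    vertex = "integer",
                                    x = "numeric", y = "numeric")),
    contacts = contacts,
    contact_sections = contact_sections,
    perisynaptic = perisynaptic %||% empty_df(c(haircell_id = "character",
                                                terminal_id = "character"))
  ), class = "neuromast_connectome")
  conn
}

empty_haircells <- function() {
  empty_df(c(cell_id = "character", polarity = "character",
             ap_position = "character", sibling_id = "character",
             age_class = "character", age_source = "character",
             mature = "logical"))
}

empty_terminals <- function() {
  empty_df(c(terminal_id = "character", kind = "character",
             enters_neuromast = "logical", flag_bouton = "logical",
             flag_cistern = "logical", polarity_preference = "character"))
}

#' @export
print.neuromast_connectome <- function(x, ...) {
  cat(sprintf("Neuromast connectome '%s' (%s)\n", x$specimen_id, x$genotype))
  cat(sprintf("  hair cells : %d (%d mature)\n",
              nrow(x$haircells), sum(x$haircells$mature)))
  cat(sprintf("  terminals  : %d (%s)\n", nrow(x$terminals),
              paste(sprintf("%d %s", table(factor(x$terminals$kind,
                                                  KIND_LEVELS)),
                            KIND_LEVELS), collapse = ", ")))
  cat(sprintf("  ribbons    : %d (%d assigned)\n", nrow(x$ribbons),
              length(unique(x$assignments$ribbon_id))))
  cat(sprintf("  contacts   : %s\n",
              if (is.null(x$contacts)) "not computed"
              else sprintf("%d pairs, %.3g nm^2 total", nrow(x$contacts),
                           sum(x$contacts$area))))
  cat(sprintf("  perisynaptic pairs: %d\n", nrow(x$perisynaptic)))
  invisible(x)
}

#' @export
summary.neuromast_connectome <- function(object, ...) {
  print(object)
  if (nrow(object$haircells)) {
    cat("  age classes:\n")
    print(table(factor(object$haircells$age_class, AGE_LEVELS)))
  }
  invisible(object)
}

# Has the annotation stage completed?
is_annotated <- function(conn) {
  nrow(conn$terminals) > 0L &&
    all(conn$terminals$kind != "unclassified") &&
    (nrow(conn$ribbons) == 0L ||
       any(nzchar(conn$assignments$ribbon_id)) ||
       isTRUE(attr(conn, "ribbons_assigned")))
}

#' Validate a connectome against the model invariants
#'
#' Violations are data, not exceptions: every broken rule is returned as a
#' row naming the offending entity, so a specimen can be triaged in one
#' pass.  An empty result means all invariants hold.
#'
#' Checked rules: controlled vocabularies; unique ids; referential
#' integrity of ribbons, appositions, assignments, contacts, and
#' perisynaptic pairs; symmetry and irreflexivity of sibling links; ribbon
#' assignment weights in \{1, 0.5\} summing to 1 with at most two assignees;
#' no ribbon assigned to an efferent terminal; non-negative contact areas;
#' and trace rings with at least three vertices that do not self-intersect.
#'
#' @param conn A [neuromast_connectome()].
#' @param check_traces Check polygon simplicity (quadratic in vertex count;
#'   disable for very large trace stacks).
#' @return Data frame with columns `entity`, `rule`, `message`; zero rows
#'   when the connectome is valid.
#' @export
validate_connectome <- function(conn, check_traces = TRUE) {
  v <- list()
  add <- function(entity, rule, msg) {
    v[[length(v) + 1L]] <<- data.frame(entity = entity, rule = rule,
                                       message = msg,
                                       stringsAsFactors = FALSE)
  }
  hc <- conn$haircells
  tm <- conn$terminals

  if (anyDuplicated(hc$cell_id)) {
    add(hc$cell_id[duplicated(hc$cell_id)][1L], "unique_id",
        "duplicated hair-cell id")
  }
  if (anyDuplicated(tm$terminal_id)) {
    add(tm$terminal_id[duplicated(tm$terminal_id)][1L], "unique_id",
        "duplicated terminal id")
  }
  for (i in seq_len(nrow(hc))) {
    if (!hc$polarity[i] %in% POLARITY_LEVELS)
      add(hc$cell_id[i], "vocabulary", sprintf("bad polarity '%s'", hc$polarity[i]))
    if (!hc$ap_position[i] %in% AP_LEVELS)
      add(hc$cell_id[i], "vocabulary", sprintf("bad ap_position '%s'", hc$ap_position[i]))
    if (!hc$age_class[i] %in% AGE_LEVELS)
      add(hc$cell_id[i], "vocabulary", sprintf("bad age_class '%s'", hc$age_class[i]))
  }
  for (i in seq_len(nrow(tm))) {
    if (!tm$kind[i] %in% KIND_LEVELS)
      add(tm$terminal_id[i], "vocabulary", sprintf("bad kind '%s'", tm$kind[i]))
    if (!tm$polarity_preference[i] %in% PREF_LEVELS)
      add(tm$terminal_id[i], "vocabulary",
          sprintf("bad polarity_preference '%s'", tm$polarity_preference[i]))
  }

  # sibling symmetry and irreflexivity
  sib <- stats::setNames(hc$sibling_id, hc$cell_id)
  for (i in seq_len(nrow(hc))) {
    s <- hc$sibling_id[i]
    if (is.na(s)) next
    if (identical(s, hc$cell_id[i])) {
      add(hc$cell_id[i], "sibling_irreflexive", "cell is its own sibling")
    } else if (!s %in% hc$cell_id) {
      add(hc$cell_id[i], "sibling_exists", sprintf("sibling '%s' not found", s))
    } else if (is.na(sib[[s]]) || !identical(sib[[s]], hc$cell_id[i])) {
      add(hc$cell_id[i], "sibling_symmetric",
          sprintf("sibling link to '%s' is not reciprocated", s))
    }
  }

  # ribbons and appositions
  for (i in seq_len(nrow(conn$ribbons))) {
    if (!conn$ribbons$haircell_id[i] %in% hc$cell_id)
      add(conn$ribbons$ribbon_id[i], "ribbon_cell_exists",
          sprintf("hair cell '%s' not found", conn$ribbons$haircell_id[i]))
  }
  for (i in seq_len(nrow(conn$appositions))) {
    if (!conn$appositions$ribbon_id[i] %in% conn$ribbons$ribbon_id)
      add(conn$appositions$ribbon_id[i], "apposition_ribbon_exists",
          "apposition references unknown ribbon")
    if (!conn$appositions$terminal_id[i] %in% tm$terminal_id)
      add(conn$appositions$ribbon_id[i], "apposition_terminal_exists",
          sprintf("terminal '%s' not found", conn$appositions$terminal_id[i]))
  }

  asg <- conn$assignments
  if (nrow(asg)) {
    if (any(!asg$ribbon_id %in% conn$ribbons$ribbon_id)) {
      bad <- asg$ribbon_id[!asg$ribbon_id %in% conn$ribbons$ribbon_id][1L]
      add(bad, "assignment_ribbon_exists", "assignment references unknown ribbon")
    }
    if (any(!asg$terminal_id %in% tm$terminal_id)) {
      bad <- asg$ribbon_id[!asg$terminal_id %in% tm$terminal_id][1L]
      add(bad, "assignment_terminal_exists", "assignment references unknown terminal")
    }
    for (rid in unique(asg$ribbon_id)) {
      w <- asg$weight[asg$ribbon_id == rid]
      if (length(w) > 2L)
        add(rid, "ribbon_max_two_assignees",
            sprintf("%d assignees (max 2)", length(w)))
      if (abs(sum(w) - 1) > 1e-9)
        add(rid, "ribbon_weights_sum_to_one",
            sprintf("weights sum to %g", sum(w)))
      if (!all(w %in% c(1, 0.5)))
        add(rid, "ribbon_weight_values",
            sprintf("weights must be 1 or 0.5, got {%s}",
                    paste(w, collapse = ", ")))
    }
    eff <- tm$terminal_id[tm$kind == "efferent"]
    if (any(asg$terminal_id %in% eff)) {
      bad <- asg$ribbon_id[asg$terminal_id %in% eff][1L]
      add(bad, "no_efferent_ribbons", "ribbon assigned to efferent terminal")
    }
  }

  if (!is.null(conn$contacts)) {
    ids <- c(hc$cell_id, tm$terminal_id)
    for (i in seq_len(nrow(conn$contacts))) {
      if (!conn$contacts$cell_a[i] %in% ids || !conn$contacts$cell_b[i] %in% ids)
        add(paste(conn$contacts$cell_a[i], conn$contacts$cell_b[i], sep = "~"),
            "contact_ids_exist", "contact references unknown cell")
      if (conn$contacts$area[i] < 0)
        add(paste(conn$contacts$cell_a[i], conn$contacts$cell_b[i], sep = "~"),
            "contact_area_nonnegative",
            sprintf("area %g < 0", conn$contacts$area[i]))
    }
  }

  ps <- conn$perisynaptic
  for (i in seq_len(nrow(ps))) {
    if (!ps$haircell_id[i] %in% hc$cell_id)
      add(ps$haircell_id[i], "perisynaptic_cell_exists",
          "perisynaptic pair references unknown hair cell")
    if (!ps$terminal_id[i] %in% tm$terminal_id)
      add(ps$terminal_id[i], "perisynaptic_terminal_exists",
          "perisynaptic pair references unknown terminal")
  }

  tr <- conn$traces
  if (nrow(tr)) {
    if (any(!tr$cell_id %in% c(hc$cell_id, tm$terminal_id))) {
      bad <- unique(tr$cell_id[!tr$cell_id %in% c(hc$cell_id, tm$terminal_id)])[1L]
      add(bad, "trace_cell_exists", "trace references unknown cell")
    }
    key <- paste(tr$cell_id, tr$section_index)
    for (k in unique(key)) {
      sel <- key == k
      poly <- cbind(tr$x[sel], tr$y[sel])[order(tr$vertex[sel]), , drop = FALSE]
      if (nrow(poly) < 3L) {
        add(k, "trace_min_vertices",
            sprintf("%d vertices (need >= 3)", nrow(poly)))
      } else if (check_traces && !polygon_is_simple(poly)) {
        add(k, "trace_simple_polygon", "trace self-intersects")
      }
    }
  }

  if (length(v)) do.call(rbind, v) else
    empty_df(c(entity = "character", rule = "character", message = "character"))
}

# Convenience accessors ------------------------------------------------------

# Trace stack of one cell as a list of vertex matrices keyed by section.
cell_traces <- function(conn, cell_id) {
  tr <- conn$traces[conn$traces$cell_id == cell_id, , drop = FALSE]
  out <- list()
  for (s in unique(tr$section_index)) {
    sel <- tr$section_index == s
    out[[as.character(s)]] <-
      cbind(tr$x[sel], tr$y[sel])[order(tr$vertex[sel]), , drop = FALSE]
  }
  out
}

# Symmetric contact-area lookup between two named cells (0 when absent).
contact_area_between <- function(conn, a, b) {
  ct <- conn$contacts
  if (is.null(ct) || !nrow(ct)) return(0)
  sel <- (ct$cell_a == a & ct$cell_b == b) | (ct$cell_a == b & ct$cell_b == a)
  if (!any(sel)) 0 else sum(ct$area[sel])
}
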