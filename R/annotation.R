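# Circuit annotation: efferent identification, entering-terminal flags,
# ribbon-partner assignment, terminal polarity preference.

#' Annotation configuration
#'
#' @param efferent_requires_flags Require both structural flags
#'   (vesicle-filled bouton and postsynaptic cistern) for a terminal to be
#'   called efferent, in addition to the wiring rule.  Default `TRUE`.
#' @param tie_area_tolerance Relative apposition-area difference at or
#'   below which two terminals are considered to occupy the area opposite a
#'   ribbon equally, each receiving half of it.  Default 0.10; must lie in
#'   [0, 0.5).
#' @return A list of class `annotation_config`.
#' @export
annotation_config <- function(efferent_requires_flags = TRUE,
                              tie_area_tolerance = 0.10) {
  stopifnot(tie_area_tolerance >= 0, tie_area_tolerance < 0.5)
  structure(list(efferent_requires_flags = efferent_requires_flags,
                 tie_area_tolerance = tie_area_tolerance),
            class = "annotation_config")
}

#' Classify terminals as afferent or efferent
#'
#' A terminal is efferent iff it makes direct membrane contact with every
#' mature hair cell, is apposed to zero synaptic ribbons, and (by default)
#' carries both structural flags (vesicle-filled bouton, postsynaptic
#' cistern).  All other terminals are afferent.  At most one efferent is
#' expected per neuromast; more than one raises a warning, not an error.
#' The operation is idempotent.
#'
#' @param conn A [neuromast_connectome()] whose `contacts` have been
#'   computed or supplied.
#' @param config An [annotation_config()].
#' @return The connectome with `terminals$kind` set.
#' @export
classify_terminals <- function(conn, config = annotation_config()) {
  if (is.null(conn$contacts)) {
    stop("contacts have not been computed; run compute_contacts() or load a contacts table")
  }
  mature_cells <- conn$haircells$cell_id[conn$haircells$mature]
  apposed <- unique(conn$appositions$terminal_id)
  kind <- character(nrow(conn$terminals))
  for (i in seq_len(nrow(conn$terminals))) {
    tid <- conn$terminals$terminal_id[i]
    contacts_all <- length(mature_cells) > 0L &&
      all(vapply(mature_cells,
                 function(c) contact_area_between(conn, c, tid) > 0,
                 logical(1L)))
    no_ribbons <- !tid %in% apposed
    flags_ok <- !config$efferent_requires_flags ||
      (isTRUE(conn$terminals$flag_bouton[i]) &&
         isTRUE(conn$terminals$flag_cistern[i]))
    kind[i] <- if (contacts_all && no_ribbons && flags_ok) "efferent" else "afferent"
  }
  n_eff <- sum(kind == "efferent")
  if (n_eff > 1L) {
    warning(sprintf("%d efferent terminals identified in '%s' (expected at most 1)",
                    n_eff, conn$specimen_id))
  }
  conn$terminals$kind <- kind
  conn
}

#' Flag terminals that enter the neuromast
#'
#' A terminal is scored as entering if it branched from the posterior
#' lateral-line nerve and crossed the basal lamina; the crossing is an
#' annotator-supplied boolean in the input tables.  Terminals that do not
#' enter are excluded from all statistics.
#'
#' @param conn A [neuromast_connectome()].
#' @return The connectome, with any missing `enters_neuromast` values set
#'   to `FALSE`.
#' @export
identify_entering_terminals <- function(conn) {
  e <- conn$terminals$enters_neuromast
  e[is.na(e)] <- FALSE
  conn$terminals$enters_neuromast <- e
  conn
}

# Terminal ids that enter the neuromast (the statistical population).
entering_terminals <- function(conn, kind = NULL) {
  tm <- conn$terminals
  sel <- tm$enters_neuromast %in% TRUE
  if (!is.null(kind)) sel <- sel & tm$kind %in% kind
  tm$terminal_id[sel]
}

#' Assign synaptic partners to one ribbon
#'
#' The terminal with the largest apposition area opposite the ribbon is
#' assigned the whole ribbon (weight 1).  When the two largest areas
#' differ by no more than `tie_area_tolerance` (relative to the larger),
#' the area is considered equally occupied and each terminal is assigned
#' half of the ribbon (weights 0.5/0.5).  At most two terminals share a
#' ribbon.
#'
#' @param ribbon_id Ribbon identifier.
#' @param apposed Data frame `terminal_id`, `area` of terminals apposed to
#'   the ribbon.
#' @param config An [annotation_config()].
#' @return Data frame `ribbon_id`, `terminal_id`, `weight` (zero rows when
#'   no terminal is apposed; such ribbons are flagged unpartnered and
#'   counted separately, not dropped).
#' @export
assign_ribbon_partners <- function(ribbon_id, apposed,
                                   config = annotation_config()) {
  if (!nrow(apposed)) {
    return(empty_df(c(ribbon_id = "character", terminal_id = "character",
                      weight = "numeric")))
  }
  ord <- order(-apposed$area, apposed$terminal_id)
  apposed <- apposed[ord, , drop = FALSE]
  if (nrow(apposed) >= 2L) {
    a1 <- apposed$area[1L]; a2 <- apposed$area[2L]
    if (a1 > 0 && (a1 - a2) / a1 <= config$tie_area_tolerance) {
      return(data.frame(ribbon_id = ribbon_id,
                        terminal_id = apposed$terminal_id[1:2],
                        weight = c(0.5, 0.5), stringsAsFactors = FALSE))
    }
  }
  data.frame(ribbon_id = ribbon_id, terminal_id = apposed$terminal_id[1L],
             weight = 1, stringsAsFactors = FALSE)
}

#' Assign partners to every ribbon of a connectome
#'
#' @param conn A [neuromast_connectome()] with `appositions` loaded.
#' @param config An [annotation_config()].
#' @return The connectome with `assignments` filled and an
#'   `unpartnered_ribbons` attribute listing ribbons with no apposed
#'   terminal.
#' @export
assign_all_ribbons <- function(conn, config = annotation_config()) {
  out <- list(); unpartnered <- character(0)
  for (i in seq_len(nrow(conn$ribbons))) {
    rid <- conn$ribbons$ribbon_id[i]
    ap <- conn$appositions[conn$appositions$ribbon_id == rid, , drop = FALSE]
    asg <- assign_ribbon_partners(rid, ap, config)
    if (!nrow(asg)) {
      unpartnered <- c(unpartnered, rid)
      nm_log("info", sprintf("ribbon '%s' has no apposed terminal (unpartnered)", rid))
    } else {
      out[[length(out) + 1L]] <- asg
    }
  }
  conn$assignments <- if (length(out)) do.call(rbind, out) else
    empty_df(c(ribbon_id = "character", terminal_id = "character",
               weight = "numeric"))
  attr(conn, "unpartnered_ribbons") <- unpartnered
  attr(conn, "ribbons_assigned") <- TRUE
  conn
}

# Group label of each hair cell under a grouping scheme.
# "polarity": rostrad/caudad sensitivity; "ap_position": anterior/posterior
# position relative to the sibling (used for genotypes in which bundle
# polarity is uninformative).  NA for cells without a defined group.
haircell_groups <- function(conn, grouping = c("polarity", "ap_position")) {
  grouping <- match.arg(grouping)
  hc <- conn$haircells
  g <- if (grouping == "polarity") {
    ifelse(hc$polarity == "rostrad-sensitive", "rostrad",
           ifelse(hc$polarity == "caudad-sensitive", "caudad", NA_character_))
  } else {
    ifelse(hc$ap_position %in% c("anterior", "posterior"), hc$ap_position,
           NA_character_)
  }
  # nascent cells have neither a definite polarity nor a stable position
  g[hc$age_class == "0-5h"] <- NA_character_
  stats::setNames(g, hc$cell_id)
}

#' Polarity preference of one terminal
#'
#' A terminal making ribbon synapses predominantly with hair cells of one
#' sensitivity is assumed to share that functional polarity.  Preference is
#' the majority group by summed ribbon weight over mature, polarized hair
#' cells; on a tie (or zero ribbons) it falls back to the majority of
#' membrane contact area with polarized cells; a persisting tie leaves the
#' terminal unassigned.  Immature (undetermined-polarity) cells never
#' vote.
#'
#' @param terminal_id Terminal identifier.
#' @param conn A [neuromast_connectome()] with ribbon assignments.
#' @param grouping `"polarity"` (default) or `"ap_position"`.
#' @return `"rostrad"`, `"caudad"` (or `"anterior"`/`"posterior"` under
#'   positional grouping), or `"unassigned"`.
#' @export
terminal_polarity_preference <- function(terminal_id, conn,
                                         grouping = "polarity") {
  groups <- haircell_groups(conn, grouping)
  mature <- stats::setNames(conn$haircells$mature, conn$haircells$cell_id)
  lvls <- if (grouping == "polarity") c("rostrad", "caudad") else
    c("anterior", "posterior")
  votes <- stats::setNames(numeric(length(lvls)), lvls)
  asg <- conn$assignments[conn$assignments$terminal_id == terminal_id, ,
                          drop = FALSE]
  if (nrow(asg)) {
    cells <- stats::setNames(conn$ribbons$haircell_id, conn$ribbons$ribbon_id)
    for (i in seq_len(nrow(asg))) {
      cell <- cells[[asg$ribbon_id[i]]]
      g <- groups[[cell]]
      if (!is.na(g) && isTRUE(mature[[cell]])) {
        votes[g] <- votes[g] + asg$weight[i]
      }
    }
  }
  if (max(votes) > min(votes)) return(names(votes)[which.max(votes)])
  # fall back to contact-area majority with polarized cells
  areas <- stats::setNames(numeric(length(lvls)), lvls)
  for (cell in names(groups)) {
    g <- groups[[cell]]
    if (is.na(g)) next
    areas[g] <- areas[g] + contact_area_between(conn, cell, terminal_id)
  }
  if (max(areas) > min(areas)) return(names(areas)[which.max(areas)])
  "unassigned"
}

#' Run the full annotation stage
#'
#' Entering-terminal flags, terminal classification, ribbon-partner
#' assignment, and polarity preference for every afferent terminal, in
#' order.
#'
#' @param conn A [neuromast_connectome()] with contacts available.
#' @param config An [annotation_config()].
#' @param grouping Grouping scheme for preference derivation (see
#'   [terminal_polarity_preference()]).
#' @return The annotated connectome.
#' @export
annotate_connectome <- function(conn, config = annotation_config(),
                                grouping = "polarity") {
  conn <- identify_entering_terminals(conn)
  conn <- classify_terminals(conn, config)
  conn <- assign_all_ribbons(conn, config)
  pref <- character(nrow(conn$terminals))
  for (i in seq_len(nrow(conn$terminals))) {
    pref[i] <- if (conn$terminals$kind[i] == "efferent") "unassigned" else
      terminal_polarity_preference(conn$terminals$terminal_id[i], conn,
                                   grouping)
  }
  conn$terminals$polarity_preference <- pref
  attr(conn, "preference_grouping") <- grouping
  conn
}
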