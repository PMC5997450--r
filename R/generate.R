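# Synthetic connectomes, contour-trace stacks, and age cohorts with a
# planted ground-truth ledger, emulating the wiring statistics of
# wild-type, trilobite, and Notch-overexpression neuromasts.

#' Genotype model for the connectome generator
#'
#' Wiring parameters of a synthetic neuromast.  Defaults follow the
#' printed statistics of the system: 8-20 hair cells in sibling pairs,
#' about nine afferent branches plus one efferent, a ribbon-specificity
#' error of 4/344, a dominance profile of (0.55, 0.30, 0.10, 0.05) per
#' polarity, and synaptic partners rising from about one in 5-15 h cells
#' to about two in older cells.  Every parameter is overridable; the
#' generator makes no claim to reproduce unprinted distributions.
#'
#' @param genotype `"wild-type"`, `"trilobite"`, or
#'   `"notch-overexpression"`.  Wild type: siblings take opposite
#'   anteroposterior positions and opposite polarities, and wiring
#'   identity follows polarity.  trilobite: each pair is uniquely
#'   allocated the two wiring identities, but at random with respect to
#'   position, and hair bundles orient uniformly on the circle.  Notch
#'   overexpression: both siblings receive the same wiring identity and
#'   all bundles are rostrad-sensitive.
#' @param n_haircell_pairs Sibling pairs per neuromast; `NULL` draws
#'   uniformly from `pair_range`.
#' @param pair_range Range pairs are drawn from (default 5-7, giving
#'   8-20 hair cells including nascent ones).
#' @param n_afferents Afferent branches entering the neuromast (default
#'   9).  The first `2 * length(dominance_weights)` serve the two wiring
#'   identities; any remainder taper without synapsing.
#' @param specificity_error Probability that a ribbon is planted on a
#'   terminal of the opposite wiring identity (default 4/344, the
#'   observed wild-type rate).
#' @param contact_error Fraction of a hair cell's afferent contact area
#'   planted on opposite-identity terminals (default 0.08, matching the
#'   92% polarity-specific contact area of wild type).
#' @param dominance_weights Probability simplex over the same-identity
#'   terminals by which each ribbon picks its partner (default
#'   `c(0.55, 0.30, 0.10, 0.05)`).
#' @param ribbons_per_cell Mean ribbons per mature cell by age class;
#'   counts are drawn as `1 + Poisson(mean - 1)`.  Nascent (0-5 h) cells
#'   get no ribbons.
#' @param age_mix Proportions of the 0-5 h / 5-15 h / >15 h classes.
#' @param n_nonentering Fibers present in the nerve that never cross the
#'   basal lamina (excluded from all statistics).
#' @return A list of class `genotype_model`.
#' @export
genotype_model <- function(genotype = c("wild-type", "trilobite",
                                        "notch-overexpression"),
                           n_haircell_pairs = NULL,
                           pair_range = c(5L, 7L),
                           n_afferents = 9L,
                           specificity_error = 4 / 344,
                           contact_error = 0.08,
                           dominance_weights = c(0.55, 0.30, 0.10, 0.05),
                           ribbons_per_cell = c("5-15h" = 2.5, ">15h" = 5),
                           age_mix = c("0-5h" = 0.20, "5-15h" = 0.35,
                                       ">15h" = 0.45),
                           n_nonentering = 1L) {
  genotype <- match.arg(genotype)
  stopifnot(specificity_error >= 0, specificity_error <= 1,
            contact_error >= 0, contact_error < 1,
            abs(sum(dominance_weights) - 1) < 1e-9,
            all(dominance_weights >= 0),
            abs(sum(age_mix) - 1) < 1e-9)
  n_active <- sum(dominance_weights > 0)
  if (n_afferents < 2L * n_active) {
    stop(sprintf("n_afferents = %d cannot serve %d nonzero dominance entries per identity",
                 n_afferents, n_active))
  }
  structure(list(genotype = genotype, n_haircell_pairs = n_haircell_pairs,
                 pair_range = pair_range, n_afferents = n_afferents,
                 specificity_error = specificity_error,
                 contact_error = contact_error,
                 dominance_weights = dominance_weights,
                 ribbons_per_cell = ribbons_per_cell, age_mix = age_mix,
                 n_nonentering = n_nonentering),
            class = "genotype_model")
}

#' Generate a synthetic neuromast connectome
#'
#' Builds a table-level connectome (cells, terminals, ribbons with
#' apposition areas, membrane-contact areas, perisynaptic pairs) under the
#' genotype's wiring rules, together with a ground-truth ledger recording
#' every planted draw: per-cell wiring identity, per-ribbon identity-match
#' flag, per-terminal planted identity and dominance weight, and planted
#' contact areas.  Identical (model, seed) pairs reproduce the output
#' bit-for-bit.
#'
#' @param model A [genotype_model()].
#' @param seed Integer seed (required; recorded in the ledger).
#' @param specimen_id Specimen label.
#' @return A list with elements `connectome` (an unannotated
#'   [neuromast_connectome()]) and `ledger`.
#' @export
generate_connectome <- function(model = genotype_model(), seed,
                                specimen_id = sprintf("SYN%d", seed)) {
  stopifnot(inherits(model, "genotype_model"), !missing(seed))
  with_seed(seed, generate_connectome_impl(model, seed, specimen_id))
}

generate_connectome_impl <- function(model, seed, specimen_id) {
  idents <- c("caudad", "rostrad")
  n_pairs <- model$n_haircell_pairs %||%
    sample(seq(model$pair_range[1L], model$pair_range[2L]), 1L)

  # --- hair cells in sibling pairs -----------------------------------------
  ages <- sample(names(model$age_mix), n_pairs, replace = TRUE,
                 prob = model$age_mix)
  # a neuromast always carries mature hair cells; keep at least one pair
  if (all(ages == "0-5h")) ages[1L] <- ">15h"
  cells <- list()
  for (p in seq_len(n_pairs)) {
    age <- ages[p]
    nascent <- age == "0-5h"
    a_id <- sprintf("HC%02da", p); p_id <- sprintf("HC%02dp", p)
    pair_idents <- switch(model$genotype,
      # anterior cell is sensitive to caudad motion in wild type
      "wild-type" = c("caudad", "rostrad"),
      "trilobite" = sample(idents),
      "notch-overexpression" = rep(sample(idents, 1L), 2L))
    pol <- switch(model$genotype,
      "wild-type" = paste0(pair_idents, "-sensitive"),
      "trilobite" = c("undetermined", "undetermined"),
      "notch-overexpression" = c("rostrad-sensitive", "rostrad-sensitive"))
    if (nascent) pol <- c("undetermined", "undetermined")
    bundle_angle <- if (model$genotype == "trilobite")
      stats::runif(2, 0, 2 * pi) else c(NA_real_, NA_real_)
    cells[[p]] <- data.frame(
      cell_id = c(a_id, p_id), pair_id = p,
      sibling_id = c(p_id, a_id),
      ap_position = if (nascent) c("unresolved", "unresolved") else
        c("anterior", "posterior"),
      polarity = pol,
      identity = pair_idents,
      age_class = age,
      mature = !nascent,
      bundle_angle = bundle_angle,
      stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, cells)

  # --- terminals ------------------------------------------------------------
  k <- length(model$dominance_weights)
  term <- list()
  for (id in idents) {
    for (r in seq_len(k)) {
      term[[length(term) + 1L]] <- data.frame(
        terminal_id = sprintf("A_%s%d", substr(id, 1L, 1L), r),
        identity = id, role = "afferent", rank = r,
        weight = model$dominance_weights[r], enters = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  n_taper <- model$n_afferents - 2L * k
  for (t in seq_len(max(0L, n_taper))) {
    term[[length(term) + 1L]] <- data.frame(
      terminal_id = sprintf("A_taper%d", t), identity = NA_character_,
      role = "taper", rank = NA_integer_, weight = 0, enters = TRUE,
      stringsAsFactors = FALSE)
  }
  term[[length(term) + 1L]] <- data.frame(
    terminal_id = "EFF1", identity = NA_character_, role = "efferent",
    rank = NA_integer_, weight = 0, enters = TRUE, stringsAsFactors = FALSE)
  for (t in seq_len(model$n_nonentering)) {
    term[[length(term) + 1L]] <- data.frame(
      terminal_id = sprintf("FIB%d", t), identity = NA_character_,
      role = "nonentering", rank = NA_integer_, weight = 0, enters = FALSE,
      stringsAsFactors = FALSE)
  }
  term <- do.call(rbind, term)
  by_ident <- split(term$terminal_id[term$role == "afferent"],
                    term$identity[term$role == "afferent"])

  # --- ribbons --------------------------------------------------------------
  ribbons <- list(); appositions <- list(); rib_ledger <- list()
  rib_n <- 0L
  for (i in seq_len(nrow(cells))) {
    if (!cells$mature[i]) next
    age <- cells$age_class[i]
    lambda <- model$ribbons_per_cell[[age]]
    n_rib <- 1L + stats::rpois(1L, max(0, lambda - 1))
    for (r in seq_len(n_rib)) {
      rib_n <- rib_n + 1L
      rid <- sprintf("R%04d", rib_n)
      mismatch <- stats::runif(1) < model$specificity_error
      target <- if (mismatch) setdiff(idents, cells$identity[i]) else
        cells$identity[i]
      tid <- sample(by_ident[[target]], 1L, prob = model$dominance_weights)
      ribbons[[rib_n]] <- data.frame(ribbon_id = rid,
                                     haircell_id = cells$cell_id[i],
                                     stringsAsFactors = FALSE)
      appositions[[rib_n]] <- data.frame(
        ribbon_id = rid, terminal_id = tid,
        area = round(stats::rlnorm(1, log(4e4), 0.3), 1),
        stringsAsFactors = FALSE)
      rib_ledger[[rib_n]] <- data.frame(
        ribbon_id = rid, haircell_id = cells$cell_id[i], terminal_id = tid,
        target_identity = target, identity_match = !mismatch,
        stringsAsFactors = FALSE)
    }
  }
  ribbons <- if (rib_n) do.call(rbind, ribbons) else
    empty_df(c(ribbon_id = "character", haircell_id = "character"))
  appositions <- if (rib_n) do.call(rbind, appositions) else
    empty_df(c(ribbon_id = "character", terminal_id = "character",
               area = "numeric"))
  rib_ledger <- if (rib_n) do.call(rbind, rib_ledger) else NULL

  # --- membrane contacts ----------------------------------------------------
  # every ribbon partner is contacted; opposite-identity contact area is
  # planted in the proportion contact_error; the efferent contacts every
  # mature cell; Notch siblings contact the full terminal set of their
  # common identity, so each pair shares innervated terminals.
  contacts <- list(); contact_ledger <- list()
  t_weight <- stats::setNames(term$weight, term$terminal_id)
  t_ident <- stats::setNames(term$identity, term$terminal_id)
  add_contact <- function(cell, tid, area, match) {
    contacts[[length(contacts) + 1L]] <<- data.frame(
      cell_a = cell, cell_b = tid, area = round(area, 1),
      stringsAsFactors = FALSE)
    contact_ledger[[length(contact_ledger) + 1L]] <<- data.frame(
      cell_id = cell, terminal_id = tid, area = round(area, 1),
      identity_match = match, stringsAsFactors = FALSE)
  }
  partners_of <- function(cid) {
    if (is.null(rib_ledger)) character(0) else
      unique(rib_ledger$terminal_id[rib_ledger$haircell_id == cid])
  }
  for (i in seq_len(nrow(cells))) {
    cid <- cells$cell_id[i]
    ident <- cells$identity[i]
    if (!cells$mature[i]) {
      # nascent cells touch the dominant terminal of the rostrad identity
      tid <- by_ident[["rostrad"]][1L]
      add_contact(cid, tid, stats::rlnorm(1, log(8e4), 0.3), NA)
      next
    }
    partners <- partners_of(cid)
    if (model$genotype == "notch-overexpression") {
      partners <- union(partners, by_ident[[ident]])
    }
    own_area <- 0; opp_area <- 0
    for (tid in partners) {
      area <- stats::rlnorm(1, log(3e5 * max(t_weight[[tid]], 0.05)), 0.25)
      add_contact(cid, tid, area, t_ident[[tid]] == ident)
      if (identical(t_ident[[tid]], ident)) own_area <- own_area + area
      else opp_area <- opp_area + area
    }
    # top up opposite-identity contact area to the planted fraction of the
    # cell's afferent contact area (mismatched ribbon partners count)
    if (model$contact_error > 0 && own_area > 0) {
      ce <- model$contact_error
      extra <- own_area * ce / (1 - ce) - opp_area
      opp <- setdiff(by_ident[[setdiff(idents, ident)]], partners)
      # stray contacts occupy terminals the sibling does not innervate,
      # preserving the near-perfect exclusivity of sibling wiring
      avoid <- setdiff(opp, partners_of(cells$sibling_id[i]))
      if (length(avoid)) opp <- avoid
      if (extra > 0 && length(opp)) {
        n_opp <- min(length(opp), sample(1:2, 1L))
        opp_ids <- sample(opp, n_opp)
        share <- stats::runif(n_opp); share <- share / sum(share)
        for (j in seq_len(n_opp)) {
          add_contact(cid, opp_ids[j], extra * share[j], FALSE)
        }
      }
    }
    add_contact(cid, "EFF1", stats::rlnorm(1, log(1.5e5), 0.2), NA)
  }
  contacts_df <- do.call(rbind, contacts)
  # collapse duplicates (a partner may already be an error-contact target)
  contacts_df <- stats::aggregate(area ~ cell_a + cell_b, data = contacts_df,
                                  FUN = sum)

  # --- perisynaptic compartment --------------------------------------------
  # both identities occupy each mature cell's compartment
  peri <- list()
  for (i in seq_len(nrow(cells))) {
    cid <- cells$cell_id[i]
    near <- unique(contacts_df$cell_b[contacts_df$cell_a == cid])
    near <- setdiff(near, "EFF1")
    if (cells$mature[i]) {
      for (id in idents) {
        extra <- sample(by_ident[[id]], 1L)
        near <- union(near, extra)
      }
    }
    if (length(near)) {
      peri[[length(peri) + 1L]] <- data.frame(haircell_id = cid,
                                              terminal_id = sort(near),
                                              stringsAsFactors = FALSE)
    }
  }
  peri <- if (length(peri)) do.call(rbind, peri) else NULL

  haircells <- data.frame(cell_id = cells$cell_id, polarity = cells$polarity,
                          ap_position = cells$ap_position,
                          sibling_id = cells$sibling_id,
                          age_class = cells$age_class,
                          age_source = "preimaged", mature = cells$mature,
                          stringsAsFactors = FALSE)
  terminals <- data.frame(terminal_id = term$terminal_id,
                          kind = "unclassified",
                          enters_neuromast = term$enters,
                          flag_bouton = term$role == "efferent",
                          flag_cistern = term$role == "efferent",
                          polarity_preference = "unassigned",
                          stringsAsFactors = FALSE)
  conn <- neuromast_connectome(
    specimen_id = specimen_id, genotype = model$genotype,
    haircells = haircells, terminals = terminals, ribbons = ribbons,
    appositions = appositions, contacts = contacts_df, perisynaptic = peri)

  ledger <- list(seed = seed, genotype = model$genotype, model = model,
                 cells = cells[, c("cell_id", "pair_id", "identity",
                                   "age_class", "ap_position", "mature",
                                   "bundle_angle")],
                 terminals = term,
                 ribbons = rib_ledger,
                 mismatch_count = if (is.null(rib_ledger)) 0L else
                   sum(!rib_ledger$identity_match),
                 contacts = if (length(contact_ledger))
                   do.call(rbind, contact_ledger) else NULL,
                 dominance_weights = model$dominance_weights)
  list(connectome = conn, ledger = ledger)
}

#' Set terminal preferences from a ground-truth ledger
#'
#' Replaces the derived polarity preferences of a generated connectome's
#' terminals with their planted wiring identities.  Used for
#' planted-truth evaluation: a handful of mismatched ribbons cannot by
#' themselves identify which side of the synapse erred, so exact recovery
#' of the planted mismatch tally requires the planted identity as the
#' reference.  Terminals without a planted identity (efferent, tapering,
#' non-entering) are left unassigned.
#'
#' @param conn A generated [neuromast_connectome()] (after annotation).
#' @param ledger The matching ledger from [generate_connectome()].
#' @return The connectome with `polarity_preference` set to the planted
#'   identities.
#' @export
apply_planted_identities <- function(conn, ledger) {
  ident <- stats::setNames(ledger$terminals$identity,
                           ledger$terminals$terminal_id)
  pref <- ident[conn$terminals$terminal_id]
  pref[is.na(pref)] <- "unassigned"
  conn$terminals$polarity_preference <- unname(pref)
  conn
}

#' Generate a serial-section trace fixture with known contact areas
#'
#' Lays out rectangular cell profiles in a row with specified inter-cell
#' gaps, replicated over `n_sections` sections, optionally with occluder
#' traces filling chosen gaps.  The ledger holds closed-form contact areas
#' for each adjacent pair: `facing_area` counts the facing edge only
#' (`height x thickness x n_sections`), `expected_area` additionally
#' counts the boundary beyond the facing corners that still lies within
#' the proximity threshold (`(height + 2 (threshold - gap)) x thickness x
#' n_sections`); both are 0 for occluded pairs and for gaps at or above
#' the threshold.
#'
#' @param n_cells Number of cells in the row.
#' @param gaps Gap(s) in nm between adjacent cells (recycled).
#' @param n_sections Number of identical sections.
#' @param cell_width,cell_height Rectangle dimensions in nm (the facing
#'   edges have length `cell_height`).
#' @param occlude Integer indices of gaps to fill with an occluder trace.
#' @param config A [geometry_config()] (supplies threshold and section
#'   thickness for the ledger's closed forms).
#' @param seed Optional seed (layout is deterministic; kept for metadata).
#' @return A list with `traces` (trace table) and `ledger` (data frame of
#'   pairwise closed-form areas plus parameters).
#' @export
generate_traces <- function(n_cells = 2L, gaps = 50, n_sections = 10L,
                            cell_width = 800, cell_height = 1000,
                            occlude = integer(0),
                            config = geometry_config(), seed = NULL) {
  if (any(gaps < 0)) stop("gaps must be non-negative")
  stopifnot(n_cells >= 2L, n_sections >= 1L)
  gaps <- rep_len(gaps, n_cells - 1L)
  x0 <- cumsum(c(0, rep(cell_width, n_cells - 1L) + gaps))
  rect <- function(x, y, w, h) {
    cbind(x = c(x, x + w, x + w, x), y = c(y, y, y + h, y + h))
  }
  rows <- list()
  add_poly <- function(id, poly, s) {
    rows[[length(rows) + 1L]] <<- data.frame(
      cell_id = id, section_index = s, vertex = seq_len(nrow(poly)),
      x = poly[, 1L], y = poly[, 2L], stringsAsFactors = FALSE)
  }
  for (s in seq_len(n_sections) - 1L) {
    for (i in seq_len(n_cells)) {
      add_poly(sprintf("cell%d", i),
               rect(x0[i], 0, cell_width, cell_height), s)
    }
    for (g in occlude) {
      gp <- gaps[g]
      ow <- gp / 3
      ox <- x0[g] + cell_width + (gp - ow) / 2
      margin <- config$contact_threshold + 10
      add_poly(sprintf("occluder%d", g),
               rect(ox, -margin, ow, cell_height + 2 * margin), s)
    }
  }
  traces <- do.call(rbind, rows)

  th <- config$contact_threshold
  led <- list()
  for (i in seq_len(n_cells - 1L)) {
    gp <- gaps[i]
    blocked <- i %in% occlude
    open <- !blocked && gp < th
    led[[i]] <- data.frame(
      cell_a = sprintf("cell%d", i), cell_b = sprintf("cell%d", i + 1L),
      gap = gp, occluded = blocked,
      facing_area = if (open) cell_height * config$section_thickness * n_sections else 0,
      expected_area = if (open)
        (cell_height + 2 * (th - gp)) * config$section_thickness * n_sections
        else 0,
      stringsAsFactors = FALSE)
  }
  list(traces = traces, ledger = do.call(rbind, led))
}

#' Generate a synthetic age cohort for the classifier
#'
#' Draws class-conditional morphometric features (log-normal cell volumes
#' increasing with age, surface area scaling as volume^(2/3), near-zero
#' ribbon volume for nascent cells, growing apical area) with a
#' configurable class separation.  `separation` scales every
#' class-dependent effect, including the absence of ribbons in nascent
#' cells, so `separation = 0` yields class-blind features and chance-level
#' classification.
#'
#' @param n_cells Cohort size (default 149, with 88 labelled, the regime
#'   the classifier is meant for).
#' @param class_mix Proportions of the three age classes.
#' @param separation Class-separation multiplier (default 1; large values
#'   give linearly separable classes).
#' @param labeled_fraction Fraction of cells carrying an age label.
#' @param seed Integer seed.
#' @return A list: `features` (data frame of the four features), `labels`
#'   (factor, `NA` for unlabelled cells), `true_labels`, `labeled_idx`.
#' @export
generate_age_cohort <- function(n_cells = 149L,
                                class_mix = c(0.20, 0.35, 0.45),
                                separation = 1,
                                labeled_fraction = 88 / 149,
                                seed) {
  stopifnot(!missing(seed), separation >= 0,
            abs(sum(class_mix) - 1) < 1e-9)
  classes <- c("0-5h", "5-15h", ">15h")
  with_seed(seed, {
    k <- sample.int(3L, n_cells, replace = TRUE, prob = class_mix)
    s <- separation
    off <- (k - 1) * 0.45 * s
    volume <- stats::rlnorm(n_cells, log(2e10) + off, 0.35)
    area <- volume^(2 / 3) * 6 * exp(stats::rnorm(n_cells, 0, 0.15))
    # nascent cells lack ribbons only insofar as classes differ at all
    p_zero <- c(0.95, 0.10, 0.02)[k]
    p_zero <- 0.35 + (p_zero - 0.35) * min(s, 1)
    has_rib <- stats::runif(n_cells) >= p_zero
    ribbon <- ifelse(has_rib,
                     stats::rlnorm(n_cells, log(2e7) + (k - 2) * 0.5 * s, 0.4),
                     0)
    apical <- stats::rlnorm(n_cells, log(2e5) + (k - 1) * 0.6 * s, 0.4)
    labels <- factor(classes[k], levels = classes)
    labeled_idx <- sort(sample.int(n_cells, round(labeled_fraction * n_cells)))
    obs <- labels
    obs[-labeled_idx] <- NA
    list(features = data.frame(cell_area = area, cell_volume = volume,
                               ribbon_volume_total = ribbon,
                               apical_contact_area = apical),
         labels = obs, true_labels = labels, labeled_idx = labeled_idx,
         seed = seed)
  })
}
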