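# Connectome summary statistics: polarity specificity, redundancy,
# dominance, sibling exclusivity, shared innervation across positions,
# branch counts, and the two-tailed t test used for group comparisons.

# Shared bookkeeping ---------------------------------------------------------

# Long table of ribbon assignments joined to cell metadata, restricted to
# entering afferent terminals.
ribbon_table <- function(conn) {
  asg <- conn$assignments
  if (!nrow(asg)) {
    return(empty_df(c(ribbon_id = "character", terminal_id = "character",
                      weight = "numeric", haircell_id = "character",
                      age_class = "character", mature = "logical")))
  }
  keep <- entering_terminals(conn, kind = c("afferent", "unclassified"))
  asg <- asg[asg$terminal_id %in% keep, , drop = FALSE]
  cells <- conn$ribbons[match(asg$ribbon_id, conn$ribbons$ribbon_id), ]
  hc <- conn$haircells[match(cells$haircell_id, conn$haircells$cell_id), ]
  data.frame(ribbon_id = asg$ribbon_id, terminal_id = asg$terminal_id,
             weight = asg$weight, haircell_id = cells$haircell_id,
             age_class = hc$age_class, mature = hc$mature,
             stringsAsFactors = FALSE)
}

# Hair-cell x afferent contact table with cell metadata.
contact_table <- function(conn) {
  ct <- conn$contacts
  if (is.null(ct) || !nrow(ct)) {
    return(empty_df(c(haircell_id = "character", terminal_id = "character",
                      area = "numeric", age_class = "character")))
  }
  hc_ids <- conn$haircells$cell_id
  aff <- entering_terminals(conn, kind = c("afferent", "unclassified"))
  a_is_cell <- ct$cell_a %in% hc_ids
  cell <- ifelse(a_is_cell, ct$cell_a, ct$cell_b)
  term <- ifelse(a_is_cell, ct$cell_b, ct$cell_a)
  keep <- cell %in% hc_ids & term %in% aff
  hc <- conn$haircells[match(cell[keep], hc_ids), ]
  data.frame(haircell_id = cell[keep], terminal_id = term[keep],
             area = ct$area[keep], age_class = hc$age_class,
             stringsAsFactors = FALSE)
}

terminal_prefs <- function(conn) {
  stats::setNames(conn$terminals$polarity_preference,
                  conn$terminals$terminal_id)
}

# Specificity ----------------------------------------------------------------

#' Polarity specificity of ribbons, contacts, and perisynaptic pairs
#'
#' An association between a hair cell and an afferent terminal is
#' polarity-appropriate when the terminal's derived preference matches the
#' cell's group.  A ribbon is appropriate iff every assignee matches;
#' half-ribbon assignees contribute their weight to the mismatch tally.
#' Contact-area specificity is the polarity-appropriate fraction of total
#' hair-cell/afferent contact area.  Results are stratified by age class
#' (5-15 h, >15 h); nascent (0-5 h) cells, which have neither a definite
#' polarity nor a stable position, are excluded.
#'
#' Counts are pooled across specimens (micro-average); per-specimen
#' fractions (macro-average) are reported alongside, as are integer
#' active-zone counts in which each ribbon counts once regardless of
#' splitting.
#'
#' @param connectomes A list of annotated [neuromast_connectome()]s (a
#'   single connectome is accepted).
#' @param grouping `"polarity"` (wild-type) or `"ap_position"`
#'   (genotypes scored by rearrangement position).
#' @return A list of class `specificity_report`: `by_age` (per age class
#'   and association type), `pooled` (overall weighted fractions, integer
#'   ribbon counts, contact-area specificity), `per_specimen`.
#' @export
specificity_stats <- function(connectomes, grouping = "polarity") {
  connectomes <- as_connectome_list(connectomes)
  if (!length(connectomes)) stop("empty connectome list")

  per_spec <- list(); acc <- list()
  for (conn in connectomes) {
    pref <- terminal_prefs(conn)
    groups <- haircell_groups(conn, grouping)
    rt <- ribbon_table(conn)
    rt$group <- groups[rt$haircell_id]
    rt <- rt[!is.na(rt$group) & rt$age_class %in% MATURE_AGES, , drop = FALSE]
    rt$match <- pref[rt$terminal_id] == rt$group
    # specimen-scoped ribbon ids so pooled integer counts do not collide
    rt$ribbon_uid <- paste(conn$specimen_id, rt$ribbon_id, sep = ":")

    ct <- contact_table(conn)
    ct$group <- groups[ct$haircell_id]
    ct <- ct[!is.na(ct$group) & ct$age_class %in% MATURE_AGES, , drop = FALSE]
    ct$match <- pref[ct$terminal_id] == ct$group

    ps <- conn$perisynaptic
    hc <- conn$haircells[match(ps$haircell_id, conn$haircells$cell_id), ]
    psd <- data.frame(haircell_id = ps$haircell_id,
                      terminal_id = ps$terminal_id,
                      age_class = hc$age_class, stringsAsFactors = FALSE)
    psd <- psd[psd$terminal_id %in%
                 entering_terminals(conn, c("afferent", "unclassified")), ,
               drop = FALSE]
    psd$group <- groups[psd$haircell_id]
    psd <- psd[!is.na(psd$group) & psd$age_class %in% MATURE_AGES, ,
               drop = FALSE]
    psd$match <- pref[psd$terminal_id] == psd$group

    acc[[conn$specimen_id]] <- list(rt = rt, ct = ct, ps = psd)

    rib_w <- sum(rt$weight)
    per_spec[[conn$specimen_id]] <- data.frame(
      specimen_id = conn$specimen_id,
      ribbon_specificity = if (rib_w > 0)
        sum(rt$weight[rt$match]) / rib_w else NA_real_,
      contact_specificity = if (sum(ct$area) > 0)
        sum(ct$area[ct$match]) / sum(ct$area) else NA_real_,
      perisynaptic_specificity = if (nrow(psd) > 0)
        mean(psd$match) else NA_real_,
      stringsAsFactors = FALSE)
  }

  rt <- do.call(rbind, lapply(acc, `[[`, "rt"))
  ct <- do.call(rbind, lapply(acc, `[[`, "ct"))
  psd <- do.call(rbind, lapply(acc, `[[`, "ps"))

  by_age <- list()
  for (age in MATURE_AGES) {
    r <- rt[rt$age_class == age, , drop = FALSE]
    c2 <- ct[ct$age_class == age, , drop = FALSE]
    p2 <- psd[psd$age_class == age, , drop = FALSE]
    by_age[[age]] <- data.frame(
      age_class = age,
      assoc = c("ribbon", "contact", "perisynaptic"),
      fraction_appropriate = c(
        if (sum(r$weight) > 0) sum(r$weight[r$match]) / sum(r$weight) else NA_real_,
        if (sum(c2$area) > 0) sum(c2$area[c2$match]) / sum(c2$area) else NA_real_,
        if (nrow(p2) > 0) mean(p2$match) else NA_real_),
      stringsAsFactors = FALSE)
  }

  # integer active-zone counts: each ribbon counts once; it is opposite if
  # any assignee mismatches
  rib_ids <- unique(rt$ribbon_uid)
  opp <- vapply(rib_ids,
                function(r) any(!rt$match[rt$ribbon_uid == r]), logical(1L))
  structure(list(
    grouping = grouping,
    by_age = do.call(rbind, by_age),
    pooled = list(
      total_ribbons = length(rib_ids),
      opposite_ribbons = sum(opp),
      ribbon_specificity = if (sum(rt$weight) > 0)
        sum(rt$weight[rt$match]) / sum(rt$weight) else NA_real_,
      mismatch_weight = sum(rt$weight[!rt$match]),
      total_ribbon_weight = sum(rt$weight),
      contact_area_specificity = if (sum(ct$area) > 0)
        sum(ct$area[ct$match]) / sum(ct$area) else NA_real_,
      perisynaptic_specificity = if (nrow(psd) > 0) mean(psd$match) else NA_real_),
    per_specimen = do.call(rbind, per_spec)
  ), class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat(sprintf("Specificity report (grouping: %s)\n", x$grouping))
  cat(sprintf("  ribbons: %d total, %d apposed to opposite-preference terminals\n",
              x$pooled$total_ribbons, x$pooled$opposite_ribbons))
  cat(sprintf("  weighted ribbon specificity : %.3f\n", x$pooled$ribbon_specificity))
  cat(sprintf("  contact-area specificity    : %.3f\n", x$pooled$contact_area_specificity))
  cat(sprintf("  perisynaptic specificity    : %.3f\n", x$pooled$perisynaptic_specificity))
  print(x$by_age, row.names = FALSE)
  invisible(x)
}

# Redundancy -----------------------------------------------------------------

#' Synaptic partners per hair cell, by age class
#'
#' For each hair cell, the number of distinct entering afferent terminals
#' with which it forms ribbon synapses, membrane contacts, or perisynaptic
#' associations (half-ribbon assignees count as partners).  Cells with no
#' associations contribute zero to all three tallies.
#'
#' @param connectomes A list of annotated [neuromast_connectome()]s.
#' @return A list of class `redundancy_report`: `per_cell` (one row per
#'   hair cell) and `by_age` (mean and SEM per age class and association
#'   type).
#' @export
redundancy_stats <- function(connectomes) {
  connectomes <- as_connectome_list(connectomes)
  rows <- list()
  for (conn in connectomes) {
    rt <- ribbon_table(conn)
    ct <- contact_table(conn)
    ps <- conn$perisynaptic
    ps <- ps[ps$terminal_id %in%
               entering_terminals(conn, c("afferent", "unclassified")), ,
             drop = FALSE]
    for (i in seq_len(nrow(conn$haircells))) {
      cid <- conn$haircells$cell_id[i]
      rows[[length(rows) + 1L]] <- data.frame(
        specimen_id = conn$specimen_id, cell_id = cid,
        age_class = conn$haircells$age_class[i],
        ribbon_partners = length(unique(rt$terminal_id[rt$haircell_id == cid])),
        contact_partners = length(unique(ct$terminal_id[ct$haircell_id == cid])),
        perisynaptic_partners = length(unique(ps$terminal_id[ps$haircell_id == cid])),
        stringsAsFactors = FALSE)
    }
  }
  per_cell <- do.call(rbind, rows)
  by_age <- list()
  for (age in c("0-5h", "5-15h", ">15h")) {
    sub <- per_cell[per_cell$age_class == age, , drop = FALSE]
    for (assoc in c("ribbon_partners", "contact_partners",
                    "perisynaptic_partners")) {
      by_age[[paste(age, assoc)]] <- data.frame(
        age_class = age, assoc = sub("_partners", "", assoc),
        mean = if (nrow(sub)) mean(sub[[assoc]]) else NA_real_,
        sem = sem(sub[[assoc]]), n = nrow(sub), stringsAsFactors = FALSE)
    }
  }
  structure(list(per_cell = per_cell, by_age = do.call(rbind, by_age)),
            class = "redundancy_report")
}

#' @export
print.redundancy_report <- function(x, ...) {
  cat("Redundancy report (terminals per hair cell)\n")
  print(x$by_age, row.names = FALSE)
  invisible(x)
}

# Dominance ------------------------------------------------------------------

#' Dominant-terminal statistics
#'
#' Per hair cell, the dominant terminal is the one receiving the greatest
#' summed ribbon weight, with the larger contact area breaking ties
#' (lexicographic rule); its share of the cell's ribbons and contact area
#' is reported by age class.  Per neuromast and hair-cell group, terminals
#' are ranked by their share of the group's ribbon synapses; the 1st/2nd/
#' 3rd ranked shares of polarity-specific ribbons and contacts summarize
#' the dominance hierarchy.
#'
#' Cells with zero assigned ribbons are excluded from per-cell dominance
#' (logged).
#'
#' @param connectomes A list of annotated [neuromast_connectome()]s.
#' @param grouping Hair-cell grouping for the per-neuromast ranking.
#' @return A list of class `dominance_report`: `per_cell`,
#'   `per_cell_by_age` (mean dominant shares by age class), and `ranked`
#'   (per specimen x group ranked shares).
#' @export
dominance_stats <- function(connectomes, grouping = "polarity") {
  connectomes <- as_connectome_list(connectomes)
  cells <- list(); ranked <- list()
  for (conn in connectomes) {
    rt <- ribbon_table(conn)
    ct <- contact_table(conn)
    for (i in seq_len(nrow(conn$haircells))) {
      cid <- conn$haircells$cell_id[i]
      r <- rt[rt$haircell_id == cid, , drop = FALSE]
      if (!nrow(r)) {
        nm_log("debug", sprintf("cell '%s' has no assigned ribbons; excluded from dominance", cid))
        next
      }
      w <- tapply(r$weight, r$terminal_id, sum)
      cc <- ct[ct$haircell_id == cid, , drop = FALSE]
      areas <- stats::setNames(rep(0, length(w)), names(w))
      known <- tapply(cc$area, cc$terminal_id, sum)
      areas[names(known)[names(known) %in% names(areas)]] <-
        known[names(known) %in% names(areas)]
      # lexicographic: max ribbon weight, then max contact area
      ord <- order(-w, -areas, names(w))
      dom <- names(w)[ord][1L]
      cells[[length(cells) + 1L]] <- data.frame(
        specimen_id = conn$specimen_id, cell_id = cid,
        age_class = conn$haircells$age_class[i],
        dominant_terminal = dom,
        ribbon_share = as.numeric(w[dom] / sum(w)),
        contact_share = if (sum(cc$area) > 0)
          sum(cc$area[cc$terminal_id == dom]) / sum(cc$area) else NA_real_,
        stringsAsFactors = FALSE)
    }
    # per-neuromast ranking within each hair-cell group
    groups <- haircell_groups(conn, grouping)
    rt$group <- groups[rt$haircell_id]
    ct$group <- groups[ct$haircell_id]
    for (g in stats::na.omit(unique(groups))) {
      rg <- rt[!is.na(rt$group) & rt$group == g, , drop = FALSE]
      cg <- ct[!is.na(ct$group) & ct$group == g, , drop = FALSE]
      if (!nrow(rg)) next
      w <- tapply(rg$weight, rg$terminal_id, sum)
      shares <- sort(as.numeric(w) / sum(w), decreasing = TRUE)
      careas <- if (nrow(cg)) tapply(cg$area, cg$terminal_id, sum) else numeric(0)
      cshares <- if (length(careas) && sum(careas) > 0)
        sort(as.numeric(careas) / sum(careas), decreasing = TRUE) else numeric(0)
      pad <- function(v, k) c(v, rep(NA_real_, max(0, k - length(v))))[seq_len(k)]
      ranked[[length(ranked) + 1L]] <- data.frame(
        specimen_id = conn$specimen_id, group = g,
        rank = 1:3,
        ribbon_share = pad(shares, 3L),
        contact_share = pad(cshares, 3L),
        stringsAsFactors = FALSE)
    }
  }
  per_cell <- if (length(cells)) do.call(rbind, cells) else NULL
  by_age <- list()
  for (age in c("0-5h", "5-15h", ">15h")) {
    sub <- per_cell[per_cell$age_class == age, , drop = FALSE]
    by_age[[age]] <- data.frame(
      age_class = age,
      mean_ribbon_share = if (nrow(sub)) mean(sub$ribbon_share) else NA_real_,
      sem_ribbon_share = sem(sub$ribbon_share),
      mean_contact_share = if (nrow(sub))
        mean(sub$contact_share, na.rm = TRUE) else NA_real_,
      sem_contact_share = sem(sub$contact_share),
      n = nrow(sub), stringsAsFactors = FALSE)
  }
  structure(list(per_cell = per_cell,
                 per_cell_by_age = do.call(rbind, by_age),
                 ranked = if (length(ranked)) do.call(rbind, ranked) else NULL),
            class = "dominance_report")
}

#' @export
print.dominance_report <- function(x, ...) {
  cat("Dominance report (dominant-terminal shares)\n")
  print(x$per_cell_by_age, row.names = FALSE)
  if (!is.null(x$ranked)) {
    agg <- stats::aggregate(cbind(ribbon_share, contact_share) ~ rank,
                            data = x$ranked, FUN = mean, na.action = stats::na.omit)
    cat("  mean ranked shares per neuromast and group:\n")
    print(agg, row.names = FALSE)
  }
  invisible(x)
}

# Mean ranked shares across specimens/groups (rank 1..3).
ranked_share_means <- function(dom_report) {
  rk <- dom_report$ranked
  out <- numeric(3)
  for (r in 1:3) {
    out[r] <- mean(rk$ribbon_share[rk$rank == r], na.rm = TRUE)
  }
  out
}

# Sibling exclusivity --------------------------------------------------------

#' Sibling exclusivity of ribbon-synapse partners
#'
#' A ribbon is "shared" if any of its assignee terminals also makes a
#' membrane contact with the hair cell's sibling.  Reports weighted and
#' integer shared/total counts plus a per-pair exclusivity flag.  Unpaired
#' cells are skipped with a log entry.
#'
#' @param connectomes A list of annotated [neuromast_connectome()]s.
#' @return A list of class `sibling_report`: `shared_weight`,
#'   `total_weight`, `shared_count`, `total_count`, `per_pair`.
#' @export
sibling_exclusivity <- function(connectomes) {
  connectomes <- as_connectome_list(connectomes)
  pairs <- list(); shared_w <- 0; total_w <- 0
  shared_n <- 0L; total_n <- 0L
  for (conn in connectomes) {
    rt <- ribbon_table(conn)
    hc <- conn$haircells
    seen <- character(0)
    for (i in seq_len(nrow(hc))) {
      cid <- hc$cell_id[i]; sid <- hc$sibling_id[i]
      if (is.na(sid)) {
        nm_log("debug", sprintf("cell '%s' unpaired; skipped in sibling exclusivity", cid))
        next
      }
      key <- paste(sort(c(cid, sid)), collapse = "~")
      if (key %in% seen) next
      seen <- c(seen, key)
      pw <- 0; pt <- 0; pn <- 0L; ptn <- 0L
      for (cell in c(cid, sid)) {
        sib <- if (cell == cid) sid else cid
        r <- rt[rt$haircell_id == cell, , drop = FALSE]
        if (!nrow(r)) next
        for (rid in unique(r$ribbon_id)) {
          rr <- r[r$ribbon_id == rid, , drop = FALSE]
          is_shared <- any(vapply(rr$terminal_id, function(t)
            contact_area_between(conn, sib, t) > 0, logical(1L)))
          w <- sum(rr$weight)
          pt <- pt + w; ptn <- ptn + 1L
          if (is_shared) { pw <- pw + w; pn <- pn + 1L }
        }
      }
      shared_w <- shared_w + pw; total_w <- total_w + pt
      shared_n <- shared_n + pn; total_n <- total_n + ptn
      pairs[[length(pairs) + 1L]] <- data.frame(
        specimen_id = conn$specimen_id, cell_a = cid, cell_b = sid,
        shared_weight = pw, total_weight = pt,
        shared_count = pn, total_count = ptn,
        exclusive = pn == 0L,
        shared_fraction = if (pt > 0) pw / pt else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(shared_weight = shared_w, total_weight = total_w,
                 shared_count = shared_n, total_count = total_n,
                 per_pair = if (length(pairs)) do.call(rbind, pairs) else NULL),
            class = "sibling_report")
}

#' @export
print.sibling_report <- function(x, ...) {
  cat(sprintf("Sibling exclusivity: %d of %d ribbons shared with the sibling's terminals\n",
              x$shared_count, x$total_count))
  if (!is.null(x$per_pair)) {
    cat(sprintf("  exclusive pairs: %d of %d\n",
                sum(x$per_pair$exclusive), nrow(x$per_pair)))
  }
  invisible(x)
}

# Shared innervation across positions ----------------------------------------

#' Fraction of ribbons on terminals innervated by both positions
#'
#' A terminal is "mixed" when it receives ribbon synapses from both
#' anteriorly and posteriorly positioned hair cells.  Returns the fraction
#' of total ribbon weight assigned to mixed terminals, excluding nascent
#' (0-5 h) cells, which can be assigned no stable anteroposterior
#' position.  An integer active-zone version is reported alongside.
#'
#' @param connectomes A list of annotated [neuromast_connectome()]s with
#'   `ap_position` annotated.
#' @return A list of class `mixed_report`: `fraction` (weighted),
#'   `fraction_count` (integer active zones), `mixed_terminals`,
#'   `per_specimen`.
#' @export
mixed_terminal_fraction <- function(connectomes) {
  connectomes <- as_connectome_list(connectomes)
  tot_w <- 0; mix_w <- 0; tot_n <- 0L; mix_n <- 0L
  per_spec <- list(); mixed_terms <- character(0)
  for (conn in connectomes) {
    rt <- ribbon_table(conn)
    pos <- stats::setNames(conn$haircells$ap_position, conn$haircells$cell_id)
    rt$pos <- pos[rt$haircell_id]
    rt <- rt[rt$age_class != "0-5h" & rt$pos %in% c("anterior", "posterior"), ,
             drop = FALSE]
    mixed <- vapply(unique(rt$terminal_id), function(t) {
      p <- unique(rt$pos[rt$terminal_id == t])
      all(c("anterior", "posterior") %in% p)
    }, logical(1L))
    mixed_ids <- unique(rt$terminal_id)[mixed]
    mixed_terms <- union(mixed_terms,
                         paste(conn$specimen_id, mixed_ids, sep = ":"))
    w <- sum(rt$weight)
    mw <- sum(rt$weight[rt$terminal_id %in% mixed_ids])
    rib_ids <- unique(rt$ribbon_id)
    m_rib <- vapply(rib_ids, function(r)
      any(rt$terminal_id[rt$ribbon_id == r] %in% mixed_ids), logical(1L))
    tot_w <- tot_w + w; mix_w <- mix_w + mw
    tot_n <- tot_n + length(rib_ids); mix_n <- mix_n + sum(m_rib)
    per_spec[[conn$specimen_id]] <- data.frame(
      specimen_id = conn$specimen_id,
      fraction = if (w > 0) mw / w else NA_real_,
      stringsAsFactors = FALSE)
  }
  structure(list(fraction = if (tot_w > 0) mix_w / tot_w else NA_real_,
                 fraction_count = if (tot_n > 0) mix_n / tot_n else NA_real_,
                 mixed_terminals = mixed_terms,
                 per_specimen = do.call(rbind, per_spec)),
            class = "mixed_report")
}

#' @export
print.mixed_report <- function(x, ...) {
  cat(sprintf("Mixed-terminal fraction: %.3f of ribbon weight (%.3f of active zones)\n",
              x$fraction, x$fraction_count))
  invisible(x)
}

# Branch counts --------------------------------------------------------------

#' Entering neuronal branches per neuromast
#'
#' Counts afferent plus efferent terminals flagged as entering the
#' neuromast, per specimen, with mean and SEM across specimens.
#'
#' @param connectomes A list of annotated [neuromast_connectome()]s.
#' @return A list of class `branch_report`: `per_specimen`, `mean`, `sem`.
#' @export
branch_count_stats <- function(connectomes) {
  connectomes <- as_connectome_list(connectomes)
  counts <- vapply(connectomes, function(conn)
    length(entering_terminals(conn, kind = c("afferent", "efferent"))),
    integer(1L))
  per <- data.frame(specimen_id = vapply(connectomes, `[[`, "", "specimen_id"),
                    branches = counts, stringsAsFactors = FALSE)
  structure(list(per_specimen = per, mean = mean(counts), sem = sem(counts)),
            class = "branch_report")
}

#' @export
print.branch_report <- function(x, ...) {
  cat(sprintf("Entering branches per neuromast: mean %.2f +- %.2f SEM (n = %d)\n",
              x$mean, if (is.na(x$sem)) 0 else x$sem, nrow(x$per_specimen)))
  invisible(x)
}

# t test ---------------------------------------------------------------------

#' Two-tailed Student's t test with SEMs and star coding
#'
#' Classic pooled-variance two-sample t test (two-tailed); p values are
#' star-coded at 0.05 / 0.01 / 0.001.  When both samples have zero
#' variance and equal means, p is 1 by convention.
#'
#' @param sample_a,sample_b Numeric vectors, each with at least two
#'   values.
#' @return A list of class `two_tailed_t`: `t`, `df`, `p`, `mean_a`,
#'   `mean_b`, `sem_a`, `sem_b`, `stars`.
#' @export
two_tailed_t <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 2L, length(sample_b) >= 2L)
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b)) {
      res <- list(t = 0, df = length(sample_a) + length(sample_b) - 2L, p = 1)
    } else {
      res <- list(t = sign(mean(sample_a) - mean(sample_b)) * Inf,
                  df = length(sample_a) + length(sample_b) - 2L, p = 0)
    }
  } else {
    tt <- stats::t.test(sample_a, sample_b, var.equal = TRUE)
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value)
  }
  structure(c(res, list(mean_a = mean(sample_a), mean_b = mean(sample_b),
                        sem_a = sem(sample_a), sem_b = sem(sample_b),
                        stars = p_stars(res$p))),
            class = "two_tailed_t")
}

#' @export
print.two_tailed_t <- function(x, ...) {
  cat(sprintf("t = %.3f, df = %g, p = %.4g %s\n", x$t, x$df, x$p,
              if (x$stars == "ns") "" else x$stars))
  cat(sprintf("  means: %.4g +- %.3g vs %.4g +- %.3g (SEM)\n",
              x$mean_a, x$sem_a, x$mean_b, x$sem_b))
  invisible(x)
}

as_connectome_list <- function(x) {
  if (inherits(x, "neuromast_connectome")) list(x) else x
}
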