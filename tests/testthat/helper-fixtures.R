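# Fixtures built in code: toy connectomes with hand-computable wiring and
# random polygon pairs for the geometry oracle.

# Random convex polygon around (cx, cy); uses the caller's RNG stream.
convex_poly <- function(cx, cy, r, n = 12L) {
  ang <- sort(stats::runif(n, 0, 2 * pi))
  rad <- r * stats::runif(n, 0.75, 1.25)
  p <- cbind(cx + rad * cos(ang), cy + rad * sin(ang))
  p[grDevices::chull(p), , drop = FALSE]
}

# Two random convex polygons separated by `gap` nm at their closest
# x-extremes, as a trace table.
random_pair_traces <- function(r = 250, gap = NULL) {
  a <- convex_poly(0, 0, r)
  b <- convex_poly(0, 0, r)
  if (is.null(gap)) gap <- stats::runif(1, 5, 40)
  b[, 1L] <- b[, 1L] - min(b[, 1L]) + max(a[, 1L]) + gap
  rbind(
    data.frame(cell_id = "a", section_index = 0L, vertex = seq_len(nrow(a)),
               x = a[, 1L], y = a[, 2L], stringsAsFactors = FALSE),
    data.frame(cell_id = "b", section_index = 0L, vertex = seq_len(nrow(b)),
               x = b[, 1L], y = b[, 2L], stringsAsFactors = FALSE))
}

trace_df <- function(cell_id, poly, section = 0L) {
  data.frame(cell_id = cell_id, section_index = section,
             vertex = seq_len(nrow(poly)), x = poly[, 1L], y = poly[, 2L],
             stringsAsFactors = FALSE)
}

# A hand-wired two-pair neuromast: one >15 h pair (HC1 anterior/caudad,
# HC2 posterior/rostrad), one 5-15 h pair (HC3/HC4), terminals A1 (serves
# HC1, HC3), A2 (serves HC2, HC4), efferent EFF contacting all cells.
toy_connectome <- function() {
  hc <- data.frame(
    cell_id = c("HC1", "HC2", "HC3", "HC4"),
    polarity = c("caudad-sensitive", "rostrad-sensitive",
                 "caudad-sensitive", "rostrad-sensitive"),
    ap_position = c("anterior", "posterior", "anterior", "posterior"),
    sibling_id = c("HC2", "HC1", "HC4", "HC3"),
    age_class = c(">15h", ">15h", "5-15h", "5-15h"),
    age_source = "preimaged", mature = TRUE, stringsAsFactors = FALSE)
  tm <- data.frame(
    terminal_id = c("A1", "A2", "EFF"),
    kind = "unclassified",
    enters_neuromast = TRUE,
    flag_bouton = c(FALSE, FALSE, TRUE),
    flag_cistern = c(FALSE, FALSE, TRUE),
    polarity_preference = "unassigned", stringsAsFactors = FALSE)
  ribbons <- data.frame(
    ribbon_id = c("R1", "R2", "R3", "R4", "R5", "R6"),
    haircell_id = c("HC1", "HC1", "HC1", "HC2", "HC3", "HC4"),
    stringsAsFactors = FALSE)
  appositions <- data.frame(
    ribbon_id = ribbons$ribbon_id,
    terminal_id = c("A1", "A1", "A1", "A2", "A1", "A2"),
    area = c(5e4, 4e4, 6e4, 5e4, 3e4, 3e4), stringsAsFactors = FALSE)
  contacts <- data.frame(
    cell_a = c("HC1", "HC2", "HC3", "HC4", "HC1", "HC2", "HC3", "HC4"),
    cell_b = c("A1", "A2", "A1", "A2", "EFF", "EFF", "EFF", "EFF"),
    area = c(2e5, 2e5, 1e5, 1e5, 5e4, 5e4, 5e4, 5e4),
    stringsAsFactors = FALSE)
  peri <- data.frame(
    haircell_id = c("HC1", "HC1", "HC2", "HC2"),
    terminal_id = c("A1", "A2", "A2", "A1"), stringsAsFactors = FALSE)
  neuromast_connectome("TOY1", "wild-type", haircells = hc, terminals = tm,
                       ribbons = ribbons, appositions = appositions,
                       contacts = contacts, perisynaptic = peri)
}

annotated_toy <- function() annotate_connectome(toy_connectome())

# Minimal connectome with `n_afferent` entering afferents + optional
# efferent, classified by hand; used for branch-count arithmetic.
branch_fixture <- function(n_afferent, n_efferent = 1L,
                           n_nonentering = 0L, id = "B1") {
  n <- n_afferent + n_efferent + n_nonentering
  tm <- data.frame(
    terminal_id = sprintf("T%02d", seq_len(n)),
    kind = c(rep("afferent", n_afferent), rep("efferent", n_efferent),
             rep("afferent", n_nonentering)),
    enters_neuromast = c(rep(TRUE, n_afferent + n_efferent),
                         rep(FALSE, n_nonentering)),
    flag_bouton = FALSE, flag_cistern = FALSE,
    polarity_preference = "unassigned", stringsAsFactors = FALSE)
  neuromast_connectome(id, "wild-type", terminals = tm,
                       contacts = data.frame(cell_a = character(0),
                                             cell_b = character(0),
                                             area = numeric(0)))
}
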