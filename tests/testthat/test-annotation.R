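# Annotation rules: efferent identification, ribbon-partner assignment,
# polarity preference, idempotence.

test_that("the efferent rule requires full coverage, zero ribbons, and flags", {
  conn <- annotate_connectome(toy_connectome())
  kind <- setNames(conn$terminals$kind, conn$terminals$terminal_id)
  expect_equal(unname(kind["EFF"]), "efferent")
  expect_equal(unname(kind[c("A1", "A2")]), c("afferent", "afferent"))

  # give the efferent a ribbon apposition: it becomes afferent
  conn2 <- toy_connectome()
  conn2$appositions <- rbind(conn2$appositions,
                             data.frame(ribbon_id = "R1", terminal_id = "EFF",
                                        area = 1e3, stringsAsFactors = FALSE))
  conn2 <- classify_terminals(identify_entering_terminals(conn2))
  expect_false("efferent" %in% conn2$terminals$kind)

  # remove one of its contacts: coverage broken, so afferent
  conn3 <- toy_connectome()
  conn3$contacts <- conn3$contacts[!(conn3$contacts$cell_a == "HC3" &
                                       conn3$contacts$cell_b == "EFF"), ]
  conn3 <- classify_terminals(identify_entering_terminals(conn3))
  expect_false("efferent" %in% conn3$terminals$kind)

  # without the structural flags the wiring rule alone is insufficient
  conn4 <- toy_connectome()
  conn4$terminals$flag_cistern <- FALSE
  conn4 <- classify_terminals(identify_entering_terminals(conn4))
  expect_false("efferent" %in% conn4$terminals$kind)
  conn5 <- classify_terminals(identify_entering_terminals(toy_connectome()),
                              annotation_config(efferent_requires_flags = FALSE))
  expect_true("efferent" %in% conn5$terminals$kind)
})

test_that("classification requires contacts and is idempotent", {
  conn <- toy_connectome()
  conn$contacts <- NULL
  expect_error(classify_terminals(conn), "contacts")

  once <- annotate_connectome(toy_connectome())
  twice <- annotate_connectome(once)
  expect_equal(twice$terminals, once$terminals)
  expect_equal(twice$assignments, once$assignments)
})

test_that("two efferent candidates raise a warning, not an error", {
  conn <- toy_connectome()
  conn$terminals <- rbind(conn$terminals,
                          data.frame(terminal_id = "EFF2",
                                     kind = "unclassified",
                                     enters_neuromast = TRUE,
                                     flag_bouton = TRUE, flag_cistern = TRUE,
                                     polarity_preference = "unassigned",
                                     stringsAsFactors = FALSE))
  conn$contacts <- rbind(conn$contacts,
                         data.frame(cell_a = c("HC1", "HC2", "HC3", "HC4"),
                                    cell_b = "EFF2", area = 1e4,
                                    stringsAsFactors = FALSE))
  expect_warning(classify_terminals(identify_entering_terminals(conn)),
                 "expected at most 1")
})

test_that("ribbon partners follow the largest-area / equal-split rule", {
  cfg <- annotation_config()
  one <- assign_ribbon_partners("R1",
                                data.frame(terminal_id = "A1", area = 1e5))
  expect_equal(one$weight, 1)

  equal <- assign_ribbon_partners("R1",
                                  data.frame(terminal_id = c("A1", "A2"),
                                             area = c(1e5, 1e5)))
  expect_equal(equal$weight, c(0.5, 0.5))

  near <- data.frame(terminal_id = c("A1", "A2"), area = c(1e5, 9.5e4))
  expect_equal(assign_ribbon_partners("R1", near, cfg)$weight, c(0.5, 0.5))
  tight <- annotation_config(tie_area_tolerance = 0.01)
  res <- assign_ribbon_partners("R1", near, tight)
  expect_equal(res$terminal_id, "A1")
  expect_equal(res$weight, 1)

  # at most two assignees even with three near-equal areas
  three <- data.frame(terminal_id = c("A1", "A2", "A3"),
                      area = c(1e5, 9.9e4, 9.8e4))
  expect_lte(nrow(assign_ribbon_partners("R1", three, cfg)), 2L)

  none <- assign_ribbon_partners("R1", data.frame(terminal_id = character(0),
                                                  area = numeric(0)))
  expect_equal(nrow(none), 0L)
})

test_that("unpartnered ribbons are flagged, not dropped", {
  conn <- toy_connectome()
  conn$ribbons <- rbind(conn$ribbons,
                        data.frame(ribbon_id = "R9", haircell_id = "HC1",
                                   stringsAsFactors = FALSE))
  conn <- assign_all_ribbons(conn)
  expect_equal(attr(conn, "unpartnered_ribbons"), "R9")
  expect_false("R9" %in% conn$assignments$ribbon_id)
  expect_equal(nrow(conn$ribbons), 7L)
})

test_that("terminal preference is the ribbon-weight majority with a contact fallback", {
  conn <- annotate_connectome(toy_connectome())
  pref <- setNames(conn$terminals$polarity_preference,
                   conn$terminals$terminal_id)
  expect_equal(unname(pref["A1"]), "caudad")
  expect_equal(unname(pref["A2"]), "rostrad")
  expect_equal(unname(pref["EFF"]), "unassigned")

  # balanced ribbon weights: contact area 2:1 with caudad cells decides
  conn2 <- toy_connectome()
  # A1 receives one ribbon from a caudad cell (R1) and one from a rostrad
  # cell (R4): a genuine tie on ribbon weight
  conn2$appositions$terminal_id <- c("A1", "A2", "A2", "A1", "A2", "A2")
  conn2$contacts$area[conn2$contacts$cell_a == "HC1" &
                        conn2$contacts$cell_b == "A1"] <- 2e5
  conn2$contacts <- rbind(conn2$contacts,
                          data.frame(cell_a = "HC2", cell_b = "A1", area = 1e5,
                                     stringsAsFactors = FALSE))
  conn2 <- identify_entering_terminals(conn2)
  conn2 <- classify_terminals(conn2)
  conn2 <- assign_all_ribbons(conn2)
  w <- conn2$assignments[conn2$assignments$terminal_id == "A1", ]
  expect_setequal(w$ribbon_id, c("R1", "R4"))
  expect_equal(terminal_polarity_preference("A1", conn2), "caudad")
})

test_that("terminals with no associations stay unassigned", {
  conn <- toy_connectome()
  conn$terminals <- rbind(conn$terminals,
                          data.frame(terminal_id = "A9",
                                     kind = "unclassified",
                                     enters_neuromast = TRUE,
                                     flag_bouton = FALSE, flag_cistern = FALSE,
                                     polarity_preference = "unassigned",
                                     stringsAsFactors = FALSE))
  conn <- annotate_connectome(conn)
  expect_equal(conn$terminals$polarity_preference[
    conn$terminals$terminal_id == "A9"], "unassigned")
})

test_that("immature cells do not vote in preference derivation", {
  conn <- toy_connectome()
  # make HC3/HC4 nascent: their ribbons must stop influencing preference
  conn$haircells$age_class[3:4] <- "0-5h"
  conn$haircells$mature[3:4] <- FALSE
  conn$haircells$polarity[3:4] <- "undetermined"
  conn$haircells$ap_position[3:4] <- "unresolved"
  conn <- annotate_connectome(conn)
  pref <- setNames(conn$terminals$polarity_preference,
                   conn$terminals$terminal_id)
  expect_equal(unname(pref["A1"]), "caudad")
  expect_equal(unname(pref["A2"]), "rostrad")
})

test_that("zero-error wild-type preferences recover the planted identities", {
  model <- genotype_model(specificity_error = 0, contact_error = 0)
  for (seed in 1:25) {
    g <- generate_connectome(model, seed = seed)
    conn <- annotate_connectome(g$connectome)
    led <- g$ledger$terminals
    served <- unique(g$ledger$ribbons$terminal_id)
    for (tid in served) {
      expect_equal(
        conn$terminals$polarity_preference[conn$terminals$terminal_id == tid],
        led$identity[led$terminal_id == tid],
        info = sprintf("seed %d terminal %s", seed, tid))
    }
    # weights sum to one and no efferent carries a ribbon
    expect_equal(nrow(validate_connectome(conn)), 0L)
    expect_equal(sum(conn$terminals$kind == "efferent"), 1L)
  }
})
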