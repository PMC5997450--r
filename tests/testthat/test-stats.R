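# Connectome statistics: specificity, redundancy, dominance, sibling
# exclusivity, shared-position innervation, branch counts, and the t test.

test_that("specificity is perfect on a cleanly wired toy circuit", {
  rep <- specificity_stats(annotated_toy())
  expect_equal(rep$pooled$ribbon_specificity, 1)
  expect_equal(rep$pooled$contact_area_specificity, 1)
  expect_equal(rep$pooled$total_ribbons, 6L)
  expect_equal(rep$pooled$opposite_ribbons, 0L)
  # the toy perisynaptic pairs are half appropriate by construction
  expect_equal(rep$pooled$perisynaptic_specificity, 0.5)
})

test_that("specificity conserves weight between matches and mismatches", {
  for (seed in c(5L, 6L)) {
    g <- generate_connectome(genotype_model(specificity_error = 0.2),
                             seed = seed)
    conn <- apply_planted_identities(annotate_connectome(g$connectome),
                                     g$ledger)
    rep <- specificity_stats(conn)
    match_w <- rep$pooled$ribbon_specificity * rep$pooled$total_ribbon_weight
    expect_equal(match_w + rep$pooled$mismatch_weight,
                 rep$pooled$total_ribbon_weight)
    expect_equal(rep$pooled$mismatch_weight, g$ledger$mismatch_count)
  }
})

test_that("specificity errors on an empty connectome list", {
  expect_error(specificity_stats(list()), "empty")
})

test_that("reports are invariant to specimen relabeling and input order", {
  gens <- lapply(1:3, function(i)
    generate_connectome(genotype_model(), seed = 60 + i,
                        specimen_id = sprintf("S%d", i)))
  conns <- lapply(gens, function(g) annotate_connectome(g$connectome))
  fwd <- specificity_stats(conns)
  rev_conns <- rev(conns)
  rev_conns <- lapply(rev_conns, function(conn) {
    conn$specimen_id <- paste0("X", conn$specimen_id)
    conn
  })
  bwd <- specificity_stats(rev_conns)
  expect_equal(bwd$pooled$ribbon_specificity, fwd$pooled$ribbon_specificity)
  expect_equal(bwd$pooled$contact_area_specificity,
               fwd$pooled$contact_area_specificity)
  expect_equal(bwd$pooled$total_ribbons, fwd$pooled$total_ribbons)
  expect_equal(mixed_terminal_fraction(rev_conns)$fraction,
               mixed_terminal_fraction(conns)$fraction)
})

test_that("redundancy counts distinct partner terminals per cell", {
  rep <- redundancy_stats(annotated_toy())
  pc <- rep$per_cell
  expect_equal(pc$ribbon_partners[pc$cell_id == "HC1"], 1L)
  expect_equal(pc$perisynaptic_partners[pc$cell_id == "HC1"], 2L)
  expect_equal(pc$contact_partners[pc$cell_id == "HC3"], 1L)

  # a cell with no associations scores zero in all three tallies
  conn <- toy_connectome()
  conn$haircells <- rbind(conn$haircells,
                          data.frame(cell_id = "HC9", polarity = "undetermined",
                                     ap_position = "unresolved", sibling_id = NA,
                                     age_class = "0-5h",
                                     age_source = "preimaged", mature = FALSE,
                                     stringsAsFactors = FALSE))
  rep2 <- redundancy_stats(annotate_connectome(conn))
  pc2 <- rep2$per_cell
  expect_equal(unlist(pc2[pc2$cell_id == "HC9",
                          c("ribbon_partners", "contact_partners",
                            "perisynaptic_partners")], use.names = FALSE),
               c(0L, 0L, 0L))
})

test_that("redundancy matches the generator ledger's distinct partners", {
  g <- generate_connectome(genotype_model(), seed = 77)
  conn <- annotate_connectome(g$connectome)
  rep <- redundancy_stats(conn)
  led <- g$ledger$ribbons
  for (cid in unique(led$haircell_id)) {
    expect_equal(
      rep$per_cell$ribbon_partners[rep$per_cell$cell_id == cid],
      length(unique(led$terminal_id[led$haircell_id == cid])),
      info = cid)
  }
})

test_that("per-cell dominance applies the lexicographic rule", {
  conn <- toy_connectome()
  # HC1 ribbons: A1 x3, A2 x1 -> dominant A1, share 0.75
  conn$appositions$terminal_id[conn$appositions$ribbon_id == "R3"] <- "A1"
  conn$ribbons <- rbind(conn$ribbons,
                        data.frame(ribbon_id = "R7", haircell_id = "HC1",
                                   stringsAsFactors = FALSE))
  conn$appositions <- rbind(conn$appositions,
                            data.frame(ribbon_id = "R7", terminal_id = "A2",
                                       area = 1e4, stringsAsFactors = FALSE))
  conn$contacts <- rbind(conn$contacts,
                         data.frame(cell_a = "HC1", cell_b = "A2", area = 1e4,
                                    stringsAsFactors = FALSE))
  rep <- dominance_stats(annotate_connectome(conn))
  hc1 <- rep$per_cell[rep$per_cell$cell_id == "HC1", ]
  expect_equal(hc1$dominant_terminal, "A1")
  expect_equal(hc1$ribbon_share, 0.75)

  # tie on ribbon count: the larger contact area wins
  conn2 <- toy_connectome()
  conn2$appositions$terminal_id <- c("A1", "A1", "A2", "A2", "A1", "A2")
  conn2$ribbons$haircell_id[conn2$ribbons$ribbon_id %in% c("R3", "R4")] <- "HC1"
  conn2$contacts <- rbind(conn2$contacts,
                          data.frame(cell_a = "HC1", cell_b = "A2", area = 5e4,
                                     stringsAsFactors = FALSE))
  rep2 <- dominance_stats(annotate_connectome(conn2))
  hc1b <- rep2$per_cell[rep2$per_cell$cell_id == "HC1", ]
  expect_equal(hc1b$dominant_terminal, "A1")  # 2e5 > 5e4 contact area
})

test_that("adding ribbons to a terminal never lowers its rank", {
  conn <- annotated_toy()
  rep0 <- dominance_stats(conn)
  rk0 <- rep0$ranked[rep0$ranked$group == "caudad", ]
  # add two more A1 ribbons on the caudad side
  conn2 <- toy_connectome()
  extra <- data.frame(ribbon_id = c("R8", "R9"), haircell_id = "HC3",
                      stringsAsFactors = FALSE)
  conn2$ribbons <- rbind(conn2$ribbons, extra)
  conn2$appositions <- rbind(conn2$appositions,
                             data.frame(ribbon_id = c("R8", "R9"),
                                        terminal_id = "A1", area = 1e4,
                                        stringsAsFactors = FALSE))
  rep1 <- dominance_stats(annotate_connectome(conn2))
  rk1 <- rep1$ranked[rep1$ranked$group == "caudad", ]
  expect_gte(rk1$ribbon_share[rk1$rank == 1L], rk0$ribbon_share[rk0$rank == 1L])
})

test_that("cells without ribbons are excluded from per-cell dominance", {
  conn <- toy_connectome()
  conn$haircells <- rbind(conn$haircells,
                          data.frame(cell_id = "HC9", polarity = "undetermined",
                                     ap_position = "unresolved", sibling_id = NA,
                                     age_class = "0-5h",
                                     age_source = "preimaged", mature = FALSE,
                                     stringsAsFactors = FALSE))
  rep <- dominance_stats(annotate_connectome(conn))
  expect_false("HC9" %in% rep$per_cell$cell_id)
})

test_that("sibling exclusivity flags ribbons whose partner touches the sibling", {
  # toy wiring is fully exclusive: A1 never contacts HC2/HC4
  rep <- sibling_exclusivity(annotated_toy())
  expect_equal(rep$shared_count, 0L)
  expect_equal(rep$total_count, 6L)
  expect_true(all(rep$per_pair$exclusive))

  # give A1 a contact with HC2: every HC1 ribbon on A1 becomes shared
  conn <- toy_connectome()
  conn$contacts <- rbind(conn$contacts,
                         data.frame(cell_a = "HC2", cell_b = "A1", area = 1e4,
                                    stringsAsFactors = FALSE))
  rep2 <- sibling_exclusivity(annotate_connectome(conn))
  expect_equal(rep2$shared_count, 3L)
  pair1 <- rep2$per_pair[rep2$per_pair$cell_a == "HC1", ]
  expect_false(pair1$exclusive)
})

test_that("unpaired cells are skipped in sibling statistics", {
  conn <- toy_connectome()
  conn$haircells$sibling_id[3:4] <- NA
  rep <- sibling_exclusivity(annotate_connectome(conn))
  expect_equal(nrow(rep$per_pair), 1L)
  expect_equal(rep$total_count, 4L)  # only the HC1/HC2 pair's ribbons
})

test_that("mixed-terminal fraction is exact on a one-terminal toy", {
  conn <- toy_connectome()
  # both HC1 (anterior) and HC2 (posterior) synapse on A1
  conn$appositions$terminal_id[conn$appositions$ribbon_id == "R4"] <- "A1"
  rep <- mixed_terminal_fraction(annotate_connectome(conn))
  # A1 now carries 5 of 6 ribbons (from both positions) and is mixed;
  # A2 keeps one single-position ribbon
  expect_equal(rep$fraction, 5 / 6)
  # with every ribbon on A1 the fraction is exactly 1
  conn2 <- toy_connectome()
  conn2$appositions$terminal_id <- "A1"
  expect_equal(mixed_terminal_fraction(annotate_connectome(conn2))$fraction, 1)
})

test_that("nascent cells are excluded from the mixed fraction", {
  conn <- toy_connectome()
  conn$appositions$terminal_id[conn$appositions$ribbon_id == "R6"] <- "A1"
  # HC4 rostrad ribbon on A1 makes A1 mixed; ageing HC4 to 0-5 h removes it
  conn$haircells$age_class[4L] <- "0-5h"
  conn$haircells$mature[4L] <- FALSE
  conn$haircells$polarity[4L] <- "undetermined"
  conn$haircells$ap_position[4L] <- "unresolved"
  rep <- mixed_terminal_fraction(annotate_connectome(conn))
  expect_equal(rep$fraction, 0)
})

test_that("branch counts average entering afferent and efferent terminals", {
  one <- branch_count_stats(branch_fixture(9L, 1L))
  expect_equal(one$per_specimen$branches, 10L)

  counts <- c(10L, 9L, 9L, 10L, 9L, 9L, 10L, 8L)
  conns <- lapply(seq_along(counts), function(i)
    branch_fixture(counts[i] - 1L, 1L, id = sprintf("B%d", i)))
  rep <- branch_count_stats(conns)
  expect_equal(rep$mean, 9.25)
  expect_equal(rep$sem, sd(counts) / sqrt(8))

  # a fiber that never crosses the basal lamina is not a branch
  rep2 <- branch_count_stats(branch_fixture(9L, 1L, n_nonentering = 2L))
  expect_equal(rep2$per_specimen$branches, 10L)
})

test_that("the generator's non-entering fibers are excluded end to end", {
  g <- generate_connectome(genotype_model(n_nonentering = 3L), seed = 31)
  conn <- annotate_connectome(g$connectome)
  rep <- branch_count_stats(conn)
  led <- g$ledger$terminals
  expect_equal(rep$per_specimen$branches, sum(led$enters))
})

test_that("the two-tailed t test behaves at its boundary cases", {
  same <- two_tailed_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  shift <- two_tailed_t(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shift$p, 0.001)
  expect_equal(shift$stars, "***")

  flat <- two_tailed_t(c(2, 2, 2), c(2, 2))
  expect_equal(flat$p, 1)

  # agrees with the reference implementation on ordinary data
  set.seed(8)
  a <- rnorm(12); b <- rnorm(10, 0.5)
  mine <- two_tailed_t(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(mine$t, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value)
})
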