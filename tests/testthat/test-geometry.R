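# Contact geometry: closed forms, the strict 60 nm rule, occlusion,
# symmetry, monotonicity, rigid invariance, and oracle agreement.

cfg <- geometry_config()

test_that("parallel facing edges give the closed-form contact area", {
  # facing edges of length 1000 nm at gap 50 nm: the facing edge is in
  # contact, plus the boundary beyond each corner that is still closer
  # than the threshold (threshold - gap on each side)
  tr <- generate_traces(n_cells = 2L, gaps = 50, n_sections = 10L,
                        cell_height = 1000)
  mc <- contact_area("cell1", "cell2", tr$traces, cfg)
  step_area <- cfg$arc_sampling_step * cfg$section_thickness * 10L
  expect_lt(abs(mc$area - tr$ledger$expected_area), step_area)
  expect_equal(tr$ledger$expected_area,
               (1000 + 2 * (60 - 50)) * 30 * 10)
  expect_equal(nrow(mc$per_section), 10L)
})

test_that("contact requires strictly less than the threshold separation", {
  tr60 <- generate_traces(n_cells = 2L, gaps = 60, n_sections = 1L)
  expect_equal(contact_area("cell1", "cell2", tr60$traces, cfg)$area, 0)
  tr70 <- generate_traces(n_cells = 2L, gaps = 70, n_sections = 1L)
  expect_equal(contact_area("cell1", "cell2", tr70$traces, cfg)$area, 0)
  tr59 <- generate_traces(n_cells = 2L, gaps = 59.9, n_sections = 1L)
  expect_gt(contact_area("cell1", "cell2", tr59$traces, cfg)$area, 0)
})

test_that("an intervening trace occludes the contact in both modes", {
  tro <- generate_traces(n_cells = 2L, gaps = 50, n_sections = 2L,
                         occlude = 1L)
  expect_equal(contact_area("cell1", "cell2", tro$traces, cfg)$area, 0)
  corr <- geometry_config(occlusion_mode = "corridor")
  expect_equal(contact_area("cell1", "cell2", tro$traces, corr)$area, 0)
  # the occluder does not block the adjacent unoccluded pair
  tr3 <- generate_traces(n_cells = 3L, gaps = c(50, 50), n_sections = 1L,
                         occlude = 2L)
  expect_gt(contact_area("cell1", "cell2", tr3$traces, cfg)$area, 0)
  expect_equal(contact_area("cell2", "cell3", tr3$traces, cfg)$area, 0)
})

test_that("overlapping traces are rejected as segmentation defects", {
  a <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
  b <- a; b[, 1L] <- b[, 1L] + 50
  expect_error(contact_length_on_section(a, b, list(), cfg),
               "segmentation defect")
})

test_that("cells with no shared section have zero contact area", {
  a <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
  tr <- rbind(trace_df("a", a, section = 0L),
              trace_df("b", a, section = 5L))
  expect_equal(contact_area("a", "b", tr, cfg)$area, 0)
})

test_that("concentric squares match the inner-perimeter closed form", {
  inner <- cbind(c(0, 2000, 2000, 0), c(0, 0, 2000, 2000))
  outer <- cbind(c(-30, 2030, 2030, -30), c(-30, -30, 2030, 2030))
  tr <- rbind(trace_df("in", inner), trace_df("out", outer))
  closed <- 4 * 2000 * 30
  m <- contact_area("in", "out", tr, cfg)$area
  o <- brute_force_contact_area("in", "out", tr, cfg)
  expect_lt(abs(m - closed) / closed, 0.02)
  expect_lt(abs(o - closed) / closed, 0.02)
})

test_that("a zero threshold yields zero contact everywhere", {
  cfg0 <- geometry_config(contact_threshold = 0, arc_sampling_step = 6)
  tr <- generate_traces(n_cells = 2L, gaps = 1, n_sections = 1L)
  expect_equal(brute_force_contact_area("cell1", "cell2", tr$traces, cfg0), 0)
})

test_that("directed lengths agree on parallel-edge fixtures; areas swap-symmetrically", {
  # on matched straight boundaries the two directed measurements differ
  # only by arc-length sampling
  set.seed(41)
  for (i in 1:6) {
    gap <- runif(1, 5, 55)
    h <- round(runif(1, 400, 2000))
    tr <- generate_traces(n_cells = 2L, gaps = gap, n_sections = 1L,
                          cell_height = h)$traces
    a <- cbind(tr$x[tr$cell_id == "cell1"], tr$y[tr$cell_id == "cell1"])
    b <- cbind(tr$x[tr$cell_id == "cell2"], tr$y[tr$cell_id == "cell2"])
    la <- contact_length_on_section(a, b, list(), cfg)
    lb <- contact_length_on_section(b, a, list(), cfg)
    expect_lt(abs(la - lb) / max(la, lb), 0.01)
  }
  # on irregular boundaries the directed measures can genuinely differ;
  # the averaged area is symmetric in its arguments by construction
  for (i in 1:4) {
    tr <- random_pair_traces()
    expect_equal(contact_area("b", "a", tr, cfg)$area,
                 contact_area("a", "b", tr, cfg)$area)
  }
})

test_that("contact area is non-decreasing in the threshold", {
  set.seed(42)
  for (i in 1:5) {
    tr <- random_pair_traces()
    areas <- vapply(c(20, 40, 60, 80), function(th) {
      contact_area("a", "b", tr,
                   geometry_config(contact_threshold = th,
                                   arc_sampling_step = 6))$area
    }, numeric(1L))
    expect_true(all(diff(areas) >= -1e-9))
  }
})

test_that("contact area is invariant under rigid transforms", {
  set.seed(43)
  tr <- random_pair_traces(gap = 25)
  base <- contact_area("a", "b", tr, cfg)$area
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  xy <- as.matrix(tr[, c("x", "y")]) %*% R
  tr2 <- tr
  tr2$x <- xy[, 1L] + 5000; tr2$y <- xy[, 2L] - 1234
  moved <- contact_area("a", "b", tr2, cfg)$area
  expect_lt(abs(base - moved) / base, 0.01)
})

test_that("the fast algorithm agrees with the brute-force oracle", {
  set.seed(44)
  step_area <- cfg$arc_sampling_step * cfg$section_thickness
  for (i in 1:20) {
    tr <- random_pair_traces()
    m <- contact_area("a", "b", tr, cfg)$area
    o <- brute_force_contact_area("a", "b", tr, cfg)
    expect_lt(abs(m - o), max(0.02 * max(m, o), 2 * step_area))
  }
})

test_that("apical contact area follows the perimeter closed form", {
  sq <- cbind(c(0, 500, 500, 0), c(0, 0, 500, 500))  # perimeter 2000 nm
  tr <- do.call(rbind, lapply(0:6, function(s) trace_df("HC1", sq, s)))
  conn <- neuromast_connectome(
    "AP1",
    haircells = data.frame(cell_id = "HC1", polarity = "caudad-sensitive",
                           ap_position = "anterior", sibling_id = NA,
                           age_class = ">15h", age_source = "preimaged",
                           mature = TRUE, stringsAsFactors = FALSE),
    traces = tr)
  cfg_ap <- geometry_config(apical_sections = 0:4)
  expect_equal(apical_contact_area("HC1", conn, cfg_ap), 2000 * 5 * 30)
  cfg_deep <- geometry_config(apical_sections = 20:24)
  expect_equal(apical_contact_area("HC1", conn, cfg_deep), 0)
  expect_error(apical_contact_area("HC1", conn, cfg), "apical_sections")
})

test_that("geometry_config rejects inconsistent parameters", {
  expect_error(geometry_config(arc_sampling_step = 40), "arc_sampling_step")
  expect_error(geometry_config(section_thickness = -1))
  expect_error(generate_traces(gaps = -5), "non-negative")
})
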