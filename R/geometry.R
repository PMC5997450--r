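# Membrane contact geometry on serial-section contour traces.
#
# Two membranes are in contact wherever their traces run closer than a
# proximity threshold (60 nm by default, the tracing precision) AND no
# other trace intervenes between them.  Per-section contact lengths are
# integrated across sections (length x section thickness) to give a
# contact area in nm^2.

#' Geometry configuration
#'
#' @param contact_threshold Proximity threshold in nm below which two
#'   traces are considered in contact (strict inequality).  Default 60 nm,
#'   the precision of manual membrane tracing.
#' @param section_thickness Section thickness in nm (default 30).
#' @param arc_sampling_step Arc-length step in nm at which boundaries are
#'   sampled (default 6 nm, the lateral pixel pitch, so discretization
#'   error matches the source data's resolution).
#' @param occlusion_mode How "no other trace intervened" is tested.
#'   `"strict"`: the straight segment from a sampled boundary point to its
#'   nearest point on the other trace must cross no third-trace boundary.
#'   `"corridor"`: additionally no third trace may enter the quadrilateral
#'   corridor spanned by consecutive matched point pairs.
#' @param apical_sections Integer vector of section indices forming the
#'   organ's apical surface (used by [apical_contact_area()]); `NULL` until
#'   annotated.
#' @return A list of class `geometry_config`.
#' @export
geometry_config <- function(contact_threshold = 60,
                            section_thickness = 30,
                            arc_sampling_step = 6,
                            occlusion_mode = c("strict", "corridor"),
                            apical_sections = NULL) {
  occlusion_mode <- match.arg(occlusion_mode)
  stopifnot(contact_threshold >= 0, section_thickness > 0,
            arc_sampling_step > 0)
  if (contact_threshold > 0 && arc_sampling_step > contact_threshold / 2) {
    stop("arc_sampling_step must be <= contact_threshold / 2")
  }
  structure(list(contact_threshold = contact_threshold,
                 section_thickness = section_thickness,
                 arc_sampling_step = arc_sampling_step,
                 occlusion_mode = occlusion_mode,
                 apical_sections = apical_sections),
            class = "geometry_config")
}

# Polygon primitives ---------------------------------------------------------
# Rings are n x 2 matrices of vertices in order; the closing edge back to
# the first vertex is implicit.

polygon_signed_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Polygon area (shoelace formula)
#' @param poly n x 2 vertex matrix of a closed ring (closing edge implicit).
#' @return Unsigned area.
#' @export
polygon_area <- function(poly) abs(polygon_signed_area(poly))

#' Polygon perimeter
#' @inheritParams polygon_area
#' @return Total boundary length.
#' @export
polygon_perimeter <- function(poly) {
  d <- poly[c(seq_len(nrow(poly))[-1L], 1L), , drop = FALSE] - poly
  sum(sqrt(rowSums(d^2)))
}

# Normalize ring orientation to counter-clockwise.
polygon_ccw <- function(poly) {
  if (polygon_signed_area(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  else poly
}

# Do segments p1-p2 and q1-q2 intersect (including touching)?
segments_intersect <- function(p1, p2, q1, q2, eps = 1e-9) {
  d1 <- cross2(q2 - q1, p1 - q1)
  d2 <- cross2(q2 - q1, p2 - q1)
  d3 <- cross2(p2 - p1, q1 - p1)
  d4 <- cross2(p2 - p1, q2 - p1)
  if (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
      ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))) return(TRUE)
  if (abs(d1) <= eps && on_segment(q1, q2, p1, eps)) return(TRUE)
  if (abs(d2) <= eps && on_segment(q1, q2, p2, eps)) return(TRUE)
  if (abs(d3) <= eps && on_segment(p1, p2, q1, eps)) return(TRUE)
  if (abs(d4) <= eps && on_segment(p1, p2, q2, eps)) return(TRUE)
  FALSE
}

cross2 <- function(u, v) u[1L] * v[2L] - u[2L] * v[1L]

on_segment <- function(a, b, p, eps = 1e-9) {
  p[1L] >= min(a[1L], b[1L]) - eps && p[1L] <= max(a[1L], b[1L]) + eps &&
    p[2L] >= min(a[2L], b[2L]) - eps && p[2L] <= max(a[2L], b[2L]) + eps
}

polygon_edges <- function(poly) {
  n <- nrow(poly)
  list(a = poly, b = poly[c(seq_len(n)[-1L], 1L), , drop = FALSE])
}

#' Is a ring a simple (non-self-intersecting) polygon?
#' @inheritParams polygon_area
#' @return Logical.
#' @export
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(FALSE)
  e <- polygon_edges(poly)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (shared endpoint) incl. the wrap-around pair
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_intersect(e$a[i, ], e$b[i, ], e$a[j, ], e$b[j, ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Even-odd point-in-polygon test
#' @param pt Length-2 numeric.
#' @inheritParams polygon_area
#' @return Logical; boundary points count as inside.
#' @export
point_in_polygon <- function(pt, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    # boundary counts as inside
    if (point_seg_dist_one(pt, c(xi, yi), c(xj, yj)) < 1e-9) return(TRUE)
    if ((yi > pt[2L]) != (yj > pt[2L]) &&
        pt[1L] < (xj - xi) * (pt[2L] - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

point_seg_dist_one <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  q <- a + t * ab
  sqrt(sum((p - q)^2))
}

# Nearest points on a polygon boundary for many query points at once.
# pts: m x 2; returns list(dist = m-vector, nearest = m x 2 matrix).
nearest_on_boundary <- function(pts, poly) {
  e <- polygon_edges(poly)
  ax <- e$a[, 1L]; ay <- e$a[, 2L]
  bx <- e$b[, 1L]; by <- e$b[, 2L]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  len2[len2 == 0] <- 1e-300
  m <- nrow(pts)
  dist <- numeric(m)
  nearest <- matrix(0, m, 2L)
  for (i in seq_len(m)) {
    px <- pts[i, 1L]; py <- pts[i, 2L]
    t <- ((px - ax) * dx + (py - ay) * dy) / len2
    t <- pmin(1, pmax(0, t))
    qx <- ax + t * dx; qy <- ay + t * dy
    d2 <- (px - qx)^2 + (py - qy)^2
    k <- which.min(d2)
    dist[i] <- sqrt(d2[k])
    nearest[i, ] <- c(qx[k], qy[k])
  }
  list(dist = dist, nearest = nearest)
}

# Sample points along a ring's boundary at arc-length midpoints of steps of
# size `step`: each sample represents `step` nm of boundary.
sample_boundary <- function(poly, step) {
  per <- polygon_perimeter(poly)
  n <- max(1L, floor(per / step))
  s <- (seq_len(n) - 0.5) * (per / n)
  points_at_arclength(poly, s)
}

points_at_arclength <- function(poly, s) {
  e <- polygon_edges(poly)
  seg_len <- sqrt(rowSums((e$b - e$a)^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  s <- s %% total
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx > nrow(poly)] <- nrow(poly)
  frac <- (s - cum[idx]) / pmax(seg_len[idx], 1e-300)
  e$a[idx, , drop = FALSE] + frac * (e$b[idx, , drop = FALSE] - e$a[idx, , drop = FALSE])
}

# Does segment p-q cross any edge of any polygon in `others`?  Endpoints of
# the query segment lie on traces a and b, so intersections are sought
# strictly between them by shrinking the segment slightly.
segment_blocked <- function(p, q, others, shrink = 1e-6) {
  if (!length(others)) return(FALSE)
  v <- q - p
  p2 <- p + shrink * v
  q2 <- q - shrink * v
  for (poly in others) {
    e <- polygon_edges(poly)
    for (k in seq_len(nrow(poly))) {
      if (segments_intersect(p2, q2, e$a[k, ], e$b[k, ])) return(TRUE)
    }
  }
  FALSE
}

# Corridor occlusion: does any third-trace vertex or edge enter the
# quadrilateral hull spanned by consecutive matched pairs (p_i, q_i),
# (p_j, q_j)?
quad_blocked <- function(p1, q1, p2, q2, others) {
  hull <- rbind(p1, p2, q2, q1)
  hull <- hull[grDevices::chull(hull), , drop = FALSE]
  if (nrow(hull) < 3L) return(FALSE)
  e <- polygon_edges(hull)
  for (poly in others) {
    for (k in seq_len(nrow(poly))) {
      if (point_in_polygon(poly[k, ], hull)) return(TRUE)
    }
    pe <- polygon_edges(poly)
    for (k in seq_len(nrow(poly))) {
      for (m in seq_len(nrow(hull))) {
        if (segments_intersect(pe$a[k, ], pe$b[k, ], e$a[m, ], e$b[m, ])) {
          return(TRUE)
        }
      }
    }
  }
  FALSE
}

# Do the boundaries of two rings intersect (a segmentation defect)?
polygons_overlap <- function(a, b) {
  ea <- polygon_edges(a); eb <- polygon_edges(b)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (segments_intersect(ea$a[i, ], ea$b[i, ], eb$a[j, ], eb$b[j, ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Contact operations ---------------------------------------------------------

#' Directed contact length between two traces on one section
#'
#' Total arc length of `trace_a`'s boundary lying closer than the contact
#' threshold (strict inequality) to `trace_b`'s boundary, with no other
#' trace intervening between the matched points.  The boundary of
#' `trace_a` is sampled at the configured arc step; each accepted sample
#' contributes one step of length.
#'
#' @param trace_a,trace_b n x 2 vertex matrices (closed rings, nm).
#' @param other_traces List of vertex matrices of all other traces on the
#'   same section (candidate occluders); must exclude a and b.
#' @param config A [geometry_config()].
#' @return Directed contact length in nm (from a's perspective).  Zero when
#'   the traces are everywhere farther apart than the threshold.
#' @export
contact_length_on_section <- function(trace_a, trace_b, other_traces = list(),
                                      config = geometry_config()) {
  stopifnot(nrow(trace_a) >= 3L, nrow(trace_b) >= 3L)
  if (polygons_overlap(trace_a, trace_b)) {
    stop("traces intersect: segmentation defect between the two cells")
  }
  # cheap reject: bounding boxes farther apart than the threshold
  if (bbox_gap(trace_a, trace_b) >= config$contact_threshold) return(0)
  step <- config$arc_sampling_step
  pts <- sample_boundary(trace_a, step)
  per <- polygon_perimeter(trace_a)
  n <- nrow(pts)
  step_eff <- per / n
  nb <- nearest_on_boundary(pts, trace_b)
  ok <- nb$dist < config$contact_threshold
  if (!any(ok)) return(0)
  if (length(other_traces)) {
    idx <- which(ok)
    for (i in idx) {
      if (segment_blocked(pts[i, ], nb$nearest[i, ], other_traces)) {
        ok[i] <- FALSE
      }
    }
    if (config$occlusion_mode == "corridor" && any(ok)) {
      idx <- which(ok)
      keep <- ok
      for (i in idx) {
        j <- if (i == n) 1L else i + 1L
        if (ok[j] &&
            quad_blocked(pts[i, ], nb$nearest[i, ], pts[j, ], nb$nearest[j, ],
                         other_traces)) {
          keep[i] <- FALSE
          keep[j] <- FALSE
        }
      }
      ok <- keep
    }
  }
  if (!any(ok)) return(0)
  # corridor acceptance is defined pairwise on coarse samples; report the
  # coarse measure in that mode
  if (config$occlusion_mode == "corridor") return(sum(ok) * step_eff)
  # Coarse measure: one step of arc per accepted sample.  Samples adjacent
  # to an acceptance flip are re-measured at 1 nm so the contact-boundary
  # localization error does not accumulate into the arc-length estimate.
  prev <- c(ok[n], ok[-n]); nxt <- c(ok[-1L], ok[1L])
  interior <- ok & prev & nxt
  edge <- (ok != prev) | (ok != nxt)
  total <- sum(interior & !edge) * step_eff
  point_ok <- function(p) {
    r <- nearest_on_boundary(matrix(p, 1L), trace_b)
    r$dist < config$contact_threshold &&
      !(length(other_traces) &&
          segment_blocked(p, r$nearest[1L, ], other_traces))
  }
  for (i in which(edge)) {
    s0 <- (i - 1L) * step_eff
    nf <- max(2L, ceiling(step_eff))
    sf <- s0 + (seq_len(nf) - 0.5) * (step_eff / nf)
    pf <- points_at_arclength(trace_a, sf)
    accf <- vapply(seq_len(nf), function(j) point_ok(pf[j, ]), logical(1L))
    total <- total + sum(accf) * (step_eff / nf)
  }
  total
}

bbox_gap <- function(a, b) {
  dx <- max(0, max(min(b[, 1L]) - max(a[, 1L]), min(a[, 1L]) - max(b[, 1L])))
  dy <- max(0, max(min(b[, 2L]) - max(a[, 2L]), min(a[, 2L]) - max(b[, 2L])))
  sqrt(dx^2 + dy^2)
}

#' Membrane contact area between two cells
#'
#' Integrates per-section contact lengths over the sections both cells
#' occupy: `area = sum(length x section_thickness)`.  The directed lengths
#' measured from each cell's boundary are averaged per section so the
#' result is symmetric in the two cells.
#'
#' @param cell_a,cell_b Cell identifiers.
#' @param traces Trace table (`cell_id`, `section_index`, `vertex`, `x`,
#'   `y`) covering all cells on the relevant sections, or a
#'   [neuromast_connectome()].
#' @param config A [geometry_config()].
#' @return A list of class `membrane_contact`: `cell_a`, `cell_b`, `area`
#'   (nm^2) and `per_section` (data frame `section_index`, `length`).
#' @export
contact_area <- function(cell_a, cell_b, traces, config = geometry_config()) {
  tr <- if (inherits(traces, "neuromast_connectome")) traces$traces else traces
  secs <- section_polygons(tr)
  per_section <- list()
  for (s in names(secs)) {
    polys <- secs[[s]]
    if (!cell_a %in% names(polys) || !cell_b %in% names(polys)) next
    others <- polys[setdiff(names(polys), c(cell_a, cell_b))]
    la <- contact_length_on_section(polys[[cell_a]], polys[[cell_b]],
                                    others, config)
    lb <- contact_length_on_section(polys[[cell_b]], polys[[cell_a]],
                                    others, config)
    per_section[[s]] <- data.frame(section_index = as.integer(s),
                                   length = (la + lb) / 2)
  }
  per_section <- if (length(per_section)) do.call(rbind, per_section) else
    empty_df(c(section_index = "integer", length = "numeric"))
  structure(list(cell_a = cell_a, cell_b = cell_b,
                 area = sum(per_section$length) * config$section_thickness,
                 per_section = per_section),
            class = "membrane_contact")
}

# Split a trace table into per-section named lists of vertex matrices.
section_polygons <- function(tr) {
  out <- list()
  for (s in unique(tr$section_index)) {
    sel <- tr$section_index == s
    sub <- tr[sel, , drop = FALSE]
    polys <- list()
    for (cid in unique(sub$cell_id)) {
      ss <- sub[sub$cell_id == cid, , drop = FALSE]
      polys[[cid]] <- cbind(ss$x, ss$y)[order(ss$vertex), , drop = FALSE]
    }
    out[[as.character(s)]] <- polys
  }
  out
}

#' Brute-force contact area (test oracle)
#'
#' Same contract as [contact_area()] but implemented by dense point
#' sampling of both boundaries (step at most 1 nm) with nearest-point
#' distances and exhaustive per-point occlusion checks.  Quadratic per
#' section; intended for verification on small fixtures, not production
#' use.
#'
#' @inheritParams contact_area
#' @param step Dense sampling step in nm (must be at most 1).
#' @return Contact area in nm^2.
#' @export
brute_force_contact_area <- function(cell_a, cell_b, traces,
                                     config = geometry_config(), step = 1) {
  stopifnot(step <= 1)
  tr <- if (inherits(traces, "neuromast_connectome")) traces$traces else traces
  secs <- section_polygons(tr)
  total <- 0
  for (s in names(secs)) {
    polys <- secs[[s]]
    if (!cell_a %in% names(polys) || !cell_b %in% names(polys)) next
    others <- polys[setdiff(names(polys), c(cell_a, cell_b))]
    la <- brute_directed_length(polys[[cell_a]], polys[[cell_b]], others,
                                config, step)
    lb <- brute_directed_length(polys[[cell_b]], polys[[cell_a]], others,
                                config, step)
    total <- total + (la + lb) / 2 * config$section_thickness
  }
  total
}

brute_directed_length <- function(a, b, others, config, step) {
  if (config$contact_threshold <= 0) return(0)
  pa <- dense_boundary(a, step)
  pb <- dense_boundary(b, step)
  # nearest dense point on b for every dense point on a
  d2 <- outer(pa[, 1L], pb[, 1L], "-")^2 + outer(pa[, 2L], pb[, 2L], "-")^2
  k <- max.col(-d2, ties.method = "first")
  dmin <- sqrt(d2[cbind(seq_len(nrow(pa)), k)])
  ok <- dmin < config$contact_threshold
  if (any(ok) && length(others)) {
    for (i in which(ok)) {
      if (segment_blocked(pa[i, ], pb[k[i], ], others)) ok[i] <- FALSE
    }
  }
  per <- polygon_perimeter(a)
  sum(ok) * (per / nrow(pa))
}

dense_boundary <- function(poly, step) {
  per <- polygon_perimeter(poly)
  n <- max(3L, ceiling(per / step))
  s <- (seq_len(n) - 0.5) * (per / n)
  points_at_arclength(poly, s)
}

#' Apical contact area of a cell
#'
#' Membrane area a cell exposes at the organ's apical surface: the cell's
#' trace perimeter times section thickness, summed over the annotated
#' apical sections.  Used as a hair-cell maturity feature (nascent cells
#' have not yet expanded an apical surface).
#'
#' @param cell_id Cell identifier.
#' @param conn A [neuromast_connectome()] (or bare trace table).
#' @param config A [geometry_config()] whose `apical_sections` names the
#'   apical section indices.
#' @return Area in nm^2; 0 (with a log note) when the cell does not reach
#'   the apical sections.
#' @export
apical_contact_area <- function(cell_id, conn, config = geometry_config()) {
  if (is.null(config$apical_sections)) {
    stop("geometry_config$apical_sections is not set")
  }
  tr <- if (inherits(conn, "neuromast_connectome")) conn$traces else conn
  tr <- tr[tr$cell_id == cell_id &
             tr$section_index %in% config$apical_sections, , drop = FALSE]
  if (!nrow(tr)) {
    nm_log("info", sprintf("cell '%s' absent from apical sections", cell_id))
    return(0)
  }
  total <- 0
  for (s in unique(tr$section_index)) {
    sel <- tr$section_index == s
    poly <- cbind(tr$x[sel], tr$y[sel])[order(tr$vertex[sel]), , drop = FALSE]
    total <- total + polygon_perimeter(poly) * config$section_thickness
  }
  total
}

#' Compute all hair-cell/terminal contacts of a connectome
#'
#' Runs [contact_area()] for every hair-cell x terminal pair (and
#' optionally all cell pairs) that share at least one section, and stores
#' the results on the connectome.
#'
#' @param conn A [neuromast_connectome()] with traces.
#' @param config A [geometry_config()].
#' @param pairs `"haircell-terminal"` (default) or `"all"`.
#' @return The connectome with `contacts` and `contact_sections` filled.
#' @export
compute_contacts <- function(conn, config = geometry_config(),
                             pairs = c("haircell-terminal", "all")) {
  pairs <- match.arg(pairs)
  if (!nrow(conn$traces)) stop("connectome has no traces")
  ids_a <- conn$haircells$cell_id
  ids_b <- if (pairs == "all") c(conn$haircells$cell_id,
                                 conn$terminals$terminal_id)
           else conn$terminals$terminal_id
  rows <- list(); secs <- list()
  for (a in ids_a) {
    for (b in ids_b) {
      if (a == b) next
      mc <- contact_area(a, b, conn, config)
      if (mc$area > 0) {
        rows[[length(rows) + 1L]] <- data.frame(cell_a = a, cell_b = b,
                                                area = mc$area,
                                                stringsAsFactors = FALSE)
        ms <- mc$per_section
        ms$cell_a <- a; ms$cell_b <- b
        secs[[length(secs) + 1L]] <- ms
      }
    }
  }
  conn$contacts <- if (length(rows)) do.call(rbind, rows) else
    empty_df(c(cell_a = "character", cell_b = "character", area = "numeric"))
  conn$contact_sections <- if (length(secs)) do.call(rbind, secs) else NULL
  conn
}
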