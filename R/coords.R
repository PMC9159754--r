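#' Cell-distance field over the connectivity graph
#'
#' Shortest-path distance from every cell to the nearest seed cell
#' (multi-source Dijkstra semantics). Edge weights: `euclidean` uses
#' centroid-to-centroid distance (micrometres), `cells` counts cells
#' crossed (1 per edge), `inv_wall` uses the reciprocal of the shared wall
#' measure (floored at 1e-9). Seeds get distance 0; unreachable cells are
#' unassigned (NA).
#'
#' @param graph a `cell_graph` from [build_cell_graph()].
#' @param seeds non-empty integer vector of seed labels.
#' @param weight_mode `"euclidean"`, `"cells"` or `"inv_wall"`.
#' @return tibble `label`, `distance`.
#' @export
cell_distance <- function(graph, seeds,
                          weight_mode = c("euclidean", "cells", "inv_wall")) {
  weight_mode <- match.arg(weight_mode)
  seeds <- unique(as.integer(seeds))
  if (!length(seeds)) stop("seed set is empty")
  if (!all(seeds %in% graph$nodes$label))
    stop("seeds absent from graph: ",
         paste(setdiff(seeds, graph$nodes$label), collapse = ", "))
  e <- graph$edges
  w <- switch(weight_mode,
    cells = rep(1, nrow(e)),
    inv_wall = 1 / pmax(e$wall, 1e-9),
    euclidean = {
      a <- match(e$from, graph$nodes$label)
      b <- match(e$to, graph$nodes$label)
      xyz <- as.matrix(graph$nodes[, c("x", "y", "z")])
      sqrt(rowSums((xyz[a, , drop = FALSE] - xyz[b, , drop = FALSE])^2))
    })
  g <- as_igraph(graph)
  dm <- igraph::distances(g, v = as.character(seeds), weights = w)
  d <- apply(dm, 2, min)
  d[!is.finite(d)] <- NA_real_
  tibble::tibble(label = as.integer(colnames(dm)), distance = as.numeric(d)) |>
    dplyr::arrange(.data$label)
}

#' Bezier axis coordinate of each cell
#'
#' For each cell centroid, finds the nearest point on the organ-axis spline
#' (dense polyline scan refined by golden-section search) and reports the
#' arc length at that point (`coord`), the Euclidean distance to it
#' (`distance`), and the unit spline tangent there. Centroids beyond the
#' spline ends clamp to arc length 0 or the total length.
#'
#' @param mesh a mesh or a centroid tibble (`label`, `x`, `y`, `z`).
#' @param spline a [bezier_spline()].
#' @return tibble `label`, `coord`, `distance`, `tx`, `ty`, `tz`.
#' @export
bezier_line_coord <- function(mesh, spline) {
  cen <- if (is.data.frame(mesh)) mesh else cell_centroids(mesh)
  out <- lapply(seq_len(nrow(cen)), function(i) {
    p <- c(cen$x[i], cen$y[i], cen$z[i])
    t <- bezier_nearest_t(spline, p)
    q <- bezier_eval(spline, t)[1, ]
    tg <- bezier_deriv(spline, t)[1, ]
    tg <- tg / max(vnorm(tg), 1e-300)
    tibble::tibble(label = cen$label[i],
                   coord = bezier_arclength_at(spline, t),
                   distance = vnorm(p - q),
                   tx = tg[1], ty = tg[2], tz = tg[3])
  })
  dplyr::bind_rows(out)
}

#' Polar coordinate of cells around a Cartesian axis
#'
#' Angle of each centroid's projection onto the plane perpendicular to
#' `axis`, measured counterclockwise from `reference`, in `[0, 360)`
#' degrees. Cells whose centroid lies on the axis are unassigned.
#'
#' @param mesh mesh or centroid tibble.
#' @param axis `"x"`, `"y"`, `"z"` or a 3-vector.
#' @param reference direction defining 0 degrees (not parallel to axis).
#' @param origin point on the axis (default organ centroid mean).
#' @return tibble `label`, `angle` (degrees).
#' @export
polar_coord <- function(mesh, axis = "z", reference = c(1, 0, 0),
                        origin = NULL) {
  cen <- if (is.data.frame(mesh)) mesh else cell_centroids(mesh)
  ax <- if (is.character(axis))
    switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  else unitv(axis)
  ref <- reference - sum(reference * ax) * ax
  if (vnorm(ref) < 1e-9) stop("reference direction is parallel to the axis")
  ref <- unitv(ref)
  e2 <- cross3(ax, ref)
  if (is.null(origin)) origin <- c(0, 0, 0)
  p <- sweep(as.matrix(cen[, c("x", "y", "z")]), 2, origin)
  u <- p %*% ref
  v <- p %*% e2
  r <- sqrt(u^2 + v^2)
  ang <- (atan2(v, u) * 180 / pi) %% 360
  ang[r < 1e-12] <- NA_real_
  tibble::tibble(label = cen$label, angle = as.numeric(ang))
}

#' Distance from cell centroids to another mesh
#'
#' Per-cell minimum Euclidean distance from the centroid to the vertex set
#' of another (typically surface) mesh.
#'
#' @param mesh mesh or centroid tibble.
#' @param other a mesh whose vertices define the target surface.
#' @return tibble `label`, `distance` (micrometres).
#' @export
mesh_distance <- function(mesh, other) {
  cen <- if (is.data.frame(mesh)) mesh else cell_centroids(mesh)
  v <- if (is.matrix(other)) other else other$vertices
  if (is.null(v) || !nrow(v)) stop("other mesh has no vertices")
  d <- vapply(seq_len(nrow(cen)), function(i) {
    p <- c(cen$x[i], cen$y[i], cen$z[i])
    sqrt(min((v[, 1] - p[1])^2 + (v[, 2] - p[2])^2 + (v[, 3] - p[3])^2))
  }, 0)
  tibble::tibble(label = cen$label, distance = d)
}

#' Relative radial coordinate between organ axis and surface
#'
#' For each cell, a ray is cast from the nearest axis point through the
#' centroid; the relative coordinate is the centroid's distance from the
#' axis divided by the distance at which the ray exits the organ surface,
#' so 0 lies on the axis and 1 on the surface. Cells whose ray misses the
#' surface are unassigned with a warning.
#'
#' @param mesh mesh or centroid tibble (cells to annotate).
#' @param axis a [bezier_spline()] along the organ center.
#' @param surface a [surface_cell_mesh()] (or list with `vertices`,
#'   `triangles`) bounding the organ.
#' @return tibble `label`, `relative` in `[0, 1]`, `radial` (micrometres).
#' @export
relative_radial_coord <- function(mesh, axis, surface) {
  cen <- if (is.data.frame(mesh)) mesh else cell_centroids(mesh)
  miss <- integer(0)
  out <- lapply(seq_len(nrow(cen)), function(i) {
    p <- c(cen$x[i], cen$y[i], cen$z[i])
    t <- bezier_nearest_t(axis, p)
    a <- bezier_eval(axis, t)[1, ]
    r <- p - a
    rad <- vnorm(r)
    if (rad < 1e-12)
      return(tibble::tibble(label = cen$label[i], relative = 0, radial = 0))
    hits <- ray_mesh_hits(a, r / rad, surface$vertices, surface$triangles)
    if (!length(hits)) {
      miss <<- c(miss, cen$label[i])
      return(tibble::tibble(label = cen$label[i], relative = NA_real_,
                            radial = rad))
    }
    hit <- max(hits)  # organ exit point along the ray
    tibble::tibble(label = cen$label[i],
                   relative = min(rad / hit, 1), radial = rad)
  })
  if (length(miss))
    warning("ray missed the organ surface for cells: ",
            paste(miss, collapse = ", "))
  dplyr::bind_rows(out)
}

#' Per-cell direction frames from an attribute gradient
#'
#' Fits, for every cell with at least two annotated neighbors, a linear
#' model of the attribute over the centroids of the cell and its graph
#' neighbors (1-ring), projected into the cell's tangent plane. The frame
#' has d1 = in-plane unit gradient (e.g. the proximal-distal direction of
#' a distance field), d2 = cell surface normal, d3 = d1 x d2 (the in-plane
#' orthogonal, e.g. medial-lateral). Cells with a locally constant
#' attribute are unassigned and flagged.
#'
#' @param mesh a [surface_cell_mesh()].
#' @param attr tibble `label`, `value` (or second column used as value).
#' @param graph optional precomputed [build_cell_graph()] result.
#' @return tibble `label`, `d1x..d3z`, `ok` (logical).
#' @export
attribute_gradient_directions <- function(mesh, attr, graph = NULL) {
  if (is.null(graph)) graph <- build_cell_graph(mesh)
  vals <- stats::setNames(attr[[2]], attr$label)
  geo <- cell_geometry(mesh)
  out <- lapply(geo$label, function(lb) {
    nb <- graph_neighbors(graph, lb)
    ids <- c(lb, nb)
    ids <- ids[as.character(ids) %in% names(vals)]
    ids <- ids[!is.na(vals[as.character(ids)])]
    empty <- tibble::tibble(label = lb, d1x = NA_real_, d1y = NA_real_,
                            d1z = NA_real_, d2x = NA_real_, d2y = NA_real_,
                            d2z = NA_real_, d3x = NA_real_, d3y = NA_real_,
                            d3z = NA_real_, ok = FALSE)
    if (!(lb %in% ids) || length(ids) < 3) return(empty)
    row <- geo[geo$label == lb, ]
    b <- tangent_basis(c(row$nx, row$ny, row$nz))
    cm <- as.matrix(geo[match(ids, geo$label), c("x", "y", "z")])
    cm <- sweep(cm, 2, c(row$x, row$y, row$z))
    uv <- cbind(cm %*% b$e1, cm %*% b$e2)
    y <- vals[as.character(ids)]
    fit <- stats::lm.fit(cbind(1, uv), y)
    g <- fit$coefficients[2:3]
    if (anyNA(g) || sqrt(sum(g^2)) < 1e-12) return(empty)
    d1 <- unitv(g[1] * b$e1 + g[2] * b$e2)
    d2 <- b$n
    d3 <- cross3(d1, d2)
    tibble::tibble(label = lb, d1x = d1[1], d1y = d1[2], d1z = d1[3],
                   d2x = d2[1], d2y = d2[2], d2z = d2[3],
                   d3x = d3[1], d3y = d3[2], d3z = d3[3], ok = TRUE)
  })
  dplyr::bind_rows(out)
}

#' Build a right-handed orthonormal cell frame from two directions
#'
#' Gram-Schmidt re-orthogonalizes the secondary direction against the
#' primary one and completes the triad with d3 = d1 x d2, e.g. combining a
#' Bezier tangent (longitudinal) with a nearest-surface normal (radial) to
#' obtain the width direction. Near-parallel inputs (|d1 . d2| > 0.99) are
#' unassigned and flagged.
#'
#' @param d1 tibble `label`, `x`, `y`, `z` (or columns 2:4) of primary
#'   directions per cell.
#' @param d2 same layout, secondary directions.
#' @return tibble `label`, `d1x..d3z`, `ok`.
#' @export
build_cell_frame <- function(d1, d2) {
  m <- dplyr::inner_join(
    stats::setNames(d1[, 1:4], c("label", "ax", "ay", "az")),
    stats::setNames(d2[, 1:4], c("label", "bx", "by", "bz")), by = "label")
  out <- lapply(seq_len(nrow(m)), function(i) {
    a <- c(m$ax[i], m$ay[i], m$az[i])
    b <- c(m$bx[i], m$by[i], m$bz[i])
    empty <- tibble::tibble(label = m$label[i], d1x = NA_real_,
                            d1y = NA_real_, d1z = NA_real_, d2x = NA_real_,
                            d2y = NA_real_, d2z = NA_real_, d3x = NA_real_,
                            d3y = NA_real_, d3z = NA_real_, ok = FALSE)
    if (anyNA(a) || anyNA(b) || vnorm(a) < 1e-12 || vnorm(b) < 1e-12)
      return(empty)
    a <- unitv(a); b <- unitv(b)
    if (abs(sum(a * b)) > 0.99) return(empty)
    b2 <- unitv(b - sum(a * b) * a)
    d3 <- cross3(a, b2)
    tibble::tibble(label = m$label[i], d1x = a[1], d1y = a[2], d1z = a[3],
                   d2x = b2[1], d2y = b2[2], d2z = b2[3],
                   d3x = d3[1], d3y = d3[2], d3z = d3[3], ok = TRUE)
  })
  dplyr::bind_rows(out)
}
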