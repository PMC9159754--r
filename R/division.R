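#' Mothers that divided exactly once
#'
#' @param parents tibble `child`, `parent`.
#' @return integer vector of mother labels with exactly two children.
#' @export
detect_divisions <- function(parents) {
  cnt <- table(parents$parent)
  sort(as.integer(names(cnt)[cnt == 2L]))
}

#' Fit the actual division plane (or line) to the shared daughter wall
#'
#' PCA of the wall vertex positions: in 3D the plane passes through the
#' vertex centroid with normal along the smallest-variance principal axis;
#' in 2.5D the best-fit line direction is the largest-variance axis within
#' the tissue tangent plane.
#'
#' @param wall_vertices k x 3 matrix of vertex positions on the shared
#'   wall (k >= 3 in 3D, k >= 2 in 2.5D).
#' @param dim 3 for a plane, 2 for a line in the tangent plane.
#' @param tangent_normal surface normal used to constrain the 2.5D fit.
#' @return list with `point` (centroid), `normal` (3D) or `direction`
#'   (2.5D line direction and `normal` = in-plane normal), and
#'   `degenerate` flag.
#' @export
fit_division_plane <- function(wall_vertices, dim = 3,
                               tangent_normal = NULL) {
  V <- as.matrix(wall_vertices)
  ctr <- colMeans(V)
  Vc <- sweep(V, 2, ctr)
  if (dim == 3) {
    if (nrow(V) < 3) stop("need >= 3 wall vertices in 3D")
    eg <- eigen(crossprod(Vc) / nrow(V), symmetric = TRUE)
    degenerate <- eg$values[2] < 1e-12 * max(eg$values[1], 1e-300)
    list(point = ctr, normal = unitv(eg$vectors[, 3]),
         degenerate = degenerate)
  } else {
    if (nrow(V) < 2) stop("need >= 2 wall vertices in 2.5D")
    b <- tangent_basis(tangent_normal %||% c(0, 0, 1))
    uv <- Vc %*% cbind(b$e1, b$e2)
    eg <- eigen(crossprod(uv) / nrow(uv), symmetric = TRUE)
    d2 <- eg$vectors[, 1]
    dir3 <- unitv(d2[1] * b$e1 + d2[2] * b$e2)
    list(point = ctr, direction = dir3,
         normal = unitv(cross3(b$n, dir3)), degenerate = FALSE)
  }
}

# vertices on the wall shared by the two daughters
shared_wall_vertices <- function(mesh, daughters) {
  if (inherits(mesh, "volumetric_cell_mesh")) {
    cl <- mesh$cells[[as.character(daughters[1])]]
    if (is.null(cl)) stop("unknown daughter label ", daughters[1])
    sel <- cl$wall_tag == daughters[2]
    if (!any(sel)) stop("daughters ", daughters[1], " and ", daughters[2],
                        " share no wall")
    ids <- unique(as.vector(cl$triangles[sel, , drop = FALSE]))
    cl$vertices[ids, , drop = FALSE]
  } else {
    tr <- mesh$triangles; lab <- mesh$face_label
    e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
    el <- rep(lab, 3L)
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    k1 <- unique(key[el == daughters[1]])
    k2 <- unique(key[el == daughters[2]])
    shared <- intersect(k1, k2)
    if (!length(shared)) stop("daughters share no boundary edge")
    ids <- unique(as.integer(unlist(strsplit(shared, " "))))
    mesh$vertices[ids, , drop = FALSE]
  }
}

# Fibonacci lattice of n distinct directions on the upper hemisphere
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n)
  z <- (i - 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

# area of the cross-section of a closed, outward-oriented mesh with the
# plane through `point` with unit normal `normal` (disjoint parts summed)
mesh_plane_section_area <- function(vertices, triangles, point, normal) {
  n <- unitv(normal)
  h <- as.numeric(sweep(vertices, 2, point) %*% n)
  segs <- list()
  for (i in seq_len(nrow(triangles))) {
    vid <- triangles[i, ]
    hv <- h[vid]
    below <- hv < 0
    if (all(below) || all(!below)) next
    P <- vertices[vid, , drop = FALSE]
    pts <- list()
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      h1 <- hv[e[1]]; h2 <- hv[e[2]]
      if ((h1 < 0) != (h2 < 0)) {
        t <- h1 / (h1 - h2)
        pts[[length(pts) + 1L]] <- P[e[1], ] + t * (P[e[2], ] - P[e[1], ])
      }
    }
    if (length(pts) != 2) next
    a <- pts[[1]]; b <- pts[[2]]
    # orient the segment so the section boundary winds CCW about +n:
    # tangent along n x triangle-normal
    tn <- cross3(vertices[vid[2], ] - vertices[vid[1], ],
                 vertices[vid[3], ] - vertices[vid[1], ])
    tdir <- cross3(n, tn)
    if (sum((b - a) * tdir) < 0) { tmp <- a; a <- b; b <- tmp }
    segs[[length(segs) + 1L]] <- c(a, b)
  }
  if (!length(segs)) return(0)
  S <- do.call(rbind, segs)
  a <- sweep(S[, 1:3, drop = FALSE], 2, point)
  b <- sweep(S[, 4:6, drop = FALSE], 2, point)
  # signed area: 1/2 sum (a x b) . n over oriented boundary segments
  abs(sum(cross3_rows(a, b) %*% n) / 2)
}

#' Simulate equally distributed candidate division planes
#'
#' Samples `n` plane normals equally distributed on the hemisphere (a
#' Fibonacci lattice), all planes passing through the mother cell's volume
#' centroid, and computes each plane's cell cross-section area by
#' mesh-plane intersection. Disjoint section polygons (non-convex cells)
#' have their areas summed.
#'
#' @param cell list with `vertices`, `triangles` (closed outward surface),
#'   e.g. an entry of a [volumetric_cell_mesh()]'s `cells` -- typically the
#'   merged mother obtained from the two daughters.
#' @param n number of candidate planes (default 1000).
#' @return tibble `nx`, `ny`, `nz` (plane normals), `area` (um^2), plus
#'   the centroid as an attribute `"centroid"`.
#' @export
enumerate_candidate_planes <- function(cell, n = 1000) {
  if (n < 1) stop("n must be >= 1")
  if (!is_watertight(cell$triangles))
    stop("mother cell surface is not watertight")
  ctr <- closed_surface_centroid(cell$vertices, cell$triangles)
  dirs <- fibonacci_hemisphere(n)
  area <- vapply(seq_len(n), function(i)
    mesh_plane_section_area(cell$vertices, cell$triangles, ctr, dirs[i, ]),
    0)
  out <- tibble::tibble(nx = dirs[, 1], ny = dirs[, 2], nz = dirs[, 3],
                        area = area)
  attr(out, "centroid") <- ctr
  out
}

#' Candidate division chords of a 2.5D cell
#'
#' Chords of the cell polygon (flattened to its tangent plane) through the
#' area centroid, sampled at `step` degree direction increments over
#' `[0, 180)`. The chord length is the total in-polygon length along the
#' direction line (disjoint intervals summed for non-convex cells).
#'
#' @param mesh a [surface_cell_mesh()].
#' @param label mother cell label (typically after merging daughters).
#' @param step direction step in degrees (default 1).
#' @return tibble `theta_deg`, `dx`, `dy`, `dz` (chord direction in 3D),
#'   `length` (um).
#' @export
enumerate_candidate_chords <- function(mesh, label, step = 1) {
  poly <- cell_polygon_2d(mesh, label)
  ctr <- polygon_centroid_2d(poly$xy)
  thetas <- seq(0, 180 - step, by = step)
  out <- lapply(thetas, function(th) {
    d <- c(cos(th * pi / 180), sin(th * pi / 180))
    len <- chord_length_through(poly$xy, ctr, d)
    d3 <- d[1] * poly$basis$e1 + d[2] * poly$basis$e2
    tibble::tibble(theta_deg = th, dx = d3[1], dy = d3[2], dz = d3[3],
                   length = len)
  })
  dplyr::bind_rows(out)
}

# total length of {p = ctr + t d} inside polygon xy (even-odd intervals);
# degenerate crossings (line through a vertex / parallel edge) are resolved
# by a tiny direction perturbation
chord_length_through <- function(xy, ctr, d, depth = 0) {
  n <- nrow(xy)
  a <- xy
  b <- xy[c(2:n, 1L), , drop = FALSE]
  # solve ctr + t d = a + s (b - a), 0 <= s < 1
  ts <- numeric(0)
  degenerate <- FALSE
  for (i in seq_len(n)) {
    e <- b[i, ] - a[i, ]
    det <- d[1] * (-e[2]) - d[2] * (-e[1])
    if (abs(det) < 1e-12 * max(vnorm(e), 1)) next
    rhs <- a[i, ] - ctr
    t <- (rhs[1] * (-e[2]) - rhs[2] * (-e[1])) / det
    s <- (d[1] * rhs[2] - d[2] * rhs[1]) / det
    if (abs(s) < 1e-9 || abs(s - 1) < 1e-9) degenerate <- TRUE
    if (s >= 0 && s < 1) ts <- c(ts, t)
  }
  if ((length(ts) %% 2 == 1 || degenerate) && depth < 4) {
    ang <- 1e-5 * (depth + 1)
    d2 <- c(cos(ang) * d[1] - sin(ang) * d[2],
            sin(ang) * d[1] + cos(ang) * d[2])
    return(chord_length_through(xy, ctr, d2, depth + 1))
  }
  ts <- sort(ts)
  if (length(ts) < 2) return(0)
  sum(ts[seq(2, length(ts), by = 2)] - ts[seq(1, length(ts) - 1, by = 2)])
}

#' Rank candidate division planes
#'
#' Finds the global minimum-area (or minimum-length) candidate, local
#' minima (candidates smaller than all their angular neighbors: adjacent
#' directions on the sampled circle in 2.5D, the `k` nearest directions in
#' 3D, sign-folded), and the percentile rank of the actual division
#' plane's area among the candidates.
#'
#' @param candidates output of [enumerate_candidate_planes()] (column
#'   `area`) or [enumerate_candidate_chords()] (column `length`).
#' @param actual_value area (3D) or length (2.5D) of the actual plane;
#'   optional.
#' @param k neighborhood size for 3D local minima (default 6).
#' @return list with `global_min` (row index), `local_minima` (row
#'   indices), `rank` (percentile of actual among candidates, 0 = smallest;
#'   NA if no actual given).
#' @export
rank_planes <- function(candidates, actual_value = NULL, k = 6) {
  val <- if ("area" %in% names(candidates)) candidates$area
         else candidates$length
  m <- length(val)
  if ("theta_deg" %in% names(candidates)) {
    nbr <- lapply(seq_len(m), function(i)
      c(if (i == 1) m else i - 1, if (i == m) 1 else i + 1))
  } else {
    D <- as.matrix(candidates[, c("nx", "ny", "nz")])
    dot <- abs(D %*% t(D))        # axial: fold antipodal directions
    nbr <- lapply(seq_len(m), function(i) {
      o <- order(dot[i, ], decreasing = TRUE)
      setdiff(o, i)[seq_len(min(k, m - 1))]
    })
  }
  loc <- which(vapply(seq_len(m), function(i)
    all(val[i] <= val[nbr[[i]]]) && !all(val[i] == val[nbr[[i]]]), TRUE))
  rank <- if (is.null(actual_value)) NA_real_ else
    100 * mean(val < actual_value)
  list(global_min = which.min(val), local_minima = loc, rank = rank)
}

#' Angle between a division plane and an organ axis
#'
#' Reports the angle between the plane itself and the axis, folded into
#' `[0, 90]` degrees: 90 when the plane is perpendicular to the axis
#' (normal parallel to it), 0 when the plane contains the axis.
#'
#' @param normal plane unit normal (3-vector), or a matrix of normals.
#' @param axis organ axis direction (3-vector).
#' @return numeric angle(s) in degrees.
#' @export
division_plane_angles <- function(normal, axis) {
  if (is.null(normal) || anyNA(normal) || is.null(axis) || anyNA(axis))
    return(NA_real_)
  ax <- unitv(as.numeric(axis))
  nm <- rbind(normal)
  vapply(seq_len(nrow(nm)), function(i) {
    n <- unitv(nm[i, ])
    a <- acos(pmin(abs(sum(n * ax)), 1)) * 180 / pi  # normal-axis in [0,90]
    90 - a
  }, 0)
}

#' Daughter size asymmetry
#'
#' `|s1 - s2| / (s1 + s2)` with s the daughter areas (2.5D) or volumes
#' (3D); 0 for equal daughters, invariant under relabeling.
#'
#' @param s1,s2 daughter sizes.
#' @return asymmetry in `[0, 1)`.
#' @export
daughter_asymmetry <- function(s1, s2) abs(s1 - s2) / (s1 + s2)

#' Full division record for one mother
#'
#' Combines the actual-plane fit, candidate simulation, ranking, daughter
#' asymmetry and (optionally) the angle to an organ axis for one division.
#'
#' @param mesh mesh at the later time point containing both daughters.
#' @param daughters integer vector of the two daughter labels.
#' @param mother mother label (metadata only).
#' @param axis optional organ axis for the angle.
#' @param n_planes candidate count (3D; 2.5D uses 1-degree chords).
#' @return one-row tibble with `mother`, `asymmetry`, `actual` (area or
#'   length), `min_candidate`, `rank`, `angle` and the plane normal.
#' @export
division_record <- function(mesh, daughters, mother = NA_integer_,
                            axis = NULL, n_planes = 1000) {
  stopifnot(length(daughters) == 2)
  W <- shared_wall_vertices(mesh, daughters)
  if (inherits(mesh, "volumetric_cell_mesh")) {
    pl <- fit_division_plane(W, dim = 3)
    g <- cell_geometry_3d(mesh)
    s <- g$volume[match(daughters, g$label)]
    merged <- merge_daughter_cells(mesh, daughters)
    cand <- enumerate_candidate_planes(merged, n_planes)
    actual <- mesh_plane_section_area(merged$vertices, merged$triangles,
                                      attr(cand, "centroid"), pl$normal)
    rk <- rank_planes(cand, actual)
    nrm <- pl$normal
    minc <- min(cand$area)
  } else {
    g <- cell_geometry(mesh)
    nrm0 <- colSums(as.matrix(
      g[match(daughters, g$label), c("nx", "ny", "nz")]))
    pl <- fit_division_plane(W, dim = 2, tangent_normal = nrm0)
    s <- g$area[match(daughters, g$label)]
    merged_mesh <- relabel_cells(mesh, daughters, daughters[1])
    cand <- enumerate_candidate_chords(merged_mesh, daughters[1])
    poly <- cell_polygon_2d(merged_mesh, daughters[1])
    dd <- c(sum(pl$direction * poly$basis$e1),
            sum(pl$direction * poly$basis$e2))
    actual <- chord_length_through(poly$xy, polygon_centroid_2d(poly$xy),
                                   unitv(c(dd, 0))[1:2])
    rk <- rank_planes(cand, actual)
    nrm <- pl$normal
    minc <- min(cand$length)
  }
  angle <- if (is.null(axis)) NA_real_ else division_plane_angles(nrm, axis)
  tibble::tibble(mother = mother, daughter1 = daughters[1],
                 daughter2 = daughters[2],
                 asymmetry = daughter_asymmetry(s[1], s[2]),
                 actual = actual, min_candidate = minc, rank = rk$rank,
                 angle = angle, nx = nrm[1], ny = nrm[2], nz = nrm[3])
}

# merge the two daughters' closed surfaces into the mother surface by
# dropping the shared wall and welding coincident vertices
merge_daughter_cells <- function(mesh, daughters) {
  stopifnot(inherits(mesh, "volumetric_cell_mesh"))
  parts <- lapply(daughters, function(d) {
    cl <- mesh$cells[[as.character(d)]]
    keep <- cl$wall_tag != setdiff(daughters, d)[1]
    list(vertices = cl$vertices,
         triangles = cl$triangles[keep, , drop = FALSE],
         wall_tag = cl$wall_tag[keep])
  })
  keymap <- new.env(hash = TRUE); pool <- list(); nv <- 0L
  tris <- list(); tags <- integer(0)
  for (p in parts) {
    keys <- vertex_key(p$vertices)
    idx <- integer(length(keys))
    for (i in seq_along(keys)) {
      j <- keymap[[keys[i]]]
      if (is.null(j)) {
        nv <- nv + 1L; keymap[[keys[i]]] <- nv; pool[[nv]] <- p$vertices[i, ]
        j <- nv
      }
      idx[i] <- j
    }
    tris[[length(tris) + 1L]] <- matrix(idx[p$triangles], ncol = 3)
    tags <- c(tags, p$wall_tag)
  }
  list(vertices = do.call(rbind, pool), triangles = do.call(rbind, tris),
       wall_tag = tags)
}

# reassign a set of labels to one label on a surface mesh
relabel_cells <- function(mesh, from, to) {
  mesh$face_label[mesh$face_label %in% from] <- as.integer(to)
  mesh
}
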