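#' Border signal polarity of a surface cell
#'
#' The signal along the cell border is binned by angle about the cell
#' centroid in the tangent plane; each bin's value is the area-weighted
#' mean intensity of its border samples (signal per unit border area, so
#' an elongated cell with uniform membrane signal is not spuriously
#' polar). The polarity direction is the angle of the vector resultant
#' sum(m_b (cos t_b, sin t_b)) over the bin means and the magnitude is
#' |resultant| / sum(m_b) -- 1 when all signal sits in one direction, 0
#' for a uniform or symmetric distribution.
#'
#' The band is sampled strictly inside the cell: vertices lying exactly on
#' the shared outline (whose signal belongs as much to the neighbor as to
#' the cell) are excluded by a small inner offset, mirroring how membrane
#' signal is projected from just within each cell.
#'
#' @param mesh a [surface_cell_mesh()] with `vertex_signal`.
#' @param labels cells to measure (default all).
#' @param n_bins angular histogram resolution (>= 4).
#' @param border_width border band width in micrometres.
#' @param inner_offset exclusion distance from the outline (um).
#' @return tibble `label`, `dx`, `dy`, `dz` (unit direction, tangent
#'   plane), `magnitude`, `total_signal`.
#' @export
border_polarity <- function(mesh, labels = NULL, n_bins = 72,
                            border_width = 1, inner_offset = 1e-6) {
  if (is.null(mesh$vertex_signal)) stop("mesh carries no vertex signal")
  if (n_bins < 4) stop("n_bins must be >= 4")
  labels <- labels %||% mesh_labels(mesh)
  out <- lapply(labels, function(lb) {
    poly <- cell_polygon_2d(mesh, lb)
    w <- cell_vertex_weights(mesh, lb)
    ids <- as.integer(names(w))
    # border vertices: within border_width of the outline
    bpts <- mesh$vertices[poly$loop, , drop = FALSE]
    nb <- nrow(bpts); nxt <- c(2:nb, 1L)
    d2b <- vapply(ids, function(vi) {
      p <- mesh$vertices[vi, ]
      min(vapply(seq_len(nb), function(i)
        point_segment_distance(p, bpts[i, ], bpts[nxt[i], ]), 0))
    }, 0)
    sel <- d2b <= border_width & d2b > inner_offset
    if (!any(sel)) sel <- d2b <= border_width
    ids <- ids[sel]; wv <- w[sel]
    s <- mesh$vertex_signal[ids] * wv
    tot <- sum(s)
    if (tot <= 0)
      return(tibble::tibble(label = lb, dx = NA_real_, dy = NA_real_,
                            dz = NA_real_, magnitude = NA_real_,
                            total_signal = 0))
    pc <- sweep(mesh$vertices[ids, , drop = FALSE], 2, poly$origin)
    u <- pc %*% poly$basis$e1
    v <- pc %*% poly$basis$e2
    th <- atan2(v, u)
    nb_eff <- min(n_bins, max(8L, length(s) %/% 4L))
    bin <- pmin(floor((th + pi) / (2 * pi) * nb_eff) + 1L, nb_eff)
    n_bins <- nb_eff
    m_b <- tapply(s, bin, sum) / tapply(wv, bin, sum)  # mean intensity
    th_b <- (as.integer(names(m_b)) - 0.5) * 2 * pi / n_bins - pi
    res <- c(sum(m_b * cos(th_b)), sum(m_b * sin(th_b)))
    mag <- vnorm(res) / sum(m_b)
    d3 <- if (mag > 1e-12)
      unitv(res[1] * poly$basis$e1 + res[2] * poly$basis$e2)
    else c(NA_real_, NA_real_, NA_real_)
    tibble::tibble(label = lb, dx = d3[1], dy = d3[2], dz = d3[3],
                   magnitude = mag, total_signal = tot)
  })
  dplyr::bind_rows(out)
}

#' Fibril (microtubule) orientation from signal texture
#'
#' Adaptation of fibril-orientation analysis to labeled surfaces: each
#' triangle's in-plane signal gradient g (linear shape functions) feeds an
#' area-weighted nematic tensor mean(ghat ghat') over the cell; the fibril
#' orientation is the eigenvector of the smaller eigenvalue (fibrils run
#' perpendicular to the dominant intensity gradient of a striped texture)
#' and the anisotropy score is (l1 - l2)/(l1 + l2) in [0, 1], 0 for
#' isotropic signal. Orientation is axial (defined up to sign).
#'
#' @param mesh a [surface_cell_mesh()] with `vertex_signal`.
#' @param labels cells to measure (default all).
#' @return tibble `label`, `ox`, `oy`, `oz` (unit axial direction),
#'   `anisotropy`.
#' @export
fibril_orientation <- function(mesh, labels = NULL) {
  if (is.null(mesh$vertex_signal)) stop("mesh carries no vertex signal")
  labels <- labels %||% mesh_labels(mesh)
  geo <- cell_geometry(mesh)
  out <- lapply(labels, function(lb) {
    sel <- mesh$face_label == lb
    tr <- mesh$triangles[sel, , drop = FALSE]
    row <- geo[geo$label == lb, ]
    b <- tangent_basis(c(row$nx, row$ny, row$nz))
    N <- matrix(0, 2, 2); wsum <- 0
    for (i in seq_len(nrow(tr))) {
      p <- mesh$vertices[tr[i, ], , drop = FALSE]
      s <- mesh$vertex_signal[tr[i, ]]
      e1 <- p[2, ] - p[1, ]; e2 <- p[3, ] - p[1, ]
      nrm <- cross3(e1, e2)
      a2 <- vnorm(nrm)
      if (a2 < 1e-300) next
      # linear-shape-function gradient: grad s = sum_i s_i (nhat x e_i)/(2A)
      # with e_i the edge opposite vertex i (CCW) and |nrm| = 2A
      eo1 <- p[3, ] - p[2, ]; eo2 <- p[1, ] - p[3, ]; eo3 <- p[2, ] - p[1, ]
      g <- cross3(nrm, s[1] * eo1 + s[2] * eo2 + s[3] * eo3) / (a2 * a2)
      gn <- vnorm(g)
      if (gn < 1e-12) next
      gu <- c(sum(g * b$e1), sum(g * b$e2)) / gn
      ar <- a2 / 2
      N <- N + ar * outer(gu, gu)
      wsum <- wsum + ar
    }
    if (wsum <= 0 || sum(abs(N)) < 1e-300)
      return(tibble::tibble(label = lb, ox = NA_real_, oy = NA_real_,
                            oz = NA_real_, anisotropy = NA_real_))
    N <- N / wsum
    eg <- eigen(N, symmetric = TRUE)
    v <- eg$vectors[, 2]                     # smaller-eigenvalue direction
    o3 <- unitv(v[1] * b$e1 + v[2] * b$e2)
    tibble::tibble(label = lb, ox = o3[1], oy = o3[2], oz = o3[3],
                   anisotropy = (eg$values[1] - eg$values[2]) /
                     (eg$values[1] + eg$values[2]))
  })
  dplyr::bind_rows(out)
}

#' Wall-signal polarity of a volumetric cell
#'
#' Area-weighted resultant of wall-element signal about the cell centroid:
#' direction = unit of sum(s_i a_i (p_i - c)) over wall triangles with
#' signal s_i, area a_i and centroid p_i; magnitude = |sum| /
#' sum(s_i a_i |p_i - c|), 1 for signal concentrated at one pole, ~0 for
#' uniform signal.
#'
#' @param cell list with `vertices`, `triangles`, or a
#'   [volumetric_cell_mesh()] plus `label`.
#' @param wall_signal numeric per-triangle signal.
#' @param label cell label when `cell` is a volumetric mesh.
#' @return one-row tibble `dx`, `dy`, `dz`, `magnitude`, `total_signal`.
#' @export
polarity_3d <- function(cell, wall_signal, label = NULL) {
  if (inherits(cell, "volumetric_cell_mesh"))
    cell <- cell$cells[[as.character(label)]]
  stopifnot(length(wall_signal) == nrow(cell$triangles))
  ar <- tri_areas(cell$vertices, cell$triangles)
  cen <- (cell$vertices[cell$triangles[, 1], , drop = FALSE] +
          cell$vertices[cell$triangles[, 2], , drop = FALSE] +
          cell$vertices[cell$triangles[, 3], , drop = FALSE]) / 3
  ctr <- closed_surface_centroid(cell$vertices, cell$triangles)
  rel <- sweep(cen, 2, ctr)
  s <- wall_signal * ar
  tot <- sum(s)
  if (tot <= 0)
    return(tibble::tibble(dx = NA_real_, dy = NA_real_, dz = NA_real_,
                          magnitude = NA_real_, total_signal = 0))
  res <- unname(colSums(rel * s))
  denom <- sum(s * sqrt(rowSums(rel * rel)))
  mag <- vnorm(res) / denom
  d <- if (vnorm(res) > 1e-12) unitv(res) else c(NA_real_, NA_real_,
                                                 NA_real_)
  tibble::tibble(dx = d[1], dy = d[2], dz = d[3], magnitude = mag,
                 total_signal = tot)
}

#' Angle between a direction and a frame axis
#'
#' Polar vectors give angles in `[0, 180]` degrees; axial directions
#' (fibril orientations, defined up to sign) are folded into `[0, 90]`.
#'
#' @param v direction 3-vector (NA allowed -> NA).
#' @param axis reference axis 3-vector.
#' @param axial fold to `[0, 90]` (default FALSE).
#' @return angle in degrees.
#' @export
direction_angle <- function(v, axis, axial = FALSE) {
  if (anyNA(v) || anyNA(axis)) return(NA_real_)
  a <- unitv(as.numeric(v)); b <- unitv(as.numeric(axis))
  d <- sum(a * b)
  if (axial) d <- abs(d)
  acos(pmin(pmax(d, -1), 1)) * 180 / pi
}
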