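#' Triangulated 2.5D tissue mesh with per-face cell labels
#'
#' A `surface_cell_mesh` represents a curved, triangulated surface carrying a
#' cellular segmentation: every triangle belongs to exactly one cell (a
#' positive integer label; 0 marks unlabeled triangles) and vertices may carry
#' a fluorescence-like signal. Junctions -- vertices where at least three
#' cells meet, or two cells meet the tissue border -- are derived on demand
#' and serve as material landmarks for growth analysis.
#'
#' @param vertices numeric n x 3 matrix of positions (micrometres).
#' @param triangles integer m x 3 matrix of 1-based vertex indices,
#'   outward-oriented.
#' @param face_label integer vector of length m; positive cell labels,
#'   0 = unlabeled.
#' @param vertex_signal optional numeric vector of length n, non-negative.
#' @return An object of class `surface_cell_mesh`.
#' @export
surface_cell_mesh <- function(vertices, triangles, face_label,
                              vertex_signal = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3,
            length(face_label) == nrow(triangles))
  if (any(triangles < 1L) || any(triangles > nrow(vertices)))
    stop("triangle indices out of range")
  face_label <- as.integer(face_label)
  if (any(face_label < 0L)) stop("cell labels must be non-negative")
  if (!is.null(vertex_signal)) {
    stopifnot(length(vertex_signal) == nrow(vertices))
    if (any(vertex_signal < 0)) stop("vertex_signal must be non-negative")
  }
  structure(list(vertices = vertices, triangles = triangles,
                 face_label = face_label,
                 vertex_signal = vertex_signal),
            class = "surface_cell_mesh")
}

#' @export
print.surface_cell_mesh <- function(x, ...) {
  cat("<surface_cell_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$triangles), " triangles, ",
      length(unique(x$face_label[x$face_label > 0L])), " cells",
      if (!is.null(x$vertex_signal)) ", with signal" else "", "\n", sep = "")
  invisible(x)
}

#' @export
mesh_labels <- function(mesh) UseMethod("mesh_labels")

#' @export
mesh_labels.surface_cell_mesh <- function(mesh)
  sort(unique(mesh$face_label[mesh$face_label > 0L]))

# edges of each triangle as a 3m x 2 matrix (sorted vertex pairs)
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

# vertices on the mesh border (incident to an edge used by one triangle only)
border_vertices <- function(mesh) {
  e <- mesh_edges(mesh)
  key <- paste(e[, 1], e[, 2])
  cnt <- table(key)
  open_ <- names(cnt)[cnt == 1L]
  if (!length(open_)) return(integer(0))
  idx <- do.call(rbind, strsplit(open_, " "))
  sort(unique(as.integer(idx)))
}

#' Junction vertices of a labeled surface mesh
#'
#' Junctions are vertices incident to triangles of at least three distinct
#' cell labels, or to two labels while lying on the mesh border. They are the
#' material landmarks used for growth-tensor fitting.
#'
#' @param mesh a [surface_cell_mesh()].
#' @return integer vector of vertex indices, sorted.
#' @export
mesh_junctions <- function(mesh) {
  tr <- mesh$triangles
  lab <- mesh$face_label
  vl <- data.frame(v = as.vector(tr), l = rep(lab, 3L))
  vl <- unique(vl)
  nlab <- tapply(vl$l, vl$v, function(z) length(unique(z)))
  v_ids <- as.integer(names(nlab))
  brd <- border_vertices(mesh)
  j <- v_ids[nlab >= 3L | (nlab == 2L & v_ids %in% brd)]
  sort(j)
}

#' Per-cell centroids, areas and normals of a surface mesh
#'
#' Centroids are area-weighted means of triangle centroids, areas are summed
#' triangle areas, and normals are unit area-weighted mean triangle normals
#' (each cell's tangent-plane convention throughout the package).
#'
#' @param mesh a [surface_cell_mesh()].
#' @return A tibble with columns `label`, `x`, `y`, `z`, `area`,
#'   `nx`, `ny`, `nz`.
#' @export
cell_geometry <- function(mesh) {
  lab <- mesh$face_label
  keep <- lab > 0L
  tr <- mesh$triangles[keep, , drop = FALSE]
  lab <- lab[keep]
  nrm <- tri_normals(mesh$vertices, tr)
  ar <- 0.5 * sqrt(rowSums(nrm * nrm))
  cen <- (mesh$vertices[tr[, 1], , drop = FALSE] +
          mesh$vertices[tr[, 2], , drop = FALSE] +
          mesh$vertices[tr[, 3], , drop = FALSE]) / 3
  f <- factor(lab)
  area <- tapply(ar, f, sum)
  w <- ar
  cx <- tapply(w * cen[, 1], f, sum) / area
  cy <- tapply(w * cen[, 2], f, sum) / area
  cz <- tapply(w * cen[, 3], f, sum) / area
  nx <- tapply(nrm[, 1], f, sum)
  ny <- tapply(nrm[, 2], f, sum)
  nz <- tapply(nrm[, 3], f, sum)
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  nn[nn < 1e-300] <- 1
  tibble::tibble(label = as.integer(levels(f)),
                 x = as.numeric(cx), y = as.numeric(cy), z = as.numeric(cz),
                 area = as.numeric(area),
                 nx = as.numeric(nx / nn), ny = as.numeric(ny / nn),
                 nz = as.numeric(nz / nn))
}

#' @export
cell_centroids <- function(mesh) {
  if (inherits(mesh, "volumetric_cell_mesh")) return(cell_centroids_3d(mesh))
  g <- cell_geometry(mesh)
  g[, c("label", "x", "y", "z")]
}

# ordered closed boundary loop (vertex indices) of one cell's triangle patch
cell_boundary_loop <- function(mesh, label) {
  tr <- mesh$triangles[mesh$face_label == label, , drop = FALSE]
  if (!nrow(tr)) stop("no triangles with label ", label)
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  bnd <- e[cnt[key] == 1L, , drop = FALSE]  # directed, outward-winding order
  if (!nrow(bnd)) stop("cell ", label, " has no boundary (closed surface?)")
  nxt <- bnd[, 2]
  names(nxt) <- as.character(bnd[, 1])
  loop <- integer(nrow(bnd))
  loop[1] <- bnd[1, 1]
  for (i in seq_len(nrow(bnd) - 1L)) {
    nx <- nxt[as.character(loop[i])]
    if (is.na(nx)) stop("cell ", label, " boundary is not a closed loop")
    loop[i + 1L] <- nx
  }
  if (nxt[as.character(loop[length(loop)])] != loop[1])
    stop("cell ", label, " boundary is not a single closed loop")
  loop
}

# flatten a cell to its tangent plane: list(xy = k x 2 polygon (CCW),
# loop = vertex ids, basis = tangent basis, origin = centroid)
cell_polygon_2d <- function(mesh, label) {
  g <- cell_geometry(mesh)
  row <- g[g$label == label, ]
  if (!nrow(row)) stop("unknown label ", label)
  b <- tangent_basis(c(row$nx, row$ny, row$nz))
  loop <- cell_boundary_loop(mesh, label)
  p <- mesh$vertices[loop, , drop = FALSE]
  orig <- c(row$x, row$y, row$z)
  pc <- sweep(p, 2, orig)
  xy <- cbind(pc %*% b$e1, pc %*% b$e2)
  if (polygon_area_2d(xy) < 0) {        # enforce CCW in-plane winding
    xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
    loop <- rev(loop)
  }
  list(xy = xy, loop = loop, basis = b, origin = orig)
}

# per-vertex area weight within one cell (1/3 of incident triangle areas)
cell_vertex_weights <- function(mesh, label) {
  tr <- mesh$triangles[mesh$face_label == label, , drop = FALSE]
  ar <- tri_areas(mesh$vertices, tr)
  w <- tapply(rep(ar / 3, 3L), factor(as.vector(tr)), sum)
  out <- as.numeric(w)
  names(out) <- names(w)
  out
}
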