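#' Volumetric cell complex: closed per-cell surfaces with tagged walls
#'
#' A `volumetric_cell_mesh` stores, per cell label, a closed outward-oriented
#' triangulated surface plus a per-triangle wall tag giving the label of the
#' neighboring cell on the other side of that wall patch (0 = organ outside).
#' Shared walls of adjacent cells have matching areas.
#'
#' @param cells named list (names = labels) of lists with elements
#'   `vertices` (n x 3), `triangles` (m x 3, 1-based, outward), and
#'   `wall_tag` (integer m, neighbor label or 0).
#' @return An object of class `volumetric_cell_mesh`.
#' @export
volumetric_cell_mesh <- function(cells) {
  stopifnot(is.list(cells), length(cells) > 0, !is.null(names(cells)))
  for (nm in names(cells)) {
    cl <- cells[[nm]]
    stopifnot(ncol(cl$vertices) == 3, ncol(cl$triangles) == 3,
              length(cl$wall_tag) == nrow(cl$triangles))
    cells[[nm]]$vertices <- `storage.mode<-`(as.matrix(cl$vertices), "double")
    cells[[nm]]$triangles <- `storage.mode<-`(as.matrix(cl$triangles), "integer")
    cells[[nm]]$wall_tag <- as.integer(cl$wall_tag)
  }
  structure(list(cells = cells), class = "volumetric_cell_mesh")
}

#' @export
print.volumetric_cell_mesh <- function(x, ...) {
  cat("<volumetric_cell_mesh> ", length(x$cells), " cells\n", sep = "")
  invisible(x)
}

#' @export
mesh_labels.volumetric_cell_mesh <- function(mesh)
  sort(as.integer(names(mesh$cells)))

# signed volume of a closed surface by the divergence theorem
closed_surface_volume <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c_ <- vertices[triangles[, 3], , drop = FALSE]
  sum(rowSums(a * cross3_rows(b, c_))) / 6
}

# volume centroid of a closed surface (tetrahedra to origin)
closed_surface_centroid <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c_ <- vertices[triangles[, 3], , drop = FALSE]
  w <- rowSums(a * cross3_rows(b, c_)) / 6   # signed tet volumes
  cen <- (a + b + c_) / 4
  colSums(cen * w) / sum(w)
}

#' Per-cell volume, wall areas and centroid of a volumetric mesh
#'
#' Volume is computed by the divergence theorem over each cell's closed
#' surface; `outside_area` sums wall patches tagged 0 and `outside_ratio`
#' is the proportion of wall area not shared with a neighbor cell.
#'
#' @param mesh a [volumetric_cell_mesh()].
#' @return tibble with `label`, `x`, `y`, `z`, `volume`, `wall_area`,
#'   `outside_area`, `outside_ratio`.
#' @export
cell_geometry_3d <- function(mesh) {
  rows <- lapply(names(mesh$cells), function(nm) {
    cl <- mesh$cells[[nm]]
    ar <- tri_areas(cl$vertices, cl$triangles)
    vol <- closed_surface_volume(cl$vertices, cl$triangles)
    cen <- closed_surface_centroid(cl$vertices, cl$triangles)
    tibble::tibble(label = as.integer(nm), x = cen[1], y = cen[2], z = cen[3],
                   volume = vol, wall_area = sum(ar),
                   outside_area = sum(ar[cl$wall_tag == 0L]))
  })
  out <- dplyr::bind_rows(rows)
  out$outside_ratio <- out$outside_area / out$wall_area
  dplyr::arrange(out, .data$label)
}

cell_centroids_3d <- function(mesh) {
  g <- cell_geometry_3d(mesh)
  g[, c("label", "x", "y", "z")]
}

# is a closed triangulated surface watertight (every edge used exactly twice,
# once in each direction)?
is_watertight <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  fwd <- paste(e[, 1], e[, 2])
  rev_ <- paste(e[, 2], e[, 1])
  !anyDuplicated(fwd) && all(fwd %in% rev_)
}

#' Validate mesh invariants
#'
#' Checks the structural invariants of a mesh and reports violations:
#' for surface meshes, unlabeled triangles and per-cell edge-connectivity
#' and closed boundary loops; for volumetric meshes, watertightness,
#' positive volumes and matching wall-patch areas between neighbor pairs.
#' An empty report means every invariant holds.
#'
#' @param mesh a [surface_cell_mesh()] or [volumetric_cell_mesh()].
#' @param tol relative tolerance for wall-area matching.
#' @return tibble with columns `check`, `label`, `detail` (zero rows if valid).
#' @export
validate_mesh <- function(mesh, tol = 1e-6) UseMethod("validate_mesh")

#' @export
validate_mesh.surface_cell_mesh <- function(mesh, tol = 1e-6) {
  bad <- list()
  if (any(mesh$face_label == 0L))
    bad[[length(bad) + 1L]] <- tibble::tibble(
      check = "unlabeled_faces", label = NA_integer_,
      detail = paste(sum(mesh$face_label == 0L), "unlabeled triangles"))
  for (lb in mesh_labels(mesh)) {
    tr <- mesh$triangles[mesh$face_label == lb, , drop = FALSE]
    # edge connectivity of the cell's triangle patch
    if (nrow(tr) > 1L) {
      ekey <- function(i, j) paste(pmin(i, j), pmax(i, j))
      keys <- cbind(ekey(tr[, 1], tr[, 2]), ekey(tr[, 2], tr[, 3]),
                    ekey(tr[, 3], tr[, 1]))
      g <- igraph::graph_from_edgelist(
        do.call(rbind, lapply(1:3, function(k)
          cbind(as.character(seq_len(nrow(tr))), keys[, k]))),
        directed = FALSE)
      comp <- igraph::components(g)
      if (comp$no > 1L)
        bad[[length(bad) + 1L]] <- tibble::tibble(
          check = "disconnected_cell", label = lb,
          detail = paste(comp$no, "components"))
    }
    ok <- tryCatch({cell_boundary_loop(mesh, lb); TRUE},
                   error = function(e) FALSE)
    if (!ok)
      bad[[length(bad) + 1L]] <- tibble::tibble(
        check = "open_boundary", label = lb,
        detail = "boundary is not a single closed loop")
  }
  if (length(bad)) dplyr::bind_rows(bad) else
    tibble::tibble(check = character(), label = integer(),
                   detail = character())
}

#' @export
validate_mesh.volumetric_cell_mesh <- function(mesh, tol = 1e-6) {
  bad <- list()
  areas <- list()  # areas[["i|j"]] = wall area of patch tagged j in cell i
  for (nm in names(mesh$cells)) {
    cl <- mesh$cells[[nm]]
    if (!is_watertight(cl$triangles))
      bad[[length(bad) + 1L]] <- tibble::tibble(
        check = "non_watertight", label = as.integer(nm),
        detail = "cell surface has open or inconsistent edges")
    vol <- closed_surface_volume(cl$vertices, cl$triangles)
    if (!(vol > 0))
      bad[[length(bad) + 1L]] <- tibble::tibble(
        check = "non_positive_volume", label = as.integer(nm),
        detail = sprintf("volume %.6g", vol))
    ar <- tri_areas(cl$vertices, cl$triangles)
    for (tg in unique(cl$wall_tag[cl$wall_tag > 0L]))
      areas[[paste(nm, tg, sep = "|")]] <- sum(ar[cl$wall_tag == tg])
  }
  for (k in names(areas)) {
    ij <- strsplit(k, "|", fixed = TRUE)[[1]]
    back <- paste(ij[2], ij[1], sep = "|")
    a1 <- areas[[k]]; a2 <- areas[[back]]
    if (is.null(a2)) {
      bad[[length(bad) + 1L]] <- tibble::tibble(
        check = "unmatched_wall", label = as.integer(ij[1]),
        detail = paste("wall tagged", ij[2], "has no counterpart"))
    } else if (abs(a1 - a2) > tol * max(a1, a2, 1)) {
      if (ij[1] < ij[2])  # report each mismatched pair once
        bad[[length(bad) + 1L]] <- tibble::tibble(
          check = "wall_area_mismatch", label = as.integer(ij[1]),
          detail = sprintf("wall %s-%s: %.6g vs %.6g", ij[1], ij[2], a1, a2))
    }
  }
  if (length(bad)) dplyr::bind_rows(bad) else
    tibble::tibble(check = character(), label = integer(),
                   detail = character())
}
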