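#' Principal directions of growth between two time points
#'
#' For every tracked mother cell, a linear map with translation (the cell
#' deformation gradient F) is least-squares fitted from the cell's junction
#' landmarks at t0 to the corresponding landmarks of its daughters' union
#' at t1. On surface meshes the fit is done in the cell's local tangent
#' frame (2 x 2 F); the right stretch tensor U = sqrt(F'F) is obtained by
#' polar decomposition and its eigenvalues/vectors are the principal
#' stretch ratios kmax >= kmin and the principal directions of growth.
#' Cells with fewer than 3 usable landmarks (4 in 3D) or rank-deficient
#' landmark configurations are unassigned and flagged.
#'
#' @param mesh_t0,mesh_t1 surface meshes of the two time points.
#' @param parents tibble `child`, `parent` (children at t1 to mothers at
#'   t0; non-dividing cells appear as child = their own label).
#' @param correspondence tibble `vertex_t0`, `vertex_t1` matching junction
#'   vertices across time; by default vertex indices are shared (as emitted
#'   by the synthetic time-lapse generator and deformation-field transport).
#' @return tibble per mother: `label`, `kmax`, `kmin`, `emax_x/y/z`,
#'   `emin_x/y/z`, `det_f` (areal extension of the fit), `f11,f12,f21,f22`
#'   (F in the tangent frame), `n_landmarks`, `ok`.
#' @export
compute_pdgs <- function(mesh_t0, mesh_t1, parents, correspondence = NULL) {
  if (is.null(correspondence)) {
    nshared <- min(nrow(mesh_t0$vertices), nrow(mesh_t1$vertices))
    correspondence <- tibble::tibble(vertex_t0 = seq_len(nshared),
                                     vertex_t1 = seq_len(nshared))
  }
  v1of0 <- stats::setNames(correspondence$vertex_t1,
                           correspondence$vertex_t0)
  j0 <- mesh_junctions(mesh_t0)
  geo0 <- cell_geometry(mesh_t0)
  # vertex -> incident labels at t0
  tr0 <- mesh_t0$triangles; lab0 <- mesh_t0$face_label
  vl <- unique(data.frame(v = as.vector(tr0), l = rep(lab0, 3L)))
  vl <- vl[vl$v %in% j0 & vl$l > 0L, ]
  mothers <- sort(unique(parents$parent))
  out <- lapply(mothers, function(m) {
    jm <- vl$v[vl$l == m]
    jm <- jm[as.character(jm) %in% names(v1of0)]
    empty <- tibble::tibble(label = m, kmax = NA_real_, kmin = NA_real_,
                            emax_x = NA_real_, emax_y = NA_real_,
                            emax_z = NA_real_, emin_x = NA_real_,
                            emin_y = NA_real_, emin_z = NA_real_,
                            det_f = NA_real_, f11 = NA_real_,
                            f12 = NA_real_, f21 = NA_real_, f22 = NA_real_,
                            n_landmarks = length(jm), ok = FALSE)
    if (length(jm) < 3) return(empty)
    X0 <- mesh_t0$vertices[jm, , drop = FALSE]
    X1 <- mesh_t1$vertices[v1of0[as.character(jm)], , drop = FALSE]
    row <- geo0[geo0$label == m, ]
    b0 <- tangent_basis(c(row$nx, row$ny, row$nz))
    # t1 frame: normal of the daughters' union, x-axis aligned with e1 of t0
    kids <- parents$child[parents$parent == m]
    sel1 <- mesh_t1$face_label %in% kids
    if (!any(sel1)) return(empty)
    n1 <- colSums(tri_normals(mesh_t1$vertices,
                              mesh_t1$triangles[sel1, , drop = FALSE]))
    n1 <- unitv(n1)
    e1p <- b0$e1 - sum(b0$e1 * n1) * n1
    if (vnorm(e1p) < 1e-9) e1p <- b0$e2 - sum(b0$e2 * n1) * n1
    e1p <- unitv(e1p)
    e2p <- cross3(n1, e1p)
    u0 <- sweep(X0, 2, colMeans(X0)) %*% cbind(b0$e1, b0$e2)
    u1 <- sweep(X1, 2, colMeans(X1)) %*% cbind(e1p, e2p)
    # F: u1 ~ u0 %*% t(F); rank check on the landmark configuration
    A <- cbind(u0)
    if (qr(A, tol = 1e-10)$rank < 2) return(empty)
    Ft <- qr.solve(crossprod(A), crossprod(A, u1))  # 2x2, F = t(Ft)
    Fm <- t(Ft)
    sv <- svd(Fm)
    k <- sv$d
    # right stretch tensor U = V diag(k) V'; eigenvectors = V columns
    vmax <- sv$v[, 1]; vmin <- sv$v[, 2]
    emax <- unitv(vmax[1] * b0$e1 + vmax[2] * b0$e2)
    emin <- unitv(vmin[1] * b0$e1 + vmin[2] * b0$e2)
    tibble::tibble(label = m, kmax = k[1], kmin = k[2],
                   emax_x = emax[1], emax_y = emax[2], emax_z = emax[3],
                   emin_x = emin[1], emin_y = emin[2], emin_z = emin[3],
                   det_f = det(Fm), f11 = Fm[1, 1], f12 = Fm[1, 2],
                   f21 = Fm[2, 1], f22 = Fm[2, 2],
                   n_landmarks = length(jm), ok = TRUE)
  })
  dplyr::bind_rows(out)
}

#' Areal (or volumetric) extension per mother cell
#'
#' Ratio of the summed daughter sizes at t1 to the mother's size at t0;
#' areas for surface meshes, volumes for volumetric meshes. Mothers with
#' missing daughters are unassigned.
#'
#' @param mesh_t0,mesh_t1 meshes of matching kind.
#' @param parents tibble `child`, `parent`.
#' @return tibble `label`, `extension`.
#' @export
areal_extension <- function(mesh_t0, mesh_t1, parents) {
  size <- function(mesh) {
    if (inherits(mesh, "volumetric_cell_mesh")) {
      g <- cell_geometry_3d(mesh)
      stats::setNames(g$volume, g$label)
    } else {
      g <- cell_geometry(mesh)
      stats::setNames(g$area, g$label)
    }
  }
  s0 <- size(mesh_t0); s1 <- size(mesh_t1)
  mothers <- sort(unique(parents$parent))
  ext <- vapply(mothers, function(m) {
    kids <- as.character(parents$child[parents$parent == m])
    if (!all(kids %in% names(s1)) || !(as.character(m) %in% names(s0)))
      return(NA_real_)
    sum(s1[kids]) / s0[as.character(m)]
  }, 0)
  tibble::tibble(label = mothers, extension = as.numeric(ext))
}

#' Proliferation: number of terminal descendants per ancestor
#'
#' Composes one or more child-to-parent maps over successive intervals and
#' counts, for every ancestor cell of the first time point, how many cells
#' of the final time point descend from it. A non-dividing cell has
#' proliferation 1; a mother that divided exactly once has proliferation 2.
#'
#' @param parents a tibble `child`, `parent`, or a list of them ordered
#'   from the earliest interval to the latest.
#' @return tibble `label` (ancestor), `proliferation` (cell count).
#' @export
proliferation <- function(parents) {
  if (is.data.frame(parents)) parents <- list(parents)
  for (i in seq_along(parents)[-1]) {
    prev_children <- parents[[i - 1]]$child
    missing <- setdiff(unique(parents[[i]]$parent), prev_children)
    if (length(missing))
      stop("children reference parents absent from the previous interval: ",
           paste(missing, collapse = ", "))
  }
  # map each terminal cell back to its earliest ancestor
  last <- parents[[length(parents)]]
  anc <- stats::setNames(last$parent, last$child)
  if (length(parents) > 1) {
    for (i in rev(seq_len(length(parents) - 1))) {
      lk <- stats::setNames(parents[[i]]$parent, parents[[i]]$child)
      anc <- lk[as.character(anc)]
      names(anc) <- last$child
    }
  }
  cnt <- table(anc)
  tibble::tibble(label = as.integer(names(cnt)),
                 proliferation = as.integer(cnt)) |>
    dplyr::arrange(.data$label)
}

#' Project a growth tensor onto a direction
#'
#' Stretch of a material fiber initially along direction d: |F d|, with F
#' the cell's deformation gradient in its t0 tangent frame. The
#' perpendicular component is the same quantity for the in-frame
#' orthogonal of d. Equals kmax (kmin) when d is the corresponding
#' principal direction, and for a pure axis-aligned stretch it reproduces
#' the axis stretches exactly.
#'
#' @param tensor one row of [compute_pdgs()] output, or a list/row with
#'   `f11,f12,f21,f22` and the frame columns, or a plain 2x2/3x3 matrix F.
#' @param direction direction in the tensor's frame: length-2 vector for a
#'   2x2 F (tangent-frame coordinates), length-3 for 3D.
#' @return scalar stretch ratio (dimensionless).
#' @export
project_growth <- function(tensor, direction) {
  Fm <- if (is.matrix(tensor)) tensor
        else matrix(c(tensor$f11, tensor$f21, tensor$f12, tensor$f22), 2)
  d <- as.numeric(direction)
  stopifnot(length(d) == ncol(Fm))
  n <- vnorm(d)
  if (abs(n - 1) > 1e-8) {
    warning("direction is not unit length; normalizing")
    d <- d / n
  }
  vnorm(Fm %*% d)
}

#' Change map of an attribute across a tracked interval
#'
#' Per-mother change of an attribute between time points, with daughters
#' aggregated by sum (sizes) or mean (intensities). Modes: `ratio`
#' (t1/t0), `percent` (100 * (t1 - t0)/t0), `difference` (t1 - t0, in the
#' attribute's units).
#'
#' @param attr_t0,attr_t1 tibbles `label`, value (second column).
#' @param parents tibble `child`, `parent`.
#' @param mode `"ratio"`, `"percent"` or `"difference"`.
#' @param aggregate `"sum"` or `"mean"` over daughters.
#' @return tibble `label`, `change`.
#' @export
change_map <- function(attr_t0, attr_t1, parents,
                       mode = c("ratio", "percent", "difference"),
                       aggregate = c("sum", "mean")) {
  mode <- match.arg(mode)
  aggregate <- match.arg(aggregate)
  v0 <- stats::setNames(attr_t0[[2]], attr_t0$label)
  v1 <- stats::setNames(attr_t1[[2]], attr_t1$label)
  mothers <- sort(unique(parents$parent))
  agg <- vapply(mothers, function(m) {
    kids <- as.character(parents$child[parents$parent == m])
    if (!all(kids %in% names(v1))) return(NA_real_)
    if (aggregate == "sum") sum(v1[kids]) else mean(v1[kids])
  }, 0)
  base <- v0[as.character(mothers)]
  ch <- switch(mode,
               ratio = agg / base,
               percent = 100 * (agg - base) / base,
               difference = agg - base)
  tibble::tibble(label = mothers, change = as.numeric(ch))
}
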