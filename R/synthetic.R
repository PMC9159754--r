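# Synthetic-tissue generators. Every generator is deterministic per seed and
# emits ground truth consistent with the meshes, so each analysis algorithm
# can be tested against known answers without microscopy data.

with_seed <- function(seed, code) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  code
}

#' Generate a segmented 2.5D epidermal tissue
#'
#' Lloyd-relaxed Voronoi cells tiling a square parametric domain, lifted
#' onto a plane, paraboloid or sphere cap and fan-triangulated with
#' per-face cell labels. Cell polygons partition the domain exactly;
#' junction vertices arise where three cells (or two cells and the tissue
#' border) meet. Optional midpoint subdivision refines the triangulation
#' for vertex-resolved signal fields.
#'
#' @param n_cells number of cells.
#' @param surface `"plane"`, `"paraboloid"` or `"sphere_cap"`.
#' @param seed RNG seed (bit-reproducible output per seed).
#' @param cell_area target mean cell area in um^2 (default 25, a typical
#'   epidermal cell footprint).
#' @param lloyd_iters Lloyd relaxation rounds (default 5).
#' @param refine rounds of 4-way midpoint triangle subdivision.
#' @param bend_radius curvature radius of the lifted surface in um
#'   (paraboloid / sphere cap; default 4 x domain side).
#' @return list with `mesh` (a [surface_cell_mesh()]) and `truth` (tibble
#'   `label`, `seed_x`, `seed_y`; plus the domain side `L` as attribute).
#' @export
make_surface_tissue <- function(n_cells, surface = c("plane", "paraboloid",
                                                     "sphere_cap"),
                                seed = 1, cell_area = 25, lloyd_iters = 5,
                                refine = 0, bend_radius = NULL) {
  surface <- match.arg(surface)
  stopifnot(n_cells >= 1)
  L <- sqrt(n_cells * cell_area)
  pts <- with_seed(seed, matrix(stats::runif(2 * n_cells), ncol = 2) * L)
  for (it in seq_len(lloyd_iters)) {
    polys <- voronoi_cells(pts, L)
    pts <- do.call(rbind, lapply(polys, polygon_centroid_2d))
  }
  polys <- voronoi_cells(pts, L)
  lift <- surface_lift(surface, L, bend_radius)
  mesh <- polygons_to_mesh(polys, lift)
  if (refine > 0) mesh <- subdivide_mesh(mesh, refine)
  truth <- tibble::tibble(label = seq_len(n_cells),
                          seed_x = pts[, 1], seed_y = pts[, 2])
  attr(truth, "L") <- L
  list(mesh = mesh, truth = truth)
}

surface_lift <- function(surface, L, bend_radius = NULL) {
  R <- bend_radius %||% (4 * L)
  switch(surface,
    plane = function(xy) cbind(xy, 0),
    paraboloid = function(xy) {
      u <- xy[, 1] - L / 2; v <- xy[, 2] - L / 2
      cbind(xy, -(u^2 + v^2) / (2 * R))
    },
    sphere_cap = function(xy) {
      u <- xy[, 1] - L / 2; v <- xy[, 2] - L / 2
      cbind(xy, sqrt(pmax(R^2 - u^2 - v^2, 0)) - R)
    })
}

# Voronoi polygons (convex, CCW) by half-plane clipping of the domain
# rectangle against the nearest neighbor seeds
voronoi_cells <- function(pts, L, k_near = 30) {
  n <- nrow(pts)
  lapply(seq_len(n), function(i) {
    poly <- rbind(c(0, 0), c(L, 0), c(L, L), c(0, L))
    d2 <- rowSums(sweep(pts, 2, pts[i, ])^2)
    nbrs <- order(d2)[-1]
    nbrs <- nbrs[seq_len(min(k_near, length(nbrs)))]
    for (j in nbrs) {
      m <- (pts[i, ] + pts[j, ]) / 2
      nrm <- pts[j, ] - pts[i, ]
      poly <- clip_halfplane(poly, m, nrm)
      if (nrow(poly) < 3) break
    }
    poly
  })
}

# Sutherland-Hodgman clip: keep points with (x - m) . nrm <= 0
clip_halfplane <- function(poly, m, nrm) {
  n <- nrow(poly)
  out <- list()
  h <- as.numeric(sweep(poly, 2, m) %*% nrm)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (h[i] <= 0) out[[length(out) + 1L]] <- poly[i, ]
    if ((h[i] <= 0) != (h[j] <= 0)) {
      t <- h[i] / (h[i] - h[j])
      out[[length(out) + 1L]] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  if (!length(out)) return(poly[0, , drop = FALSE])
  res <- do.call(rbind, out)
  # drop near-duplicate consecutive vertices
  keep <- c(TRUE, rowSums((res[-1, , drop = FALSE] -
                           res[-nrow(res), , drop = FALSE])^2) > 1e-18)
  res <- res[keep, , drop = FALSE]
  if (nrow(res) > 1 && sum((res[1, ] - res[nrow(res), ])^2) <= 1e-18)
    res <- res[-nrow(res), , drop = FALSE]
  res
}

# assemble labeled fan-triangulated mesh from 2D polygons + lift function
polygons_to_mesh <- function(polys, lift) {
  keymap <- new.env(hash = TRUE); pool <- list(); nv <- 0L
  get_id <- function(p3) {
    k <- paste(round(p3, 6), collapse = "|")
    j <- keymap[[k]]
    if (is.null(j)) {
      nv <<- nv + 1L; keymap[[k]] <- nv; pool[[nv]] <<- p3; j <- nv
    }
    j
  }
  tris <- list(); labs <- integer(0)
  for (ci in seq_along(polys)) {
    xy <- polys[[ci]]
    if (nrow(xy) < 3) stop("degenerate Voronoi cell ", ci)
    if (polygon_area_2d(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), ]
    ids <- vapply(seq_len(nrow(xy)),
                  function(i) get_id(lift(xy[i, , drop = FALSE])[1, ]), 0L)
    ctr <- matrix(polygon_centroid_2d(xy), 1)
    cid <- get_id(lift(ctr)[1, ])
    m <- length(ids)
    for (i in seq_len(m)) {
      j <- if (i == m) 1L else i + 1L
      tris[[length(tris) + 1L]] <- c(cid, ids[i], ids[j])
      labs <- c(labs, ci)
    }
  }
  surface_cell_mesh(do.call(rbind, pool), do.call(rbind, tris), labs)
}

#' 4-way midpoint subdivision of a labeled surface mesh
#'
#' Each triangle splits into four via shared edge midpoints; labels are
#' inherited and any vertex signal is linearly interpolated.
#'
#' @param mesh a [surface_cell_mesh()].
#' @param rounds number of subdivision rounds.
#' @return the refined [surface_cell_mesh()].
#' @export
subdivide_mesh <- function(mesh, rounds = 1) {
  for (r in seq_len(rounds)) {
    v <- mesh$vertices
    sig <- mesh$vertex_signal
    midmap <- new.env(hash = TRUE)
    newv <- list(); nn <- nrow(v)
    midpoint <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      j <- midmap[[k]]
      if (is.null(j)) {
        nn <<- nn + 1L
        newv[[length(newv) + 1L]] <<- list(id = nn, a = a, b = b)
        midmap[[k]] <- nn
        j <- nn
      }
      j
    }
    tr <- mesh$triangles
    nt <- nrow(tr)
    out <- matrix(0L, 4L * nt, 3L)
    for (i in seq_len(nt)) {
      a <- tr[i, 1]; b <- tr[i, 2]; c_ <- tr[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      out[4 * i - 3, ] <- c(a, ab, ca)
      out[4 * i - 2, ] <- c(ab, b, bc)
      out[4 * i - 1, ] <- c(ca, bc, c_)
      out[4 * i, ] <- c(ab, bc, ca)
    }
    addv <- do.call(rbind, lapply(newv, function(e) (v[e$a, ] + v[e$b, ]) / 2))
    v2 <- rbind(v, addv)
    sig2 <- if (is.null(sig)) NULL else
      c(sig, vapply(newv, function(e) (sig[e$a] + sig[e$b]) / 2, 0))
    mesh <- surface_cell_mesh(v2, out, rep(mesh$face_label, each = 4L), sig2)
  }
  mesh
}

#' Generate a layered cylindrical 3D organ
#'
#' Concentric layers of watertight wedge cells around a straight or bent
#' centerline: `n_layers` radial layers x `cells_per_ring` sectors x
#' `n_rings` longitudinal rings, with matched shared walls tagged by
#' neighbor label and the outer/end walls tagged 0. Ground truth records
#' each cell's layer (1 = innermost), sector, ring and mid-layer relative
#' radial coordinate. With `core = TRUE` the innermost layer is a single
#' central cell file (one prism per ring), providing an explicit axis file
#' for organ-axis fitting.
#'
#' @param n_layers,cells_per_ring,n_rings tissue dimensions (positive).
#' @param curvature centerline curvature in 1/um (0 = straight; must be
#'   < 1/radius).
#' @param seed RNG seed (kept for interface symmetry; construction is
#'   deterministic).
#' @param radius organ radius in um.
#' @param ring_height cell height along the axis in um.
#' @param n_arc arc subdivisions per sector (roundness of walls).
#' @param core make layer 1 a single axial cell file.
#' @return list with `mesh` (a [volumetric_cell_mesh()]) and `truth`
#'   (tibble `label`, `layer`, `sector`, `ring`, `rel_radial`), plus
#'   `centerline` (function t -> 3D point, t in um along the axis) and
#'   `axis_length`.
#' @export
make_organ_3d <- function(n_layers, cells_per_ring, n_rings, curvature = 0,
                          seed = 1, radius = 20, ring_height = 8,
                          n_arc = 2, core = FALSE) {
  stopifnot(n_layers >= 1, cells_per_ring >= 3, n_rings >= 1)
  if (curvature < 0 || (curvature > 0 && curvature >= 1 / radius))
    stop("curvature must be in [0, 1/radius)")
  S <- cells_per_ring
  radii <- radius * (0:n_layers) / n_layers
  zs <- ring_height * (0:n_rings)
  lab_of <- function(l, j, k) {
    if (core) {
      if (l == 1) return((k - 1L) * (1L + (n_layers - 1L) * S) + 1L)
      (k - 1L) * (1L + (n_layers - 1L) * S) + 1L + (l - 2L) * S + j
    } else (k - 1L) * n_layers * S + (l - 1L) * S + j
  }
  bend <- if (curvature > 0) {
    Rb <- 1 / curvature
    function(p) {
      phi <- p[, 3] / Rb
      cbind(Rb - (Rb - p[, 1]) * cos(phi), p[, 2],
            (Rb - p[, 1]) * sin(phi))
    }
  } else identity
  cells <- list(); truth <- list()
  add_cell <- function(label, quads, tags, l, j, k, ra, rb) {
    keymap <- new.env(hash = TRUE); pool <- list(); nv <- 0L
    tris <- list(); tg <- integer(0)
    for (qi in seq_along(quads)) {
      q <- quads[[qi]]
      # drop duplicated corners (degenerate at the axis)
      keep <- !duplicated(round(q, 9))
      q <- q[keep, , drop = FALSE]
      if (nrow(q) < 3) next
      ids <- integer(nrow(q))
      keys <- apply(round(q, 9), 1, paste, collapse = "|")
      for (i in seq_len(nrow(q))) {
        jx <- keymap[[keys[i]]]
        if (is.null(jx)) {
          nv <- nv + 1L; keymap[[keys[i]]] <- nv; pool[[nv]] <- q[i, ]
          jx <- nv
        }
        ids[i] <- jx
      }
      if (nrow(q) == 3) {
        tris[[length(tris) + 1L]] <- matrix(ids, 1)
        tg <- c(tg, tags[qi])
      } else {
        tris[[length(tris) + 1L]] <- rbind(ids[c(1, 2, 3)], ids[c(1, 3, 4)])
        tg <- c(tg, tags[qi], tags[qi])
      }
    }
    V <- do.call(rbind, pool)
    cells[[as.character(label)]] <<- list(vertices = bend(V),
                                          triangles = do.call(rbind, tris),
                                          wall_tag = tg)
    truth[[length(truth) + 1L]] <<- tibble::tibble(
      label = label, layer = l, sector = if (core && l == 1) NA_integer_
      else j, ring = k, rel_radial = ((ra + rb) / 2) / radius)
  }
  cyl <- function(r, th, z) c(r * cos(th), r * sin(th), z)
  for (k in seq_len(n_rings)) {
    z0 <- zs[k]; z1 <- zs[k + 1]
    for (l in seq_len(n_layers)) {
      if (core && l == 1) {
        # central prism: polygonal cross-section with S * n_arc sides
        r1 <- radii[2]
        ths <- seq(0, 2 * pi, length.out = S * n_arc + 1)
        quads <- list(); tags <- integer(0)
        for (ti in seq_len(length(ths) - 1)) {
          tha <- ths[ti]; thb <- ths[ti + 1]
          quads[[length(quads) + 1L]] <- rbind(cyl(r1, tha, z0),
                                               cyl(r1, thb, z0),
                                               cyl(r1, thb, z1),
                                               cyl(r1, tha, z1))
          jj <- ((ti - 1L) %/% n_arc) + 1L
          tags <- c(tags, if (n_layers > 1) lab_of(2, jj, k) else 0L)
        }
        # caps: fans from the axis
        for (ti in seq_len(length(ths) - 1)) {
          tha <- ths[ti]; thb <- ths[ti + 1]
          quads[[length(quads) + 1L]] <- rbind(cyl(0, 0, z1),
                                               cyl(r1, tha, z1),
                                               cyl(r1, thb, z1))
          tags <- c(tags, if (k < n_rings) lab_of(1, 1, k + 1) else 0L)
          quads[[length(quads) + 1L]] <- rbind(cyl(0, 0, z0),
                                               cyl(r1, thb, z0),
                                               cyl(r1, tha, z0))
          tags <- c(tags, if (k > 1) lab_of(1, 1, k - 1) else 0L)
        }
        add_cell(lab_of(1, 1, k), quads, tags, 1L, 1L, k, 0, radii[2])
        next
      }
      ra <- radii[l]; rb <- radii[l + 1]
      for (j in seq_len(S)) {
        th0 <- 2 * pi * (j - 1) / S
        th1 <- 2 * pi * j / S
        ths <- seq(th0, th1, length.out = n_arc + 1)
        lb <- lab_of(l, j, k)
        quads <- list(); tags <- integer(0)
        jm <- if (j == 1) S else j - 1L
        jp <- if (j == S) 1L else j + 1L
        for (ti in seq_len(n_arc)) {
          tha <- ths[ti]; thb <- ths[ti + 1]
          # outer radial wall (+r)
          quads[[length(quads) + 1L]] <- rbind(cyl(rb, tha, z0),
                                               cyl(rb, thb, z0),
                                               cyl(rb, thb, z1),
                                               cyl(rb, tha, z1))
          tags <- c(tags, if (l < n_layers) lab_of(l + 1, j, k) else 0L)
          # inner radial wall (-r), absent at the axis
          if (ra > 0) {
            quads[[length(quads) + 1L]] <- rbind(cyl(ra, thb, z0),
                                                 cyl(ra, tha, z0),
                                                 cyl(ra, tha, z1),
                                                 cyl(ra, thb, z1))
            tags <- c(tags, if (l > 1)
              (if (core && l == 2) lab_of(1, 1, k) else lab_of(l - 1, j, k))
              else 0L)
          }
          # top cap (+z) and bottom cap (-z)
          quads[[length(quads) + 1L]] <- rbind(cyl(ra, tha, z1),
                                               cyl(rb, tha, z1),
                                               cyl(rb, thb, z1),
                                               cyl(ra, thb, z1))
          tags <- c(tags, if (k < n_rings) lab_of(l, j, k + 1) else 0L)
          quads[[length(quads) + 1L]] <- rbind(cyl(ra, thb, z0),
                                               cyl(rb, thb, z0),
                                               cyl(rb, tha, z0),
                                               cyl(ra, tha, z0))
          tags <- c(tags, if (k > 1) lab_of(l, j, k - 1) else 0L)
        }
        # azimuthal walls at th0 (-theta) and th1 (+theta)
        quads[[length(quads) + 1L]] <- rbind(cyl(ra, th0, z0),
                                             cyl(rb, th0, z0),
                                             cyl(rb, th0, z1),
                                             cyl(ra, th0, z1))
        tags <- c(tags, lab_of(l, jm, k))
        quads[[length(quads) + 1L]] <- rbind(cyl(rb, th1, z0),
                                             cyl(ra, th1, z0),
                                             cyl(ra, th1, z1),
                                             cyl(rb, th1, z1))
        tags <- c(tags, lab_of(l, jp, k))
        add_cell(lb, quads, tags, l, j, k, ra, rb)
      }
    }
  }
  centerline <- if (curvature > 0) {
    Rb <- 1 / curvature
    function(t) cbind(Rb - Rb * cos(t / Rb), 0 * t, Rb * sin(t / Rb))
  } else function(t) cbind(0 * t, 0 * t, t)
  list(mesh = volumetric_cell_mesh(cells),
       truth = dplyr::bind_rows(truth),
       centerline = centerline,
       axis_length = ring_height * n_rings)
}

# analytic deformation families for time-lapse generation; each returns
# list(f = point map (n x 3 -> n x 3), J = Jacobian at a single point)
timelapse_deformation <- function(kind, params, domain_size) {
  L <- domain_size
  switch(kind,
    affine = {
      A <- params$A %||% diag(c(2, 1, 1))
      tr <- params$t %||% c(0, 0, 0)
      if (det(A) <= 0) stop("deformation is not orientation-preserving")
      list(f = function(p) sweep(p %*% t(A), 2, tr, `+`),
           J = function(x) A)
    },
    radial_gradient = {
      a <- params$a %||% 0.5
      if (a <= -1) stop("deformation is not invertible on the domain")
      list(f = function(p) cbind(p[, 1] * (1 + a * p[, 1] / (2 * L)),
                                 p[, 2] * (1 + a * p[, 1] / L),
                                 p[, 3]),
           J = function(x) matrix(c(1 + a * x[1] / L, a * x[2] / L, 0,
                                    0, 1 + a * x[1] / L, 0,
                                    0, 0, 1), 3, 3))
    },
    bending = {
      cc <- params$curvature %||% (0.5 / L)
      list(f = function(p) {
        phi <- cc * p[, 1]
        cbind((1 / cc + p[, 3]) * sin(phi), p[, 2],
              (1 / cc + p[, 3]) * cos(phi) - 1 / cc)
      },
      J = function(x) {
        phi <- cc * x[1]
        matrix(c((1 + cc * x[3]) * cos(phi), 0, -(1 + cc * x[3]) * sin(phi),
                 0, 1, 0,
                 sin(phi), 0, cos(phi)), 3, 3)
      })
    },
    stop("unknown deformation kind: ", kind))
}

#' Apply an analytic growth deformation (with optional divisions)
#'
#' Maps all mesh vertices through a smooth, orientation-preserving
#' deformation (`affine`, `radial_gradient` growth along x, or `bending`)
#' and then splits a seeded fraction of cells by a straight wall through
#' their centroid (shortest-wall or random orientation), retriangulating
#' the daughters. Vertex indices of the undivided tissue are preserved, so
#' junction correspondence across the pair is the identity. The returned
#' ground truth carries the analytic map and its Jacobian.
#'
#' @param tissue a [surface_cell_mesh()] (or the list returned by
#'   [make_surface_tissue()]).
#' @param kind `"affine"`, `"radial_gradient"` or `"bending"`.
#' @param params deformation parameters (see details: `A`, `t`; `a`;
#'   `curvature`).
#' @param division_rate fraction of cells that divide once.
#' @param seed RNG seed for division choice/orientation.
#' @param orientation `"shortest"` (wall along the minimal chord) or
#'   `"random"`.
#' @return list with `mesh_t1`, `parents` (tibble `child`, `parent`,
#'   identity rows for undivided cells), `divided` (mother labels),
#'   `map` and `jacobian` (functions), `kind`.
#' @export
apply_timelapse <- function(tissue, kind = "affine", params = list(),
                            division_rate = 0, seed = 1,
                            orientation = c("shortest", "random")) {
  orientation <- match.arg(orientation)
  mesh <- if (inherits(tissue, "surface_cell_mesh")) tissue else tissue$mesh
  L <- max(apply(mesh$vertices, 2, function(x) diff(range(x))))
  def <- timelapse_deformation(kind, params, L)
  m1 <- mesh
  m1$vertices <- def$f(mesh$vertices)
  labs <- mesh_labels(mesh)
  parents <- tibble::tibble(child = labs, parent = labs)
  divided <- integer(0)
  if (division_rate > 0) {
    n_div <- floor(division_rate * length(labs))
    mothers <- with_seed(seed, sample(labs, n_div))
    angles <- with_seed(seed + 1, stats::runif(n_div, 0, 180))
    next_label <- max(labs)
    for (di in seq_along(mothers)) {
      m <- mothers[di]
      res <- split_surface_cell(m1, m, next_label + 1L, next_label + 2L,
                                orientation, angles[di])
      if (is.null(res)) next
      m1 <- res
      divided <- c(divided, m)
      parents <- parents[parents$child != m, ]
      parents <- dplyr::bind_rows(parents,
        tibble::tibble(child = c(next_label + 1L, next_label + 2L),
                       parent = c(m, m)))
      next_label <- next_label + 2L
    }
  }
  list(mesh_t1 = m1, parents = dplyr::arrange(parents, .data$child),
       divided = sort(divided), map = def$f, jacobian = def$J, kind = kind)
}

# split one (convex) surface cell by a plane through its centroid; returns
# the modified mesh or NULL when the cut is degenerate
split_surface_cell <- function(mesh, label, lab1, lab2, orientation,
                               random_angle) {
  poly <- tryCatch(cell_polygon_2d(mesh, label), error = function(e) NULL)
  if (is.null(poly)) return(NULL)
  ctr2 <- polygon_centroid_2d(poly$xy)
  theta <- if (orientation == "random") random_angle else {
    cand <- seq(0, 179, by = 1)
    lens <- vapply(cand, function(th)
      chord_length_through(poly$xy, ctr2,
                           c(cos(th * pi / 180), sin(th * pi / 180))), 0)
    cand[which.min(lens)]
  }
  d2 <- c(cos(theta * pi / 180), sin(theta * pi / 180))
  n2 <- c(-d2[2], d2[1])
  h <- as.numeric(sweep(poly$xy, 2, ctr2) %*% n2)
  m <- nrow(poly$xy)
  crossings <- integer(0)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    if ((h[i] < 0) != (h[j] < 0)) crossings <- c(crossings, i)
  }
  if (length(crossings) != 2) return(NULL)
  # 3D crossing points on the boundary edges
  cross_pt <- function(i) {
    j <- if (i == m) 1L else i + 1L
    t <- h[i] / (h[i] - h[j])
    a <- mesh$vertices[poly$loop[i], ]
    b <- mesh$vertices[poly$loop[j], ]
    a + t * (b - a)
  }
  p1 <- cross_pt(crossings[1]); p2 <- cross_pt(crossings[2])
  v <- mesh$vertices
  id1 <- nrow(v) + 1L; id2 <- nrow(v) + 2L
  v <- rbind(v, p1, p2)
  # boundary ids split into the two daughter chains
  i1 <- crossings[1]; i2 <- crossings[2]
  seq_wrap <- function(a, b) if (a <= b) seq(a, b) else c(seq(a, m), seq(1, b))
  chainA <- c(id1, poly$loop[seq_wrap((i1 %% m) + 1L, i2)], id2)
  chainB <- c(id2, poly$loop[seq_wrap((i2 %% m) + 1L, i1)], id1)
  sig <- mesh$vertex_signal
  if (!is.null(sig)) {
    interp_sig <- function(i, p) {
      j <- if (i == m) 1L else i + 1L
      t <- h[i] / (h[i] - h[j])
      sig[poly$loop[i]] + t * (sig[poly$loop[j]] - sig[poly$loop[i]])
    }
    sig <- c(sig, interp_sig(crossings[1]), interp_sig(crossings[2]))
  }
  fan <- function(chain, lab) {
    ctr <- colMeans(v[chain, , drop = FALSE])
    cid <- nrow(v) + 1L
    v <<- rbind(v, ctr)
    if (!is.null(sig)) sig <<- c(sig, mean(sig[chain]))
    nc <- length(chain)
    tr <- t(vapply(seq_len(nc), function(i) {
      j <- if (i == nc) 1L else i + 1L
      c(cid, chain[i], chain[j])
    }, integer(3)))
    list(tr = tr, lab = rep(lab, nc))
  }
  fa <- fan(chainA, lab1)
  fb <- fan(chainB, lab2)
  keep <- mesh$face_label != label
  surface_cell_mesh(v,
                    rbind(mesh$triangles[keep, , drop = FALSE], fa$tr, fb$tr),
                    c(mesh$face_label[keep], fa$lab, fb$lab),
                    sig)
}

#' Plant a per-vertex signal field with known structure
#'
#' Signal kinds: `polarized` (signal accumulates on the side of each cell
#' facing a planted direction, sharpness-controlled von-Mises-like
#' profile), `striped` (sinusoidal stripes of a given axial orientation
#' and wavelength, emulating a fibril texture), `uniform`, and `noise`
#' (log-normal multiplicative noise, reflecting fluorescence statistics).
#' The planted direction/orientation is returned as ground truth.
#'
#' @param mesh a [surface_cell_mesh()].
#' @param kind `"polarized"`, `"striped"`, `"uniform"` or `"noise"`.
#' @param direction planted polarity direction (3-vector, `polarized`).
#' @param sharpness concentration of the polarized profile (default 4).
#' @param orientation_deg stripe (fibril) axial direction in degrees in
#'   the xy-plane (`striped`).
#' @param wavelength stripe wavelength in um; must exceed twice the median
#'   edge length (aliasing guard).
#' @param noise_sd log-normal sigma applied multiplicatively (0 = none).
#' @param seed RNG seed for noise.
#' @return list with `mesh` (signal attached) and `truth` (list with the
#'   planted parameters).
#' @export
make_signal_field <- function(mesh, kind = c("polarized", "striped",
                                             "uniform", "noise"),
                              direction = c(1, 0, 0), sharpness = 4,
                              orientation_deg = 0, wavelength = 10,
                              noise_sd = 0, seed = 1) {
  kind <- match.arg(kind)
  v <- mesh$vertices
  med_edge <- stats::median(sqrt(rowSums((v[mesh$triangles[, 1], ] -
                                          v[mesh$triangles[, 2], ])^2)))
  sig <- switch(kind,
    uniform = rep(1, nrow(v)),
    noise = with_seed(seed, stats::rlnorm(nrow(v), 0,
                                          max(noise_sd, 0.25))),
    striped = {
      if (wavelength < 2 * med_edge)
        stop("wavelength below twice the vertex spacing (",
             sprintf("%.3g", med_edge), " um): aliasing")
      th <- orientation_deg * pi / 180
      w <- c(-sin(th), cos(th), 0)  # stripes vary perpendicular to fibrils
      1 + cos(2 * pi * (v %*% w) / wavelength)
    },
    polarized = {
      geo <- cell_geometry(mesh)
      own <- vertex_owner_cell(mesh)
      idx <- match(own, geo$label)
      ctr <- as.matrix(geo[idx, c("x", "y", "z")])
      rel <- v - ctr
      nrm <- as.matrix(geo[idx, c("nx", "ny", "nz")])
      rel <- rel - nrm * rowSums(rel * nrm)
      rn <- sqrt(rowSums(rel * rel))
      rn[rn < 1e-12] <- 1
      d <- unitv(direction)
      exp(sharpness * (rel %*% d) / rn)
    })
  if (noise_sd > 0 && kind != "noise")
    sig <- sig * with_seed(seed, stats::rlnorm(length(sig), 0, noise_sd))
  mesh$vertex_signal <- as.numeric(sig)
  list(mesh = mesh,
       truth = list(kind = kind, direction = unitv(direction),
                    orientation_deg = orientation_deg,
                    wavelength = wavelength))
}

# owning cell per vertex: the lowest incident label
vertex_owner_cell <- function(mesh) {
  own <- rep(NA_integer_, nrow(mesh$vertices))
  tr <- mesh$triangles; lab <- mesh$face_label
  for (k in 1:3) {
    ids <- tr[, k]
    cur <- own[ids]
    repl <- is.na(cur) | lab < cur
    own[ids[repl & lab > 0]] <- lab[repl & lab > 0]
  }
  own
}

#' Planted 2D feature blobs for classifier tests
#'
#' Gaussian blobs in a two-feature plane with known class assignment.
#'
#' @param n_per_class points per class.
#' @param centers k x 2 matrix of blob centers.
#' @param sd within-blob standard deviation.
#' @param seed RNG seed.
#' @return tibble `label`, `f1`, `f2`, `class`.
#' @export
make_feature_blobs <- function(n_per_class = 25,
                               centers = rbind(c(0, 0), c(5, 5)),
                               sd = 0.5, seed = 1) {
  k <- nrow(centers)
  with_seed(seed, {
    f1 <- f2 <- cls <- c()
    for (i in seq_len(k)) {
      f1 <- c(f1, stats::rnorm(n_per_class, centers[i, 1], sd))
      f2 <- c(f2, stats::rnorm(n_per_class, centers[i, 2], sd))
      cls <- c(cls, rep(i, n_per_class))
    }
    tibble::tibble(label = seq_along(f1), f1 = f1, f2 = f2,
                   class = as.integer(cls))
  })
}

#' Icosphere test cell
#'
#' Watertight triangulated sphere (subdivided icosahedron, vertices
#' projected to the radius), used as a reference cell for volumetric
#' measures and division-plane analysis.
#'
#' @param radius sphere radius in um.
#' @param subdiv subdivision rounds (default 3, 1280 triangles).
#' @param center sphere center.
#' @return list with `vertices`, `triangles`, `wall_tag` (all 0).
#' @export
make_sphere_cell <- function(radius = 1, subdiv = 3, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v * v))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7),
             c(8, 2, 9), c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9),
             c(4, 9, 10), c(6, 5, 10), c(5, 12, 3), c(3, 11, 7),
             c(7, 8, 9), c(9, 2, 10))
  for (s in seq_len(subdiv)) {
    midmap <- new.env(hash = TRUE)
    nf <- matrix(0L, 0, 3)
    mid <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      j <- midmap[[k]]
      if (is.null(j)) {
        v <<- rbind(v, unitv(v[a, ] + v[b, ]))
        j <- nrow(v); midmap[[k]] <- j
      }
      j
    }
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- mid(a, b); bc <- mid(b, c_); ca <- mid(c_, a)
      nf <- rbind(nf, c(a, ab, ca), c(ab, b, bc), c(ca, bc, c_),
                  c(ab, bc, ca))
    }
    f <- nf
  }
  # orient all faces outward
  nrm <- tri_normals(v, f)
  cen <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  flip <- rowSums(nrm * cen) < 0
  f[flip, ] <- f[flip, c(1, 3, 2)]
  list(vertices = sweep(v * radius, 2, center, `+`),
       triangles = f, wall_tag = rep(0L, nrow(f)))
}

#' Rectangular grid tissue
#'
#' `nx` x `ny` axis-aligned rectangular cells of size `w` x `h` um on the
#' z = 0 plane -- exact fixtures for adjacency, wall-length and
#' rectangularity checks (diagonal cells share only a corner point, hence
#' are not adjacent).
#'
#' @param nx,ny grid dimensions.
#' @param w,h cell width and height in um.
#' @return a [surface_cell_mesh()]; labels raster-ordered row by row.
#' @export
make_grid_tissue <- function(nx = 2, ny = 2, w = 1, h = 1) {
  polys <- list()
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    x0 <- (i - 1) * w; y0 <- (j - 1) * h
    polys[[length(polys) + 1L]] <- rbind(c(x0, y0), c(x0 + w, y0),
                                         c(x0 + w, y0 + h), c(x0, y0 + h))
  }
  polygons_to_mesh(polys, function(xy) cbind(xy, 0))
}

#' Single-cell mesh from a 2D polygon
#'
#' Fan-triangulates one polygon (CCW) on the z = 0 plane into a one-cell
#' surface mesh -- a direct fixture for contour measures.
#'
#' @param xy k x 2 polygon vertex matrix.
#' @param label cell label.
#' @return a [surface_cell_mesh()].
#' @export
polygon_cell_mesh <- function(xy, label = 1L) {
  xy <- as.matrix(xy)
  if (polygon_area_2d(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), ]
  ctr <- polygon_centroid_2d(xy)
  # star-triangulate from the centroid (valid for star-shaped polygons);
  # for non-star shapes use ear clipping
  n <- nrow(xy)
  if (all(mgcv::in.out(rbind(xy, xy[1, ]),
                       rbind((xy + matrix(ctr, n, 2, byrow = TRUE)) / 2)))) {
    v <- rbind(cbind(xy, 0), c(ctr, 0))
    tr <- t(vapply(seq_len(n), function(i)
      c(n + 1L, i, if (i == n) 1L else i + 1L), integer(3)))
    return(surface_cell_mesh(v, tr, rep(as.integer(label), n)))
  }
  tr <- ear_clip(xy)
  surface_cell_mesh(cbind(xy, 0), tr, rep(as.integer(label), nrow(tr)))
}

# ear-clipping triangulation of a simple CCW polygon (indices into xy)
ear_clip <- function(xy) {
  idx <- seq_len(nrow(xy))
  tris <- matrix(0L, 0, 3)
  cross_z <- function(a, b, c_) (b[1] - a[1]) * (c_[2] - a[2]) -
    (b[2] - a[2]) * (c_[1] - a[1])
  in_tri <- function(p, a, b, c_) {
    d1 <- cross_z(a, b, p); d2 <- cross_z(b, c_, p); d3 <- cross_z(c_, a, p)
    (d1 >= -1e-12) && (d2 >= -1e-12) && (d3 >= -1e-12)
  }
  guard <- 0
  while (length(idx) > 3 && guard < 10000) {
    guard <- guard + 1
    n <- length(idx)
    clipped <- FALSE
    for (k in seq_len(n)) {
      ia <- idx[if (k == 1) n else k - 1]; ib <- idx[k]
      ic <- idx[if (k == n) 1 else k + 1]
      a <- xy[ia, ]; b <- xy[ib, ]; c_ <- xy[ic, ]
      if (cross_z(a, b, c_) <= 1e-14) next
      others <- setdiff(idx, c(ia, ib, ic))
      if (any(vapply(others, function(o) in_tri(xy[o, ], a, b, c_), TRUE)))
        next
      tris <- rbind(tris, c(ia, ib, ic))
      idx <- idx[idx != ib]
      clipped <- TRUE
      break
    }
    if (!clipped) stop("ear clipping failed: polygon may self-intersect")
  }
  rbind(tris, idx)
}
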