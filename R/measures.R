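#' 2.5D geometry measures per cell
#'
#' The surface-cell geometry catalogue: area (summed triangle areas,
#' um^2), perimeter (boundary length, um), major/minor axis lengths and
#' directions from an area-weighted PCA of the triangle centroids in the
#' cell's tangent plane, aspect ratio (major/minor), average/maximum/
#' minimum radius from the cell center to its border (um), and the
#' maximum/minimum distance between neighboring junctions of the cell.
#' Axis lengths use the full-extent convention 2 sqrt(3 lambda), which
#' reproduces the side lengths of a uniform rectangle.
#'
#' @param mesh a [surface_cell_mesh()].
#' @param labels cells to measure (default all).
#' @return tibble, one row per cell.
#' @export
geometry_measures_2d <- function(mesh, labels = NULL) {
  labels <- labels %||% mesh_labels(mesh)
  geo <- cell_geometry(mesh)
  juncs <- mesh_junctions(mesh)
  out <- lapply(labels, function(lb) {
    poly <- cell_polygon_2d(mesh, lb)
    xy <- poly$xy
    row <- geo[geo$label == lb, ]
    # area-weighted PCA over triangle centroids (flattened)
    sel <- mesh$face_label == lb
    tr <- mesh$triangles[sel, , drop = FALSE]
    ar <- tri_areas(mesh$vertices, tr)
    cen3 <- (mesh$vertices[tr[, 1], , drop = FALSE] +
             mesh$vertices[tr[, 2], , drop = FALSE] +
             mesh$vertices[tr[, 3], , drop = FALSE]) / 3
    cen3 <- sweep(cen3, 2, poly$origin)
    uv <- cbind(cen3 %*% poly$basis$e1, cen3 %*% poly$basis$e2)
    w <- ar / sum(ar)
    mu <- colSums(uv * w)
    uvc <- sweep(uv, 2, mu)
    # exact uniform-area covariance: between-triangle (centroid) term plus
    # the within-triangle second moment (1/12) sum (p_i - g)(p_i - g)'
    C <- crossprod(uvc * sqrt(w))
    for (ti in seq_len(nrow(tr))) {
      P3 <- sweep(mesh$vertices[tr[ti, ], , drop = FALSE], 2, poly$origin)
      p2 <- cbind(P3 %*% poly$basis$e1, P3 %*% poly$basis$e2)
      gd <- sweep(p2, 2, colMeans(p2))
      C <- C + w[ti] / 12 * crossprod(gd)
    }
    eg <- eigen(C, symmetric = TRUE)
    len <- 2 * sqrt(3 * pmax(eg$values, 0))
    maj3 <- eg$vectors[1, 1] * poly$basis$e1 +
            eg$vectors[2, 1] * poly$basis$e2
    ctr2 <- polygon_centroid_2d(xy)
    rad <- sqrt(rowSums(sweep(xy, 2, ctr2)^2))
    nseg <- nrow(xy)
    nxt <- c(2:nseg, 1L)
    minr <- min(vapply(seq_len(nseg), function(i)
      point_segment_distance(ctr2, xy[i, ], xy[nxt[i], ]), 0))
    # perimeter-weighted mean boundary radius
    mid <- (xy + xy[nxt, , drop = FALSE]) / 2
    slen <- sqrt(rowSums((xy[nxt, , drop = FALSE] - xy)^2))
    avgr <- sum(sqrt(rowSums(sweep(mid, 2, ctr2)^2)) * slen) / sum(slen)
    # neighboring-junction distances along the ordered boundary
    jv <- poly$loop %in% juncs
    jd_max <- jd_min <- NA_real_
    if (sum(jv) >= 2) {
      jpos <- mesh$vertices[poly$loop[jv], , drop = FALSE]
      njc <- nrow(jpos)
      dd <- sqrt(rowSums((jpos[c(2:njc, 1L), , drop = FALSE] - jpos)^2))
      jd_max <- max(dd); jd_min <- min(dd)
    }
    tibble::tibble(label = lb, area = row$area,
                   perimeter = polygon_perimeter_2d(xy),
                   major_axis = len[1], minor_axis = len[2],
                   aspect_ratio = len[1] / max(len[2], 1e-12),
                   major_x = maj3[1], major_y = maj3[2], major_z = maj3[3],
                   avg_radius = avgr, max_radius = max(rad),
                   min_radius = minr,
                   junction_dist_max = jd_max, junction_dist_min = jd_min)
  })
  dplyr::bind_rows(out)
}

#' Contour-complexity (lobeyness family) measures
#'
#' Dimensionless descriptors of the flattened cell polygon, all equal to 1
#' for simple convex shapes: circularity `P^2 / (4 pi A)`; lobeyness
#' (perimeter over convex-hull perimeter); rectangularity (area over
#' smallest enclosing rectangle area, 1 for rectangles); solidarity
#' (convex-hull area over cell area, larger for complicated contours);
#' visibility_stomata, the probability that the segment between two random
#' boundary points stays inside the polygon (Monte Carlo with a fixed
#' internal seed, 1 for convex shapes); and visibility_pavement = 1 -
#' visibility_stomata.
#'
#' @param mesh a [surface_cell_mesh()].
#' @param labels cells to measure (default all).
#' @param n_pairs Monte Carlo boundary-point pairs for visibility.
#' @param seed fixed seed for the visibility estimate.
#' @return tibble, one row per cell.
#' @export
lobeyness_measures <- function(mesh, labels = NULL, n_pairs = 10000,
                               seed = 0) {
  labels <- labels %||% mesh_labels(mesh)
  out <- lapply(labels, function(lb) {
    xy <- cell_polygon_2d(mesh, lb)$xy
    A <- polygon_area_2d(xy)
    P <- polygon_perimeter_2d(xy)
    h <- grDevices::chull(xy)
    hull <- xy[h, , drop = FALSE]
    hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]  # chull is CW
    hA <- polygon_area_2d(hull)
    hP <- polygon_perimeter_2d(hull)
    vis <- segment_visibility(xy, n_pairs, seed)
    tibble::tibble(label = lb,
                   circularity = P^2 / (4 * pi * A),
                   lobeyness = P / hP,
                   rectangularity = A / min_bounding_rect_area(xy),
                   solidarity = hA / A,
                   visibility_stomata = vis,
                   visibility_pavement = 1 - vis)
  })
  dplyr::bind_rows(out)
}

# probability that the chord between two uniform boundary points lies
# inside the polygon; deterministic given the seed
segment_visibility <- function(xy, n_pairs = 10000, seed = 0) {
  n <- nrow(xy)
  nxt <- c(2:n, 1L)
  el <- sqrt(rowSums((xy[nxt, , drop = FALSE] - xy)^2))
  cum <- c(0, cumsum(el))
  Ptot <- cum[n + 1]
  if (is_convex_polygon(xy)) return(1)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  s <- matrix(stats::runif(2 * n_pairs, 0, Ptot), ncol = 2)
  bp <- function(d) {  # boundary point at arc distance d
    i <- findInterval(d, cum, rightmost.closed = TRUE)
    i[i > n] <- n
    t <- (d - cum[i]) / el[i]
    xy[i, , drop = FALSE] + (xy[nxt[i], , drop = FALSE] - xy[i, , drop = FALSE]) * t
  }
  a <- bp(s[, 1]); b <- bp(s[, 2])
  # segment is visible iff interior sample points along it are all inside
  ts <- seq(0.08, 0.92, length.out = 7)
  inside <- rep(TRUE, n_pairs)
  for (t in ts) {
    p <- a + (b - a) * t
    inside <- inside & mgcv::in.out(rbind(xy, xy[1, ]), p)
  }
  mean(inside)
}

is_convex_polygon <- function(xy, tol = 1e-9) {
  n <- nrow(xy)
  a <- xy[c(2:n, 1L), , drop = FALSE] - xy
  b <- a[c(2:n, 1L), , drop = FALSE]
  cr <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  all(cr > -tol * max(abs(cr)))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' 3D geometry measures per cell
#'
#' Volume by the divergence theorem over the closed cell surface (um^3),
#' total wall area (um^2), outside wall area (patches tagged 0) and the
#' outside wall ratio.
#'
#' @param mesh a [volumetric_cell_mesh()].
#' @return tibble, one row per cell.
#' @export
geometry_measures_3d <- function(mesh) {
  for (nm in names(mesh$cells))
    if (!is_watertight(mesh$cells[[nm]]$triangles))
      stop("cell ", nm, " is not watertight")
  g <- cell_geometry_3d(mesh)
  g[, c("label", "volume", "wall_area", "outside_area", "outside_ratio")]
}

#' Cell length along a direction by ray casting
#'
#' Shoots rays from the cell's (volume) centroid along +d and -d and
#' reports the distance between the two wall hits -- the cell size along an
#' organ-centric direction.
#'
#' @param cell list with `vertices`, `triangles` (closed surface), or a
#'   [volumetric_cell_mesh()] plus `label`.
#' @param direction unit 3-vector.
#' @param label cell label when `cell` is a volumetric mesh.
#' @return length in micrometres (NA if a ray misses).
#' @export
cell_length_along_direction <- function(cell, direction, label = NULL) {
  if (inherits(cell, "volumetric_cell_mesh"))
    cell <- cell$cells[[as.character(label)]]
  d <- unitv(as.numeric(direction))
  ctr <- closed_surface_centroid(cell$vertices, cell$triangles)
  h1 <- ray_mesh_hits(ctr, d, cell$vertices, cell$triangles)
  h2 <- ray_mesh_hits(ctr, -d, cell$vertices, cell$triangles)
  if (!length(h1) || !length(h2)) return(NA_real_)
  min(h1) + min(h2)
}

#' 3D shape analysis by principal component analysis
#'
#' Mass-weighted PCA of interior sample points (e.g. voxel centers of the
#' segmented cell). Axis lengths use the solid-ellipsoid convention
#' `2 sqrt(3 lambda)` (exact extents for boxes and ellipsoids); shape
#' anisotropy is `(max - 0.5 mid - 0.5 min) / (max + mid + min)`,
#' elongation `max/mid` and flatness `mid/min`.
#'
#' @param points k x 3 matrix of interior samples (k >= 4, non-coplanar).
#' @param weights optional per-point mass weights.
#' @return one-row tibble with lengths, unit directions and the three
#'   shape indices.
#' @export
shape_pca_3d <- function(points, weights = NULL) {
  P <- as.matrix(points)
  if (nrow(P) < 4) stop("need at least 4 sample points")
  w <- weights %||% rep(1, nrow(P))
  w <- w / sum(w)
  mu <- colSums(P * w)
  Pc <- sweep(P, 2, mu)
  C <- crossprod(Pc * sqrt(w))
  eg <- eigen(C, symmetric = TRUE)
  if (eg$values[3] < 1e-12 * max(eg$values[1], 1e-300))
    stop("degenerate (coplanar) sample points")
  len <- 2 * sqrt(3 * eg$values)
  tibble::tibble(len_max = len[1], len_mid = len[2], len_min = len[3],
                 max_x = eg$vectors[1, 1], max_y = eg$vectors[2, 1],
                 max_z = eg$vectors[3, 1],
                 mid_x = eg$vectors[1, 2], mid_y = eg$vectors[2, 2],
                 mid_z = eg$vectors[3, 2],
                 min_x = eg$vectors[1, 3], min_y = eg$vectors[2, 3],
                 min_z = eg$vectors[3, 3],
                 anisotropy = (len[1] - 0.5 * len[2] - 0.5 * len[3]) /
                   sum(len),
                 elongation = len[1] / len[2],
                 flatness = len[2] / len[3])
}

#' Interior sample points of a watertight cell
#'
#' Voxel-center samples on a regular grid, kept when inside the closed
#' surface (ray-parity test); used as input to [shape_pca_3d()].
#'
#' @param cell list with `vertices`, `triangles`.
#' @param spacing grid spacing in micrometres.
#' @return k x 3 matrix.
#' @export
cell_interior_samples <- function(cell, spacing = 1) {
  v <- cell$vertices
  gx <- seq(min(v[, 1]) + spacing / 2, max(v[, 1]), by = spacing)
  gy <- seq(min(v[, 2]) + spacing / 2, max(v[, 2]), by = spacing)
  gz <- seq(min(v[, 3]) + spacing / 2, max(v[, 3]), by = spacing)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  dir <- unitv(c(0.57213, 0.31987, 0.75524))  # fixed irrational direction
  keep <- vapply(seq_len(nrow(pts)), function(i) {
    h <- ray_mesh_hits(pts[i, ], dir, cell$vertices, cell$triangles)
    length(h) %% 2 == 1
  }, TRUE)
  pts[keep, , drop = FALSE]
}

#' Cell-network centrality measures
#'
#' Neighbor count, shortest-path betweenness centrality and current-flow
#' (random-walk) betweenness on the cell connectivity graph. Weighted mode
#' uses edge distance 1 / wall measure for shortest paths and wall measure
#' as conductance for current flow. Values are unnormalized by default.
#'
#' @param graph a [build_cell_graph()] result.
#' @param weighting `"unweighted"` or `"inv_wall"`.
#' @param normalized divide betweenness by (n-1)(n-2)/2.
#' @return tibble `label`, `n_neighbors`, `betweenness`,
#'   `current_flow_betweenness`.
#' @export
network_measures <- function(graph, weighting = c("unweighted", "inv_wall"),
                             normalized = FALSE) {
  weighting <- match.arg(weighting)
  g <- as_igraph(graph)
  w <- if (weighting == "inv_wall") 1 / pmax(graph$edges$wall, 1e-9)
       else rep(1, nrow(graph$edges))
  btw <- igraph::betweenness(g, weights = w, directed = FALSE)
  cfb <- current_flow_betweenness(graph, weighting)
  deg <- igraph::degree(g)
  n <- nrow(graph$nodes)
  if (normalized && n > 2) {
    scale <- 2 / ((n - 1) * (n - 2))
    btw <- btw * scale; cfb <- cfb * scale
  }
  tibble::tibble(label = as.integer(names(btw)),
                 n_neighbors = as.integer(deg),
                 betweenness = as.numeric(btw),
                 current_flow_betweenness =
                   as.numeric(cfb[names(btw)])) |>
    dplyr::arrange(.data$label)
}

# Newman's current-flow betweenness from the Laplacian pseudo-inverse;
# connected components handled independently
current_flow_betweenness <- function(graph, weighting = "unweighted") {
  labs <- graph$nodes$label
  out <- stats::setNames(rep(0, length(labs)), labs)
  g <- as_igraph(graph)
  comp <- igraph::components(g)
  for (ci in seq_len(comp$no)) {
    nodes <- names(comp$membership)[comp$membership == ci]
    n <- length(nodes)
    if (n < 3) next
    idx <- stats::setNames(seq_len(n), nodes)
    e <- graph$edges
    sel <- as.character(e$from) %in% nodes
    ef <- idx[as.character(e$from[sel])]
    et <- idx[as.character(e$to[sel])]
    cond <- if (weighting == "inv_wall") e$wall[sel] else rep(1, sum(sel))
    L <- matrix(0, n, n)
    for (k in seq_along(ef)) {
      L[ef[k], et[k]] <- L[ef[k], et[k]] - cond[k]
      L[et[k], ef[k]] <- L[et[k], ef[k]] - cond[k]
    }
    diag(L) <- -rowSums(L)
    Tm <- svd_pinv(L)
    thr <- numeric(n)
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      p <- Tm[, s] - Tm[, t]
      cur <- numeric(n)
      for (k in seq_along(ef)) {
        I <- cond[k] * abs(p[ef[k]] - p[et[k]])
        cur[ef[k]] <- cur[ef[k]] + I
        cur[et[k]] <- cur[et[k]] + I
      }
      tv <- cur / 2
      tv[c(s, t)] <- 0  # endpoints excluded, as in shortest-path counting
      thr <- thr + tv
    }
    out[nodes] <- thr
  }
  out
}

#' Border and interior signal of a cell
#'
#' Area-weighted vertex means of the signal over the whole cell (`total`),
#' over the border region (vertices within `border_width` of the cell
#' outline) and over the interior remainder. An empty interior (border
#' wider than the inradius) is flagged with NA.
#'
#' @param mesh a [surface_cell_mesh()] with `vertex_signal`.
#' @param labels cells to measure (default all).
#' @param border_width border band width in micrometres (default 1).
#' @return tibble `label`, `total`, `border`, `interior`.
#' @export
signal_measures <- function(mesh, labels = NULL, border_width = 1) {
  if (is.null(mesh$vertex_signal)) stop("mesh carries no vertex signal")
  if (border_width < 0) stop("border width must be >= 0")
  labels <- labels %||% mesh_labels(mesh)
  out <- lapply(labels, function(lb) {
    w <- cell_vertex_weights(mesh, lb)
    ids <- as.integer(names(w))
    sig <- mesh$vertex_signal[ids]
    loop <- cell_boundary_loop(mesh, lb)
    bpts <- mesh$vertices[loop, , drop = FALSE]
    nb <- nrow(bpts)
    nxt <- c(2:nb, 1L)
    d2b <- vapply(ids, function(vi) {
      p <- mesh$vertices[vi, ]
      min(vapply(seq_len(nb), function(i)
        point_segment_distance(p, bpts[i, ], bpts[nxt[i], ]), 0))
    }, 0)
    isb <- d2b <= border_width
    wm <- function(sel) if (any(sel)) sum(sig[sel] * w[sel]) / sum(w[sel])
                        else NA_real_
    tibble::tibble(label = lb, total = wm(rep(TRUE, length(sig))),
                   border = wm(isb), interior = wm(!isb))
  })
  dplyr::bind_rows(out)
}

#' Tissue curvature per cell
#'
#' Mean curvature (1/um) from a quadric fit of the surface over all mesh
#' vertices within `radius` of each cell centroid, evaluated in the cell's
#' tangent frame. Sign convention: bumps (convex toward the outside
#' normal) are positive.
#'
#' @param mesh a [surface_cell_mesh()].
#' @param radius neighborhood radius in micrometres.
#' @return tibble `label`, `mean_curvature`.
#' @export
tissue_curvature <- function(mesh, radius) {
  geo <- cell_geometry(mesh)
  v <- mesh$vertices
  med_edge <- stats::median(sqrt(rowSums((v[mesh$triangles[, 1], ] -
                                          v[mesh$triangles[, 2], ])^2)))
  if (radius < med_edge)
    stop("radius is smaller than the local vertex spacing (",
         sprintf("%.3g", med_edge), " um)")
  out <- lapply(seq_len(nrow(geo)), function(i) {
    ctr <- c(geo$x[i], geo$y[i], geo$z[i])
    b <- tangent_basis(c(geo$nx[i], geo$ny[i], geo$nz[i]))
    d2 <- rowSums(sweep(v, 2, ctr)^2)
    sel <- d2 <= radius^2
    P <- sweep(v[sel, , drop = FALSE], 2, ctr)
    u <- P %*% b$e1; w_ <- P %*% b$e2; h <- P %*% b$n
    X <- cbind(1, u, w_, u^2, u * w_, w_^2)
    if (nrow(X) < 6 || qr(X)$rank < 6)
      return(tibble::tibble(label = geo$label[i],
                            mean_curvature = NA_real_))
    cf <- qr.solve(X, h)
    # z = f(u,w); H at the centroid's foot with slopes p, q
    p <- cf[2]; q <- cf[3]; r2 <- 2 * cf[4]; s <- cf[5]; t2 <- 2 * cf[6]
    H <- ((1 + q^2) * r2 - 2 * p * q * s + (1 + p^2) * t2) /
      (2 * (1 + p^2 + q^2)^1.5)
    # surface bending away from the outward normal (cap) => positive
    tibble::tibble(label = geo$label[i], mean_curvature = -H)
  })
  dplyr::bind_rows(out)
}

#' Heat-map smoothing, local maxima and binning
#'
#' `heat_smooth()` replaces each cell's value by the mean over itself and
#' its graph neighbors, repeated `rounds` times. `local_maxima()` returns
#' cells whose value is >= all neighbors, keeping one representative
#' (lowest label) per connected plateau. `heat_bin()` assigns half-open
#' bins `[lo, hi)` of a given width (or count) and reports per-bin mean
#' and standard deviation.
#'
#' @param attr tibble `label`, value (second column).
#' @param graph a [build_cell_graph()] result.
#' @param rounds number of smoothing rounds (>= 0).
#' @return `heat_smooth`: tibble like `attr`.
#' @export
heat_smooth <- function(attr, graph, rounds = 1) {
  if (rounds < 0) stop("rounds must be >= 0")
  vals <- stats::setNames(attr[[2]], attr$label)
  for (r in seq_len(rounds)) {
    new <- vals
    for (lb in names(vals)) {
      nb <- graph_neighbors(graph, as.integer(lb))
      nb <- nb[as.character(nb) %in% names(vals)]
      new[lb] <- mean(c(vals[lb], vals[as.character(nb)]))
    }
    vals <- new
  }
  tibble::tibble(label = as.integer(names(vals)), value = as.numeric(vals))
}

#' @rdname heat_smooth
#' @export
local_maxima <- function(attr, graph) {
  vals <- stats::setNames(attr[[2]], attr$label)
  labs <- as.integer(names(vals))
  cand <- vapply(labs, function(lb) {
    nb <- graph_neighbors(graph, lb)
    nb <- nb[as.character(nb) %in% names(vals)]
    all(vals[[as.character(lb)]] >= vals[as.character(nb)])
  }, TRUE)
  cl <- labs[cand]
  if (!length(cl)) return(integer(0))
  # one representative per connected equal-value plateau: lowest label
  keep <- logical(length(cl))
  visited <- rep(FALSE, length(cl))
  for (i in seq_along(cl)) {
    if (visited[i]) next
    grp <- i
    frontier <- cl[i]
    repeat {
      nbx <- unique(unlist(lapply(frontier, function(l)
        graph_neighbors(graph, l))))
      add <- which(cl %in% nbx & !visited &
                     vals[as.character(cl)] == vals[[as.character(cl[i])]] &
                     !(seq_along(cl) %in% grp))
      if (!length(add)) break
      grp <- c(grp, add)
      visited[add] <- TRUE
      frontier <- cl[add]
    }
    visited[grp] <- TRUE
    keep[grp[which.min(cl[grp])]] <- TRUE
  }
  sort(cl[keep])
}

#' @rdname heat_smooth
#' @param width bin width in the attribute's units (exclusive with `n_bins`).
#' @param n_bins number of equal-width bins.
#' @export
heat_bin <- function(attr, width = NULL, n_bins = NULL) {
  v <- attr[[2]]
  lo <- min(v)
  if (is.null(width)) {
    if (is.null(n_bins)) stop("give either width or n_bins")
    width <- (max(v) - lo) / n_bins
    bin <- pmin(floor((v - lo) / width) + 1L, n_bins)
  } else {
    bin <- floor((v - lo) / width) + 1L
  }
  per_bin <- tibble::tibble(bin = bin, value = v) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop")
  list(bins = tibble::tibble(label = attr$label, bin = as.integer(bin)),
       summary = per_bin)
}
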