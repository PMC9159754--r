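test_that("2D geometry: square, rectangle, and shoelace/edge-sum oracles", {
  sq <- polygon_cell_mesh(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  g <- geometry_measures_2d(sq)
  expect_equal(g$area, 1, tolerance = 1e-12)
  expect_equal(g$perimeter, 4, tolerance = 1e-12)
  r <- geometry_measures_2d(rect_mesh())
  expect_equal(r$aspect_ratio, 2, tolerance = 1e-9)
  expect_equal(r$major_axis, 2, tolerance = 1e-9)
  expect_equal(abs(r$major_x), 1, tolerance = 1e-9)
  expect_equal(r$max_radius, sqrt(1.25), tolerance = 1e-9)
  expect_equal(r$min_radius, 0.5, tolerance = 1e-9)
  # random polygon vs shoelace / edge-sum oracle
  set.seed(3)
  pts <- matrix(rnorm(20), ncol = 2)
  hull <- pts[grDevices::chull(pts), ]
  hull <- hull[rev(seq_len(nrow(hull))), ]
  m <- polygon_cell_mesh(hull)
  gm <- geometry_measures_2d(m)
  n <- nrow(hull); nxt <- c(2:n, 1)
  shoelace <- 0.5 * abs(sum(hull[, 1] * hull[nxt, 2] -
                              hull[nxt, 1] * hull[, 2]))
  edgesum <- sum(sqrt(rowSums((hull[nxt, ] - hull)^2)))
  expect_equal(gm$area, shoelace, tolerance = 1e-9)
  expect_equal(gm$perimeter, edgesum, tolerance = 1e-9)
})

test_that("junction distances on a grid tissue", {
  g <- geometry_measures_2d(make_grid_tissue(3, 3, 2, 1))
  ctr <- g[g$label == 5, ]  # interior cell: all 4 corners are junctions
  expect_equal(ctr$junction_dist_max, 2)
  expect_equal(ctr$junction_dist_min, 1)
})

test_that("lobeyness family: convex fixtures give exactly 1", {
  lm <- lobeyness_measures(hexagon_mesh())
  expect_equal(lm$lobeyness, 1, tolerance = 1e-9)
  expect_equal(lm$solidarity, 1, tolerance = 1e-9)
  expect_equal(lm$visibility_stomata, 1)
  expect_equal(lm$visibility_pavement, 0)
  sq <- polygon_cell_mesh(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(lobeyness_measures(sq)$circularity, 4 / pi,
               tolerance = 1e-9)
  expect_equal(lobeyness_measures(rect_mesh())$rectangularity, 1,
               tolerance = 1e-9)
})

test_that("non-convex contours: hull oracle via gift wrapping", {
  lm <- lobeyness_measures(plus_mesh())
  # gift-wrapping convex hull of the plus shape
  xy <- tissuecoords:::cell_polygon_2d(plus_mesh(), 1)$xy
  giftwrap <- function(p) {
    start <- which.min(p[, 1])
    hull <- start; cur <- start; prev_ang <- pi / 2
    repeat {
      rest <- setdiff(seq_len(nrow(p)), cur)
      angs <- atan2(p[rest, 2] - p[cur, 2], p[rest, 1] - p[cur, 1])
      rel <- (angs - prev_ang + pi) %% (2 * pi) - pi
      nxt <- rest[which.max(rel)]
      if (nxt == start) break
      hull <- c(hull, nxt); prev_ang <- angs[which.max(rel)]; cur <- nxt
      if (length(hull) > nrow(p)) break
    }
    p[hull, ]
  }
  h <- giftwrap(xy)
  hp <- sum(sqrt(rowSums((h[c(2:nrow(h), 1), ] - h)^2)))
  n <- nrow(h); nxt <- c(2:n, 1)
  ha <- 0.5 * abs(sum(h[, 1] * h[nxt, 2] - h[nxt, 1] * h[, 2]))
  P <- tissuecoords:::polygon_perimeter_2d(xy)
  A <- tissuecoords:::polygon_area_2d(xy)
  expect_equal(lm$lobeyness, P / hp, tolerance = 1e-9)
  expect_equal(lm$solidarity, ha / A, tolerance = 1e-9)
  expect_gt(lm$lobeyness, 1)
  expect_gt(lm$solidarity, 1)
  expect_lt(lm$visibility_stomata, 1)
})

test_that("lobeyness measures are rigid-motion and scale invariant", {
  xy0 <- tissuecoords:::cell_polygon_2d(plus_mesh(), 1)$xy
  l0 <- lobeyness_measures(plus_mesh())
  th <- 0.53; s <- 3.7
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  m2 <- polygon_cell_mesh(sweep(s * xy0 %*% t(R), 2, c(11, -4), `+`))
  l1 <- lobeyness_measures(m2)
  for (col in c("circularity", "lobeyness", "rectangularity", "solidarity"))
    expect_equal(l1[[col]], l0[[col]], tolerance = 1e-6)
  # visibility is a seeded Monte Carlo estimate over boundary-point pairs;
  # rotation reparameterizes the boundary, so invariance is statistical
  expect_equal(l1$visibility_stomata, l0$visibility_stomata,
               tolerance = 0.08)
})

test_that("circularity decreases toward 1 with n-gon refinement", {
  circ <- vapply(c(4, 8, 16, 64), function(n) {
    th <- 2 * pi * (0:(n - 1)) / n
    lobeyness_measures(polygon_cell_mesh(cbind(cos(th),
                                               sin(th))))$circularity
  }, 0)
  expect_true(all(diff(circ) < 0))
  expect_true(all(circ >= 1))
  expect_lt(circ[4] - 1, 0.002)
})

test_that("3D geometry: cubes, stacking, sphere volume", {
  iso <- label_array_to_mesh(array(1L, dim = c(1, 1, 1)))
  g <- geometry_measures_3d(iso)
  expect_equal(g$volume, 1)
  expect_equal(g$wall_area, 6)
  expect_equal(g$outside_ratio, 1)
  stacked <- label_array_to_mesh(array(c(1L, 2L), dim = c(2, 1, 1)))
  gs <- geometry_measures_3d(stacked)
  expect_equal(gs$outside_ratio, c(5 / 6, 5 / 6))
  s <- make_sphere_cell(2, 3)
  vol <- tissuecoords:::closed_surface_volume(s$vertices, s$triangles)
  expect_equal(vol, 4 * pi * 8 / 3, tolerance = 0.02 * 4 * pi * 8 / 3)
})

test_that("volume of merged neighbors equals the sum of parts", {
  vm <- two_cubes()
  merged <- tissuecoords:::merge_daughter_cells(vm, c(1, 2))
  vsum <- sum(cell_geometry_3d(vm)$volume)
  vm2 <- tissuecoords:::closed_surface_volume(merged$vertices,
                                              merged$triangles)
  expect_equal(vm2, vsum, tolerance = 1e-6 * vsum)
})

test_that("ray-cast cell lengths match brute-force triangle intersection", {
  box <- label_array_to_mesh(array(1L, dim = c(2, 1, 1)))$cells[["1"]]
  expect_equal(cell_length_along_direction(box, c(1, 0, 0)), 2)
  expect_equal(cell_length_along_direction(box, c(0, 1, 0)), 1)
  s <- sphere_fixture()
  expect_equal(cell_length_along_direction(s, c(0.3, 0.5, 0.81)), 2,
               tolerance = 0.02)
  # brute-force oracle on a random direction
  set.seed(9)
  d <- tissuecoords:::unitv(rnorm(3))
  ctr <- tissuecoords:::closed_surface_centroid(s$vertices, s$triangles)
  hits <- function(dir) {
    out <- c()
    for (i in seq_len(nrow(s$triangles))) {
      h <- tissuecoords:::ray_mesh_hits(ctr, dir, s$vertices,
                                        s$triangles[i, , drop = FALSE])
      out <- c(out, h)
    }
    min(out)
  }
  expect_equal(cell_length_along_direction(s, d), hits(d) + hits(-d),
               tolerance = 1e-9)
})

test_that("3D shape PCA: sphere, printed formula, ellipsoid recovery", {
  set.seed(2)
  sp <- shape_pca_3d(sphere_fixture()$vertices)
  expect_equal(sp$anisotropy, 0, tolerance = 0.01)
  expect_equal(sp$elongation, 1, tolerance = 0.01)
  expect_equal(sp$flatness, 1, tolerance = 0.01)
  # printed formula at axis lengths (4, 2, 1)
  expect_equal((4 - 0.5 * 2 - 0.5 * 1) / (4 + 2 + 1), 0.3571429,
               tolerance = 1e-6)
  g <- as.matrix(expand.grid(x = seq(-2, 2, 0.1), y = seq(-1, 1, 0.1),
                             z = seq(-1, 1, 0.1)))
  g <- g[g[, 1]^2 / 4 + g[, 2]^2 + g[, 3]^2 <= 1, ]
  se <- shape_pca_3d(g)
  expect_equal(se$len_max / se$len_mid, 2, tolerance = 0.03 * 2)
  expect_equal(se$elongation, 2, tolerance = 0.03 * 2)
  expect_error(shape_pca_3d(cbind(runif(10), runif(10), 0)), "degenerate")
})

test_that("interior samples of a box recover its extents", {
  box <- label_array_to_mesh(array(1L, dim = c(4, 2, 1)))$cells[["1"]]
  pts <- cell_interior_samples(box, spacing = 0.25)
  sp <- shape_pca_3d(pts)
  expect_equal(sp$len_max, 4, tolerance = 0.1)
  expect_equal(sp$len_mid, 2, tolerance = 0.1)
})

test_that("network measures: path, star, and exhaustive oracle", {
  nm <- network_measures(build_cell_graph(make_grid_tissue(3, 1)))
  expect_equal(nm$betweenness, c(0, 1, 0))
  expect_equal(nm$current_flow_betweenness, c(0, 1, 0), tolerance = 1e-9)
  star <- structure(list(
    nodes = tibble::tibble(label = 1:5, x = c(0, 1, -1, 0, 0),
                           y = c(0, 0, 0, 1, -1), z = 0),
    edges = tibble::tibble(from = 1L, to = 2:5, wall = 1),
    dim = 2L), class = "cell_graph")
  ns <- network_measures(star)
  expect_equal(ns$betweenness[ns$label == 1], 6)  # C(4,2) pairs
  expect_equal(ns$n_neighbors[ns$label == 1], 4)
  # random graphs with <= 8 nodes: exact match to path-counting oracle
  set.seed(6)
  for (trial in 1:3) {
    n <- 8
    repeat {
      A <- matrix(runif(n * n) < 0.35, n, n)
      A[lower.tri(A, diag = TRUE)] <- FALSE
      ed <- which(A, arr.ind = TRUE)
      g <- structure(list(
        nodes = tibble::tibble(label = 1:n, x = rnorm(n), y = rnorm(n),
                               z = 0),
        edges = tibble::tibble(from = as.integer(ed[, 1]),
                               to = as.integer(ed[, 2]), wall = 1),
        dim = 2L), class = "cell_graph")
      if (igraph::is_connected(tissuecoords:::as_igraph(g))) break
    }
    got <- network_measures(g)
    oracle <- betweenness_oracle(1:n, g$edges)
    expect_equal(got$betweenness, unname(oracle[as.character(got$label)]),
                 tolerance = 1e-9)
  }
})

test_that("signal measures: uniform, zero, and border-ring hand computation", {
  sq <- subdivide_mesh(polygon_cell_mesh(rbind(c(0, 0), c(4, 0), c(4, 4),
                                               c(0, 4))), 3)
  sq$vertex_signal <- rep(5, nrow(sq$vertices))
  sm <- signal_measures(sq, border_width = 1)
  expect_equal(c(sm$total, sm$border, sm$interior), c(5, 5, 5))
  sq$vertex_signal <- rep(0, nrow(sq$vertices))
  sm0 <- signal_measures(sq, border_width = 1)
  expect_equal(c(sm0$total, sm0$border, sm0$interior), c(0, 0, 0))
  # signal 1 on the border ring only
  v <- sq$vertices
  d2edge <- pmin(v[, 1], 4 - v[, 1], v[, 2], 4 - v[, 2])
  sq$vertex_signal <- as.numeric(d2edge <= 1)
  smr <- signal_measures(sq, border_width = 1)
  expect_equal(smr$border, 1, tolerance = 1e-9)
  expect_equal(smr$interior, 0, tolerance = 1e-9)
  expect_gt(smr$total, smr$interior); expect_lt(smr$total, smr$border)
  expect_error(signal_measures(make_grid_tissue(1, 1)), "signal")
})

test_that("tissue curvature: plane zero, sphere 1/R, saddle near zero", {
  tp <- make_surface_tissue(60, "plane", seed = 2, refine = 1)
  expect_lt(max(abs(tissue_curvature(tp$mesh, 6)$mean_curvature),
                na.rm = TRUE), 1e-6)
  ts <- make_surface_tissue(80, "sphere_cap", seed = 2, bend_radius = 50,
                            refine = 1)
  cv <- tissue_curvature(ts$mesh, 6)$mean_curvature
  expect_equal(mean(cv, na.rm = TRUE), 1 / 50, tolerance = 0.05)
  # saddle z = xy/20: mean curvature ~ 0 at the origin
  g <- make_grid_tissue(4, 4, 2, 2)
  v <- g$vertices
  v[, 1] <- v[, 1] - 4; v[, 2] <- v[, 2] - 4
  v[, 3] <- v[, 1] * v[, 2] / 20
  g$vertices <- v
  g <- subdivide_mesh(g, 2)
  g$vertices[, 3] <- g$vertices[, 1] * g$vertices[, 2] / 20
  cs <- tissue_curvature(g, 3)
  cen <- cell_centroids(g)
  near0 <- which(abs(cen$x) < 1.5 & abs(cen$y) < 1.5)
  expect_lt(max(abs(cs$mean_curvature[near0])), 0.01)
  expect_error(tissue_curvature(g, 1e-6), "spacing")
})

test_that("heat smoothing, plateau maxima and binning", {
  gp <- build_cell_graph(make_grid_tissue(3, 1))
  const <- tibble::tibble(label = 1:3, value = 4)
  expect_equal(heat_smooth(const, gp, 2)$value, rep(4, 3))
  expect_equal(local_maxima(const, gp), 1L)  # one per plateau, lowest label
  spike <- tibble::tibble(label = 1:3, value = c(0, 9, 0))
  hs <- heat_smooth(spike, gp, 1)
  expect_equal(hs$value, c(4.5, 3, 4.5))  # hand arithmetic on the path
  expect_equal(local_maxima(spike, gp), 2L)
  hb <- heat_bin(tibble::tibble(label = 1:10, v = 0:9), width = 2)
  expect_equal(hb$summary$n, rep(2L, 5))
  expect_equal(max(hb$bins$bin), 5)
  hb2 <- heat_bin(tibble::tibble(label = 1:10, v = 0:9), n_bins = 5)
  expect_equal(hb2$summary$n, rep(2L, 5))
  expect_error(heat_smooth(const, gp, -1), ">= 0")
})
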