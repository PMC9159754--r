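test_that("cell distance: path examples and modes", {
  gp <- build_cell_graph(make_grid_tissue(3, 1, 5, 5))
  expect_equal(cell_distance(gp, 1, "cells")$distance, c(0, 1, 2))
  expect_equal(cell_distance(gp, 1, "euclidean")$distance, c(0, 5, 10))
  expect_equal(cell_distance(gp, c(1, 3), "cells")$distance, c(0, 1, 0))
  expect_error(cell_distance(gp, integer(0)), "empty")
  expect_error(cell_distance(gp, 99), "absent")
})

test_that("cell distance equals an independent Dijkstra on a random tissue", {
  t <- small_tissue()
  g <- build_cell_graph(t$mesh)
  for (mode in c("euclidean", "cells", "inv_wall")) {
    w <- switch(mode,
      cells = rep(1, nrow(g$edges)),
      inv_wall = 1 / pmax(g$edges$wall, 1e-9),
      euclidean = {
        a <- match(g$edges$from, g$nodes$label)
        b <- match(g$edges$to, g$nodes$label)
        xyz <- as.matrix(g$nodes[, c("x", "y", "z")])
        sqrt(rowSums((xyz[a, ] - xyz[b, ])^2))
      })
    oracle <- dijkstra_oracle(g$nodes$label, g$edges, w, seeds = c(3, 17))
    got <- cell_distance(g, c(3, 17), mode)
    expect_equal(got$distance, unname(oracle[as.character(got$label)]),
                 tolerance = 1e-12)
  }
})

test_that("cell distance is zero exactly on seeds, triangle inequality holds", {
  t <- small_tissue()
  g <- build_cell_graph(t$mesh)
  d <- cell_distance(g, 5, "cells")
  expect_identical(d$label[d$distance == 0], 5L)
  dv <- stats::setNames(d$distance, d$label)
  for (k in seq_len(nrow(g$edges))) {
    e <- g$edges[k, ]
    expect_lte(abs(dv[as.character(e$from)] - dv[as.character(e$to)]), 1)
  }
})

test_that("bezier line coordinate: straight axis, clamping, tangent", {
  sp <- bezier_spline(rbind(c(0, 0, 0), c(100, 0, 0)))
  r <- bezier_line_coord(tibble::tibble(label = 1, x = 50, y = 7, z = 0), sp)
  expect_equal(r$coord, 50, tolerance = 1e-6)
  expect_equal(r$distance, 7, tolerance = 1e-6)
  expect_equal(c(r$tx, r$ty, r$tz), c(1, 0, 0), tolerance = 1e-9)
  beyond <- bezier_line_coord(tibble::tibble(label = 1, x = 150, y = 3,
                                             z = 0), sp)
  expect_equal(beyond$coord, 100, tolerance = 1e-6)
})

test_that("curved bezier coordinate matches a dense-sampling oracle", {
  sp <- bezier_spline(rbind(c(0, 0, 0), c(30, 40, 0), c(60, -10, 20),
                            c(100, 30, 10)))
  pts <- rbind(c(40, 20, 5), c(10, 10, 0), c(80, 0, 15))
  ts <- seq(0, 1, length.out = 1e5)
  curve <- tissuecoords:::bezier_eval(sp, ts)
  for (i in seq_len(nrow(pts))) {
    d2 <- colSums((t(curve) - pts[i, ])^2)
    best <- which.min(d2)
    oracle_coord <- tissuecoords:::bezier_arclength_at(sp, ts[best])
    r <- bezier_line_coord(tibble::tibble(label = 1, x = pts[i, 1],
                                          y = pts[i, 2], z = pts[i, 3]), sp)
    expect_equal(r$coord, oracle_coord, tolerance = 0.1)
    expect_equal(r$distance, sqrt(min(d2)), tolerance = 0.1)
  }
})

test_that("bezier coordinate is invariant under joint rigid motion", {
  sp_ctrl <- rbind(c(0, 0, 0), c(30, 40, 0), c(60, -10, 20), c(100, 30, 10))
  cen <- tibble::tibble(label = 1:2, x = c(40, 15), y = c(20, 5),
                        z = c(5, 2))
  r0 <- bezier_line_coord(cen, bezier_spline(sp_ctrl))
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr <- c(12, -5, 30)
  move <- function(p) sweep(p %*% t(R), 2, tr, `+`)
  cen_m <- cen
  cen_m[, c("x", "y", "z")] <- move(as.matrix(cen[, c("x", "y", "z")]))
  r1 <- bezier_line_coord(cen_m, bezier_spline(move(sp_ctrl)))
  expect_equal(r1$coord, r0$coord, tolerance = 1e-5)
  expect_equal(r1$distance, r0$distance, tolerance = 1e-6)
})

test_that("bezier from cell file: straight, two-cell and arc cases", {
  cen <- tibble::tibble(label = 1:5, x = c(0, 10, 20, 30, 40), y = 0, z = 0)
  sp <- bezier_from_cell_file(1:5, cen)
  expect_equal(tissuecoords:::bezier_eval(sp, 0.5)[1, ], c(20, 0, 0),
               tolerance = 1e-6)
  sp2 <- bezier_from_cell_file(1:2, cen)
  expect_equal(bezier_length(sp2), 10, tolerance = 1e-6)
  expect_error(bezier_from_cell_file(1L, cen), "at least 2")
  # circular arc: fitted spline within 2% of radius of all centroids
  th <- seq(0, pi / 2, length.out = 12)
  R <- 50
  arc <- tibble::tibble(label = seq_along(th), x = R * cos(th),
                        y = R * sin(th), z = 0)
  spa <- bezier_from_cell_file(arc$label, arc)
  dev <- vapply(seq_along(th), function(i) {
    p <- c(arc$x[i], arc$y[i], arc$z[i])
    t <- tissuecoords:::bezier_nearest_t(spa, p)
    tissuecoords:::vnorm(tissuecoords:::bezier_eval(spa, t)[1, ] - p)
  }, 0)
  expect_lt(max(dev), 0.02 * R)
})

test_that("polar coordinate matches direct trigonometry", {
  cen <- tibble::tibble(label = 1:3, x = c(1, 0, 0), y = c(0, 1, 0),
                        z = c(5, 5, 5))
  r <- polar_coord(cen, "z", c(1, 0, 0))
  expect_equal(r$angle[1:2], c(0, 90))
  expect_true(is.na(r$angle[3]))  # centroid on the axis
  set.seed(4)
  rc <- tibble::tibble(label = 1:30, x = rnorm(30), y = rnorm(30),
                       z = rnorm(30))
  got <- polar_coord(rc, "z", c(1, 0, 0))
  oracle <- (atan2(rc$y, rc$x) * 180 / pi) %% 360
  expect_equal(got$angle, oracle, tolerance = 1e-9)
  expect_error(polar_coord(cen, "z", c(0, 0, 1)), "parallel")
})

test_that("mesh distance equals the brute-force minimum over vertices", {
  t <- small_tissue()
  other <- make_grid_tissue(3, 3, 4, 4)
  other$vertices[, 3] <- other$vertices[, 3] + 5
  got <- mesh_distance(t$mesh, other)
  cen <- cell_centroids(t$mesh)
  for (i in c(1, 10, 25)) {
    p <- c(cen$x[i], cen$y[i], cen$z[i])
    d <- sqrt(min(rowSums(sweep(other$vertices, 2, p)^2)))
    expect_equal(got$distance[got$label == cen$label[i]], d,
                 tolerance = 1e-12)
  }
  coincident <- mesh_distance(
    tibble::tibble(label = 1, x = other$vertices[1, 1],
                   y = other$vertices[1, 2], z = other$vertices[1, 3]),
    other)
  expect_equal(coincident$distance, 0)
})

test_that("relative radial coordinate: analytic cases and layer ordering", {
  axis <- bezier_spline(rbind(c(0, 0, 0), c(0, 0, 48)))
  sph <- make_sphere_cell(10, 3, center = c(0, 0, 24))
  mid <- relative_radial_coord(
    tibble::tibble(label = 1:2, x = c(5, 10), y = 0, z = 24), axis, sph)
  expect_equal(mid$relative, c(0.5, 1), tolerance = 0.01)
  o <- make_organ_3d(4, 8, 6)
  pooled <- tissuecoords:::pool_volumetric(o$mesh)
  surface <- list(vertices = pooled$vertices,
                  triangles = pooled$triangles[pooled$wall == 0, ])
  rr <- suppressWarnings(relative_radial_coord(o$mesh, axis, surface))
  expect_true(all(rr$relative >= 0 & rr$relative <= 1, na.rm = TRUE))
  m <- dplyr::inner_join(rr, o$truth, by = "label")
  layer_means <- tapply(m$relative, m$layer, mean, na.rm = TRUE)
  expect_true(all(diff(layer_means) > 0))  # strictly increasing outward
})

test_that("attribute gradient directions recover a linear field", {
  t <- small_tissue()
  cen <- cell_centroids(t$mesh)
  gd <- attribute_gradient_directions(
    t$mesh, tibble::tibble(label = cen$label, value = cen$x))
  ok <- gd$ok
  expect_gt(sum(ok), 40)
  expect_equal(abs(gd$d1x[ok]), rep(1, sum(ok)), tolerance = 1e-6)
  expect_equal(abs(gd$d3y[ok]), rep(1, sum(ok)), tolerance = 1e-6)
  for (i in which(ok)[1:5]) expect_orthonormal_frame(gd[i, ])
  # constant attribute -> flagged unassigned
  gc <- attribute_gradient_directions(
    t$mesh, tibble::tibble(label = cen$label, value = 1))
  expect_true(all(!gc$ok))
})

test_that("noisy linear field gradient equals the normal-equations oracle", {
  t <- small_tissue()
  g <- build_cell_graph(t$mesh)
  cen <- cell_centroids(t$mesh)
  set.seed(7)
  vals <- 2 * cen$x + 0.5 * cen$y + rnorm(nrow(cen), 0, 0.3)
  attr <- tibble::tibble(label = cen$label, value = vals)
  gd <- attribute_gradient_directions(t$mesh, attr, g)
  lb <- 10L
  nb <- c(lb, g$edges$to[g$edges$from == lb], g$edges$from[g$edges$to == lb])
  sub <- cen[cen$label %in% nb, ]
  X <- cbind(1, sub$x, sub$y)
  beta <- solve(crossprod(X), crossprod(X, vals[match(sub$label,
                                                      cen$label)]))
  oracle <- tissuecoords:::unitv(c(beta[2], beta[3], 0))
  got <- c(gd$d1x[gd$label == lb], gd$d1y[gd$label == lb],
           gd$d1z[gd$label == lb])
  expect_equal(abs(sum(got * oracle)), 1, tolerance = 1e-8)
})

test_that("cell frames: Gram-Schmidt, handedness, parallel rejection", {
  f <- build_cell_frame(tibble::tibble(label = 1, x = 0, y = 0, z = 1),
                        tibble::tibble(label = 1, x = 1, y = 0, z = 0))
  expect_equal(unlist(f[, c("d3x", "d3y", "d3z")]), c(d3x = 0, d3y = 1,
                                                      d3z = 0))
  g <- build_cell_frame(
    tibble::tibble(label = 1, x = 0, y = 0, z = 1),
    tibble::tibble(label = 1, x = 1 / sqrt(2), y = 0, z = 1 / sqrt(2)))
  expect_equal(unlist(g[, c("d2x", "d2y", "d2z")]), c(d2x = 1, d2y = 0,
                                                      d2z = 0),
               tolerance = 1e-9)
  par <- build_cell_frame(
    tibble::tibble(label = 1, x = 0, y = 0, z = 1),
    tibble::tibble(label = 1, x = 0, y = 0, z = -1))
  expect_false(par$ok)
  set.seed(3)
  for (i in 1:10) {
    a <- tissuecoords:::unitv(rnorm(3)); b <- tissuecoords:::unitv(rnorm(3))
    if (abs(sum(a * b)) > 0.99) next
    fr <- build_cell_frame(tibble::tibble(label = 1, x = a[1], y = a[2],
                                          z = a[3]),
                           tibble::tibble(label = 1, x = b[1], y = b[2],
                                          z = b[3]))
    expect_orthonormal_frame(fr)
  }
})
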