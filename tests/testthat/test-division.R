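test_that("division detection keeps exactly-twice-divided mothers", {
  pm <- tibble::tibble(child = c(11, 12, 3, 21, 22, 23),
                       parent = c(1, 1, 3, 2, 2, 2))
  expect_equal(detect_divisions(pm), 1L)  # 3 children excluded
  expect_equal(detect_divisions(tibble::tibble(child = 1, parent = 1)),
               integer(0))
})

test_that("plane fits match the eigen-decomposition oracle", {
  set.seed(2)
  # exactly coplanar points with normal (1,2,3)/|.|
  n0 <- tissuecoords:::unitv(c(1, 2, 3))
  b <- tissuecoords:::tangent_basis(n0)
  uv <- matrix(runif(40, -1, 1), ncol = 2)
  pts <- uv %*% rbind(b$e1, b$e2)
  fit <- fit_division_plane(pts, dim = 3)
  expect_equal(abs(sum(fit$normal * n0)), 1, tolerance = 1e-9)
  # isotropic noise sigma = 0.01: normal within 1 degree
  noisy <- pts + matrix(rnorm(length(pts), 0, 0.01), ncol = 3)
  fitn <- fit_division_plane(noisy, dim = 3)
  C <- crossprod(sweep(noisy, 2, colMeans(noisy)))
  oracle <- eigen(C, symmetric = TRUE)$vectors[, 3]
  expect_equal(abs(sum(fitn$normal * oracle)), 1, tolerance = 1e-12)
  expect_lt(acos(min(abs(sum(fitn$normal * n0)), 1)) * 180 / pi, 1)
  # 2.5D: straight wall along y
  wall <- cbind(0, seq(0, 1, 0.25), 0)
  f2 <- fit_division_plane(wall, dim = 2, tangent_normal = c(0, 0, 1))
  expect_equal(abs(f2$direction[2]), 1, tolerance = 1e-9)
})

test_that("candidate planes: count, sphere sections, box minimum", {
  s <- sphere_fixture()
  cand <- enumerate_candidate_planes(s, 100)
  expect_equal(nrow(cand), 100)
  expect_equal(nrow(unique(cand[, c("nx", "ny", "nz")])), 100)
  expect_lt(max(abs(cand$area - pi)) / pi, 0.02)  # central sphere sections
  box <- label_array_to_mesh(array(1L, dim = c(2, 1, 1)))$cells[["1"]]
  cb <- enumerate_candidate_planes(box, 1000)
  expect_equal(nrow(cb), 1000)
  imin <- which.min(cb$area)
  expect_equal(min(cb$area), 1, tolerance = 0.02)
  expect_gt(abs(cb$nx[imin]), 0.99)  # shortest plane perp to the long axis
  open_mesh <- list(vertices = s$vertices,
                    triangles = s$triangles[-1, , drop = FALSE])
  expect_error(enumerate_candidate_planes(open_mesh), "watertight")
})

test_that("sphere section spread shrinks with mesh resolution", {
  s2 <- make_sphere_cell(1, 2)
  s3 <- sphere_fixture()
  sd2 <- sd(enumerate_candidate_planes(s2, 60)$area)
  sd3 <- sd(enumerate_candidate_planes(s3, 60)$area)
  expect_lt(sd3, sd2)
})

test_that("chord ranking: rectangle, ellipse minor axis, dense-sweep oracle", {
  rect <- rect_mesh()
  cr <- enumerate_candidate_chords(rect, 1)
  expect_equal(min(cr$length), 1, tolerance = 1e-9)
  th <- seq(0, 2 * pi, length.out = 501)[-501]
  ell <- polygon_cell_mesh(cbind(2 * cos(th), sin(th)))
  cc <- enumerate_candidate_chords(ell, 1)
  rp <- rank_planes(cc)
  expect_equal(cc$theta_deg[rp$global_min], 90)
  # exactly one local-minimum direction family, at the minor axis
  expect_true(all(abs(cc$theta_deg[rp$local_minima] - 90) <= 2))
  # random convex polygon: global minimum matches a 3600-direction sweep
  set.seed(5)
  pts <- matrix(rnorm(24), ncol = 2)
  hull <- pts[grDevices::chull(pts), ]
  hull <- hull[rev(seq_len(nrow(hull))), ]
  poly <- polygon_cell_mesh(hull)
  cp <- enumerate_candidate_chords(poly, 1)
  ctr <- tissuecoords:::polygon_centroid_2d(
    tissuecoords:::cell_polygon_2d(poly, 1)$xy)
  xy <- tissuecoords:::cell_polygon_2d(poly, 1)$xy
  sweep_min <- min(vapply(seq(0, 180, length.out = 3600), function(a)
    tissuecoords:::chord_length_through(
      xy, ctr, c(cos(a * pi / 180), sin(a * pi / 180))), 0))
  expect_equal(min(cp$length), sweep_min, tolerance = 1e-3)
})

test_that("division plane angles: conventions, range, closed form", {
  expect_equal(division_plane_angles(c(1, 0, 0), c(1, 0, 0)), 90)
  expect_equal(division_plane_angles(c(0, 1, 0), c(1, 0, 0)), 0)
  set.seed(8)
  for (i in 1:20) {
    n <- tissuecoords:::unitv(rnorm(3)); ax <- tissuecoords:::unitv(rnorm(3))
    a <- division_plane_angles(n, ax)
    oracle <- 90 - acos(abs(sum(n * ax))) * 180 / pi
    expect_equal(a, oracle, tolerance = 1e-9)
    expect_gte(a, 0); expect_lte(a, 90)
  }
  expect_true(is.na(division_plane_angles(c(NA, 0, 0), c(1, 0, 0))))
})

test_that("angles of random planes follow the sine-weighted density", {
  set.seed(11)
  n <- matrix(rnorm(3e4), ncol = 3)
  n <- n / sqrt(rowSums(n^2))
  ang <- 90 - acos(abs(n[, 3])) * 180 / pi
  got <- vapply(seq_len(nrow(n)), function(i)
    division_plane_angles(n[i, ], c(0, 0, 1)), 0)
  expect_equal(got, ang, tolerance = 1e-9)
  # P(plane angle <= phi) = sin(phi) for uniform random normals
  ks <- suppressWarnings(stats::ks.test(got * pi / 180, function(q)
    sin(pmin(pmax(q, 0), pi / 2))))
  expect_gt(ks$p.value, 0.01)
})

test_that("daughter asymmetry: zero for equal daughters, label-invariant", {
  expect_equal(daughter_asymmetry(5, 5), 0)
  expect_equal(daughter_asymmetry(2, 6), daughter_asymmetry(6, 2))
  expect_lt(daughter_asymmetry(1, 99), 1)
})

test_that("full 2.5D division records rank planted shortest walls first", {
  t <- make_surface_tissue(40, "plane", seed = 8)
  tl <- apply_timelapse(t$mesh, "affine", list(A = diag(c(1.2, 1.1, 1))),
                        division_rate = 0.3, seed = 3)
  dv <- detect_divisions(tl$parents)
  expect_setequal(dv, tl$divided)
  recs <- dplyr::bind_rows(lapply(dv[1:5], function(m) {
    kids <- tl$parents$child[tl$parents$parent == m]
    division_record(tl$mesh_t1, kids, m, axis = c(1, 0, 0))
  }))
  expect_true(all(recs$rank <= 5))  # planted shortest walls rank at the bottom
  expect_true(all(recs$asymmetry < 0.2))
  expect_true(all(recs$angle >= 0 & recs$angle <= 90))
  expect_equal(recs$actual, recs$min_candidate, tolerance = 0.05)
})

test_that("3D division record on a split pair of cubes", {
  vm <- two_cubes()
  pm <- tibble::tibble(child = c(1, 2), parent = c(10, 10))
  rec <- division_record(vm, c(1, 2), 10, axis = c(1, 0, 0), n_planes = 200)
  expect_equal(rec$asymmetry, 0, tolerance = 1e-9)
  expect_gt(abs(rec$nx), 0.99)            # actual wall normal along x
  expect_equal(rec$angle, 90, tolerance = 1)  # wall perpendicular to x axis
  expect_equal(rec$actual, 100, tolerance = 2)
})
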