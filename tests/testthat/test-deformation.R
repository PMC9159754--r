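random_landmarks <- function(n = 30, seed = 3) {
  set.seed(seed)
  matrix(runif(3 * n, 0, 10), ncol = 3)
}

test_that("RBF fit: polynomial reproduction and exact interpolation", {
  src <- random_landmarks()
  # pure translation: zero RBF weights, field(x) = x + t everywhere
  f <- fit_deformation(src, sweep(src, 2, c(3, -2, 1), `+`))
  expect_lt(sqrt(sum(f$weights^2)), 1e-8)
  test_pts <- random_landmarks(5, 9)
  expect_equal(evaluate_deformation(f, test_pts),
               sweep(test_pts, 2, c(3, -2, 1), `+`), tolerance = 1e-8)
  # affine map reproduced exactly at arbitrary points
  A <- rbind(c(2, 0.1, 0), c(0, 1.5, -0.2), c(0.05, 0, 1))
  fa <- fit_deformation(src, src %*% t(A))
  expect_lt(sqrt(sum(fa$weights^2)), 1e-8)
  expect_equal(evaluate_deformation(fa, test_pts), test_pts %*% t(A),
               tolerance = 1e-8)
  # random smooth warp: interpolation condition at the landmarks
  dst <- src + 0.3 * sin(src[, c(2, 3, 1)])
  fw <- fit_deformation(src, dst)
  expect_lt(max(abs(evaluate_deformation(fw, src) - dst)), 1e-8)
})

test_that("side conditions hold after every fit", {
  for (seed in 1:4) {
    src <- random_landmarks(seed = seed)
    dst <- src + 0.5 * cos(src[, c(3, 1, 2)])
    f <- fit_deformation(src, dst)
    expect_lt(max(abs(colSums(f$weights))), 1e-8)
    expect_lt(max(abs(t(f$weights) %*% f$centers)), 1e-8)
  }
})

test_that("coplanar landmark sets are rejected with guidance", {
  src <- cbind(matrix(runif(20), ncol = 2), 0)
  expect_error(fit_deformation(src, src), "coplanar|landmarks")
})

test_that("analytic gradient matches central finite differences", {
  src <- random_landmarks()
  dst <- src + 0.3 * sin(src[, c(2, 3, 1)])
  f <- fit_deformation(src, dst)
  h <- 1e-4
  for (p0 in list(c(4.2, 5.1, 3.3), c(1, 9, 2))) {
    Fa <- deformation_gradient(f, p0)
    Fd <- matrix(0, 3, 3)
    for (k in 1:3) {
      e <- numeric(3); e[k] <- h
      Fd[, k] <- (evaluate_deformation(f, rbind(p0 + e)) -
                    evaluate_deformation(f, rbind(p0 - e))) / (2 * h)
    }
    expect_lt(max(abs(Fa - Fd)) / max(abs(Fd)), 1e-5)
  }
  # identity and affine fields have constant gradients
  fi <- fit_deformation(src, src)
  expect_equal(deformation_gradient(fi, c(2, 2, 2)), diag(3),
               tolerance = 1e-8)
  A <- rbind(c(2, 0, 0), c(0, 1, 0), c(0, 0, 1))
  fa <- fit_deformation(src, src %*% t(A))
  expect_equal(deformation_gradient(fa, c(7, 1, 3)), A, tolerance = 1e-8)
})

test_that("subcellular growth: affine products and analytic Jacobians", {
  t <- make_surface_tissue(30, "paraboloid", seed = 3, refine = 1)
  j0 <- mesh_junctions(t$mesh)
  # identity -> stretch product 1 everywhere
  fi <- fit_deformation(t$mesh$vertices[j0, ], t$mesh$vertices[j0, ])
  sgi <- subcellular_growth(fi, t$mesh)
  expect_equal(sgi$area_growth, rep(1, nrow(sgi)), tolerance = 1e-6)
  # spatially varying warp: vertex stretches match the analytic Jacobian
  tl <- apply_timelapse(t$mesh, "bending", list(curvature = 0.02), seed = 1)
  f <- fit_deformation(t$mesh$vertices[j0, ], tl$mesh_t1$vertices[j0, ])
  sg <- subcellular_growth(f, t$mesh)
  vn <- tissuecoords:::vertex_normals(t$mesh)
  v <- t$mesh$vertices
  L <- max(v[, 1]) - min(v[, 1])
  interior <- v[, 1] > min(v[, 1]) + 0.1 * L & v[, 1] < max(v[, 1]) - 0.1 * L &
    v[, 2] > min(v[, 2]) + 0.1 * L & v[, 2] < max(v[, 2]) - 0.1 * L
  errs <- vapply(which(interior), function(i) {
    J <- tl$jacobian(v[i, ])
    s <- tissuecoords:::surface_stretch(J, vn[i, ])
    abs(sg$area_growth[i] - s$kmax * s$kmin) / (s$kmax * s$kmin)
  }, 0)
  expect_lt(max(errs), 0.01)
})

test_that("subcellular growth of a planted global stretch", {
  t <- make_surface_tissue(25, "plane", seed = 4)
  tl <- apply_timelapse(t$mesh, "affine", list(A = diag(c(2, 1, 1))),
                        seed = 1)
  j0 <- mesh_junctions(t$mesh)
  f <- tissuecoords:::fit_deformation_robust(t$mesh$vertices[j0, ],
                                             tl$mesh_t1$vertices[j0, ])
  sg <- subcellular_growth(f, t$mesh)
  expect_equal(sg$kmax, rep(2, nrow(sg)), tolerance = 1e-6)
  expect_equal(sg$kmin, rep(1, nrow(sg)), tolerance = 1e-6)
  expect_equal(sg$area_growth, rep(2, nrow(sg)), tolerance = 1e-6)
})

test_that("lineage tracking recovers a clean warped time-lapse from 3 seeds", {
  t <- make_surface_tissue(100, "plane", seed = 3)
  tl <- apply_timelapse(t$mesh, "bending", list(), division_rate = 0,
                        seed = 1)
  truth <- tl$parents
  seeds <- truth[c(5, 50, 90), ]
  res <- suppressWarnings(auto_parent_label(t$mesh, tl$mesh_t1, seeds))
  m <- dplyr::inner_join(res$parents, truth, by = "child",
                         suffix = c("_got", "_true"))
  expect_equal(nrow(res$parents), nrow(truth))  # 100% assigned
  expect_equal(sum(m$parent_got != m$parent_true), 0)  # 0 false
  expect_length(res$unresolved, 0)
})

test_that("lineage tracking assigns daughters to their mothers", {
  t <- make_surface_tissue(100, "plane", seed = 6)
  tl <- apply_timelapse(t$mesh, "radial_gradient", list(a = 0.5),
                        division_rate = 0.2, seed = 5)
  truth <- tl$parents
  und <- truth$child[truth$child == truth$parent]
  seeds <- tibble::tibble(child = und[c(1, 40, 75)],
                          parent = und[c(1, 40, 75)])
  res <- suppressWarnings(auto_parent_label(t$mesh, tl$mesh_t1, seeds))
  m <- dplyr::inner_join(res$parents, truth, by = "child",
                         suffix = c("_got", "_true"))
  expect_equal(sum(m$parent_got != m$parent_true), 0)
  daughters <- truth$child[truth$child != truth$parent]
  expect_true(all(daughters %in% res$parents$child))
})

test_that("structures absent at t0 are left unresolved, never misassigned", {
  t <- make_surface_tissue(60, "plane", seed = 4)
  tl <- apply_timelapse(t$mesh, "affine", list(A = diag(c(1.3, 1.1, 1))),
                        seed = 1)
  m1 <- tl$mesh_t1
  patch <- make_surface_tissue(5, "plane", seed = 9)$mesh
  pv <- patch$vertices; pv[, 1] <- pv[, 1] + 500
  off <- nrow(m1$vertices)
  maxl <- max(mesh_labels(m1))
  m1b <- surface_cell_mesh(rbind(m1$vertices, pv),
                           rbind(m1$triangles, patch$triangles + off),
                           c(m1$face_label, patch$face_label + maxl))
  seeds <- tl$parents[c(2, 30, 55), ]
  res <- suppressWarnings(auto_parent_label(t$mesh, m1b, seeds))
  extra <- (maxl + 1):(maxl + 5)
  expect_false(any(res$parents$child %in% extra))
  expect_true(all(extra %in% res$unresolved))
  expect_error(auto_parent_label(t$mesh, m1b, tl$parents[0, ]), "seed")
})

test_that("tracked map passes its own neighborhood verification", {
  t <- make_surface_tissue(80, "plane", seed = 2)
  tl <- apply_timelapse(t$mesh, "bending", list(), division_rate = 0.15,
                        seed = 4)
  truth <- tl$parents
  und <- truth$child[truth$child == truth$parent]
  seeds <- tibble::tibble(child = und[c(2, 30, 60)],
                          parent = und[c(2, 30, 60)])
  res <- suppressWarnings(auto_parent_label(t$mesh, tl$mesh_t1, seeds))
  g0 <- build_cell_graph(t$mesh); g1 <- build_cell_graph(tl$mesh_t1)
  amap <- stats::setNames(res$parents$parent, res$parents$child)
  for (i in seq_len(nrow(res$parents))) {
    ch <- res$parents$child[i]; p <- res$parents$parent[i]
    nbp <- amap[as.character(tissuecoords:::graph_neighbors(g1, ch))]
    nbp <- nbp[!is.na(nbp)]
    if (!length(nbp)) next
    okset <- c(p, tissuecoords:::graph_neighbors(g0, p))
    expect_true(all(nbp %in% okset))
  }
})

test_that("morphing: linear midpoint, knot reproduction, heat interpolation", {
  t <- make_surface_tissue(20, "plane", seed = 3)
  tl <- apply_timelapse(t$mesh, "affine", list(A = diag(c(1.5, 1, 1))),
                        seed = 1)
  fr <- morph_sequence(list(t$mesh, tl$mesh_t1), 3,
                       heat = list(rep(0, 20), rep(10, 20)))
  expect_equal(fr[[2]]$mesh$vertices,
               (t$mesh$vertices + tl$mesh_t1$vertices) / 2,
               tolerance = 1e-12)
  expect_equal(fr[[2]]$heat, rep(5, 20))
  expect_equal(fr[[1]]$mesh$vertices, t$mesh$vertices)
  # heat 0 -> 10, frame at 30%
  fr10 <- morph_sequence(list(t$mesh, tl$mesh_t1), 11,
                         heat = list(rep(0, 20), rep(10, 20)))
  expect_equal(fr10[[4]]$heat, rep(3, 20), tolerance = 1e-9)
  # four knots reproduced exactly
  ms <- lapply(c(1, 1.1, 1.3, 1.35), function(s) {
    m <- t$mesh; m$vertices <- t$mesh$vertices * s; m
  })
  fr4 <- morph_sequence(ms, 7)
  for (k in 1:4)
    expect_equal(fr4[[2 * k - 1]]$mesh$vertices, ms[[k]]$vertices,
                 tolerance = 1e-9)
  expect_error(morph_sequence(list(t$mesh, tl$mesh_t1), 1), "2")
})

test_that("two-frame morphing is time-reversal symmetric", {
  t <- make_surface_tissue(15, "plane", seed = 8)
  tl <- apply_timelapse(t$mesh, "affine", list(A = diag(c(1.4, 1.2, 1))),
                        seed = 1)
  f <- morph_sequence(list(t$mesh, tl$mesh_t1), 5)
  b <- morph_sequence(list(tl$mesh_t1, t$mesh), 5)
  for (k in 1:5)
    expect_equal(f[[k]]$mesh$vertices, b[[6 - k]]$mesh$vertices,
                 tolerance = 1e-12)
})
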