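test_that("mesh I/O round trips are lossless across formats", {
  t <- small_tissue()
  mesh <- make_signal_field(t$mesh, "noise", seed = 2)$mesh
  for (binary in c(TRUE, FALSE)) {
    f <- withr::local_tempfile(fileext = ".ply")
    write_mesh(mesh, f, binary = binary)
    r <- read_mesh(f)
    expect_equal(r$vertices, mesh$vertices, tolerance = 1e-12)
    expect_identical(r$face_label, mesh$face_label)
    expect_equal(r$vertex_signal, mesh$vertex_signal, tolerance = 1e-12)
  }
  fo <- withr::local_tempfile(fileext = ".obj")
  write_mesh(t$mesh, fo)
  ro <- read_mesh(fo)
  expect_equal(ro$vertices, t$mesh$vertices, tolerance = 1e-12)
  expect_identical(ro$face_label, t$mesh$face_label)
})

test_that("volumetric PLY round trip preserves cells, walls and volumes", {
  o <- make_organ_3d(2, 4, 2)
  f <- withr::local_tempfile(fileext = ".ply")
  write_mesh(o$mesh, f)
  r <- read_mesh(f)
  expect_setequal(mesh_labels(r), mesh_labels(o$mesh))
  g1 <- cell_geometry_3d(o$mesh); g2 <- cell_geometry_3d(r)
  expect_equal(g2$volume[order(g2$label)], g1$volume[order(g1$label)],
               tolerance = 1e-9)
  expect_equal(nrow(validate_mesh(r)), 0L)
})

test_that("label-image import: two abutting cubes share a tagged 100 um^2 wall", {
  vm <- two_cubes()
  expect_length(vm$cells, 2)
  g <- cell_geometry_3d(vm)
  expect_equal(g$volume, c(1000, 1000))
  cl <- vm$cells[["1"]]
  ar <- sum(tissuecoords:::tri_areas(cl$vertices, cl$triangles)[
    cl$wall_tag == 2L])
  expect_equal(ar, 100, tolerance = 0.05 * 100)
  expect_equal(nrow(validate_mesh(vm)), 0L)
})

test_that("label-image import handles a single label (all walls outside)", {
  vm <- label_array_to_mesh(array(1L, dim = c(3, 3, 3)))
  expect_length(vm$cells, 1)
  expect_true(all(vm$cells[["1"]]$wall_tag == 0L))
  expect_equal(cell_geometry_3d(vm)$outside_ratio, 1)
})

test_that("TIFF stacks read back as the voxel label array", {
  skip_if_not_installed("tiff")
  arr <- array(0L, dim = c(6, 5, 4)); arr[1:3, , ] <- 1L; arr[4:6, , ] <- 7L
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(seq_len(dim(arr)[3]), function(k) arr[, , k] / 65535),
                  f, bits.per.sample = 16)
  vm <- read_mesh(f, "tiff")
  expect_setequal(mesh_labels(vm), c(1L, 7L))
})

test_that("cell graph: grid adjacency, wall lengths, no diagonal contacts", {
  g <- build_cell_graph(make_grid_tissue(2, 2, 1, 1))
  expect_equal(nrow(g$nodes), 4)
  expect_equal(nrow(g$edges), 4)  # diagonal cells share only a point
  expect_equal(g$edges$wall, rep(1, 4))
  gp <- build_cell_graph(make_grid_tissue(3, 1))
  expect_equal(nrow(gp$edges), 2)  # path graph
  expect_false(any(gp$edges$from == 1 & gp$edges$to == 3))
})

test_that("cell graph matches a brute-force shared-boundary scan", {
  t <- small_tissue()
  g <- build_cell_graph(t$mesh)
  # oracle: two labels adjacent iff they share >= 1 undirected triangle edge
  tr <- t$mesh$triangles; lab <- t$mesh$face_label
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  el <- rep(lab, 3)
  found <- unique(do.call(rbind, lapply(split(el, key), function(ls) {
    u <- sort(unique(ls))
    if (length(u) == 2) u else NULL
  })))
  oracle <- found[order(found[, 1], found[, 2]), ]
  got <- as.matrix(g$edges[, c("from", "to")])
  dimnames(got) <- NULL; dimnames(oracle) <- NULL
  expect_equal(got, oracle)
})

test_that("graph construction is independent of label enumeration order", {
  t <- small_tissue()
  m2 <- t$mesh
  perm <- rev(seq_len(nrow(m2$triangles)))
  m2$triangles <- m2$triangles[perm, , drop = FALSE]
  m2$face_label <- m2$face_label[perm]
  g1 <- build_cell_graph(t$mesh); g2 <- build_cell_graph(m2)
  expect_equal(g1$edges, g2$edges, tolerance = 1e-12)
})

test_that("attribute CSV export/import is lossless, preserving missingness", {
  a <- tibble::tibble(label = c(1L, 3L), area = c(2.0, 3.5))
  b <- tibble::tibble(label = 1:3, t_xx = c(1, 2, 3),
                      t_xy = c(0.5, -12.25, 0))
  f <- withr::local_tempfile(fileext = ".csv")
  export_attributes(list(a, b), f)
  hdr <- readLines(f, 1)
  expect_match(hdr, "^Label,")
  imp <- import_attributes(f)
  expect_equal(imp$area, c(2, NA, 3.5))
  expect_equal(imp$t_xy, b$t_xy)
  expect_error(export_attributes(list(a, a), f), "duplicate")
})

test_that("validate_mesh flags broken volumetric invariants", {
  o <- make_organ_3d(2, 4, 1)
  expect_equal(nrow(validate_mesh(o$mesh)), 0L)
  broken <- o$mesh
  lb <- names(broken$cells)[1]
  broken$cells[[lb]]$triangles <-
    broken$cells[[lb]]$triangles[-1, , drop = FALSE]
  broken$cells[[lb]]$wall_tag <- broken$cells[[lb]]$wall_tag[-1]
  rep_ <- validate_mesh(broken)
  expect_true("non_watertight" %in% rep_$check)
  expect_true(as.integer(lb) %in% rep_$label)
  tagged <- o$mesh
  tagged$cells[[lb]]$wall_tag[tagged$cells[[lb]]$wall_tag > 0][1] <- 999L
  expect_gt(nrow(validate_mesh(tagged)), 0)
})

test_that("junction set is deterministic and sits on 3-cell corners", {
  t <- small_tissue()
  j1 <- mesh_junctions(t$mesh)
  j2 <- mesh_junctions(t$mesh)
  expect_identical(j1, j2)
  expect_gt(length(j1), nrow(cell_centroids(t$mesh)))  # more junctions than cells
  # every junction is incident to >= 2 labels
  vl <- unique(data.frame(v = as.vector(t$mesh$triangles),
                          l = rep(t$mesh$face_label, 3)))
  nlab <- tapply(vl$l, vl$v, function(z) length(unique(z)))
  expect_true(all(nlab[as.character(j1)] >= 2))
})

test_that("malformed mesh files produce parse errors naming the element", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 1",
               "property double x", "end_header", "0"), f)
  expect_error(read_mesh(f), "vertex|face|parse")
  f2 <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "usemtl wrongname",
               "f 1 2 3"), f2)
  expect_error(read_mesh(f2), "cell_<label>")
})
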