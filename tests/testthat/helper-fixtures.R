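# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

hexagon_mesh <- function() fixture("hex", function()
  polygon_cell_mesh(cbind(cos(2 * pi * (0:5) / 6),
                          sin(2 * pi * (0:5) / 6))))

rect_mesh <- function() fixture("rect", function()
  polygon_cell_mesh(rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1))))

# plus / cross shaped cell: strongly non-convex contour
plus_mesh <- function() fixture("plus", function()
  polygon_cell_mesh(rbind(c(1, 0), c(2, 0), c(2, 1), c(3, 1), c(3, 2),
                          c(2, 2), c(2, 3), c(1, 3), c(1, 2), c(0, 2),
                          c(0, 1), c(1, 1))))

small_tissue <- function() fixture("tissue50", function()
  make_surface_tissue(50, "plane", seed = 1))

sphere_fixture <- function() fixture("sphere", function()
  make_sphere_cell(1, 3))

# two abutting 10x10x10 voxel cubes as a volumetric mesh
two_cubes <- function() fixture("cubes", function() {
  arr <- array(0L, dim = c(20, 10, 10))
  arr[1:10, , ] <- 1L
  arr[11:20, , ] <- 2L
  label_array_to_mesh(arr, c(1, 1, 1))
})

# textbook Dijkstra (binary-heap-free, O(n^2)) as an independent oracle
dijkstra_oracle <- function(nodes, edges, weights, seeds) {
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- idx[as.character(edges$from[k])]
    j <- idx[as.character(edges$to[k])]
    adj[[i]] <- rbind(adj[[i]], c(j, weights[k]))
    adj[[j]] <- rbind(adj[[j]], c(i, weights[k]))
  }
  dist <- rep(Inf, n)
  dist[idx[as.character(seeds)]] <- 0
  done <- rep(FALSE, n)
  repeat {
    u <- which(!done & is.finite(dist))
    if (!length(u)) break
    u <- u[which.min(dist[u])]
    done[u] <- TRUE
    for (r in seq_len(NROW(adj[[u]]))) {
      v <- adj[[u]][r, 1]; w <- adj[[u]][r, 2]
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  stats::setNames(dist, nodes)
}

# exhaustive shortest-path betweenness by path enumeration (small graphs)
betweenness_oracle <- function(nodes, edges) {
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  A <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(edges))) {
    i <- idx[as.character(edges$from[k])]; j <- idx[as.character(edges$to[k])]
    A[i, j] <- A[j, i] <- TRUE
  }
  all_paths <- function(s, t) {
    out <- list()
    grow <- function(path) {
      u <- path[length(path)]
      if (u == t) { out[[length(out) + 1L]] <<- path; return() }
      for (v in which(A[u, ])) if (!(v %in% path)) grow(c(path, v))
    }
    grow(s)
    out
  }
  btw <- rep(0, n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    ps <- all_paths(s, t)
    if (!length(ps)) next
    lens <- lengths(ps)
    sps <- ps[lens == min(lens)]
    for (p in sps) {
      inner <- setdiff(p, c(s, t))
      btw[inner] <- btw[inner] + 1 / length(sps)
    }
  }
  stats::setNames(btw, nodes)
}

expect_orthonormal_frame <- function(row, tol = 1e-6) {
  d1 <- c(row$d1x, row$d1y, row$d1z)
  d2 <- c(row$d2x, row$d2y, row$d2z)
  d3 <- c(row$d3x, row$d3y, row$d3z)
  expect_equal(sum(d1 * d1), 1, tolerance = tol)
  expect_equal(sum(d2 * d2), 1, tolerance = tol)
  expect_equal(sum(d3 * d3), 1, tolerance = tol)
  expect_lt(abs(sum(d1 * d2)), tol)
  expect_lt(abs(sum(d1 * d3)), tol)
  expect_lt(abs(sum(d2 * d3)), tol)
  cr <- c(d1[2] * d2[3] - d1[3] * d2[2],
          d1[3] * d2[1] - d1[1] * d2[3],
          d1[1] * d2[2] - d1[2] * d2[1])
  expect_gt(sum(cr * d3), 0)
}
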