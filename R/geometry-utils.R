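# Internal vector/triangle/polygon helpers. All geometry is in micrometres,
# right-handed axes; labels are positive integers, 0 = background/outside.

vnorm <- function(x) sqrt(sum(x * x))

unitv <- function(x) {
  n <- vnorm(x)
  if (n < 1e-300) stop("cannot normalize a zero vector")
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# rowwise cross product for n x 3 matrices
cross3_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

tri_normals <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c_ <- vertices[triangles[, 3], , drop = FALSE]
  cross3_rows(b - a, c_ - a)  # length = 2 * area, direction = face normal
}

tri_areas <- function(vertices, triangles) {
  n <- tri_normals(vertices, triangles)
  0.5 * sqrt(rowSums(n * n))
}

# orthonormal in-plane basis (e1, e2) for a unit normal
tangent_basis <- function(normal) {
  n <- unitv(normal)
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitv(ref - sum(ref * n) * n)
  e2 <- cross3(n, e1)
  list(e1 = e1, e2 = e2, n = n)
}

polygon_area_2d <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(n, seq_len(n - 1L))
  0.5 * sum(x[j] * y - x * y[j])
}

polygon_perimeter_2d <- function(xy) {
  d <- xy - xy[c(nrow(xy), seq_len(nrow(xy) - 1L)), , drop = FALSE]
  sum(sqrt(rowSums(d * d)))
}

polygon_centroid_2d <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-300) return(colMeans(xy))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

# smallest enclosing rectangle area via rotating the hull edge directions
min_bounding_rect_area <- function(xy) {
  h <- grDevices::chull(xy)
  hull <- xy[h, , drop = FALSE]
  n <- nrow(hull)
  if (n < 3) return(0)
  e <- hull[c(2:n, 1L), , drop = FALSE] - hull
  ang <- atan2(e[, 2], e[, 1])
  best <- Inf
  for (a in ang) {
    ca <- cos(a); sa <- sin(a)
    u <- hull[, 1] * ca + hull[, 2] * sa
    v <- -hull[, 1] * sa + hull[, 2] * ca
    area <- (max(u) - min(u)) * (max(v) - min(v))
    if (area < best) best <- area
  }
  best
}

# min distance from point p to segment ab (2D or 3D)
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / max(sum(ab * ab), 1e-300)
  t <- min(max(t, 0), 1)
  vnorm(p - (a + t * ab))
}

# Moller-Trumbore: distances t >= 0 where ray origin + t*dir hits triangles.
# Returns sorted vector of hit distances (possibly empty).
ray_mesh_hits <- function(origin, dir, vertices, triangles, eps = 1e-9) {
  v0 <- vertices[triangles[, 1], , drop = FALSE]
  e1 <- vertices[triangles[, 2], , drop = FALSE] - v0
  e2 <- vertices[triangles[, 3], , drop = FALSE] - v0
  d <- matrix(dir, nrow(v0), 3, byrow = TRUE)
  p <- cross3_rows(d, e2)
  det <- rowSums(e1 * p)
  ok <- abs(det) > eps
  tvec <- matrix(origin, nrow(v0), 3, byrow = TRUE)
  tvec <- -(v0 - tvec)
  u <- rowSums(tvec * p) / det
  q <- cross3_rows(tvec, e1)
  v <- rowSums(d * q) / det
  t <- rowSums(e2 * q) / det
  hit <- ok & u >= -1e-9 & v >= -1e-9 & (u + v) <= 1 + 1e-9 & t > eps
  sort(t[hit])
}

# golden-section minimization on [a, b]
golden_min <- function(f, a, b, tol = 1e-10) {
  gr <- (sqrt(5) - 1) / 2
  c_ <- b - gr * (b - a); d_ <- a + gr * (b - a)
  fc <- f(c_); fd <- f(d_)
  while (abs(b - a) > tol) {
    if (fc < fd) {
      b <- d_; d_ <- c_; fd <- fc
      c_ <- b - gr * (b - a); fc <- f(c_)
    } else {
      a <- c_; c_ <- d_; fc <- fd
      d_ <- a + gr * (b - a); fd <- f(d_)
    }
  }
  (a + b) / 2
}

# deterministic key for merging coincident vertices
vertex_key <- function(xyz, digits = 6) {
  apply(round(xyz, digits), 1, paste, collapse = "|")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
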