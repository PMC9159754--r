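#' Fit a cubic radial-basis-function deformation field
#'
#' Scattered-data interpolation of landmark correspondences with the cubic
#' kernel phi(r) = r^3 plus a full linear polynomial (affine) term. With
#' ridge `eps = 0` the field interpolates the landmarks exactly; `eps > 0`
#' is added to the kernel diagonal for noisy landmarks. Coordinates are
#' pre-scaled to unit RMS radius for conditioning and unscaled on output.
#' The polynomial side conditions (RBF weights orthogonal to constants and
#' coordinates) hold by construction.
#'
#' @param source n x 3 matrix of source landmark positions (micrometres).
#' @param target n x 3 matrix of corresponding target positions.
#' @param eps ridge added to the kernel diagonal (default 0, exact
#'   interpolation).
#' @return An object of class `deformation_field`.
#' @export
fit_deformation <- function(source, target, eps = 0) {
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(ncol(source) == 3, ncol(target) == 3,
            nrow(source) == nrow(target))
  n <- nrow(source)
  if (n < 4)
    stop("need at least 4 landmarks; for fewer, use an affine fit or add ",
         "landmarks")
  ctr <- colMeans(source)
  sc <- sqrt(mean(rowSums(sweep(source, 2, ctr)^2)))
  if (sc < 1e-12) stop("degenerate landmark set: all sources coincide")
  X <- sweep(source, 2, ctr) / sc
  Y <- sweep(target, 2, ctr) / sc
  r <- as.matrix(stats::dist(X))
  K <- r^3 + diag(eps, n)
  P <- cbind(1, X)
  if (qr(P)$rank < 4)
    stop("coplanar/degenerate landmark configuration: add landmarks or ",
         "use eps > 0 with a least-squares fit")
  M <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(Y, matrix(0, 4, 3))
  sol <- solve(M, rhs)
  structure(list(centers = X, weights = sol[1:n, , drop = FALSE],
                 affine = sol[(n + 1):(n + 4), , drop = FALSE],
                 eps = eps, scale = sc, origin = ctr),
            class = "deformation_field")
}

# minimal-norm augmented solve used by the tracker, tolerant of coplanar
# centroid sets (surface tissues); falls back to least-squares affine
fit_deformation_robust <- function(source, target, eps = 0) {
  n <- nrow(source)
  if (n >= 4) {
    f <- tryCatch(fit_deformation(source, target, eps = eps),
                  error = function(e) NULL)
    if (!is.null(f)) return(f)
    # coplanar landmarks (flat tissues): minimal-norm solve of the same
    # augmented system
    ctr <- colMeans(source)
    sc <- sqrt(mean(rowSums(sweep(source, 2, ctr)^2)))
    if (sc > 1e-12) {
      X <- sweep(source, 2, ctr) / sc
      Y <- sweep(target, 2, ctr) / sc
      K <- as.matrix(stats::dist(X))^3 + diag(eps, n)
      P <- cbind(1, X)
      M <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
      sol <- svd_pinv(M) %*% rbind(Y, matrix(0, 4, 3))
      f <- structure(list(centers = X, weights = sol[1:n, , drop = FALSE],
                          affine = sol[(n + 1):(n + 4), , drop = FALSE],
                          eps = eps, scale = sc, origin = ctr),
                     class = "deformation_field")
      resid <- max(abs(evaluate_deformation(f, source) - target))
      if (eps > 0 || resid < 1e-6 * sc) return(f)
    }
  }
  # similarity (Kabsch + isotropic scale) fallback for tiny or degenerate
  # landmark sets: extrapolates sanely where an under-determined affine
  # fit would not
  ctr <- colMeans(source)
  sc <- sqrt(mean(rowSums(sweep(source, 2, ctr)^2)))
  if (sc < 1e-12) sc <- 1
  X <- sweep(source, 2, ctr) / sc
  Y <- sweep(target, 2, ctr) / sc
  if (n >= 2) {
    Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
    H <- crossprod(Xc, Yc)
    s <- svd(H)
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    denom <- sum(Xc * Xc)
    k <- if (denom > 1e-12) sum(diag(R %*% crossprod(Xc, Yc))) / denom else 1
    if (!is.finite(k) || k <= 0) k <- 1
    B <- k * t(R)                       # y = x %*% B + b
    b <- colMeans(Y) - colMeans(X) %*% B
    A <- rbind(as.numeric(b), B)
  } else {
    A <- rbind(colMeans(Y) - colMeans(X), diag(3))
  }
  structure(list(centers = X[0, , drop = FALSE],
                 weights = matrix(0, 0, 3), affine = A,
                 eps = 0, scale = sc, origin = ctr),
            class = "deformation_field")
}

svd_pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.deformation_field <- function(x, ...) {
  cat("<deformation_field> ", nrow(x$centers), " RBF centers, eps = ",
      x$eps, "\n", sep = "")
  invisible(x)
}

#' Evaluate a deformation field at points
#'
#' @param field a [fit_deformation()] result.
#' @param points m x 3 matrix (micrometres).
#' @return m x 3 matrix of mapped points.
#' @export
evaluate_deformation <- function(field, points) {
  points <- rbind(as.matrix(points))
  X <- sweep(points, 2, field$origin) / field$scale
  P <- cbind(1, X)
  out <- P %*% field$affine
  if (nrow(field$centers)) {
    for (i in seq_len(nrow(field$centers))) {
      dv <- sweep(X, 2, field$centers[i, ])
      r <- sqrt(rowSums(dv * dv))
      out <- out + outer(r^3, field$weights[i, ])
    }
  }
  sweep(out * field$scale, 2, field$origin, `+`)
}

#' Analytic deformation gradient
#'
#' The 3 x 3 Jacobian F of the field at a point: the affine matrix plus,
#' per RBF center c with weight w, the term 3 r (x - c) outer w with
#' r = |x - c|. For the identity field F is the identity matrix.
#'
#' @param field a [fit_deformation()] result.
#' @param point length-3 position.
#' @return 3 x 3 matrix F (dimensionless).
#' @export
deformation_gradient <- function(field, point) {
  x <- (as.numeric(point) - field$origin) / field$scale
  Fm <- t(field$affine[2:4, , drop = FALSE])  # F_jk = d y_j / d x_k
  if (nrow(field$centers)) {
    for (i in seq_len(nrow(field$centers))) {
      d <- x - field$centers[i, ]
      r <- vnorm(d)
      if (r > 0) Fm <- Fm + 3 * r * outer(field$weights[i, ], d)
    }
  }
  dimnames(Fm) <- NULL
  Fm
}

# 2x2 surface stretch at a point: kmax, kmin and 3D emax from the tangent
# restriction of F
surface_stretch <- function(Fm, normal) {
  b <- tangent_basis(normal)
  a1 <- Fm %*% b$e1
  a2 <- Fm %*% b$e2
  C <- matrix(c(sum(a1 * a1), sum(a1 * a2), sum(a1 * a2), sum(a2 * a2)), 2)
  eg <- eigen(C, symmetric = TRUE)
  k <- sqrt(pmax(eg$values, 0))
  v1 <- eg$vectors[, 1]
  emax <- unitv(v1[1] * b$e1 + v1[2] * b$e2)
  list(kmax = k[1], kmin = k[2], emax = emax)
}

#' Subcellular growth from a deformation function
#'
#' Because the deformation field is continuous over the whole mesh, growth
#' can be evaluated at every vertex rather than once per cell: the analytic
#' gradient F is restricted to the local tangent plane and polar-decomposed
#' into principal stretches. The reported heat value is the product of the
#' maximal and minimal stretch (the local area multiplication factor).
#'
#' @param field a [fit_deformation()] result (t0 -> t1).
#' @param mesh the t0 [surface_cell_mesh()].
#' @return tibble `vertex`, `kmax`, `kmin`, `area_growth`.
#' @export
subcellular_growth <- function(field, mesh) {
  vn <- vertex_normals(mesh)
  out <- matrix(0, nrow(mesh$vertices), 2)
  for (i in seq_len(nrow(mesh$vertices))) {
    Fm <- deformation_gradient(field, mesh$vertices[i, ])
    s <- surface_stretch(Fm, vn[i, ])
    out[i, ] <- c(s$kmax, s$kmin)
  }
  tibble::tibble(vertex = seq_len(nrow(mesh$vertices)),
                 kmax = out[, 1], kmin = out[, 2],
                 area_growth = out[, 1] * out[, 2])
}

# area-weighted vertex normals
vertex_normals <- function(mesh) {
  nrm <- tri_normals(mesh$vertices, mesh$triangles)
  grp <- c(mesh$triangles[, 1], mesh$triangles[, 2], mesh$triangles[, 3])
  sums <- rowsum(rbind(nrm, nrm, nrm), group = grp)
  vn <- matrix(0, nrow(mesh$vertices), 3)
  vn[as.integer(rownames(sums)), ] <- sums
  nn <- sqrt(rowSums(vn * vn))
  nn[nn < 1e-300] <- 1
  vn / nn
}

#' Semi-automatic parent labeling between time points
#'
#' Iteratively tracks cell lineage from a handful of seed pairs: (1) a
#' deformation field mapping later-time centroids into the earlier frame is
#' fitted from the currently verified pairs; (2) every unassigned child
#' centroid is mapped and assigned to the earlier cell with the nearest
#' centroid; (3) each assignment is verified by neighborhood
#' correspondence: all assigned graph neighbors of a child must map to the
#' same parent or to one of the parent's graph neighbors, and at least one
#' neighbor must be assigned; failing labels are cleared; (4) repeat until
#' the verified set is stable (max 50 iterations). Only verified
#' assignments are returned; the rest are listed for manual curation.
#'
#' Mapped children landing further from every earlier centroid than
#' `gate_factor` times the median earlier-mesh neighbor spacing are left
#' unassigned, which keeps structures with no counterpart (e.g. newly
#' appeared tissue) from being falsely matched.
#'
#' @param mesh_t0,mesh_t1 the two time points (surface meshes).
#' @param seeds tibble with columns `child`, `parent` (>= 1 pair; >= 4
#'   enables the full RBF fit, fewer fall back to an affine fit with a
#'   warning).
#' @param strictness fraction of assigned neighbors that must be
#'   compatible (default 1 = all).
#' @param max_iter iteration cap.
#' @param gate_factor distance gate in units of median centroid spacing.
#' @param refine_rounds refinement passes (trim geometrically inconsistent
#'   correspondences against a ridge-smoothed field, refit, reassign).
#' @return list with `parents` (tibble `child`, `parent`) and `unresolved`
#'   (integer labels).
#' @export
auto_parent_label <- function(mesh_t0, mesh_t1, seeds, strictness = 1,
                              max_iter = 50, gate_factor = 3,
                              refine_rounds = 10) {
  if (!nrow(seeds)) stop("need at least one seed pair")
  if (nrow(seeds) < 4)
    warning("fewer than 4 seed pairs: initial fit is affine-only")
  g0 <- build_cell_graph(mesh_t0)
  g1 <- build_cell_graph(mesh_t1)
  c0 <- g0$nodes; c1 <- g1$nodes
  xyz0 <- as.matrix(c0[, c("x", "y", "z")])
  xyz1 <- as.matrix(c1[, c("x", "y", "z")])
  nb0 <- lapply(stats::setNames(c0$label, c0$label),
                function(l) graph_neighbors(g0, l))
  nb1 <- lapply(stats::setNames(c1$label, c1$label),
                function(l) graph_neighbors(g1, l))
  local_nn <- vapply(seq_len(nrow(xyz0)), function(i) {
    d2 <- rowSums(sweep(xyz0, 2, xyz0[i, ])^2)
    sqrt(min(d2[d2 > 0]))
  }, 0)
  spacing <- stats::median(local_nn)
  seed_child <- as.character(seeds$child)
  assigned <- stats::setNames(rep(NA_integer_, nrow(c1)),
                              as.character(c1$label))
  assigned[seed_child] <- as.integer(seeds$parent)

  # one landmark pair per parent: daughters of a divided mother collapse to
  # their mean centroid, so the field tracks the tissue deformation rather
  # than folding at divisions
  collapse_pairs <- function(asg) {
    ok <- !is.na(asg)
    src <- rowsum(xyz1[match(as.integer(names(asg)[ok]), c1$label), ,
                       drop = FALSE], group = asg[ok])
    src <- src / as.vector(table(asg[ok]))
    list(src = src,
         dst = xyz0[match(as.integer(rownames(src)), c0$label), ,
                    drop = FALSE],
         parent = as.integer(rownames(src)))
  }
  # worst-first trimming against a smoothing (ridge) field: topologically
  # self-consistent but shifted patches disagree with the smooth majority
  trim_pairs <- function(asg) {
    repeat {
      cp <- collapse_pairs(asg)
      if (nrow(cp$src) < 8) return(asg)
      fs <- fit_deformation_robust(cp$src, cp$dst, eps = 2)
      r <- sqrt(rowSums((evaluate_deformation(fs, cp$src) - cp$dst)^2)) /
        local_nn[match(cp$parent, c0$label)]
      if (max(r) <= 0.15) return(asg)
      worst <- cp$parent[r > max(0.15, 0.7 * max(r))]
      drop <- which(!is.na(asg) & asg %in% worst &
                      !(names(asg) %in% seed_child))
      if (!length(drop)) return(asg)
      asg[drop] <- NA_integer_
    }
  }
  # strict neighborhood verification, swept to a fixed point so that
  # incompatible patches erode from their edges; seeds are trusted
  erode <- function(asg) {
    repeat {
      cleared <- integer(0)
      for (i in seq_along(asg)) {
        if (is.na(asg[i]) || names(asg)[i] %in% seed_child) next
        p <- asg[i]
        nbp <- asg[as.character(nb1[[names(asg)[i]]])]
        nbp <- nbp[!is.na(nbp)]
        if (!length(nbp)) { cleared <- c(cleared, i); next }
        okset <- c(p, nb0[[as.character(p)]])
        if (mean(nbp %in% okset) < strictness - 1e-12)
          cleared <- c(cleared, i)
      }
      if (!length(cleared)) return(asg)
      asg[cleared] <- NA_integer_
    }
  }
  nearest_parent <- function(p) {
    d2 <- rowSums(sweep(xyz0, 2, p)^2)
    j <- which.min(d2)  # lowest index on ties
    c(j, sqrt(d2[j]))
  }

  # phase 1: bootstrap by region growing from the seeds under a tight
  # distance gate, so one early mistake cannot snowball into the fit
  for (iter in seq_len(max_iter)) {
    prev <- assigned
    cp <- collapse_pairs(assigned)
    fld <- fit_deformation_robust(cp$src, cp$dst)
    mapped <- evaluate_deformation(fld, xyz1)
    frontier <- which(is.na(assigned) & vapply(seq_along(assigned),
      function(i) any(!is.na(assigned[as.character(nb1[[
        names(assigned)[i]]])])), TRUE))
    if (!length(frontier)) frontier <- which(is.na(assigned))
    n_new <- 0L
    for (i in frontier) {
      np <- nearest_parent(mapped[i, ])
      if (np[2] <= 0.6 * local_nn[np[1]]) {
        assigned[i] <- c0$label[np[1]]
        n_new <- n_new + 1L
      }
    }
    if (n_new == 0L) {
      for (i in frontier) {
        np <- nearest_parent(mapped[i, ])
        if (np[2] <= gate_factor * spacing) assigned[i] <- c0$label[np[1]]
      }
    }
    assigned <- erode(assigned)
    if (identical(assigned, prev)) break
  }

  # phase 2: refinement -- trim geometrically inconsistent pairs, refit the
  # interpolating field from the survivors, reassign every child, erode
  for (round in seq_len(refine_rounds)) {
    prev <- assigned
    trimmed <- trim_pairs(assigned)
    cp <- collapse_pairs(trimmed)
    if (nrow(cp$src) < 4) break
    fld <- fit_deformation_robust(cp$src, cp$dst)
    mapped <- evaluate_deformation(fld, xyz1)
    for (i in seq_along(assigned)) {
      if (names(assigned)[i] %in% seed_child) next
      np <- nearest_parent(mapped[i, ])
      assigned[i] <- if (np[2] <= 0.6 * local_nn[np[1]])
        c0$label[np[1]] else NA_integer_
    }
    assigned <- erode(assigned)
    if (identical(assigned, prev)) break
  }
  done <- !is.na(assigned)
  list(parents = tibble::tibble(child = as.integer(names(assigned)[done]),
                                parent = as.integer(assigned[done])),
       unresolved = sort(as.integer(names(assigned)[!done])))
}

#' Morph a mesh sequence with Catmull-Rom interpolation
#'
#' Produces intermediate frames between time points whose meshes share a
#' per-vertex correspondence (same vertex count and ordering, e.g. from
#' deformation-field transport). Two time points interpolate linearly;
#' three or more use centripetal Catmull-Rom splines (alpha = 0.5, no
#' cusps; endpoint tangents from one-sided differences). Frames at the
#' knots reproduce the input meshes exactly. Optional per-cell heat values
#' are interpolated the same way.
#'
#' @param meshes list of >= 2 surface meshes with identical vertex counts.
#' @param n_frames total number of output frames (>= 2), evenly spaced in
#'   knot time.
#' @param heat optional list of numeric per-cell/per-vertex value vectors
#'   (one per mesh) to interpolate alongside.
#' @return list of frames; each has `mesh` and optionally `heat`.
#' @export
morph_sequence <- function(meshes, n_frames, heat = NULL) {
  k <- length(meshes)
  if (k < 2) stop("need at least 2 time points")
  if (n_frames < 2) stop("need at least 2 output frames")
  nv <- nrow(meshes[[1]]$vertices)
  for (m in meshes)
    if (nrow(m$vertices) != nv)
      stop("meshes must share a per-vertex correspondence")
  times <- seq(0, k - 1, length.out = n_frames)
  vmats <- lapply(meshes, `[[`, "vertices")
  frames <- lapply(times, function(t) {
    v <- interp_sequence(vmats, t)
    m <- meshes[[1]]
    m$vertices <- v
    out <- list(mesh = m, time = t)
    if (!is.null(heat)) {
      hmat <- lapply(heat, function(h) matrix(h, ncol = 1))
      out$heat <- as.numeric(interp_sequence(hmat, t))
    }
    out
  })
  frames
}

# interpolate a list of equally-shaped matrices at knot-time t in [0, k-1]
interp_sequence <- function(mats, t) {
  k <- length(mats)
  if (abs(t - round(t)) < 1e-12 && round(t) >= 0 && round(t) <= k - 1)
    return(mats[[round(t) + 1]])
  if (k == 2) return(mats[[1]] * (1 - t) + mats[[2]] * t)
  i <- min(max(floor(t), 0), k - 2)      # segment [i, i+1]
  u <- t - i
  p1 <- mats[[i + 1]]; p2 <- mats[[i + 2]]
  p0 <- if (i >= 1) mats[[i]] else 2 * p1 - p2       # one-sided endpoints
  p3 <- if (i + 3 <= k) mats[[i + 3]] else 2 * p2 - p1
  catmull_rom(p0, p1, p2, p3, u)
}

# centripetal Catmull-Rom (alpha = 0.5) evaluated elementwise on matrices
catmull_rom <- function(p0, p1, p2, p3, u, alpha = 0.5) {
  dst <- function(a, b) max(mean(sqrt(rowSums((a - b)^2)))^alpha, 1e-8)
  t0 <- 0
  t1 <- t0 + dst(p0, p1)
  t2 <- t1 + dst(p1, p2)
  t3 <- t2 + dst(p2, p3)
  t <- t1 + u * (t2 - t1)
  A1 <- p0 * ((t1 - t) / (t1 - t0)) + p1 * ((t - t0) / (t1 - t0))
  A2 <- p1 * ((t2 - t) / (t2 - t1)) + p2 * ((t - t1) / (t2 - t1))
  A3 <- p2 * ((t3 - t) / (t3 - t2)) + p3 * ((t - t2) / (t3 - t2))
  B1 <- A1 * ((t2 - t) / (t2 - t0)) + A2 * ((t - t0) / (t2 - t0))
  B2 <- A2 * ((t3 - t) / (t3 - t1)) + A3 * ((t - t1) / (t3 - t1))
  B1 * ((t2 - t) / (t2 - t1)) + B2 * ((t - t1) / (t2 - t1))
}
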