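#' Composite cubic Bezier spline for organ axes
#'
#' Organ midlines and developmental axes are represented as clamped
#' composite cubic Bezier curves: with `3k + 1` control points the curve
#' has `k` cubic segments joined C0; evaluation at parameter 0/1 returns
#' the first/last control point. Two control points define a straight
#' segment (elevated to cubic). The arc-length lookup table is built from
#' a dense per-segment sampling with 5-point Gauss-Legendre quadrature on
#' each subinterval, giving arc lengths accurate far below mesh resolution.
#'
#' @param control n x 3 matrix of control points (micrometres); n must be 2
#'   or `3k + 1`.
#' @param samples_per_segment density of the parameter-to-length lookup
#'   table (default 1000).
#' @return An object of class `bezier_spline`.
#' @export
bezier_spline <- function(control, samples_per_segment = 1000) {
  control <- as.matrix(control)
  stopifnot(ncol(control) == 3)
  if (nrow(control) == 2)  # straight segment, degree-elevated to cubic
    control <- rbind(control[1, ],
                     control[1, ] + (control[2, ] - control[1, ]) / 3,
                     control[1, ] + 2 * (control[2, ] - control[1, ]) / 3,
                     control[2, ])
  n <- nrow(control)
  if ((n - 1) %% 3 != 0)
    stop("composite cubic Bezier needs 3k + 1 control points, got ", n)
  if (max(apply(control, 2, function(x) diff(range(x)))) < 1e-12)
    stop("degenerate spline: all control points coincide")
  k <- (n - 1) %/% 3
  obj <- structure(list(control = control, n_segments = k), class = "bezier_spline")
  obj$lut <- bezier_build_lut(obj, samples_per_segment)
  obj
}

#' @export
print.bezier_spline <- function(x, ...) {
  cat("<bezier_spline> ", x$n_segments, " cubic segment(s), arc length ",
      sprintf("%.4g", bezier_length(x)), " um\n", sep = "")
  invisible(x)
}

# segment-local Bernstein evaluation; t global in [0,1]
bezier_eval <- function(spline, t) {
  t <- pmin(pmax(t, 0), 1)
  k <- spline$n_segments
  seg <- pmin(floor(t * k), k - 1)
  u <- t * k - seg
  out <- matrix(0, length(t), 3)
  for (s in unique(seg)) {
    i <- seg == s
    p <- spline$control[(3 * s + 1):(3 * s + 4), , drop = FALSE]
    uu <- u[i]
    b <- cbind((1 - uu)^3, 3 * uu * (1 - uu)^2, 3 * uu^2 * (1 - uu), uu^3)
    out[i, ] <- b %*% p
  }
  out
}

# derivative with respect to the global parameter t
bezier_deriv <- function(spline, t) {
  t <- pmin(pmax(t, 0), 1)
  k <- spline$n_segments
  seg <- pmin(floor(t * k), k - 1)
  u <- t * k - seg
  out <- matrix(0, length(t), 3)
  for (s in unique(seg)) {
    i <- seg == s
    p <- spline$control[(3 * s + 1):(3 * s + 4), , drop = FALSE]
    uu <- u[i]
    b <- cbind(-3 * (1 - uu)^2,
               3 * (1 - uu)^2 - 6 * uu * (1 - uu),
               6 * uu * (1 - uu) - 3 * uu^2,
               3 * uu^2)
    out[i, ] <- (b %*% p) * k
  }
  out
}

bezier_build_lut <- function(spline, samples_per_segment) {
  k <- spline$n_segments
  m <- k * samples_per_segment
  ts <- seq(0, 1, length.out = m + 1)
  # 5-point Gauss-Legendre on each subinterval of |dp/dt|
  gx <- c(-0.9061798459386640, -0.5384693101056831, 0,
          0.5384693101056831, 0.9061798459386640)
  gw <- c(0.2369268850561891, 0.4786286704993665, 0.5688888888888889,
          0.4786286704993665, 0.2369268850561891)
  h <- 1 / m
  mids <- (ts[-1] + ts[-(m + 1)]) / 2
  seg_len <- numeric(m)
  for (q in 1:5) {
    d <- bezier_deriv(spline, mids + gx[q] * h / 2)
    seg_len <- seg_len + gw[q] * sqrt(rowSums(d * d)) * h / 2
  }
  list(t = ts, s = c(0, cumsum(seg_len)),
       points = bezier_eval(spline, ts))
}

#' @export
bezier_length <- function(spline) spline$lut$s[length(spline$lut$s)]

# arc length at global parameter t (monotone interpolation of the LUT)
bezier_arclength_at <- function(spline, t) {
  stats::approx(spline$lut$t, spline$lut$s, xout = pmin(pmax(t, 0), 1),
                rule = 2)$y
}

# nearest parameter on the spline to point p: dense polyline scan over the
# LUT points, then golden-section refinement on the winning neighborhood
bezier_nearest_t <- function(spline, p) {
  pts <- spline$lut$points
  d2 <- (pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 + (pts[, 3] - p[3])^2
  i <- which.min(d2)
  ts <- spline$lut$t
  lo <- ts[max(i - 1L, 1L)]; hi <- ts[min(i + 1L, length(ts))]
  f <- function(t) sum((bezier_eval(spline, t)[1, ] - p)^2)
  golden_min(f, lo, hi, tol = 1e-12)
}

#' Fit a composite cubic Bezier through an ordered cell file
#'
#' Builds an organ-axis spline from an ordered run of cells (a "cell file")
#' by least-squares fitting cubic segments through their centroids with
#' chord-length parameterization. Segment boundaries are placed at
#' centroids, which the fitted spline interpolates exactly (clamped ends).
#'
#' @param labels ordered integer vector of cell labels (length >= 2).
#' @param mesh the mesh providing centroids, or a tibble of centroids with
#'   columns `label`, `x`, `y`, `z`.
#' @param max_segments upper bound on the number of cubic segments.
#' @return a [bezier_spline()].
#' @export
bezier_from_cell_file <- function(labels, mesh, max_segments = 8) {
  if (length(labels) < 2) stop("a cell file needs at least 2 cells")
  cen <- if (is.data.frame(mesh)) mesh else cell_centroids(mesh)
  ix <- match(labels, cen$label)
  if (anyNA(ix)) stop("labels missing from mesh: ",
                      paste(labels[is.na(ix)], collapse = ", "))
  pts <- as.matrix(cen[ix, c("x", "y", "z")])
  fit_composite_bezier(pts, max_segments)
}

# least-squares composite cubic through ordered points; knots at points
fit_composite_bezier <- function(pts, max_segments = 8) {
  n <- nrow(pts)
  if (n == 2) return(bezier_spline(pts))
  k <- max(1L, min(as.integer(max_segments), (n - 1L) %/% 4L))
  cuts <- round(seq(1, n, length.out = k + 1))
  ctrl <- NULL
  for (s in seq_len(k)) {
    sub <- pts[cuts[s]:cuts[s + 1], , drop = FALSE]
    cp <- fit_cubic_segment(sub)
    ctrl <- if (is.null(ctrl)) cp else rbind(ctrl, cp[-1, , drop = FALSE])
  }
  bezier_spline(ctrl)
}

# single clamped cubic through sub[1,] and sub[m,], LSQ over interior points
fit_cubic_segment <- function(sub) {
  m <- nrow(sub)
  p0 <- sub[1, ]; p3 <- sub[m, ]
  if (m == 2)
    return(rbind(p0, p0 + (p3 - p0) / 3, p0 + 2 * (p3 - p0) / 3, p3))
  d <- sqrt(rowSums((sub[-1, , drop = FALSE] -
                     sub[-m, , drop = FALSE])^2))
  u <- c(0, cumsum(d)) / sum(d)  # chord-length parameters
  b0 <- (1 - u)^3; b1 <- 3 * u * (1 - u)^2
  b2 <- 3 * u^2 * (1 - u); b3 <- u^3
  rhs <- sub - outer(b0, p0) - outer(b3, p3)
  A <- cbind(b1, b2)
  sol <- tryCatch(qr.solve(crossprod(A), crossprod(A, rhs)),
                  error = function(e) NULL)
  if (is.null(sol)) {  # degenerate (e.g. collinear duplicated params)
    p1 <- p0 + (p3 - p0) / 3; p2 <- p0 + 2 * (p3 - p0) / 3
  } else { p1 <- sol[1, ]; p2 <- sol[2, ] }
  rbind(p0, p1, p2, p3)
}
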