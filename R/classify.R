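#' Threshold classification of a cell attribute
#'
#' `k` sorted thresholds partition the attribute range into `k + 1`
#' classes by half-open intervals: a value exactly at a threshold joins
#' the upper class.
#'
#' @param attr tibble `label`, value (second column).
#' @param thresholds sorted increasing numeric vector.
#' @return tibble `label`, `class` (integer 1..k+1).
#' @export
threshold_classify <- function(attr, thresholds) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  cls <- findInterval(attr[[2]], thresholds, left.open = FALSE) + 1L
  tibble::tibble(label = attr$label, class = as.integer(cls))
}

#' 2D feature-space clustering of cells
#'
#' Clusters cells in a two-feature plane, replacing the interactive 2D
#' heat-map selection with either k-means on z-score-standardized features
#' (deterministic given `seed`) or polygon gates supplied as 2D polygons
#' in raw feature units, evaluated in order (first match wins; ungated
#' cells get class 0).
#'
#' @param features tibble with `label` and two feature columns (or name
#'   them with `x`/`y`).
#' @param x,y feature column names (default 2nd and 3rd column).
#' @param method `"kmeans"` or `"gates"`.
#' @param k number of k-means clusters (>= 2).
#' @param gates list of m x 2 polygon matrices (gate order = class order).
#' @param seed RNG seed for k-means.
#' @return tibble `label`, `class`.
#' @export
cluster_2d <- function(features, x = NULL, y = NULL,
                       method = c("kmeans", "gates"), k = 2, gates = NULL,
                       seed = 0) {
  method <- match.arg(method)
  x <- x %||% names(features)[2]
  y <- y %||% names(features)[3]
  X <- cbind(features[[x]], features[[y]])
  if (method == "kmeans") {
    if (k < 2) stop("k must be >= 2")
    Z <- apply(X, 2, function(col) {
      s <- stats::sd(col)
      if (!is.finite(s) || s < 1e-12) rep(0, length(col))
      else (col - mean(col)) / s
    })
    if (all(Z == 0) || nrow(unique(Z)) < k) {
      cls <- rep(1L, nrow(Z))       # degenerate: everything one cluster
    } else {
      old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
      set.seed(seed)
      cls <- stats::kmeans(Z, centers = k, nstart = 10)$cluster
    }
  } else {
    if (is.null(gates)) stop("gates method needs a list of polygons")
    cls <- rep(0L, nrow(X))
    for (gi in seq_along(gates)) {
      g <- as.matrix(gates[[gi]])
      inside <- mgcv::in.out(rbind(g, g[1, , drop = FALSE]), X)
      cls[cls == 0L & inside] <- gi
    }
  }
  tibble::tibble(label = features$label, class = as.integer(cls))
}

#' Train and apply an SVM cell-type classifier
#'
#' Multi-class support-vector machine (RBF kernel, one-vs-one) on any set
#' of cell measures and coordinates. Features are z-score standardized
#' with training-set statistics, which are stored in the model and reused
#' at prediction, so predictions are invariant to feature rescaling.
#'
#' @param features tibble with `label`, feature columns, and a `class`
#'   column for training rows.
#' @param feature_cols character vector of feature column names (default:
#'   all numeric columns except `label` and `class`).
#' @param cost,gamma SVM hyperparameters (defaults C = 1,
#'   gamma = 1/n_features).
#' @return `svm_train`: an object of class `cell_svm`.
#' @export
svm_train <- function(features, feature_cols = NULL, cost = 1,
                      gamma = NULL) {
  stopifnot("class" %in% names(features))
  train <- features[!is.na(features$class), , drop = FALSE]
  if (length(unique(train$class)) < 2)
    stop("need at least 2 classes with training rows")
  feature_cols <- feature_cols %||%
    setdiff(names(features)[vapply(features, is.numeric, TRUE)],
            c("label", "class"))
  X <- as.matrix(train[, feature_cols, drop = FALSE])
  mu <- colMeans(X)
  sg <- apply(X, 2, stats::sd)
  sg[!is.finite(sg) | sg < 1e-12] <- 1
  Z <- scale(X, center = mu, scale = sg)
  gamma <- gamma %||% (1 / length(feature_cols))
  fit <- e1071::svm(Z, factor(train$class), kernel = "radial", cost = cost,
                    gamma = gamma, scale = FALSE)
  structure(list(fit = fit, feature_cols = feature_cols, center = mu,
                 scale = sg), class = "cell_svm")
}

#' @rdname svm_train
#' @param model a `cell_svm` from [svm_train()].
#' @return `svm_predict`: tibble `label`, `class` for all rows with
#'   complete features.
#' @export
svm_predict <- function(model, features) {
  missing <- setdiff(model$feature_cols, names(features))
  if (length(missing))
    stop("features absent at prediction time: ",
         paste(missing, collapse = ", "))
  X <- as.matrix(features[, model$feature_cols, drop = FALSE])
  ok <- stats::complete.cases(X)
  Z <- scale(X[ok, , drop = FALSE], center = model$center,
             scale = model$scale)
  pred <- stats::predict(model$fit, Z)
  tibble::tibble(label = features$label[ok],
                 class = as.character(pred))
}

#' @export
print.cell_svm <- function(x, ...) {
  cat("<cell_svm> ", length(x$feature_cols), " features, ",
      length(x$fit$levels), " classes, ", x$fit$tot.nSV,
      " support vectors\n", sep = "")
  invisible(x)
}

#' Broom-style summaries for the SVM classifier
#' @param x a `cell_svm`.
#' @param ... unused.
#' @export
glance.cell_svm <- function(x, ...) {
  tibble::tibble(n_features = length(x$feature_cols),
                 n_classes = length(x$fit$levels),
                 n_support_vectors = x$fit$tot.nSV,
                 cost = x$fit$cost, gamma = x$fit$gamma)
}

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Cell-layer detection
#'
#' `radial` mode clusters the relative radial coordinate (1D k-means into
#' `k` layers, numbered from the outside: layer 1 has the largest mean
#' relative coordinate, i.e. lies at the surface). `surface` mode bins the
#' absolute distance from a surface mesh into layers of fixed thickness:
#' layer = floor(distance / thickness) + 1.
#'
#' @param attr tibble `label`, value: relative radial coordinate (radial
#'   mode) or absolute surface distance in micrometres (surface mode).
#' @param mode `"radial"` or `"surface"`.
#' @param k number of layers (radial mode).
#' @param thickness layer thickness in micrometres (surface mode).
#' @param seed k-means seed.
#' @return tibble `label`, `layer` (1 = outermost).
#' @export
detect_layers <- function(attr, mode = c("radial", "surface"), k = NULL,
                          thickness = NULL, seed = 0) {
  mode <- match.arg(mode)
  v <- attr[[2]]
  if (mode == "surface") {
    stopifnot(!is.null(thickness), thickness > 0)
    layer <- floor(v / thickness) + 1L
  } else {
    stopifnot(!is.null(k))
    if (k > length(unique(v)))
      stop("k exceeds the number of distinct coordinate values")
    if (k == 1L) {
      layer <- rep(1L, length(v))
    } else {
      # deterministic starting centers: evenly spaced distinct coordinates
      uq <- sort(unique(v))
      starts <- uq[round(seq(1, length(uq), length.out = k))]
      km <- stats::kmeans(v, centers = starts, iter.max = 100)
      # renumber from outside (largest relative coordinate) inward
      ord <- order(km$centers, decreasing = TRUE)
      remap <- integer(k); remap[ord] <- seq_len(k)
      layer <- remap[km$cluster]
    }
  }
  tibble::tibble(label = attr$label, layer = as.integer(layer))
}
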