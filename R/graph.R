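#' Build the cell connectivity graph of a labeled mesh
#'
#' Two cells are adjacent iff they share a boundary of positive measure:
#' at least one common triangle edge on a surface mesh (shared wall length,
#' micrometres) or a shared wall patch on a volumetric mesh (shared wall
#' area, square micrometres). A single shared vertex does not create an
#' edge, which prevents diagonal-adjacency artifacts.
#'
#' @param mesh a [surface_cell_mesh()] or [volumetric_cell_mesh()].
#' @return A `cell_graph`: list with `nodes` (tibble label/x/y/z), `edges`
#'   (tibble from/to/wall with from < to), and `dim` (2 or 3).
#' @export
build_cell_graph <- function(mesh) UseMethod("build_cell_graph")

#' @export
build_cell_graph.surface_cell_mesh <- function(mesh) {
  lab <- mesh$face_label
  if (all(lab == 0L)) stop("mesh has no labeled triangles")
  keep <- lab > 0L
  tr <- mesh$triangles[keep, , drop = FALSE]
  lab <- lab[keep]
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  el <- rep(lab, 3L)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  df <- data.frame(key = key, lab = el, len = len)
  # edges shared by exactly two triangles of different labels
  sp <- split(df, df$key)
  pairs <- lapply(sp, function(d) {
    u <- unique(d$lab)
    if (length(u) == 2L)
      data.frame(from = min(u), to = max(u), wall = d$len[1])
    else NULL
  })
  ed <- do.call(rbind, pairs)
  cen <- cell_centroids(mesh)
  if (is.null(ed)) {
    edges <- tibble::tibble(from = integer(), to = integer(),
                            wall = numeric())
  } else {
    agg <- stats::aggregate(wall ~ from + to, ed, sum)
    edges <- tibble::as_tibble(agg[order(agg$from, agg$to), ])
    edges$from <- as.integer(edges$from); edges$to <- as.integer(edges$to)
  }
  structure(list(nodes = cen, edges = edges, dim = 2L), class = "cell_graph")
}

#' @export
build_cell_graph.volumetric_cell_mesh <- function(mesh) {
  rows <- list()
  for (nm in names(mesh$cells)) {
    cl <- mesh$cells[[nm]]
    i <- as.integer(nm)
    ar <- tri_areas(cl$vertices, cl$triangles)
    for (tg in unique(cl$wall_tag[cl$wall_tag > 0L])) {
      if (i < tg)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          from = i, to = as.integer(tg), wall = sum(ar[cl$wall_tag == tg]))
    }
  }
  edges <- if (length(rows)) dplyr::arrange(dplyr::bind_rows(rows),
                                            .data$from, .data$to)
           else tibble::tibble(from = integer(), to = integer(),
                               wall = numeric())
  structure(list(nodes = cell_centroids_3d(mesh), edges = edges, dim = 3L),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat("<cell_graph> ", nrow(x$nodes), " cells, ", nrow(x$edges),
      " adjacencies (", if (x$dim == 2L) "2.5D" else "3D", ")\n", sep = "")
  invisible(x)
}

# igraph view with vertex name = label and edge attribute wall
as_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(graph$edges$from),
               to = as.character(graph$edges$to),
               wall = graph$edges$wall),
    directed = FALSE,
    vertices = data.frame(name = as.character(graph$nodes$label)))
  g
}

# neighbor labels of one cell
graph_neighbors <- function(graph, label) {
  e <- graph$edges
  sort(c(e$to[e$from == label], e$from[e$to == label]))
}
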