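#' Heat-map plot of a per-cell attribute on a surface mesh
#'
#' Draws the cell polygons (projected to the xy-plane) filled by an
#' attribute value -- the ggplot2 counterpart of an on-mesh heat map.
#'
#' @param mesh a [surface_cell_mesh()].
#' @param attr tibble `label`, value (second column used as fill).
#' @return a ggplot object.
#' @export
plot_cell_heatmap <- function(mesh, attr) {
  polys <- lapply(mesh_labels(mesh), function(lb) {
    loop <- cell_boundary_loop(mesh, lb)
    tibble::tibble(label = lb, x = mesh$vertices[loop, 1],
                   y = mesh$vertices[loop, 2])
  })
  df <- dplyr::bind_rows(polys)
  vname <- names(attr)[2]
  df <- dplyr::left_join(df, stats::setNames(attr[, 1:2],
                                             c("label", "..value")),
                         by = "label")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$label,
                                   fill = .data$..value)) +
    ggplot2::geom_polygon(color = "grey20", linewidth = 0.2) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = vname, x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Plot principal directions of growth on cell centroids
#'
#' Line segments along each cell's maximal-stretch direction, scaled by
#' kmax, over the cell outlines -- the usual PDG "crosses" display,
#' reduced to its major axis.
#'
#' @param mesh the t0 [surface_cell_mesh()].
#' @param pdgs output of [compute_pdgs()].
#' @param scale segment half-length per unit stretch (um).
#' @return a ggplot object.
#' @export
plot_pdgs <- function(mesh, pdgs, scale = 1.5) {
  cen <- cell_centroids(mesh)
  d <- dplyr::inner_join(cen, pdgs[pdgs$ok, ], by = "label")
  seg <- tibble::tibble(x = d$x - scale * d$kmax * d$emax_x,
                        xend = d$x + scale * d$kmax * d$emax_x,
                        y = d$y - scale * d$kmax * d$emax_y,
                        yend = d$y + scale * d$kmax * d$emax_y)
  base <- plot_cell_heatmap(mesh, tibble::tibble(label = cen$label,
                                                 value = NA_real_))
  base +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend),
                          inherit.aes = FALSE, color = "red") +
    ggplot2::labs(fill = NULL)
}

#' Tidy a PDG table into long form
#'
#' Broom-style `tidy()` for growth-tensor results: one row per cell and
#' quantity (`kmax`, `kmin`, `det_f`).
#'
#' @param x output tibble of [compute_pdgs()].
#' @param ... unused.
#' @export
tidy_pdgs <- function(x, ...) {
  x[x$ok, c("label", "kmax", "kmin", "det_f")] |>
    tidyr_pivot()
}

tidyr_pivot <- function(d) {
  out <- lapply(c("kmax", "kmin", "det_f"), function(q)
    tibble::tibble(label = d$label, quantity = q, value = d[[q]]))
  dplyr::bind_rows(out)
}
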