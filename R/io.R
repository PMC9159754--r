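#' Read a segmented cellular mesh
#'
#' Supported formats: PLY (per-face integer property `label`, optional
#' per-vertex `signal`; an additional per-face `wall` property marks a
#' volumetric cell complex), OBJ (geometry plus per-face label via material
#' names `cell_<label>`), and 3D label-TIFF stacks (unsigned integer voxel
#' labels; each cell's surface is extracted at the half-voxel iso-level of
#' its binary mask, unsmoothed, with wall patches tagged by neighbor label).
#'
#' @param path file path.
#' @param format one of `"ply"`, `"obj"`, `"tiff"`; guessed from the file
#'   extension by default.
#' @param voxel_size numeric length-3 voxel spacing in micrometres
#'   (TIFF only).
#' @return A [surface_cell_mesh()] or [volumetric_cell_mesh()].
#' @export
read_mesh <- function(path, format = NULL, voxel_size = c(1, 1, 1)) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- switch(tolower(tools::file_ext(path)),
                     ply = "ply", obj = "obj",
                     tif = "tiff", tiff = "tiff",
                     stop("cannot guess format of ", path))
  switch(match.arg(format, c("ply", "obj", "tiff")),
         ply = read_ply(path),
         obj = read_obj(path),
         tiff = read_label_stack(path, voxel_size))
}

#' Write a mesh to PLY or OBJ
#'
#' @param mesh a mesh object.
#' @param path output path.
#' @param format `"ply"` (default) or `"obj"` (surface meshes only).
#' @param binary write binary little-endian PLY (default) or ASCII.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = TRUE) {
  if (is.null(format))
    format <- switch(tolower(tools::file_ext(path)), obj = "obj", "ply")
  if (format == "obj") {
    if (!inherits(mesh, "surface_cell_mesh"))
      stop("OBJ export is supported for surface meshes only")
    write_obj(mesh, path)
  } else write_ply(mesh, path, binary = binary)
  invisible(path)
}

# ---- PLY ------------------------------------------------------------------
# Dialect: vertex properties x,y,z (double) [+ signal]; face list property
# vertex_indices plus int property "label" [+ int "wall" for volumetric].

ply_type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                   short = 2, ushort = 2, int16 = 2, uint16 = 2,
                   int = 4, uint = 4, int32 = 4, uint32 = 4,
                   float = 4, float32 = 4, double = 8, float64 = 8)

ply_read_scalar <- function(con, type) {
  sz <- ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64"))
    readBin(con, "double", 1, size = sz, endian = "little")
  else
    readBin(con, "integer", 1, size = sz, endian = "little",
            signed = !(sz < 4 && startsWith(type, "u")) )
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, 1)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL; elements <- list(); cur <- NULL
  repeat {
    ln <- readLines(con, 1)
    if (!length(ln)) stop("PLY parse error: unexpected end of header")
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!length(tok)) next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("PLY parse error: property before element")
      if (tok[2] == "list")
        elements[[cur]]$props[[tok[5]]] <- list(list = TRUE,
                                                count_type = tok[3],
                                                type = tok[4])
      else
        elements[[cur]]$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
    } else if (tok[1] == "end_header") break
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian"))
    stop("PLY parse error: unsupported format ", fmt %||% "<missing>")
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY parse error: missing vertex or face element")

  read_elem <- function(el) {
    out <- vector("list", el$count)
    if (fmt == "ascii") {
      for (i in seq_len(el$count)) {
        tok <- as.numeric(strsplit(trimws(readLines(con, 1)), "\\s+")[[1]])
        row <- list(); k <- 1L
        for (pn in names(el$props)) {
          p <- el$props[[pn]]
          if (p$list) {
            cnt <- tok[k]; row[[pn]] <- tok[(k + 1):(k + cnt)]; k <- k + 1L + cnt
          } else { row[[pn]] <- tok[k]; k <- k + 1L }
        }
        out[[i]] <- row
      }
    } else {
      for (i in seq_len(el$count)) {
        row <- list()
        for (pn in names(el$props)) {
          p <- el$props[[pn]]
          if (p$list) {
            cnt <- ply_read_scalar(con, p$count_type)
            row[[pn]] <- vapply(seq_len(cnt), function(j)
              ply_read_scalar(con, p$type), 0)
          } else row[[pn]] <- ply_read_scalar(con, p$type)
        }
        out[[i]] <- row
      }
    }
    out
  }
  vrows <- read_elem(elements$vertex)
  frows <- read_elem(elements$face)
  v <- t(vapply(vrows, function(r) c(r$x, r$y, r$z), numeric(3)))
  signal <- if ("signal" %in% names(elements$vertex$props))
    vapply(vrows, `[[`, 0, "signal") else NULL
  idx <- lapply(frows, function(r) r$vertex_indices %||% r$vertex_index)
  if (any(lengths(idx) != 3L)) stop("PLY parse error: non-triangular face")
  tr <- do.call(rbind, idx) + 1L
  lab <- if ("label" %in% names(elements$face$props))
    vapply(frows, `[[`, 0, "label") else rep(0, nrow(tr))
  if ("wall" %in% names(elements$face$props)) {
    wall <- vapply(frows, `[[`, 0, "wall")
    return(faces_to_volumetric(v, tr, as.integer(lab), as.integer(wall)))
  }
  surface_cell_mesh(v, tr, as.integer(lab), signal)
}

# regroup a pooled face soup (label = owner cell, wall = neighbor tag) into
# per-cell closed surfaces
faces_to_volumetric <- function(v, tr, lab, wall) {
  cells <- list()
  for (lb in sort(unique(lab))) {
    sel <- lab == lb
    t2 <- tr[sel, , drop = FALSE]
    used <- sort(unique(as.vector(t2)))
    remap <- integer(nrow(v)); remap[used] <- seq_along(used)
    cells[[as.character(lb)]] <- list(
      vertices = v[used, , drop = FALSE],
      triangles = matrix(remap[t2], ncol = 3),
      wall_tag = wall[sel])
  }
  volumetric_cell_mesh(cells)
}

write_ply <- function(mesh, path, binary = TRUE) {
  if (inherits(mesh, "volumetric_cell_mesh")) {
    pooled <- pool_volumetric(mesh)
    v <- pooled$vertices; tr <- pooled$triangles
    lab <- pooled$label; wall <- pooled$wall
    signal <- NULL
  } else {
    v <- mesh$vertices; tr <- mesh$triangles
    lab <- mesh$face_label; wall <- NULL
    signal <- mesh$vertex_signal
  }
  hdr <- c("ply",
           paste("format", if (binary) "binary_little_endian" else "ascii",
                 "1.0"),
           paste("element vertex", nrow(v)),
           "property double x", "property double y", "property double z",
           if (!is.null(signal)) "property double signal",
           paste("element face", nrow(tr)),
           "property list uchar int vertex_indices",
           "property int label",
           if (!is.null(wall)) "property int wall",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (binary) {
    vm <- if (is.null(signal)) v else cbind(v, signal)
    writeBin(as.vector(t(vm)), con, size = 8, endian = "little")
    for (i in seq_len(nrow(tr))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(tr[i, ] - 1L), con, size = 4, endian = "little")
      writeBin(as.integer(lab[i]), con, size = 4, endian = "little")
      if (!is.null(wall))
        writeBin(as.integer(wall[i]), con, size = 4, endian = "little")
    }
  } else {
    vm <- if (is.null(signal)) v else cbind(v, signal)
    writeLines(apply(vm, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), con)
    for (i in seq_len(nrow(tr)))
      writeLines(paste(c(3L, tr[i, ] - 1L, lab[i],
                         if (!is.null(wall)) wall[i]), collapse = " "), con)
  }
  invisible(path)
}

# merge per-cell surfaces into one vertex pool (coincident vertices merged)
pool_volumetric <- function(mesh) {
  vs <- list(); trs <- list(); labs <- list(); walls <- list()
  keymap <- new.env(hash = TRUE); nv <- 0L
  pool <- list()
  for (nm in names(mesh$cells)) {
    cl <- mesh$cells[[nm]]
    keys <- vertex_key(cl$vertices)
    idx <- integer(length(keys))
    for (i in seq_along(keys)) {
      k <- keys[i]
      j <- keymap[[k]]
      if (is.null(j)) {
        nv <- nv + 1L
        keymap[[k]] <- nv
        pool[[nv]] <- cl$vertices[i, ]
        j <- nv
      }
      idx[i] <- j
    }
    trs[[nm]] <- matrix(idx[cl$triangles], ncol = 3)
    labs[[nm]] <- rep(as.integer(nm), nrow(cl$triangles))
    walls[[nm]] <- cl$wall_tag
  }
  list(vertices = do.call(rbind, pool),
       triangles = do.call(rbind, trs),
       label = unlist(labs, use.names = FALSE),
       wall = unlist(walls, use.names = FALSE))
}

# ---- OBJ ------------------------------------------------------------------

read_obj <- function(path) {
  ln <- readLines(path)
  vlines <- grep("^v ", ln, value = TRUE)
  v <- do.call(rbind, lapply(strsplit(vlines, "\\s+"), function(t)
    as.numeric(t[2:4])))
  cur <- 0L; tris <- list(); labs <- integer(0)
  for (l in ln) {
    if (startsWith(l, "usemtl")) {
      m <- regmatches(l, regexec("cell_([0-9]+)", l))[[1]]
      if (length(m) < 2) stop("OBJ parse error: material name ", l,
                              " (expected cell_<label>)")
      cur <- as.integer(m[2])
    } else if (startsWith(l, "f ")) {
      tok <- strsplit(trimws(l), "\\s+")[[1]][-1]
      ix <- as.integer(vapply(strsplit(tok, "/"), `[[`, "", 1))
      if (length(ix) != 3L) stop("OBJ parse error: non-triangular face")
      tris[[length(tris) + 1L]] <- ix
      labs <- c(labs, cur)
    }
  }
  surface_cell_mesh(v, do.call(rbind, tris), labs)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(mesh$vertices, 1, function(r)
    paste("v", paste(sprintf("%.17g", r), collapse = " "))), con)
  ord <- order(mesh$face_label, seq_along(mesh$face_label))
  cur <- -1L
  for (i in ord) {
    lb <- mesh$face_label[i]
    if (lb != cur) { writeLines(paste0("usemtl cell_", lb), con); cur <- lb }
    writeLines(paste("f", paste(mesh$triangles[i, ], collapse = " ")), con)
  }
  invisible(path)
}

# ---- label TIFF -----------------------------------------------------------

#' Import a 3D label image as a volumetric cell mesh
#'
#' Every labeled voxel region becomes one cell; the cell surface is the
#' exact 0.5-level isosurface of the voxel mask (axis-aligned voxel faces,
#' two triangles each, no smoothing), so wall areas equal voxel-face counts
#' times the face area. Faces are tagged with the neighboring voxel's label
#' (0 at the image border or next to background).
#'
#' @param path TIFF stack path (unsigned integer labels, one slice per page).
#' @param voxel_size numeric length-3 spacing in micrometres.
#' @return A [volumetric_cell_mesh()].
#' @export
read_label_stack <- function(path, voxel_size = c(1, 1, 1)) {
  slices <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  arr <- array(0L, dim = c(nrow(slices[[1]]), ncol(slices[[1]]),
                           length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- as.integer(round(slices[[k]]))
  label_array_to_mesh(arr, voxel_size)
}

#' @rdname read_label_stack
#' @param labels integer 3D array of voxel labels (0 = background).
#' @export
label_array_to_mesh <- function(labels, voxel_size = c(1, 1, 1)) {
  stopifnot(length(dim(labels)) == 3)
  s <- as.numeric(voxel_size)
  d <- dim(labels)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- labels
  quads <- list()  # each row: owner, neighbor, face id, voxel ijk (unpadded)
  it <- which(pad > 0L, arr.ind = TRUE)
  for (r in seq_len(nrow(it))) {
    i <- it[r, 1]; j <- it[r, 2]; k <- it[r, 3]
    own <- pad[i, j, k]
    nb6 <- rbind(c(i + 1, j, k), c(i - 1, j, k), c(i, j + 1, k),
                 c(i, j - 1, k), c(i, j, k + 1), c(i, j, k - 1))
    for (f in 1:6) {
      nb <- pad[nb6[f, 1], nb6[f, 2], nb6[f, 3]]
      if (nb != own)
        quads[[length(quads) + 1L]] <- c(own, nb, f, i - 1L, j - 1L, k - 1L)
    }
  }
  if (!length(quads)) stop("label image contains no labeled voxels")
  qm <- do.call(rbind, quads)
  # voxel (i,j,k) in 1-based unpadded coords spans [(i-1),i]*s etc.
  face_corners <- function(f, i, j, k) {
    x0 <- (i - 1) * s[1]; x1 <- i * s[1]
    y0 <- (j - 1) * s[2]; y1 <- j * s[2]
    z0 <- (k - 1) * s[3]; z1 <- k * s[3]
    # corners ordered CCW as seen from outside the voxel
    switch(f,
      rbind(c(x1, y0, z0), c(x1, y1, z0), c(x1, y1, z1), c(x1, y0, z1)), # +x
      rbind(c(x0, y0, z0), c(x0, y0, z1), c(x0, y1, z1), c(x0, y1, z0)), # -x
      rbind(c(x0, y1, z0), c(x0, y1, z1), c(x1, y1, z1), c(x1, y1, z0)), # +y
      rbind(c(x0, y0, z0), c(x1, y0, z0), c(x1, y0, z1), c(x0, y0, z1)), # -y
      rbind(c(x0, y0, z1), c(x1, y0, z1), c(x1, y1, z1), c(x0, y1, z1)), # +z
      rbind(c(x0, y0, z0), c(x0, y1, z0), c(x1, y1, z0), c(x1, y0, z0))) # -z
  }
  cells <- list()
  for (lb in sort(unique(qm[, 1]))) {
    sel <- qm[, 1] == lb
    keymap <- new.env(hash = TRUE); pool <- list(); nv <- 0L
    tris <- list(); tags <- integer(0)
    for (r in which(sel)) {
      cr <- face_corners(qm[r, 3], qm[r, 4], qm[r, 5], qm[r, 6])
      idx <- integer(4)
      keys <- vertex_key(cr)
      for (ci in 1:4) {
        key <- keys[ci]
        jx <- keymap[[key]]
        if (is.null(jx)) {
          nv <- nv + 1L; keymap[[key]] <- nv; pool[[nv]] <- cr[ci, ]; jx <- nv
        }
        idx[ci] <- jx
      }
      tris[[length(tris) + 1L]] <- rbind(idx[c(1, 2, 3)], idx[c(1, 3, 4)])
      tags <- c(tags, qm[r, 2], qm[r, 2])
    }
    cells[[as.character(lb)]] <- list(vertices = do.call(rbind, pool),
                                      triangles = do.call(rbind, tris),
                                      wall_tag = tags)
  }
  volumetric_cell_mesh(cells)
}

# ---- CSV attribute maps, lineage, Bezier control points -------------------

#' Export and import per-cell attribute maps as CSV
#'
#' One row per label, one column per attribute; vector/tensor components use
#' suffixed headers (already flattened in the tibble). Missing labels keep
#' empty fields and survive a round trip.
#'
#' @param attrs a tibble with a `label` column, or a named list of such
#'   tibbles joined on `label`.
#' @param path output CSV path (header `Label,<attr>,...`).
#' @export
export_attributes <- function(attrs, path) {
  if (!is.data.frame(attrs)) {
    nms <- unlist(lapply(attrs, function(d) setdiff(names(d), "label")))
    if (anyDuplicated(nms)) stop("duplicate attribute names: ",
                                 paste(unique(nms[duplicated(nms)]),
                                       collapse = ", "))
    attrs <- Reduce(function(a, b) dplyr::full_join(a, b, by = "label"),
                    attrs)
  }
  if (anyDuplicated(setdiff(names(attrs), "label")))
    stop("duplicate attribute names")
  out <- dplyr::arrange(attrs, .data$label)
  names(out)[names(out) == "label"] <- "Label"
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname export_attributes
#' @export
import_attributes <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  names(d)[tolower(names(d)) == "label"] <- "label"
  d$label <- as.integer(d$label)
  tibble::as_tibble(d)
}

#' Read and write child-to-parent lineage tables
#'
#' The parent map relates each cell label at the later time point (`child`)
#' to its mother's label at the earlier time point (`parent`); the relation
#' is many-to-one and children may be unassigned (absent rows).
#'
#' @param path CSV path with header `child,parent`.
#' @return tibble with integer columns `child`, `parent`.
#' @export
read_parent_map <- function(path) {
  d <- utils::read.csv(path)
  names(d) <- tolower(names(d))
  stopifnot(all(c("child", "parent") %in% names(d)))
  pm <- tibble::tibble(child = as.integer(d$child),
                       parent = as.integer(d$parent))
  if (anyDuplicated(pm$child)) stop("parent map is not many-to-one: ",
                                    "duplicate child labels")
  pm
}

#' @rdname read_parent_map
#' @param parents tibble with columns `child`, `parent`.
#' @export
write_parent_map <- function(parents, path) {
  utils::write.csv(parents[, c("child", "parent")], path, row.names = FALSE)
  invisible(path)
}

#' Read Bezier control points from CSV
#'
#' @param path CSV with columns `x,y,z` (one control point per row).
#' @return a [bezier_spline()].
#' @export
read_bezier_csv <- function(path) {
  d <- utils::read.csv(path)
  names(d) <- tolower(names(d))
  bezier_spline(as.matrix(d[, c("x", "y", "z")]))
}
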