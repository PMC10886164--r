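# Surface-mesh containers and STL / legacy-VTK I/O.
#
# A surface mesh is a list(vertices = n x 3 matrix [mm], faces = m x 3
# integer matrix, 1-based, outward-oriented). Volume meshes carry cell data
# (HU, material) into VTK unstructured output for inspection.

surface_mesh <- function(vertices, faces) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 3,
            is.matrix(faces), ncol(faces) == 3)
  structure(list(vertices = vertices, faces = matrix(as.integer(faces), ncol = 3)),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("Surface mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Check that a triangle mesh is watertight (closed, 2-manifold, consistently oriented)
#'
#' @param mesh a surface mesh (list with `vertices`, `faces`).
#' @return logical scalar; attributes `n_boundary_edges` and `euler` carry
#'   diagnostics (Euler characteristic 2 for a genus-0 closed surface).
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key_dir <- paste(e[, 1], e[, 2])
  key_und <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key_und)
  manifold <- all(cnt == 2L)
  oriented <- !any(duplicated(key_dir))   # each directed edge appears once
  nv <- length(unique(as.vector(f)))
  ne <- length(cnt)
  nf <- nrow(f)
  ok <- manifold && oriented
  structure(ok, n_boundary_edges = sum(cnt == 1L), euler = nv - ne + nf)
}

mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(rowSums(a * cross3m(b, cc))) / 6
}

#' Write a surface mesh as STL
#'
#' @param mesh surface mesh.
#' @param path output path.
#' @param binary write binary STL (default) or ASCII.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices; f <- mesh$faces
  n <- nrow(f)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  nrm <- cross3m(b - a, cc - a)
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(n), con, size = 4, endian = "little")
    tri <- t(cbind(nrm, a, b, cc))           # 12 floats per facet
    for (i in seq_len(n)) {
      writeBin(as.numeric(tri[, i]), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(n)) {
      writeLines(sprintf("facet normal %g %g %g", nrm[i, 1], nrm[i, 2], nrm[i, 3]), con)
      writeLines(" outer loop", con)
      writeLines(sprintf("  vertex %g %g %g", a[i, 1], a[i, 2], a[i, 3]), con)
      writeLines(sprintf("  vertex %g %g %g", b[i, 1], b[i, 2], b[i, 3]), con)
      writeLines(sprintf("  vertex %g %g %g", cc[i, 1], cc[i, 2], cc[i, 3]), con)
      writeLines(" endloop", con)
      writeLines("endfacet", con)
    }
    writeLines("endsolid mesh", con)
  }
  invisible(path)
}

#' Read an STL file (binary or ASCII) into a surface mesh
#'
#' Duplicate vertices are merged exactly (coordinate triple identity).
#'
#' @param path STL file path.
#' @return a surface mesh.
#' @export
read_stl <- function(path) {
  hdr <- readBin(path, "raw", n = 6)
  is_ascii <- identical(rawToChar(hdr[1:5]), "solid") &&
    !is_binary_stl(path)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  verts <- matrix(tri, ncol = 3, byrow = TRUE)
  key <- paste(verts[, 1], verts[, 2], verts[, 3])
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  v <- verts[uk, , drop = FALSE]
  f <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(v, f)
}

is_binary_stl <- function(path) {
  sz <- file.info(path)$size
  if (sz < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  n <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  sz == 84 + 50 * as.numeric(n)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  n <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  out <- numeric(9 * n)
  for (i in seq_len(n)) {
    rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    readBin(con, "integer", n = 1, size = 2, endian = "little")
    out[(9 * (i - 1) + 1):(9 * i)] <- rec[4:12]
  }
  out
}

read_stl_ascii <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", ln, value = TRUE)
  as.numeric(unlist(lapply(strsplit(trimws(vl), "\\s+"), function(x) x[2:4])))
}

#' Write a tetrahedral volume mesh as legacy-VTK unstructured grid (ASCII)
#'
#' Cell data arrays (e.g. per-element HU, material id, modulus) and point
#' data arrays can be attached for inspection in ParaView.
#'
#' @param mesh a `volume_mesh` (see [tetrahedralize()]).
#' @param path output path.
#' @param cell_data named list of numeric vectors, one value per element.
#' @param point_data named list of numeric vectors, one value per node.
#' @export
write_vtk <- function(mesh, path, cell_data = list(), point_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0", "tibiofit volume mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", nn), con)
  writeLines(apply(mesh$nodes, 1, function(p) paste(p, collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", ne, 5 * ne), con)
  writeLines(apply(mesh$tets - 1L, 1, function(t) paste(c(4, t), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("10", ne), con)
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", ne), con)
    for (nm in names(cell_data)) {
      writeLines(sprintf("SCALARS %s double 1", nm), con)
      writeLines("LOOKUP_TABLE default", con)
      writeLines(format(cell_data[[nm]], digits = 10), con)
    }
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nn), con)
    for (nm in names(point_data)) {
      writeLines(sprintf("SCALARS %s double 1", nm), con)
      writeLines("LOOKUP_TABLE default", con)
      writeLines(format(point_data[[nm]], digits = 10), con)
    }
  }
  invisible(path)
}

#' Write / read a rigid transform as JSON (row-major rotation + translation)
#'
#' @param tf a `rigid_transform`.
#' @param path file path.
#' @export
write_transform_json <- function(tf, path) {
  jsonlite::write_json(
    list(rotation = as.vector(t(tf$rotation)), translation = tf$translation),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(x$rotation, 3, 3, byrow = TRUE), x$translation)
}
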