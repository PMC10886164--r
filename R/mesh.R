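# Tetrahedralization.
#
# Solids handled by the pipeline (cut bone, extruded tray/insert plates,
# generic star-shaped closed surfaces) are meshed by a layered structured
# scheme: each axial level carries a centre node plus concentric rings
# following the section outline; cells between levels (wedges at the core,
# warped hexahedra elsewhere) are split into tetrahedra with a fixed
# template whose face diagonals agree between neighbours, so the mesh is
# conforming by construction. Discretisation density follows the target
# edge-length interval (times a global scale factor for coarse runs).

#' Volume mesh constructor
#'
#' @param nodes n x 3 node coordinates (mm).
#' @param tets e x 4 integer connectivity (1-based); all signed volumes
#'   must be positive.
#' @param element_hu,element_material optional per-element data.
#' @param node_sets named list of integer node-index vectors.
#' @return a `volume_mesh`.
#' @export
volume_mesh <- function(nodes, tets, element_hu = NULL,
                        element_material = NULL, node_sets = list()) {
  tets <- matrix(as.integer(tets), ncol = 4)
  vol <- tet_volumes(nodes, tets)
  if (any(vol <= 0)) stop("volume mesh has non-positive tetrahedra", call. = FALSE)
  for (s in node_sets) {
    if (length(s) && (min(s) < 1 || max(s) > nrow(nodes))) {
      stop("node set references invalid nodes", call. = FALSE)
    }
  }
  structure(list(nodes = nodes, tets = tets, element_hu = element_hu,
                 element_material = element_material, node_sets = node_sets),
            class = "volume_mesh")
}

#' @export
print.volume_mesh <- function(x, ...) {
  cat(sprintf("Volume mesh: %d nodes, %d tets, sets: %s\n",
              nrow(x$nodes), nrow(x$tets),
              paste(names(x$node_sets), collapse = ", ")))
  invisible(x)
}

#' Signed tetrahedron volumes
#'
#' @param nodes n x 3 coordinates.
#' @param tets e x 4 connectivity.
#' @return numeric vector of signed volumes (mm^3).
#' @export
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  cc <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (cc[, 2] * d[, 3] - cc[, 3] * d[, 2]) -
   b[, 2] * (cc[, 1] * d[, 3] - cc[, 3] * d[, 1]) +
   b[, 3] * (cc[, 1] * d[, 2] - cc[, 2] * d[, 1])) / 6
}

#' Edge lengths of a tetrahedral mesh (unique edges)
#'
#' @param mesh a `volume_mesh`.
#' @return numeric vector of edge lengths (mm).
#' @export
mesh_edge_lengths <- function(mesh) {
  t <- mesh$tets
  e <- rbind(t[, c(1, 2)], t[, c(1, 3)], t[, c(1, 4)],
             t[, c(2, 3)], t[, c(2, 4)], t[, c(3, 4)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  sqrt(rowSums((mesh$nodes[e[, 1], , drop = FALSE] -
                mesh$nodes[e[, 2], , drop = FALSE])^2))
}

# Boundary triangles of a volume mesh whose three nodes all belong to
# `node_set` (e.g. the resection surface). Returned oriented so normals
# point along +direction if given.
mesh_surface_faces <- function(mesh, node_set, direction = NULL) {
  inset <- rep(FALSE, nrow(mesh$nodes)); inset[node_set] <- TRUE
  t <- mesh$tets
  faces_local <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  out <- list()
  for (fl in seq_len(4)) {
    f <- t[, faces_local[fl, ], drop = FALSE]
    keep <- inset[f[, 1]] & inset[f[, 2]] & inset[f[, 3]]
    if (any(keep)) out[[length(out) + 1]] <- f[keep, , drop = FALSE]
  }
  f <- do.call(rbind, out)
  # keep only boundary faces: interior faces are shared by two tets
  key <- apply(t(apply(f, 1, sort)), 1, paste, collapse = "_")
  cnt <- table(key)
  f <- f[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
  if (!is.null(direction)) {
    a <- mesh$nodes[f[, 1], , drop = FALSE]
    b <- mesh$nodes[f[, 2], , drop = FALSE]
    cc <- mesh$nodes[f[, 3], , drop = FALSE]
    n <- cross3m(b - a, cc - a)
    flip <- n %*% direction < 0
    f[flip, 2:3] <- f[flip, c(3, 2), drop = FALSE]
  }
  f
}

# --- layered structured mesher -------------------------------------------

# 6-tet hexahedron template (all tets share the 0-6 body diagonal); face
# diagonals agree between structured-grid neighbours.
hex_template <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                      c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))

# Build a layered mesh. `levels` is the vector of axial coordinates;
# `section_at(z)` returns list(center = c(x, y), radius = f(theta_vec)).
# When `r_fix` is given, ring 1 is pinned at that absolute radius at every
# level (e.g. a bore or peg wall); outer rings interpolate from it to the
# section boundary. `keep_cell(j, k)` masks cells per layer gap j and ring
# band k (k = 0 is the centre wedge band, k >= 1 the band between rings k
# and k+1); orphaned nodes are dropped and indices remapped.
build_layered_mesh <- function(levels, section_at, ntheta, nr,
                               set_names = c(bottom = "bottom", top = "top"),
                               layer_tag = NULL, r_fix = NULL,
                               keep_cell = NULL) {
  nl <- length(levels)
  theta <- seq(0, 2 * pi, length.out = ntheta + 1)[-(ntheta + 1)]
  per <- 1L + nr * ntheta
  nid <- function(j, k, i) {     # k = 0 centre, else ring k, angle index i (1-based, wraps)
    base <- (j - 1L) * per
    if (k == 0L) return(rep(base + 1L, length(i)))
    base + 1L + (k - 1L) * ntheta + ((i - 1L) %% ntheta) + 1L
  }
  nodes <- matrix(0, nl * per, 3)
  for (j in seq_len(nl)) {
    s <- section_at(levels[j])
    r <- s$radius(theta)
    base <- (j - 1L) * per
    nodes[base + 1L, ] <- c(s$center, levels[j])
    for (k in seq_len(nr)) {
      rk <- if (is.null(r_fix)) {
        (k / nr) * r
      } else if (k == 1L) {
        rep(r_fix, ntheta)
      } else {
        r_fix + (r - r_fix) * (k - 1) / (nr - 1)
      }
      rows <- base + 1L + (k - 1L) * ntheta + seq_len(ntheta)
      nodes[rows, ] <- cbind(s$center[1] + rk * cos(theta),
                             s$center[2] + rk * sin(theta),
                             levels[j])
    }
  }

  tets <- vector("list", nl - 1L)
  tag <- character(0)
  for (j in seq_len(nl - 1L)) {
    cells <- list()
    i <- seq_len(ntheta)
    if (is.null(keep_cell) || keep_cell(j, 0L)) {
      # core wedges: centre to ring 1
      a <- nid(j, 0L, i); b <- nid(j, 1L, i); cc <- nid(j, 1L, i + 1L)
      d <- nid(j + 1L, 0L, i); e <- nid(j + 1L, 1L, i); f <- nid(j + 1L, 1L, i + 1L)
      cells[[length(cells) + 1]] <-
        rbind(cbind(a, b, cc, f), cbind(a, b, f, e), cbind(a, e, f, d))
    }
    if (nr >= 2) {
      for (k in seq_len(nr - 1L)) {
        if (!is.null(keep_cell) && !keep_cell(j, k)) next
        v <- cbind(nid(j, k, i), nid(j, k, i + 1L),
                   nid(j, k + 1L, i + 1L), nid(j, k + 1L, i),
                   nid(j + 1L, k, i), nid(j + 1L, k, i + 1L),
                   nid(j + 1L, k + 1L, i + 1L), nid(j + 1L, k + 1L, i))
        for (tt in seq_len(6)) {
          cells[[length(cells) + 1]] <- v[, hex_template[tt, ], drop = FALSE]
        }
      }
    }
    layer_cells <- do.call(rbind, cells)
    tets[[j]] <- layer_cells
    if (!is.null(layer_tag)) tag <- c(tag, rep(layer_tag[j], nrow(layer_cells)))
  }
  tets <- do.call(rbind, tets)

  # drop orphaned nodes (deleted regions), remap connectivity
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nl * per)
  remap[used] <- seq_along(used)
  nodes <- nodes[used, , drop = FALSE]
  tets <- matrix(remap[tets], ncol = 4)

  # enforce positive orientation element-wise
  vol <- tet_volumes(nodes, tets)
  neg <- vol < 0
  tets[neg, 3:4] <- tets[neg, c(4, 3), drop = FALSE]
  vol <- tet_volumes(nodes, tets)
  if (any(vol <= 0)) stop("mesher failure: degenerate tetrahedra", call. = FALSE)

  grid_ids <- function(j, k, i = seq_len(ntheta)) {
    ids <- remap[nid(j, k, i)]
    ids[ids > 0L]
  }
  level_nodes <- function(j) {
    ids <- c(grid_ids(j, 0L, 1L),
             unlist(lapply(seq_len(nr), function(k) grid_ids(j, k))))
    unique(ids)
  }
  sets <- list()
  sets[[set_names[["bottom"]]]] <- level_nodes(1L)
  sets[[set_names[["top"]]]] <- level_nodes(nl)
  list(nodes = nodes, tets = tets, node_sets = sets, layer_tag = tag,
       per_layer = per, ntheta = ntheta, nr = nr, grid_ids = grid_ids,
       nl = nl)
}

# Discretisation parameters from the edge-length target.
mesh_density <- function(extent, rmax, cfg) {
  h <- mean(cfg$edge_length) * cfg$edge_scale
  nl <- max(2L, as.integer(round(extent / h)) + 1L)
  nr <- max(2L, as.integer(round(rmax / h)))
  ntheta <- max(8L, as.integer(round(2 * pi * rmax * 0.75 / h)))
  list(nl = nl, nr = nr, ntheta = ntheta, h = h)
}

#' Tetrahedralize a solid
#'
#' Methods exist for `cut_solid` (the resected bone; proximal face becomes
#' the `interface_bone` set, distal face the `distal_fixed` set), for
#' `surface_mesh` (any closed star-shaped surface, e.g. an STL read with
#' [read_stl()]), and for implant plates built with [implant_volume()].
#'
#' @param solid the solid to mesh.
#' @param cfg a [geometry_config()]; the edge-length interval (times
#'   `edge_scale`) controls density.
#' @param ... passed to methods.
#' @return a `volume_mesh` with populated node sets and, for bone, the
#'   per-element HU sampled at element centroids.
#' @export
tetrahedralize <- function(solid, cfg = geometry_config(), ...) {
  UseMethod("tetrahedralize")
}

#' @export
#' @rdname tetrahedralize
#' @param bore optional central bore for the fixation peg:
#'   `list(radius, depth, center = c(x, y))` (mm, below the resection).
tetrahedralize.cut_solid <- function(solid, cfg = geometry_config(),
                                     bore = NULL, ...) {
  extent <- solid$z_prox - solid$z_dist
  s0 <- solid$section(solid$z_prox, seq(0, 2 * pi, length.out = 60)[-60])
  rmax <- max(s0$radius)
  dd <- mesh_density(extent, rmax, cfg)
  ctr_fix <- if (!is.null(bore)) (bore$center %||% c(0, 0)) else NULL
  if (is.null(bore)) {
    levels <- seq(solid$z_dist, solid$z_prox, length.out = dd$nl)
    r_fix <- NULL; keep <- NULL
  } else {
    zb <- solid$z_prox - bore$depth
    if (zb <= solid$z_dist) stop("bore deeper than the cut solid", call. = FALSE)
    h <- dd$h
    lower <- seq(solid$z_dist, zb, length.out = max(2L, round((zb - solid$z_dist) / h) + 1L))
    upper <- seq(zb, solid$z_prox, length.out = max(2L, round(bore$depth / (h / 2)) + 1L))
    levels <- c(lower, upper[-1])
    jb <- length(lower)                 # bore floor gap index
    r_fix <- bore$radius
    keep <- function(j, k) !(k == 0L && j >= jb)
  }
  section_at <- function(z) {
    th_probe <- seq(0, 2 * pi, length.out = 2 * dd$ntheta + 1)[-(2 * dd$ntheta + 1)]
    s <- solid$section(z, th_probe, center = ctr_fix)
    list(center = s$center,
         radius = function(theta) {
           # nearest-angle lookup on the probed outline
           idx <- round(theta / (2 * pi) * length(th_probe)) %% length(th_probe) + 1
           s$radius[idx]
         })
  }
  nr <- if (is.null(bore)) dd$nr else {
    max(3L, as.integer(round((rmax - bore$radius) / dd$h)) + 1L)
  }
  lm <- build_layered_mesh(levels, section_at, dd$ntheta, nr,
                           set_names = c(bottom = "distal_fixed",
                                         top = "interface_bone"),
                           r_fix = r_fix, keep_cell = keep)
  sets <- lm$node_sets
  if (!is.null(bore)) {
    jb <- which(abs(levels - (solid$z_prox - bore$depth)) < 1e-9)[1]
    wall <- unlist(lapply(jb:lm$nl, function(j) lm$grid_ids(j, 1L)))
    sets$bore_wall <- unique(wall)
    floorn <- c(lm$grid_ids(jb, 0L, 1L), lm$grid_ids(jb, 1L))
    sets$bore_floor <- unique(floorn)
  }
  centroids <- (lm$nodes[lm$tets[, 1], ] + lm$nodes[lm$tets[, 2], ] +
                lm$nodes[lm$tets[, 3], ] + lm$nodes[lm$tets[, 4], ]) / 4
  world <- apply_transform(invert_transform(solid$to_local), centroids)
  hu <- sample_hu(solid$tibia, world)
  m <- volume_mesh(lm$nodes, lm$tets, element_hu = hu,
                   element_material = rep("bone", nrow(lm$tets)),
                   node_sets = sets)
  attr(m, "analytic_volume") <- solid$analytic_volume
  m
}

#' @export
tetrahedralize.surface_mesh <- function(solid, cfg = geometry_config(), ...) {
  v <- solid$vertices
  zr <- range(v[, 3])
  eps <- 1e-6 * diff(zr)
  extent <- diff(zr)
  segs_top <- plane_section_segments(solid, zr[2] - max(eps, 1e-9))
  rmax <- max(sqrt((segs_top[, c(1, 3)] - mean(v[, 1]))^2 +
                   (segs_top[, c(2, 4)] - mean(v[, 2]))^2))
  # probe a few levels for the true max radius
  probe_z <- seq(zr[1] + eps, zr[2] - eps, length.out = 5)
  rmax <- max(vapply(probe_z, function(z) {
    s <- plane_section_segments(solid, z)
    ctr <- c(mean(c(s[, 1], s[, 3])), mean(c(s[, 2], s[, 4])))
    max(sqrt((c(s[, 1], s[, 3]) - ctr[1])^2 + (c(s[, 2], s[, 4]) - ctr[2])^2))
  }, 0))
  dd <- mesh_density(extent, rmax, cfg)
  levels <- seq(zr[1], zr[2], length.out = dd$nl)
  section_at <- function(z) {
    zq <- min(max(z, zr[1] + eps), zr[2] - eps)
    segs <- plane_section_segments(solid, zq)
    ctr <- c(mean(c(segs[, 1], segs[, 3])), mean(c(segs[, 2], segs[, 4])))
    list(center = ctr,
         radius = function(theta) segments_radius(segs, ctr, theta))
  }
  lm <- build_layered_mesh(levels, section_at, dd$ntheta, dd$nr)
  volume_mesh(lm$nodes, lm$tets, node_sets = lm$node_sets)
}

#' Implant plate solid (tray + bonded insert) for one catalog size
#'
#' The tray occupies the distal slab (distal face at `z0`), the insert the
#' proximal slab; they share nodes at the interface (bonded).
#'
#' @param size_entry one element of `implant_catalog()$sizes`.
#' @param z0 distal-face level (mm), usually the resection plane.
#' @param placement optional in-plane `rigid_transform` from
#'   [select_tray_size()].
#' @return an `implant_solid`.
#' @export
implant_volume <- function(size_entry, z0 = 0, placement = NULL) {
  structure(list(entry = size_entry, z0 = z0, placement = placement),
            class = "implant_solid")
}

#' @export
tetrahedralize.implant_solid <- function(solid, cfg = geometry_config(), ...) {
  en <- solid$entry
  h <- mean(cfg$edge_length) * cfg$edge_scale
  # axial levels: peg tip, distal face, tray/insert bond plane (exact),
  # insert top; refined within each slab to the target edge length
  z_bond <- solid$z0 + en$tray_thickness
  z_top <- z_bond + en$insert_thickness
  z_tip <- solid$z0 - en$peg_length
  lv0 <- seq(z_tip, solid$z0, length.out = max(2L, round(en$peg_length / (h / 2)) + 1L))
  lv1 <- seq(solid$z0, z_bond, length.out = max(2L, round(en$tray_thickness / h) + 1L))
  lv2 <- seq(z_bond, z_top, length.out = max(2L, round(en$insert_thickness / h) + 1L))
  levels <- c(lv0, lv1[-1], lv2[-1])
  j0 <- length(lv0)                    # tray distal-face level index
  tag <- c(rep("tray", length(lv0) - 1L + length(lv1) - 1L),
           rep("insert", length(lv2) - 1L))
  rmax <- max(sqrt(rowSums(en$outline^2)))
  nr <- max(3L, as.integer(round((rmax - en$peg_radius) / h)) + 1L)
  ntheta <- max(8L, as.integer(round(2 * pi * rmax * 0.75 / h)))
  th0 <- atan2(en$outline[, 2], en$outline[, 1])
  r0 <- sqrt(rowSums(en$outline^2))
  ord <- order(th0)
  th_s <- th0[ord]; r_s <- r0[ord]
  bnd <- function(theta) {
    stats::approx(c(th_s - 2 * pi, th_s, th_s + 2 * pi),
                  c(r_s, r_s, r_s), xout = theta)$y
  }
  # below the tray only the peg (centre band) exists
  section_at <- function(z) {
    if (z < solid$z0 - 1e-9) {
      list(center = c(0, 0), radius = function(theta) {
        rep(en$peg_radius * 1.0001, length(theta))  # degenerate outer rings, removed
      })
    } else {
      list(center = c(0, 0), radius = bnd)
    }
  }
  keep <- function(j, k) j >= j0 || k == 0L
  lm <- build_layered_mesh(levels, section_at, ntheta, nr,
                           set_names = c(bottom = "peg_tip",
                                         top = "load_surface"),
                           layer_tag = tag, r_fix = en$peg_radius,
                           keep_cell = keep)
  sets <- lm$node_sets
  sets$interface_implant <- unique(unlist(lapply(seq_len(nr), function(k) {
    lm$grid_ids(j0, k)
  })))
  sets$peg_wall <- unique(unlist(lapply(seq_len(j0), function(j) {
    lm$grid_ids(j, 1L)
  })))
  nodes <- lm$nodes
  if (!is.null(solid$placement)) nodes <- apply_transform(solid$placement, nodes)
  volume_mesh(nodes, lm$tets,
              element_material = lm$layer_tag,
              node_sets = sets)
}

#' Structured solid cylinder mesh
#'
#' Layered structured cylinder; node sets `z0`, `z1` (end faces) and
#' `side` (lateral surface). Used by the interference-fit benchmark peg.
#'
#' @param radius,height cylinder dimensions, mm.
#' @param nr,ntheta,nz divisions.
#' @return a `volume_mesh`.
#' @export
mesh_cylinder <- function(radius, height, nr = 3, ntheta = 24, nz = 2) {
  levels <- seq(0, height, length.out = nz + 1)
  section_at <- function(z) {
    list(center = c(0, 0), radius = function(theta) rep(radius, length(theta)))
  }
  lm <- build_layered_mesh(levels, section_at, ntheta, nr,
                           set_names = c(bottom = "z0", top = "z1"))
  sets <- lm$node_sets
  sets$side <- unique(unlist(lapply(seq_len(lm$nl), function(j) {
    lm$grid_ids(j, nr)
  })))
  volume_mesh(lm$nodes, lm$tets, node_sets = sets)
}

#' Structured tetrahedral box mesh
#'
#' Regular grid of hexahedra split into six tetrahedra each; used by the
#' verification benchmarks (patch test, cantilever).
#'
#' @param lx,ly,lz box dimensions (mm).
#' @param nx,ny,nz element divisions per direction.
#' @param origin corner coordinates.
#' @return a `volume_mesh` with face node sets `x0`, `x1`, `y0`, `y1`,
#'   `z0`, `z1`.
#' @export
mesh_box <- function(lx, ly, lz, nx, ny, nz, origin = c(0, 0, 0)) {
  xs <- seq(0, lx, length.out = nx + 1) + origin[1]
  ys <- seq(0, ly, length.out = ny + 1) + origin[2]
  zs <- seq(0, lz, length.out = nz + 1) + origin[3]
  nid <- function(i, j, k) {
    (k - 1L) * (nx + 1L) * (ny + 1L) + (j - 1L) * (nx + 1L) + i
  }
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  colnames(nodes) <- NULL
  cells <- list()
  for (k in seq_len(nz)) for (j in seq_len(ny)) {
    i <- seq_len(nx)
    v <- cbind(nid(i, j, k), nid(i + 1L, j, k), nid(i + 1L, j + 1L, k), nid(i, j + 1L, k),
               nid(i, j, k + 1L), nid(i + 1L, j, k + 1L), nid(i + 1L, j + 1L, k + 1L),
               nid(i, j + 1L, k + 1L))
    for (tt in seq_len(6)) {
      cells[[length(cells) + 1]] <- v[, hex_template[tt, ], drop = FALSE]
    }
  }
  tets <- do.call(rbind, cells)
  vol <- tet_volumes(nodes, tets)
  neg <- vol < 0
  tets[neg, 3:4] <- tets[neg, c(4, 3), drop = FALSE]
  tolxyz <- 1e-9 * max(lx, ly, lz)
  sets <- list(
    x0 = which(abs(nodes[, 1] - origin[1]) < tolxyz),
    x1 = which(abs(nodes[, 1] - (origin[1] + lx)) < tolxyz),
    y0 = which(abs(nodes[, 2] - origin[2]) < tolxyz),
    y1 = which(abs(nodes[, 2] - (origin[2] + ly)) < tolxyz),
    z0 = which(abs(nodes[, 3] - origin[3]) < tolxyz),
    z1 = which(abs(nodes[, 3] - (origin[3] + lz)) < tolxyz)
  )
  volume_mesh(nodes, tets, node_sets = sets)
}

#' Structured tetrahedral tube (thick-walled cylinder) mesh
#'
#' Used by the interference-fit pressure benchmark.
#'
#' @param ri,ro inner and outer radius (mm), `ri < ro`.
#' @param height axial length (mm).
#' @param nr,ntheta,nz divisions.
#' @return a `volume_mesh` with node sets `inner`, `outer`, `z0`, `z1`.
#' @export
mesh_tube <- function(ri, ro, height, nr = 3, ntheta = 24, nz = 2) {
  stopifnot(ri > 0, ro > ri)
  nr <- as.integer(nr); ntheta <- as.integer(ntheta); nz <- as.integer(nz)
  theta <- seq(0, 2 * pi, length.out = ntheta + 1)[-(ntheta + 1)]
  rs <- seq(ri, ro, length.out = nr + 1)
  zs <- seq(0, height, length.out = nz + 1)
  per <- (nr + 1L) * ntheta
  nid <- function(j, k, i) {
    (j - 1L) * per + (k - 1L) * ntheta + ((i - 1L) %% ntheta) + 1L
  }
  nodes <- matrix(0, (nz + 1L) * per, 3)
  for (j in seq_len(nz + 1L)) for (k in seq_len(nr + 1L)) {
    rows <- (j - 1L) * per + (k - 1L) * ntheta + seq_len(ntheta)
    nodes[rows, ] <- cbind(rs[k] * cos(theta), rs[k] * sin(theta), zs[j])
  }
  cells <- list()
  for (j in seq_len(nz)) for (k in seq_len(nr)) {
    i <- seq_len(ntheta)
    v <- cbind(
      vapply(i, function(ii) nid(j, k, ii), 0L),
      vapply(i, function(ii) nid(j, k, ii + 1L), 0L),
      vapply(i, function(ii) nid(j, k + 1L, ii + 1L), 0L),
      vapply(i, function(ii) nid(j, k + 1L, ii), 0L),
      vapply(i, function(ii) nid(j + 1L, k, ii), 0L),
      vapply(i, function(ii) nid(j + 1L, k, ii + 1L), 0L),
      vapply(i, function(ii) nid(j + 1L, k + 1L, ii + 1L), 0L),
      vapply(i, function(ii) nid(j + 1L, k + 1L, ii), 0L)
    )
    for (tt in seq_len(6)) {
      cells[[length(cells) + 1]] <- v[, hex_template[tt, ], drop = FALSE]
    }
  }
  tets <- do.call(rbind, cells)
  vol <- tet_volumes(nodes, tets)
  neg <- vol < 0
  tets[neg, 3:4] <- tets[neg, c(4, 3), drop = FALSE]
  r <- sqrt(nodes[, 1]^2 + nodes[, 2]^2)
  sets <- list(
    inner = which(abs(r - ri) < 1e-9 * ro),
    outer = which(abs(r - ro) < 1e-9 * ro),
    z0 = which(abs(nodes[, 3]) < 1e-9 * height),
    z1 = which(abs(nodes[, 3] - height) < 1e-9 * height)
  )
  volume_mesh(nodes, tets, node_sets = sets)
}
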