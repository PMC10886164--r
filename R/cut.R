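# Bone cuts.
#
# The cut solid is represented implicitly: the posed tibia surface is
# brought into the anatomical frame (joint line at z = 0) and the solid is
# the slab between the proximal resection plane (proximal_cut_depth below
# the articular surface, orthogonal to the proximal-distal axis) and the
# distal truncation plane (distal_cut_level from the joint line). Sections
# are recovered by plane-mesh intersection and star-shaped ray casting,
# which is also what the tetrahedralizer consumes.

#' Geometry configuration
#'
#' @param proximal_cut_depth mm below the articular surface, default 8.9.
#' @param distal_cut_level mm from the joint line to the distal truncation,
#'   default 100.
#' @param max_overhang allowed tray overhang beyond the cut outline, mm.
#' @param edge_length target tetrahedral edge-length interval, mm.
#' @param edge_scale global multiplier on `edge_length` so coarse desk-scale
#'   meshes use the same configuration surface.
#' @return a `geometry_config` list.
#' @export
geometry_config <- function(proximal_cut_depth = 8.9,
                            distal_cut_level = 100,
                            max_overhang = 2,
                            edge_length = c(2.0, 2.5),
                            edge_scale = 1) {
  stopifnot(proximal_cut_depth >= 0, distal_cut_level > 0,
            max_overhang > 0, edge_scale > 0,
            length(edge_length) == 2, edge_length[1] < edge_length[2],
            edge_length[1] > 0)
  structure(list(proximal_cut_depth = proximal_cut_depth,
                 distal_cut_level = distal_cut_level,
                 max_overhang = max_overhang,
                 edge_length = edge_length,
                 edge_scale = edge_scale),
            class = "geometry_config")
}

# Intersection of a triangle mesh with the plane z = z0: a matrix of 2D
# segments (x1, y1, x2, y2), one per crossing triangle.
plane_section_segments <- function(mesh, z0) {
  v <- mesh$vertices; f <- mesh$faces
  dz <- v[, 3] - z0
  s <- matrix(dz[f], ncol = 3)
  cross <- (apply(s, 1, max) > 0) & (apply(s, 1, min) < 0)
  f <- f[cross, , drop = FALSE]
  if (nrow(f) == 0) stop("cut plane misses the mesh", call. = FALSE)
  segs <- matrix(NA_real_, nrow(f), 4)
  for (r in seq_len(nrow(f))) {
    tri <- f[r, ]
    p <- v[tri, , drop = FALSE]
    d <- p[, 3] - z0
    pts <- matrix(NA_real_, 0, 2)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      d1 <- d[e[1]]; d2 <- d[e[2]]
      if ((d1 > 0) != (d2 > 0)) {
        t <- d1 / (d1 - d2)
        pts <- rbind(pts, p[e[1], 1:2] + t * (p[e[2], 1:2] - p[e[1], 1:2]))
      }
    }
    if (nrow(pts) >= 2) segs[r, ] <- c(pts[1, ], pts[2, ])
  }
  segs[stats::complete.cases(segs), , drop = FALSE]
}

# Star-shaped radius of a section: for each angle, the farthest intersection
# of the ray from `center` with the section segments.
segments_radius <- function(segs, center, theta) {
  p1x <- segs[, 1] - center[1]; p1y <- segs[, 2] - center[2]
  p2x <- segs[, 3] - center[1]; p2y <- segs[, 4] - center[2]
  ex <- p2x - p1x; ey <- p2y - p1y
  vapply(theta, function(th) {
    dx <- cos(th); dy <- sin(th)
    den <- dx * ey - dy * ex
    ok <- abs(den) > 1e-14
    s <- (dy * p1x - dx * p1y) / den
    r <- (p1x * ey - p1y * ex) / den
    hit <- ok & s >= -1e-9 & s <= 1 + 1e-9 & r > 0
    if (!any(hit)) return(NA_real_)
    max(r[hit])
  }, 0)
}

#' Perform the proximal and distal bone cuts
#'
#' The proximal resection plane lies `proximal_cut_depth` below the
#' articular surface along the proximal-distal axis; the distal truncation
#' plane lies `distal_cut_level` from the joint line. Both planes are
#' orthogonal to the proximal-distal axis by construction.
#'
#' @param tibia a `synthetic_tibia`.
#' @param frame its `anatomical_frame` (see [assign_frame()]).
#' @param cfg a [geometry_config()].
#' @param align optional extra `rigid_transform` (e.g. a CPD refinement)
#'   applied after the frame transform, in local coordinates.
#' @return a `cut_solid`: the frame-local surface mesh, cut levels
#'   `z_prox`, `z_dist`, the resection outline polygon (n x 2, mm), a
#'   section evaluator, and the analytic solid volume.
#' @export
cut_bone <- function(tibia, frame, cfg = geometry_config(), align = NULL) {
  to_local <- frame_to_local(frame)
  if (!is.null(align)) to_local <- compose_transform(align, to_local)
  v <- apply_transform(to_local, tibia$surface$vertices)
  mesh <- surface_mesh(v, tibia$surface$faces)

  z_prox <- -cfg$proximal_cut_depth
  z_dist <- -cfg$distal_cut_level
  zr <- range(v[, 3])
  if (z_prox <= zr[1] || z_prox >= zr[2]) {
    stop("proximal cut plane misses the mesh", call. = FALSE)
  }
  if (z_dist <= zr[1] || z_dist >= zr[2]) {
    stop("distal cut plane misses the mesh", call. = FALSE)
  }
  eps <- 1e-6 * diff(zr)
  zeval <- function(z) min(max(z, zr[1] + eps), zr[2] - eps)

  section <- function(z, theta, center = NULL) {
    segs <- plane_section_segments(mesh, zeval(z))
    ctr <- center %||%
      c(mean(c(segs[, 1], segs[, 3])), mean(c(segs[, 2], segs[, 4])))
    r <- segments_radius(segs, ctr, theta)
    if (anyNA(r)) stop("section ray casting failed (non-star-shaped?)", call. = FALSE)
    list(center = ctr, radius = r)
  }

  nth <- 360
  theta <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]
  s0 <- section(z_prox, theta)
  outline <- cbind(x = s0$center[1] + s0$radius * cos(theta),
                   y = s0$center[2] + s0$radius * sin(theta))

  # analytic volume: integrate section polygon areas over the slab
  nzi <- 80
  zs <- seq(z_dist, z_prox, length.out = nzi)
  areas <- vapply(zs, function(z) {
    s <- section(z, theta)
    polygon_area(cbind(s$center[1] + s$radius * cos(theta),
                       s$center[2] + s$radius * sin(theta)))
  }, 0)
  vol <- sum((areas[-1] + areas[-nzi]) / 2) * diff(zs)[1]

  structure(list(
    mesh = mesh, z_prox = z_prox, z_dist = z_dist,
    outline = outline, section = section,
    analytic_volume = vol, to_local = to_local,
    tibia = tibia
  ), class = "cut_solid")
}

#' @export
print.cut_solid <- function(x, ...) {
  cat(sprintf("Cut solid: z in [%.1f, %.1f] mm, outline area %.0f mm^2, volume %.0f mm^3\n",
              x$z_dist, x$z_prox, polygon_area(x$outline), x$analytic_volume))
  invisible(x)
}
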