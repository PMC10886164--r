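# Tray sizing against the resection outline.
#
# The tray size is chosen to cover the cut surface optimally subject to an
# overhang bound: overhang is the largest outward signed distance of the
# tray footprint boundary beyond the bone outline, sampled at >= 360
# boundary points. Coverage is the area of the footprint that lies inside
# the outline, evaluated on a deterministic grid.

# Even-odd point-in-polygon test, vectorised over points.
points_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  inside <- rep(FALSE, nrow(pts))
  x <- pts[, 1]; y <- pts[, 2]
  for (k in seq_len(n)) {
    xi <- poly[k, 1]; yi <- poly[k, 2]
    xj <- poly[j[k], 1]; yj <- poly[j[k], 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  inside
}

# Unsigned distance from points to a polygon boundary (fully vectorised:
# m points x n edges in one pass).
points_polygon_distance <- function(pts, poly) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  e <- b - a
  el2 <- rowSums(e^2); el2[el2 == 0] <- 1e-300
  px <- outer(pts[, 1], a[, 1], `-`)       # m x n
  py <- outer(pts[, 2], a[, 2], `-`)
  t <- sweep(sweep(px, 2, e[, 1], `*`) + sweep(py, 2, e[, 2], `*`), 2, el2, `/`)
  t[t < 0] <- 0; t[t > 1] <- 1
  dx <- px - sweep(t, 2, e[, 1], `*`)
  dy <- py - sweep(t, 2, e[, 2], `*`)
  sqrt(apply(dx * dx + dy * dy, 1, min))
}

# Signed distance: positive outside the polygon.
points_polygon_signed <- function(pts, poly) {
  d <- points_polygon_distance(pts, poly)
  ifelse(points_in_polygon(pts, poly), -d, d)
}

# Maximum overhang (mm) of a footprint placed at offset (tx, ty).
footprint_overhang <- function(outline_fp, bone_outline, tx, ty, n_samples = 360) {
  fp <- resample_closed(outline_fp, n_samples)
  fp[, 1] <- fp[, 1] + tx
  fp[, 2] <- fp[, 2] + ty
  max(points_polygon_signed(fp, bone_outline))
}

# Resample a closed polygon to n points by arc length.
resample_closed <- function(poly, n) {
  p <- rbind(poly, poly[1, ])
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  si <- seq(0, total, length.out = n + 1)[seq_len(n)]
  ix <- findInterval(si, s, rightmost.closed = TRUE)
  t <- (si - s[ix]) / pmax(seg[ix], 1e-300)
  p[ix, , drop = FALSE] + t * (p[ix + 1, , drop = FALSE] - p[ix, , drop = FALSE])
}

# Covered cut-surface area: area of footprint inside the outline.
footprint_coverage <- function(outline_fp, bone_outline, tx, ty, n_grid = 40) {
  bb <- apply(outline_fp, 2, range)
  gx <- seq(bb[1, 1], bb[2, 1], length.out = n_grid)
  gy <- seq(bb[1, 2], bb[2, 2], length.out = n_grid)
  g <- as.matrix(expand.grid(x = gx, y = gy))
  in_fp <- points_in_polygon(g, outline_fp)
  gs <- cbind(g[, 1] + tx, g[, 2] + ty)
  in_bone <- points_in_polygon(gs, bone_outline)
  cell <- diff(gx)[1] * diff(gy)[1]
  sum(in_fp & in_bone) * cell
}

#' Select the tray size for a resection outline
#'
#' Returns the catalog size maximising covered cut-surface area subject to
#' the overhang bound; ties break toward the smaller size. For each size
#' the in-plane placement is optimised (translation only) to minimise the
#' maximum overhang before the bound is checked.
#'
#' @param cut_outline resection outline polygon (n x 2, mm), e.g.
#'   `cut_solid$outline`.
#' @param catalog an [implant_catalog()].
#' @param max_overhang allowed overhang, mm (default 2).
#' @return a `tray_selection`: `size` (index), `placement`
#'   (`rigid_transform` in the cut plane: footprint coordinates ->
#'   outline coordinates), `overhang` (mm), `coverage` (mm^2), and the
#'   per-size score table `candidates`.
#' @export
select_tray_size <- function(cut_outline, catalog, max_overhang = 2) {
  if (!length(catalog$sizes)) stop("empty implant catalog", call. = FALSE)
  ctr <- colMeans(cut_outline)
  cand <- lapply(catalog$sizes, function(sz) {
    fp120 <- resample_closed(sz$outline, 120)   # coarse samples for the search
    obj <- function(par) {
      max(points_polygon_signed(cbind(fp120[, 1] + ctr[1] + par[1],
                                      fp120[, 2] + ctr[2] + par[2]),
                                cut_outline))
    }
    opt <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                        control = list(maxit = 80, reltol = 1e-4))
    tx <- ctr[1] + opt$par[1]; ty <- ctr[2] + opt$par[2]
    list(size = sz$size,
         overhang = footprint_overhang(sz$outline, cut_outline, tx, ty),
         coverage = footprint_coverage(sz$outline, cut_outline, tx, ty),
         tx = tx, ty = ty)
  })
  tab <- data.frame(
    size = vapply(cand, `[[`, 0, "size"),
    overhang = vapply(cand, `[[`, 0, "overhang"),
    coverage = vapply(cand, `[[`, 0, "coverage")
  )
  ok <- tab$overhang <= max_overhang
  if (!any(ok)) {
    stop(sprintf("no tray size satisfies overhang <= %g mm (best violating overhang %.2f mm, size %d)",
                 max_overhang, min(tab$overhang), tab$size[which.min(tab$overhang)]),
         call. = FALSE)
  }
  feas <- which(ok)
  best <- feas[order(-tab$coverage[feas], tab$size[feas])][1]
  structure(list(
    size = tab$size[best],
    placement = rigid_transform(diag(3), c(cand[[best]]$tx, cand[[best]]$ty, 0)),
    overhang = tab$overhang[best],
    coverage = tab$coverage[best],
    candidates = tab
  ), class = "tray_selection")
}

#' @export
print.tray_selection <- function(x, ...) {
  cat(sprintf("Tray selection: size %d (overhang %.2f mm, coverage %.0f mm^2)\n",
              x$size, x$overhang, x$coverage))
  invisible(x)
}
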