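# Parametric cementless tray / insert catalog.
#
# Each size is a rounded asymmetric footprint (slightly flattened
# posteriorly, like a tibial baseplate), extruded to a flat tray with the
# polyethylene insert bonded on top. Tray + insert thickness equals the
# 8.9 mm proximal resection, so the reconstruction restores the original
# tibial length. Footprint areas are strictly increasing with size.

#' Build the implant size catalog
#'
#' @param halfwidths medial-lateral half-extents (mm) of the footprint,
#'   one per size, strictly increasing.
#' @param depth_ratio anterior-posterior half-extent as a fraction of the
#'   half-width.
#' @param tray_thickness tray plate thickness, mm.
#' @param insert_thickness insert thickness, mm; tray + insert default to
#'   the 8.9 mm resection stack.
#' @param peg_ratio central fixation peg radius as a fraction of the
#'   half-width; the peg carries the radial interference fit.
#' @param peg_length peg length below the tray distal face, mm.
#' @param n_outline points on the footprint outline polygon.
#' @return an `implant_catalog`: list of sizes ordered by footprint area,
#'   each with `halfwidth`, `halfdepth`, `outline` (n x 2 polygon, mm),
#'   `area`, `tray_thickness`, `insert_thickness`, `stem` descriptor.
#' @export
implant_catalog <- function(halfwidths = c(26, 29, 32, 35, 38, 41),
                            depth_ratio = 0.66,
                            tray_thickness = 4.0,
                            insert_thickness = 4.9,
                            peg_ratio = 0.22,
                            peg_length = 12,
                            n_outline = 72) {
  if (any(diff(halfwidths) <= 0)) {
    stop("halfwidths must be strictly increasing", call. = FALSE)
  }
  sizes <- lapply(seq_along(halfwidths), function(k) {
    a <- halfwidths[k]; b <- a * depth_ratio
    th <- seq(0, 2 * pi, length.out = n_outline + 1)[-(n_outline + 1)]
    r <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
    r <- r * (1 - 0.06 * pmax(0, -sin(th))^2)   # posterior flattening
    outline <- cbind(x = r * cos(th), y = r * sin(th))
    area <- polygon_area(outline)
    list(size = k, halfwidth = a, halfdepth = b, outline = outline,
         area = area, tray_thickness = tray_thickness,
         insert_thickness = insert_thickness,
         peg_radius = peg_ratio * a, peg_length = peg_length,
         stem = list(type = "central_peg", radius = peg_ratio * a,
                     length = peg_length))
  })
  stopifnot(all(diff(vapply(sizes, `[[`, 0, "area")) > 0))
  structure(list(sizes = sizes), class = "implant_catalog")
}

#' @export
print.implant_catalog <- function(x, ...) {
  cat(sprintf("Implant catalog: %d sizes, footprint areas %s mm^2\n",
              length(x$sizes),
              paste(round(vapply(x$sizes, `[[`, 0, "area")), collapse = ", ")))
  invisible(x)
}

# Shoelace area of a simple polygon (n x 2).
polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

# Surface mesh of the extruded tray (or insert) for one catalog size,
# distal face at z = z0, extruded upward by `thickness`.
implant_surface_mesh <- function(size_entry, z0 = 0,
                                 thickness = size_entry$tray_thickness) {
  o <- size_entry$outline
  n <- nrow(o)
  vb <- cbind(o, z0)            # bottom ring
  vt <- cbind(o, z0 + thickness)
  cb <- c(0, 0, z0)
  ct <- c(0, 0, z0 + thickness)
  verts <- rbind(vb, vt, cb, ct)
  ib <- seq_len(n); it <- n + ib
  icb <- 2L * n + 1L; ict <- 2L * n + 2L
  nxt <- function(i) (i %% n) + 1L
  faces <- rbind(
    cbind(ib, ib[nxt(seq_len(n))], it),                       # side
    cbind(ib[nxt(seq_len(n))], it[nxt(seq_len(n))], it),
    cbind(icb, ib[nxt(seq_len(n))], ib),                      # bottom (-z out)
    cbind(ict, it, it[nxt(seq_len(n))])                       # top (+z out)
  )
  surface_mesh(verts, faces)
}
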