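# Interface micromotion metric.
#
# Micromotion is the relative displacement of implant contact nodes over
# the apposed bone faces in the shearing (in-plane) direction. Each
# implant node is projected onto the closest bone contact face at the
# start of the tracked cycle; the correspondence is then held material,
# and the node's position is expressed in the co-moving local frame of
# that face. The per-node micromotion is the largest in-plane excursion
# from the cycle-start position during the full cycle. Nodes with a large
# mean normal gap (e.g. overhang regions) are excluded. Summaries report
# the peak, the 95th percentile over nodes (outlier suppression) and the
# area fraction below the osseointegration threshold (112 um).

# Local orthonormal frame of a triangle: origin a, basis e1, e2, normal n.
face_frame <- function(a, b, cc) {
  e1 <- unit(b - a)
  n <- unit(cross3(b - a, cc - a))
  e2 <- cross3(n, e1)
  list(origin = a, e1 = e1, e2 = e2, n = n)
}

# Closest-point projection of p onto triangle (a, b, cc) in 3-D.
project_point_triangle <- function(p, a, b, cc) {
  fr <- face_frame(a, b, cc)
  d <- p - fr$origin
  xi <- c(sum(d * fr$e1), sum(d * fr$e2))
  gap <- sum(d * fr$n)
  # barycentric in the face plane
  b2 <- c(sum((b - a) * fr$e1), sum((b - a) * fr$e2))
  c2 <- c(sum((cc - a) * fr$e1), sum((cc - a) * fr$e2))
  den <- b2[1] * c2[2] - b2[2] * c2[1]
  v <- (xi[1] * c2[2] - xi[2] * c2[1]) / den
  w <- (b2[1] * xi[2] - b2[2] * xi[1]) / den
  list(bary = c(1 - v - w, v, w), gap = gap, inside = (v >= -1e-9 && w >= -1e-9 && v + w <= 1 + 1e-9))
}

#' Track implant contact nodes over the bone faces for one cycle
#'
#' Re-establishes the node-to-face correspondence at the first increment
#' of the requested cycle (closest face, clamped barycentric foot-point)
#' and expresses each node's position in the co-moving orthonormal frame
#' of its face at every increment of that cycle. The returned traces are
#' the in-plane displacements relative to the cycle-start position, so a
#' common rigid motion of all bodies yields identically zero traces.
#'
#' @param history an `interface_history` from [run_activity()] (or built
#'   synthetically with the same fields).
#' @param cycle cycle index to track (default: last cycle).
#' @param search_radius maximum projection distance, mm; nodes without a
#'   face within it are excluded with a reason.
#' @return a `micromotion_traces` object: `trace` (nodes x increments
#'   in-plane excursion magnitudes, mm), `mean_gap`, `excluded`
#'   (indices + reason), per-node `area`.
#' @export
project_and_track <- function(history, cycle = history$n_cycles,
                              search_radius = 5) {
  sel <- which(history$cycle == cycle)
  if (!length(sel)) stop("requested cycle not present in history", call. = FALSE)
  t0 <- sel[1]
  ns <- dim(history$node_pos)[1]
  nt <- length(sel)
  faces <- history$faces
  nf <- nrow(faces)

  bp0 <- history$bone_pos[, , t0]
  np0 <- history$node_pos[, , t0]
  fctr <- (bp0[faces[, 1], , drop = FALSE] + bp0[faces[, 2], , drop = FALSE] +
           bp0[faces[, 3], , drop = FALSE]) / 3

  assign_face <- integer(ns)
  bary <- matrix(0, ns, 3)
  xi0 <- matrix(0, ns, 2)
  excluded <- logical(ns)
  for (i in seq_len(ns)) {
    p <- np0[i, ]
    d2 <- (fctr[, 1] - p[1])^2 + (fctr[, 2] - p[2])^2 + (fctr[, 3] - p[3])^2
    cand <- order(d2)[seq_len(min(10L, nf))]
    best <- NA_integer_; bd <- Inf
    for (f in cand) {
      pr <- project_point_triangle(p, bp0[faces[f, 1], ], bp0[faces[f, 2], ],
                                   bp0[faces[f, 3], ])
      w <- pmax(pr$bary, 0); w <- w / sum(w)
      foot <- w[1] * bp0[faces[f, 1], ] + w[2] * bp0[faces[f, 2], ] +
        w[3] * bp0[faces[f, 3], ]
      dd <- vnorm(p - foot)
      if (dd < bd) { bd <- dd; best <- f; bary[i, ] <- w }
    }
    if (bd > search_radius) {
      excluded[i] <- TRUE
    } else {
      assign_face[i] <- best
      fr <- face_frame(bp0[faces[best, 1], ], bp0[faces[best, 2], ],
                       bp0[faces[best, 3], ])
      d <- p - fr$origin
      xi0[i, ] <- c(sum(d * fr$e1), sum(d * fr$e2))
    }
  }

  trace <- matrix(NA_real_, ns, nt)
  gap_tr <- matrix(NA_real_, ns, nt)
  for (tt in seq_len(nt)) {
    bpt <- history$bone_pos[, , sel[tt]]
    npt <- history$node_pos[, , sel[tt]]
    for (i in which(!excluded)) {
      f <- assign_face[i]
      fr <- face_frame(bpt[faces[f, 1], ], bpt[faces[f, 2], ], bpt[faces[f, 3], ])
      d <- npt[i, ] - fr$origin
      xi <- c(sum(d * fr$e1), sum(d * fr$e2))
      trace[i, tt] <- sqrt(sum((xi - xi0[i, ])^2))
      gap_tr[i, tt] <- sum(d * fr$n)
    }
  }

  structure(list(
    trace = trace,
    mean_gap = rowMeans(gap_tr),
    excluded = which(excluded),
    exclusion_reason = if (any(excluded)) "no bone face within search radius" else NULL,
    area = history$tributary_area,
    cycle = cycle
  ), class = "micromotion_traces")
}

#' Per-node micromotion field from tracked traces
#'
#' Per-node micromotion is the maximum in-plane relative displacement over
#' the tracked cycle; nodes whose mean normal gap exceeds `gap_threshold`
#' are excluded (large-gap regions, e.g. overhang).
#'
#' @param traces a `micromotion_traces` from [project_and_track()].
#' @param gap_threshold mean normal gap above which a node is excluded, mm.
#' @return a `micromotion_field`: `value_um` per included node, exclusion
#'   bookkeeping, per-node areas, `time_of_peak` per node.
#' @export
micromotion_field <- function(traces, gap_threshold = 0.5) {
  ns <- nrow(traces$trace)
  excl <- rep(FALSE, ns)
  reason <- rep(NA_character_, ns)
  excl[traces$excluded] <- TRUE
  reason[traces$excluded] <- "no face"
  big_gap <- !excl & traces$mean_gap > gap_threshold
  excl[big_gap] <- TRUE
  reason[big_gap] <- "large normal gap"
  if (all(excl)) stop("micromotion metric error: empty inclusion set", call. = FALSE)
  value <- rep(NA_real_, ns)
  tpk <- rep(NA_integer_, ns)
  inc <- which(!excl)
  value[inc] <- apply(traces$trace[inc, , drop = FALSE], 1, max) * 1000  # mm -> um
  tpk[inc] <- apply(traces$trace[inc, , drop = FALSE], 1, which.max)
  structure(list(
    value_um = value, included = inc, excluded = which(excl),
    exclusion_reason = reason, area = traces$area,
    time_of_peak = tpk, gap_threshold = gap_threshold
  ), class = "micromotion_field")
}

#' Summarise a micromotion field
#'
#' @param field a `micromotion_field`.
#' @param threshold osseointegration threshold, um (default 112).
#' @return a `micromotion_summary`: `peak` and `p95` (um; linear
#'   interpolation percentile over included nodes),
#'   `area_fraction_below_threshold` (face-area weighted), `threshold`,
#'   `time_of_peak`, the per-node field.
#' @export
summarize_micromotion <- function(field, threshold = 112) {
  v <- field$value_um[field$included]
  a <- field$area[field$included]
  peak <- max(v)
  p95 <- as.numeric(stats::quantile(v, 0.95, type = 7))
  frac <- sum(a[v < threshold]) / sum(a)
  structure(list(
    peak = peak, p95 = p95,
    area_fraction_below_threshold = frac,
    threshold = threshold,
    time_of_peak = field$time_of_peak[field$included][which.max(v)],
    n_included = length(v), n_excluded = length(field$excluded),
    field = field
  ), class = "micromotion_summary")
}

#' @export
print.micromotion_summary <- function(x, ...) {
  cat(sprintf("Micromotion: peak %.1f um, p95 %.1f um (%d nodes, %d excluded)\n",
              x$peak, x$p95, x$n_included, x$n_excluded))
  cat(sprintf("  area fraction below %g um: %.3f\n",
              x$threshold, x$area_fraction_below_threshold))
  invisible(x)
}

#' Full metric for a solved activity: track, field, summary
#'
#' @param history an `interface_history`.
#' @param cycle tracked cycle (default: final).
#' @param gap_threshold mm, see [micromotion_field()].
#' @param threshold um, see [summarize_micromotion()].
#' @return a `micromotion_summary`.
#' @export
micromotion_summary <- function(history, cycle = history$n_cycles,
                                gap_threshold = 0.5, threshold = 112) {
  tr <- project_and_track(history, cycle)
  fl <- micromotion_field(tr, gap_threshold)
  summarize_micromotion(fl, threshold)
}

#' Write the per-node micromotion field as VTK point data on the tray
#' interface
#'
#' @param field a `micromotion_field`.
#' @param history the `interface_history` it came from.
#' @param path output path.
#' @export
write_micromotion_vtk <- function(field, history, path) {
  ns <- length(field$value_um)
  np0 <- history$node_pos[, , 1]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "micromotion field", "ASCII",
               "DATASET POLYDATA"), con)
  writeLines(sprintf("POINTS %d double", ns), con)
  writeLines(apply(np0, 1, paste, collapse = " "), con)
  writeLines(sprintf("POINT_DATA %d", ns), con)
  writeLines("SCALARS micromotion_um double 1", con)
  writeLines("LOOKUP_TABLE default", con)
  v <- field$value_um; v[is.na(v)] <- -1
  writeLines(format(v, digits = 8), con)
  invisible(path)
}
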