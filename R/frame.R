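# Anatomical reference frames and rigid transforms.

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 proper orthonormal matrix.
#' @param translation length-3 vector, mm.
#' @return a `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop("rotation must be proper orthonormal (det +1)", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param tf a `rigid_transform`.
#' @param pts n x 3 matrix (or length-3 vector).
#' @return transformed points, same shape.
#' @export
apply_transform <- function(tf, pts) {
  if (is.null(dim(pts))) return(as.numeric(tf$rotation %*% pts + tf$translation))
  sweep(pts %*% t(tf$rotation), 2, tf$translation, `+`)
}

#' Compose / invert rigid transforms
#'
#' `compose_transform(a, b)` applies `b` first, then `a`.
#' @param a,b,tf rigid transforms.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_transform
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation), -as.numeric(t(tf$rotation) %*% tf$translation))
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("Rigid transform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Assign an anatomical reference frame to a tibia
#'
#' The proximal-distal axis points from the distal shaft landmark towards
#' the inter-condylar midpoint; the medial-lateral axis points from the
#' medial to the lateral condylar centre (orthogonalised against the PD
#' axis); the anterior-posterior axis completes a right-handed triad
#' (AP = PD x ML). The origin is the inter-condylar midpoint.
#'
#' @param tibia a `synthetic_tibia`, or any list with a `landmarks` matrix
#'   carrying rows `medial_condyle`, `lateral_condyle`, `shaft_distal`.
#' @return an `anatomical_frame`: `origin` and a 3 x 3 `axes` matrix with
#'   rows `pd`, `ml`, `ap` (unit, orthonormal, right-handed).
#' @export
assign_frame <- function(tibia) {
  lmk <- tibia$landmarks
  need <- c("medial_condyle", "lateral_condyle", "shaft_distal")
  if (is.null(lmk) || !all(need %in% rownames(lmk))) {
    stop("landmarks medial_condyle, lateral_condyle, shaft_distal required",
         call. = FALSE)
  }
  m <- lmk["medial_condyle", ]; l <- lmk["lateral_condyle", ]
  s <- lmk["shaft_distal", ]
  origin <- (m + l) / 2
  v1 <- origin - s
  v2 <- l - m
  if (vnorm(cross3(v1, v2)) < 1e-9 * vnorm(v1) * vnorm(v2)) {
    stop("degenerate landmarks: collinear", call. = FALSE)
  }
  pd <- unit(v1)
  ml <- unit(v2 - sum(v2 * pd) * pd)
  ap <- cross3(pd, ml)
  axes <- rbind(pd = pd, ml = ml, ap = ap)
  structure(list(origin = origin, axes = axes), class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("Anatomical frame\n  origin:", sprintf("%.2f", x$origin), "\n")
  for (nm in rownames(x$axes)) {
    cat(sprintf("  %s: % .4f % .4f % .4f\n", nm,
                x$axes[nm, 1], x$axes[nm, 2], x$axes[nm, 3]))
  }
  invisible(x)
}

#' Transform mapping world coordinates into a frame's local coordinates
#'
#' Local axes are x = medial-lateral, y = anterior-posterior,
#' z = proximal-distal (z = 0 at the joint line, negative distally).
#'
#' @param frame an `anatomical_frame`.
#' @return a `rigid_transform` from world to local coordinates.
#' @export
frame_to_local <- function(frame) {
  R <- rbind(frame$axes["ml", ], frame$axes["ap", ], frame$axes["pd", ])
  if (det(R) < 0) stop("frame is not right-handed", call. = FALSE)
  rigid_transform(R, -as.numeric(R %*% frame$origin))
}
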