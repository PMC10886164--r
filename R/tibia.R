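# Synthetic proximal tibia geometry.
#
# A parametric condyle-plus-tapered-shaft solid stands in for segmented CT
# anatomy: the testable content of the pipeline is the mechanics and the
# micromotion metric, not anatomical shape fidelity. The articular surface
# is the plane z = 0 (the joint line); z decreases distally. For a right
# tibia +x points laterally; left tibiae are mirror images through x.
#
# The Hounsfield-unit field is analytic: a dense cortical shell (default
# 1200 HU) over a less dense trabecular interior (default 300 HU), blended
# by a sigmoid of depth below the outer surface, with smooth seeded spatial
# noise. Elements sample it at their centroids.

#' Default tibia geometry specification
#'
#' @param condylar_radius base proximal radius (mm) at reference height
#'   1.71 m; scales linearly with patient height.
#' @param shaft_fraction shaft radius as a fraction of the condylar radius.
#' @param flare_length axial length scale (mm) of the metaphyseal flare.
#' @param length total generated length (mm) below the joint line.
#' @param cortical_hu,trabecular_hu HU levels of shell and interior.
#' @param cortical_thickness_prox,cortical_thickness_shaft shell thickness
#'   (mm) at the joint line and in the diaphysis.
#' @param noise_amp relative amplitude of smooth surface shape noise.
#' @param hu_noise_amp HU noise amplitude.
#' @param pose_noise_deg,pose_noise_mm random pose perturbation applied to
#'   the generated mesh (exercised by the registration stage).
#' @param n_theta,n_z surface tessellation density.
#' @return a list of geometry parameters.
#' @export
tibia_spec <- function(condylar_radius = 30,
                       shaft_fraction = 0.45,
                       flare_length = 30,
                       length = 120,
                       cortical_hu = 1200,
                       trabecular_hu = 300,
                       cortical_thickness_prox = 1.8,
                       cortical_thickness_shaft = 5,
                       noise_amp = 0.03,
                       hu_noise_amp = 60,
                       pose_noise_deg = 4,
                       pose_noise_mm = 8,
                       n_theta = 48,
                       n_z = 36) {
  as.list(environment())
}

# Section radius of the canonical (right-side) tibia at angle theta, level z.
# theta measured from +x (lateral for a right tibia), z <= 0.
tibia_radius <- function(theta, z, spec, scale = 1, noise = NULL) {
  R0 <- spec$condylar_radius * scale
  Rs <- R0 * spec$shaft_fraction
  fl <- exp(-((-z) / spec$flare_length)^1.8)
  Rz <- Rs + (R0 - Rs) * fl
  # asymmetric section: slightly elliptical, medial condyle fuller
  shp <- 1 + 0.12 * cos(2 * theta) + 0.07 * fl * cos(theta - pi)
  r <- Rz * shp
  if (!is.null(noise)) {
    r <- r * (1 + noise$amp * sin(3 * theta + noise$phi1) *
                sin(2 * pi * z / 45 + noise$phi2))
  }
  r
}

#' Generate a synthetic tibia for one patient record
#'
#' @param patient one row of a `patient_cohort` (or a list with `height`,
#'   `side`).
#' @param spec geometry spec from [tibia_spec()].
#' @param seed integer seed (shape noise, HU noise phases, pose).
#' @param apply_pose_noise perturb the output pose by a small random rigid
#'   motion (recovered later by registration). Set `FALSE` for canonical
#'   output.
#' @return a `synthetic_tibia`: `surface` (triangle mesh, mm), `landmarks`
#'   (named 3-vectors: medial_condyle, lateral_condyle, shaft_distal),
#'   `side`, an analytic HU field specification `hu`, and the canonical
#'   geometry parameters needed to evaluate it.
#' @export
generate_tibia <- function(patient, spec = tibia_spec(), seed = 1,
                           apply_pose_noise = TRUE) {
  side <- patient$side %||% "right"
  if (!side %in% c("left", "right")) stop("side must be left or right", call. = FALSE)
  scale <- (patient$height %||% 1.71) / 1.71

  with_seed(seed, {
    noise <- if (spec$noise_amp > 0) {
      list(amp = spec$noise_amp, phi1 = stats::runif(1, 0, 2 * pi),
           phi2 = stats::runif(1, 0, 2 * pi))
    } else NULL
    hu_phases <- stats::runif(6, 0, 2 * pi)
    pose <- if (apply_pose_noise) {
      ang <- stats::runif(3, -1, 1) * spec$pose_noise_deg * pi / 180
      list(R = rot_xyz(ang), t = stats::runif(3, -1, 1) * spec$pose_noise_mm)
    } else {
      list(R = diag(3), t = c(0, 0, 0))
    }

    nth <- spec$n_theta; nz <- spec$n_z
    theta <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]
    zlev <- seq(0, -spec$length, length.out = nz)

    ring <- function(z) {
      r <- tibia_radius(theta, z, spec, scale, noise)
      if (any(r <= 0)) stop("tibia generation error: non-positive section radius",
                            call. = FALSE)
      cbind(r * cos(theta), r * sin(theta), z)
    }
    verts <- do.call(rbind, lapply(zlev, ring))
    top_c <- c(0, 0, 0)
    bot_c <- c(0, 0, -spec$length)
    verts <- rbind(verts, top_c, bot_c)
    i_top <- nrow(verts) - 1L
    i_bot <- nrow(verts)

    idx <- function(j, i) (j - 1L) * nth + ((i - 1L) %% nth) + 1L
    faces <- list()
    for (j in seq_len(nz - 1)) {
      i <- seq_len(nth)
      # outward orientation: normals point away from the axis
      faces[[length(faces) + 1]] <- cbind(idx(j, i), idx(j + 1, i), idx(j, i + 1))
      faces[[length(faces) + 1]] <- cbind(idx(j, i + 1), idx(j + 1, i), idx(j + 1, i + 1))
    }
    i <- seq_len(nth)
    faces[[length(faces) + 1]] <- cbind(i_top, idx(1, i), idx(1, i + 1))       # top cap (+z out)
    faces[[length(faces) + 1]] <- cbind(i_bot, idx(nz, i + 1), idx(nz, i))     # bottom cap (-z out)
    faces <- do.call(rbind, faces)

    lmk <- rbind(
      medial_condyle  = c(-0.55 * spec$condylar_radius * scale, 0, 0),
      lateral_condyle = c(0.55 * spec$condylar_radius * scale, 0, 0),
      shaft_distal    = c(0, 0, -spec$length)
    )

    if (side == "left") {   # mirror through x, restore orientation
      verts[, 1] <- -verts[, 1]
      lmk[, 1] <- -lmk[, 1]
      faces <- faces[, c(1, 3, 2)]
    }

    verts <- sweep(verts %*% t(pose$R), 2, pose$t, `+`)
    lmk <- sweep(lmk %*% t(pose$R), 2, pose$t, `+`)

    structure(list(
      surface = surface_mesh(verts, faces),
      landmarks = lmk,
      side = side,
      scale = scale,
      spec = spec,
      shape_noise = noise,
      hu = list(cortical = spec$cortical_hu, trabecular = spec$trabecular_hu,
                t_prox = spec$cortical_thickness_prox,
                t_shaft = spec$cortical_thickness_shaft,
                noise_amp = spec$hu_noise_amp, phases = hu_phases),
      pose = pose
    ), class = "synthetic_tibia")
  })
}

#' @export
print.synthetic_tibia <- function(x, ...) {
  cat(sprintf("Synthetic tibia (%s): %d vertices, %d faces, scale %.3f\n",
              x$side, nrow(x$surface$vertices), nrow(x$surface$faces), x$scale))
  invisible(x)
}

# Evaluate the analytic HU field at points given in CANONICAL coordinates
# (joint line z = 0, right-side convention; callers undo pose/mirror first).
tibia_hu_at <- function(tibia, pts) {
  spec <- tibia$spec; hu <- tibia$hu
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  th <- atan2(pts[, 2], pts[, 1])
  z <- pmin(pts[, 3], 0)
  rs <- tibia_radius(th, z, spec, tibia$scale, tibia$shape_noise)
  depth <- rs - r                               # depth below outer surface
  fl <- exp(-((-z) / spec$flare_length)^1.8)
  tc <- hu$t_shaft + (hu$t_prox - hu$t_shaft) * fl
  base <- hu$trabecular +
    (hu$cortical - hu$trabecular) * stats::plogis((tc - depth) / 0.6)
  ph <- hu$phases
  noise <- hu$noise_amp * (
    sin(2 * pi * pts[, 1] / 23 + ph[1]) * sin(2 * pi * pts[, 2] / 19 + ph[2]) +
    0.6 * sin(2 * pi * z / 31 + ph[3]) * sin(2 * pi * pts[, 1] / 17 + ph[4]))
  pmax(base + noise, -200)
}

# Map world points of a posed tibia back to canonical coordinates.
tibia_to_canonical <- function(tibia, pts) {
  p <- sweep(pts, 2, tibia$pose$t, `-`) %*% tibia$pose$R
  if (tibia$side == "left") p[, 1] <- -p[, 1]
  p
}

#' Sample the HU field of a synthetic tibia at world-coordinate points
#'
#' @param tibia a `synthetic_tibia`.
#' @param pts n x 3 matrix of points (mm, same frame as `tibia$surface`).
#' @return numeric vector of HU values.
#' @export
sample_hu <- function(tibia, pts) {
  tibia_hu_at(tibia, tibia_to_canonical(tibia, pts))
}

rot_xyz <- function(ang) {
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}
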