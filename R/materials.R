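# Bone and implant material assignment.
#
# CT intensities are mapped to equivalent mineral density through a
# piecewise-linear calibration anchored at the known intensities of air,
# fat and muscle, then to an elastic-plastic card through a power-law
# density-modulus relation clamped to the physiological 5.0-20.5 GPa range.
# Bone yields according to a Von Mises criterion (perfectly plastic by
# default, yield stress a fixed strain fraction of the modulus); tray and
# insert are linear elastic.

#' CT calibration anchors (air / fat / muscle)
#'
#' @param hu_air,hu_fat,hu_muscle anchor intensities, HU.
#' @param rho_air,rho_fat,rho_muscle equivalent densities, g/cm^3.
#' @return a `calibration_anchors` list.
#' @export
calibration_anchors <- function(hu_air = -1000, hu_fat = -100, hu_muscle = 40,
                                rho_air = 0, rho_fat = 0.95, rho_muscle = 1.05) {
  if (!(hu_air < hu_fat && hu_fat < hu_muscle)) {
    stop("anchors must satisfy hu_air < hu_fat < hu_muscle", call. = FALSE)
  }
  if (rho_air > rho_fat || rho_fat > rho_muscle) {
    stop("anchor densities must be non-decreasing", call. = FALSE)
  }
  structure(list(hu = c(hu_air, hu_fat, hu_muscle),
                 rho = c(rho_air, rho_fat, rho_muscle)),
            class = "calibration_anchors")
}

#' Convert Hounsfield units to equivalent density
#'
#' Piecewise-linear through the three anchor pairs, linearly extrapolated
#' above the muscle anchor, clamped at zero below air. Total and monotone
#' non-decreasing.
#'
#' @param hu numeric HU values.
#' @param anchors a [calibration_anchors()].
#' @return densities, g/cm^3.
#' @export
hu_to_density <- function(hu, anchors = calibration_anchors()) {
  h <- anchors$hu; r <- anchors$rho
  out <- numeric(length(hu))
  lo <- hu <= h[1]
  s1 <- hu > h[1] & hu <= h[2]
  s2 <- hu > h[2] & hu <= h[3]
  hi <- hu > h[3]
  out[lo] <- r[1]
  out[s1] <- r[1] + (r[2] - r[1]) * (hu[s1] - h[1]) / (h[2] - h[1])
  out[s2] <- r[2] + (r[3] - r[2]) * (hu[s2] - h[2]) / (h[3] - h[2])
  out[hi] <- r[3] + (r[3] - r[2]) / (h[3] - h[2]) * (hu[hi] - h[3])
  pmax(out, 0)
}

#' Bone density-to-modulus mapping
#'
#' Power law `E = a * rho^b` (GPa, rho in g/cm^3), clamped afterwards to
#' `modulus_bounds`.
#'
#' @param a,b power-law coefficient and exponent.
#' @param modulus_bounds clamp interval, GPa (defaults to the physiological
#'   5.0--20.5 GPa bone range).
#' @param yield_strain yield stress as a fraction of the modulus;
#'   `yield_stress = yield_strain * E`.
#' @param poisson Poisson ratio for bone.
#' @param hardening_modulus plastic hardening modulus, MPa (0 = perfectly
#'   plastic).
#' @return a `bone_material_map`.
#' @export
bone_material_map <- function(a = 6.85, b = 2,
                              modulus_bounds = c(5.0, 20.5),
                              yield_strain = 0.008,
                              poisson = 0.3,
                              hardening_modulus = 0) {
  stopifnot(a > 0, b > 0, modulus_bounds[1] < modulus_bounds[2],
            yield_strain > 0, poisson > 0, poisson < 0.5)
  structure(list(a = a, b = b, modulus_bounds = modulus_bounds,
                 yield_strain = yield_strain, poisson = poisson,
                 hardening_modulus = hardening_modulus),
            class = "bone_material_map")
}

#' Material card
#'
#' @param name token.
#' @param youngs_modulus GPa (> 0).
#' @param poisson_ratio in (0, 0.5).
#' @param yield_stress MPa, or `NULL` for purely elastic.
#' @param hardening_modulus MPa (0 = perfectly plastic).
#' @return a `material_card`.
#' @export
material_card <- function(name, youngs_modulus, poisson_ratio,
                          yield_stress = NULL, hardening_modulus = 0) {
  stopifnot(youngs_modulus > 0, poisson_ratio > 0, poisson_ratio < 0.5)
  if (!is.null(yield_stress) && yield_stress <= 0) {
    stop("yield_stress must be > 0 when present", call. = FALSE)
  }
  structure(list(name = name, youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio, yield_stress = yield_stress,
                 hardening_modulus = hardening_modulus),
            class = "material_card")
}

#' Map one density to an elastic-plastic bone card
#'
#' @param rho density, g/cm^3 (>= 0).
#' @param map a [bone_material_map()].
#' @return a [material_card()] with modulus clamped into the configured
#'   bounds and `yield_stress = yield_strain * E`.
#' @export
density_to_card <- function(rho, map = bone_material_map()) {
  stopifnot(rho >= 0)
  E <- min(max(map$a * rho^map$b, map$modulus_bounds[1]), map$modulus_bounds[2])
  material_card("bone", E, map$poisson,
                yield_stress = map$yield_strain * E * 1000,  # GPa -> MPa
                hardening_modulus = map$hardening_modulus)
}

#' Implant material cards
#'
#' Tray: PEEK 3.7 GPa or titanium 109 GPa; insert: UHMWPE 0.974 GPa. All
#' linear elastic.
#'
#' @param tray_material `"PEEK"` or `"titanium"`.
#' @return list of `material_card`s `tray`, `insert`.
#' @export
implant_cards <- function(tray_material = c("PEEK", "titanium")) {
  tray_material <- match.arg(tray_material)
  tray <- if (tray_material == "PEEK") {
    material_card("PEEK", 3.7, 0.36)
  } else {
    material_card("titanium", 109, 0.3)
  }
  list(tray = tray, insert = material_card("UHMWPE", 0.974, 0.46))
}

#' Assign per-element material cards to a volume mesh
#'
#' Bone elements (material id `"bone"`) receive calibrated elastic-plastic
#' cards from their element HU; `"tray"` elements the selected tray card;
#' `"insert"` elements the UHMWPE card.
#'
#' @param mesh a `volume_mesh` with `element_material` populated.
#' @param tray_material `"PEEK"` or `"titanium"`.
#' @param anchors a [calibration_anchors()].
#' @param map a [bone_material_map()].
#' @return a `material_table`: data.frame with per-element `E` (GPa), `nu`,
#'   `yield` (MPa, NA when elastic), `hardening` (MPa), `material`.
#' @export
assign_materials <- function(mesh, tray_material = c("PEEK", "titanium"),
                             anchors = calibration_anchors(),
                             map = bone_material_map()) {
  tray_material <- match.arg(tray_material)
  mat <- mesh$element_material
  if (is.null(mat)) stop("mesh has no element_material ids", call. = FALSE)
  known <- c("bone", "tray", "insert")
  if (!all(mat %in% known)) {
    stop("unknown material id: ", paste(setdiff(unique(mat), known), collapse = ", "),
         call. = FALSE)
  }
  ne <- nrow(mesh$tets)
  E <- numeric(ne); nu <- numeric(ne)
  yield <- rep(NA_real_, ne); hard <- numeric(ne)
  ib <- mat == "bone"
  if (any(ib)) {
    if (is.null(mesh$element_hu)) stop("bone elements need element_hu", call. = FALSE)
    rho <- hu_to_density(mesh$element_hu[ib], anchors)
    Eb <- pmin(pmax(map$a * rho^map$b, map$modulus_bounds[1]), map$modulus_bounds[2])
    E[ib] <- Eb
    nu[ib] <- map$poisson
    yield[ib] <- map$yield_strain * Eb * 1000
    hard[ib] <- map$hardening_modulus
  }
  cards <- implant_cards(tray_material)
  it <- mat == "tray"
  E[it] <- cards$tray$youngs_modulus; nu[it] <- cards$tray$poisson_ratio
  ii <- mat == "insert"
  E[ii] <- cards$insert$youngs_modulus; nu[ii] <- cards$insert$poisson_ratio
  structure(data.frame(E = E, nu = nu, yield = yield, hardening = hard,
                       material = mat, stringsAsFactors = FALSE),
            class = c("material_table", "data.frame"))
}
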