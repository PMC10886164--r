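# Activity load profiles.
#
# Tibiofemoral contact forces and centres of pressure over one activity
# cycle, applied over several cycles so the implant settles numerically.
# Only the increment counts (73 gait / 67 squat), the reference peak
# (1514 N) and proportional bodyweight scaling are prescribed inputs; the
# curve shapes are smooth parametric stand-ins (two-peak stance curve for
# gait, single mid-cycle peak for squat) and can be overridden.

#' Build a bodyweight-scaled activity load profile
#'
#' The total tibiofemoral force over one cycle peaks at
#' `reference_peak * bodyweight / reference_bodyweight` (exactly, at the
#' sampled increments) and is split into medial and lateral components with
#' centres of pressure that shift across the insert during the cycle.
#'
#' @param activity `"gait"` (73 increments per cycle) or `"squat"` (67).
#' @param bodyweight patient bodyweight, kg (> 0).
#' @param reference_bodyweight bodyweight at which the reference peak
#'   applies, kg. Default 75.
#' @param reference_peak peak total force at the reference bodyweight, N.
#'   Default 1514.
#' @param n_cycles number of loading cycles, default 4.
#' @param insert_halfwidth,insert_halfdepth medial-lateral and
#'   anterior-posterior half-extents (mm) of the articular footprint the
#'   CoPs must stay inside.
#' @param shape_fun optional function(t in [0,1)) -> non-negative total
#'   force shape, overriding the built-in curve.
#' @return a `load_profile` object: per-increment `medial_force`,
#'   `lateral_force` (N) and `cop_medial`, `cop_lateral` (n x 2 matrices,
#'   mm, columns medial-lateral x and anterior-posterior y).
#' @export
build_load_profile <- function(activity = c("gait", "squat"),
                               bodyweight,
                               reference_bodyweight = 75,
                               reference_peak = 1514,
                               n_cycles = 4,
                               insert_halfwidth = 21,
                               insert_halfdepth = 14,
                               shape_fun = NULL) {
  activity <- match.arg(activity)
  if (!is.numeric(bodyweight) || bodyweight <= 0) {
    stop("bodyweight must be > 0", call. = FALSE)
  }
  n <- if (activity == "gait") 73L else 67L
  t <- (seq_len(n) - 1) / n

  shape <- if (!is.null(shape_fun)) {
    shape_fun(t)
  } else if (activity == "gait") {
    # two-peak stance curve, low swing-phase baseline
    0.08 + exp(-((t - 0.16) / 0.085)^2) + 0.93 * exp(-((t - 0.47) / 0.10)^2)
  } else {
    # squat: single peak at deepest flexion
    0.15 + exp(-((t - 0.5) / 0.17)^2)
  }
  if (any(shape < 0)) stop("load shape must be non-negative", call. = FALSE)
  shape <- shape / max(shape)

  peak <- reference_peak * (bodyweight / reference_bodyweight)
  total <- shape * peak

  # medial share of the total force, varying over the cycle
  share <- if (activity == "gait") {
    pmin(0.78, pmax(0.35, 0.60 + 0.10 * sin(2 * pi * t)))
  } else {
    rep(0.55, n)
  }
  medial <- share * total
  lateral <- (1 - share) * total

  # CoP trajectories, mm, in the tray frame (x medial->lateral, y posterior->anterior)
  w <- insert_halfwidth
  d <- insert_halfdepth
  if (activity == "gait") {
    y_m <- d * (0.35 - 0.65 * pmin(1, t / 0.62))     # anterior -> posterior over stance
    y_l <- d * (0.30 - 0.55 * pmin(1, t / 0.62))
    x_m <- -w * (0.45 + 0.05 * sin(2 * pi * t))
    x_l <- w * (0.45 - 0.05 * sin(2 * pi * t))
  } else {
    y_m <- -d * 0.55 * sin(pi * t)                    # rolls posterior with flexion
    y_l <- -d * 0.60 * sin(pi * t)
    x_m <- rep(-w * 0.45, n)
    x_l <- rep(w * 0.45, n)
  }

  structure(list(
    activity = activity,
    n_increments = n,
    n_cycles = as.integer(n_cycles),
    medial_force = medial,
    lateral_force = lateral,
    cop_medial = cbind(x = x_m, y = y_m),
    cop_lateral = cbind(x = x_l, y = y_l),
    reference_peak = reference_peak,
    bodyweight_scale = bodyweight / reference_bodyweight,
    insert_halfwidth = w,
    insert_halfdepth = d
  ), class = "load_profile")
}

#' @export
print.load_profile <- function(x, ...) {
  cat(sprintf("Load profile: %s, %d increments x %d cycles\n",
              x$activity, x$n_increments, x$n_cycles))
  cat(sprintf("  peak total force %.1f N (scale %.3f x %g N)\n",
              max(x$medial_force + x$lateral_force),
              x$bodyweight_scale, x$reference_peak))
  invisible(x)
}
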