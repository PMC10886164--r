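# Press-fit contact between implant and bone.
#
# Single-sided node-to-face contact: slave nodes on the implant surface
# (tray distal face and fixation-peg wall) are paired with master
# triangles on the bone (resection surface and bore wall). Normal
# behaviour is penalty-regularised; the interference fit enters as a
# surface offset measured from the as-assembled (line-to-line) state, so
# contact pressure builds wherever the relative normal approach falls
# short of the current fit - on the peg wall this squeezes the peg
# radially, which is the press-fit. Friction follows a bilinear Coulomb
# law: traction grows linearly with relative tangential displacement up
# to mu * pressure over the slip tolerance (stick), then stays at
# mu * pressure while the anchor point slides (slip).
#
# Pairing is established in the reference configuration and held material
# thereafter (small-displacement contact).

#' Contact parameters
#'
#' @param friction_coefficient Coulomb coefficient, default 0.5.
#' @param interference_fit interference magnitude, micrometres; default 500.
#' @param ramp_increments increments of the linear implantation ramp.
#' @param penalty_normal normal penalty, N/mm^3 (pressure per unit
#'   penetration); the default keeps the penalty compliance below ~5%
#'   of the interference in the thick-walled-cylinder benchmark.
#' @param slip_tolerance relative tangential displacement at which the
#'   stick traction reaches the Coulomb limit, mm (bilinear breakpoint).
#' @return a `contact_parameters` list.
#' @export
contact_parameters <- function(friction_coefficient = 0.5,
                               interference_fit = 500,
                               ramp_increments = 20,
                               penalty_normal = 5000,
                               slip_tolerance = 0.01) {
  stopifnot(friction_coefficient >= 0, interference_fit >= 0,
            penalty_normal > 0, slip_tolerance > 0, ramp_increments >= 1)
  structure(list(friction_coefficient = friction_coefficient,
                 interference_fit = interference_fit,
                 ramp_increments = as.integer(ramp_increments),
                 penalty_normal = penalty_normal,
                 slip_tolerance = slip_tolerance),
            class = "contact_parameters")
}

# Closest-point pairing of slave nodes onto master triangles (3-D).
# Returns face index, clamped barycentric weights, face normal (oriented
# along `orient`, a per-face n x 3 matrix of preferred directions), and
# the reference gap.
pair_nodes_to_faces <- function(slave_xyz, master_xyz, faces, orient,
                                search_radius) {
  fa <- master_xyz[faces[, 1], , drop = FALSE]
  fb <- master_xyz[faces[, 2], , drop = FALSE]
  fc <- master_xyz[faces[, 3], , drop = FALSE]
  fn <- cross3m(fb - fa, fc - fa)
  fn <- fn / sqrt(rowSums(fn^2))
  flip <- rowSums(fn * orient) < 0
  fn[flip, ] <- -fn[flip, , drop = FALSE]
  fctr <- (fa + fb + fc) / 3
  ns <- nrow(slave_xyz)
  out_face <- integer(ns); out_w <- matrix(0, ns, 3)
  out_n <- matrix(0, ns, 3); out_g0 <- numeric(ns)
  ok <- logical(ns)
  for (s in seq_len(ns)) {
    p <- slave_xyz[s, ]
    d2 <- (fctr[, 1] - p[1])^2 + (fctr[, 2] - p[2])^2 + (fctr[, 3] - p[3])^2
    cand <- order(d2)[seq_len(min(12L, nrow(faces)))]
    best <- NA_integer_; bw <- NULL; bd <- Inf
    for (f in cand) {
      pr <- project_point_triangle(p, master_xyz[faces[f, 1], ],
                                   master_xyz[faces[f, 2], ],
                                   master_xyz[faces[f, 3], ])
      w <- pmax(pr$bary, 0); w <- w / sum(w)
      foot <- w[1] * master_xyz[faces[f, 1], ] + w[2] * master_xyz[faces[f, 2], ] +
        w[3] * master_xyz[faces[f, 3], ]
      dd <- vnorm(p - foot)
      if (dd < bd) { bd <- dd; best <- f; bw <- w }
    }
    if (bd <= search_radius) {
      ok[s] <- TRUE
      out_face[s] <- best
      out_w[s, ] <- bw
      out_n[s, ] <- fn[best, ]
      foot <- bw[1] * master_xyz[faces[best, 1], ] +
        bw[2] * master_xyz[faces[best, 2], ] + bw[3] * master_xyz[faces[best, 3], ]
      out_g0[s] <- sum((p - foot) * fn[best, ])
    }
  }
  list(ok = ok, face = out_face, w = out_w, n = out_n, g0 = out_g0)
}

# Tributary area per node of a triangulated surface (1/3 of adjacent faces).
node_tributary_area <- function(nodes, faces, n_nodes) {
  a <- nodes[faces[, 1], , drop = FALSE]
  b <- nodes[faces[, 2], , drop = FALSE]
  cc <- nodes[faces[, 3], , drop = FALSE]
  fare <- sqrt(rowSums(cross3m(b - a, cc - a)^2)) / 2
  area <- numeric(n_nodes)
  for (k in 1:3) {
    acc <- tapply(fare / 3, faces[, k], sum)
    ids <- as.integer(names(acc))
    area[ids] <- area[ids] + as.numeric(acc)
  }
  area
}

#' Build contact pairs between implant surface nodes and bone faces
#'
#' Two groups are paired: the tray distal face against the resection
#' surface, and (when present) the peg wall against the bore wall. Nodes
#' without a master face within `search_radius` are excluded (overhang)
#' and reported.
#'
#' @param bone_mesh,implant_mesh `volume_mesh` objects; bone needs node
#'   sets `interface_bone` (and `bore_wall` for a pegged implant), the
#'   implant `interface_implant` (and `peg_wall`).
#' @param params a [contact_parameters()].
#' @param search_radius maximum projection distance (mm), default 2.
#' @return a `contact_pairs` object (node indices local to each mesh;
#'   [contact_model()] offsets them into the combined system).
#' @export
build_contact_pairs <- function(bone_mesh, implant_mesh, params = contact_parameters(),
                                search_radius = 2) {
  bset <- bone_mesh$node_sets$interface_bone
  iset <- implant_mesh$node_sets$interface_implant

  groups <- list()
  if (length(bset) && length(iset)) {
    groups <- list(list(slaves = iset,
                        faces = mesh_surface_faces(bone_mesh, bset, direction = c(0, 0, 1)),
                        orient_fun = function(fctr) {
                          matrix(rep(c(0, 0, 1), each = nrow(fctr)), ncol = 3)
                        },
                        name = "tray_resection"))
  }
  if (!is.null(bone_mesh$node_sets$bore_wall) &&
      !is.null(implant_mesh$node_sets$peg_wall)) {
    axis_xy <- colMeans(bone_mesh$nodes[bone_mesh$node_sets$bore_wall, 1:2, drop = FALSE])
    groups <- c(groups, list(list(
      slaves = implant_mesh$node_sets$peg_wall,
      faces = {
        fs <- mesh_surface_faces(bone_mesh, bone_mesh$node_sets$bore_wall)
        fs
      },
      orient_fun = function(fctr) {
        # bore-wall normals point inward (from bone toward the peg)
        v <- cbind(axis_xy[1] - fctr[, 1], axis_xy[2] - fctr[, 2], 0)
        v / sqrt(rowSums(v^2))
      },
      name = "peg_bore")))
  }
  if (!length(groups)) stop("interface node sets missing", call. = FALSE)

  slave_nodes <- integer(0); faces <- matrix(0L, 0, 3); weights <- matrix(0, 0, 3)
  normals <- matrix(0, 0, 3); g0 <- numeric(0); group <- character(0)
  excluded <- integer(0)
  for (g in groups) {
    sxyz <- implant_mesh$nodes[g$slaves, , drop = FALSE]
    fctr <- (bone_mesh$nodes[g$faces[, 1], , drop = FALSE] +
             bone_mesh$nodes[g$faces[, 2], , drop = FALSE] +
             bone_mesh$nodes[g$faces[, 3], , drop = FALSE]) / 3
    pr <- pair_nodes_to_faces(sxyz, bone_mesh$nodes, g$faces,
                              g$orient_fun(fctr), search_radius)
    keep <- pr$ok
    slave_nodes <- c(slave_nodes, g$slaves[keep])
    faces <- rbind(faces, g$faces[pr$face[keep], , drop = FALSE])
    weights <- rbind(weights, pr$w[keep, , drop = FALSE])
    normals <- rbind(normals, pr$n[keep, , drop = FALSE])
    g0 <- c(g0, pr$g0[keep])
    group <- c(group, rep(g$name, sum(keep)))
    excluded <- c(excluded, g$slaves[!keep])
  }

  # tangential basis per pair
  t1 <- matrix(0, nrow(normals), 3)
  for (i in seq_len(nrow(normals))) {
    n <- normals[i, ]
    ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    t1[i, ] <- unit(cross3(ref, n))
  }
  t2 <- cross3m(normals, t1)

  # tributary areas: distal tray surface + peg wall surface
  surf_nodes <- unique(c(implant_mesh$node_sets$interface_implant,
                         implant_mesh$node_sets$peg_wall))
  ifaces <- mesh_surface_faces(implant_mesh, surf_nodes)
  area <- node_tributary_area(implant_mesh$nodes, ifaces, nrow(implant_mesh$nodes))
  trib <- area[slave_nodes]

  structure(list(
    slave_nodes = slave_nodes,
    excluded_nodes = excluded,
    exclusion_reason = if (length(excluded)) "no bone face within search radius (overhang)" else NULL,
    faces = faces, weights = weights,
    normal = normals, t1 = t1, t2 = t2, g0 = g0, group = group,
    tributary_area = trib,
    n_pairs = length(slave_nodes),
    bone_faces_all = do.call(rbind, lapply(groups, `[[`, "faces")),
    bone_interface_nodes = sort(unique(c(bset %||% integer(0),
      bone_mesh$node_sets$bore_wall %||% integer(0))))
  ), class = "contact_pairs")
}

#' @export
print.contact_pairs <- function(x, ...) {
  cat(sprintf("Contact pairs: %d implant nodes paired (%s), %d excluded\n",
              x$n_pairs, paste(names(table(x$group)), table(x$group),
                               collapse = ", ", sep = ": "),
              length(x$excluded_nodes)))
  invisible(x)
}

#' Evaluate contact forces and tangent for a combined displacement state
#'
#' Normal penalty force is proportional to the penetration measured
#' against a surface offset of `current_fit` from the as-assembled state
#' (press-fit pressure); tangential traction is bilinear Coulomb around
#' the committed slip anchors.
#'
#' @param pairs a `contact_pairs` (node indices in the combined system).
#' @param u combined displacement vector.
#' @param nodes combined reference coordinates.
#' @param state list with `anchor` (n x 2 committed slip anchors, in the
#'   pair tangent basis) and `pressure` (committed normal pressures, used
#'   for the stick stiffness).
#' @param params [contact_parameters()].
#' @param current_fit current interference, mm.
#' @return list: force vector `f`, tangent triplets, per-pair `gap`,
#'   `pressure` (MPa), `traction`, `status` (open/stick/slip), updated
#'   `anchor`.
#' @export
contact_update <- function(pairs, u, nodes, state, params, current_fit) {
  n <- pairs$n_pairs
  ndof <- length(u)
  f <- numeric(ndof)
  if (n == 0) {
    return(list(f = f, trip = NULL, gap = numeric(0), pressure = numeric(0),
                traction = matrix(0, 0, 2), status = character(0),
                anchor = matrix(0, 0, 2), normal_force = numeric(0)))
  }
  mu_f <- params$friction_coefficient
  stol <- params$slip_tolerance
  kA <- params$penalty_normal * pairs$tributary_area   # N/mm per node

  s <- pairs$slave_nodes
  us <- matrix(u[node_dofs(s)], ncol = 3, byrow = TRUE)
  um <- matrix(0, n, 3)
  for (k in 1:3) {
    mk <- pairs$faces[, k]
    um <- um + pairs$weights[, k] * matrix(u[node_dofs(mk)], ncol = 3, byrow = TRUE)
  }
  du <- us - um                            # relative displacement
  dgap <- rowSums(du * pairs$normal)       # normal approach change from assembly
  gap <- pairs$g0 + dgap                   # physical gap (reported)
  pen <- current_fit - dgap                # interference measured from assembly
  active <- pen > 0
  Nf <- ifelse(active, kA * pen, 0)
  pressure <- Nf / pairs$tributary_area

  # friction bound and stick stiffness from the committed pressure: the
  # Coulomb limit lags one increment behind the (implicit) normal force,
  # which decouples friction from the normal solve and keeps the tangent
  # symmetric and exact for the resulting bilinear spring
  zeta <- cbind(rowSums(du * pairs$t1), rowSums(du * pairs$t2)) - state$anchor
  Ncommit <- pmax(state$pressure * pairs$tributary_area, 0)
  # stick stiffness capped at the normal penalty stiffness: at extreme
  # press-fit pressures the bilinear breakpoint grows beyond
  # slip_tolerance instead of ruining the tangent conditioning
  kT <- ifelse(active, pmin(mu_f * Ncommit / stol, kA), 0)
  ftt <- kT * zeta
  tmag <- sqrt(ftt[, 1]^2 + ftt[, 2]^2)
  flim <- mu_f * Ncommit
  slip <- active & tmag > flim & tmag > 0
  scalef <- ifelse(slip, flim / pmax(tmag, 1e-300), 1)
  ftt <- ftt * ifelse(active, scalef, 0)

  anchor_new <- state$anchor
  if (any(slip)) {
    ov <- which(slip)
    z <- zeta[ov, , drop = FALSE]
    zl <- sqrt(rowSums(z^2))
    keep <- ifelse(kT[ov] > 0, flim[ov] / kT[ov], 0) / pmax(zl, 1e-300)
    anchor_new[ov, ] <- state$anchor[ov, , drop = FALSE] + z * (1 - keep)
  }
  status <- ifelse(!active, "open", ifelse(slip, "slip", "stick"))

  # nodal forces: slave gets +n*N - t*ft; masters the opposite (weighted);
  # contributions are accumulated (nodes can appear in several pairs)
  fs <- pairs$normal * Nf - pairs$t1 * ftt[, 1] - pairs$t2 * ftt[, 2]
  idx <- c(node_dofs(s),
           unlist(lapply(1:3, function(k) node_dofs(pairs$faces[, k]))))
  val <- c(as.vector(t(fs)),
           unlist(lapply(1:3, function(k) as.vector(t(-fs * pairs$weights[, k])))))
  acc <- rowsum(val, idx)
  f[as.integer(rownames(acc))] <- acc[, 1]

  # tangent: kN on the normal relative dof; in the tangent plane the
  # stick stiffness kT, except for slip pairs which keep the consistent
  # direction-rotation stiffness mu*N/|zeta| perpendicular to the slip
  # direction and none along it. Open/slip directions keep a small floor
  # stiffness so the implant never loses all constraint mid-iteration
  # (Jacobian only - the forces above are the exact contact law).
  floorK <- 1e-6 * kA
  zl2 <- sqrt(rowSums(zeta^2))
  d3 <- pairs$t1 * (zeta[, 1] / pmax(zl2, 1e-300)) +
    pairs$t2 * (zeta[, 2] / pmax(zl2, 1e-300))
  d3[zl2 < 1e-300, ] <- pairs$t1[zl2 < 1e-300, , drop = FALSE]
  e3 <- cross3m(pairs$normal, d3)
  k_par <- pmax(ifelse(slip | !active, 0, kT), floorK)
  k_perp <- pmax(ifelse(!active, 0, ifelse(slip, flim / pmax(zl2, 1e-300), kT)),
                 floorK)
  kNeff <- pmax(ifelse(active, kA, 0), floorK)
  # triplets are built lazily: the Newton loop only needs them when it
  # refactors the tangent
  trip_fun <- function() contact_tangent_triplets(pairs, kNeff, k_par, k_perp,
                                                  d3 = d3, e3 = e3)

  list(f = f, trip_fun = trip_fun, gap = gap, pressure = pressure,
       traction = ftt, status = status, anchor = anchor_new,
       normal_force = Nf)
}

# Triplets of sum_p [kN (c x n)(c x n)^T + k_par (c x d)(c x d)^T +
# k_perp (c x e)(c x e)^T], c = (+1, -w1, -w2, -w3) over the pair's
# nodes; d/e span the tangent plane (slip direction and its orthogonal).
contact_tangent_triplets <- function(pairs, kN, k_par, k_perp = k_par,
                                     d3 = pairs$t1, e3 = pairs$t2) {
  n <- pairs$n_pairs
  nodes4 <- cbind(pairs$slave_nodes, pairs$faces)          # n x 4
  coef <- cbind(rep(1, n), -pairs$weights)                 # n x 4
  nrm <- pairs$normal
  nblk <- 144L * n
  ii <- integer(nblk); jj <- integer(nblk); xx <- numeric(nblk)
  pos <- 0L
  for (a in 1:4) for (b in 1:4) {
    cab <- coef[, a] * coef[, b]
    for (di in 1:3) for (dj in 1:3) {
      v <- cab * (kN * nrm[, di] * nrm[, dj] +
                  k_par * d3[, di] * d3[, dj] +
                  k_perp * e3[, di] * e3[, dj])
      idx <- pos + seq_len(n)
      ii[idx] <- 3L * (nodes4[, a] - 1L) + di
      jj[idx] <- 3L * (nodes4[, b] - 1L) + dj
      xx[idx] <- v
      pos <- pos + n
    }
  }
  keep <- xx != 0
  list(i = ii[keep], j = jj[keep], x = xx[keep])
}
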