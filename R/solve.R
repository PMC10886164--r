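# Quasi-static incremental solution: virtual implantation (linearly ramped
# interference fit) followed by multi-cycle activity loading.
#
# Newton iterations use the elastic stiffness plus the current contact
# stiffness (modified Newton for plasticity); the factorisation is reused
# across iterations and increments while the contact status is unchanged,
# and increments are bisected on divergence.

#' Build the combined implant-bone contact model
#'
#' Stacks the bone and implant meshes into one system, assigns materials
#' (calibrated elastic-plastic bone; elastic tray and insert), and pairs
#' the implant's distal nodes with the bone resection faces.
#'
#' @param bone_mesh bone `volume_mesh` (sets `interface_bone`,
#'   `distal_fixed`).
#' @param implant_mesh implant `volume_mesh` (sets `interface_implant`,
#'   `load_surface`).
#' @param tray_material `"PEEK"` or `"titanium"`.
#' @param params [contact_parameters()].
#' @param anchors,map material calibration, see [assign_materials()].
#' @param search_radius pairing radius, mm.
#' @param materials optional explicit per-element material table for the
#'   stacked system (bone elements first), bypassing the HU calibration
#'   (used by the verification benchmarks).
#' @return a `contact_model`.
#' @export
contact_model <- function(bone_mesh, implant_mesh,
                          tray_material = c("PEEK", "titanium"),
                          params = contact_parameters(),
                          anchors = calibration_anchors(),
                          map = bone_material_map(),
                          search_radius = 2,
                          materials = NULL) {
  tray_material <- match.arg(tray_material)
  if (is.null(materials)) {
    mat_bone <- assign_materials(bone_mesh, tray_material, anchors, map)
    mat_imp <- assign_materials(implant_mesh, tray_material, anchors, map)
  } else {
    nb_el <- nrow(bone_mesh$tets)
    mat_bone <- materials[seq_len(nb_el), , drop = FALSE]
    mat_imp <- materials[-seq_len(nb_el), , drop = FALSE]
  }

  nb <- nrow(bone_mesh$nodes)
  nodes <- rbind(bone_mesh$nodes, implant_mesh$nodes)
  tets <- rbind(bone_mesh$tets, implant_mesh$tets + nb)
  sets <- list(
    distal_fixed = bone_mesh$node_sets$distal_fixed,
    interface_bone = bone_mesh$node_sets$interface_bone,
    interface_implant = implant_mesh$node_sets$interface_implant + nb,
    load_surface = implant_mesh$node_sets$load_surface + nb
  )
  combined <- volume_mesh(nodes, tets, node_sets = sets)
  materials <- rbind(as.data.frame(mat_bone), as.data.frame(mat_imp))
  model <- fe_assemble(combined, materials)

  pairs <- build_contact_pairs(bone_mesh, implant_mesh, params, search_radius)
  pairs$slave_nodes <- pairs$slave_nodes + nb
  pairs$excluded_nodes <- pairs$excluded_nodes + nb

  structure(list(
    model = model, pairs = pairs, params = params,
    tray_material = tray_material,
    fixed_dofs = node_dofs(sets$distal_fixed),
    load_nodes = sets$load_surface,
    n_bone_nodes = nb,
    bone_mesh = bone_mesh, implant_mesh = implant_mesh
  ), class = "contact_model")
}

#' @export
print.contact_model <- function(x, ...) {
  cat(sprintf("Contact model (%s tray): %d dof, %d contact pairs, %d fixed dofs\n",
              x$tray_material, x$model$ndof, x$pairs$n_pairs, length(x$fixed_dofs)))
  invisible(x)
}

#' Solver control settings
#'
#' @param tol_rel relative force residual tolerance.
#' @param max_iter Newton iterations per increment before bisection.
#' @param max_bisect maximum bisection depth.
#' @param refactor_every refactor the tangent at least every this many
#'   Newton iterations.
#' @return a list of control values.
#' @export
solver_control <- function(tol_rel = 1e-8, max_iter = 25, max_bisect = 4,
                           refactor_every = 4) {
  list(tol_rel = tol_rel, max_iter = max_iter, max_bisect = max_bisect,
       refactor_every = refactor_every)
}

# Fresh solver state (committed quantities).
new_solver_state <- function(cm) {
  np <- cm$pairs$n_pairs
  list(
    u = numeric(cm$model$ndof),
    ep = matrix(0, cm$model$ne, 6),
    alpha = numeric(cm$model$ne),
    anchor = matrix(0, np, 2),
    pressure = numeric(np),
    status = rep("open", np),
    fit = 0,
    phase = "implantation",
    increment_index = 0L,
    cycle_index = 0L
  )
}

# One equilibrium solve at external force f_ext and interference fit.
# Mutates nothing; returns the converged state or signals non-convergence.
solve_equilibrium <- function(cm, state, f_ext, fit, ctrl, cache) {
  model <- cm$model
  free <- cache$free
  u <- state$u
  converged <- FALSE
  last_res <- Inf
  fi <- NULL; cu <- NULL     # reused from the accepted line-search trial
  for (it in seq_len(ctrl$max_iter)) {
    if (is.null(fi)) {
      fi <- fe_internal_force(model, u, state$ep, state$alpha)
      cu <- contact_update(cm$pairs, u, model$mesh$nodes,
                           state, cm$params, fit)
    }
    res <- f_ext + cu$f - fi$f
    rfree <- res[free]
    ref <- max(sqrt(sum(f_ext^2)), sqrt(sum(cu$f^2)), 1)
    rn <- sqrt(sum(rfree^2))
    if (rn <= ctrl$tol_rel * ref) {
      converged <- TRUE
      break
    }
    n_changed <- if (is.null(cache$last_status)) Inf else {
      sum(cu$status != cache$last_status)
    }
    status_changed <- n_changed > max(2, 0.03 * length(cu$status))
    plastic_active <- any(fi$rr$yielding)
    # refactor as soon as yielding appears under an elastic factor: the
    # committed state sits on the yield surface, so the first iterate of
    # an increment under-reports plasticity
    if (is.null(cache$chol) || status_changed || plastic_active ||
        it %% ctrl$refactor_every == 0 || (rn > 0.5 * last_res && it > 2)) {
      K <- if (plastic_active) {
        fe_tangent(model, u, state$ep, state$alpha)
      } else {
        model$K
      }
      trip <- cu$trip_fun()
      if (length(trip$i)) {
        Kc <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                                   dims = c(model$ndof, model$ndof))
        K <- K + Kc
      }
      Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
      cache$chol <- tryCatch(
        Matrix::Cholesky(Kff, LDL = FALSE, perm = TRUE, super = TRUE),
        error = function(e) NULL)
      if (is.null(cache$chol)) {
        if (!is.null(cache$stats)) cache$stats$fallbacks <- (cache$stats$fallbacks %||% 0) + 1
        # semidefinite elastoplastic tangent: fall back to the elastic one
        K <- model$K
        if (length(trip$i)) K <- K + Kc
        cache$chol <- Matrix::Cholesky(
          Matrix::forceSymmetric(K[free, free, drop = FALSE]),
          LDL = FALSE, perm = TRUE, super = TRUE)
      }
      cache$last_status <- cu$status
      cache$last_plastic <- plastic_active
      if (!is.null(cache$stats)) cache$stats$factors <- cache$stats$factors + 1
    }
    du <- as.numeric(Matrix::solve(cache$chol, rfree))
    # backtracking line search on the force residual (semismooth Newton
    # can overshoot across stick/slip/open boundaries); the accepted
    # trial's force evaluation is reused by the next iteration
    alpha <- 1
    for (ls in 1:6) {
      u_try <- u
      u_try[free] <- u[free] + alpha * du
      fi <- fe_internal_force(model, u_try, state$ep, state$alpha)
      cu <- contact_update(cm$pairs, u_try, model$mesh$nodes,
                           state, cm$params, fit)
      rt <- sqrt(sum((f_ext + cu$f - fi$f)[free]^2))
      if (rt <= rn * (1 - 1e-4 * alpha) || ls == 6) break
      alpha <- alpha / 2
    }
    u <- u_try
    last_res <- rn
  }
  if (!is.null(cache$stats)) {
    cache$stats$iters <- cache$stats$iters + it
  }
  if (!converged) return(list(converged = FALSE))
  # commit (fi and cu were evaluated at the accepted u)
  state$u <- u
  state$ep <- fi$rr$ep
  state$alpha <- fi$rr$alpha
  state$anchor <- cu$anchor
  state$pressure <- cu$pressure
  state$status <- cu$status
  state$fit <- fit
  state$gap <- cu$gap
  state$contact_force <- cu$f
  state$internal_force <- fi$f
  state$external_force <- f_ext
  list(converged = TRUE, state = state)
}

# Equilibrium with bisection between the committed state and the target.
solve_step <- function(cm, state, f_target, fit_target, ctrl, cache, depth = 0) {
  out <- solve_equilibrium(cm, state, f_target, fit_target, ctrl, cache)
  if (out$converged) return(out$state)
  if (depth >= ctrl$max_bisect) {
    stop(sprintf("solver divergence: increment failed after %d bisections (fit %.4f mm)",
                 depth, fit_target), call. = FALSE)
  }
  f_half <- (state$external_force %||% numeric(cm$model$ndof) + f_target) / 2
  fit_half <- (state$fit + fit_target) / 2
  mid <- solve_step(cm, state, f_half, fit_half, ctrl, cache, depth + 1)
  solve_step(cm, mid, f_target, fit_target, ctrl, cache, depth + 1)
}

#' Virtual implantation phase
#'
#' Ramps the interference fit linearly from zero to its full value over
#' `params$ramp_increments` equilibrium increments; bone near the
#' interface may yield plastically.
#'
#' @param cm a [contact_model()].
#' @param ctrl [solver_control()].
#' @return a `solver_state` (committed displacements, plastic state,
#'   contact anchors/status, realised fit).
#' @export
virtual_implantation <- function(cm, ctrl = solver_control()) {
  state <- new_solver_state(cm)
  cache <- new.env(parent = emptyenv())
  cache$free <- setdiff(seq_len(cm$model$ndof), cm$fixed_dofs)
  cache$chol <- NULL; cache$last_status <- NULL
  fit_full <- cm$params$interference_fit / 1000   # um -> mm
  nramp <- cm$params$ramp_increments
  f0 <- numeric(cm$model$ndof)
  state$external_force <- f0
  for (k in seq_len(nramp)) {
    state <- solve_step(cm, state, f0, fit_full * k / nramp, ctrl, cache)
    state$increment_index <- k
  }
  state$phase <- "loading"
  attr(state, "cache") <- cache
  class(state) <- "solver_state"
  state
}

#' @export
print.solver_state <- function(x, ...) {
  cat(sprintf("Solver state: phase %s, fit %.3f mm, max |u| %.4f mm\n",
              x$phase, x$fit, max(abs(x$u))))
  if (length(x$status)) {
    cat(sprintf("  contact: %d stick, %d slip, %d open; peak pressure %.2f MPa\n",
                sum(x$status == "stick"), sum(x$status == "slip"),
                sum(x$status == "open"), max(x$pressure)))
  }
  invisible(x)
}

# External force vector for one profile increment: medial and lateral
# forces distributed over insert-top nodes near their centres of pressure
# by inverse-distance weights, applied along -z (compression).
increment_force <- function(cm, profile, inc, load_radius = 12) {
  f <- numeric(cm$model$ndof)
  xy <- cm$model$mesh$nodes[cm$load_nodes, 1:2, drop = FALSE]
  for (sidecop in list(list(F = profile$medial_force[inc], cop = profile$cop_medial[inc, ]),
                       list(F = profile$lateral_force[inc], cop = profile$cop_lateral[inc, ]))) {
    if (sidecop$F <= 0) next
    d <- sqrt((xy[, 1] - sidecop$cop[1])^2 + (xy[, 2] - sidecop$cop[2])^2)
    sel <- which(d <= load_radius)
    if (length(sel) < 3) sel <- order(d)[1:3]
    w <- 1 / (d[sel] + 3)
    w <- w / sum(w)
    f[node_dofs(cm$load_nodes[sel], 3)] <-
      f[node_dofs(cm$load_nodes[sel], 3)] - sidecop$F * w
  }
  f
}

#' Run an activity (multi-cycle loading) and record interface kinematics
#'
#' Executes `n_cycles x n_increments` equilibrium solves with the
#' interference fit held at its maximum and records, per increment, the
#' positions of the paired implant contact nodes, the bone resection-face
#' nodes, and the normal gaps.
#'
#' @param cm a [contact_model()].
#' @param state the `solver_state` returned by [virtual_implantation()].
#' @param profile a [build_load_profile()].
#' @param ctrl [solver_control()].
#' @param load_radius CoP force-distribution radius, mm.
#' @return an `interface_history`.
#' @export
run_activity <- function(cm, state, profile, ctrl = solver_control(),
                         load_radius = 12) {
  if (state$phase != "loading") stop("implantation must be completed first", call. = FALSE)
  cache <- attr(state, "cache")
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    cache$free <- setdiff(seq_len(cm$model$ndof), cm$fixed_dofs)
    cache$chol <- NULL; cache$last_status <- NULL
  }
  # offset CoPs by the tray placement (nodes already carry the placement)
  n_inc <- profile$n_increments
  n_cyc <- profile$n_cycles
  total <- n_inc * n_cyc
  ns <- cm$pairs$n_pairs
  bset <- cm$pairs$bone_interface_nodes
  nbn <- length(bset)
  node_pos <- array(NA_real_, c(ns, 3, total))
  foot_pos <- array(NA_real_, c(ns, 3, total))
  bone_pos <- array(NA_real_, c(nbn, 3, total))
  gap <- matrix(NA_real_, ns, total)
  cyc <- integer(total)
  nodes <- cm$model$mesh$nodes
  s <- cm$pairs$slave_nodes
  bidx <- match(as.vector(cm$pairs$faces), bset)
  faces_local <- matrix(bidx, ncol = 3)
  fit <- state$fit

  t_idx <- 0L
  for (c_i in seq_len(n_cyc)) {
    for (inc in seq_len(n_inc)) {
      t_idx <- t_idx + 1L
      f_ext <- increment_force(cm, profile, inc, load_radius)
      state <- solve_step(cm, state, f_ext, fit, ctrl, cache)
      state$increment_index <- inc
      state$cycle_index <- c_i
      us <- matrix(state$u[node_dofs(s)], ncol = 3, byrow = TRUE)
      node_pos[, , t_idx] <- nodes[s, , drop = FALSE] + us
      ub <- matrix(state$u[node_dofs(bset)], ncol = 3, byrow = TRUE)
      bone_pos[, , t_idx] <- nodes[bset, , drop = FALSE] + ub
      xm <- matrix(0, ns, 3)
      for (k in 1:3) {
        xm <- xm + cm$pairs$weights[, k] * bone_pos[faces_local[, k], , t_idx]
      }
      foot_pos[, , t_idx] <- xm
      gap[, t_idx] <- state$gap
      cyc[t_idx] <- c_i
    }
  }
  attr(state, "cache") <- NULL

  structure(list(
    node_pos = node_pos, foot_pos = foot_pos, bone_pos = bone_pos,
    faces = faces_local, gap = gap, cycle = cyc,
    n_increments = n_inc, n_cycles = n_cyc,
    slave_nodes = s, bone_nodes = bset,
    tributary_area = cm$pairs$tributary_area,
    excluded_nodes = cm$pairs$excluded_nodes,
    final_state = state
  ), class = "interface_history")
}

#' @export
print.interface_history <- function(x, ...) {
  cat(sprintf("Interface history: %d contact nodes x %d increments (%d cycles)\n",
              dim(x$node_pos)[1], dim(x$node_pos)[3], x$n_cycles))
  invisible(x)
}

#' Reaction balance at the distal fixation
#'
#' @param cm a `contact_model`.
#' @param state a converged `solver_state`.
#' @return list with `reaction` (summed fixed-DOF reaction, N),
#'   `applied` (summed external force), `residual_rel`.
#' @export
reaction_balance <- function(cm, state) {
  r <- (state$internal_force - state$contact_force - state$external_force)
  reac <- matrix(r[cm$fixed_dofs], ncol = 3, byrow = TRUE)
  app <- matrix(state$external_force, ncol = 3, byrow = TRUE)
  tot_r <- colSums(reac)
  tot_a <- colSums(app)
  list(reaction = tot_r, applied = tot_a,
       residual_rel = vnorm(tot_r + tot_a) / max(vnorm(tot_a), 1))
}
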