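# Verification benchmarks for the mechanics core: patch test, cantilever
# beam against Euler-Bernoulli theory, Coulomb stick/slip threshold, and
# press-fit interface pressure against the Lame thick-walled-cylinder
# closed form. These run on small structured meshes and are used both by
# the test suite and the acceptance script.

#' FE patch test
#'
#' A block whose boundary nodes are prescribed an affine displacement
#' field must reproduce the corresponding constant strain state exactly
#' (linear tetrahedra contain affine fields).
#'
#' @param E,nu elastic constants (GPa, -).
#' @return list with `max_rel_error` (max relative strain deviation from
#'   the exact constant state).
#' @export
benchmark_patch_test <- function(E = 10, nu = 0.3) {
  bm <- mesh_box(2, 1, 1, 4, 2, 2)
  model <- fe_assemble(bm, material_card("elastic", E, nu))
  A <- matrix(c(1e-3, 2e-4, -1e-4, 3e-4, 5e-4, 1e-4, -2e-4, 4e-4, 2e-4), 3, 3)
  bnodes <- sort(unique(unlist(bm$node_sets)))
  fixed <- node_dofs(bnodes)
  uvals <- as.vector(t(bm$nodes[bnodes, , drop = FALSE] %*% t(A)))
  sol <- fe_solve_elastic(model, fixed, uvals)
  eps_exact <- c(A[1, 1], A[2, 2], A[3, 3],
                 A[1, 2] + A[2, 1], A[2, 3] + A[3, 2], A[1, 3] + A[3, 1])
  err <- max(abs(sweep(sol$strain, 2, eps_exact))) / max(abs(eps_exact))
  list(max_rel_error = err)
}

#' Cantilever tip-deflection benchmark
#'
#' Slender elastic beam, fixed at one end, transverse tip load; the FE
#' tip deflection is compared with the Euler-Bernoulli closed form
#' P L^3 / (3 E I).
#'
#' @param L,h beam length and square cross-section side, mm.
#' @param nx,n axial and through-thickness element divisions.
#' @param E,nu elastic constants (GPa, -).
#' @param P tip load, N.
#' @return list with `fe_deflection`, `theory`, `ratio`.
#' @export
benchmark_cantilever <- function(L = 16, h = 2, nx = 56, n = 14,
                                 E = 10, nu = 0.3, P = 1) {
  bm <- mesh_box(L, h, h, nx, n, n)
  model <- fe_assemble(bm, material_card("elastic", E, nu))
  tip <- bm$node_sets$x1
  f <- numeric(model$ndof)
  f[node_dofs(tip, 3)] <- P / length(tip)
  sol <- fe_solve_elastic(model, node_dofs(bm$node_sets$x0), 0, f)
  w <- mean(sol$u[node_dofs(tip, 3)])
  I <- h^4 / 12
  th <- P * L^3 / (3 * (E * 1000) * I)
  list(fe_deflection = w, theory = th, ratio = w / th)
}

# Two stacked elastic blocks joined by the contact machinery; used by the
# Coulomb threshold benchmark. Returns a contact_model plus handy sets.
coulomb_fixture <- function(mu = 0.5, penalty = 5000, slip_tol = 0.01) {
  lower <- mesh_box(20, 20, 10, 4, 4, 2)
  upper <- mesh_box(20, 20, 6, 4, 4, 2, origin = c(0, 0, 10))
  lower$node_sets <- list(distal_fixed = lower$node_sets$z0,
                          interface_bone = lower$node_sets$z1)
  upper$node_sets <- list(interface_implant = upper$node_sets$z0,
                          load_surface = upper$node_sets$z1)
  lower$element_material <- rep("bone", nrow(lower$tets))
  lower$element_hu <- rep(1200, nrow(lower$tets))
  upper$element_material <- rep("tray", nrow(upper$tets))
  params <- contact_parameters(friction_coefficient = mu, interference_fit = 0,
                               penalty_normal = penalty,
                               slip_tolerance = slip_tol)
  ne_l <- nrow(lower$tets); ne_u <- nrow(upper$tets)
  mats <- data.frame(
    E = c(rep(10, ne_l), rep(109, ne_u)),
    nu = rep(0.3, ne_l + ne_u),
    yield = NA_real_, hardening = 0,
    material = c(rep("bone", ne_l), rep("tray", ne_u)),
    stringsAsFactors = FALSE)
  contact_model(lower, upper, "titanium", params, materials = mats)
}

#' Coulomb stick/slip threshold benchmark
#'
#' An elastic block pressed onto another with total normal force `N` is
#' (a) loaded tangentially below the Coulomb limit - it must stick with
#' the tangential reaction equal to the applied force and no accumulated
#' slip - and (b) dragged far beyond the slip tolerance - the total
#' tangential contact traction must equal mu * N.
#'
#' @param N total normal force, N.
#' @param mu friction coefficient.
#' @param stick_fraction tangential load as a fraction of mu * N for the
#'   stick case.
#' @param drag prescribed tangential displacement for the sliding case,
#'   mm (far beyond the slip tolerance).
#' @return list with `stick` (status table, tangential reaction, max
#'   anchor slip) and `slide` (tangential traction sum, `ratio` to
#'   mu * N).
#' @export
benchmark_coulomb <- function(N = 1000, mu = 0.5, stick_fraction = 0.49,
                              drag = 0.2) {
  cm <- coulomb_fixture(mu = mu)
  ctrl <- solver_control()
  top <- cm$load_nodes
  press <- function() {
    st <- new_solver_state(cm)
    cache <- new.env(parent = emptyenv())
    cache$free <- setdiff(seq_len(cm$model$ndof), cm$fixed_dofs)
    cache$chol <- NULL; cache$last_status <- NULL
    f <- numeric(cm$model$ndof)
    f[node_dofs(top, 3)] <- -N / length(top)
    st$external_force <- numeric(cm$model$ndof)
    for (k in 1:2) st <- solve_step(cm, st, f, 0, ctrl, cache)  # commit pressure
    list(st = st, cache = cache, f = f)
  }

  # (a) stick below the Coulomb limit
  pr <- press()
  f_t <- pr$f
  f_t[node_dofs(top, 1)] <- stick_fraction * mu * N / length(top)
  st_a <- solve_step(cm, pr$st, f_t, 0, ctrl, pr$cache)
  tang_reaction <- sum(st_a$contact_force[node_dofs(cm$pairs$slave_nodes, 1)])
  stick <- list(
    status = table(st_a$status),
    tangential_reaction = -tang_reaction,
    applied = stick_fraction * mu * N,
    max_anchor_slip = max(abs(st_a$anchor))
  )

  # (b) steady sliding under prescribed drag
  pr <- press()
  fixed2 <- c(cm$fixed_dofs, node_dofs(top, 1))
  cache2 <- pr$cache
  cache2$free <- setdiff(seq_len(cm$model$ndof), fixed2)
  cache2$chol <- NULL
  st_b <- pr$st
  nsteps <- 4
  for (k in seq_len(nsteps)) {
    st_b$u[node_dofs(top, 1)] <- drag * k / nsteps
    out <- solve_equilibrium(cm, st_b, pr$f, 0, ctrl, cache2)
    if (!out$converged) stop("coulomb benchmark: drag step failed", call. = FALSE)
    st_b <- out$state
  }
  s <- cm$pairs$slave_nodes
  tang <- -sum(st_b$contact_force[node_dofs(s, 1)])
  slide <- list(
    tangential_traction = tang,
    limit = mu * sum(st_b$pressure * cm$pairs$tributary_area),
    ratio = tang / (mu * N),
    status = table(st_b$status)
  )
  list(stick = stick, slide = slide)
}

#' Closed-form press-fit interface pressure (Lame thick-walled cylinders)
#'
#' Radial interference `delta` between an elastic shaft (radius `a`,
#' modulus `Ei`, Poisson `nui`) and an elastic tube (inner `a`, outer
#' `b`, `Eo`, `nuo`); plane strain.
#'
#' @param delta radial interference, mm.
#' @param a,b radii, mm.
#' @param Ei,Eo moduli, MPa.
#' @param nui,nuo Poisson ratios.
#' @return interface pressure, MPa.
#' @export
lame_interference_pressure <- function(delta, a, b, Ei, Eo, nui, nuo) {
  # plane-strain transformation of the plane-stress press-fit formula
  Eo_ <- Eo / (1 - nuo^2); nuo_ <- nuo / (1 - nuo)
  Ei_ <- Ei / (1 - nui^2); nui_ <- nui / (1 - nui)
  delta / (a * ((b^2 + a^2) / (Eo_ * (b^2 - a^2)) + nuo_ / Eo_ +
                  (1 - nui_) / Ei_))
}

#' Interference-fit pressure benchmark (peg in an elastic bore)
#'
#' A cylindrical elastic peg is press-fitted into an elastic tube via the
#' contact-algorithm offset (the virtual-implantation path); the mean FE
#' contact pressure is compared with the Lame closed form. Both bodies
#' are kept elastic (the interference is chosen small enough that the
#' bone-range modulus stays below yield in the real model).
#'
#' @param delta interference, mm (radial).
#' @param a peg / bore radius, mm.
#' @param b tube outer radius, mm.
#' @param E_bone,E_peg moduli, GPa.
#' @param ntheta,nr,nz tube discretisation.
#' @param penalty contact penalty, N/mm^3 (stiff here so the penalty
#'   compliance stays below ~5% of the interference).
#' @return list with `fe_pressure`, `lame_pressure`, `rel_error`.
#' @export
benchmark_interference <- function(delta = 0.02, a = 7, b = 30,
                                   E_bone = 10, E_peg = 109,
                                   ntheta = 36, nr = 7, nz = 2,
                                   penalty = 20000) {
  h <- 6
  tube <- mesh_tube(a, b, h, nr = nr, ntheta = ntheta, nz = nz)
  peg <- mesh_cylinder(a, h, nr = 3, ntheta = ntheta, nz = nz)
  tube$node_sets <- list(bore_wall = tube$node_sets$inner,
                         tube_z = c(tube$node_sets$z0, tube$node_sets$z1),
                         outer = tube$node_sets$outer)
  peg$node_sets <- list(peg_wall = peg$node_sets$side,
                        peg_z = c(peg$node_sets$z0, peg$node_sets$z1))
  tube$element_material <- rep("bone", nrow(tube$tets))
  tube$element_hu <- rep(1200, nrow(tube$tets))
  peg$element_material <- rep("tray", nrow(peg$tets))
  ne_t <- nrow(tube$tets); ne_p <- nrow(peg$tets)
  mats <- data.frame(
    E = c(rep(E_bone, ne_t), rep(E_peg, ne_p)),
    nu = rep(0.3, ne_t + ne_p),
    yield = NA_real_, hardening = 0,
    material = c(rep("bone", ne_t), rep("tray", ne_p)),
    stringsAsFactors = FALSE)
  params <- contact_parameters(friction_coefficient = 0,
                               interference_fit = delta * 1000,
                               ramp_increments = 5,
                               penalty_normal = penalty)
  cm <- contact_model(tube, peg, "titanium", params, materials = mats)
  # plane strain: axial displacement fixed on all end faces; pin two
  # outer nodes in-plane against rigid drift
  nb <- nrow(tube$nodes)
  zfix <- c(node_dofs(tube$node_sets$tube_z, 3),
            node_dofs(peg$node_sets$peg_z + nb, 3))
  pin <- tube$node_sets$outer[1:2]
  cm$fixed_dofs <- sort(unique(c(zfix, node_dofs(pin, 1:2))))
  st <- virtual_implantation(cm, solver_control())
  closed <- st$status != "open"
  p_fe <- mean(st$pressure[closed])
  p_th <- lame_interference_pressure(delta, a, b,
                                     E_peg * 1000, E_bone * 1000, 0.3, 0.3)
  # realized interference: relative normal approach at the interface,
  # i.e. the configured fit minus the penalty compliance p / kN
  realized <- mean(st$gap[closed] - cm$pairs$g0[closed])
  list(fe_pressure = p_fe, lame_pressure = p_th,
       rel_error = abs(p_fe - p_th) / p_th,
       fit_mm = delta, realized_offset_mm = realized,
       penalty_compliance_mm = p_fe / penalty)
}
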