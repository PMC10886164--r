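# Finite-element core: linear tetrahedra, isotropic elasticity, Von Mises
# plasticity with radial return.
#
# Units: mm, N, MPa (moduli supplied in GPa are converted on assembly).
# Voigt order [xx, yy, zz, xy, yz, zx] with engineering shear strains.
# The global strain-displacement operator is kept as one sparse matrix so
# strain evaluation, the internal force and the elastic stiffness are
# single sparse products - the whole solver is vectorised over elements.

#' Assemble an FE model from a volume mesh and a material table
#'
#' Returns the elastic tangent operator and an internal-force evaluator
#' consistent with it (plasticity enters through the radial-return stress
#' update inside the evaluator).
#'
#' @param mesh a `volume_mesh`.
#' @param materials a `material_table` from [assign_materials()], or a
#'   single [material_card()] applied to all elements.
#' @return an `fe_model`: sparse strain operator `B` (6e x 3n), element
#'   volumes, Lame parameters, yield data, elastic stiffness `K`, and
#'   `ndof`.
#' @export
fe_assemble <- function(mesh, materials) {
  if (inherits(materials, "material_card")) {
    ne <- nrow(mesh$tets)
    materials <- data.frame(
      E = rep(materials$youngs_modulus, ne),
      nu = rep(materials$poisson_ratio, ne),
      yield = rep(materials$yield_stress %||% NA_real_, ne),
      hardening = rep(materials$hardening_modulus, ne),
      material = rep(materials$name, ne), stringsAsFactors = FALSE)
  }
  nodes <- mesh$nodes; tets <- mesh$tets
  ne <- nrow(tets); nn <- nrow(nodes)
  vol <- tet_volumes(nodes, tets)
  stopifnot(all(vol > 0), nrow(materials) == ne)

  p1 <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - p1
  e2 <- nodes[tets[, 3], , drop = FALSE] - p1
  e3 <- nodes[tets[, 4], , drop = FALSE] - p1
  # inverse Jacobian rows via adjugate; grads of N2..N4 are rows of inv(J)
  detJ <- 6 * vol
  ix <- function(a, b) a[, 2] * b[, 3] - a[, 3] * b[, 2]
  iy <- function(a, b) a[, 3] * b[, 1] - a[, 1] * b[, 3]
  iz <- function(a, b) a[, 1] * b[, 2] - a[, 2] * b[, 1]
  g2 <- cbind(ix(e2, e3), iy(e2, e3), iz(e2, e3)) / detJ
  g3 <- cbind(ix(e3, e1), iy(e3, e1), iz(e3, e1)) / detJ
  g4 <- cbind(ix(e1, e2), iy(e1, e2), iz(e1, e2)) / detJ
  g1 <- -(g2 + g3 + g4)
  grads <- list(g1, g2, g3, g4)   # each ne x 3

  # sparse strain-displacement operator: rows (e-1)*6 + (1..6)
  reps <- 9L * 4L * ne
  ii <- integer(reps); jj <- integer(reps); xx <- numeric(reps)
  pos <- 0L
  row0 <- (seq_len(ne) - 1L) * 6L
  for (a in 1:4) {
    nd <- tets[, a]
    cx <- 3L * (nd - 1L) + 1L; cy <- cx + 1L; cz <- cx + 2L
    gx <- grads[[a]][, 1]; gy <- grads[[a]][, 2]; gz <- grads[[a]][, 3]
    put <- function(r, cc, v) {
      idx <- pos + seq_len(ne)
      ii[idx] <<- row0 + r; jj[idx] <<- cc; xx[idx] <<- v
      pos <<- pos + ne
    }
    put(1L, cx, gx); put(2L, cy, gy); put(3L, cz, gz)
    put(4L, cx, gy); put(4L, cy, gx)
    put(5L, cy, gz); put(5L, cz, gy)
    put(6L, cx, gz); put(6L, cz, gx)
  }
  B <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(6L * ne, 3L * nn))

  E <- materials$E * 1000            # GPa -> MPa
  nu <- materials$nu
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))

  # elastic constitutive block-diagonal (volume-scaled)
  nD <- 12L * ne
  di <- integer(nD); dj <- integer(nD); dx <- numeric(nD)
  p <- 0L
  for (r in 1:3) for (cc in 1:3) {
    idx <- p + seq_len(ne)
    di[idx] <- row0 + r; dj[idx] <- row0 + cc
    dx[idx] <- vol * (lam + (r == cc) * 2 * mu)
    p <- p + ne
  }
  for (r in 4:6) {
    idx <- p + seq_len(ne)
    di[idx] <- row0 + r; dj[idx] <- row0 + r
    dx[idx] <- vol * mu
    p <- p + ne
  }
  Dv <- Matrix::sparseMatrix(i = di, j = dj, x = dx, dims = c(6L * ne, 6L * ne))
  K <- Matrix::forceSymmetric(Matrix::t(B) %*% (Dv %*% B))

  structure(list(
    mesh = mesh, B = B, Bt = Matrix::t(B), K = K, vol = vol,
    lam = lam, mu = mu, E = E, nu = nu,
    yield = materials$yield, hardening = materials$hardening,
    material = materials$material,
    ne = ne, nn = nn, ndof = 3L * nn
  ), class = "fe_model")
}

#' @export
print.fe_model <- function(x, ...) {
  cat(sprintf("FE model: %d nodes (%d dof), %d tets, %d plastic elements\n",
              x$nn, x$ndof, x$ne, sum(!is.na(x$yield))))
  invisible(x)
}

# Element strains (ne x 6) for a displacement vector.
fe_strains <- function(model, u) {
  matrix(as.numeric(model$B %*% u), ncol = 6, byrow = TRUE)
}

# Vectorised Von Mises radial return over all elements.
# eps: total strain (ne x 6); ep: committed plastic strain; alpha:
# committed equivalent plastic strain. Elements with NA yield stay elastic.
fe_radial_return <- function(model, eps, ep, alpha) {
  lam <- model$lam; mu <- model$mu
  ee <- eps - ep
  tr <- ee[, 1] + ee[, 2] + ee[, 3]
  sig <- cbind(lam * tr + 2 * mu * ee[, 1],
               lam * tr + 2 * mu * ee[, 2],
               lam * tr + 2 * mu * ee[, 3],
               mu * ee[, 4], mu * ee[, 5], mu * ee[, 6])
  pm <- (sig[, 1] + sig[, 2] + sig[, 3]) / 3
  s <- sig; s[, 1:3] <- sig[, 1:3] - pm
  q <- sqrt(pmax(0, 1.5 * (s[, 1]^2 + s[, 2]^2 + s[, 3]^2) +
                    3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2)))
  sy <- model$yield + model$hardening * alpha
  yielding <- !is.na(model$yield) & q > sy & q > 0
  if (any(yielding)) {
    dg <- (q[yielding] - sy[yielding]) /
      (3 * mu[yielding] + model$hardening[yielding])
    fac <- 1 - 3 * mu[yielding] * dg / q[yielding]
    n_norm <- 1.5 * s[yielding, 1:3, drop = FALSE] / q[yielding]
    n_shr <- 3 * s[yielding, 4:6, drop = FALSE] / q[yielding]
    ep[yielding, 1:3] <- ep[yielding, 1:3, drop = FALSE] + dg * n_norm
    ep[yielding, 4:6] <- ep[yielding, 4:6, drop = FALSE] + dg * n_shr
    alpha[yielding] <- alpha[yielding] + dg
    s[yielding, ] <- s[yielding, , drop = FALSE] * fac
    sig[yielding, 1:3] <- s[yielding, 1:3, drop = FALSE] + pm[yielding]
    sig[yielding, 4:6] <- s[yielding, 4:6, drop = FALSE]
  }
  list(stress = sig, ep = ep, alpha = alpha, yielding = yielding)
}

#' Von Mises radial-return stress update for one integration point
#'
#' Elastic-predictor / plastic-corrector update enforcing the Von Mises
#' criterion with isotropic hardening (perfectly plastic when the
#' hardening modulus is zero).
#'
#' @param strain total strain, Voigt 6-vector (engineering shears).
#' @param card a [material_card()] with a `yield_stress`.
#' @param state optional list with `ep` (plastic strain 6-vector) and
#'   `alpha` (equivalent plastic strain); defaults to a virgin state.
#' @return list with `stress` (MPa), `ep`, `alpha`, `vm` (Von Mises
#'   stress), `yielded` (logical).
#' @export
radial_return <- function(strain, card, state = NULL) {
  if (is.null(card$yield_stress)) stop("card has no yield_stress", call. = FALSE)
  model <- list(
    lam = card$youngs_modulus * 1000 * card$poisson_ratio /
      ((1 + card$poisson_ratio) * (1 - 2 * card$poisson_ratio)),
    mu = card$youngs_modulus * 1000 / (2 * (1 + card$poisson_ratio)),
    yield = card$yield_stress,
    hardening = card$hardening_modulus
  )
  ep <- matrix(state$ep %||% rep(0, 6), 1)
  alpha <- state$alpha %||% 0
  r <- fe_radial_return(model, matrix(strain, 1), ep, alpha)
  sig <- r$stress[1, ]
  pm <- mean(sig[1:3])
  s <- sig; s[1:3] <- s[1:3] - pm
  vm <- sqrt(1.5 * sum(s[1:3]^2) + 3 * sum(s[4:6]^2))
  list(stress = sig, ep = r$ep[1, ], alpha = r$alpha, vm = vm,
       yielded = r$yielding[1])
}

# Consistent tangent stiffness at displacement u (elastoplastic where the
# trial state yields; equals the elastic stiffness K elsewhere).
# D_ep = kappa 1x1 + 2G theta I_dev + 3G [H/(3G+H) - theta] m x m,
# theta = q_new/q_trial, m = s_trial/q_trial (Voigt, engineering shears).
fe_tangent <- function(model, u, ep, alpha) {
  eps <- fe_strains(model, u)
  rrk <- fe_radial_return(model, eps, ep, alpha)
  yl <- which(rrk$yielding)
  if (!length(yl)) return(model$K)

  lam <- model$lam[yl]; mu <- model$mu[yl]; H <- model$hardening[yl]
  vol <- model$vol[yl]
  # recompute the trial deviator for the yielding elements
  ee <- eps[yl, , drop = FALSE] - ep[yl, , drop = FALSE]
  tr <- ee[, 1] + ee[, 2] + ee[, 3]
  sig <- cbind(lam * tr + 2 * mu * ee[, 1],
               lam * tr + 2 * mu * ee[, 2],
               lam * tr + 2 * mu * ee[, 3],
               mu * ee[, 4], mu * ee[, 5], mu * ee[, 6])
  pm <- (sig[, 1] + sig[, 2] + sig[, 3]) / 3
  s <- sig; s[, 1:3] <- sig[, 1:3] - pm
  q <- sqrt(1.5 * (s[, 1]^2 + s[, 2]^2 + s[, 3]^2) +
              3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))
  sy0 <- model$yield[yl] + H * alpha[yl]
  dg <- (q - sy0) / (3 * mu + H)
  theta <- 1 - 3 * mu * dg / q
  # tangent-only numerical hardening: keeps the operator positive
  # definite under perfect plasticity (the stress update is unaffected)
  H_tan <- pmax(H, 1e-3 * model$E[yl])
  cmm <- 3 * mu * (H_tan / (3 * mu + H_tan) - theta)
  m <- s / q

  # correction over the yielding elements only:
  # D_ep - D_el = 2G (theta - 1) I_dev + cmm m x m
  one <- c(1, 1, 1, 0, 0, 0)
  Jd <- c(1, 1, 1, 0.5, 0.5, 0.5)
  nyl <- length(yl)
  rows <- rep((yl - 1L) * 6L, each = 6L) + rep(1:6, nyl)
  Bsub <- Matrix::t(model$Bt[, rows, drop = FALSE])
  di <- integer(36L * nyl); dj <- integer(36L * nyl); dx <- numeric(36L * nyl)
  pos <- 0L
  row0 <- (seq_len(nyl) - 1L) * 6L
  for (r in 1:6) for (cc in 1:6) {
    v <- 2 * mu * (theta - 1) * ((r == cc) * Jd[r] - one[r] * one[cc] / 3) +
      cmm * m[, r] * m[, cc]
    idx <- pos + seq_len(nyl)
    di[idx] <- row0 + r; dj[idx] <- row0 + cc
    dx[idx] <- vol * v
    pos <- pos + nyl
  }
  Dd <- Matrix::sparseMatrix(i = di, j = dj, x = dx,
                             dims = c(6L * nyl, 6L * nyl))
  Matrix::forceSymmetric(model$K + Matrix::t(Bsub) %*% (Dd %*% Bsub))
}

# Internal force for displacement u and committed plastic state.
fe_internal_force <- function(model, u, ep, alpha) {
  eps <- fe_strains(model, u)
  rr <- fe_radial_return(model, eps, ep, alpha)
  sv <- as.numeric(t(rr$stress * model$vol))
  f <- as.numeric(model$Bt %*% sv)
  list(f = f, rr = rr)
}

#' Solve a linear elastic static problem
#'
#' Supports prescribed (possibly non-zero) displacements and nodal loads.
#'
#' @param model an `fe_model` (elastic path: plastic state held at zero).
#' @param fixed integer DOF indices with prescribed values.
#' @param fixed_values prescribed displacements (recycled), mm.
#' @param f_ext external nodal force vector (length `ndof`), N.
#' @return list with `u` (displacements), `reactions` at the fixed DOFs,
#'   `strain` and `stress` per element.
#' @export
fe_solve_elastic <- function(model, fixed, fixed_values = 0, f_ext = NULL) {
  nd <- model$ndof
  if (is.null(f_ext)) f_ext <- numeric(nd)
  if (length(fixed) == 0) stop("no constraints: rigid-body modes (6 in 3-D)",
                               call. = FALSE)
  u <- numeric(nd)
  u[fixed] <- rep_len(fixed_values, length(fixed))
  free <- setdiff(seq_len(nd), fixed)
  K <- model$K
  rhs <- f_ext[free] - as.numeric(K[free, fixed, drop = FALSE] %*% u[fixed])
  Kff <- K[free, free, drop = FALSE]
  ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE),
                 error = function(e) {
    stop("singular system with insufficient constraints (rigid-body modes remain)",
         call. = FALSE)
  })
  u[free] <- as.numeric(Matrix::solve(ch, rhs))
  eps <- fe_strains(model, u)
  tr <- eps[, 1] + eps[, 2] + eps[, 3]
  sig <- cbind(model$lam * tr + 2 * model$mu * eps[, 1],
               model$lam * tr + 2 * model$mu * eps[, 2],
               model$lam * tr + 2 * model$mu * eps[, 3],
               model$mu * eps[, 4], model$mu * eps[, 5], model$mu * eps[, 6])
  reac <- as.numeric(K %*% u - f_ext)[fixed]
  list(u = u, reactions = reac, strain = eps, stress = sig)
}

# DOF indices (x, y, z or all) for node ids.
node_dofs <- function(nodes, comp = 1:3) {
  as.vector(t(outer(3L * (nodes - 1L), comp, `+`)))
}
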